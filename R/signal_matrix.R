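#' Signal matrix over genomic regions
#'
#' The central container: an `n x m` numeric matrix of signal (raw counts or
#' log2-normalized values) over `n` genomic regions (rows) and `m` samples
#' (columns), together with region coordinates and sample metadata. Regions
#' use BED conventions: 0-based, half-open `[start, end)`, unstranded.
#'
#' @param values numeric matrix, one row per region, one column per sample.
#' @param regions data frame with columns `chrom`, `start`, `end`, `id`
#'   (canonical id `"chrom:start-end"`). If `NULL`, parsed from
#'   `rownames(values)`.
#' @param samples data frame with columns `sample_id`, `time_point`,
#'   `replicate` and optionally `batch`. `time_point` must be coercible to a
#'   numeric rank. If `NULL`, a minimal frame is derived from
#'   `colnames(values)` (one time point per column, one replicate each).
#'
#' @return An object of class `"signal_matrix"` with elements `values`,
#'   `regions`, `samples`.
#' @export
signal_matrix <- function(values, regions = NULL, samples = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("signal matrix needs at least one region")
  if (is.null(regions)) {
    if (is.null(rownames(values)))
      stop("regions not given and values has no rownames to parse")
    regions <- parse_region_ids(rownames(values))
  }
  regions <- as.data.frame(regions, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(regions)))
    stop("regions must have columns chrom, start, end")
  if (is.null(regions$id))
    regions$id <- region_id(regions$chrom, regions$start, regions$end)
  if (nrow(regions) != nrow(values))
    stop(sprintf("region count mismatch: %d regions vs %d matrix rows",
                 nrow(regions), nrow(values)))
  validate_regions(regions)
  rownames(values) <- regions$id

  if (is.null(samples)) {
    ids <- colnames(values)
    if (is.null(ids)) ids <- paste0("S", seq_len(ncol(values)))
    samples <- data.frame(sample_id = ids,
                          time_point = seq_along(ids),
                          replicate = "rep1",
                          stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_point", "replicate")
  if (!all(need %in% names(samples)))
    stop("samples must have columns sample_id, time_point, replicate")
  if (nrow(samples) != ncol(values))
    stop(sprintf("sample count mismatch: %d metadata rows vs %d matrix columns",
                 nrow(samples), ncol(values)))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in metadata")
  tp <- suppressWarnings(as.numeric(samples$time_point))
  if (anyNA(tp)) stop("time_point values must be numeric (rankable)")
  samples$time_point <- tp
  colnames(values) <- samples$sample_id
  if (anyNA(values)) stop("signal matrix contains missing values")

  structure(list(values = values, regions = regions, samples = samples),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d regions x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$regions$chrom), collapse = ", ")))
  tp <- sort(unique(x$samples$time_point))
  cat(sprintf("  time points: %s\n", paste(tp, collapse = ", ")))
  invisible(x)
}

#' @export
dim.signal_matrix <- function(x) dim(x$values)

#' Canonical region identifier
#'
#' @param chrom,start,end vectors of coordinates (BED convention).
#' @return character vector `"chrom:start-end"`.
#' @export
region_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Parse canonical region ids
#'
#' @param ids character vector of the form `"chrom:start-end"`.
#' @return data frame with columns `chrom`, `start`, `end`, `id`.
#' @export
parse_region_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop(sprintf("region id not parseable as chrom:start-end: '%s' (row %d)",
                 ids[bad[1]], bad[1]))
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end   = as.integer(vapply(m, `[`, "", 4L)),
             id    = ids,
             stringsAsFactors = FALSE)
}

validate_regions <- function(regions) {
  bad <- which(regions$start < 0 | regions$end <= regions$start)
  if (length(bad))
    stop(sprintf("invalid region at row %d: %s:%d-%d (need start >= 0, end > start)",
                 bad[1], regions$chrom[bad[1]], regions$start[bad[1]],
                 regions$end[bad[1]]))
  if (anyDuplicated(regions$id))
    stop("duplicate region ids")
  invisible(TRUE)
}

subset_sm <- function(sm, keep) {
  signal_matrix(sm$values[keep, , drop = FALSE],
                regions = sm$regions[keep, , drop = FALSE],
                samples = sm$samples)
}
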