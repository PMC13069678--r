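#' Read a counts matrix with sample metadata
#'
#' Reads a rectangular TSV/CSV counts table (header row of sample ids, first
#' column region id), a sample metadata table (columns `sample_id`,
#' `time_point`, `replicate`, optional `batch`), and optionally a BED file
#' supplying region coordinates in matrix row order. Without a BED file the
#' region ids must be canonical `"chrom:start-end"` strings.
#'
#' @param matrix_path path to the counts table (TSV or CSV by extension).
#' @param meta_path path to the sample metadata TSV.
#' @param bed_path optional BED3+ path; row order must match the matrix.
#' @return A [signal_matrix()] of raw counts.
#' @export
read_counts <- function(matrix_path, meta_path, bed_path = NULL) {
  sep <- if (grepl("\\.csv$", matrix_path)) "," else "\t"
  tab <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(colnames(values) %in% meta$sample_id) ||
      ncol(values) != nrow(meta))
    stop(sprintf("sample mismatch: matrix has %d columns, metadata %d rows",
                 ncol(values), nrow(meta)))
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]

  if (!is.null(bed_path)) {
    regions <- read_bed(bed_path)
    if (nrow(regions) != nrow(values))
      stop(sprintf("region count mismatch: matrix has %d rows, BED has %d",
                   nrow(values), nrow(regions)))
    regions$id <- region_id(regions$chrom, regions$start, regions$end)
  } else {
    regions <- parse_region_ids(ids)
  }
  signal_matrix(values, regions = regions, samples = meta)
}

#' Read a BED file
#'
#' BED3+ reader: tab-separated, no header, columns chrom/start/end and an
#' optional name column. Coordinates are validated (0-based half-open).
#'
#' @param path BED file path.
#' @return data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3) stop(sprintf("malformed BED '%s': fewer than 3 columns", path))
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]),
                    end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4) out$name <- as.character(tab[[4]])
  bad <- which(out$start < 0 | out$end <= out$start | is.na(out$start) | is.na(out$end))
  if (length(bad))
    stop(sprintf("malformed BED '%s' at line %d: start=%s end=%s",
                 path, bad[1], tab[[2]][bad[1]], tab[[3]][bad[1]]))
  out
}

#' Write a signal matrix to disk
#'
#' Writes the matrix TSV (first column `region_id`), the sample metadata
#' TSV, and a BED3 of the regions, the same layout [read_counts()] accepts.
#'
#' @param sm a [signal_matrix()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix, default `"matrix"`.
#' @return invisibly, the paths written.
#' @export
write_signal_matrix <- function(sm, dir, prefix = "matrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, paste0(prefix, ".tsv"))
  tab <- data.frame(region_id = sm$regions$id, sm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  sp <- file.path(dir, "meta.tsv")
  utils::write.table(sm$samples, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  bp <- file.path(dir, "regions.bed")
  utils::write.table(sm$regions[, c("chrom", "start", "end", "id")], bp,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(matrix = mp, meta = sp, bed = bp))
}

#' Read gene models
#'
#' @param path TSV with header and columns `symbol`, `chrom`, `strand`, `tss`.
#' @return data frame of gene models (one TSS per gene).
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("symbol", "chrom", "strand", "tss")
  if (!all(need %in% names(tab)))
    stop("gene model table needs columns symbol, chrom, strand, tss")
  if (!all(tab$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  tab$tss <- as.integer(tab$tss)
  tab
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 50))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
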