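#' Log2 counts-per-million normalization
#'
#' Converts raw counts to log2 counts per million with a small prior:
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)` where `libsize` is
#' the column sum of raw counts. This is a self-contained normalization in
#' the log-CPM family; it does not rescale the prior by library size.
#'
#' @param sm raw-count [signal_matrix()]; entries must be non-negative.
#' @param prior pseudo-count added to each entry (default 0.5).
#' @return [signal_matrix()] of log2-CPM values.
#' @export
log_cpm <- function(sm, prior = 0.5) {
  v <- sm$values
  if (any(v < 0)) stop("log_cpm expects non-negative raw counts")
  lib <- colSums(v)
  if (any(lib <= 0)) {
    zero <- colnames(v)[lib <= 0]
    stop("zero library size in sample(s): ", paste(zero, collapse = ", "))
  }
  out <- log2(sweep(v + prior, 2, lib + 2 * prior, "/") * 1e6)
  signal_matrix(out, regions = sm$regions, samples = sm$samples)
}

#' Remove additive batch effects
#'
#' Per feature, fits a batch indicator model by least squares and subtracts
#' the batch-mean deviations (zero-sum contrasts), so that after the
#' transform each feature's batch means are equal and its grand mean is
#' preserved. A single-sample batch is allowed; a single batch overall is an
#' identity transform with a warning.
#'
#' @param sm [signal_matrix()] whose `samples` carry a `batch` column.
#' @return corrected [signal_matrix()].
#' @export
remove_batch_effect <- function(sm) {
  batch <- sm$samples$batch
  if (is.null(batch) || anyNA(batch))
    stop("batch labels must be present for all samples")
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) {
    warning("single batch: returning input unchanged")
    return(sm)
  }
  v <- sm$values
  # per-batch feature means and their sample-size-weighted grand offset:
  # subtracting (batch mean - weighted mean of batch means) equalizes batch
  # means per feature and leaves the overall feature mean unchanged
  bm <- vapply(levels(batch), function(b)
    rowMeans(v[, batch == b, drop = FALSE]), numeric(nrow(v)))
  bm <- matrix(bm, nrow = nrow(v))
  w <- as.numeric(table(batch)) / length(batch)
  center <- bm %*% w
  adj <- bm - as.vector(center)            # n x nbatch deviations
  out <- v - adj[, as.integer(batch), drop = FALSE]
  signal_matrix(out, regions = sm$regions, samples = sm$samples)
}

#' Filter regions by chromosome, variance, and id
#'
#' Retains rows whose chromosome is not in `drop_chroms`, whose sample
#' variance (denominator `m - 1`) is at least `min_variance`, and whose id
#' is not in `drop_ids`. Optional quantile trimming of row means (`low_q`,
#' `high_q`) removes extremely low / high signals. Chromosome matching is an
#' exact string match ("chrX" is not "X").
#'
#' @param sm a [signal_matrix()].
#' @param drop_chroms character set of chromosomes to drop (e.g.
#'   `c("chrX", "chrY")`); default empty.
#' @param min_variance minimum row sample variance, default 0.
#' @param drop_ids optional character set of region ids to drop.
#' @param low_q,high_q optional quantile bounds on row means; rows with mean
#'   below the `low_q` or above the `high_q` quantile are removed.
#' @return filtered [signal_matrix()], row order preserved.
#' @export
filter_regions <- function(sm, drop_chroms = character(), min_variance = 0,
                           drop_ids = NULL, low_q = NULL, high_q = NULL) {
  if (min_variance < 0) stop("min_variance must be >= 0")
  keep <- !(sm$regions$chrom %in% drop_chroms)
  if (min_variance > 0) {
    rv <- row_variances(sm$values)
    keep <- keep & rv >= min_variance
  }
  if (!is.null(drop_ids)) keep <- keep & !(sm$regions$id %in% drop_ids)
  if (!is.null(low_q) || !is.null(high_q)) {
    mu <- rowMeans(sm$values)
    if (!is.null(low_q)) keep <- keep & mu >= stats::quantile(mu, low_q)
    if (!is.null(high_q)) keep <- keep & mu <= stats::quantile(mu, high_q)
  }
  if (!any(keep)) stop("all regions removed by filtering; no network to build")
  subset_sm(sm, keep)
}

#' Average replicates within time points
#'
#' Collapses columns to one per distinct time point (ordered by time rank),
#' each entry the arithmetic mean over that time point's replicates.
#'
#' @param sm a [signal_matrix()].
#' @return [signal_matrix()] with one column per time point.
#' @export
average_replicates <- function(sm) {
  tp <- sm$samples$time_point
  tps <- sort(unique(tp))
  out <- vapply(tps, function(t)
    rowMeans(sm$values[, tp == t, drop = FALSE]), numeric(nrow(sm$values)))
  out <- matrix(out, nrow = nrow(sm$values))
  samples <- data.frame(sample_id = paste0("t", tps), time_point = tps,
                        replicate = "mean", stringsAsFactors = FALSE)
  signal_matrix(out, regions = sm$regions, samples = samples)
}

#' Z-score rows
#'
#' Standardizes each row to mean 0 and sample standard deviation 1
#' (denominator `m - 1`); used for cross-region trend comparison.
#'
#' @param sm a [signal_matrix()].
#' @return standardized [signal_matrix()].
#' @export
zscore_rows <- function(sm) {
  v <- sm$values
  mu <- rowMeans(v)
  sdv <- sqrt(row_variances(v))
  zero <- sdv == 0
  if (any(zero))
    stop("zero-variance rows cannot be z-scored: ",
         paste(utils::head(sm$regions$id[zero], 5), collapse = ", "))
  out <- (v - mu) / sdv
  signal_matrix(out, regions = sm$regions, samples = sm$samples)
}

# row-wise sample variance, denominator m - 1
row_variances <- function(v) {
  m <- ncol(v)
  if (m < 2) stop("variance needs at least 2 samples")
  mu <- rowMeans(v)
  rowSums((v - mu)^2) / (m - 1)
}
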