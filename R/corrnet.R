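#' Minimum correlation for a target p-value
#'
#' Converts a two-sided significance level into the minimum Spearman
#' correlation magnitude that attains it, via the Student t-distribution:
#' `t_crit = qt(1 - p/2, df)` with `df = m - 2`, then
#' `r_min = t_crit / sqrt(t_crit^2 + df)`.
#'
#' @param p target two-sided p-value in (0, 1].
#' @param m number of samples (columns); must be at least 3 so `df >= 1`.
#' @return minimum correlation in `[0, 1)`.
#' @export
pvalue_to_min_correlation <- function(p, m) {
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  if (m < 3) stop("need m >= 3 samples (degrees of freedom m - 2 >= 1)")
  df <- m - 2
  t_crit <- stats::qt(1 - p / 2, df = df)
  t_crit / sqrt(t_crit^2 + df)
}

#' Correlation threshold configuration
#'
#' Either a direct lower bound on the correlation (`mode = "corr"`) or a
#' two-sided p-value converted through [pvalue_to_min_correlation()]
#' (`mode = "pval"`).
#'
#' @param mode `"pval"` or `"corr"`.
#' @param value the target p-value or minimum correlation.
#' @param m number of samples (required for `mode = "pval"`).
#' @return list with `mode`, `value`, `df`, `r_min`, class
#'   `"threshold_config"`.
#' @export
threshold_config <- function(mode = c("pval", "corr"), value, m = NULL) {
  mode <- match.arg(mode)
  if (mode == "pval") {
    if (is.null(m)) stop("mode 'pval' needs the sample count m")
    r_min <- pvalue_to_min_correlation(value, m)
    df <- m - 2
  } else {
    if (value < 0 || value > 1) stop("minimum correlation must be in [0, 1]")
    r_min <- value
    df <- if (is.null(m)) NA_integer_ else m - 2
  }
  structure(list(mode = mode, value = value, df = df, r_min = r_min),
            class = "threshold_config")
}

#' Batch plan for chunked correlation computation
#'
#' Memory control for all-pairs correlation: `chunk_size` rows are handled
#' per chunk, and within a chunk the opposing rows are split so at most
#' `step_size` pairwise correlations are materialized at once. The plan
#' never changes the result, only the schedule.
#'
#' @param chunk_size rows per chunk (default 1000).
#' @param step_size maximum simultaneous pairwise correlations
#'   (default 1e5).
#' @param workers reserved for parallel execution; scheduling is
#'   deterministic for any value (default 1).
#' @return list of class `"batch_plan"`.
#' @export
batch_plan <- function(chunk_size = 1000L, step_size = 1e5, workers = 1L) {
  if (chunk_size < 1 || step_size < 1 || workers < 1)
    stop("chunk_size, step_size and workers must all be >= 1")
  structure(list(chunk_size = as.integer(chunk_size),
                 step_size = as.numeric(step_size),
                 workers = as.integer(workers)),
            class = "batch_plan")
}

#' Rank-transform and standardize rows
#'
#' Each row is replaced by its tie-averaged ranks across samples, centered
#' to mean 0 and scaled by the population standard deviation (denominator
#' `m`), so that for two rows `a`, `b` the dot product `Z_a . Z_b / m` is
#' exactly the Pearson correlation of the ranks, i.e. the Spearman
#' correlation.
#'
#' @param x a [signal_matrix()] or a numeric matrix.
#' @return numeric matrix of standardized ranks, same dimnames.
#' @export
rank_standardize <- function(x) {
  v <- if (inherits(x, "signal_matrix")) x$values else as.matrix(x)
  m <- ncol(v)
  r <- t(apply(v, 1, rank, ties.method = "average"))
  mu <- rowMeans(r)
  sdv <- sqrt(rowSums((r - mu)^2) / m)   # population sd
  zero <- sdv == 0
  if (any(zero))
    stop("constant rows (zero rank variance), filter first: ",
         paste(utils::head(rownames(v)[zero], 5), collapse = ", "))
  (r - mu) / sdv
}

#' Spearman correlations for a block of row pairs
#'
#' @param Z standardized rank matrix from [rank_standardize()].
#' @param rows_a,rows_b integer row indices.
#' @return `length(rows_a) x length(rows_b)` matrix of Spearman
#'   correlations (`rho = Z_a . Z_b / m`).
#' @export
spearman_block <- function(Z, rows_a, rows_b) {
  tcrossprod(Z[rows_a, , drop = FALSE], Z[rows_b, , drop = FALSE]) / ncol(Z)
}

#' Build the co-accessibility network
#'
#' Computes all-pairs Spearman correlations of the signal matrix in
#' memory-bounded blocks, keeps the pairs passing the threshold, and
#' persists them to a correlation-binned [edge_store] on disk. The output
#' is identical for any [batch_plan()]: edges within each 0.1-wide bin are
#' sorted by `(source_id, target_id)` before writing.
#'
#' @param sm a log-normalized [signal_matrix()].
#' @param tc a [threshold_config()]; a bare p-value is also accepted.
#' @param plan a [batch_plan()].
#' @param out output directory for the edge store.
#' @param edge_sign `"positive"` keeps only `rho >= r_min` (default);
#'   `"absolute"` keeps `|rho| >= r_min`, binned by `|rho|` with the sign
#'   stored in `rho`.
#' @param format `"parquet"` (default) or `"csv"` (identical schema).
#' @return an [edge_store] handle.
#' @export
build_network <- function(sm, tc, plan = batch_plan(), out,
                          edge_sign = c("positive", "absolute"),
                          format = c("parquet", "csv")) {
  edge_sign <- match.arg(edge_sign)
  format <- match.arg(format)
  if (is.numeric(tc)) tc <- threshold_config("pval", tc, m = ncol(sm$values))
  n <- nrow(sm$values)
  m <- ncol(sm$values)
  if (n < 2) stop("need at least 2 regions to build a network")
  Z <- rank_standardize(sm)
  ids <- sm$regions$id
  # C-locale (bytewise) lexicographic rank of each id: pair orientation and
  # within-bin sorting must not depend on the session collation
  id_rank <- match(ids, sort(ids, method = "radix"))
  r_min <- tc$r_min

  bin_lo <- bin_floor(r_min)
  bins <- seq(bin_lo, 0.9, by = 0.1)
  acc <- rep(list(list()), length(bins))   # per-bin list of edge frames

  chunk_starts <- seq(1L, n, by = plan$chunk_size)
  for (cs in chunk_starts) {
    a_idx <- cs:min(cs + plan$chunk_size - 1L, n)
    # pair block a x b with b from the chunk start onward (upper triangle)
    b_from <- cs
    while (b_from <= n) {
      b_len <- max(1L, min(n - b_from + 1L,
                           as.integer(plan$step_size %/% length(a_idx))))
      b_idx <- b_from:min(b_from + b_len - 1L, n)
      rho <- spearman_block(Z, a_idx, b_idx)
      ii <- rep(a_idx, times = length(b_idx))
      jj <- rep(b_idx, each = length(a_idx))
      keep <- ii < jj
      if (any(keep)) {
        r <- as.vector(rho)[keep]
        i2 <- ii[keep]; j2 <- jj[keep]
        mag <- if (edge_sign == "absolute") abs(r) else r
        pass <- round(mag, 12) >= round(r_min, 12)
        if (any(pass)) {
          ef <- edge_frame(i2[pass], j2[pass], ids, id_rank, r[pass],
                           round(mag[pass], 12))
          bi <- bin_index(ef$mag, bin_lo)
          for (b in unique(bi)) {
            acc[[b]][[length(acc[[b]]) + 1L]] <-
              ef[bi == b, c("source_id", "target_id", "rho",
                            "src_rank", "tgt_rank"), drop = FALSE]
          }
        }
      }
      b_from <- b_from + length(b_idx)
    }
  }

  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  counts <- integer(length(bins))
  for (b in seq_along(bins)) {
    df <- if (length(acc[[b]]))
      do.call(rbind, acc[[b]])
    else
      data.frame(source_id = character(), target_id = character(),
                 rho = numeric(), src_rank = integer(),
                 tgt_rank = integer(), stringsAsFactors = FALSE)
    df <- df[order(df$src_rank, df$tgt_rank), , drop = FALSE]
    df <- df[, c("source_id", "target_id", "rho"), drop = FALSE]
    rownames(df) <- NULL
    counts[b] <- nrow(df)
    write_bin(df, out, bins[b], format)
  }
  manifest <- list(n = n, m = m, mode = tc$mode, value = tc$value,
                   r_min = r_min, edge_sign = edge_sign, format = format,
                   bins = data.frame(lo = bins, hi = bins + 0.1,
                                     count = counts),
                   node_ids = ids)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  edge_store(out)
}

# edges are binned by |rho| rounded to 12 decimals; [lo, lo + 0.1) with the
# top bin closed at 1.0
bin_floor <- function(r) min(0.9, floor(round(r, 12) * 10 + 1e-9) / 10)

bin_index <- function(mag, bin_lo) {
  idx <- floor(mag * 10 + 1e-9) - as.integer(round(bin_lo * 10)) + 1L
  nmax <- 9L - as.integer(round(bin_lo * 10)) + 1L
  pmin(pmax(idx, 1L), nmax)
}

# i, j are row indices; orientation by C-locale id rank (source < target)
edge_frame <- function(i, j, ids, id_rank, rho, mag) {
  swap <- id_rank[i] > id_rank[j]
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  data.frame(source_id = ids[i], target_id = ids[j], rho = rho, mag = mag,
             src_rank = id_rank[i], tgt_rank = id_rank[j],
             stringsAsFactors = FALSE)
}

bin_file <- function(root, lo, format) {
  file.path(root, sprintf("edges_%.1f_%.1f.%s", lo, lo + 0.1,
                          if (format == "parquet") "parquet" else "csv"))
}

write_bin <- function(df, root, lo, format) {
  path <- bin_file(root, lo, format)
  if (format == "parquet") arrow::write_parquet(df, path)
  else utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_bin <- function(store, lo) {
  path <- bin_file(store$root, lo, store$manifest$format)
  if (!file.exists(path))
    stop(sprintf("missing edge bin file for [%.1f, %.1f): %s",
                 lo, lo + 0.1, path))
  if (store$manifest$format == "parquet")
    as.data.frame(arrow::read_parquet(path))
  else
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
}

#' Open an edge store
#'
#' An edge store is a directory of columnar edge files, one per 0.1-wide
#' correlation bin (`edges_<lo>_<hi>.parquet` with columns `source_id`,
#' `target_id`, `rho`), plus `manifest.json` recording `n`, `m`, the
#' threshold, the sign policy, per-bin counts, and the full node id list.
#'
#' @param root store directory written by [build_network()].
#' @return list of class `"edge_store"` with `root` and the parsed
#'   manifest.
#' @export
edge_store <- function(root) {
  mf <- file.path(root, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", root)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  manifest$bins <- as.data.frame(manifest$bins)
  structure(list(root = root, manifest = manifest), class = "edge_store")
}

#' @export
print.edge_store <- function(x, ...) {
  cat(sprintf("edge_store: %d nodes, %d edges (r_min = %.4f, %s)\n",
              x$manifest$n, sum(x$manifest$bins$count), x$manifest$r_min,
              x$manifest$edge_sign))
  cat(sprintf("  bins: %s\n",
              paste(sprintf("[%.1f,%.1f)=%d", x$manifest$bins$lo,
                            x$manifest$bins$hi, x$manifest$bins$count),
                    collapse = " ")))
  invisible(x)
}

#' Load edges at or above a threshold
#'
#' Reads only the bins intersecting `[tau, 1]` and filters exactly.
#' Thresholding is on the binned magnitude (`|rho|` under the absolute sign
#' policy), rounded to 12 decimals like the store itself.
#'
#' @param store an [edge_store].
#' @param tau minimum correlation; default the store's `r_min`.
#' @return data frame with columns `source_id`, `target_id`, `rho`.
#' @export
load_edges <- function(store, tau = store$manifest$r_min) {
  bins <- store$manifest$bins
  hit <- bins$lo + 0.1 > round(tau, 12) - 1e-12
  parts <- lapply(bins$lo[hit], function(lo) read_bin(store, lo))
  df <- if (length(parts)) do.call(rbind, parts)
  else data.frame(source_id = character(), target_id = character(),
                  rho = numeric(), stringsAsFactors = FALSE)
  mag <- round(abs(df$rho), 12)
  df[mag >= round(tau, 12), , drop = FALSE]
}
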