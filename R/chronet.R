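#' Fit a time-aware chromatin co-accessibility network
#'
#' The main entry point: from a log-normalized [signal_matrix()] it
#' (1) computes all-pairs Spearman correlations in memory-bounded blocks
#' and persists the significant edges to a correlation-binned store,
#' (2) scans network topology over the store's thresholds and selects the
#' threshold maximizing the relative largest connected component (rLCC),
#' (3) runs Leiden community detection over a resolution grid on the
#' thresholded weighted graph and selects the resolution maximizing
#' modularity.
#'
#' @param sm a log-normalized [signal_matrix()] (preprocess raw counts
#'   with [log_cpm()], [remove_batch_effect()], [filter_regions()],
#'   [average_replicates()] first).
#' @param threshold a [threshold_config()], or a p-value scalar (default
#'   0.1, converted via the Student t inversion).
#' @param plan a [batch_plan()].
#' @param store_dir directory for the edge store (default: a session
#'   temporary directory).
#' @param tau optional fixed correlation threshold, overriding automatic
#'   rLCC selection.
#' @param resolutions Leiden resolution grid (default `seq(0.5, 1.5,
#'   0.1)`).
#' @param seed seed for community detection (default 42).
#' @param include_disconnected treat isolated nodes as one extra
#'   community (default TRUE; they are always retained as nodes).
#' @param edge_sign,format passed to [build_network()].
#' @return An object of class `"chronet"`: a list with `store`, `series`,
#'   `tau` (selected threshold), `partitions`, `gamma` (selected
#'   resolution), `labels` (named community labels at the selected
#'   resolution), `network`, and the call.
#' @seealso [print.chronet()], [summary.chronet()], [plot.chronet()]
#' @export
chronet <- function(sm, threshold = 0.1, plan = batch_plan(),
                    store_dir = tempfile("edgestore"), tau = NULL,
                    resolutions = seq(0.5, 1.5, by = 0.1), seed = 42L,
                    include_disconnected = TRUE,
                    edge_sign = "positive", format = "parquet") {
  if (is.numeric(threshold))
    threshold <- threshold_config("pval", threshold, m = ncol(sm$values))
  store <- build_network(sm, threshold, plan, store_dir,
                         edge_sign = edge_sign, format = format)
  series <- build_series(store)
  if (is.null(tau)) tau <- select_threshold(series)
  net <- materialize(store, tau)
  cfg <- community_config(resolutions = resolutions, seed = seed,
                          include_disconnected = include_disconnected)
  parts <- detect_communities(net, cfg)
  gamma <- select_resolution(parts)
  best <- parts[[which(vapply(parts, `[[`, 0, "gamma") == gamma)[1]]]
  structure(list(store = store, series = series, tau = tau,
                 partitions = parts, gamma = gamma,
                 labels = best$labels, modularity = best$modularity,
                 network = net, config = cfg, call = match.call()),
            class = "chronet")
}

#' @export
print.chronet <- function(x, ...) {
  ns <- x$series[x$series$tau == x$tau, ]
  cat("Time-aware chromatin co-accessibility network\n")
  cat(sprintf("  nodes: %d (%d connected)   edges at tau: %d\n",
              ns$n_total_nodes, ns$n_connected_nodes, ns$n_edges))
  cat(sprintf("  selected tau (rLCC): %.4f   rLCC: %.4f   density: %.4g\n",
              x$tau, ns$rlcc, ns$density))
  cat(sprintf("  selected resolution (modularity): %.2f   Q: %.4f\n",
              x$gamma, x$modularity))
  sz <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("  communities: %d   sizes: %s\n", length(sz),
              paste(utils::head(as.integer(sz), 10), collapse = ", ")))
  invisible(x)
}

#' Summarize a fitted chromatin network
#'
#' @param object a `"chronet"` object.
#' @param ... unused.
#' @return list with the threshold series, the per-resolution modularity
#'   table, and the community size table at the selected resolution.
#' @export
summary.chronet <- function(object, ...) {
  qtab <- data.frame(
    gamma = vapply(object$partitions, `[[`, 0, "gamma"),
    modularity = vapply(object$partitions, `[[`, 0, "modularity"),
    n_communities = vapply(object$partitions,
                           function(p) length(p$sizes), 0L))
  out <- list(series = object$series, resolutions = qtab,
              tau = object$tau, gamma = object$gamma,
              sizes = sort(table(object$labels), decreasing = TRUE))
  class(out) <- "summary.chronet"
  out
}

#' @export
print.summary.chronet <- function(x, ...) {
  cat("Threshold series:\n")
  print.data.frame(x$series, row.names = FALSE, digits = 4)
  cat(sprintf("\nSelected tau: %.4f\n\nResolution scan:\n", x$tau))
  print.data.frame(x$resolutions, row.names = FALSE, digits = 4)
  cat(sprintf("\nSelected gamma: %.2f\nCommunity sizes:\n", x$gamma))
  print(x$sizes)
  invisible(x)
}

#' Diagnostic plots for a fitted chromatin network
#'
#' Base-graphics panel: rLCC and edge count against the correlation
#' threshold (with the selected tau marked), modularity against the
#' resolution (with the selected gamma marked), and community sizes.
#'
#' @param x a `"chronet"` object.
#' @param ... passed to `plot`.
#' @export
plot.chronet <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  s <- x$series
  plot(s$tau, s$rlcc, type = "b", xlab = "correlation threshold",
       ylab = "rLCC", main = "threshold selection", ...)
  graphics::abline(v = x$tau, lty = 2)
  plot(s$tau, s$n_edges, type = "b", log = "y",
       xlab = "correlation threshold", ylab = "edges", main = "edge count")
  gam <- vapply(x$partitions, `[[`, 0, "gamma")
  q <- vapply(x$partitions, `[[`, 0, "modularity")
  plot(gam, q, type = "b", xlab = "resolution", ylab = "modularity (Q)",
       main = "resolution selection")
  graphics::abline(v = x$gamma, lty = 2)
  sz <- sort(table(x$labels), decreasing = TRUE)
  graphics::barplot(as.integer(sz), names.arg = names(sz),
                    xlab = "community", ylab = "regions",
                    main = "community sizes")
  invisible(x)
}

#' Community labels of a fitted network
#'
#' @param object a `"chronet"` object.
#' @param ... unused.
#' @return named integer vector of community labels over region ids.
#' @export
labels.chronet <- function(object, ...) object$labels
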