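#' Topology metrics of the thresholded network
#'
#' Builds the graph of edges with `rho >= tau` over ALL nodes recorded in
#' the store manifest (isolated nodes are retained) and computes: edge
#' count, connected node count, total node count, density
#' (`n_edges / choose(n_total, 2)`), global transitivity (3 x triangles /
#' connected triples, 0 when there are no triples), the largest connected
#' component size (LCC) and the relative LCC
#' (`rlcc = lcc / n_total`).
#'
#' @param store an [edge_store].
#' @param tau correlation threshold.
#' @return one-row data frame of metrics.
#' @export
compute_metrics <- function(store, tau) {
  edges <- load_edges(store, tau)
  n_total <- store$manifest$n
  n_edges <- nrow(edges)
  if (n_edges == 0) {
    return(data.frame(tau = tau, n_edges = 0L, n_connected_nodes = 0L,
                      n_total_nodes = n_total, density = 0,
                      transitivity = 0, lcc = 1L, rlcc = 1 / n_total))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("source_id", "target_id")], directed = FALSE,
    vertices = data.frame(name = store$manifest$node_ids))
  comp <- igraph::components(g)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  data.frame(
    tau = tau,
    n_edges = n_edges,
    n_connected_nodes = sum(igraph::degree(g) > 0),
    n_total_nodes = n_total,
    density = n_edges / (n_total * (n_total - 1) / 2),
    transitivity = trans,
    lcc = max(comp$csize),
    rlcc = max(comp$csize) / n_total)
}

#' Per-threshold metric series
#'
#' Computes [compute_metrics()] for each threshold in `taus` (default: the
#' lower boundaries of the bins present in the store, clipped to `r_min`).
#'
#' @param store an [edge_store].
#' @param taus numeric vector of thresholds; a user grid is clipped to the
#'   store's available bins.
#' @return data frame of class `"network_series"`, one row per tau in
#'   increasing order.
#' @export
build_series <- function(store, taus = NULL) {
  bins <- store$manifest$bins
  if (is.null(taus)) {
    taus <- pmax(bins$lo, store$manifest$r_min)
    taus <- unique(round(taus, 12))
  } else {
    lo <- min(bins$lo)
    taus <- sort(unique(taus))
    taus <- taus[taus >= lo & taus <= 1]
    if (!length(taus)) stop("no requested tau intersects the store's bins")
  }
  taus <- sort(taus)
  out <- do.call(rbind, lapply(taus, function(t) compute_metrics(store, t)))
  class(out) <- c("network_series", "data.frame")
  out
}

#' Select the correlation threshold from a metric series
#'
#' Returns the tau with the highest relative largest-connected-component
#' (rLCC); among ties, the most stringent (largest) tau, which removes
#' low-value edges without altering the reachable topology.
#'
#' @param series a `"network_series"` from [build_series()].
#' @return the selected tau (numeric scalar).
#' @export
select_threshold <- function(series) {
  if (nrow(series) == 0) stop("empty series")
  best <- series$rlcc == max(series$rlcc)
  max(series$tau[best])
}

#' @export
print.network_series <- function(x, ...) {
  cat("network_series over", nrow(x), "threshold(s)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
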