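#' Materialize the thresholded chromatin network
#'
#' Builds an igraph graph with ALL nodes from the store manifest and the
#' edges with `rho >= tau`, weighted by `rho`.
#'
#' @param store an [edge_store].
#' @param tau correlation threshold.
#' @return list of class `"chromatin_network"` with the igraph `graph`,
#'   the `tau` used, and the node id vector.
#' @export
materialize <- function(store, tau) {
  edges <- load_edges(store, tau)
  g <- igraph::graph_from_data_frame(
    cbind(edges[, c("source_id", "target_id")], weight = edges$rho),
    directed = FALSE,
    vertices = data.frame(name = store$manifest$node_ids))
  structure(list(graph = g, tau = tau, nodes = store$manifest$node_ids),
            class = "chromatin_network")
}

#' @export
print.chromatin_network <- function(x, ...) {
  cat(sprintf("chromatin_network: %d nodes, %d edges (tau = %.4f)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$tau))
  invisible(x)
}

#' Weighted modularity with a resolution parameter
#'
#' Newman-Girvan modularity of a labeling on the weighted graph:
#' `Q = (1/2W) * sum_ij [w_ij - gamma * s_i s_j / (2W)] * delta(c_i, c_j)`
#' with `W` the total edge weight and `s_i` the weighted degree. Isolated
#' nodes have `s_i = 0` and contribute nothing; nodes missing from `labels`
#' must be isolated.
#'
#' @param net a `"chromatin_network"` (or an igraph graph).
#' @param labels named vector/factor of community labels, names = node ids
#'   (unnamed vectors are taken in graph vertex order).
#' @param gamma resolution (default 1).
#' @return modularity Q (scalar).
#' @export
network_modularity <- function(net, labels, gamma = 1) {
  g <- if (inherits(net, "chromatin_network")) net$graph else net
  if (igraph::ecount(g) == 0)
    stop("modularity is undefined on an edgeless graph")
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  vn <- igraph::V(g)$name
  lab <- align_labels(labels, vn)
  deg <- igraph::strength(g, weights = w)
  if (any(is.na(lab) & deg > 0))
    stop("labels must cover all non-isolated nodes")
  W2 <- 2 * sum(w)
  same <- !is.na(lab[ends[, 1]]) & lab[ends[, 1]] == lab[ends[, 2]]
  within_w <- sum(w[same])
  # expected within-community weight under the configuration null
  s_by_c <- tapply(deg, lab, sum)
  q <- 2 * within_w / W2 - gamma * sum(s_by_c^2) / W2^2
  unname(q)
}

align_labels <- function(labels, node_names) {
  if (!is.null(names(labels))) {
    lab <- labels[node_names]
    names(lab) <- node_names
  } else {
    if (length(labels) != length(node_names))
      stop("unnamed labels must have one entry per graph vertex")
    lab <- stats::setNames(labels, node_names)
  }
  as.vector(lab, mode = "character") -> out
  stats::setNames(out, node_names)
}

#' Community detection configuration
#'
#' @param resolutions Leiden resolution grid (default `seq(0.5, 1.5, 0.1)`).
#' @param seed RNG seed fixed before each Leiden run (default 42).
#' @param n_iterations Leiden iterations; `-1` runs to convergence
#'   (default).
#' @param weighted use edge weights (default TRUE).
#' @param include_disconnected if TRUE, isolated nodes form one extra
#'   community labeled `"disconnected"`, id = max id + 1.
#' @return list of class `"community_config"`.
#' @export
community_config <- function(resolutions = seq(0.5, 1.5, by = 0.1),
                             seed = 42L, n_iterations = -1L,
                             weighted = TRUE,
                             include_disconnected = FALSE) {
  if (!length(resolutions) || any(resolutions <= 0))
    stop("resolutions must be a non-empty grid of positive values")
  structure(list(resolutions = resolutions, seed = as.integer(seed),
                 n_iterations = as.integer(n_iterations),
                 weighted = isTRUE(weighted),
                 include_disconnected = isTRUE(include_disconnected)),
            class = "community_config")
}

#' Leiden community detection over a resolution grid
#'
#' Runs the Leiden algorithm (RB-configuration modularity objective with
#' resolution gamma) on the connected part of the weighted graph, once per
#' resolution, with a fixed seed for reproducibility. Community ids are
#' reassigned by decreasing size (community 1 = largest). Each partition
#' also records `modularity`: Q of the labeling evaluated at the standard
#' gamma = 1 objective, so values are comparable across the grid.
#'
#' @param net a `"chromatin_network"`.
#' @param cfg a [community_config()].
#' @return list of partitions, one per resolution; each is a list with
#'   `gamma`, `labels` (named integer vector over nodes; isolated nodes NA
#'   unless `include_disconnected`), `modularity`, `sizes`.
#' @export
detect_communities <- function(net, cfg = community_config()) {
  g <- net$graph
  if (igraph::ecount(g) == 0)
    stop("cannot detect communities on an edgeless graph")
  w <- if (cfg$weighted) igraph::E(g)$weight else rep(1, igraph::ecount(g))
  deg <- igraph::degree(g)
  gc <- igraph::induced_subgraph(g, which(deg > 0))
  wc <- if (cfg$weighted) igraph::E(gc)$weight else rep(1, igraph::ecount(gc))
  lapply(cfg$resolutions, function(gamma) {
    set.seed(cfg$seed)
    cl <- igraph::cluster_leiden(gc, objective_function = "modularity",
                                 weights = wc, resolution = gamma,
                                 n_iterations = cfg$n_iterations)
    memb <- igraph::membership(cl)
    # densify ids by decreasing community size; ties broken by old id
    sz <- table(memb)
    new_id <- stats::setNames(rank(-as.vector(sz), ties.method = "first"),
                              names(sz))
    lab <- stats::setNames(as.integer(new_id[as.character(memb)]),
                           igraph::V(gc)$name)
    full <- stats::setNames(rep(NA_integer_, length(net$nodes)), net$nodes)
    full[names(lab)] <- lab
    if (cfg$include_disconnected && any(is.na(full)))
      full[is.na(full)] <- max(lab) + 1L
    q <- network_modularity(net, full[!is.na(full)], gamma = 1)
    sizes <- table(full, useNA = "no")
    list(gamma = gamma, labels = full, modularity = q,
         sizes = stats::setNames(as.integer(sizes), names(sizes)))
  })
}

#' Select the Leiden resolution by modularity
#'
#' Returns the resolution whose partition maximizes modularity (evaluated
#' at the standard gamma = 1 objective); ties go to the smaller gamma
#' (coarser, more conservative partition).
#'
#' @param partitions list from [detect_communities()].
#' @return the selected gamma.
#' @export
select_resolution <- function(partitions) {
  if (!length(partitions)) stop("no partitions")
  q <- vapply(partitions, `[[`, 0, "modularity")
  gam <- vapply(partitions, `[[`, 0, "gamma")
  min(gam[q == max(q)])
}

#' Pairwise partition stability
#'
#' Adjusted Rand Index between every pair of partitions in the list,
#' computed over the nodes labeled in both; reports fragmentation across
#' the resolution grid.
#'
#' @param partitions list from [detect_communities()] (length >= 2).
#' @return symmetric matrix of ARI values, dimnames = resolutions.
#' @export
partition_stability <- function(partitions) {
  if (length(partitions) < 2) stop("need at least 2 partitions")
  k <- length(partitions)
  out <- diag(1, k)
  gam <- vapply(partitions, `[[`, 0, "gamma")
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    a <- partitions[[i]]$labels
    b <- partitions[[j]]$labels
    ok <- !is.na(a) & !is.na(b)
    out[i, j] <- out[j, i] <- adjusted_rand_index(a[ok], b[ok])
  }
  dimnames(out) <- list(gam, gam)
  out
}

#' Adjusted Rand Index
#'
#' Chance-corrected agreement between two labelings of the same items:
#' 1 = identical partitions (up to label permutation), 0 = expected
#' agreement of a random partition.
#'
#' @param a,b label vectors of equal length.
#' @return ARI (scalar).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)   # both partitions trivial and identical in structure
  (nij - expected) / denom
}
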