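# independent oracles and fixture builders used across the suite

# random signal matrix with canonical region ids on chr1
random_sm <- function(n, m, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  rownames(x) <- sprintf("chr1:%d-%d", (1:n) * 1000L, (1:n) * 1000L + 500L)
  signal_matrix(x)
}

# brute-force Spearman: stats::cor on the raw rows
spearman_bruteforce <- function(x) {
  stats::cor(t(x), method = "spearman")
}

# brute-force graph metrics from an edge list over node ids
metrics_bruteforce <- function(edges, node_ids) {
  n <- length(node_ids)
  idx <- stats::setNames(seq_len(n), node_ids)
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    ij <- cbind(idx[edges$source_id], idx[edges$target_id])
    A[ij] <- 1; A[ij[, c(2, 1), drop = FALSE]] <- 1
  }
  deg <- rowSums(A)
  triples <- sum(deg * (deg - 1) / 2)
  tri3 <- sum(diag(A %*% A %*% A))    # 6 x triangles
  trans <- if (triples == 0) 0 else tri3 / (2 * triples)
  # components via BFS
  comp <- integer(n); cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, which(A[v, ] > 0 & comp == 0L))
    }
  }
  lcc <- max(tabulate(comp))
  list(n_edges = nrow(edges), density = nrow(edges) / (n * (n - 1) / 2),
       transitivity = trans, lcc = lcc, rlcc = lcc / n,
       n_connected = sum(deg > 0))
}

# per-base regulatory-domain oracle on a single toy chromosome: returns,
# for each base, the set of genes whose domain covers it, by direct
# evaluation of the basal + capped-extension rule
domains_perbase <- function(genes, L, basal_up = 5000, basal_down = 1000,
                            max_ext = 1e6) {
  plus <- genes$strand == "+"
  bs <- pmax(0, ifelse(plus, genes$tss - basal_up, genes$tss - basal_down))
  be <- pmin(L, ifelse(plus, genes$tss + basal_down, genes$tss + basal_up))
  cover <- vector("list", nrow(genes))
  for (k in seq_len(nrow(genes))) {
    lo <- max(0, genes$tss[k] - max_ext)
    hi <- min(L, genes$tss[k] + max_ext)
    # per-base membership of every OTHER gene's basal domain
    other <- logical(L)
    for (j in setdiff(seq_len(nrow(genes)), k))
      if (be[j] > bs[j]) other[(bs[j] + 1):be[j]] <- TRUE  # 1-based shift
    # extend left base by base until a foreign basal base blocks
    if (bs[k] - 1 < lo) s <- bs[k]
    else {
      xs <- (bs[k] - 1):lo                      # descending positions
      t <- which(other[xs + 1L])[1]
      s <- if (is.na(t)) lo else bs[k] - (t - 1L)
    }
    # extend right likewise
    if (be[k] > hi - 1) e <- be[k]
    else {
      xs <- be[k]:(hi - 1)
      t <- which(other[xs + 1L])[1]
      e <- if (is.na(t)) hi else be[k] + (t - 1L)
    }
    cover[[k]] <- c(s, e)
  }
  data.frame(gene = genes$symbol,
             start = vapply(cover, `[`, 0, 1),
             end = vapply(cover, `[`, 0, 2))
}

# exact one-sided Fisher p for a 2x2 table [[a, b], [c_, d]] by
# enumerating the hypergeometric tail P(X >= a)
fisher_enum <- function(a, b, c_, d) {
  xs <- a:min(a + b, a + c_)
  sum(stats::dhyper(xs, a + b, c_ + d, a + c_))
}
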