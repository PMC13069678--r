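#' Basal-plus-extension regulatory domains
#'
#' GREAT-style gene regulatory domains. Each gene gets a basal domain
#' `[tss - basal_up, tss + basal_down)` on the + strand (mirrored on -),
#' then the domain is extended in both directions up to `max_ext` from the
#' TSS, stopping early at the nearest neighboring basal domain, and clipped
#' to the chromosome bounds. Basal domains are always retained even when
#' they overlap a neighbor.
#'
#' @param genes data frame of gene models (`symbol`, `chrom`, `strand`,
#'   `tss`), e.g. from [read_gene_models()].
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param basal_up,basal_down basal window upstream/downstream of the TSS
#'   in bp (defaults 5000 / 1000).
#' @param max_ext maximum distance of the extension from the TSS in bp
#'   (default 1e6).
#' @return data frame with columns `gene`, `chrom`, `start`, `end`
#'   (0-based half-open extended domains).
#' @export
regulatory_domains <- function(genes, chrom_sizes, basal_up = 5000,
                               basal_down = 1000, max_ext = 1e6) {
  missing_chr <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(missing_chr))
    stop("chrom_sizes missing: ", paste(missing_chr, collapse = ", "))
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, genes$tss - basal_up, genes$tss - basal_down)
  basal_end <- ifelse(plus, genes$tss + basal_down, genes$tss + basal_up)
  L <- chrom_sizes[genes$chrom]
  if (any(genes$tss < 0 | genes$tss > L))
    stop("gene TSS beyond chromosome bounds: ",
         paste(genes$symbol[genes$tss < 0 | genes$tss > L], collapse = ", "))
  basal_start <- pmax(0, basal_start)
  basal_end <- pmin(L, basal_end)

  out <- genes[, c("symbol", "chrom"), drop = FALSE]
  names(out)[1] <- "gene"
  out$start <- NA_real_; out$end <- NA_real_
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    bs <- basal_start[idx]; be <- basal_end[idx]; tss <- genes$tss[idx]
    for (k in seq_along(idx)) {
      # nearest neighboring basal boundary on each side (strand-agnostic);
      # an overlapping neighbor basal clamps the extension to zero, the
      # basal domain itself is always kept
      left_lim <- max(c(0, be[-k][bs[-k] < bs[k]]))
      right_lim <- min(c(chrom_sizes[chr], bs[-k][be[-k] > be[k]]))
      ext_start <- max(left_lim, tss[k] - max_ext, 0)
      ext_end <- min(right_lim, tss[k] + max_ext, chrom_sizes[chr])
      out$start[idx[k]] <- min(bs[k], ext_start)
      out$end[idx[k]] <- max(be[k], ext_end)
    }
  }
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  rownames(out) <- NULL
  out
}

#' Assign target genes to regions
#'
#' A region is assigned every gene whose regulatory domain it overlaps by
#' at least 1 bp (or whose domain contains the region midpoint when
#' `midpoint = TRUE`). Regions overlapping nothing map to an empty set.
#'
#' @param regions data frame with `chrom`, `start`, `end`, `id`.
#' @param domains data frame from [regulatory_domains()].
#' @param midpoint use midpoint containment instead of 1 bp overlap.
#' @return named list: region id -> character vector of gene symbols.
#' @export
assign_targets <- function(regions, domains, midpoint = FALSE) {
  out <- stats::setNames(vector("list", nrow(regions)), regions$id)
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    di <- which(domains$chrom == chr)
    if (!length(di)) { out[ri] <- list(character()); next }
    for (k in ri) {
      s <- regions$start[k]; e <- regions$end[k]
      hit <- if (midpoint) {
        mid <- (s + e) %/% 2
        domains$start[di] <= mid & mid < domains$end[di]
      } else {
        domains$start[di] < e & s < domains$end[di]
      }
      out[[k]] <- sort(unique(domains$gene[di][hit]))
    }
  }
  out
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric test per gene set: with `N` background genes,
#' `K` of them in the set, `n` query genes and `k` in the overlap, the
#' p-value is `P(X >= k)`. Gene sets are intersected with the background
#' before testing; BH correction is applied across all tested sets.
#'
#' @param query_genes character vector (must be a subset of background
#'   after intersection; genes outside the background are dropped).
#' @param background_genes character vector, the network-node universe.
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]).
#' @param q_max report sets with BH q-value below this (default 0.05);
#'   set to `Inf` to keep all.
#' @param p_max optional raw p-value filter used instead of `q_max` when
#'   not `NULL`.
#' @return data frame with columns `term`, `k`, `K`, `n`, `N`, `fold`,
#'   `p`, `q`, sorted by `q` then decreasing fold.
#' @export
enrich_genesets <- function(query_genes, background_genes, gene_sets,
                            q_max = 0.05, p_max = NULL) {
  bg <- unique(background_genes)
  q <- unique(intersect(query_genes, bg))
  if (!length(q)) {
    warning("empty query after background intersection")
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), fold = numeric(),
                      p = numeric(), q = numeric()))
  }
  N <- length(bg); n <- length(q)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], bg)
    K <- length(set)
    if (K == 0) return(NULL)
    k <- length(intersect(q, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N,
               fold = (k / n) / (K / N), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(term = character(), k = integer(),
                                      K = integer(), n = integer(),
                                      N = integer(), fold = numeric(),
                                      p = numeric(), q = numeric()))
  out$q <- stats::p.adjust(out$p, method = "BH")
  keep <- if (is.null(p_max)) out$q < q_max else out$p < p_max
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$q, -out$fold), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genomic-class annotation fractions per community
#'
#' Assigns each region the class of its maximal-overlap annotation
#' interval (ties broken by annotation order; no overlap gives
#' `"unclassified"`), then tabulates class fractions per community.
#'
#' @param regions data frame with `chrom`, `start`, `end`, `id`.
#' @param annotation data frame with `chrom`, `start`, `end`, `name`
#'   (class label, e.g. PLS/pELS/dELS), e.g. from [read_bed()].
#' @param labels optional named community labels over region ids; when
#'   `NULL` a single pseudo-community is used.
#' @return list with `classes` (named vector region id -> class) and
#'   `fractions` (community x class matrix of fractions summing to 1 per
#'   row).
#' @export
annotate_classes <- function(regions, annotation, labels = NULL) {
  if (is.null(annotation$name) || any(!nzchar(annotation$name)))
    stop("annotation BED must carry a non-empty class label (name column)")
  cls <- rep("unclassified", nrow(regions))
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    ai <- which(annotation$chrom == chr)
    if (!length(ai)) next
    for (k in ri) {
      ov <- pmin(regions$end[k], annotation$end[ai]) -
        pmax(regions$start[k], annotation$start[ai])
      if (any(ov > 0)) {
        best <- ai[which.max(ov)]   # first index wins ties (BED order)
        cls[k] <- annotation$name[best]
      }
    }
  }
  names(cls) <- regions$id
  if (is.null(labels)) labels <- stats::setNames(rep(1L, nrow(regions)),
                                                 regions$id)
  lab <- labels[regions$id]
  tab <- table(community = lab, class = cls)
  frac <- tab / rowSums(tab)
  list(classes = cls, fractions = unclass(frac))
}

#' GIGGLE-style enrichment score
#'
#' `-log10(p) * log2(odds_ratio)`: combines the significance and the
#' magnitude of an interval-overlap enrichment.
#'
#' @param p p-value in (0, 1]; callers must floor p before the log.
#' @param odds_ratio odds ratio (> 0).
#' @return numeric score.
#' @export
giggle_score <- function(p, odds_ratio) {
  if (any(p <= 0)) stop("p = 0: floor the p-value before scoring")
  if (any(p > 1)) stop("p must be <= 1")
  if (any(odds_ratio <= 0)) stop("odds_ratio must be > 0")
  -log10(p) * log2(odds_ratio)
}

#' Score TF-binding experiments against a community
#'
#' For each TF ChIP-seq experiment BED, builds the 2x2 table of community
#' vs rest-of-universe regions by overlap (>= 1 bp) with the experiment's
#' intervals, computes the Fisher exact p-value and the sample odds ratio
#' (+0.5 Haldane-Anscombe correction when any cell is zero, p floored at
#' 1e-300), and converts them to a [giggle_score()].
#'
#' @param community_ids character vector of region ids in the community.
#' @param tf_beds named list of BED data frames (`chrom`, `start`, `end`);
#'   names of the form `"TF"` or `"TF:experiment"`.
#' @param universe data frame of all regions (`chrom`, `start`, `end`,
#'   `id`); must contain the community.
#' @return data frame with columns `tf`, `experiment`, `p`, `odds_ratio`,
#'   `score`.
#' @export
score_tf_experiments <- function(community_ids, tf_beds, universe) {
  if (!nrow(universe)) stop("empty universe")
  if (!all(community_ids %in% universe$id))
    stop("community regions missing from universe")
  in_comm <- universe$id %in% community_ids
  rows <- lapply(names(tf_beds), function(nm) {
    bed <- tf_beds[[nm]]
    ov <- overlaps_any(universe, bed)
    a <- sum(in_comm & ov); b <- sum(in_comm & !ov)
    c_ <- sum(!in_comm & ov); d <- sum(!in_comm & !ov)
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2),
                            alternative = "greater")$p.value
    p <- max(p, 1e-300)
    or <- if (any(c(a, b, c_, d) == 0))
      (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c_ + 0.5))
    else a * d / (b * c_)
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    data.frame(tf = parts[1],
               experiment = if (length(parts) > 1) parts[2] else nm,
               p = p, odds_ratio = or,
               score = giggle_score(p, or), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

overlaps_any <- function(regions, bed) {
  hit <- logical(nrow(regions))
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    bi <- which(bed$chrom == chr)
    if (!length(bi)) next
    for (k in ri)
      hit[k] <- any(bed$start[bi] < regions$end[k] &
                      regions$start[k] < bed$end[bi])
  }
  hit
}

#' Aggregate TF scores across experiments
#'
#' Mean GIGGLE score per TF over its experiments, ranked by decreasing
#' mean (ties by TF name ascending), truncated to `top_k`.
#'
#' @param table data frame from [score_tf_experiments()].
#' @param top_k number of top TFs to keep (default 10).
#' @return data frame `tf`, `mean_score`, `n_experiments`, `rank`.
#' @export
aggregate_tf <- function(table, top_k = 10) {
  if (!nrow(table)) stop("empty GIGGLE table")
  means <- tapply(table$score, table$tf, mean)
  out <- data.frame(tf = names(means), mean_score = as.vector(means),
                    n_experiments = as.vector(table(table$tf)[names(means)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_score, out$tf), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Per-community temporal trend summaries
#'
#' Z-scores each region's signal across time, then summarizes each
#' community per time point by the median and quartiles, the numbers
#' behind trend box plots.
#'
#' @param sm a [signal_matrix()] (typically replicate-averaged).
#' @param labels named community labels over region ids.
#' @return data frame with columns `community`, `time_point`, `median`,
#'   `q1`, `q3`, `n_regions`.
#' @export
community_trends <- function(sm, labels) {
  z <- zscore_rows(sm)
  comm <- unique(stats::na.omit(labels))
  comm <- comm[order(comm)]
  tps <- sort(unique(sm$samples$time_point))
  rows <- list()
  for (cc in comm) {
    ids <- intersect(names(labels)[!is.na(labels) & labels == cc],
                     sm$regions$id)
    if (!length(ids)) {
      warning("community ", cc, " absent from the matrix; skipped")
      next
    }
    zz <- z$values[ids, , drop = FALSE]
    for (t in tps) {
      vals <- as.vector(zz[, sm$samples$time_point == t, drop = FALSE])
      qs <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(community = cc, time_point = t, median = qs[2],
                   q1 = qs[1], q3 = qs[3], n_regions = length(ids))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coordinate liftover hook
#'
#' Pass-through for pre-lifted coordinates. Supplying a chain file is not
#' supported: inputs must already be on the target assembly.
#'
#' @param regions region data frame.
#' @param chain must be `NULL`.
#' @return `regions` unchanged.
#' @export
lift_regions <- function(regions, chain = NULL) {
  if (!is.null(chain))
    stop("chain-file liftover is not supported; supply pre-lifted coordinates")
  regions
}
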