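#' Planted longitudinal community design
#'
#' Describes the synthetic study: K communities of regions, each following
#' one temporal archetype on the time rank (monotone up/down, early peak,
#' transient dip, bimodal), profiled at `m` time points with replicates,
#' with Gaussian noise on the log2 scale and Poisson count sampling.
#'
#' @param n_communities number of planted communities K (default 5).
#' @param regions_per_community regions in each community (default 200).
#' @param m number of time points (default 8).
#' @param replicates replicates per time point (default 2).
#' @param noise_sd standard deviation of the log2-scale Gaussian noise
#'   (default 0.2).
#' @param archetypes character vector of trend names, one used per
#'   community, from `"up"`, `"down"`, `"early_peak"`, `"transient_dip"`,
#'   `"bimodal"`; recycled shapes are not allowed (need >= K).
#' @param batch_shift optional numeric vector of per-batch log2 offsets;
#'   when given, replicates are assigned round-robin to batches.
#' @param n_decoys number of noise-only decoy regions placed on chrX, so
#'   the chromosome filter is exercised (default 50).
#' @param base_log2 baseline log2 expected count (default 8, i.e. ~256
#'   counts), a typical coverage for accessible regions.
#' @param seed RNG seed (default 7).
#' @return list of class `"planted_design"`.
#' @export
planted_design <- function(n_communities = 5, regions_per_community = 200,
                           m = 8, replicates = 2, noise_sd = 0.2,
                           archetypes = c("up", "down", "early_peak",
                                          "transient_dip", "bimodal"),
                           batch_shift = NULL, n_decoys = 50,
                           base_log2 = 8, seed = 7) {
  if (n_communities < 1) stop("need at least one community")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(archetypes) < n_communities)
    stop("need at least one archetype per community")
  structure(list(n_communities = n_communities,
                 regions_per_community = regions_per_community,
                 m = m, replicates = replicates, noise_sd = noise_sd,
                 archetypes = archetypes[seq_len(n_communities)],
                 batch_shift = batch_shift, n_decoys = n_decoys,
                 base_log2 = base_log2, seed = seed),
            class = "planted_design")
}

# trend archetypes on the time rank, scaled to unit range [0, 1]
archetype_profile <- function(name, m) {
  t <- seq(0, 1, length.out = m)
  y <- switch(name,
    up = t,
    down = 1 - t,
    early_peak = exp(-((t - 0.2) / 0.18)^2),
    transient_dip = 1 - exp(-((t - 0.45) / 0.18)^2),
    bimodal = (exp(-((t - 0.1) / 0.12)^2) + exp(-((t - 0.8) / 0.15)^2)),
    stop("unknown archetype: ", name))
  (y - min(y)) / (max(y) - min(y))
}

#' Simulate a planted longitudinal count matrix
#'
#' Region `i` in community `c` has expected log2 signal
#' `base_log2 + archetype_c(t)` (unit-range archetype on the time rank),
#' plus i.i.d. Gaussian noise (`noise_sd`) per observation, plus the batch
#' shift of its batch; the expectation is exponentiated and Poisson-sampled
#' to raw counts. Regions are laid out on two autosomes; `n_decoys`
#' pure-noise regions go on chrX to exercise the chromosome filter.
#'
#' @param design a [planted_design()].
#' @return list with `sm` (raw-count [signal_matrix()]), `truth` (named
#'   integer labels over planted region ids; decoys are absent), and
#'   `design`.
#' @export
simulate_signal <- function(design) {
  set.seed(design$seed)
  K <- design$n_communities
  npc <- design$regions_per_community
  m <- design$m; reps <- design$replicates
  n <- K * npc
  n_cols <- m * reps

  profiles <- vapply(design$archetypes, archetype_profile, numeric(m),
                     m = m)
  comm <- rep(seq_len(K), each = npc)
  mu_log <- design$base_log2 + t(profiles[, comm, drop = FALSE])
  mu_log <- mu_log[, rep(seq_len(m), each = reps), drop = FALSE]

  batch <- rep("b1", n_cols)
  if (!is.null(design$batch_shift)) {
    nb <- length(design$batch_shift)
    batch <- paste0("b", rep_len(seq_len(nb), reps))[
      rep(seq_len(reps), times = m)]
    shift <- design$batch_shift[as.integer(sub("b", "", batch))]
    mu_log <- sweep(mu_log, 2, shift, "+")
  }
  noise <- matrix(stats::rnorm(n * n_cols, sd = design$noise_sd), n, n_cols)
  lam <- 2^(mu_log + noise)
  counts <- matrix(stats::rpois(n * n_cols, as.vector(lam)), n, n_cols)

  if (design$n_decoys > 0) {
    dl <- matrix(stats::rnorm(design$n_decoys * n_cols, sd = design$noise_sd),
                 design$n_decoys, n_cols) + design$base_log2
    counts <- rbind(counts, matrix(stats::rpois(design$n_decoys * n_cols,
                                                as.vector(2^dl)),
                                   design$n_decoys, n_cols))
  }

  regions <- synthetic_regions(n, design$n_decoys)
  tp <- rep(seq_len(m), each = reps)
  samples <- data.frame(
    sample_id = sprintf("t%02d_r%d", tp, rep(seq_len(reps), times = m)),
    time_point = tp,
    replicate = paste0("r", rep(seq_len(reps), times = m)),
    batch = batch, stringsAsFactors = FALSE)
  sm <- signal_matrix(counts, regions = regions, samples = samples)
  truth <- stats::setNames(comm, regions$id[seq_len(n)])
  list(sm = sm, truth = truth, design = design)
}

# planted regions alternate between chr1 and chr2 in 1 kb windows spaced
# 10 kb apart; decoys sit on chrX
synthetic_regions <- function(n, n_decoys) {
  chrom <- rep(c("chr1", "chr2"), length.out = n)
  slot <- unlist(lapply(c("chr1", "chr2"), function(ch) {
    k <- sum(chrom == ch); seq_len(k)
  }))
  slot_by <- integer(n)
  slot_by[chrom == "chr1"] <- seq_len(sum(chrom == "chr1"))
  slot_by[chrom == "chr2"] <- seq_len(sum(chrom == "chr2"))
  start <- (slot_by - 1L) * 10000L + 1000L
  regions <- data.frame(chrom = chrom, start = start, end = start + 1000L,
                        stringsAsFactors = FALSE)
  if (n_decoys > 0) {
    ds <- (seq_len(n_decoys) - 1L) * 10000L + 1000L
    regions <- rbind(regions,
                     data.frame(chrom = "chrX", start = ds, end = ds + 1000L,
                                stringsAsFactors = FALSE))
  }
  regions$id <- region_id(regions$chrom, regions$start, regions$end)
  regions
}

#' Simulate matching annotation resources
#'
#' Builds gene models, gene sets, a genomic-class annotation BED and TF
#' experiment BEDs that align with the planted communities: each community
#' gets a dedicated set of genes whose regulatory domains cover its
#' regions (making that gene set the expected top enrichment) and a
#' dedicated TF whose intervals overlap a fraction `tf_hit` of the
#' community's regions but only `tf_bg` of the rest (making that TF the
#' expected top-scoring one).
#'
#' @param sim output of [simulate_signal()].
#' @param genes_per_community genes planted per community (default 20).
#' @param tf_hit fraction of a community's regions overlapped by its
#'   planted TF (default 1.0).
#' @param tf_bg fraction of non-community regions overlapped (default
#'   0.05).
#' @return list with `genes` (gene-model data frame), `gene_sets` (named
#'   list), `classes` (annotation BED data frame), `tf_beds` (named list
#'   of BED data frames, one per planted TF), `chrom_sizes`.
#' @export
simulate_annotations <- function(sim, genes_per_community = 20,
                                 tf_hit = 1.0, tf_bg = 0.05) {
  set.seed(sim$design$seed + 1L)
  truth <- sim$truth
  regions <- sim$sm$regions
  planted <- regions[regions$id %in% names(truth), , drop = FALSE]
  K <- sim$design$n_communities
  chrom_sizes <- c(chr1 = max(planted$end[planted$chrom == "chr1"]) + 1e4,
                   chr2 = max(planted$end[planted$chrom == "chr2"]) + 1e4,
                   chrX = 1e7)

  # one gene right next to every (genes_per_community)-th region of each
  # community: its basal domain covers that region, so assignment is exact
  genes <- list(); gene_sets <- list()
  for (cc in seq_len(K)) {
    ids <- names(truth)[truth == cc]
    pick <- planted[planted$id %in% ids, , drop = FALSE]
    pick <- pick[seq_len(min(genes_per_community, nrow(pick))), ,
                 drop = FALSE]
    sym <- sprintf("C%dG%d", cc, seq_len(nrow(pick)))
    genes[[cc]] <- data.frame(symbol = sym, chrom = pick$chrom,
                              strand = "+",
                              tss = pick$start + 100L,
                              stringsAsFactors = FALSE)
    gene_sets[[sprintf("SET_COMMUNITY_%d", cc)]] <- sym
  }
  genes <- do.call(rbind, genes)

  # decoy gene sets: random draws from all planted genes
  all_sym <- genes$symbol
  for (d in seq_len(K)) {
    gene_sets[[sprintf("SET_DECOY_%d", d)]] <-
      sample(all_sym, min(length(all_sym), genes_per_community))
  }

  # class annotation: promoters (PLS) near gene TSS, the rest dELS
  classes <- rbind(
    data.frame(chrom = genes$chrom, start = pmax(0L, genes$tss - 200L),
               end = genes$tss + 200L, name = "PLS",
               stringsAsFactors = FALSE),
    data.frame(chrom = planted$chrom, start = planted$start,
               end = planted$end, name = "dELS", stringsAsFactors = FALSE))

  tf_beds <- list()
  for (cc in seq_len(K)) {
    own <- planted[planted$id %in% names(truth)[truth == cc], , drop = FALSE]
    other <- planted[!(planted$id %in% own$id), , drop = FALSE]
    n_hit <- ceiling(tf_hit * nrow(own))
    n_bg <- ceiling(tf_bg * nrow(other))
    hit <- own[seq_len(n_hit), , drop = FALSE]
    bg <- other[sample(nrow(other), n_bg), , drop = FALSE]
    peaks <- rbind(hit, bg)[, c("chrom", "start", "end")]
    # TF peak = 200 bp window inside the region
    peaks$start <- peaks$start + 400L
    peaks$end <- peaks$start + 200L
    tf_beds[[sprintf("TF%d:exp1", cc)]] <- peaks
  }

  list(genes = genes, gene_sets = gene_sets, classes = classes,
       tf_beds = tf_beds, chrom_sizes = chrom_sizes)
}

#' Write simulation outputs to a directory
#'
#' Emits `matrix.tsv`, `meta.tsv`, `regions.bed`, `truth.tsv`,
#' `genes.tsv`, `sets.gmt`, `classes.bed` and `tf_beds/` in the plain-text
#' layout the readers of this package accept.
#'
#' @param sim output of [simulate_signal()].
#' @param ann output of [simulate_annotations()]; optional.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_simulation <- function(sim, ann = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_signal_matrix(sim$sm, dir)
  utils::write.table(
    data.frame(region_id = names(sim$truth), community = sim$truth),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(ann)) {
    utils::write.table(ann$genes, file.path(dir, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gmt(ann$gene_sets, file.path(dir, "sets.gmt"))
    utils::write.table(ann$classes, file.path(dir, "classes.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    tfd <- file.path(dir, "tf_beds")
    dir.create(tfd, showWarnings = FALSE)
    for (nm in names(ann$tf_beds)) {
      fn <- file.path(tfd, paste0(gsub(":", "_", nm), ".bed"))
      utils::write.table(ann$tf_beds[[nm]], fn, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}
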