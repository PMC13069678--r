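#' Read and validate a run configuration
#'
#' A single YAML document holding every stage's parameters. Unknown keys
#' are rejected; defaults are the method's standard settings (p-value 0.1,
#' resolution grid 0.5-1.5 step 0.1, step size 1e5, seed 42).
#'
#' @param path YAML file path, or a named list already in memory.
#' @return validated config list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    matrix = NULL, meta = NULL, bed = NULL,
    prior = 0.5, batch_correct = FALSE,
    drop_chroms = c("chrX", "chrY"), min_variance = 0.1,
    low_q = NULL, high_q = NULL, average_replicates = TRUE,
    threshold_mode = "pval", threshold_value = 0.1,
    chunk_size = 1000, step_size = 1e5, workers = 1,
    edge_sign = "positive", format = "parquet",
    tau = NULL, res_min = 0.5, res_max = 1.5, res_step = 0.1,
    seed = 42, include_disconnected = TRUE,
    genes = NULL, gmt = NULL, classes = NULL, tf_beds = NULL,
    q_max = 0.05, p_max = NULL, top_k = 10, out = "chronet_out")
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  if (!out$threshold_mode %in% c("pval", "corr"))
    stop("threshold_mode must be 'pval' or 'corr'")
  structure(out, class = "run_config")
}

#' Run the full pipeline
#'
#' Executes preprocess (log-CPM, optional batch correction, chromosome /
#' variance filters, replicate averaging), network construction, threshold
#' series with automatic tau selection, community detection with automatic
#' resolution selection, and (when annotation inputs are configured)
#' community characterization. A run manifest with the seed, selected
#' parameters and output checksums is written to the output directory.
#'
#' @param config a `"run_config"` (or path / list accepted by
#'   [read_run_config()]).
#' @return invisibly, a list with the fitted [chronet] object, the
#'   preprocessed matrix, annotation results (or NULL) and the manifest.
#' @export
run_all <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  if (is.null(cfg$matrix) || is.null(cfg$meta))
    stop("stage preprocess: config needs 'matrix' and 'meta' paths")
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    message(sprintf("[%s] running", name))
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  raw <- stage("read", read_counts(cfg$matrix, cfg$meta, cfg$bed))
  sm <- stage("preprocess", {
    x <- log_cpm(raw, prior = cfg$prior)
    if (isTRUE(cfg$batch_correct)) x <- remove_batch_effect(x)
    x <- filter_regions(x, drop_chroms = unlist(cfg$drop_chroms),
                        min_variance = cfg$min_variance,
                        low_q = cfg$low_q, high_q = cfg$high_q)
    if (isTRUE(cfg$average_replicates)) x <- average_replicates(x)
    if (ncol(x$values) < 3)
      stop("need at least 3 samples after preprocessing (df = m - 2 >= 1)")
    x
  })

  fit <- stage("network", chronet(
    sm,
    threshold = threshold_config(cfg$threshold_mode, cfg$threshold_value,
                                 m = ncol(sm$values)),
    plan = batch_plan(cfg$chunk_size, cfg$step_size, cfg$workers),
    store_dir = file.path(cfg$out, "edgestore"),
    tau = cfg$tau,
    resolutions = seq(cfg$res_min, cfg$res_max, by = cfg$res_step),
    seed = cfg$seed, include_disconnected = cfg$include_disconnected,
    edge_sign = cfg$edge_sign, format = cfg$format))

  lab_path <- file.path(cfg$out, "labels.tsv")
  utils::write.table(
    data.frame(region_id = names(fit$labels), community = fit$labels),
    lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fit$series, file.path(cfg$out, "series.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ann <- NULL
  if (!is.null(cfg$genes)) {
    ann <- stage("annotate",
                 annotate_communities(sm, fit$labels, cfg))
    save_annotation(ann, cfg$out)
  }

  manifest <- list(
    seed = cfg$seed, tau = fit$tau, gamma = fit$gamma,
    modularity = fit$modularity,
    n_regions = nrow(sm$values), n_samples = ncol(sm$values),
    n_communities = length(unique(stats::na.omit(fit$labels))),
    labels_md5 = unname(tools::md5sum(lab_path)))
  jsonlite::write_json(manifest, file.path(cfg$out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, sm = sm, annotation = ann, manifest = manifest))
}

# characterize every community: trends, targets, enrichment, classes, TF
annotate_communities <- function(sm, labels, cfg) {
  genes <- read_gene_models(cfg$genes)
  chrom_sizes <- infer_chrom_sizes(sm$regions, genes)
  domains <- regulatory_domains(genes, chrom_sizes)
  targets <- assign_targets(sm$regions, domains)
  background <- sort(unique(unlist(targets)))
  gene_sets <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
  class_bed <- if (!is.null(cfg$classes)) read_bed(cfg$classes) else NULL
  tf_beds <- if (!is.null(cfg$tf_beds)) read_tf_beds(cfg$tf_beds) else NULL

  comm <- sort(unique(stats::na.omit(labels[sm$regions$id])))
  per_comm <- lapply(comm, function(cc) {
    ids <- names(labels)[!is.na(labels) & labels == cc]
    ids <- intersect(ids, sm$regions$id)
    res <- list(community = cc,
                targets = sort(unique(unlist(targets[ids]))))
    if (!is.null(gene_sets))
      res$enrichment <- enrich_genesets(res$targets, background, gene_sets,
                                        q_max = cfg$q_max, p_max = cfg$p_max)
    if (!is.null(tf_beds))
      res$tf <- aggregate_tf(
        score_tf_experiments(ids, tf_beds, sm$regions), top_k = cfg$top_k)
    res
  })
  names(per_comm) <- paste0("community_", comm)
  out <- list(communities = per_comm,
              trends = community_trends(sm, labels))
  if (!is.null(class_bed))
    out$classes <- annotate_classes(sm$regions, class_bed,
                                    labels[sm$regions$id])
  out
}

save_annotation <- function(ann, out_dir) {
  dir.create(file.path(out_dir, "annotation"), showWarnings = FALSE)
  utils::write.table(ann$trends,
                     file.path(out_dir, "annotation", "trends.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(ann$communities)) {
    cc <- ann$communities[[nm]]
    if (!is.null(cc$enrichment))
      utils::write.table(cc$enrichment,
                         file.path(out_dir, "annotation",
                                   paste0(nm, "_enrichment.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cc$tf))
      utils::write.table(cc$tf,
                         file.path(out_dir, "annotation",
                                   paste0(nm, "_tf.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

read_tf_beds <- function(dir) {
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  if (!length(files)) stop("no .bed files in ", dir)
  beds <- lapply(files, read_bed)
  names(beds) <- sub("_([^_]+)$", ":\\1",
                     tools::file_path_sans_ext(basename(files)))
  beds
}

infer_chrom_sizes <- function(regions, genes) {
  chroms <- union(unique(regions$chrom), unique(genes$chrom))
  vapply(chroms, function(ch) {
    m <- max(c(regions$end[regions$chrom == ch],
               genes$tss[genes$chrom == ch] + 1, 0))
    m + 1e4
  }, numeric(1))
}
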