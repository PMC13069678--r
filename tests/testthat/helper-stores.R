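# write an edge store with a prescribed edge list through the package's own
# bin writer, so graph-level operations can be tested on known topologies
store_from_edges <- function(edges, node_ids, dir, r_min = 0.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bins <- seq(chronet:::bin_floor(r_min), 0.9, by = 0.1)
  counts <- integer(length(bins))
  for (b in seq_along(bins)) {
    lo <- bins[b]
    sel <- if (nrow(edges)) {
      round(edges$rho, 12) >= lo &
        (round(edges$rho, 12) < lo + 0.1 | lo == 0.9)
    } else logical(0)
    df <- edges[sel, c("source_id", "target_id", "rho"), drop = FALSE]
    df <- df[order(df$source_id, df$target_id, method = "radix"), ,
             drop = FALSE]
    rownames(df) <- NULL
    counts[b] <- nrow(df)
    chronet:::write_bin(df, dir, lo, "parquet")
  }
  manifest <- list(n = length(node_ids), m = 8, mode = "corr",
                   value = r_min, r_min = r_min, edge_sign = "positive",
                   format = "parquet",
                   bins = data.frame(lo = bins, hi = bins + 0.1,
                                     count = counts),
                   node_ids = node_ids)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  edge_store(dir)
}

clique_edges <- function(nodes, rho = 0.9) {
  p <- t(combn(nodes, 2))
  data.frame(source_id = pmin(p[, 1], p[, 2]),
             target_id = pmax(p[, 1], p[, 2]), rho = rho,
             stringsAsFactors = FALSE)
}

make_net <- function(edges, nodes, dir) {
  st <- store_from_edges(edges, nodes, dir)
  materialize(st, st$manifest$r_min)
}
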