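test_that("materialize retains all nodes and the thresholded weighted edges", {
  d <- withr::local_tempdir()
  sm <- random_sm(60, 8, seed = 31)
  st <- build_network(sm, threshold_config("corr", 0.5),
                      out = file.path(d, "s"))
  net <- materialize(st, 0.5)
  expect_equal(igraph::vcount(net$graph), 60)
  expect_equal(igraph::ecount(net$graph), nrow(load_edges(st, 0.5)))
  # threshold above the maximum: edgeless but all nodes present
  net0 <- materialize(st, 0.999)
  expect_equal(igraph::vcount(net0$graph), 60)
  expect_equal(igraph::ecount(net0$graph), 0)
  # isomorphic to brute-force construction: same weighted edge set
  e <- load_edges(st, 0.7)
  net7 <- materialize(st, 0.7)
  got <- igraph::as_data_frame(net7$graph)
  expect_setequal(
    paste(pmin(got$from, got$to), pmax(got$from, got$to),
          round(got$weight, 10)),
    paste(pmin(e$source_id, e$target_id),
          pmax(e$source_id, e$target_id), round(e$rho, 10)))
})

test_that("network_modularity matches closed forms and the igraph oracle", {
  d <- withr::local_tempdir()
  # one community: Q = 0
  net <- make_net(clique_edges(letters[1:5]), letters[1:5],
                  file.path(d, "k5"))
  one <- setNames(rep(1, 5), letters[1:5])
  expect_equal(network_modularity(net, one), 0, tolerance = 1e-12)
  # two disjoint equal cliques, each its own community: Q = 0.5
  nodes <- letters[1:8]
  e2 <- rbind(clique_edges(letters[1:4], 1), clique_edges(letters[5:8], 1))
  net2 <- make_net(e2, nodes, file.path(d, "cc"))
  lab2 <- setNames(rep(1:2, each = 4), nodes)
  expect_equal(network_modularity(net2, lab2), 0.5, tolerance = 1e-12)
  # random weighted graphs, random labels: igraph reference within 1e-10
  set.seed(41)
  for (rep in 1:10) {
    n <- 25
    nn <- sprintf("v%02d", 1:n)
    p <- t(combn(nn, 2))
    keep <- runif(nrow(p)) < 0.15
    edges <- data.frame(source_id = p[keep, 1], target_id = p[keep, 2],
                        rho = runif(sum(keep), 0.5, 1),
                        stringsAsFactors = FALSE)
    netr <- make_net(edges, nn, file.path(d, paste0("r", rep)))
    lab <- setNames(sample(1:4, n, replace = TRUE), nn)
    gamma <- sample(c(0.7, 1, 1.3), 1)
    got <- network_modularity(netr, lab, gamma = gamma)
    deg <- igraph::degree(netr$graph)
    conn <- deg > 0
    ref <- igraph::modularity(
      igraph::induced_subgraph(netr$graph, which(conn)),
      membership = lab[igraph::V(netr$graph)$name[conn]],
      weights = igraph::E(igraph::induced_subgraph(netr$graph,
                                                   which(conn)))$weight,
      resolution = gamma)
    expect_equal(got, ref, tolerance = 1e-10)
  }
  # edgeless graph errors
  st0 <- store_from_edges(
    data.frame(source_id = character(), target_id = character(),
               rho = numeric()), letters[1:3], file.path(d, "e0"))
  net0 <- materialize(st0, 0.5)
  expect_error(network_modularity(net0, setNames(1:3, letters[1:3])),
               "edgeless")
})

test_that("detect_communities recovers planted structure deterministically", {
  d <- withr::local_tempdir()
  # two 10-cliques joined by one bridge: 2 communities at every gamma
  n1 <- sprintf("a%02d", 1:10); n2 <- sprintf("b%02d", 1:10)
  edges <- rbind(clique_edges(n1, 0.9), clique_edges(n2, 0.9),
                 data.frame(source_id = "a10", target_id = "b01",
                            rho = 0.9, stringsAsFactors = FALSE))
  net <- make_net(edges, c(n1, n2), file.path(d, "2c"))
  parts <- detect_communities(net, community_config())
  for (p in parts) {
    expect_equal(length(unique(p$labels)), 2)
    expect_equal(unname(length(unique(p$labels[n1]))), 1)
    expect_equal(unname(length(unique(p$labels[n2]))), 1)
  }
  # the 2-community split is the exhaustive modularity optimum among
  # balanced cuts: compare against the all-in-one and random partitions
  q2 <- network_modularity(net, parts[[6]]$labels)
  expect_gt(q2, network_modularity(net, setNames(rep(1, 20), c(n1, n2))))

  # single clique at gamma 1: one community
  netk <- make_net(clique_edges(letters[1:6], 0.9), letters[1:6],
                   file.path(d, "k6"))
  pk <- detect_communities(netk, community_config(resolutions = 1))
  expect_equal(length(unique(pk[[1]]$labels)), 1)

  # determinism under a fixed seed
  p1 <- detect_communities(net, community_config(seed = 42))
  p2 <- detect_communities(net, community_config(seed = 42))
  expect_identical(lapply(p1, `[[`, "labels"), lapply(p2, `[[`, "labels"))

  # community ids are dense, 1 = largest
  sizes <- parts[[6]]$sizes
  expect_equal(sort(as.integer(names(sizes))), seq_along(sizes))
  expect_true(all(diff(sizes[order(as.integer(names(sizes)))]) <= 0))
})

test_that("isolated nodes become a trailing 'disconnected' community when asked", {
  d <- withr::local_tempdir()
  nodes <- c(letters[1:6], "x", "y")
  net <- make_net(clique_edges(letters[1:6], 0.9), nodes,
                  file.path(d, "iso"))
  keep <- detect_communities(net, community_config(
    resolutions = 1, include_disconnected = TRUE))[[1]]
  expect_false(anyNA(keep$labels))
  expect_equal(unname(keep$labels["x"]), unname(keep$labels["y"]))
  expect_equal(unname(keep$labels["x"]), max(keep$labels))
  expect_equal(sum(keep$sizes), 8)
  drop <- detect_communities(net, community_config(
    resolutions = 1, include_disconnected = FALSE))[[1]]
  expect_true(all(is.na(drop$labels[c("x", "y")])))
  expect_equal(sum(drop$sizes), 6)
})

test_that("select_resolution maximizes gamma=1 modularity with ties to smaller gamma", {
  mk <- function(gam, q) Map(function(g, qq)
    list(gamma = g, modularity = qq), gam, q)
  expect_equal(select_resolution(mk(c(0.9, 1.0, 1.1), c(0.30, 0.41, 0.39))),
               1.0)
  expect_equal(select_resolution(mk(c(0.5, 1.0, 1.5), c(0.4, 0.4, 0.4))),
               0.5)
  expect_error(select_resolution(list()), "no partitions")
})

test_that("partition stability and ARI behave as closed forms require", {
  a <- setNames(c(1, 1, 2, 2, 3), letters[1:5])
  perm <- setNames(c(7, 7, 5, 5, 9), letters[1:5])   # same partition, new names
  singletons <- setNames(1:5, letters[1:5])
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, perm), 1)
  expect_equal(adjusted_rand_index(setNames(rep(1, 5), letters[1:5]),
                                   singletons), 0)
  skip_if_not_installed("mclust")
  set.seed(51)
  for (rep in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})

test_that("stability matrix is symmetric with unit diagonal", {
  parts <- list(
    list(gamma = 0.5, labels = setNames(c(1, 1, 2, 2), letters[1:4])),
    list(gamma = 1.0, labels = setNames(c(1, 1, 2, 2), letters[1:4])),
    list(gamma = 1.5, labels = setNames(c(1, 2, 3, 4), letters[1:4])))
  s <- partition_stability(parts)
  expect_equal(dim(s), c(3, 3))
  expect_equal(diag(s), rep(1, 3), ignore_attr = TRUE)
  expect_equal(s[1, 2], 1)
  expect_equal(s, t(s))
})
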