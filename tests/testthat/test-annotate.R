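test_that("regulatory_domains reproduces the capped-extension closed forms", {
  # single + strand gene, no neighbors: domain = [tss - 1e6, tss + 1e6)
  g <- data.frame(symbol = "G1", chrom = "chr1", strand = "+", tss = 2e6)
  d <- regulatory_domains(g, c(chr1 = 1e7))
  expect_equal(d$start, 1e6)
  expect_equal(d$end, 3e6)

  # two + strand genes 10 kb apart: extension stops at the neighbor basal
  g2 <- data.frame(symbol = c("A", "B"), chrom = "chr1", strand = "+",
                   tss = c(100000, 110000))
  d2 <- regulatory_domains(g2, c(chr1 = 1e7))
  # A basal [95000, 101000); B basal [105000, 111000)
  expect_equal(d2$end[d2$gene == "A"], 105000)    # stops at B's basal start
  expect_equal(d2$start[d2$gene == "B"], 101000)  # stops at A's basal end
  # outward extensions still reach the 1 Mb cap (clipped at 0)
  expect_equal(d2$start[d2$gene == "A"], 0)
  expect_equal(d2$end[d2$gene == "B"], 110000 + 1e6)

  # minus strand mirrors the basal window
  gm <- data.frame(symbol = "M", chrom = "chr1", strand = "-", tss = 50000)
  dm <- regulatory_domains(gm, c(chr1 = 6e4), max_ext = 1e4)
  expect_equal(dm$start, 40000)   # tss - max_ext
  expect_equal(dm$end, 6e4)       # clipped at chromosome end

  expect_error(regulatory_domains(
    data.frame(symbol = "X", chrom = "chr1", strand = "+", tss = 2e6),
    c(chr1 = 1e6)), "beyond chromosome")
})

test_that("regulatory_domains and assign_targets match the per-base oracle", {
  set.seed(61)
  L <- 100000
  for (rep in 1:5) {
    ng <- sample(3:6, 1)
    genes <- data.frame(symbol = paste0("g", seq_len(ng)), chrom = "chr1",
                        strand = sample(c("+", "-"), ng, replace = TRUE),
                        tss = sort(sample(5000:95000, ng)))
    dom <- regulatory_domains(genes, c(chr1 = L), basal_up = 2000,
                              basal_down = 500, max_ext = 20000)
    oracle <- domains_perbase(genes, L, basal_up = 2000, basal_down = 500,
                              max_ext = 20000)
    expect_equal(dom$start, oracle$start[match(dom$gene, oracle$gene)])
    expect_equal(dom$end, oracle$end[match(dom$gene, oracle$gene)])

    # random regions: >= 1 bp overlap assignment equals interval checks
    rs <- sort(sample(0:(L - 500), 30))
    regions <- data.frame(chrom = "chr1", start = rs, end = rs + 400)
    regions$id <- region_id(regions$chrom, regions$start, regions$end)
    got <- assign_targets(regions, dom)
    for (k in seq_len(nrow(regions))) {
      want <- sort(dom$gene[dom$start < regions$end[k] &
                              regions$start[k] < dom$end])
      expect_equal(got[[regions$id[k]]], want)
    }
  }
})

test_that("assign_targets handles containment, spanning, and empty cases", {
  dom <- data.frame(gene = c("A", "B"), chrom = "chr1",
                    start = c(0, 1000), end = c(1000, 2000))
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(100, 900, 0), end = c(200, 1100, 100))
  regions$id <- region_id(regions$chrom, regions$start, regions$end)
  got <- assign_targets(regions, dom)
  expect_equal(got[[1]], "A")
  expect_equal(got[[2]], c("A", "B"))       # spans both domains
  expect_equal(got[[3]], character(0))      # nothing on chr2
  # midpoint containment mode
  mid <- assign_targets(regions, dom, midpoint = TRUE)
  expect_equal(mid[[2]], "B")               # midpoint 1000 is in [1000, 2000)
})

test_that("enrich_genesets matches exact hypergeometric combinatorics", {
  bg <- paste0("g", 1:20)
  sets <- list(T1 = paste0("g", 1:10))
  query <- paste0("g", 1:5)
  out <- enrich_genesets(query, bg, sets, q_max = Inf)
  # all 5 query genes inside the 10-gene term: p = C(10,5)/C(20,5)
  expect_equal(out$p, choose(10, 5) / choose(20, 5), tolerance = 1e-12)
  expect_equal(out$p, 252 / 15504, tolerance = 1e-12)
  expect_equal(out$k, 5); expect_equal(out$K, 10)
  expect_equal(out$fold, (5 / 5) / (10 / 20))

  # query = background: k = K and the upper tail P(X >= K) = 1
  full <- enrich_genesets(bg, bg, sets, q_max = Inf)
  expect_equal(full$k, full$K)
  expect_equal(full$p, 1)
  expect_equal(full$fold, 1)

  # disjoint term: k = 0, p = 1
  disj <- enrich_genesets(paste0("g", 1:5), bg,
                          list(D = paste0("g", 11:15)), q_max = Inf)
  expect_equal(disj$k, 0)
  expect_equal(disj$p, 1)

  # uniform draws from the background are not significant (type I control)
  set.seed(71)
  n_sig <- 0
  for (rep in 1:100) {
    q <- sample(bg, 5)
    r <- enrich_genesets(q, bg, sets, q_max = Inf)
    if (r$p < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 12)   # nominal 5% with simulation slack

  expect_warning(enrich_genesets(character(), bg, sets), "empty query")
})

test_that("annotate_classes uses maximal overlap and fractions sum to one", {
  ann <- data.frame(chrom = "chr1", start = c(0, 140), end = c(150, 400),
                    name = c("PLS", "dELS"))
  regions <- data.frame(chrom = "chr1", start = c(10, 100, 900),
                        end = c(100, 190, 950))
  regions$id <- region_id(regions$chrom, regions$start, regions$end)
  out <- annotate_classes(regions, ann)
  # region 2 overlaps PLS and dELS by 50 bp each: tie -> first BED row
  expect_equal(unname(out$classes), c("PLS", "PLS", "unclassified"))
  ann2 <- data.frame(chrom = "chr1", start = c(0, 150), end = c(150, 400),
                     name = c("PLS", "dELS"))
  regions2 <- data.frame(chrom = "chr1", start = 140, end = 160)
  regions2$id <- region_id(regions2$chrom, regions2$start, regions2$end)
  # 10 bp PLS vs 10 bp dELS: first wins
  expect_equal(unname(annotate_classes(regions2, ann2)$classes), "PLS")
  # maximal-overlap rule: 10 bp PLS vs 50 bp dELS
  regions3 <- data.frame(chrom = "chr1", start = 140, end = 200)
  regions3$id <- region_id(regions3$chrom, regions3$start, regions3$end)
  expect_equal(unname(annotate_classes(regions3, ann2)$classes), "dELS")

  # brute-force fractions on random communities
  set.seed(81)
  rs <- sort(sample(0:5000, 40)) * 10
  regions4 <- data.frame(chrom = "chr1", start = rs, end = rs + 80)
  regions4$id <- region_id(regions4$chrom, regions4$start, regions4$end)
  ann4 <- data.frame(chrom = "chr1",
                     start = sort(sample(0:5e4, 15)),
                     end = 0, name = sample(c("PLS", "pELS", "dELS"), 15,
                                            replace = TRUE))
  ann4$end <- ann4$start + sample(50:500, 15)
  labels <- setNames(sample(1:3, 40, replace = TRUE), regions4$id)
  out4 <- annotate_classes(regions4, ann4, labels)
  expect_lt(max(abs(rowSums(out4$fractions) - 1)), 1e-12)
  # quadratic sweep oracle for the per-region class
  for (k in seq_len(nrow(regions4))) {
    ov <- pmin(regions4$end[k], ann4$end) - pmax(regions4$start[k], ann4$start)
    want <- if (all(ov <= 0)) "unclassified" else ann4$name[which.max(ov)]
    expect_equal(unname(out4$classes[k]), want)
  }
})

test_that("giggle_score follows -log10(p) * log2(OR) and its monotonicities", {
  expect_equal(giggle_score(0.01, 4), 4)
  expect_equal(giggle_score(0.5, 1), 0)
  expect_equal(giggle_score(1, 7), 0)
  expect_error(giggle_score(0, 2), "floor")
  ors <- c(1.5, 2, 4, 8)
  expect_true(all(diff(giggle_score(0.01, ors)) > 0))
  ps <- c(0.2, 0.05, 0.001)
  expect_true(all(diff(giggle_score(ps, 4)) > 0))
})

test_that("score_tf_experiments matches the exact 2x2 enumeration oracle", {
  # 10 community + 30 background regions on a line
  starts <- (0:39) * 1000
  universe <- data.frame(chrom = "chr1", start = starts, end = starts + 500)
  universe$id <- region_id(universe$chrom, universe$start, universe$end)
  comm <- universe$id[1:10]
  # experiment hits 8 community regions and 3 background regions
  hit_rows <- c(1:8, 15, 20, 25)
  bed <- data.frame(chrom = "chr1", start = starts[hit_rows] + 100,
                    end = starts[hit_rows] + 200)
  tab <- score_tf_experiments(comm, list("TFA:e1" = bed), universe)
  a <- 8; b <- 2; c_ <- 3; d <- 27
  expect_equal(tab$p, fisher_enum(a, b, c_, d), tolerance = 1e-12)
  expect_equal(tab$odds_ratio, a * d / (b * c_))
  expect_equal(tab$score, giggle_score(tab$p, tab$odds_ratio))

  # zero cell: Haldane-Anscombe corrected odds ratio
  bed_all <- data.frame(chrom = "chr1", start = starts[1:10] + 100,
                        end = starts[1:10] + 200)
  t2 <- score_tf_experiments(comm, list("TFB:e1" = bed_all), universe)
  expect_equal(t2$odds_ratio, (10.5 * 30.5) / (0.5 * 0.5))

  # equal overlap fractions: OR ~ 1, score ~ 0
  bed_eq <- data.frame(chrom = "chr1",
                       start = starts[c(1:5, 11:25)] + 100,
                       end = starts[c(1:5, 11:25)] + 200)
  t3 <- score_tf_experiments(comm, list("TFC:e1" = bed_eq), universe)
  expect_equal(t3$odds_ratio, 1)
  expect_lt(abs(t3$score), 0.1)

  # dominance: an experiment covering all community, no background, wins
  t4 <- score_tf_experiments(comm,
    list("TFB:e1" = bed_all, "TFC:e1" = bed_eq), universe)
  expect_equal(t4$tf[which.max(t4$score)], "TFB")
  expect_error(score_tf_experiments(comm, list(), universe[0, ]),
               "empty universe")
})

test_that("aggregate_tf ranks per-TF mean scores with name tie-breaks", {
  tab <- data.frame(tf = c("A", "A", "B", "C"),
                    experiment = c("e1", "e2", "e1", "e1"),
                    p = 0.01, odds_ratio = 2,
                    score = c(4, 6, 5, 5))
  out <- aggregate_tf(tab, top_k = 10)
  expect_equal(out$mean_score[out$tf == "A"], 5)
  expect_equal(out$n_experiments[out$tf == "A"], 2)
  # B and C tie at 5: B ranks first by name
  expect_equal(out$tf, c("A", "B", "C"))
  expect_equal(out$rank, 1:3)
  expect_equal(nrow(aggregate_tf(tab, top_k = 2)), 2)
  # group-mean oracle on a random table
  set.seed(91)
  big <- data.frame(tf = sample(LETTERS[1:6], 50, replace = TRUE),
                    experiment = paste0("e", 1:50), p = 0.01,
                    odds_ratio = 2, score = rnorm(50))
  got <- aggregate_tf(big, top_k = 6)
  want <- sort(tapply(big$score, big$tf, mean), decreasing = TRUE)
  expect_equal(got$mean_score, as.vector(want))
  expect_equal(got$tf, names(want))
})

test_that("community_trends summarizes z-scored temporal medians", {
  # identical rows: medians equal the common z-score profile
  prof <- c(1, 3, 2, 5)
  v <- matrix(rep(prof, each = 4), 4)
  rownames(v) <- sprintf("chr1:%d-%d", 1:4, 2:5)
  sm <- signal_matrix(v)
  lab <- setNames(rep(1L, 4), rownames(v))
  tr <- community_trends(sm, lab)
  expect_equal(tr$median, as.vector(scale(prof)), tolerance = 1e-12)
  expect_equal(tr$q1, tr$q3)   # no spread within identical rows

  # mirror-image communities have opposite medians
  v2 <- rbind(matrix(rep(prof, each = 3), 3),
              matrix(rep(rev(prof), each = 3), 3))
  rownames(v2) <- sprintf("chr1:%d-%d", 1:6, 2:7)
  sm2 <- signal_matrix(v2)
  lab2 <- setNames(rep(1:2, each = 3), rownames(v2))
  tr2 <- community_trends(sm2, lab2)
  m1 <- tr2$median[tr2$community == 1]
  m2 <- tr2$median[tr2$community == 2]
  expect_equal(m1, rev(m2), tolerance = 1e-12)
  expect_warning(community_trends(sm2, c(lab2, "chr9:1-2" = 3L)),
                 "absent")
})

test_that("lift_regions is a pass-through that rejects chain files", {
  r <- data.frame(chrom = "chr1", start = 0, end = 10)
  expect_identical(lift_regions(r), r)
  expect_error(lift_regions(r, chain = "hg19ToHg38.over.chain"),
               "pre-lifted")
})
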