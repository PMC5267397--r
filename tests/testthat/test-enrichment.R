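make_tracks <- function(ann, w, ip_fun, input_fun) {
  ip <- lapply(ann$chrom_sizes, function(L) ip_fun(L / w))
  input <- lapply(ann$chrom_sizes, function(L) input_fun(L / w))
  list(ip = signal_track("RNAPII", "log", "IP", w, ip),
       input = signal_track("RNAPII", "log", "input", w, input))
}

test_that("scores follow the log2 IP/input model", {
  ann <- grid_annotation()
  # IP identical to input: every score is 0
  tr <- make_tracks(ann, 50, function(n) rep(100, n), function(n) rep(100, n))
  tab <- score_genes(tr$ip, tr$input, ann)
  expect_equal(tab$score, c(0, 0))

  # IP = 2 x input at level 100: score 1 within pseudocount effect
  tr2 <- make_tracks(ann, 50, function(n) rep(200, n),
                     function(n) rep(100, n))
  tab2 <- score_genes(tr2$ip, tr2$input, ann)
  expect_lt(max(abs(tab2$score - 1)), 0.02)

  # scale invariance: multiplying both channels by a constant moves scores
  # by less than 0.01 at signal >= 100x the pseudocount
  tr3 <- make_tracks(ann, 50, function(n) rep(1000, n),
                     function(n) rep(400, n))
  tr3b <- make_tracks(ann, 50, function(n) rep(5000, n),
                      function(n) rep(2000, n))
  expect_lt(max(abs(score_genes(tr3$ip, tr3$input, ann)$score -
                      score_genes(tr3b$ip, tr3b$input, ann)$score)), 0.01)

  # a gene shorter than one bin is scored from its single overlapping bin
  tiny <- genome_annotation(c(chrI = 1000), data.frame(
    id = "g1", chrom = "chrI", start = 110, end = 140, strand = "+",
    class = "ORF"))
  tr4 <- make_tracks(tiny, 50, function(n) 100 * seq_len(n),
                     function(n) rep(100, n))
  tab4 <- score_genes(tr4$ip, tr4$input, tiny)
  expect_equal(tab4$n_bins, 1L)
  expect_equal(tab4$score, log2(301 / 101))

  # a gene beyond the track extent is an error naming the gene
  short <- signal_track("RNAPII", "log", "IP", 50, list(chrI = rep(1, 10)))
  short_in <- signal_track("RNAPII", "log", "input", 50,
                           list(chrI = rep(1, 10)))
  expect_error(score_genes(short, short_in, ann), "gA")
})

test_that("scores equal brute-force per-bin recomputation on noisy tracks", {
  withr::with_seed(42, {
    for (rep in 1:3) {
      cfg <- tiny_cfg(n_genes = 20, seed = 100 + rep)
      g <- generate_genome(cfg)
      s <- simulate_signal(g$annotation, "H3K79me3", "log", g$truth, cfg)
      tab <- score_genes(s$ip, s$input, g$annotation)
      for (gene in sample(tab$gene, 8)) {
        expect_equal(tab$score[tab$gene == gene],
                     oracle_gene_score(s$ip, s$input, g$annotation, gene),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("marked-gene calling is thresholded, monotone, and recovers truth", {
  scores <- stats::setNames(c(-1, 0.5, 1, 1.5, 3),
                            paste0("g", 1:5))
  tab <- table_from_scores(scores)
  expect_equal(call_marked(tab, Inf)$genes, character(0))
  expect_setequal(call_marked(tab, -Inf)$genes, names(scores))
  expect_setequal(call_marked(tab, 1)$genes, c("g3", "g4", "g5"))

  # monotonicity: raising tau never adds genes
  taus <- sort(stats::runif(10, -2, 4))
  sets <- lapply(taus, function(t) call_marked(tab, t)$genes)
  for (i in seq_along(taus)[-1])
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))

  # noiseless synthetic data with log2 effect 2 and tau = 1: the called set
  # equals the ground-truth marked set exactly
  cfg <- tiny_cfg(n_genes = 80, noise_sd = 0, seed = 31)
  g <- generate_genome(cfg)
  for (st in STATES) {
    s <- simulate_signal(g$annotation, "H3K36me3", st, g$truth, cfg)
    called <- call_marked(score_genes(s$ip, s$input, g$annotation), 1)
    cats <- g$truth$categories[g$truth$categories$mark == "H3K36me3", ]
    truth_set <- cats$gene[cats$category %in%
                             c(paste0(st, "-only"), "common-higher-log",
                               "common-higher-Q")]
    expect_setequal(called$genes, truth_set)
  }
})

test_that("top-quartile selection handles ties and matches a sort oracle", {
  tab <- table_from_scores(stats::setNames(c(8:1), paste0("g", 1:8)))
  tq <- top_quartile(tab)
  expect_setequal(tq$genes, c("g1", "g2"))
  expect_false(tq$tie)

  tied <- table_from_scores(stats::setNames(rep(2, 8), paste0("g", 1:8)))
  tq2 <- top_quartile(tied)
  expect_equal(sort(tq2$genes), c("g1", "g2"))
  expect_true(tq2$tie)

  expect_error(top_quartile(table_from_scores(c(a = 1, b = 2, c = 3))),
               "at least 4")

  withr::with_seed(7, {
    sc <- stats::setNames(round(stats::rnorm(1000), 2),
                          sprintf("g%04d", 1:1000))
    tq3 <- top_quartile(table_from_scores(sc))
    k <- ceiling(1000 / 4)
    ord <- names(sc)[order(-sc, names(sc), method = "radix")]
    expect_setequal(tq3$genes, ord[1:k])
  })
})

test_that("the enrichment five-number summary matches percentile oracles", {
  tab <- table_from_scores(stats::setNames(1:5, paste0("g", 1:5)))
  d <- enrichment_distribution(tab)
  expect_equal(unname(d$stats[c("q1", "median", "q3")]), c(2, 3, 4))
  expect_equal(unname(d$stats[["whisker_lo"]]), 1)
  expect_equal(unname(d$stats[["whisker_hi"]]), 5)

  one <- enrichment_distribution(table_from_scores(c(gX = 2.5)))
  expect_true(all(one$stats == 2.5))

  expect_error(enrichment_distribution(tab, genes = "nope"), "empty")

  withr::with_seed(99, {
    x <- stats::rnorm(10000)
    tab2 <- table_from_scores(stats::setNames(x, sprintf("g%05d", 1:10000)))
    d2 <- enrichment_distribution(tab2)
    # independent type-7 interpolation oracle
    xs <- sort(x)
    q7 <- function(p) {
      h <- (length(xs) - 1) * p + 1
      xs[floor(h)] + (h - floor(h)) * (xs[floor(h) + 1] - xs[floor(h)])
    }
    expect_equal(unname(d2$stats[["median"]]), q7(0.5), tolerance = 1e-12)
    expect_equal(unname(d2$stats[["q1"]]), q7(0.25), tolerance = 1e-12)
    expect_equal(unname(d2$stats[["q3"]]), q7(0.75), tolerance = 1e-12)
    iqr <- q7(0.75) - q7(0.25)
    expect_equal(unname(d2$stats[["whisker_lo"]]),
                 min(xs[xs >= q7(0.25) - 1.5 * iqr]))
    expect_equal(unname(d2$stats[["whisker_hi"]]),
                 max(xs[xs <= q7(0.75) + 1.5 * iqr]))
  })
})

test_that("H3 normalization subtracts the per-gene H3 score", {
  k4 <- table_from_scores(c(g1 = 2, g2 = 1.5), mark = "H3K4me3")
  h3 <- table_from_scores(c(g2 = 0.5, g1 = 1), mark = "H3")
  adj <- normalize_to_h3(k4, h3)
  expect_equal(adj$score, c(1, 1))
  expect_error(normalize_to_h3(k4, table_from_scores(c(g1 = 1), mark = "H3")),
               "g2")
})
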