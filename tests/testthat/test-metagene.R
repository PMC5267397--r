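rect_tracks <- function(ann, gene_row, fold = 4, level = 100, w = 50) {
  ip <- lapply(ann$chrom_sizes, function(L) rep(level, L / w))
  g <- gene_row
  b1 <- floor(g$start / w) + 1; b2 <- ceiling(g$end / w)
  ip[[g$chrom]][b1:b2] <- level * fold
  list(ip = signal_track("H3K36me3", "log", "IP", w, ip),
       input = signal_track("H3K36me3", "log", "input", w,
                            lapply(ann$chrom_sizes,
                                   function(L) rep(level, L / w))))
}

test_that("a rectangular body signal gives a flat body profile at the body ratio", {
  for (strand in c("+", "-")) {
    genes <- data.frame(id = "g1", chrom = "chrI", start = 5000, end = 8000,
                        strand = strand, class = "ORF")
    ann <- genome_annotation(c(chrI = 20000), genes)
    tr <- rect_tracks(ann, genes[1, ])
    pr <- tss_tes_profile(tr$ip, tr$input, ann, "g1", flank = 250,
                          body_bins = 100)
    body_val <- log2((400 + 1) / (100 + 1))
    expect_equal(pr$mean[pr$zone == "body"], rep(body_val, 100))
    # flanks beyond the enriched rectangle sit at background (ratio 0);
    # the flank bins touching the gene's partial edge bins may differ
    up <- pr$mean[pr$zone == "upstream"]
    expect_equal(up[1:4], rep(0, 4))
    dn <- pr$mean[pr$zone == "downstream"]
    expect_equal(dn[2:5], rep(0, 4))
    expect_true(all(pr$n[pr$zone == "body"] == 1))
  }
})

test_that("plus and minus strand genes with mirrored signal give equal profiles", {
  genes <- data.frame(id = c("gp", "gm"), chrom = c("chrI", "chrII"),
                      start = 5000, end = 8000, strand = c("+", "-"),
                      class = "ORF")
  ann <- genome_annotation(c(chrI = 20000, chrII = 20000), genes)
  w <- 50
  mk <- function(vals_fun) {
    ip <- list(chrI = rep(100, 400), chrII = rep(100, 400))
    # 5' ramp on gp (chrI) and its mirror on gm (chrII)
    body_bins <- (floor(5000 / w) + 1):ceiling(8000 / w)
    ramp <- seq(400, 100, length.out = length(body_bins))
    ip$chrI[body_bins] <- ramp
    ip$chrII[body_bins] <- rev(ramp)
    signal_track("RNAPII", "log", "IP", w, ip)
  }
  input <- signal_track("RNAPII", "log", "input", w,
                        list(chrI = rep(100, 400), chrII = rep(100, 400)))
  ip <- mk()
  pp <- tss_tes_profile(ip, input, ann, "gp")
  pm <- tss_tes_profile(ip, input, ann, "gm")
  expect_equal(pp$mean[pp$zone == "body"], pm$mean[pm$zone == "body"],
               tolerance = 1e-12)
})

test_that("Q-state RNAP II profiles peak at the TES and log-state at the TSS", {
  cfg <- tiny_cfg(n_genes = 60, noise_sd = 0, seed = 23)
  g <- generate_genome(cfg)
  for (st in STATES) {
    s <- simulate_signal(g$annotation, "RNAPII", st, g$truth, cfg)
    tab <- score_genes(s$ip, s$input, g$annotation)
    pr <- tss_tes_profile(s$ip, s$input, g$annotation, top_quartile(tab))
    amax <- which.max(pr$mean)
    fb <- sum(pr$zone == "upstream")
    B <- sum(pr$zone == "body")
    if (st == "Q") {
      # argmax in the last 10% of body bins or the downstream flank
      expect_gte(amax, fb + 0.9 * B)
    } else {
      # argmax within the first 10% of body bins or the upstream flank
      expect_lte(amax, fb + 0.1 * B)
    }
  }
})

test_that("metagene grid values match an independent per-gene recomputation", {
  withr::with_seed(31, {
    cfg <- tiny_cfg(n_genes = 12, seed = 44)
    g <- generate_genome(cfg)
    ip <- random_track(g$annotation, cfg$bin_width)
    input <- random_track(g$annotation, cfg$bin_width, channel = "input")
    ids <- orfs(g$annotation)$id
    B <- 40
    pr <- tss_tes_profile(ip, input, g$annotation, ids, flank = 250,
                          body_bins = B)
    grids <- sapply(ids, function(id)
      oracle_gene_grid(ip, input, g$annotation, id, flank = 250, B = B))
    expected <- rowMeans(grids, na.rm = TRUE)
    expect_equal(pr$mean, expected, tolerance = 1e-9)
    expect_equal(pr$n, rowSums(!is.na(grids)))
  })
})

test_that("profile rejects empty sets and misaligned flanks, skips short genes", {
  genes <- data.frame(id = c("g1", "tiny"), chrom = "chrI",
                      start = c(5000, 12000), end = c(8000, 12060),
                      strand = "+", class = "ORF")
  ann <- genome_annotation(c(chrI = 20000), genes)
  tr <- rect_tracks(ann, genes[1, ])
  expect_error(tss_tes_profile(tr$ip, tr$input, ann, character(0)), "empty")
  expect_error(tss_tes_profile(tr$ip, tr$input, ann, "g1", flank = 240),
               "multiple")
  pr <- tss_tes_profile(tr$ip, tr$input, ann, c("g1", "tiny"))
  expect_equal(attr(pr, "excluded_short"), 1)
  expect_equal(attr(pr, "n_genes"), 1)
  expect_error(tss_tes_profile(tr$ip, tr$input, ann, "tiny"),
               "shorter than two bins")
})

test_that("length-sorted occupancy matrices mask past the TES and sort rows", {
  genes <- data.frame(id = c("long", "short"), chrom = "chrI",
                      start = c(3000, 10000), end = c(5000, 11000),
                      strand = "+", class = "ORF")
  ann <- genome_annotation(c(chrI = 20000), genes)
  tr <- rect_tracks(ann, genes[1, ])
  cm <- chromatra(tr$ip, tr$input, ann, upstream = 500, downstream = 5000,
                  binsize = 100)
  expect_equal(cm$ids, c("short", "long"))   # ascending length
  offs <- as.numeric(colnames(cm$values))
  expect_true(all(is.na(cm$values["short", offs >= 1000])))
  expect_true(all(cm$mask["short", offs >= 1000]))
  expect_false(any(cm$mask["long", offs < 2000]))
  # mask conservation for bin-multiple lengths
  for (id in cm$ids) {
    len <- cm$lengths[match(id, cm$ids)]
    expect_equal(sum(!cm$mask[id, ]), (500 + min(len, 5000)) / 100)
  }

  # constant signal: every unmasked, in-chromosome cell is constant
  flat_ip <- signal_track("H3", "log", "IP", 50,
                          list(chrI = rep(300, 400)))
  flat_in <- signal_track("H3", "log", "input", 50,
                          list(chrI = rep(100, 400)))
  cm2 <- chromatra(flat_ip, flat_in, ann, binsize = 100)
  vals <- cm2$values[!cm2$mask & !is.na(cm2$values)]
  expect_equal(unname(vals), rep(log2(301 / 101), length(vals)))

  expect_error(chromatra(tr$ip, tr$input, ann, transcripts = "nope"),
               "absent")
  expect_error(chromatra(tr$ip, tr$input, ann, binsize = 300), "divide")
})

test_that("matrix cells equal brute-force window means on random tracks", {
  withr::with_seed(77, {
    cfg <- tiny_cfg(n_genes = 10, seed = 55)
    g <- generate_genome(cfg)
    ip <- random_track(g$annotation, cfg$bin_width)
    input <- random_track(g$annotation, cfg$bin_width, channel = "input")
    cm <- chromatra(ip, input, g$annotation, upstream = 400,
                    downstream = 2000, binsize = 100)
    offs <- as.numeric(colnames(cm$values))
    for (id in sample(cm$ids, 4)) {
      for (j in sample(seq_along(offs), 6)) {
        if (cm$mask[id, j]) next
        expect_equal(cm$values[id, j],
                     oracle_chromatra_cell(ip, input, g$annotation, id,
                                           offs[j], 100),
                     tolerance = 1e-9)
      }
    }
  })
})
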