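test_that("generator handles the empty genome and is bytewise deterministic", {
  cfg <- tiny_cfg(n_genes = 0)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$annotation$features), 0)
  expect_equal(nrow(g$truth$categories), 0)
  expect_equal(nrow(g$truth$transcripts), 0)

  cfg2 <- tiny_cfg(n_genes = 80, seed = 11)
  g1 <- generate_genome(cfg2)
  g2 <- generate_genome(cfg2)
  expect_identical(g1, g2)
  f1 <- tempfile(); f2 <- tempfile()
  write_annotation(g1$annotation, f1, "bed")
  write_annotation(g2$annotation, f2, "bed")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("divergent-pair fraction matches a brute-force adjacent-pair scan", {
  cfg <- tiny_cfg(n_chromosomes = 2, chrom_length = 300000, n_genes = 200,
                  divergent_fraction = 0.5, seed = 1)
  g <- generate_genome(cfg)
  orc <- oracle_divergent_fraction(g$annotation)
  # the partition's IGR count must equal the oracle's positive-width count
  part <- build_igr_partition(g$annotation)
  expect_equal(sum(part$regions$class == "IGR"),
               oracle_igr_count(g$annotation))
  # and the realized fraction is near the configured target
  se <- sqrt(0.5 * 0.5 / orc$n_pairs)
  expect_lt(abs(orc$fraction - 0.5), 4 * se + 1e-9)

  cfg2 <- tiny_cfg(n_chromosomes = 4, chrom_length = 600000, n_genes = 1000,
                   divergent_fraction = 0.25, seed = 2)
  orc2 <- oracle_divergent_fraction(generate_genome(cfg2)$annotation)
  expect_lt(abs(orc2$fraction - 0.25), 4 * sqrt(0.25 * 0.75 / orc2$n_pairs))
})

test_that("noiseless signal shapes place peaks at the configured anchors", {
  cfg <- tiny_cfg(n_genes = 30, noise_sd = 0, seed = 4)
  g <- generate_genome(cfg)
  ann <- g$annotation
  w <- cfg$bin_width

  # H3K4me3: the maximum bin of a truly marked gene lies within the
  # configured peak width of the TSS
  s <- simulate_signal(ann, "H3K4me3", "log", g$truth, cfg)
  cats <- g$truth$categories
  marked <- cats$gene[cats$mark == "H3K4me3" &
                        cats$category %in% c("log-only", "common-higher-log")]
  gdf <- orfs(ann)
  pw <- cfg$state_params$H3K4me3$log$tss_width
  for (gene in head(marked, 5)) {
    gg <- gdf[gdf$id == gene, ]
    b <- c(floor(gg$start / w) + 1, ceiling(gg$end / w))
    prof <- s$ip$signal[[gg$chrom]][b[1]:b[2]]
    peak_bp <- (b[1] + which.max(prof) - 1 - 0.5) * w
    tss <- if (gg$strand == "+") gg$start else gg$end
    expect_lte(abs(peak_bp - tss), pw)
  }

  # RNAP II in Q: maximum within the TES-peak width of the TES, and no
  # strict local maximum within 250 bp of the TSS
  sq <- simulate_signal(ann, "RNAPII", "Q", g$truth, cfg)
  markedq <- cats$gene[cats$mark == "RNAPII" &
                         cats$category %in% c("Q-only", "common-higher-Q")]
  tw <- cfg$state_params$RNAPII$Q$tes_width
  for (gene in head(markedq, 5)) {
    gg <- gdf[gdf$id == gene, ]
    b <- c(floor(gg$start / w) + 1, ceiling(gg$end / w))
    prof <- sq$ip$signal[[gg$chrom]][b[1]:b[2]]
    peak_bp <- (b[1] + which.max(prof) - 1 - 0.5) * w
    tss <- if (gg$strand == "+") gg$start else gg$end
    tes <- if (gg$strand == "+") gg$end else gg$start
    expect_lte(abs(peak_bp - tes), tw)
    near_tss <- which(abs((b[1]:b[2] - 0.5) * w - tss) <= 250)
    for (k in near_tss) {
      if (k <= 1 || k >= length(prof)) next
      expect_false(prof[k] > prof[k - 1] && prof[k] > prof[k + 1])
    }
  }

  # nonnegativity and flat input
  expect_true(all(unlist(sq$ip$signal) >= 0))
  expect_true(all(unlist(sq$input$signal) == cfg$background))
})

test_that("ground-truth category counts match configured fractions", {
  cfg <- tiny_cfg(n_chromosomes = 4, chrom_length = 600000, n_genes = 1200,
                  seed = 9)
  g <- generate_genome(cfg)
  n <- nrow(orfs(g$annotation))
  for (mk in MARKS) {
    fr <- cfg$category_fractions[[mk]]
    cats <- g$truth$categories[g$truth$categories$mark == mk, ]
    for (pair in list(c("log-only", "log_only"), c("Q-only", "q_only"))) {
      p <- fr[[pair[2]]]
      obs <- mean(cats$category == pair[1])
      expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / n) + 1e-9)
    }
    p <- fr[["common"]]
    obs <- mean(grepl("^common", cats$category))
    expect_lt(abs(obs - p), 4 * sqrt(p * (1 - p) / n))
  }
})

test_that("input track mean stays within 5% of the configured background", {
  cfg <- tiny_cfg(n_genes = 40, noise_sd = 0.2, seed = 6)
  g <- generate_genome(cfg)
  s <- simulate_signal(g$annotation, "H3", "log", g$truth, cfg)
  expect_lt(abs(mean(unlist(s$input$signal)) / cfg$background - 1), 0.05)
})

test_that("transcript tables realize ground-truth presence and state ordering", {
  cfg <- tiny_cfg(n_genes = 100, seed = 12, transcript_params = noiseless_tp())
  g <- generate_genome(cfg)
  tabs <- simulate_transcriptome(g$annotation, g$truth, cfg)
  thr <- cfg$transcript_params$detection_threshold

  # dropout = 0: detected sets equal ground-truth presence exactly
  tr <- g$truth$transcripts
  for (st in STATES) {
    det <- detect_transcripts(tabs[[st]], thr)
    truth_ids <- tr$id[tr$category %in% c("common", paste0(st, "-only"))]
    expect_setequal(det$id, truth_ids)
  }

  # Q-only detected count equals a brute-force scan of the emitted table
  detq <- detect_transcripts(tabs$Q, thr)
  detl <- detect_transcripts(tabs$log, thr)
  brute_q_only <- 0L
  for (id in tabs$Q$id) {
    aq <- tabs$Q$abundance[tabs$Q$id == id]
    al <- tabs$log$abundance[tabs$log$id == id]
    if (aq >= thr && al < thr) brute_q_only <- brute_q_only + 1L
  }
  expect_equal(length(setdiff(detq$id, detl$id)), brute_q_only)

  # lower Q log-scale mean => lower Q median on common transcripts
  common <- intersect(detq$id, detl$id)
  expect_lt(median(tabs$Q$abundance[tabs$Q$id %in% common]),
            median(tabs$log$abundance[tabs$log$id %in% common]))

  # determinism
  expect_identical(tabs, simulate_transcriptome(g$annotation, g$truth, cfg))
})

test_that("configuration validation names the offending field", {
  expect_error(tiny_cfg(divergent_fraction = 0.7), "divergent_fraction")
  expect_error(tiny_cfg(chrom_length = 100001), "bin_width")
  expect_error(tiny_cfg(noise_sd = -1), "noise_sd")
  expect_error(tiny_cfg(n_genes = -5), "n_genes")
  bad <- default_category_fractions()
  bad$RNAPII[["common"]] <- 0.9
  expect_error(tiny_cfg(category_fractions = bad), "category_fractions")

  cfg <- tiny_cfg(n_genes = 10)
  g <- generate_genome(cfg)
  expect_error(simulate_signal(g$annotation, "H4K20me3", "log", g$truth, cfg),
               "unknown mark")
  expect_error(simulate_signal(g$annotation, "H3", "NQ", g$truth, cfg),
               "unknown state")
  broken <- g$truth
  broken$categories <- broken$categories[broken$categories$mark != "H3", ]
  expect_error(simulate_signal(g$annotation, "H3", "log", broken, cfg),
               "mismatch")
})
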