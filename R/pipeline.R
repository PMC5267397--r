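# End-to-end orchestration: simulate -> score -> classify -> profile ->
# correlate -> partition -> compare, with a JSON report and a deterministic
# manifest.

# 32-bit FNV-1a over a string, as 8 hex digits (manifest config hash);
# arithmetic in doubles since the running hash exceeds R's integer range
fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # split so intermediates stay exactly representable in doubles
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param seed mandatory integer seed for the run (overrides `sim$seed`).
#' @param out_dir output directory (created if missing); `NULL` runs
#'   in-memory only.
#' @param tau marked-gene calling threshold (log2 units).
#' @param detection_threshold transcript detection threshold.
#' @param corr_binsize analysis bin (bp) for genome-wide correlations.
#' @param flank,body_bins metagene grid geometry.
#' @param chromatra_marks marks for which a transcript-length-sorted matrix
#'   is computed (in the log state).
#' @param chromatra_binsize column width (bp) of the matrix.
#' @param reference_list optional character vector of transcript ids (an
#'   external gene list, e.g. sequestered RNAs) to overlap with detections.
#' @param write_tracks also write all simulated tracks as bedGraph.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), seed = NULL, out_dir = NULL,
                       tau = 1, detection_threshold = 1, corr_binsize = 500,
                       flank = 250, body_bins = 100,
                       chromatra_marks = "H3K4me3", chromatra_binsize = 100,
                       reference_list = NULL, write_tracks = FALSE) {
  if (is.null(seed) || length(seed) != 1 || !is.finite(seed))
    stop("validation error: 'seed' is mandatory for simulation runs")
  if (!is.finite(tau)) stop("validation error: 'tau' must be finite")
  if (detection_threshold < 0)
    stop("validation error: 'detection_threshold' must be >= 0")
  if (corr_binsize < sim$bin_width)
    stop("validation error: 'corr_binsize' below track bin width")
  if (body_bins < 1) stop("validation error: 'body_bins' must be >= 1")
  structure(list(sim = sim, seed = as.integer(seed), out_dir = out_dir,
                 tau = tau, detection_threshold = detection_threshold,
                 corr_binsize = corr_binsize, flank = flank,
                 body_bins = body_bins, chromatra_marks = chromatra_marks,
                 chromatra_binsize = chromatra_binsize,
                 reference_list = reference_list,
                 write_tracks = write_tracks),
            class = "run_config")
}

truth_marked_in_state <- function(truth, mark, state) {
  cats <- truth$categories[truth$categories$mark == mark, ]
  marked <- cats$category %in% c(paste0(state, "-only"),
                                 "common-higher-log", "common-higher-Q")
  sort(cats$gene[marked])
}

recovery_stats <- function(called, truth_set, universe) {
  tp <- length(intersect(called, truth_set))
  fp <- length(setdiff(called, truth_set))
  fn <- length(setdiff(truth_set, called))
  tn <- length(universe) - tp - fp - fn
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       n_called = length(called), n_true = length(truth_set))
}

#' Run the full comparative pipeline on simulated data
#'
#' Generates a genome, two-state signal tracks for all marks and two-state
#' transcript tables, then runs every analysis stage: per-gene enrichment and
#' calling, log/Q/common partitioning with the common subdivision, top-
#' quartile metagene profiles, transcript-length-sorted matrices, genome-wide
#' correlations (between states per mark, and across marks within each
#' state), 4-way co-enrichment Venns with Fisher comparisons, the divergent
#' IGR analysis of RNAP II sites, and the transcriptome set comparison.
#' Because inputs are simulated, the report also contains recovery statistics
#' against the generator's ground truth. Reruns with the same configuration
#' produce byte-identical manifests and reports.
#'
#' @param config a [run_config()].
#' @return the report (named list), invisibly when written to disk.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  sim <- config$sim
  sim$seed <- config$seed
  gen <- with_stage("simulate-genome", generate_genome(sim))
  ann <- gen$annotation; truth <- gen$truth

  sig <- list(); tables <- list(); ratio <- list(); called <- list()
  with_stage("simulate-signal+score", {
    for (mk in MARKS) for (st in STATES) {
      key <- paste(mk, st, sep = ".")
      s <- simulate_signal(ann, mk, st, truth, sim)
      sig[[key]] <- s
      tables[[key]] <- score_genes(s$ip, s$input, ann)
      ratio[[key]] <- log2_ratio_track(s$ip, s$input)
      called[[key]] <- call_marked(tables[[key]], config$tau)
    }
  })

  categories <- list(); recovery <- list()
  with_stage("classify", {
    for (mk in MARKS) {
      pa <- partition_marked(called[[paste0(mk, ".log")]],
                             called[[paste0(mk, ".Q")]])
      pa <- split_common(pa, tables[[paste0(mk, ".log")]],
                         tables[[paste0(mk, ".Q")]])
      categories[[mk]] <- pa
      tc <- truth$categories[truth$categories$mark == mk, ]
      agree <- mean(pa$category == tc$category[match(pa$gene, tc$gene)])
      rec <- list(category_agreement = agree)
      for (st in STATES)
        rec[[paste0("calling_", st)]] <- recovery_stats(
          called[[paste(mk, st, sep = ".")]]$genes,
          truth_marked_in_state(truth, mk, st),
          called[[paste(mk, st, sep = ".")]]$universe)
      recovery[[mk]] <- rec
    }
  })

  profiles <- list()
  with_stage("metagene", {
    for (mk in MARKS) for (st in STATES) {
      key <- paste(mk, st, sep = ".")
      tq <- top_quartile(tables[[key]])
      profiles[[key]] <- tss_tes_profile(
        sig[[key]]$ip, sig[[key]]$input, ann, tq,
        flank = config$flank, body_bins = config$body_bins)
    }
  })

  matrices <- list()
  with_stage("chromatra", {
    for (mk in config$chromatra_marks) {
      key <- paste(mk, "log", sep = ".")
      matrices[[mk]] <- chromatra(sig[[key]]$ip, sig[[key]]$input, ann,
                                  binsize = config$chromatra_binsize)
    }
  })

  correlations <- list()
  with_stage("correlate", {
    between <- vapply(MARKS, function(mk) {
      spearman_genome(ratio[[paste0(mk, ".log")]], ratio[[paste0(mk, ".Q")]],
                      config$corr_binsize)
    }, numeric(1))
    within <- lapply(stats::setNames(nm = STATES), function(st) {
      correlation_matrix(stats::setNames(
        lapply(MARKS, function(mk) ratio[[paste(mk, st, sep = ".")]]), MARKS),
        config$corr_binsize)$rho
    })
    correlations <- list(between_states = as.list(between),
                         within_state = within)
  })

  venns <- list()
  with_stage("venn", {
    marks4 <- c("RNAPII", "H3K4me3", "H3K36me3", "H3K79me3")
    for (st in STATES)
      venns[[st]] <- venn4(lapply(marks4, function(mk)
        called[[paste(mk, st, sep = ".")]]))
    venns$fisher <- coenrichment_compare(venns$log, venns$Q)
  })

  igr <- list()
  with_stage("igr", {
    partition <- build_igr_partition(ann)
    igr$partition <- partition
    g <- orfs(ann)
    igrs <- partition$regions[partition$regions$class == "IGR", ,
                              drop = FALSE]
    for (st in STATES) {
      mk <- paste0("RNAPII.", st)
      sel <- g$id %in% called[[mk]]$genes
      gene_sites <- data.frame(chrom = g$chrom[sel], start = g$start[sel],
                               end = g$end[sel], id = g$id[sel],
                               stringsAsFactors = FALSE)
      bound_igr <- igrs[0, ]
      if (nrow(igrs)) {
        sc <- score_intervals(sig[[mk]]$ip, sig[[mk]]$input, igrs)
        bound_igr <- igrs[sc >= config$tau, , drop = FALSE]
      }
      sites <- rbind(gene_sites[, c("chrom", "start", "end", "id")],
                     if (nrow(bound_igr)) data.frame(
                       chrom = bound_igr$chrom, start = bound_igr$start,
                       end = bound_igr$end, id = bound_igr$region_id))
      asn <- assign_sites(sites, partition)
      bound_ids <- asn$assignments$region_id[asn$assignments$class == "IGR"]
      igr[[st]] <- list(
        summary = asn$summary,
        feature_content = igr_feature_content(partition, bound_ids))
    }
  })

  txn <- list()
  with_stage("transcripts", {
    tabs <- simulate_transcriptome(ann, truth, sim)
    det <- lapply(tabs, detect_transcripts, config$detection_threshold)
    txn$venn <- transcript_venn(det$log, det$Q)
    txn$concordance <- lapply(stats::setNames(nm = STATES), function(st)
      rnap_concordance(det[[st]], called[[paste0("RNAPII.", st)]]))
    if (!is.null(config$reference_list))
      txn$reference_overlap <- list_overlap(det$Q, config$reference_list,
                                            class = "ORF")
    truth_present_q <- truth$transcripts$id[
      truth$transcripts$category %in% c("common", "Q-only")]
    txn$detection_recovery_Q <- recovery_stats(
      det$Q$id, sort(truth_present_q), truth$transcripts$id)
    txn$tables <- tabs
  })

  report <- list(
    n_genes = nrow(orfs(ann)),
    marked_counts = lapply(called, function(x) length(x$genes)),
    category_counts = lapply(categories, function(a)
      as.list(category_counts(a))),
    recovery = recovery,
    correlations = correlations,
    venn = list(log = venns$log, Q = venns$Q, fisher = venns$fisher),
    igr = list(log = igr$log, Q = igr$Q),
    transcripts = list(
      venn = list(counts = as.list(txn$venn$counts),
                  totals = as.list(txn$venn$totals),
                  pct_specific = as.list(txn$venn$pct_specific)),
      concordance = txn$concordance,
      reference_overlap = txn$reference_overlap,
      detection_recovery_Q = txn$detection_recovery_Q)
  )

  cfg_for_hash <- config[setdiff(names(config), "out_dir")]
  manifest <- list(package = "qchromatin",
                   version = as.character(utils::packageVersion("qchromatin")),
                   seed = config$seed,
                   config_hash = fnv1a32(paste(deparse(cfg_for_hash),
                                               collapse = "")))

  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    with_stage("write-outputs", {
      write_annotation(ann, file.path(out, "annotation.bed"), "bed")
      write_annotation(ann, file.path(out, "annotation.gff3"), "gff3")
      for (st in STATES)
        write_transcripts(txn$tables[[st]],
                          file.path(out, sprintf("transcripts_%s.tsv", st)))
      enr <- do.call(rbind, lapply(tables, as.data.frame))
      utils::write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cat_df <- do.call(rbind, lapply(categories, as.data.frame))
      utils::write.table(cat_df, file.path(out, "categories.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(igr$partition$regions,
                         file.path(out, "region_partition.bed"), sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      if (isTRUE(config$write_tracks))
        for (key in names(sig)) {
          write_bedgraph(sig[[key]]$ip,
                         file.path(out, paste0(key, ".ip.bedGraph")))
          write_bedgraph(sig[[key]]$input,
                         file.path(out, paste0(key, ".input.bedGraph")))
        }
      write_report(report, file.path(out, "report.json"))
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
    return(invisible(c(report, list(manifest = manifest))))
  }
  c(report, list(manifest = manifest))
}
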