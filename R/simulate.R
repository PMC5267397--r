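# Synthetic-data generator. Gene placement, strand assignment, state-specific
# signal shapes and two-state transcript tables are generated with known
# ground truth so every downstream stage can be validated against it.

noncoding_length_range <- list(CUT = c(200, 500), SUT = c(200, 800),
                               snRNA = c(100, 300), LTR = c(300, 350))

#' Generate a synthetic genome annotation with ground truth
#'
#' Places non-overlapping ORFs along each chromosome with log-normally
#' distributed lengths, assigns strands by a two-state Markov chain whose
#' switch probability realizes the configured divergent-pair fraction, drops
#' noncoding features (CUT/SUT/snRNA/LTR) into intergenic gaps at the
#' configured Poisson rates, and samples per-gene ground-truth categories for
#' every mark and for transcripts.
#'
#' @param config a [sim_config()].
#' @return list with elements `annotation` (a [genome_annotation]) and
#'   `truth` (list with `categories`: data.frame gene/mark/category, and
#'   `transcripts`: data.frame id/class/category).
#' @export
generate_genome <- function(config) {
  validate_sim_config(config)
  with_op_seed(config$seed, "generate_genome", {
    nchr <- as.integer(config$n_chromosomes)
    chroms <- paste0("chr", as.character(utils::as.roman(seq_len(nchr))))
    chrom_sizes <- stats::setNames(rep(config$chrom_length, nchr), chroms)
    per_chrom <- diff(round(seq(0, config$n_genes, length.out = nchr + 1)))

    feats <- list(); gidx <- 0L; ncidx <- 0L
    for (ci in seq_len(nchr)) {
      k <- per_chrom[ci]
      gaps_feats <- NULL
      if (k > 0) {
        gl <- config$gene_length
        len <- round(pmin(gl$max, pmax(gl$min,
                     stats::rlnorm(k, gl$meanlog, gl$sdlog))))
        if (sum(len) > 0.95 * config$chrom_length)
          stop("invalid 'chrom_length': cannot place ", k, " genes (",
               sum(len), " bp) on a ", config$chrom_length,
               " bp chromosome", call. = FALSE)
        raw <- stats::runif(k + 1, 0.5, 1.5)
        gaps <- raw * (config$chrom_length - sum(len)) / sum(raw)
        starts <- round(cumsum(gaps)[seq_len(k)] +
                        c(0, cumsum(len)[seq_len(k - 1)]))
        ends <- starts + len
        # strand Markov chain: switch-to-facing prob a = 2f gives stationary
        # strand frequencies 1/2 and divergent-pair fraction f
        a <- 2 * config$divergent_fraction
        strand <- character(k)
        strand[1] <- sample(c("+", "-"), 1)
        if (k > 1) {
          u <- stats::runif(k - 1)
          for (i in 2:k) {
            strand[i] <- if (strand[i - 1] == "-") {
              if (u[i - 1] < a) "+" else "-"
            } else {
              if (u[i - 1] < a) "-" else "+"
            }
          }
        }
        ids <- sprintf("gene_%05d", gidx + seq_len(k)); gidx <- gidx + k
        feats[[length(feats) + 1]] <- data.frame(
          id = ids, chrom = chroms[ci], start = starts, end = ends,
          strand = strand, class = "ORF", stringsAsFactors = FALSE)
        gap_bounds <- cbind(c(0, ends), c(starts, config$chrom_length))
      } else {
        gap_bounds <- matrix(numeric(), ncol = 2)  # no genes, no gaps
      }
      # noncoding features inside intergenic gaps
      for (gi in seq_len(nrow(gap_bounds))) {
        gs <- gap_bounds[gi, 1]; ge <- gap_bounds[gi, 2]
        if (ge - gs < 60) next
        for (cls in names(config$noncoding_rates)) {
          n <- stats::rpois(1, config$noncoding_rates[[cls]])
          if (n == 0) next
          rng <- noncoding_length_range[[cls]]
          for (j in seq_len(n)) {
            flen <- min(round(stats::runif(1, rng[1], rng[2])), ge - gs - 20)
            if (flen < 40) next
            fs <- round(stats::runif(1, gs + 10, ge - 10 - flen))
            ncidx <- ncidx + 1L
            feats[[length(feats) + 1]] <- data.frame(
              id = sprintf("%s_%05d", tolower(cls), ncidx),
              chrom = chroms[ci], start = fs, end = fs + flen,
              strand = sample(c("+", "-"), 1), class = cls,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    features <- if (length(feats)) do.call(rbind, feats) else
      data.frame(id = character(), chrom = character(), start = numeric(),
                 end = numeric(), strand = character(), class = character(),
                 stringsAsFactors = FALSE)
    annotation <- genome_annotation(chrom_sizes, features)

    truth <- list(categories = sample_mark_categories(annotation, config),
                  transcripts = sample_transcript_categories(annotation,
                                                             config))
    list(annotation = annotation, truth = truth)
  })
}

sample_mark_categories <- function(annotation, config) {
  gene_ids <- orfs(annotation)$id
  n <- length(gene_ids)
  if (n == 0)
    return(data.frame(gene = character(), mark = character(),
                      category = character(), stringsAsFactors = FALSE))
  out <- vector("list", length(MARKS))
  for (mi in seq_along(MARKS)) {
    fr <- config$category_fractions[[MARKS[mi]]]
    p <- c(fr[["log_only"]], fr[["q_only"]], fr[["common"]])
    cat0 <- if (n > 0)
      sample(c("log-only", "Q-only", "common", "unmarked"), n,
             replace = TRUE, prob = c(p, 1 - sum(p)))
    else character()
    common <- cat0 == "common"
    cat0[common] <- ifelse(stats::runif(sum(common)) < fr[["higher_log"]],
                           "common-higher-log", "common-higher-Q")
    out[[mi]] <- data.frame(gene = gene_ids, mark = MARKS[mi],
                            category = cat0, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

sample_transcript_categories <- function(annotation, config) {
  ft <- annotation$features
  if (nrow(ft) == 0)
    return(data.frame(id = character(), class = character(),
                      category = character(), stringsAsFactors = FALSE))
  tf <- config$category_fractions$transcript
  p <- c(tf[["log_only"]], tf[["q_only"]], tf[["common"]])
  cat <- character(nrow(ft))
  is_orf <- ft$class == "ORF"
  cat[is_orf] <- sample(c("log-only", "Q-only", "common", "absent"),
                        sum(is_orf), replace = TRUE, prob = c(p, 1 - sum(p)))
  cp <- config$transcript_params$class_presence
  for (cls in rownames(cp)) {
    sel <- ft$class == cls
    if (!any(sel)) next
    in_log <- stats::runif(sum(sel)) < cp[cls, "log"]
    in_q <- stats::runif(sum(sel)) < cp[cls, "Q"]
    cat[sel] <- ifelse(in_log & in_q, "common",
                ifelse(in_log, "log-only",
                ifelse(in_q, "Q-only", "absent")))
  }
  data.frame(id = ft$id, class = ft$class, category = cat,
             stringsAsFactors = FALSE)
}

# is a ground-truth category "marked/present" in the given state, and with
# what share of the full log2 effect?
effect_multiplier <- function(category, state, ratio) {
  if (state == "log") {
    full <- category %in% c("log-only", "common-higher-log")
    partial <- category == "common-higher-Q"
  } else {
    full <- category %in% c("Q-only", "common-higher-Q")
    partial <- category == "common-higher-log"
  }
  ifelse(full, 1, ifelse(partial, ratio, 0))
}

#' Simulate IP and input signal tracks for one mark and state
#'
#' Builds a clean fold-enrichment surface over genes truly marked in the
#' requested state (gene-body plateau plus Gaussian TSS and/or TES bumps,
#' strand-aware), applies multiplicative log-normal noise per bin, and
#' returns matched IP and input tracks. Common genes receive the full effect
#' in their higher state and `shared_effect_ratio` of the log2 effect in the
#' other. For RNAP II, noncoding features whose transcript is present in the
#' state also receive the body-level effect, tying intergenic polymerase
#' signal to noncoding transcription.
#'
#' @param annotation a [genome_annotation].
#' @param mark one of [MARKS].
#' @param state one of [STATES].
#' @param truth ground truth from [generate_genome()].
#' @param config the [sim_config()].
#' @return list with `ip` and `input` [signal_track]s.
#' @export
simulate_signal <- function(annotation, mark, state, truth, config) {
  validate_sim_config(config)
  if (!mark %in% MARKS) stop("unknown mark: ", mark)
  if (!state %in% STATES) stop("unknown state: ", state)
  gene_ids <- orfs(annotation)$id
  cats <- truth$categories[truth$categories$mark == mark, , drop = FALSE]
  if (!all(gene_ids %in% cats$gene))
    stop("annotation/truth mismatch: no ", mark, " label for gene ",
         setdiff(gene_ids, cats$gene)[1])
  w <- config$bin_width
  with_op_seed(config$seed, paste("simulate_signal", mark, state), {
    ip <- list(); input <- list()
    g <- orfs(annotation)
    m <- effect_multiplier(
      cats$category[match(g$id, cats$gene)], state,
      config$shared_effect_ratio)
    p <- config$state_params[[mark]][[state]]
    nc <- NULL
    if (mark == "RNAPII") {
      tr <- truth$transcripts
      present <- tr$category %in% c("common", paste0(state, "-only"))
      nc_ids <- tr$id[present & tr$class != "ORF"]
      nc <- annotation$features[annotation$features$id %in% nc_ids, ,
                                drop = FALSE]
    }
    for (chr in names(annotation$chrom_sizes)) {
      nb <- as.integer(annotation$chrom_sizes[[chr]] / w)
      fold <- rep(1, nb)
      gi <- which(g$chrom == chr & m > 0)
      if (length(gi)) {
        x_all <- (seq_len(nb) - 0.5) * w
        pad <- 3 * max(p$tss_width, p$tes_width, w)
        for (i in gi) {
          s <- g$start[i]; e <- g$end[i]
          i1 <- max(1L, as.integer((s - pad) %/% w) + 1L)
          i2 <- min(nb, as.integer(ceiling((e + pad) / w)))
          x <- x_all[i1:i2]
          tss <- if (g$strand[i] == "+") s else e
          tes <- if (g$strand[i] == "+") e else s
          f <- 1 + (p$body_fold - 1) * (x >= s & x < e) +
            p$tss_height * exp(-0.5 * ((x - tss) / (p$tss_width / 2))^2) +
            p$tes_height * exp(-0.5 * ((x - tes) / (p$tes_width / 2))^2)
          if (m[i] < 1) f <- 2^(m[i] * log2(f))
          fold[i1:i2] <- fold[i1:i2] + (f - 1)
        }
      }
      if (!is.null(nc) && any(nc$chrom == chr)) {
        for (i in which(nc$chrom == chr)) {
          i1 <- as.integer(nc$start[i] %/% w) + 1L
          i2 <- min(nb, as.integer(ceiling(nc$end[i] / w)))
          fold[i1:i2] <- fold[i1:i2] + (p$body_fold - 1)
        }
      }
      noise_ip <- if (config$noise_sd > 0)
        exp(stats::rnorm(nb, 0, config$noise_sd)) else 1
      noise_in <- if (config$noise_sd > 0)
        exp(stats::rnorm(nb, 0, config$noise_sd)) else 1
      ip[[chr]] <- config$background * fold * noise_ip
      input[[chr]] <- config$background * rep(1, nb) * noise_in
    }
    list(ip = signal_track(mark, state, "IP", w, ip),
         input = signal_track(mark, state, "input", w, input))
  })
}

#' Simulate two-state transcript abundance tables
#'
#' Every annotated feature appears in both state tables. Features whose
#' ground-truth category includes a state receive an abundance of
#' `detection_threshold` plus a log-normal draw with the state's `meanlog`
#' (so present transcripts always clear the detection threshold), except for
#' a `dropout` fraction whose abundance is pushed below threshold to emulate
#' detection failure. Absent transcripts receive sub-threshold abundance.
#'
#' @param annotation a [genome_annotation].
#' @param truth ground truth from [generate_genome()].
#' @param config the [sim_config()].
#' @return named list of two [transcript_table]s (`log`, `Q`).
#' @export
simulate_transcriptome <- function(annotation, truth, config) {
  validate_sim_config(config)
  tr <- truth$transcripts
  if (!all(tr$id %in% annotation$features$id))
    stop("annotation/truth mismatch in transcript ids")
  tp <- config$transcript_params
  thr <- tp$detection_threshold
  with_op_seed(config$seed, "simulate_transcriptome", {
    out <- list()
    for (state in STATES) {
      n <- nrow(tr)
      present <- tr$category %in% c("common", paste0(state, "-only"))
      ab <- stats::runif(n, 0, 0.5 * thr)
      ab[present] <- thr + stats::rlnorm(sum(present),
                                         tp$meanlog[[state]], tp$sdlog)
      dropped <- present & stats::runif(n) < tp$dropout
      ab[dropped] <- stats::runif(sum(dropped), 0, 0.5 * thr)
      out[[state]] <- transcript_table(tr$id, tr$class, ab, state)
    }
    out
  })
}
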