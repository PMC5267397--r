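# Simulation configuration: the generator's defaults emulate a budding-yeast
# genome (16 chromosomes, ~5000 ORFs, dense gene spacing) and the qualitative
# two-state signal structure: H3K4me3 peaked at the TSS, H3K36me3/H3K79me3 in
# gene bodies, RNAP II 5'-peaked in log cells but flat-bodied with a 3'/TES
# peak in quiescent cells, and globally lower transcript abundance in Q cells.

#' Default simulation parameter blocks
#'
#' Starting points for [sim_config()]: per-mark/state signal shapes,
#' ground-truth category fractions, and transcript abundance parameters.
#' Modify with [utils::modifyList()] to customize a scenario.
#' @return a nested list (see [sim_config()] for field meanings).
#' @export
default_state_params <- function() {
  base <- list(body_fold = 4, tss_height = 0, tss_width = 500,
               tes_height = 0, tes_width = 300)
  mod <- function(...) utils::modifyList(base, list(...))
  list(
    RNAPII   = list(log = mod(tss_height = 5, tss_width = 300),
                    Q   = mod(tes_height = 5)),
    H3K4me3  = list(log = mod(tss_height = 6), Q = mod(tss_height = 4)),
    H3K36me3 = list(log = base, Q = base),
    H3K79me3 = list(log = base, Q = base),
    H3       = list(log = base, Q = base)
  )
}

#' @rdname default_state_params
#' @export
default_category_fractions <- function() {
  list(
    RNAPII     = c(log_only = 0.20, q_only = 0.05, common = 0.11,
                   higher_log = 0.75),
    H3K4me3    = c(log_only = 0.06, q_only = 0.04, common = 0.38,
                   higher_log = 0.75),
    H3K36me3   = c(log_only = 0.06, q_only = 0.04, common = 0.38,
                   higher_log = 0.50),
    H3K79me3   = c(log_only = 0.06, q_only = 0.04, common = 0.38,
                   higher_log = 0.75),
    H3         = c(log_only = 0.02, q_only = 0.02, common = 0.80,
                   higher_log = 0.50),
    transcript = c(log_only = 0.22, q_only = 0.06, common = 0.60)
  )
}

#' @rdname default_state_params
#' @export
default_transcript_params <- function() {
  list(
    meanlog = c(log = 2.0, Q = 1.2),   # log-scale abundance means per state
    sdlog = 1.0,
    detection_threshold = 1.0,         # normalized units
    dropout = 0.03,                    # detection failure rate
    class_presence = matrix(
      c(0.90, 0.35,   # CUT: predominates in log cells
        0.50, 0.85,   # SUT: more prevalent in Q cells
        0.95, 0.95,   # snRNA: no state bias
        0.30, 0.60),  # LTR: Ty-associated transcription in Q cells
      nrow = 4, byrow = TRUE,
      dimnames = list(c("CUT", "SUT", "snRNA", "LTR"), c("log", "Q")))
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults describe
#' a yeast-like genome and a two-state chromatin/transcriptome structure; see
#' the methods vignette for the rationale behind each default.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length chromosome length (bp); must be a multiple of
#'   `bin_width`.
#' @param n_genes total number of ORFs, spread evenly over chromosomes.
#' @param divergent_fraction target fraction of adjacent ORF pairs arranged
#'   divergently (upstream gene on "-", downstream on "+", 5' ends facing the
#'   shared gap). The strand model caps this at 0.5.
#' @param noncoding_rates named vector of expected feature counts per
#'   intergenic gap for classes CUT, SUT, snRNA, LTR (Poisson rates).
#' @param bin_width signal track bin width (bp).
#' @param noise_sd standard deviation of the per-bin multiplicative
#'   log-normal noise (natural-log scale).
#' @param background mean input-channel intensity (arbitrary array units).
#' @param state_params nested list `state_params[[mark]][[state]]` of signal
#'   shape parameters: `body_fold` (IP/input fold over the gene body),
#'   `tss_height`/`tss_width` and `tes_height`/`tes_width` (Gaussian bump
#'   height in fold units and full width in bp; sigma = width/2).
#' @param shared_effect_ratio for common genes, the lower state's log2 effect
#'   as a fraction of the configured full effect (asymmetric scaling that
#'   realizes the common-higher-log / common-higher-Q ground truth).
#' @param category_fractions list per mark (plus `transcript`) of fractions
#'   `log_only`, `q_only`, `common` (and `higher_log`, the share of common
#'   genes that are higher in log cells); remaining genes are unmarked
#'   (absent, for transcripts).
#' @param transcript_params list with `meanlog` (named per state), `sdlog`,
#'   `detection_threshold`, `dropout`, and a `class_presence` matrix of
#'   per-state presence probabilities for noncoding classes.
#' @param gene_length list with `meanlog`, `sdlog`, `min`, `max` for the
#'   log-normal ORF length distribution, truncated to `[min, max]` bp.
#' @param seed integer seed; every generator operation derives its own RNG
#'   stream from `(seed, operation name)` so stages can be regenerated
#'   independently.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 16,
                       chrom_length = 800000,
                       n_genes = 5000,
                       divergent_fraction = 0.3,
                       noncoding_rates = c(CUT = 0.15, SUT = 0.12,
                                           snRNA = 0.02, LTR = 0.05),
                       bin_width = 50,
                       noise_sd = 0.3,
                       background = 100,
                       state_params = default_state_params(),
                       shared_effect_ratio = 0.7,
                       category_fractions = default_category_fractions(),
                       transcript_params = default_transcript_params(),
                       gene_length = list(meanlog = 7.2, sdlog = 0.55,
                                          min = 300, max = 8000),
                       seed = 1) {
  cfg <- structure(
    list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
         n_genes = n_genes, divergent_fraction = divergent_fraction,
         noncoding_rates = noncoding_rates, bin_width = bin_width,
         noise_sd = noise_sd, background = background,
         state_params = state_params,
         shared_effect_ratio = shared_effect_ratio,
         category_fractions = category_fractions,
         transcript_params = transcript_params,
         gene_length = gene_length, seed = seed),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why)
    stop("invalid '", field, "': ", why, call. = FALSE)
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  if (!num1(cfg$n_chromosomes) || cfg$n_chromosomes < 1)
    fail("n_chromosomes", "must be a positive number")
  if (!num1(cfg$n_genes) || cfg$n_genes < 0)
    fail("n_genes", "must be >= 0")
  if (!num1(cfg$chrom_length) || cfg$chrom_length <= 0)
    fail("chrom_length", "must be positive")
  if (!num1(cfg$bin_width) || cfg$bin_width < 1)
    fail("bin_width", "must be >= 1")
  if (cfg$chrom_length %% cfg$bin_width != 0)
    fail("bin_width", "must divide chrom_length")
  if (!num1(cfg$divergent_fraction) || cfg$divergent_fraction < 0 ||
      cfg$divergent_fraction > 0.5)
    fail("divergent_fraction",
         "must lie in [0, 0.5] (Markov strand model bound)")
  if (!num1(cfg$noise_sd) || cfg$noise_sd < 0)
    fail("noise_sd", "must be >= 0")
  if (!num1(cfg$background) || cfg$background <= 0)
    fail("background", "must be > 0")
  if (!num1(cfg$shared_effect_ratio) || cfg$shared_effect_ratio <= 0 ||
      cfg$shared_effect_ratio > 1)
    fail("shared_effect_ratio", "must lie in (0, 1]")
  if (is.null(names(cfg$noncoding_rates)) ||
      !all(names(cfg$noncoding_rates) %in% setdiff(FEATURE_CLASSES, "ORF")))
    fail("noncoding_rates", "must be named with noncoding classes")
  if (any(cfg$noncoding_rates < 0))
    fail("noncoding_rates", "rates must be >= 0")
  for (mk in MARKS) {
    if (is.null(cfg$state_params[[mk]]))
      fail("state_params", paste("missing mark", mk))
    for (st in STATES)
      if (is.null(cfg$state_params[[mk]][[st]]))
        fail("state_params", paste("missing state", st, "for mark", mk))
  }
  for (nm in c(MARKS, "transcript")) {
    fr <- cfg$category_fractions[[nm]]
    if (is.null(fr)) fail("category_fractions", paste("missing entry", nm))
    core <- fr[c("log_only", "q_only", "common")]
    if (any(is.na(core)) || any(core < 0) || any(core > 1))
      fail("category_fractions",
           paste("fractions for", nm, "must lie in [0, 1]"))
    if (sum(core) > 1 + 1e-12)
      fail("category_fractions",
           paste("fractions for", nm, "must sum to <= 1"))
    if (nm != "transcript") {
      hl <- fr[["higher_log"]]
      if (is.null(hl) || is.na(hl) || hl < 0 || hl > 1)
        fail("category_fractions",
             paste("higher_log for", nm, "must lie in [0, 1]"))
    }
  }
  tp <- cfg$transcript_params
  if (!all(STATES %in% names(tp$meanlog)))
    fail("transcript_params", "meanlog must be named for both states")
  if (tp$detection_threshold < 0)
    fail("transcript_params", "detection_threshold must be >= 0")
  if (tp$dropout < 0 || tp$dropout > 1)
    fail("transcript_params", "dropout must lie in [0, 1]")
  gl <- cfg$gene_length
  if (gl$min <= 0 || gl$max < gl$min)
    fail("gene_length", "need 0 < min <= max")
  if (!num1(cfg$seed)) fail("seed", "must be a single finite number")
  invisible(cfg)
}

# Deterministic per-operation seed derived from (config seed, op name); keeps
# independent RNG streams per stage and stays below 2^31.
derive_seed <- function(seed, op) {
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (ch in utf8ToInt(op)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

with_op_seed <- function(seed, op, code) {
  withr::with_seed(derive_seed(seed, op), code)
}
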