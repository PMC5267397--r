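# Two-state transcriptome comparison: detection, Venn partition of ORF
# transcripts, overlap with an external reference list, and concordance with
# RNAP II marked genes. Reported percentages use half-up integer rounding.

#' Round half away from zero
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values (0.5 always rounds up in magnitude).
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Detect transcripts in a state
#'
#' A transcript is detected iff its abundance is at least `threshold`.
#'
#' @param table a [transcript_table].
#' @param threshold detection threshold in normalized abundance units.
#' @return `detected_set`: data.frame with columns id, class; state and
#'   threshold carried as attributes.
#' @export
detect_transcripts <- function(table, threshold = 1) {
  if (length(threshold) != 1 || is.na(threshold) || threshold < 0)
    stop("threshold must be a single value >= 0")
  sel <- table$abundance >= threshold
  structure(data.frame(id = table$id[sel], class = table$class[sel],
                       stringsAsFactors = FALSE),
            class = c("detected_set", "data.frame"),
            state = table$state[1], threshold = threshold)
}

#' Two-state Venn partition of detected transcripts
#'
#' Restricted to one feature class (default ORF). Percent-specific values are
#' `100 * state-only / state total`, reported both raw and rounded half-up to
#' integers.
#'
#' @param detected_log,detected_q `detected_set`s from [detect_transcripts()].
#' @param class feature class to compare.
#' @return `transcript_venn`: list with the three id sets, their counts,
#'   per-state totals and specific percentages.
#' @export
transcript_venn <- function(detected_log, detected_q, class = "ORF") {
  dl <- detected_log$id[detected_log$class == class]
  dq <- detected_q$id[detected_q$class == class]
  common <- intersect(dl, dq)
  log_only <- setdiff(dl, dq)
  q_only <- setdiff(dq, dl)
  counts <- c(common = length(common), log_only = length(log_only),
              q_only = length(q_only))
  totals <- c(log = length(dl), q = length(dq))
  stopifnot(totals[["log"]] == counts[["common"]] + counts[["log_only"]],
            totals[["q"]] == counts[["common"]] + counts[["q_only"]])
  pct <- c(log_specific = 100 * counts[["log_only"]] / totals[["log"]],
           q_specific = 100 * counts[["q_only"]] / totals[["q"]])
  structure(list(class = class,
                 sets = list(common = sort(common),
                             log_only = sort(log_only),
                             q_only = sort(q_only)),
                 counts = counts, totals = totals,
                 pct_specific = pct,
                 pct_specific_rounded = round_half_up(pct)),
            class = "transcript_venn")
}

#' @export
print.transcript_venn <- function(x, ...) {
  cat(sprintf(
    "transcript_venn (%s): common %d | log-only %d (%d%%) | Q-only %d (%d%%)\n",
    x$class, x$counts[["common"]], x$counts[["log_only"]],
    x$pct_specific_rounded[["log_specific"]], x$counts[["q_only"]],
    x$pct_specific_rounded[["q_specific"]]))
  invisible(x)
}

#' Overlap of a detected set with an external reference list
#'
#' @param detected a `detected_set` (or character vector of ids); must be
#'   non-empty.
#' @param reference character vector of reference ids (e.g. transcripts
#'   reported as sequestered in RNA-protein complexes).
#' @param class optional feature class filter applied to `detected`.
#' @return list with `n_overlap`, `n_detected`, `fraction`, `pct` (half-up
#'   integer percent).
#' @export
list_overlap <- function(detected, reference, class = NULL) {
  ids <- if (is.data.frame(detected)) {
    if (!is.null(class)) detected$id[detected$class == class]
    else detected$id
  } else as.character(detected)
  if (!length(ids)) stop("empty detected set")
  n <- length(intersect(ids, reference))
  list(n_overlap = n, n_detected = length(ids), fraction = n / length(ids),
       pct = round_half_up(100 * n / length(ids)))
}

#' Concordance between detected transcripts and RNAP II marked genes
#'
#' Fraction of a state's detected ORF transcripts whose gene is in that
#' state's marked set.
#'
#' @param detected a `detected_set` (non-empty after the class filter).
#' @param marked a [marked_gene_set] (normally RNAP II, same state).
#' @param class feature class filter.
#' @return list with `n_concordant`, `n_detected`, `fraction`, `pct`.
#' @export
rnap_concordance <- function(detected, marked, class = "ORF") {
  ids <- if (is.data.frame(detected)) detected$id[detected$class == class]
  else as.character(detected)
  if (!length(ids)) stop("empty detected set")
  n <- length(intersect(ids, marked$genes))
  list(n_concordant = n, n_detected = length(ids),
       fraction = n / length(ids),
       pct = round_half_up(100 * n / length(ids)))
}
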