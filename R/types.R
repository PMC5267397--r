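# Core containers shared by all stages. Coordinates are 0-based half-open
# internally; conversion to/from 1-based formats happens only in io.R.

#' Feature classes recognized in annotations
#'
#' Closed vocabulary of feature classes: protein-coding ORFs plus the
#' noncoding classes (cryptic unstable transcripts, stable unannotated
#' transcripts, small nuclear RNAs, and Ty long terminal repeats).
#' @export
FEATURE_CLASSES <- c("ORF", "CUT", "SUT", "snRNA", "LTR")

#' Chromatin marks handled by the signal simulator and scorers
#' @export
MARKS <- c("RNAPII", "H3K4me3", "H3K36me3", "H3K79me3", "H3")

#' Cell states compared by the pipeline
#' @export
STATES <- c("log", "Q")

#' Gene category vocabulary for the two-state comparison
#' @export
GENE_CATEGORIES <- c("log-only", "Q-only", "common-higher-log",
                     "common-higher-Q", "unmarked")

#' Construct a genome annotation
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param features data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `strand`, `class`. Coordinates are 0-based half-open.
#' @param unstranded_defaulted optional character vector of feature ids whose
#'   strand was missing on input and defaulted to "+".
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chrom_sizes, features,
                              unstranded_defaulted = character()) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  required <- c("id", "chrom", "start", "end", "strand", "class")
  if (!all(required %in% names(features)))
    stop("features must have columns: ", paste(required, collapse = ", "))
  features <- features[, required, drop = FALSE]
  rownames(features) <- NULL
  if (anyDuplicated(features$id))
    stop("feature ids must be unique; duplicated: ",
         features$id[duplicated(features$id)][1])
  if (!all(features$chrom %in% names(chrom_sizes)))
    stop("feature chromosome not in chrom_sizes: ",
         setdiff(features$chrom, names(chrom_sizes))[1])
  bad <- which(!(features$start >= 0 & features$start < features$end &
                 features$end <= chrom_sizes[features$chrom]))
  if (length(bad))
    stop("feature coordinates violate 0 <= start < end <= chrom length ",
         "(feature ", features$id[bad[1]], ")")
  if (!all(features$strand %in% c("+", "-")))
    stop("unknown strand for feature ",
         features$id[!(features$strand %in% c("+", "-"))][1])
  if (!all(features$class %in% FEATURE_CLASSES))
    stop("unknown feature class: ",
         setdiff(features$class, FEATURE_CLASSES)[1])
  structure(list(chrom_sizes = chrom_sizes, features = features,
                 unstranded_defaulted = unstranded_defaulted),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chrom_sizes), "chromosomes (",
      format(sum(x$chrom_sizes), big.mark = ","), "bp ),",
      nrow(x$features), "features\n")
  print(table(x$features$class))
  invisible(x)
}

#' Extract the ORF features of an annotation
#' @param annotation a `genome_annotation`.
#' @return data.frame of ORF features.
#' @export
orfs <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  annotation$features[annotation$features$class == "ORF", , drop = FALSE]
}

#' Construct a binned signal track
#'
#' Fixed-width binned intensities for one mark/state/channel. Bin `i` of a
#' chromosome covers `[(i-1)*bin_width, i*bin_width)`.
#'
#' @param mark mark identifier (see [MARKS]; free-form ids are allowed for
#'   ratio tracks).
#' @param state state identifier ("log" or "Q").
#' @param channel one of "IP", "input", "ratio".
#' @param bin_width bin width in bp.
#' @param signal named list of per-chromosome numeric vectors.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(mark, state, channel, bin_width, signal) {
  if (!channel %in% c("IP", "input", "ratio"))
    stop("channel must be IP, input or ratio")
  if (!is.list(signal) || is.null(names(signal)))
    stop("signal must be a named list of numeric vectors")
  for (chr in names(signal)) {
    v <- signal[[chr]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("signal values must be finite numerics (chromosome ", chr, ")")
    if (channel != "ratio" && any(v < 0))
      stop("negative intensity in ", channel, " track on ", chr)
  }
  structure(list(mark = mark, state = state, channel = channel,
                 bin_width = bin_width, signal = signal),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track %s/%s [%s], bin %d bp, %d chromosomes, %d bins\n",
              x$mark, x$state, x$channel, x$bin_width,
              length(x$signal), sum(lengths(x$signal))))
  invisible(x)
}

#' Construct a per-state transcript abundance table
#'
#' @param id,class,abundance,state per-transcript columns; `abundance` is a
#'   nonnegative normalized expression value.
#' @return data.frame with class `transcript_table`.
#' @export
transcript_table <- function(id, class, abundance, state) {
  if (anyDuplicated(id)) stop("transcript ids must be unique within a state")
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop("abundance must be finite and >= 0")
  if (!all(class %in% FEATURE_CLASSES)) stop("unknown transcript class")
  if (length(unique(state)) > 1) stop("one state per table")
  state <- rep_len(as.character(state), length(id))
  structure(data.frame(id = id, class = class, abundance = abundance,
                       state = state, stringsAsFactors = FALSE),
            class = c("transcript_table", "data.frame"))
}

#' Construct a marked-gene set
#'
#' The set of genes called as carrying a mark in one state, together with the
#' threshold used and the scored universe it was drawn from.
#'
#' @param mark,state identifiers.
#' @param genes character vector of gene ids in the set.
#' @param tau calling threshold used (`NA` for rank-based sets).
#' @param universe all gene ids that were scored.
#' @param tie TRUE when a rank cutoff fell inside a tie (see [top_quartile]).
#' @return object of class `marked_gene_set`.
#' @export
marked_gene_set <- function(mark, state, genes, tau, universe, tie = FALSE) {
  genes <- as.character(genes)
  universe <- as.character(universe)
  if (!all(genes %in% universe))
    stop("marked genes must be a subset of the scored universe")
  structure(list(mark = mark, state = state, genes = sort(genes), tau = tau,
                 universe = sort(universe), tie = tie),
            class = "marked_gene_set")
}

#' @export
print.marked_gene_set <- function(x, ...) {
  cat(sprintf("marked_gene_set %s/%s: %d of %d genes (tau = %s)\n",
              x$mark, x$state, length(x$genes), length(x$universe),
              format(x$tau)))
  invisible(x)
}

# internal: stop with a stage prefix (used by run_all)
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}
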