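# Per-gene enrichment scoring from IP/input tracks. The score is the mean
# over a gene's window bins of log2((IP + c)/(input + c)) with pseudocount c,
# mirroring the relative-occupancy (IP/input) semantics of ChIP tiling-array
# data without probe-level normalization.

track_ratio_values <- function(ip, input, pseudocount) {
  if (!identical(ip$bin_width, input$bin_width))
    stop("IP and input tracks must share bin width")
  if (!setequal(names(ip$signal), names(input$signal)))
    stop("IP and input tracks must share chromosomes")
  lapply(stats::setNames(nm = names(ip$signal)), function(chr) {
    if (length(ip$signal[[chr]]) != length(input$signal[[chr]]))
      stop("IP/input bin count mismatch on ", chr)
    log2((ip$signal[[chr]] + pseudocount) /
           (input$signal[[chr]] + pseudocount))
  })
}

# bins overlapping [start, end) on the bin grid (1-based indices)
bin_span <- function(start, end, w) {
  c(as.integer(start %/% w) + 1L, as.integer(ceiling(end / w)))
}

#' Score per-gene enrichment from IP and input tracks
#'
#' For each ORF, the score is the mean pseudocounted log2 IP/input ratio over
#' the bins of the gene window. Genes shorter than one bin are scored from
#' their single overlapping bin.
#'
#' @param ip,input matched [signal_track]s (same bin width and chromosomes).
#' @param annotation a [genome_annotation].
#' @param window "gene-body" (default) scores over `[start, end)`;
#'   "tss" scores over TSS +/- `tss_flank`, clipped to the chromosome.
#' @param tss_flank half-width (bp) of the TSS window.
#' @param pseudocount added to both channels before the ratio.
#' @return `enrichment_table`: data.frame with columns gene, mark, state,
#'   score, n_bins; the scored universe, window policy and pseudocount are
#'   carried as attributes.
#' @export
score_genes <- function(ip, input, annotation,
                        window = c("gene-body", "tss"), tss_flank = 500,
                        pseudocount = 1) {
  window <- match.arg(window)
  g <- orfs(annotation)
  r <- track_ratio_values(ip, input, pseudocount)
  if (!all(g$chrom %in% names(r)))
    stop("annotation chromosome missing from tracks: ",
         setdiff(g$chrom, names(r))[1])
  w <- ip$bin_width
  cums <- lapply(r, function(v) cumsum(v))
  score <- numeric(nrow(g)); n_bins <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    if (window == "gene-body") {
      s <- g$start[i]; e <- g$end[i]
    } else {
      tss <- if (g$strand[i] == "+") g$start[i] else g$end[i]
      s <- max(0, tss - tss_flank)
      e <- min(annotation$chrom_sizes[[g$chrom[i]]], tss + tss_flank)
    }
    b <- bin_span(s, e, w)
    cs <- cums[[g$chrom[i]]]
    if (b[2] > length(cs))
      stop("gene outside track extent: ", g$id[i])
    tot <- cs[b[2]] - if (b[1] > 1) cs[b[1] - 1] else 0
    n_bins[i] <- b[2] - b[1] + 1L
    score[i] <- tot / n_bins[i]
  }
  structure(data.frame(gene = g$id, mark = ip$mark, state = ip$state,
                       score = score, n_bins = n_bins,
                       stringsAsFactors = FALSE),
            class = c("enrichment_table", "data.frame"),
            window = window, pseudocount = pseudocount,
            h3_normalized = FALSE)
}

#' Subtract the H3 score from H3-PTM enrichment scores
#'
#' Optional nucleosome-occupancy normalization: per gene, the H3 score in the
#' same state is subtracted (a log-scale ratio of ratios), mirroring
#' per-locus reporting of PTM IP/input relative to H3 IP/input.
#'
#' @param table an `enrichment_table` for an H3-PTM mark.
#' @param h3_table the matching H3 `enrichment_table` (same state).
#' @return a new `enrichment_table` with adjusted scores.
#' @export
normalize_to_h3 <- function(table, h3_table) {
  if (!identical(table$state[1], h3_table$state[1]))
    stop("H3 table must come from the same state")
  idx <- match(table$gene, h3_table$gene)
  if (anyNA(idx))
    stop("missing H3 score for gene ", table$gene[which(is.na(idx))[1]])
  out <- table
  out$score <- table$score - h3_table$score[idx]
  attr(out, "h3_normalized") <- TRUE
  out
}

#' Call marked genes by enrichment threshold
#'
#' @param table an `enrichment_table`.
#' @param tau calling threshold on the log2 enrichment score; a gene is
#'   marked iff `score >= tau`. Default 1 (2-fold).
#' @return a [marked_gene_set].
#' @export
call_marked <- function(table, tau = 1) {
  if (length(tau) != 1 || is.na(tau)) stop("tau must be a single value")
  marked_gene_set(table$mark[1], table$state[1],
                  table$gene[table$score >= tau], tau,
                  universe = table$gene)
}

#' Select the top-quartile genes by enrichment
#'
#' The `ceiling(N/4)` highest-scoring genes; ties at the cutoff are broken by
#' lexicographic gene id (C locale) and flagged.
#'
#' @param table an `enrichment_table` with at least 4 scored genes.
#' @return a [marked_gene_set] with `tau = NA` and `tie` set when the cutoff
#'   fell inside a tie.
#' @export
top_quartile <- function(table) {
  n <- nrow(table)
  if (n < 4) stop("top_quartile needs at least 4 scored genes, got ", n)
  k <- ceiling(n / 4)
  o <- order(-table$score, table$gene, method = "radix")
  tie <- k < n && table$score[o[k]] == table$score[o[k + 1]]
  marked_gene_set(table$mark[1], table$state[1], table$gene[o[seq_len(k)]],
                  tau = NA_real_, universe = table$gene, tie = tie)
}

#' Five-number summary of enrichment scores over a gene set
#'
#' Median, quartiles (type-7), and whiskers at the most extreme scores within
#' 1.5 x IQR of the quartiles (the standard box-plot rule).
#'
#' @param table an `enrichment_table`.
#' @param genes gene ids to summarize; default all scored genes.
#' @return list with `stats` (whisker_lo, q1, median, q3, whisker_hi), `n`,
#'   `outliers`, and the raw `values`.
#' @export
enrichment_distribution <- function(table, genes = NULL) {
  x <- if (is.null(genes)) table$score
  else table$score[table$gene %in% genes]
  if (!length(x)) stop("empty gene set")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  list(stats = c(whisker_lo = lo, q1 = q[1], median = q[2], q3 = q[3],
                 whisker_hi = hi),
       n = length(x), outliers = x[x < lo | x > hi], values = x)
}

# score arbitrary intervals (used for intergenic regions) with the same
# pseudocounted mean log2 ratio as gene scoring
score_intervals <- function(ip, input, intervals, pseudocount = 1) {
  r <- track_ratio_values(ip, input, pseudocount)
  w <- ip$bin_width
  vapply(seq_len(nrow(intervals)), function(i) {
    v <- r[[intervals$chrom[i]]]
    b <- bin_span(intervals$start[i], intervals$end[i], w)
    if (b[2] > length(v)) stop("interval outside track extent (row ", i, ")")
    mean(v[b[1]:b[2]])
  }, numeric(1))
}
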