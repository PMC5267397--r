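# TSS/TES-anchored averaged gene profiles and transcript-length-sorted
# occupancy matrices. Both work on the per-bp view of the pseudocounted log2
# IP/input ratio so that genes and windows need not align to the bin grid;
# body rescaling uses coverage-weighted averaging, which conserves mass.

# per-bp ratio lookup for a vector of 0-based genomic positions; NA outside
# the chromosome
bp_values <- function(ratio_chr, bps, w) {
  n_bp <- length(ratio_chr) * w
  ok <- bps >= 0 & bps < n_bp
  out <- rep(NA_real_, length(bps))
  out[ok] <- ratio_chr[bps[ok] %/% w + 1]
  out
}

chunk_stats <- function(vals, chunk) {
  m <- matrix(vals, nrow = chunk)
  n <- colSums(!is.na(m))
  s <- colSums(m, na.rm = TRUE)
  list(mean = ifelse(n > 0, s / n, NA_real_), n = n)
}

body_stats <- function(vals, B) {
  len <- length(vals)
  idx <- ((seq_len(len) - 1) * B) %/% len + 1
  ok <- !is.na(vals)
  s <- rep(0, B); n <- rep(0L, B)
  if (any(ok)) {
    agg_s <- rowsum(vals[ok], idx[ok])
    agg_n <- rowsum(rep(1L, sum(ok)), idx[ok])
    lev <- as.integer(rownames(agg_s))
    s[lev] <- agg_s[, 1]; n[lev] <- agg_n[, 1]
  }
  # chunks with no bp at all (len < B) count as absent, not zero
  covered <- tabulate(idx, nbins = B) > 0
  list(mean = ifelse(n > 0, s / n, NA_real_),
       n = ifelse(covered, n, NA_integer_))
}

# oriented 0-based bp positions of the [TSS - flank, TES + flank) window
gene_window_bps <- function(start, end, strand, flank) {
  if (strand == "+") seq.int(start - flank, end + flank - 1)
  else seq.int(end + flank - 1, start - flank)
}

#' TSS/TES-anchored metagene profile
#'
#' Each gene's log2 IP/input ratio is laid out on a common grid: `flank` bp of
#' real upstream sequence (in track-bin-width steps), the gene body rescaled
#' to `body_bins` coverage-weighted bins, and `flank` bp downstream. Genes on
#' the minus strand are reversed so the TSS is always on the left. The
#' profile value at each grid point is the mean of the per-gene values there;
#' `n` counts contributing genes. Genes shorter than two track bins are
#' excluded (count recorded in attribute `excluded_short`).
#'
#' @param ip,input matched [signal_track]s.
#' @param annotation a [genome_annotation].
#' @param genes gene ids to average (e.g. a [top_quartile()] set); must be
#'   non-empty.
#' @param flank flank length in bp; must be a multiple of the track bin
#'   width.
#' @param body_bins number of scaled body bins (B).
#' @param pseudocount pseudocount for the log2 ratio.
#' @return `metagene_profile`: data.frame with columns `grid` (1..n_grid),
#'   `zone` ("upstream"/"body"/"downstream"), `position` (bp offset for
#'   flanks, scaled bin index for the body), `mean`, `n`; grid geometry and
#'   exclusions in attributes.
#' @export
tss_tes_profile <- function(ip, input, annotation, genes, flank = 250,
                            body_bins = 100, pseudocount = 1) {
  if (inherits(genes, "marked_gene_set")) genes <- genes$genes
  if (!length(genes)) stop("empty gene set")
  w <- ip$bin_width
  if (flank %% w != 0)
    stop("flank must be a multiple of the track bin width (", w, ")")
  fb <- flank / w
  g <- orfs(annotation)
  g <- g[g$id %in% genes, , drop = FALSE]
  if (!nrow(g)) stop("no annotated ORFs among the requested genes")
  short <- g$end - g$start < 2 * w
  n_short <- sum(short)
  g <- g[!short, , drop = FALSE]
  if (!nrow(g)) stop("all requested genes shorter than two bins")
  r <- track_ratio_values(ip, input, pseudocount)
  n_grid <- fb + body_bins + fb
  tot <- rep(0, n_grid); cnt <- rep(0L, n_grid)
  for (i in seq_len(nrow(g))) {
    bps <- gene_window_bps(g$start[i], g$end[i], g$strand[i], flank)
    vals <- bp_values(r[[g$chrom[i]]], bps, w)
    len <- g$end[i] - g$start[i]
    up <- chunk_stats(vals[seq_len(flank)], w)
    body <- body_stats(vals[flank + seq_len(len)], body_bins)
    dn <- chunk_stats(vals[flank + len + seq_len(flank)], w)
    gm <- c(up$mean, body$mean, dn$mean)
    ok <- !is.na(gm)
    tot[ok] <- tot[ok] + gm[ok]
    cnt[ok] <- cnt[ok] + 1L
  }
  zone <- rep(c("upstream", "body", "downstream"), c(fb, body_bins, fb))
  position <- c(seq(-flank, -w, by = w), seq_len(body_bins),
                seq(w, flank, by = w))
  structure(data.frame(grid = seq_len(n_grid), zone = zone,
                       position = position,
                       mean = ifelse(cnt > 0, tot / cnt, NA_real_),
                       n = cnt, stringsAsFactors = FALSE),
            class = c("metagene_profile", "data.frame"),
            mark = ip$mark, state = ip$state, flank = flank,
            body_bins = body_bins, bin_width = w, n_genes = nrow(g),
            excluded_short = n_short)
}

#' Transcript-length-sorted occupancy matrix
#'
#' One row per transcript, TSS-aligned and strand-oriented, columns of
#' `binsize` bp from `-upstream` to `+downstream` relative to the TSS. Cells
#' whose column starts at or beyond the transcript's TES are masked, as are
#' cells outside the chromosome. Rows are sorted by transcript length
#' (ascending; ties by id).
#'
#' @param ip,input matched [signal_track]s.
#' @param annotation a [genome_annotation].
#' @param transcripts feature ids to include; default all ORFs. Ids absent
#'   from the annotation are an error.
#' @param upstream,downstream window extent (bp); must be multiples of
#'   `binsize`.
#' @param binsize column width in bp.
#' @param pseudocount pseudocount for the log2 ratio.
#' @return `chromatra_matrix`: list with `values` (matrix, NA where masked),
#'   `mask` (TRUE for cells past the TES), `ids`, `lengths`, and the window
#'   geometry.
#' @export
chromatra <- function(ip, input, annotation, transcripts = NULL,
                      upstream = 500, downstream = 5000, binsize = 100,
                      pseudocount = 1) {
  if (upstream %% binsize != 0 || downstream %% binsize != 0)
    stop("binsize must divide upstream and downstream spans")
  ft <- annotation$features
  if (is.null(transcripts)) transcripts <- orfs(annotation)$id
  missing <- setdiff(transcripts, ft$id)
  if (length(missing))
    stop("transcript absent from annotation: ", missing[1])
  ft <- ft[match(transcripts, ft$id), , drop = FALSE]
  len <- ft$end - ft$start
  o <- order(len, ft$id, method = "radix")
  ft <- ft[o, , drop = FALSE]; len <- len[o]
  r <- track_ratio_values(ip, input, pseudocount)
  w <- ip$bin_width
  ncol <- (upstream + downstream) / binsize
  offsets <- seq(-upstream, downstream - binsize, by = binsize)
  values <- matrix(NA_real_, nrow(ft), ncol,
                   dimnames = list(ft$id, offsets))
  mask <- matrix(FALSE, nrow(ft), ncol, dimnames = list(ft$id, offsets))
  for (i in seq_len(nrow(ft))) {
    bps <- if (ft$strand[i] == "+")
      seq.int(ft$start[i] - upstream, ft$start[i] + downstream - 1)
    else
      seq.int(ft$end[i] + upstream - 1, ft$end[i] - downstream)
    vals <- bp_values(r[[ft$chrom[i]]], bps, w)
    cs <- chunk_stats(vals, binsize)
    past_tes <- offsets >= len[i]
    mask[i, ] <- past_tes
    row <- cs$mean
    row[past_tes] <- NA_real_
    values[i, ] <- row
  }
  structure(list(values = values, mask = mask, ids = ft$id, lengths = len,
                 upstream = upstream, downstream = downstream,
                 binsize = binsize, mark = ip$mark, state = ip$state),
            class = "chromatra_matrix")
}

#' @export
print.chromatra_matrix <- function(x, ...) {
  cat(sprintf(
    "chromatra_matrix %s/%s: %d transcripts x %d bins (%d bp), -%d..+%d\n",
    x$mark, x$state, nrow(x$values), ncol(x$values), x$binsize,
    x$upstream, x$downstream))
  invisible(x)
}
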