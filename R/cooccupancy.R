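# Genome-wide co-occupancy: binned Spearman correlations between signal
# ratios, multi-set Venn partitions of marked genes, and Fisher's exact
# comparisons of region counts between states.

#' Build a log2 IP/input ratio track
#'
#' @param ip,input matched [signal_track]s.
#' @param pseudocount pseudocount added to both channels.
#' @return a [signal_track] with channel "ratio".
#' @export
log2_ratio_track <- function(ip, input, pseudocount = 1) {
  signal_track(ip$mark, ip$state, "ratio", ip$bin_width,
               track_ratio_values(ip, input, pseudocount))
}

#' Average a track into wider analysis bins
#'
#' @param track a [signal_track].
#' @param binsize target bin width (bp), a multiple of the track bin width;
#'   a trailing partial bin averages the bins it covers.
#' @return a [signal_track] at the new resolution.
#' @export
rebin_track <- function(track, binsize) {
  w <- track$bin_width
  if (binsize < w || binsize %% w != 0)
    stop("binsize must be a multiple of the track bin width (", w, ")")
  k <- binsize / w
  sig <- lapply(track$signal, function(v) {
    grp <- (seq_along(v) - 1) %/% k
    as.numeric(tapply(v, grp, mean))
  })
  signal_track(track$mark, track$state, track$channel, binsize, sig)
}

#' Genome-wide Spearman correlation between two signal ratios
#'
#' Both ratio tracks are averaged into `binsize` analysis bins, concatenated
#' over their shared chromosomes, and rank-correlated (midranks for ties).
#'
#' @param a,b [signal_track]s (normally ratio tracks) with the same bin width
#'   and chromosomes.
#' @param binsize analysis bin width in bp.
#' @return Spearman rho (single numeric).
#' @export
spearman_genome <- function(a, b, binsize = 500) {
  if (!setequal(names(a$signal), names(b$signal)))
    stop("tracks must cover the same chromosomes")
  if (!identical(a$bin_width, b$bin_width))
    stop("tracks must share bin width")
  ra <- rebin_track(a, binsize); rb <- rebin_track(b, binsize)
  x <- unlist(ra$signal[sort(names(ra$signal))], use.names = FALSE)
  y <- unlist(rb$signal[sort(names(rb$signal))], use.names = FALSE)
  if (length(x) != length(y)) stop("tracks differ in bin counts")
  if (length(x) < 3) stop("need at least 3 analysis bins, got ", length(x))
  stats::cor(x, y, method = "spearman")
}

#' Pairwise Spearman correlation matrix over several signals
#'
#' @param tracks named list of [signal_track]s.
#' @param binsize analysis bin width in bp.
#' @return list with `rho` (symmetric matrix, unit diagonal) and `n_bins`.
#' @export
correlation_matrix <- function(tracks, binsize = 500) {
  nm <- names(tracks)
  if (is.null(nm)) stop("tracks must be a named list")
  k <- length(tracks)
  rho <- diag(1, k); dimnames(rho) <- list(nm, nm)
  n_bins <- NA_integer_
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    rho[i, j] <- rho[j, i] <- spearman_genome(tracks[[i]], tracks[[j]],
                                              binsize)
  }
  if (k > 0)
    n_bins <- sum(lengths(rebin_track(tracks[[1]], binsize)$signal))
  list(rho = rho, n_bins = n_bins)
}

# region counts of the n-set Venn over a shared universe; regions labeled by
# membership bitmask (one character per set, "1" = member)
venn_regions <- function(sets, set_names = NULL) {
  if (length(sets) < 2) stop("need at least 2 sets")
  u <- sets[[1]]$universe
  for (s in sets[-1])
    if (!identical(s$universe, u))
      stop("marked sets must share the same universe")
  if (is.null(set_names)) set_names <- vapply(sets, `[[`, "", "mark")
  member <- vapply(sets, function(s) u %in% s$genes,
                   logical(length(u)))
  if (length(u) == 1) member <- matrix(member, nrow = 1)
  mask <- apply(member, 1, function(m) paste(as.integer(m), collapse = ""))
  all_masks <- vapply(seq_len(2^length(sets) - 1), function(i) {
    paste(rev(as.integer(intToBits(i))[seq_along(sets)]), collapse = "")
  }, character(1))
  counts <- table(factor(mask[rowSums(member) > 0], levels = all_masks))
  region <- vapply(all_masks, function(mk) {
    paste(set_names[strsplit(mk, "")[[1]] == "1"], collapse = "+")
  }, character(1))
  data.frame(mask = all_masks, region = region,
             count = as.integer(counts), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' 4-way Venn partition of marked-gene sets
#'
#' Exact partition of the union of four marked-gene sets (e.g. RNAP II,
#' H3K4me3, H3K36me3, H3K79me3 in one state) into the 15 membership regions.
#'
#' @param sets list of four [marked_gene_set]s over the same universe.
#' @param set_names labels for the sets; default their marks.
#' @return data.frame with columns `mask` (membership bitmask), `region`
#'   (label), `count`; attribute `union_size`.
#' @export
venn4 <- function(sets, set_names = NULL) {
  if (length(sets) != 4) stop("venn4 requires exactly four sets")
  res <- venn_regions(sets, set_names)
  attr(res, "union_size") <- sum(res$count)
  res
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact hypergeometric p (tables at least as improbable as the
#' observed one), with the sample odds ratio `ad/bc`. Degenerate margins give
#' `p = 1` and an undefined odds ratio, flagged.
#'
#' @param a,b,c,d nonnegative integer cell counts, row-wise:
#'   `[[a, b], [c, d]]`.
#' @return list with `odds_ratio`, `p_value`, `flag` ("ok",
#'   "undefined-margin", "infinite-or" or "zero-or").
#' @export
fisher2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    return(list(odds_ratio = NA_real_, p_value = 1,
                flag = "undefined-margin"))
  p <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
  or <- (a * d) / (b * c)
  flag <- if (b * c == 0) "infinite-or" else if (a * d == 0) "zero-or"
          else "ok"
  list(odds_ratio = or, p_value = min(p, 1), flag = flag)
}

#' Compare Venn region counts between states with Fisher's exact test
#'
#' For each membership region, tests the 2x2 table
#' `[[count_log, union_log - count_log], [count_q, union_q - count_q]]`,
#' i.e. whether the region's share of co-enriched genes differs between
#' states.
#'
#' @param venn_log,venn_q outputs of [venn4()] for the two states.
#' @param adjust apply Benjamini-Hochberg correction across regions
#'   (off by default; raw per-region p-values are the primary output).
#' @return data.frame with per-region counts, odds ratio, p-value, flag (and
#'   `p_adj` when `adjust = TRUE`).
#' @export
coenrichment_compare <- function(venn_log, venn_q, adjust = FALSE) {
  if (!identical(venn_log$mask, venn_q$mask))
    stop("Venn results must share regions")
  ul <- sum(venn_log$count); uq <- sum(venn_q$count)
  res <- lapply(seq_len(nrow(venn_log)), function(i) {
    ft <- fisher2x2(venn_log$count[i], ul - venn_log$count[i],
                    venn_q$count[i], uq - venn_q$count[i])
    data.frame(mask = venn_log$mask[i], region = venn_log$region[i],
               count_log = venn_log$count[i], count_q = venn_q$count[i],
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               flag = ft$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
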