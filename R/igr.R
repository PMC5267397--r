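# Divergent intergenic-region (IGR) analysis: partition each chromosome into
# gene-containing regions (GCRs), IGRs flanked by divergently transcribed
# ORFs, and "other" intergenic intervals; assign enriched loci to the
# partition and summarize the noncoding feature content of bound IGRs.

#' Partition the genome into GCR / IGR / other regions
#'
#' GCRs are the (merged) ORF spans. A gap between consecutive GCR blocks is a
#' divergent IGR when the ORF ending the left block is on "-" and the ORF
#' starting the right block is on "+" (both 5' ends face the gap); convergent
#' and tandem gaps, and chromosome-end gaps, are "other". The three classes
#' are disjoint and cover every chromosome exactly. Noncoding features fully
#' contained in an IGR are recorded per IGR.
#'
#' @param annotation a [genome_annotation].
#' @return `region_partition`: list with `regions` (data.frame chrom, start,
#'   end, class, region_id), `igr_flanks` (region_id, left_orf, right_orf)
#'   and `igr_features` (region_id, feature_id, class).
#' @export
build_igr_partition <- function(annotation) {
  regions <- list(); flanks <- list()
  rid <- 0L
  next_id <- function(cls) {
    rid <<- rid + 1L
    sprintf("%s_%05d", tolower(cls), rid)
  }
  for (chr in names(annotation$chrom_sizes)) {
    L <- annotation$chrom_sizes[[chr]]
    g <- orfs(annotation)
    g <- g[g$chrom == chr, , drop = FALSE]
    g <- g[order(g$start, g$end, method = "radix"), , drop = FALSE]
    if (nrow(g) == 0) {
      regions[[length(regions) + 1]] <- data.frame(
        chrom = chr, start = 0, end = L, class = "other",
        region_id = next_id("other"), stringsAsFactors = FALSE)
      next
    }
    # merge overlapping/abutting ORFs into GCR blocks
    bs <- g$start[1]; be <- g$end[1]
    blocks <- list()
    left_orf <- g$id[1]; left_strand <- g$strand[1]; left_end <- g$end[1]
    for (i in seq_len(nrow(g))[-1]) {
      if (g$start[i] <= be) {           # overlap or abut: extend block
        if (g$end[i] >= left_end) {
          left_orf <- g$id[i]; left_strand <- g$strand[i]
          left_end <- g$end[i]
        }
        be <- max(be, g$end[i])
      } else {
        blocks[[length(blocks) + 1]] <- list(
          start = bs, end = be, last_orf = left_orf,
          last_strand = left_strand)
        bs <- g$start[i]; be <- g$end[i]
        left_orf <- g$id[i]; left_strand <- g$strand[i]; left_end <- g$end[i]
      }
    }
    blocks[[length(blocks) + 1]] <- list(start = bs, end = be,
                                         last_orf = left_orf,
                                         last_strand = left_strand)
    # first ORF (by start) of each block, for right-flank strand tests
    starts <- vapply(blocks, `[[`, numeric(1), "start")
    first_idx <- vapply(starts, function(s) which(g$start == s)[1],
                        integer(1))
    # emit regions left to right
    if (blocks[[1]]$start > 0)
      regions[[length(regions) + 1]] <- data.frame(
        chrom = chr, start = 0, end = blocks[[1]]$start, class = "other",
        region_id = next_id("other"), stringsAsFactors = FALSE)
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      regions[[length(regions) + 1]] <- data.frame(
        chrom = chr, start = b$start, end = b$end, class = "GCR",
        region_id = next_id("GCR"), stringsAsFactors = FALSE)
      gap_end <- if (bi < length(blocks)) blocks[[bi + 1]]$start else L
      if (gap_end > b$end) {
        if (bi < length(blocks)) {
          right <- g[first_idx[bi + 1], ]
          divergent <- b$last_strand == "-" && right$strand == "+"
          cls <- if (divergent) "IGR" else "other"
          id <- next_id(cls)
          if (divergent)
            flanks[[length(flanks) + 1]] <- data.frame(
              region_id = id, left_orf = b$last_orf, right_orf = right$id,
              stringsAsFactors = FALSE)
        } else {
          cls <- "other"; id <- next_id(cls)
        }
        regions[[length(regions) + 1]] <- data.frame(
          chrom = chr, start = b$end, end = gap_end, class = cls,
          region_id = id, stringsAsFactors = FALSE)
      }
    }
  }
  regions <- do.call(rbind, regions)
  flanks <- if (length(flanks)) do.call(rbind, flanks) else
    data.frame(region_id = character(), left_orf = character(),
               right_orf = character(), stringsAsFactors = FALSE)
  # noncoding features contained in IGRs
  nc <- annotation$features[annotation$features$class != "ORF", ,
                            drop = FALSE]
  igrs <- regions[regions$class == "IGR", , drop = FALSE]
  feats <- list()
  if (nrow(nc) && nrow(igrs)) {
    for (i in seq_len(nrow(igrs))) {
      inside <- nc$chrom == igrs$chrom[i] & nc$start >= igrs$start[i] &
        nc$end <= igrs$end[i]
      if (any(inside))
        feats[[length(feats) + 1]] <- data.frame(
          region_id = igrs$region_id[i], feature_id = nc$id[inside],
          class = nc$class[inside], stringsAsFactors = FALSE)
    }
  }
  feats <- if (length(feats)) do.call(rbind, feats) else
    data.frame(region_id = character(), feature_id = character(),
               class = character(), stringsAsFactors = FALSE)
  structure(list(regions = regions, igr_flanks = flanks,
                 igr_features = feats,
                 chrom_sizes = annotation$chrom_sizes),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("region_partition:\n")
  print(table(x$regions$class))
  invisible(x)
}

#' Assign enriched loci to the GCR / IGR / other partition
#'
#' Each site goes to the region class it overlaps most; exact overlap ties
#' are resolved GCR > IGR > other. Fractions are reported with their explicit
#' denominator (the number of sites).
#'
#' @param sites data.frame with columns chrom, start, end (0-based
#'   half-open) and optionally id; must be non-empty and within chromosome
#'   bounds.
#' @param partition a `region_partition` from [build_igr_partition()].
#' @return list with `assignments` (per site: class and best region_id) and
#'   `summary` (class, count, fraction, n_sites).
#' @export
assign_sites <- function(sites, partition) {
  if (is.null(sites) || nrow(sites) == 0) stop("zero sites to assign")
  if (is.null(sites$id)) sites$id <- sprintf("site_%05d", seq_len(nrow(sites)))
  cs <- partition$chrom_sizes
  bad <- sites$start < 0 | sites$end > cs[sites$chrom] |
    sites$start >= sites$end
  if (any(bad)) stop("site outside chromosome bounds: ", sites$id[bad][1])
  prio <- c(GCR = 1, IGR = 2, other = 3)
  reg <- partition$regions
  cls <- character(nrow(sites)); best_region <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    r <- reg[reg$chrom == sites$chrom[i], , drop = FALSE]
    ov <- pmin(r$end, sites$end[i]) - pmax(r$start, sites$start[i])
    ov[ov < 0] <- 0
    by_class <- tapply(ov, r$class, sum)
    by_class <- by_class[order(-by_class, prio[names(by_class)])]
    cls[i] <- names(by_class)[1]
    within <- which(r$class == cls[i] & ov > 0)
    best_region[i] <- r$region_id[within[which.max(ov[within])]]
  }
  assignments <- data.frame(id = sites$id, chrom = sites$chrom,
                            start = sites$start, end = sites$end,
                            class = cls, region_id = best_region,
                            stringsAsFactors = FALSE)
  counts <- table(factor(cls, levels = names(prio)))
  summary <- data.frame(class = names(counts),
                        count = as.integer(counts),
                        fraction = as.numeric(counts) / nrow(sites),
                        n_sites = nrow(sites), stringsAsFactors = FALSE)
  list(assignments = assignments, summary = summary)
}

#' Noncoding feature content of RNAP II-bound IGRs
#'
#' Counts, among the IGRs bound in a state, those containing at least one
#' feature of each noncoding class, and the fraction containing at least one
#' feature of the listed classes.
#'
#' @param partition a `region_partition`.
#' @param bound_igr_ids region ids of IGRs called bound (e.g. IGR-assigned
#'   sites from [assign_sites()]).
#' @param listed_classes classes counted toward the "contains noncoding
#'   transcription unit" fraction.
#' @return list with `n_bound`, per-class counts, `n_with_listed` and
#'   `fraction_with_listed`.
#' @export
igr_feature_content <- function(partition, bound_igr_ids,
                                listed_classes = c("CUT", "SUT", "LTR")) {
  bound <- unique(bound_igr_ids)
  fc <- partition$igr_features
  fc <- fc[fc$region_id %in% bound, , drop = FALSE]
  per_class <- vapply(setdiff(FEATURE_CLASSES, "ORF"), function(cl) {
    length(unique(fc$region_id[fc$class == cl]))
  }, integer(1))
  with_listed <- length(unique(fc$region_id[fc$class %in% listed_classes]))
  list(n_bound = length(bound), per_class = as.list(per_class),
       n_with_listed = with_listed,
       fraction_with_listed = if (length(bound)) with_listed / length(bound)
                              else 0)
}
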