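# Shared fixtures and independent brute-force oracles. Oracles recompute
# quantities by direct enumeration/looping, independently of the package's
# vectorized implementations.

tiny_cfg <- function(n_chromosomes = 2, chrom_length = 100000, n_genes = 60,
                     seed = 1, ...) {
  sim_config(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
             n_genes = n_genes, seed = seed, ...)
}

noiseless_tp <- function(dropout = 0) {
  utils::modifyList(default_transcript_params(), list(dropout = dropout))
}

# fraction of adjacent ORF pairs (per chromosome, sorted by start) with the
# upstream gene on "-" and the downstream gene on "+"
oracle_divergent_fraction <- function(annotation) {
  g <- orfs(annotation)
  n_div <- 0L; n_pairs <- 0L
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) < 2) next
    for (i in seq_len(nrow(gc) - 1)) {
      n_pairs <- n_pairs + 1L
      if (gc$strand[i] == "-" && gc$strand[i + 1] == "+")
        n_div <- n_div + 1L
    }
  }
  list(fraction = n_div / n_pairs, n_divergent = n_div, n_pairs = n_pairs)
}

# count of divergent gaps with positive width (the IGRs of the partition)
oracle_igr_count <- function(annotation) {
  g <- orfs(annotation)
  n <- 0L
  for (chr in unique(g$chrom)) {
    gc <- g[g$chrom == chr, ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) < 2) next
    for (i in seq_len(nrow(gc) - 1)) {
      if (gc$strand[i] == "-" && gc$strand[i + 1] == "+" &&
          gc$start[i + 1] > gc$end[i])
        n <- n + 1L
    }
  }
  n
}

# direct bin-by-bin mean log2 ratio over a gene-body window
oracle_gene_score <- function(ip, input, annotation, gene, pseudocount = 1) {
  g <- orfs(annotation)
  g <- g[g$id == gene, ]
  w <- ip$bin_width
  b1 <- floor(g$start / w) + 1
  b2 <- ceiling(g$end / w)
  acc <- 0
  for (b in b1:b2)
    acc <- acc + log2((ip$signal[[g$chrom]][b] + pseudocount) /
                        (input$signal[[g$chrom]][b] + pseudocount))
  acc / (b2 - b1 + 1)
}

# rank-then-Pearson Spearman
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# exact two-sided Fisher p by full enumeration of tables with fixed margins
oracle_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(k)
    stats::dhyper(k, r1, r2, c1), numeric(1))
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# per-gene membership tally over Venn regions
oracle_venn_counts <- function(gene_sets, universe) {
  counts <- integer(2^length(gene_sets) - 1)
  for (g in universe) {
    m <- vapply(gene_sets, function(s) g %in% s, logical(1))
    if (!any(m)) next
    idx <- sum(2^(rev(seq_along(m) - 1))[m])
    counts[idx] <- counts[idx] + 1L
  }
  masks <- vapply(seq_along(counts), function(i) {
    paste(rev(as.integer(intToBits(i))[seq_along(gene_sets)]),
          collapse = "")
  }, character(1))
  stats::setNames(counts, masks)
}

# per-bp mean log2 ratio over [from, to) (0-based genomic, unoriented)
oracle_window_mean <- function(ratio_chr, from, to, w) {
  vals <- c()
  for (bp in seq(from, to - 1)) {
    if (bp < 0 || bp >= length(ratio_chr) * w) vals <- c(vals, NA)
    else vals <- c(vals, ratio_chr[bp %/% w + 1])
  }
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

oracle_ratio <- function(ip, input, chr, pseudocount = 1) {
  log2((ip$signal[[chr]] + pseudocount) / (input$signal[[chr]] + pseudocount))
}

# independent chromatra cell: transcript row i, column starting at `offset`
# bp from the TSS (strand-oriented)
oracle_chromatra_cell <- function(ip, input, annotation, id, offset,
                                  binsize, pseudocount = 1) {
  ft <- annotation$features
  ft <- ft[ft$id == id, ]
  r <- oracle_ratio(ip, input, ft$chrom, pseudocount)
  w <- ip$bin_width
  vals <- numeric(0)
  for (k in 0:(binsize - 1)) {
    bp <- if (ft$strand == "+") ft$start + offset + k
          else ft$end - 1 - offset - k
    vals <- c(vals, if (bp < 0 || bp >= length(r) * w) NA
              else r[bp %/% w + 1])
  }
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

# independent metagene grid recomputation for one gene (flank chunks in
# real bp, body rescaled by per-bp assignment to B equal segments)
oracle_gene_grid <- function(ip, input, annotation, id, flank, B,
                             pseudocount = 1) {
  ft <- orfs(annotation); ft <- ft[ft$id == id, ]
  r <- oracle_ratio(ip, input, ft$chrom, pseudocount)
  w <- ip$bin_width
  n_bp <- length(r) * w
  val_at <- function(bp) if (bp < 0 || bp >= n_bp) NA else r[bp %/% w + 1]
  bps <- if (ft$strand == "+") (ft$start - flank):(ft$end + flank - 1)
         else (ft$end + flank - 1):(ft$start - flank)
  vals <- vapply(bps, val_at, numeric(1))
  len <- ft$end - ft$start
  fb <- flank / w
  grid <- rep(NA_real_, fb + B + fb)
  for (j in seq_len(fb)) {
    chunk <- vals[(j - 1) * w + seq_len(w)]
    if (any(!is.na(chunk))) grid[j] <- mean(chunk, na.rm = TRUE)
  }
  body <- vals[flank + seq_len(len)]
  for (j in seq_len(B)) {
    sel <- which(((seq_len(len) - 1) * B) %/% len + 1 == j)
    if (length(sel) && any(!is.na(body[sel])))
      grid[fb + j] <- mean(body[sel], na.rm = TRUE)
  }
  for (j in seq_len(fb)) {
    chunk <- vals[flank + len + (j - 1) * w + seq_len(w)]
    if (any(!is.na(chunk))) grid[fb + B + j] <- mean(chunk, na.rm = TRUE)
  }
  grid
}

# random positive track over an annotation's chromosomes
random_track <- function(annotation, bin_width, mark = "RNAPII",
                         state = "log", channel = "IP") {
  sig <- lapply(annotation$chrom_sizes, function(L)
    stats::runif(ceiling(L / bin_width), 1, 200))
  signal_track(mark, state, channel, bin_width, sig)
}

# a small hand-built annotation on an exact bin grid
grid_annotation <- function(bin_width = 50, chrom_length = 20000,
                            genes = data.frame(
                              id = c("gA", "gB"), chrom = "chrI",
                              start = c(2000, 8000), end = c(4000, 11000),
                              strand = c("+", "-"), class = "ORF")) {
  genome_annotation(c(chrI = chrom_length), genes)
}

# enrichment table from explicit scores
table_from_scores <- function(scores, mark = "RNAPII", state = "log") {
  structure(data.frame(gene = names(scores), mark = mark, state = state,
                       score = as.numeric(scores),
                       n_bins = 1L, stringsAsFactors = FALSE),
            class = c("enrichment_table", "data.frame"),
            window = "gene-body", pseudocount = 1, h3_normalized = FALSE)
}

marked_from_ids <- function(ids, universe, mark = "RNAPII", state = "log") {
  marked_gene_set(mark, state, ids, tau = 1, universe = universe)
}
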