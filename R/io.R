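# Readers/writers for the standard formats the pipeline consumes. Internal
# coordinates are 0-based half-open; BED/bedGraph are written 0-based
# half-open and GFF3 1-based closed, converted only here at file boundaries.

#' Read a genome annotation from BED6+class or GFF3
#'
#' The BED dialect carries the feature class in a 7th column; GFF3 carries it
#' in the `type` field with the feature id in the `ID` attribute. Overlapping
#' ORFs are kept with a warning. Zero/negative-width features, unknown
#' strands and unknown classes are hard errors that name the offending record
#' number.
#'
#' @param path file to read.
#' @param dialect "bed" or "gff3".
#' @param chrom_sizes named vector of chromosome lengths; required for BED,
#'   and for GFF3 files lacking `##sequence-region` directives.
#' @return a [genome_annotation].
#' @export
read_annotation <- function(path, dialect = c("bed", "gff3"),
                            chrom_sizes = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "bed") {
    gr <- rtracklayer::import(path, format = "bed",
                              extraCols = c(class = "character"))
    ids <- gr$name
    classes <- gr$class
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
    classes <- as.character(gr$type)
    if (is.null(chrom_sizes)) {
      # parse ##sequence-region directives for chromosome lengths
      ln <- grep("^##sequence-region", readLines(path), value = TRUE)
      if (length(ln)) {
        parts <- strsplit(trimws(ln), "\\s+")
        chrom_sizes <- stats::setNames(
          vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
          vapply(parts, function(p) p[2], character(1)))
      }
    }
  }
  starts <- GenomicRanges::start(gr) - 1   # to 0-based half-open
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  bad <- which(starts >= ends)
  if (length(bad))
    stop("start >= end at record ", bad[1], " of ", path)
  defaulted <- character()
  unk <- which(!(strands %in% c("+", "-")))
  if (length(unk)) {
    noncoding <- classes[unk] != "ORF"
    if (any(!noncoding))
      stop("unknown strand for ORF at record ", unk[!noncoding][1],
           " of ", path)
    strands[unk] <- "+"          # unstranded noncoding default, flagged
    defaulted <- ids[unk]
  }
  badc <- which(!(classes %in% FEATURE_CLASSES))
  if (length(badc))
    stop("unknown feature class '", classes[badc[1]], "' at record ",
         badc[1], " of ", path)
  if (is.null(chrom_sizes)) stop("chrom_sizes required for ", dialect)
  ft <- data.frame(id = ids, chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = starts, end = ends, strand = strands,
                   class = classes, stringsAsFactors = FALSE)
  orf <- ft[ft$class == "ORF", , drop = FALSE]
  if (nrow(orf) > 1) {
    o <- order(orf$chrom, orf$start, method = "radix")
    ov <- with(orf[o, ], chrom[-1] == chrom[-nrow(orf)] &
                 start[-1] < end[-nrow(orf)])
    if (any(ov)) warning("overlapping ORFs kept: ", sum(ov), " pair(s)")
  }
  genome_annotation(chrom_sizes, ft, unstranded_defaulted = defaulted)
}

#' Write a genome annotation to BED6+class or GFF3
#'
#' @param annotation a [genome_annotation].
#' @param path output file.
#' @param dialect "bed" or "gff3".
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  ft <- annotation$features
  if (dialect == "bed") {
    df <- data.frame(ft$chrom, format(ft$start, scientific = FALSE,
                                      trim = TRUE),
                     format(ft$end, scientific = FALSE, trim = TRUE),
                     ft$id, 0, ft$strand, ft$class)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("##gff-version 3", con)
    for (chr in names(annotation$chrom_sizes))
      writeLines(sprintf("##sequence-region %s 1 %d", chr,
                         as.integer(annotation$chrom_sizes[[chr]])), con)
    if (nrow(ft))
      writeLines(sprintf("%s\tqchromatin\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                         ft$chrom, ft$class, as.integer(ft$start) + 1L,
                         as.integer(ft$end), ft$strand, ft$id), con)
  }
  invisible(path)
}

#' Read a binned signal track from bedGraph
#'
#' Intervals aligned to the bin grid are copied directly; off-grid intervals
#' are re-binned by coverage-weighted mean when `rebin = TRUE` and are an
#' error otherwise. Uncovered bins are filled with 0.
#'
#' @param path bedGraph file (4 columns, 0-based half-open).
#' @param bin_width target bin width (bp).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param mark,state,channel metadata for the resulting track.
#' @param rebin allow coverage-weighted re-binning of off-grid intervals.
#' @return a [signal_track].
#' @export
read_bedgraph <- function(path, bin_width, chrom_sizes,
                          mark = "unknown", state = "log", channel = "IP",
                          rebin = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  n_bins <- as.integer(ceiling(chrom_sizes / bin_width))
  empty <- lapply(stats::setNames(n_bins, names(chrom_sizes)), numeric)
  nonheader <- grep("^(track|#|browser|$)",
                    readLines(path, warn = FALSE), invert = TRUE)
  if (!length(nonheader))
    return(signal_track(mark, state, channel, bin_width, empty))
  gr <- rtracklayer::import(path, format = "bedGraph")
  starts <- GenomicRanges::start(gr) - 1
  ends <- GenomicRanges::end(gr)
  vals <- gr$score
  chroms <- as.character(GenomicRanges::seqnames(gr))
  if (any(vals < 0)) stop("negative value in bedGraph: ", path)
  if (!all(chroms %in% names(chrom_sizes)))
    stop("bedGraph chromosome not in chrom_sizes: ",
         setdiff(chroms, names(chrom_sizes))[1])
  on_grid <- starts %% bin_width == 0 &
    (ends %% bin_width == 0 | ends == chrom_sizes[chroms])
  if (!rebin && any(!on_grid))
    stop("off-grid interval in ", path, " with rebinning disabled (record ",
         which(!on_grid)[1], ")")
  sums <- empty
  for (chr in unique(chroms)) {
    sel <- which(chroms == chr)
    acc <- numeric(n_bins[[match(chr, names(chrom_sizes))]])
    for (i in sel) {
      b1 <- as.integer(starts[i] %/% bin_width) + 1L
      b2 <- as.integer(ceiling(ends[i] / bin_width))
      bs <- (seq(b1, b2) - 1) * bin_width
      ov <- pmin(ends[i], bs + bin_width) - pmax(starts[i], bs)
      acc[b1:b2] <- acc[b1:b2] + vals[i] * ov
    }
    sums[[chr]] <- acc / bin_width   # uncovered bp contribute 0
  }
  signal_track(mark, state, channel, bin_width, sums)
}

#' Write a signal track as bedGraph
#'
#' @param track a [signal_track].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  chrs <- rep(names(track$signal), lengths(track$signal))
  starts <- unlist(lapply(track$signal, function(v)
    (seq_along(v) - 1) * track$bin_width + 1), use.names = FALSE)
  gr <- GenomicRanges::GRanges(chrs, IRanges::IRanges(
    start = starts, width = track$bin_width),
    score = unlist(track$signal, use.names = FALSE))
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read/write a transcript abundance table (TSV with header)
#'
#' @param path file path.
#' @return a [transcript_table] (reader) or `path` invisibly (writer).
#' @export
read_transcripts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("id", "class", "abundance", "state")
  if (!all(req %in% names(df)))
    stop("transcript table must have columns: ", paste(req, collapse = ", "))
  transcript_table(df$id, df$class, df$abundance, df$state)
}

#' @rdname read_transcripts
#' @param table a [transcript_table].
#' @export
write_transcripts <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Recursively sort names and replace NaN by NA, collecting flagged paths.
sanitize_report <- function(x, path = "") {
  flags <- character()
  walk <- function(x, path) {
    if (is.list(x) && !is.data.frame(x)) {
      if (!is.null(names(x)) && all(nzchar(names(x))))
        x <- x[order(names(x), method = "radix")]
      out <- lapply(seq_along(x), function(i) {
        nm <- if (!is.null(names(x))) names(x)[i] else as.character(i)
        walk(x[[i]], paste0(path, "/", nm))
      })
      names(out) <- names(x)
      return(out)
    }
    if (is.numeric(x) && any(is.nan(x))) {
      flags <<- c(flags, paste0(path, "[", which(is.nan(x)), "]"))
      x[is.nan(x)] <- NA
    }
    x
  }
  res <- walk(x, path)
  list(value = res, nan_flags = flags)
}

#' Write a structured analysis report as JSON
#'
#' Keys are sorted recursively for deterministic output; `NaN` statistics are
#' serialized as `null` and listed under a `nan_flags` entry.
#'
#' @param results named list of results (fractions carry explicit
#'   denominators throughout the package, so no information is lost to
#'   rounding).
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (!is.list(results)) stop("results must be a list")
  san <- sanitize_report(results)
  out <- san$value
  if (length(san$nan_flags)) out$nan_flags <- san$nan_flags
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#' @param path `.json` file.
#' @return named list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
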