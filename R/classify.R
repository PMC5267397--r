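# Partition marked genes between states and subdivide the common set by
# relative enrichment.

#' Partition genes into log-only / Q-only / common / unmarked
#'
#' Pure set algebra over the two states' marked sets: log-only = L \ Q,
#' Q-only = Q \ L, common = L intersect Q; genes in the scored universe but
#' in neither set are unmarked.
#'
#' @param marked_log,marked_q [marked_gene_set]s for the same mark over the
#'   same universe.
#' @return `gene_categories`: data.frame with columns gene, mark, category
#'   (common left undifferentiated), tie (all FALSE here).
#' @export
partition_marked <- function(marked_log, marked_q) {
  if (!identical(marked_log$mark, marked_q$mark))
    stop("mark mismatch: ", marked_log$mark, " vs ", marked_q$mark)
  if (!identical(marked_log$universe, marked_q$universe))
    stop("marked sets must share the same scored universe")
  u <- marked_log$universe
  in_l <- u %in% marked_log$genes
  in_q <- u %in% marked_q$genes
  category <- ifelse(in_l & in_q, "common",
              ifelse(in_l, "log-only",
              ifelse(in_q, "Q-only", "unmarked")))
  structure(data.frame(gene = u, mark = marked_log$mark,
                       category = category, tie = FALSE,
                       stringsAsFactors = FALSE),
            class = c("gene_categories", "data.frame"))
}

#' Subdivide common genes by the state with higher enrichment
#'
#' Common genes become `common-higher-log` when the log-state score exceeds
#' the Q-state score and `common-higher-Q` when it is lower. Exact ties are
#' assigned `common-higher-log` deterministically with `tie = TRUE`; ties
#' have measure zero under the noise model but a rule is recorded anyway.
#'
#' @param assignment output of [partition_marked()].
#' @param table_log,table_q `enrichment_table`s for the two states (raw
#'   scores by default; pass H3-normalized tables to subdivide on those).
#' @return updated `gene_categories`.
#' @export
split_common <- function(assignment, table_log, table_q) {
  common <- which(assignment$category == "common")
  if (!length(common)) return(assignment)
  il <- match(assignment$gene[common], table_log$gene)
  iq <- match(assignment$gene[common], table_q$gene)
  missing <- is.na(il) | is.na(iq)
  if (any(missing))
    stop("missing score for common gene ",
         assignment$gene[common][missing][1])
  sl <- table_log$score[il]; sq <- table_q$score[iq]
  assignment$category[common] <- ifelse(sl >= sq, "common-higher-log",
                                        "common-higher-Q")
  assignment$tie[common] <- sl == sq
  assignment
}

#' Tabulate category counts
#' @param assignment a `gene_categories` data.frame.
#' @return named integer vector over [GENE_CATEGORIES] plus "common" if the
#'   common set is still undifferentiated.
#' @export
category_counts <- function(assignment) {
  table(factor(assignment$category,
               levels = union(GENE_CATEGORIES, "common")))
}
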