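# Pathway 1: variants of panel genes that carry at least one significant
# variant-drug (PGx) annotation and whose allele change hits a CpG site.

#' Filter PGx annotations for significance
#'
#' Retains annotations with `p_value < alpha` (strict: an annotation
#' exactly at the threshold is removed).  Input order is preserved and the
#' operation is idempotent.
#'
#' @param annotations PGx annotation `data.frame` (`rsid`, `gene`, `drug`,
#'   `p_value`).
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @return The retained subset, same columns.
#' @export
filter_significant_pgx <- function(annotations, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  out <- annotations[!is.na(annotations$p_value) &
                       annotations$p_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join CpG classifications with significant PGx annotations
#'
#' A variant becomes a CpG-PGx candidate when its CpG delta label is not
#' `neutral` and it has at least one significant annotation.  A variant
#' annotated to several drugs counts once as a candidate but each
#' association contributes to `n_significant_annotations`.
#'
#' @param classified Classification table from [classify_batch()] (or an
#'   equivalent table with `rsid` and `label` columns), one row per unique
#'   variant.
#' @param significant Output of [filter_significant_pgx()].
#' @return Candidate table: the non-neutral classified rows with at least
#'   one significant annotation, plus `n_significant_annotations`.
#' @export
attach_pgx <- function(classified, significant) {
  ids <- classified$rsid[!is.na(classified$rsid)]
  if (anyDuplicated(ids)) {
    stop("duplicate rsids in classification table; deduplicate before joining")
  }
  counts <- table(significant$rsid)
  keep <- !is.na(classified$label) &
    classified$label %in% c("disruptive", "forming", "both") &
    !is.na(classified$rsid) & classified$rsid %in% names(counts)
  out <- classified[keep, , drop = FALSE]
  out$n_significant_annotations <- as.integer(counts[out$rsid])
  rownames(out) <- NULL
  out
}

#' Per-gene summary of the PGx pathway
#'
#' One summary row per panel gene with at least one significant annotation
#' (or, when `significant` is not supplied, per gene with at least one
#' candidate), sorted by CpG-PGx SNP count (descending), then significant
#' annotation count (descending), then gene symbol.
#'
#' @param candidates Candidate table from [attach_pgx()].
#' @param panel Deduplicated gene panel (`gene`, `processes`,
#'   `relevance_score`).
#' @param significant Optional significant-annotation table used to count
#'   each gene's significant variant-drug associations; without it the
#'   candidate annotation counts are summed instead.
#' @return `data.frame` with `gene`, `processes`, `relevance_score`,
#'   `n_significant_annotations`, `n_cpg_pgx_snps`.
#' @export
tally_gene_pgx <- function(candidates, panel, significant = NULL) {
  cand_genes <- unique(candidates$gene[!is.na(candidates$gene)])
  missing <- setdiff(cand_genes, panel$gene)
  if (length(missing)) {
    warning("candidate gene(s) not in panel: ", paste(missing, collapse = ", "))
  }
  ann_counts <- if (!is.null(significant)) {
    table(significant$gene)
  } else {
    tapply(candidates$n_significant_annotations, candidates$gene, sum)
  }
  genes <- union(names(ann_counts)[unlist(ann_counts) > 0], cand_genes)
  cpg_counts <- table(candidates$gene)
  out <- data.frame(
    gene = genes,
    processes = panel$processes[match(genes, panel$gene)],
    relevance_score = panel$relevance_score[match(genes, panel$gene)],
    n_significant_annotations = ifelse(genes %in% names(ann_counts),
                                       as.integer(ann_counts[genes]), 0L),
    n_cpg_pgx_snps = ifelse(genes %in% names(cpg_counts),
                            as.integer(cpg_counts[genes]), 0L),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_cpg_pgx_snps, -out$n_significant_annotations,
                   out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tally candidates by primary function
#'
#' Each candidate is counted once under its primary function, obtained by
#' reducing its full label set with a precedence order (default:
#' missense > frameshift > splice > synonymous > regulatory > 3'UTR >
#' 5'UTR > intronic, where any regulatory-region feature contributes the
#' `regulatory` label).  Candidates with no label count as `unlabeled`.
#'
#' @param candidates Candidate table with `consequences` and
#'   `region_features` columns.
#' @param priority Character vector giving the precedence order.
#' @return Named integer vector of counts, sorted decreasingly; the counts
#'   sum to `nrow(candidates)`.
#' @export
tally_function <- function(candidates, priority = DEFAULT_FUNCTION_PRIORITY) {
  if (nrow(candidates) == 0L) return(integer(0))
  prim <- primary_function(candidates$consequences,
                           candidates$region_features, priority = priority)
  tab <- table(prim)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  sort(counts, decreasing = TRUE)
}
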