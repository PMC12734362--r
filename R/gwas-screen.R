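# Pathway 2: for panel genes without a significant PGx annotation, filter
# GWAS associations by genome-wide significance and minor allele frequency,
# then look for CpG-site formation/disruption among the surviving variants.

#' Filter GWAS associations by significance and MAF
#'
#' Retains associations with `p_value < p_threshold` (strict) and
#' `maf >= maf_min` (inclusive by default, so associations exactly at the
#' MAF boundary are kept; set `strict = TRUE` for a strict comparison).
#' Order is preserved and the operation is idempotent.
#'
#' @param associations GWAS association `data.frame` (`rsid`, `gene`,
#'   `trait`, `p_value`, `maf`).
#' @param p_threshold Genome-wide significance threshold; default `5e-8`.
#' @param maf_min Minimum minor allele frequency; default 0.05.
#' @param strict Use `maf > maf_min` instead of `>=`.  Default `FALSE`.
#' @return The retained subset.
#' @export
filter_gwas <- function(associations, p_threshold = 5e-8, maf_min = 0.05,
                        strict = FALSE) {
  stopifnot(p_threshold > 0, p_threshold < 1, maf_min > 0, maf_min < 1)
  maf_ok <- if (isTRUE(strict)) associations$maf > maf_min
            else associations$maf >= maf_min
  out <- associations[!is.na(associations$p_value) &
                        associations$p_value < p_threshold &
                        !is.na(maf_ok) & maf_ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false discovery rate adjustment (via [stats::p.adjust()]):
#' adjusted values are each at least their input, capped at 1, and
#' invariant to input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted values, same length and order as the input.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  stopifnot(all(p_values > 0), all(p_values <= 1))
  p.adjust(p_values, method = "BH")
}

#' Per-gene summary of the GWAS pathway
#'
#' One summary row per gene with at least one non-neutral classified
#' variant among its refined associations, sorted by CpG-SNP count
#' (descending), refined association count (descending), then gene symbol.
#' A variant appearing in several trait associations counts once in
#' `n_cpg_snps` and once per association in `n_refined_snps`.
#'
#' @param refined Output of [filter_gwas()].
#' @param classified Classification table (one row per unique variant).
#' @param panel Deduplicated gene panel.
#' @return `data.frame` with `gene`, `processes`, `relevance_score`,
#'   `n_refined_snps`, `n_cpg_snps`.
#' @export
tally_gene_gwas <- function(refined, classified, panel) {
  genes_all <- unique(refined$gene)
  missing <- setdiff(genes_all, panel$gene)
  if (length(missing)) {
    warning("refined gene(s) not in panel: ", paste(missing, collapse = ", "))
  }
  lab <- classified$label[match(refined$rsid, classified$rsid)]
  nonneutral <- !is.na(lab) & lab %in% c("disruptive", "forming", "both")
  refined_counts <- table(refined$gene)
  cpg_counts <- vapply(genes_all, function(g) {
    length(unique(refined$rsid[refined$gene == g & nonneutral]))
  }, integer(1))
  genes <- genes_all[cpg_counts[genes_all] > 0]
  out <- data.frame(
    gene = genes,
    processes = panel$processes[match(genes, panel$gene)],
    relevance_score = panel$relevance_score[match(genes, panel$gene)],
    n_refined_snps = as.integer(refined_counts[genes]),
    n_cpg_snps = as.integer(cpg_counts[genes]),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_cpg_snps, -out$n_refined_snps, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition candidates by CpG delta label
#'
#' @param candidates Classified candidate table; all rows must be
#'   non-neutral.
#' @return List with `disruptive`, `forming` and `both` subtables; the
#'   three are disjoint and their row counts sum to `nrow(candidates)`.
#' @export
split_by_delta <- function(candidates) {
  if (nrow(candidates) &&
      any(is.na(candidates$label) |
            !candidates$label %in% c("disruptive", "forming", "both"))) {
    stop("split_by_delta expects only non-neutral, classified candidates")
  }
  pick <- function(lab) {
    out <- candidates[candidates$label == lab, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(disruptive = pick("disruptive"), forming = pick("forming"),
       both = pick("both"))
}
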