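# Ranking and comparison layers: MAF-based prioritisation of candidate
# lists and the multi-factor hub-gene comparison.

#' Rank candidates by minor allele frequency
#'
#' Sorts candidates from the most to the least common allele (MAF
#' descending).  Within equal MAF, variants with a structural or regulatory
#' function (missense, synonymous, splice, frameshift, UTR, or any
#' regulatory-region feature) precede intronic-only variants; remaining
#' ties break lexicographically by rsid, so the ranking is deterministic.
#' Candidates with a missing MAF are placed last and flagged.
#'
#' @param candidates Candidate table with `rsid`, `maf`, `consequences`,
#'   `region_features` columns.
#' @return The input rows reordered, with `priority_rank` (1..n, gap-free)
#'   and `missing_maf` columns added.
#' @export
rank_by_maf <- function(candidates) {
  n <- nrow(candidates)
  if (n == 0L) {
    candidates$priority_rank <- integer(0)
    candidates$missing_maf <- logical(0)
    return(candidates)
  }
  intronic_only <- vapply(seq_len(n), function(i) {
    cons <- strsplit(ifelse(is.na(candidates$consequences[i]), "",
                            candidates$consequences[i]), ";")[[1]]
    cons <- cons[nzchar(cons)]
    reg <- candidates$region_features[i]
    has_reg <- !is.na(reg) && nzchar(reg)
    length(cons) > 0 && all(cons == "intronic") && !has_reg
  }, logical(1))
  missing_maf <- is.na(candidates$maf)
  ord <- order(missing_maf, -ifelse(missing_maf, -Inf, candidates$maf),
               intronic_only, candidates$rsid)
  out <- candidates[ord, , drop = FALSE]
  out$priority_rank <- seq_len(n)
  out$missing_maf <- missing_maf[ord]
  rownames(out) <- NULL
  out
}

#' Count distinct variant types of one gene's candidates
#'
#' The number of distinct function-label combinations (full consequence +
#' region-feature sets, not reduced to a primary function) among the
#' gene's candidates: a "missense + inframe" variant is a different type
#' from a plain missense variant.
#'
#' @param candidates Candidate table for a single gene (non-empty).
#' @return Positive integer.
#' @export
count_variant_types <- function(candidates) {
  stopifnot(nrow(candidates) > 0L)
  key <- vapply(seq_len(nrow(candidates)), function(i) {
    cons <- strsplit(ifelse(is.na(candidates$consequences[i]), "",
                            candidates$consequences[i]), ";")[[1]]
    reg <- strsplit(ifelse(is.na(candidates$region_features[i]), "",
                           candidates$region_features[i]), ";")[[1]]
    paste(sort(unique(c(cons[nzchar(cons)], reg[nzchar(reg)]))),
          collapse = "+")
  }, character(1))
  length(unique(key))
}

#' Count CpG-site formations and disruptions of one gene's candidates
#'
#' A forming variant adds one formation, a disruptive variant one
#' disruption, and a variant labelled `both` (between two CpG sites,
#' disrupting one and forming the other) adds one to each, so
#' `n_formations + n_disruptions = n_candidates + n_both`.
#'
#' @param candidates Classified candidate table for a single gene.
#' @return Named integer vector `c(n_formations, n_disruptions)`.
#' @export
count_formations_disruptions <- function(candidates) {
  c(n_formations = sum(candidates$label %in% c("forming", "both")),
    n_disruptions = sum(candidates$label %in% c("disruptive", "both")))
}

#' Multi-factor hub-gene comparison
#'
#' Each factor (column) is won by the gene(s) attaining its maximum value
#' on the raw scale (no normalisation); a tie in a factor awards it to all
#' tied genes.  The overall winner is the gene winning the most factors;
#' an overall tie is reported as a tie, not broken.
#'
#' @param factors `data.frame` with a `gene` column and one numeric column
#'   per factor (at least two genes and one factor).
#' @return List with `per_factor` (winning gene(s) per factor),
#'   `factor_wins` (named integer vector per gene), `overall_winner`
#'   (character vector, length > 1 on a tie), `winner_factor_count`, and
#'   `tie`.
#' @export
hub_comparison <- function(factors) {
  stopifnot(is.data.frame(factors), "gene" %in% colnames(factors))
  if (nrow(factors) < 2L) stop("hub comparison requires at least 2 genes")
  num_cols <- colnames(factors)[vapply(factors, is.numeric, logical(1))]
  if (length(num_cols) < 1L) stop("no numeric factor columns")
  per_factor <- lapply(num_cols, function(cl) {
    x <- factors[[cl]]
    factors$gene[!is.na(x) & x == max(x, na.rm = TRUE)]
  })
  names(per_factor) <- num_cols
  wins <- vapply(factors$gene, function(g) {
    sum(vapply(per_factor, function(w) g %in% w, logical(1)))
  }, integer(1))
  names(wins) <- factors$gene
  best <- max(wins)
  overall <- names(wins)[wins == best]
  list(per_factor = per_factor, factor_wins = wins,
       overall_winner = overall, winner_factor_count = as.integer(best),
       tie = length(overall) > 1L)
}
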