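# End-to-end orchestration of the hierarchical screen: classify every
# variant once, route panel genes into the two pathways by the presence of
# a significant PGx annotation, tally both pathways, and assemble an
# internally consistent report.

#' Run the full CpG-PGx screen
#'
#' Inputs may be given as file paths (FASTA / VCF / tab-separated tables)
#' or as already-parsed objects.  Panel genes with at least one significant
#' PGx annotation are routed to pathway 1 (PGx screen); the remaining
#' panel genes are routed to pathway 2 (GWAS screen).  Both pathways share
#' a single classification pass.
#'
#' @param config A [screen_config()].
#' @param fasta Reference: path or named character vector.
#' @param vcf Variants: path or variant `data.frame`.
#' @param pgx PGx annotations: path or `data.frame`.
#' @param gwas GWAS associations: path or `data.frame`.
#' @param panel Gene panel: path or `data.frame` (deduplicated or raw
#'   `gene`/`process`/`relevance_score` rows).
#' @param pubmed_counts Optional named integer vector of PubMed title
#'   counts per gene, enabling the hub-gene comparison among the top three
#'   pathway-1 genes.
#' @param out Optional path: write the report as JSON.
#' @return A list of class `"cpgpgx_report"`.
#' @export
run_full_screen <- function(config = screen_config(), fasta, vcf, pgx, gwas,
                            panel, pubmed_counts = NULL, out = NULL) {
  reference <- if (is.character(fasta) && length(fasta) == 1L &&
                   file.exists(fasta)) read_fasta(fasta) else fasta
  variants <- if (is.character(vcf)) read_vcf(vcf) else vcf
  pgx_tbl <- if (is.character(pgx)) read_table(pgx, "pgx") else pgx
  gwas_tbl <- if (is.character(gwas)) read_table(gwas, "gwas") else gwas
  panel_tbl <- if (is.character(panel)) read_table(panel, "panel") else panel
  if (!"processes" %in% colnames(panel_tbl)) {
    panel_tbl <- parse_annotation_table(panel_tbl, "panel")
  }

  classified <- classify_batch(variants, reference, config)
  n_failed <- sum(!is.na(classified$error))
  dup <- duplicated(classified$rsid) & !is.na(classified$rsid)
  if (any(dup)) {
    warning("dropping ", sum(dup), " duplicate rsid row(s) before joining")
    classified <- classified[!dup, , drop = FALSE]
  }

  # pathway routing
  significant <- filter_significant_pgx(pgx_tbl, config$pgx_alpha)
  message("PGx annotations: ", nrow(pgx_tbl), " in, ",
          nrow(significant), " significant at alpha = ", config$pgx_alpha)
  pathway1_genes <- sort(intersect(unique(significant$gene), panel_tbl$gene))
  pathway2_genes <- sort(setdiff(panel_tbl$gene, pathway1_genes))

  # pathway 1
  candidates1 <- attach_pgx(classified, significant)
  gene_pgx <- tally_gene_pgx(candidates1, panel_tbl, significant = significant)
  fn_tally <- tally_function(candidates1)

  # pathway 2
  gwas2 <- gwas_tbl[gwas_tbl$gene %in% pathway2_genes, , drop = FALSE]
  if (isTRUE(config$apply_fdr) && nrow(gwas2)) {
    gwas2$p_value <- adjust_fdr(gwas2$p_value)
  }
  refined <- filter_gwas(gwas2, config$gwas_p_threshold, config$maf_min,
                         strict = config$maf_strict)
  message("GWAS associations: ", nrow(gwas2), " in, ", nrow(refined),
          " refined at p < ", config$gwas_p_threshold, ", MAF ",
          if (config$maf_strict) "> " else ">= ", config$maf_min)
  gene_gwas <- tally_gene_gwas(refined, classified, panel_tbl)
  cand2_ids <- unique(refined$rsid)
  candidates2 <- classified[!is.na(classified$rsid) &
                              classified$rsid %in% cand2_ids &
                              !is.na(classified$label) &
                              classified$label != "neutral", , drop = FALSE]
  rownames(candidates2) <- NULL
  delta_split <- split_by_delta(candidates2)
  ranked <- lapply(delta_split, rank_by_maf)

  # hub comparison among the top pathway-1 genes
  hub <- NULL
  if (!is.null(pubmed_counts) && nrow(gene_pgx) >= 2L &&
      nrow(candidates1) > 0L) {
    top <- head(gene_pgx[gene_pgx$n_cpg_pgx_snps > 0L, ], 3L)
    if (nrow(top) >= 2L) {
      factors <- do.call(rbind, lapply(top$gene, function(g) {
        cg <- candidates1[candidates1$gene == g, , drop = FALSE]
        fd <- count_formations_disruptions(cg)
        data.frame(gene = g,
                   relevance_score = top$relevance_score[top$gene == g],
                   n_significant_annotations =
                     top$n_significant_annotations[top$gene == g],
                   n_cpg_pgx_snps = top$n_cpg_pgx_snps[top$gene == g],
                   n_variant_types = count_variant_types(cg),
                   n_formations = fd[["n_formations"]],
                   n_disruptions = fd[["n_disruptions"]],
                   n_pubmed_titles =
                     as.integer(pubmed_counts[g] %||% NA_integer_),
                   stringsAsFactors = FALSE)
      }))
      hub <- hub_comparison(factors)
      hub$factors <- factors
    }
  }

  report <- structure(list(
    config = unclass(config),
    routing = list(pathway1_genes = pathway1_genes,
                   pathway2_genes = pathway2_genes),
    pathway1 = list(gene_summaries = gene_pgx, function_tally = fn_tally,
                    candidates = candidates1,
                    n_cpg_pgx_snps = nrow(candidates1)),
    pathway2 = list(gene_summaries = gene_gwas,
                    refined = refined,
                    candidates = candidates2,
                    delta_split = vapply(delta_split, nrow, integer(1)),
                    ranked = ranked),
    counts = list(n_variants = nrow(variants),
                  n_classified = nrow(classified) - n_failed,
                  n_failed = n_failed,
                  n_pgx_annotations = nrow(pgx_tbl),
                  n_significant_pgx = nrow(significant),
                  n_gwas_associations = nrow(gwas_tbl),
                  n_refined_gwas = nrow(refined)),
    hub = hub,
    provenance = list(
      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
      seed = config$seed,
      inputs = input_digests(list(fasta = fasta, vcf = vcf, pgx = pgx,
                                  gwas = gwas, panel = panel))
    )
  ), class = "cpgpgx_report")
  validate_report(report)
  if (!is.null(out)) write_report(report, out)
  report
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a

input_digests <- function(inputs) {
  lapply(inputs, function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      unname(tools::md5sum(x))
    } else {
      paste0("in-memory (", paste(class(x), collapse = "/"), ")")
    }
  })
}

# Internal consistency: every count in the report must be recomputable from
# the candidate lists it contains.  Run before a report is returned/written.
validate_report <- function(report) {
  p1 <- report$pathway1
  stopifnot(
    p1$n_cpg_pgx_snps == nrow(p1$candidates),
    sum(p1$function_tally) == nrow(p1$candidates),
    sum(p1$gene_summaries$n_cpg_pgx_snps) == nrow(p1$candidates)
  )
  p2 <- report$pathway2
  stopifnot(
    sum(p2$delta_split) == nrow(p2$candidates),
    sum(p2$gene_summaries$n_cpg_snps) ==
      length(unique(p2$candidates$rsid[p2$candidates$rsid %in% p2$refined$rsid]))
  )
  for (lab in names(p2$ranked)) {
    stopifnot(setequal(p2$ranked[[lab]]$rsid,
                       p2$candidates$rsid[p2$candidates$label == lab]))
  }
  invisible(TRUE)
}

#' Write a screen report as JSON
#'
#' @param report A `"cpgpgx_report"` (or fixture replay) object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.cpgpgx_report <- function(x, ...) {
  cat("CpG-PGx screen report\n")
  cat("  variants classified:", x$counts$n_classified,
      if (x$counts$n_failed) paste0("(", x$counts$n_failed, " failed)") else "",
      "\n")
  cat("  pathway 1:", length(x$routing$pathway1_genes), "genes,",
      x$counts$n_significant_pgx, "significant annotations,",
      x$pathway1$n_cpg_pgx_snps, "CpG-PGx SNPs\n")
  cat("  pathway 2:", length(x$routing$pathway2_genes), "genes,",
      x$counts$n_refined_gwas, "refined associations,",
      nrow(x$pathway2$candidates), "CpG-SNPs (",
      paste(names(x$pathway2$delta_split), x$pathway2$delta_split,
            collapse = ", "), ")\n")
  if (!is.null(x$hub)) {
    cat("  hub gene:", paste(x$hub$overall_winner, collapse = " / "),
        "with", x$hub$winner_factor_count, "of",
        length(x$hub$per_factor), "factors\n")
  }
  invisible(x)
}

#' Replay the screen on the packaged reference tables
#'
#' Runs the tallying, prioritisation and hub-comparison layers directly on
#' the packaged tables (no sequence data involved: the CpG classifications
#' are taken from the printed per-variant labels), reproducing the
#' originating screen's printed summaries.
#'
#' @return A list of class `"cpgpgx_fixture_screen"` with pathway-1
#'   summaries recomputed from the per-variant table, the function tally,
#'   the hub comparison, pathway-2 summaries, and the MAF-ranked
#'   disruptive/forming candidate lists.
#' @examples
#' fs <- run_fixture_screen()
#' fs$hub$overall_winner           # "CYP2D6"
#' fs$function_tally[["missense"]] # 61
#' @export
run_fixture_screen <- function() {
  t1 <- load_fixture("table1")
  t2 <- load_fixture("table2")
  t3 <- load_fixture("table3")
  t4 <- load_fixture("table4")
  t5 <- load_fixture("table5")
  t6 <- load_fixture("table6")

  # panel view of the 22 genes with a significant annotation
  panel <- data.frame(gene = t1$gene, processes = t1$processes,
                      relevance_score = t1$relevance_score,
                      stringsAsFactors = FALSE)
  # per-variant candidates, classification taken from the printed labels
  candidates <- t2
  candidates$n_significant_annotations <- NA_integer_
  gene_summaries <- tally_gene_pgx(
    candidates, panel,
    significant = data.frame(gene = rep(t1$gene, t1$n_significant_pgx),
                             stringsAsFactors = FALSE)
  )
  fn_tally <- tally_function(candidates)

  # seven-factor hub comparison (printed factor table), cross-checked
  # against factors recomputed from the per-variant table
  hub <- hub_comparison(t3)
  hub$factors <- t3
  recomputed <- do.call(rbind, lapply(t3$gene, function(g) {
    cg <- candidates[candidates$gene == g, , drop = FALSE]
    fd <- count_formations_disruptions(cg)
    data.frame(gene = g, n_cpg_pgx_snps = nrow(cg),
               n_variant_types = count_variant_types(cg),
               n_formations = fd[["n_formations"]],
               n_disruptions = fd[["n_disruptions"]],
               stringsAsFactors = FALSE)
  }))
  hub$recomputed_factors <- recomputed

  gwas_summaries <- t4[order(-t4$n_cpg_snps, -t4$n_refined_snps, t4$gene), ,
                       drop = FALSE]
  rownames(gwas_summaries) <- NULL

  structure(list(
    panel = panel,
    candidates = candidates,
    gene_summaries = gene_summaries,
    function_tally = fn_tally,
    hub = hub,
    gwas_summaries = gwas_summaries,
    ranked_disruptive = rank_by_maf(t5),
    ranked_forming = rank_by_maf(t6)
  ), class = "cpgpgx_fixture_screen")
}

#' @export
print.cpgpgx_fixture_screen <- function(x, ...) {
  cat("CpG-PGx screen replayed on packaged tables\n")
  cat("  CpG-PGx SNPs:", nrow(x$candidates), "in",
      length(unique(x$candidates$gene)), "genes\n")
  cat("  function tally:",
      paste(names(x$function_tally), x$function_tally, collapse = ", "), "\n")
  cat("  hub gene:", paste(x$hub$overall_winner, collapse = " / "),
      "with", x$hub$winner_factor_count, "of", length(x$hub$per_factor),
      "factors\n")
  cat("  GWAS pathway: top gene", x$gwas_summaries$gene[1], "with",
      x$gwas_summaries$n_cpg_snps[1], "CpG-SNPs\n")
  invisible(x)
}
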