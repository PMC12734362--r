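# Packaged reference tables transcribed from the originating screen of the
# 100-gene epigenetic panel (methylation, demethylation, acetylation,
# deacetylation), shipped as plain tab-separated files under extdata/.
#
#   table1  22 panel genes with at least one significant variant-drug
#           annotation, with per-gene annotation and CpG-PGx SNP counts
#   table2  the 99 classified CpG-PGx SNPs (function + CpG-site situation)
#   table3  seven-factor comparison of the three top pharmacogenes
#   table4  per-gene tallies for the GWAS-driven pathway (48 genes)
#   table5  MAF-prioritised CpG-disruptive candidate list
#   table6  MAF-prioritised CpG-forming candidate list
#
# Label strings are preserved verbatim (including spelling variants such as
# "3UTR", "3utr + CTCF" and "Deacetylattion"); normalised columns are added
# on load.  gnomAD / ClinVar-derived columns are carried as passthrough
# metadata and never recomputed.

#' Load a packaged reference table
#'
#' @param name One of `"table1"` ... `"table6"`.
#' @return A `data.frame` with the transcribed columns plus, where
#'   applicable, normalised helper columns: `consequences` and
#'   `region_features` (";"-joined, from the raw `function` label),
#'   `label` (`disruptive` / `forming` / `both`), and `processes`.
#' @examples
#' nrow(load_fixture("table2"))  # 99 classified CpG-PGx SNPs
#' @export
load_fixture <- function(name = c("table1", "table2", "table3",
                                  "table4", "table5", "table6")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "cpgpgx")
  if (!nzchar(path)) stop("fixture not found: ", name)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "",
                   stringsAsFactors = FALSE)
  switch(name,
    table1 = ,
    table4 = {
      df$relevance_score_raw <- df$relevance_score
      # genes curated under two processes carry one score per process;
      # keep the best for ranking
      df$relevance_score <- vapply(strsplit(df$relevance_score, "/"),
                                   function(x) max(as.numeric(x)), numeric(1))
      df$processes <- vapply(strsplit(df$epigenetic_process, "/"),
                             function(x) paste(normalize_process(x), collapse = ";"),
                             character(1))
      for (cl in intersect(c("n_significant_pgx", "n_cpg_pgx_snp",
                             "n_refined_snps", "n_cpg_snps"), colnames(df))) {
        df[[cl]] <- as.integer(df[[cl]])
      }
      df
    },
    table2 = {
      parsed <- parse_function_labels(df$`function`)
      df$consequences <- parsed$consequences
      df$region_features <- parsed$region_features
      df$label <- normalize_situation(df$cpg_situation)
      df
    },
    table3 = {
      df$relevance_score <- as.numeric(df$relevance_score)
      for (cl in c("n_significant_pgx", "n_cpg_pgx_snp", "n_variant_types",
                   "n_formations", "n_disruptions", "n_pubmed_titles")) {
        df[[cl]] <- as.integer(df[[cl]])
      }
      df
    },
    table5 = ,
    table6 = {
      parsed <- parse_function_labels(df$`function`)
      df$consequences <- parsed$consequences
      df$region_features <- parsed$region_features
      df$maf <- as.numeric(df$maf)
      df$label <- if (name == "table5") "disruptive" else "forming"
      df
    }
  )
}

# Map a raw printed function label (possibly compound, e.g.
# "Synonymous/EMAR+Enhancer" or "Missense + Inframeshift") onto the
# controlled consequence and region-feature vocabularies.
parse_function_labels <- function(x) {
  one <- function(raw) {
    tokens <- trimws(strsplit(raw, "[/+;]")[[1]])
    tokens <- tokens[nzchar(tokens)]
    cons <- character(0)
    reg <- character(0)
    for (tk in tolower(tokens)) {
      if (grepl("^missense", tk)) cons <- c(cons, "missense")
      else if (grepl("^synonym", tk)) cons <- c(cons, "synonymous")
      else if (grepl("^intron", tk)) cons <- c(cons, "intronic")
      else if (grepl("^(splic|spic)", tk)) cons <- c(cons, "splice")
      else if (grepl("^frameshift", tk)) cons <- c(cons, "frameshift")
      else if (grepl("^inframe", tk)) cons <- c(cons, "inframe")
      else if (grepl("^3", tk)) cons <- c(cons, "3'UTR")
      else if (grepl("^5", tk)) cons <- c(cons, "5'UTR")
      else if (grepl("^regulat|^tf", tk)) cons <- c(cons, "regulatory")
      else if (grepl("^emar", tk)) reg <- c(reg, "EMAR")
      else if (grepl("^enhancer", tk)) reg <- c(reg, "enhancer")
      else if (grepl("^promoter", tk)) reg <- c(reg, "promoter")
      else if (grepl("^ctcf", tk)) reg <- c(reg, "CTCF")
      else if (grepl("^open", tk)) reg <- c(reg, "open-chromatin")
      else stop("unrecognised function label token: '", tk, "' in '", raw, "'")
    }
    c(paste(unique(cons), collapse = ";"), paste(unique(reg), collapse = ";"))
  }
  m <- vapply(x, one, character(2), USE.NAMES = FALSE)
  list(consequences = m[1L, ], region_features = m[2L, ])
}

normalize_situation <- function(x) {
  lx <- tolower(trimws(x))
  out <- rep(NA_character_, length(x))
  out[grepl("forming", lx) & grepl("disrupt", lx)] <- "both"
  out[grepl("^forming$", lx)] <- "forming"
  out[grepl("^disruptive$", lx)] <- "disruptive"
  if (anyNA(out)) stop("unrecognised CpG site situation label: ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

# Reduce a variant's label set to its primary function.  `consequences` and
# `region_features` are ";"-joined strings; any region feature contributes
# the "regulatory" label.
primary_function <- function(consequences, region_features = "",
                             priority = DEFAULT_FUNCTION_PRIORITY) {
  vapply(seq_along(consequences), function(i) {
    labs <- strsplit(if (is.na(consequences[i])) "" else consequences[i], ";")[[1]]
    reg <- region_features[i]
    if (!is.na(reg) && nzchar(reg)) labs <- c(labs, "regulatory")
    labs <- labs[nzchar(labs)]
    hit <- priority[priority %in% labs]
    if (length(hit)) hit[1L] else "unlabeled"
  }, character(1))
}
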