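# Readers and writers for the external formats the screen consumes, plus the
# shared tabular data model.  All public coordinates are 1-based inclusive
# (VCF convention).  Multi-valued label fields (consequences, region
# features, processes) are stored as ";"-joined strings so every table
# round-trips through plain tab-separated files.

#' Screen configuration
#'
#' Collects the tunable thresholds of the two screening pathways.
#'
#' @param pgx_alpha Significance threshold for pathway 1 (variant-drug
#'   annotations).  Annotations are retained when `p_value < pgx_alpha`
#'   (strict).  Default 0.05.
#' @param gwas_p_threshold Genome-wide significance threshold for pathway 2.
#'   Associations are retained when `p_value < gwas_p_threshold` (strict).
#'   Default `5e-8`.
#' @param maf_min Minimum minor allele frequency for pathway 2.  Inclusive by
#'   default (`maf >= maf_min`), so associations printed exactly at the
#'   boundary are kept; set `maf_strict = TRUE` for a strict filter.
#'   Default 0.05.
#' @param maf_strict Use a strict (`>`) MAF comparison.  Default `FALSE`.
#' @param flank Context half-width in bases used when building sequence
#'   windows around a variant; must be at least 1 (one base up- and
#'   downstream suffices for SNVs).  Default 1.
#' @param apply_fdr Apply Benjamini-Hochberg adjustment to GWAS p-values
#'   before thresholding.  Default `FALSE`.
#' @param seed Integer seed recorded in reports and forwarded to any
#'   stochastic step.  Default 1.
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(pgx_alpha = 0.05, gwas_p_threshold = 5e-8,
                          maf_min = 0.05, maf_strict = FALSE, flank = 1L,
                          apply_fdr = FALSE, seed = 1L) {
  stopifnot(
    is.numeric(pgx_alpha), length(pgx_alpha) == 1L,
    pgx_alpha > 0, pgx_alpha < 1,
    is.numeric(gwas_p_threshold), gwas_p_threshold > 0, gwas_p_threshold < 1,
    is.numeric(maf_min), maf_min > 0, maf_min < 1,
    is.numeric(flank), flank >= 1,
    is.logical(maf_strict), is.logical(apply_fdr)
  )
  structure(
    list(pgx_alpha = pgx_alpha, gwas_p_threshold = gwas_p_threshold,
         maf_min = maf_min, maf_strict = isTRUE(maf_strict),
         flank = as.integer(flank), apply_fdr = isTRUE(apply_fdr),
         seed = as.integer(seed)),
    class = "screen_config"
  )
}

#' Construct a variant record table
#'
#' @param chrom,pos,ref,alt Vectors describing one variant per element:
#'   sequence name, 1-based position of the first reference base, and
#'   uppercase reference/alternate alleles (A, C, G, T, N).
#' @param rsid,gene Optional identifier and gene symbol (`NA` if absent).
#' @param consequences,region_features Optional ";"-joined label strings.
#' @param maf Optional minor allele frequency in `[0, 0.5]`.
#' @return A `data.frame` with one row per variant.
#' @export
variant_record <- function(chrom, pos, ref, alt, rsid = NA_character_,
                           gene = NA_character_,
                           consequences = NA_character_,
                           region_features = NA_character_,
                           maf = NA_real_) {
  df <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = toupper(as.character(ref)), alt = toupper(as.character(alt)),
    rsid = as.character(rsid), gene = as.character(gene),
    consequences = as.character(consequences),
    region_features = as.character(region_features),
    maf = as.numeric(maf),
    stringsAsFactors = FALSE
  )
  validate_variants(df)
  df
}

validate_variants <- function(df) {
  ok_allele <- function(x) grepl("^[ACGTN]+$", x)
  if (any(!ok_allele(df$ref)) || any(!ok_allele(df$alt))) {
    stop("alleles must be non-empty strings over A, C, G, T, N")
  }
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  if (any(df$pos < 1L)) stop("positions must be >= 1")
  maf <- df$maf[!is.na(df$maf)]
  if (length(maf) && (any(maf < 0) || any(maf > 0.5))) {
    stop("maf must lie in [0, 0.5]")
  }
  invisible(df)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; names are the first whitespace-delimited token
#' of each header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("FASTA format error at line 1: empty file")
  if (!startsWith(first, ">")) {
    stop("FASTA format error at line 1: expected '>' header, got '", first, "'")
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("FASTA format error in ", path, ": ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA format error at line 1: no sequences")
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# VCF

#' Read variant calls from a VCF file
#'
#' Only the fixed columns and the optional `GENE`, `CSQ`, `REG` and `MAF`
#' INFO keys are consulted.  Multi-allelic sites are expanded into one
#' record per alternate allele; records with symbolic or breakend alternate
#' alleles are skipped with a warning.
#'
#' @param path Path to a VCF 4.x file.
#' @return A variant `data.frame` (see [variant_record()]), one row per
#'   (site, alternate allele).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF format error in ", path, ": ",
                             conditionMessage(e))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  required <- c("CHROM", "POS", "REF", "ALT")
  if (!all(required %in% colnames(fix))) {
    stop("VCF format error: missing required column(s) ",
         paste(setdiff(required, colnames(fix)), collapse = ", "))
  }
  if (nrow(fix) == 0L) return(empty_variant_table())

  info_field <- function(info, key) {
    vapply(info, function(x) {
      if (is.na(x)) return(NA_character_)
      mm <- regmatches(x, regexpr(paste0("(?:^|;)", key, "=[^;]*"), x))
      if (length(mm) == 0L) return(NA_character_)
      sub(paste0("^;?", key, "="), "", mm)
    }, character(1), USE.NAMES = FALSE)
  }
  info <- if ("INFO" %in% colnames(fix)) fix$INFO else rep(NA_character_, nrow(fix))
  genes <- info_field(info, "GENE")
  csq <- info_field(info, "CSQ")
  reg <- info_field(info, "REG")
  mafs <- info_field(info, "MAF")

  rows <- vector("list", nrow(fix))
  n_skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i])
    alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]])
    maf_i <- strsplit(if (is.na(mafs[i])) "" else mafs[i], ",", fixed = TRUE)[[1]]
    keep <- list()
    for (j in seq_along(alts)) {
      alt <- alts[j]
      if (!grepl("^[ACGTN]+$", alt) || !grepl("^[ACGTN]+$", ref)) {
        n_skipped <- n_skipped + 1L
        next
      }
      maf_j <- if (length(maf_i) >= j) suppressWarnings(as.numeric(maf_i[j]))
               else if (length(maf_i) == 1L) suppressWarnings(as.numeric(maf_i))
               else NA_real_
      keep[[length(keep) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = ref, alt = alt,
        rsid = if (is.na(fix$ID[i]) || fix$ID[i] == ".") NA_character_ else fix$ID[i],
        gene = genes[i],
        consequences = if (is.na(csq[i])) NA_character_ else gsub("&", ";", csq[i]),
        region_features = if (is.na(reg[i])) NA_character_ else gsub("&", ";", reg[i]),
        maf = if (length(maf_j)) maf_j else NA_real_,
        stringsAsFactors = FALSE
      )
    }
    rows[[i]] <- if (length(keep)) do.call(rbind, keep) else NULL
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " alternate allele(s) skipped (symbolic or non-ACGTN)")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(empty_variant_table())
  rownames(out) <- NULL
  validate_variants(out)
  out
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), rsid = character(), gene = character(),
             consequences = character(), region_features = character(),
             maf = numeric(), stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Annotation tables

TABLE_SCHEMAS <- list(
  pgx = c("rsid", "gene", "drug", "p_value"),
  gwas = c("rsid", "gene", "trait", "p_value", "maf"),
  panel = c("gene", "process", "relevance_score")
)

#' Read a tab-separated annotation table
#'
#' Supported schemas: `"pgx"` (variant-drug annotations: `rsid`, `gene`,
#' `drug`, `p_value`), `"gwas"` (variant-trait associations: `rsid`,
#' `gene`, `trait`, `p_value`, `maf`) and `"panel"` (gene panel: `gene`,
#' `process`, `relevance_score`).  Rows violating the schema's value
#' invariants (p-values outside `(0, 1]`, MAF outside `[0, 0.5]`, unknown
#' epigenetic process) are dropped with a warning naming the row numbers.
#' Panel tables are deduplicated: each gene symbol appears once with all of
#' its processes merged (";"-joined) and its maximum relevance score.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema One of `"pgx"`, `"gwas"`, `"panel"`.
#' @return A typed `data.frame`; rejected row numbers are attached as
#'   `attr(, "rejected")`.
#' @export
read_table <- function(path, schema = c("pgx", "gwas", "panel")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("table file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character", quote = "",
                   stringsAsFactors = FALSE)
  required <- TABLE_SCHEMAS[[schema]]
  if (!all(required %in% colnames(df))) {
    stop("table format error in ", path, ": missing column(s) ",
         paste(setdiff(required, colnames(df)), collapse = ", "))
  }
  parse_annotation_table(df, schema, source = path)
}

parse_annotation_table <- function(df, schema, source = "table") {
  bad <- rep(FALSE, nrow(df))
  why <- character(nrow(df))
  flag <- function(i, msg) {
    bad[i] <<- TRUE
    why[i] <<- ifelse(nzchar(why[i]), why[i], msg)
  }
  if (schema %in% c("pgx", "gwas")) {
    p <- suppressWarnings(as.numeric(df$p_value))
    flag(which(is.na(p) | p <= 0 | p > 1), "p_value not in (0, 1]")
    df$p_value <- p
  }
  if (schema == "gwas") {
    maf <- suppressWarnings(as.numeric(df$maf))
    flag(which(is.na(maf) | maf < 0 | maf > 0.5), "maf not in [0, 0.5]")
    df$maf <- maf
  }
  if (schema == "panel") {
    score <- suppressWarnings(as.numeric(df$relevance_score))
    flag(which(is.na(score) | score < 0), "relevance_score not a non-negative number")
    proc <- normalize_process(df$process)
    flag(which(is.na(proc)), "unknown epigenetic process")
    df$relevance_score <- score
    df$process <- proc
  }
  if (any(bad)) {
    warning("rejected ", sum(bad), " row(s) of ", source, ": ",
            paste0("row ", which(bad), " (", why[bad], ")", collapse = "; "))
  }
  df <- df[!bad, , drop = FALSE]
  rownames(df) <- NULL
  if (schema == "panel") df <- dedupe_panel(df)
  attr(df, "rejected") <- which(bad)
  df
}

# Map free-text process labels onto the four canonical epigenetic processes.
normalize_process <- function(x) {
  out <- rep(NA_character_, length(x))
  lx <- tolower(trimws(x))
  out[grepl("^demethyl", lx)] <- "demethylation"
  out[grepl("^methyl", lx)] <- "methylation"
  out[grepl("^deacetyl", lx)] <- "deacetylation"
  out[grepl("^acetyl", lx)] <- "acetylation"
  out
}

# One row per gene with all processes merged; the best (maximum) relevance
# score is retained alongside the per-process scores.
dedupe_panel <- function(df) {
  split_rows <- split(seq_len(nrow(df)), df$gene)
  out <- do.call(rbind, lapply(split_rows, function(idx) {
    data.frame(
      gene = df$gene[idx[1L]],
      processes = paste(sort(unique(df$process[idx])), collapse = ";"),
      relevance_score = max(df$relevance_score[idx]),
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(match(out$gene, df$gene)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a table as tab-separated text
#'
#' Companion to [read_table()]; the round trip preserves records exactly.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
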