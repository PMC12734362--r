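# Seeded generators emulating every input the screen consumes, with planted
# ground truth: reference sequences with a tunable CpG rate, variants spiked
# by construction into known delta classes (SNVs and indels), and
# annotation tables whose p-values and MAFs straddle the screening
# thresholds.  Every generated label is confirmed against a full-sequence
# brute-force check before a scenario is emitted.

#' Generate random reference sequences with a tunable CpG rate
#'
#' Sequences are drawn from a first-order Markov chain whose C->G
#' transition probability is tuned (by fixed-point iteration on the
#' stationary distribution) so that the expected CpG dinucleotide
#' frequency equals `cpg_rate` at the requested GC content.
#'
#' @param n_seqs Number of sequences.
#' @param length Length of each sequence in bases (>= 10).
#' @param gc GC content in `[0, 1]`.
#' @param cpg_rate Target CpG dinucleotide frequency (per dinucleotide
#'   position); must not exceed the attainable bound of about `gc / 2`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return Named character vector of uppercase sequences (`seq1`, ...).
#' @export
synth_reference <- function(n_seqs = 1L, length = 10000L, gc = 0.42,
                            cpg_rate = 0.02, seed = 1L) {
  stopifnot(length >= 10L, gc >= 0, gc <= 1, cpg_rate >= 0, cpg_rate <= 1)
  pi0 <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (cpg_rate > 0 && (gc == 0 || cpg_rate > gc / 2)) {
    stop("infeasible cpg_rate ", cpg_rate, " for gc ", gc,
         " (attainable maximum is about gc/2)")
  }
  # Fixed point: P(G|C) = cpg_rate / pi*(C), where the stationary pi*(C)
  # itself depends on P(G|C) through the renormalised C row.
  pi_c <- pi0[["C"]]
  p_cg <- if (pi_c > 0) cpg_rate / pi_c else 0
  if (cpg_rate > 0) {
    for (iter in 1:20) {
      p_cc <- (1 - p_cg) * pi0[["C"]] / (1 - pi0[["G"]])
      pi_c <- pi0[["C"]] / (1 + pi0[["C"]] - p_cc)
      p_cg <- min(1, cpg_rate / pi_c)
    }
  }
  bases <- c("A", "C", "G", "T")
  from_c <- c(A = (1 - p_cg) * pi0[["A"]] / (1 - pi0[["G"]]),
              C = (1 - p_cg) * pi0[["C"]] / (1 - pi0[["G"]]),
              G = p_cg,
              T = (1 - p_cg) * pi0[["T"]] / (1 - pi0[["G"]]))
  cum_pi <- cumsum(pi0)
  cum_c <- cumsum(from_c)
  withr::with_seed(as.integer(seed), {
    seqs <- vapply(seq_len(n_seqs), function(k) {
      u <- runif(length)
      idx <- integer(length)
      idx[1L] <- findInterval(u[1L], cum_pi) + 1L
      for (i in 2:length) {
        cc <- if (idx[i - 1L] == 2L) cum_c else cum_pi  # state 2 = C
        idx[i] <- findInterval(u[i], cc) + 1L
      }
      paste(bases[idx], collapse = "")
    }, character(1))
    names(seqs) <- paste0("seq", seq_len(n_seqs))
    seqs
  })
}

# Full-sequence brute-force delta check used as the generator self-check:
# apply the variant to the whole sequence and positionally compare the two
# complete CpG sets.
brute_force_delta <- function(seqstr, pos, ref, alt) {
  stopifnot(substr(seqstr, pos, pos + nchar(ref) - 1L) == ref)
  altseq <- paste0(substr(seqstr, 1L, pos - 1L), alt,
                   substr(seqstr, pos + nchar(ref), nchar(seqstr)))
  R <- cpg_starts(seqstr)
  A <- cpg_starts(altseq)
  m <- match_cpg_sets(R, A, nchar(alt) - nchar(ref))
  n_lost <- length(R) - m
  n_gained <- length(A) - m
  if (n_lost > 0L && n_gained > 0L) "both"
  else if (n_lost > 0L) "disruptive"
  else if (n_gained > 0L) "forming"
  else "neutral"
}

#' Spike variants with known CpG delta truth labels into a reference
#'
#' Constructs variants directly from the sequence so that each one's delta
#' class is known by construction: disruptive variants mutate (or delete)
#' the C or G of an existing CpG, forming variants create a CpG from an
#' XpG context (or insert one), `both` variants hit the middle base of a
#' CGG trigram (destroying one CpG and creating its neighbour), and
#' neutral variants touch no CpG.  The requested fraction of the
#' disruptive, forming and neutral variants are emitted as indels.  Every
#' emitted label is re-verified against the full mutated sequence.
#'
#' @param reference Named character vector of sequences.
#' @param n_per_class Named integer vector with (a subset of) entries
#'   `disruptive`, `forming`, `both`, `neutral`.
#' @param indel_fraction Fraction of the disruptive/forming/neutral
#'   variants emitted as indels (deletions/insertions).
#' @param seed Integer seed.
#' @param genes Optional character vector of gene symbols to assign to
#'   variants (uniformly at random).
#' @return List with `variants` (a variant `data.frame` with a
#'   `true_label` and `is_indel` column) and `vcf` (character vector of
#'   VCF lines).
#' @export
spike_variants <- function(reference, n_per_class, indel_fraction = 0,
                           seed = 1L, genes = NULL) {
  classes <- c(disruptive = 0L, forming = 0L, both = 0L, neutral = 0L)
  classes[names(n_per_class)] <- as.integer(n_per_class)
  stopifnot(all(classes >= 0L), indel_fraction >= 0, indel_fraction <= 1)
  conseq_pool <- c("missense", "synonymous", "intronic", "3'UTR", "splice")
  region_pool <- c("", "", "", "EMAR", "enhancer", "promoter")

  withr::with_seed(as.integer(seed), {
    chars <- lapply(reference, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    used <- lapply(chars, function(b) logical(length(b)))

    # candidate positions (per sequence) for each construction
    sites <- function(pred_fun) {
      do.call(rbind, lapply(seq_along(chars), function(k) {
        idx <- pred_fun(chars[[k]])
        if (length(idx)) data.frame(k = k, i = idx) else NULL
      }))
    }
    cand <- list(
      dis_snv = sites(function(b) {
        i <- 2:(length(b) - 1L)
        i[b[i] == "C" & b[i + 1L] == "G"]
      }),
      dis_del = sites(function(b) {
        i <- 2:(length(b) - 2L)
        i[b[i] == "C" & b[i + 1L] == "G" & b[i + 2L] != "G"]
      }),
      form_snv = sites(function(b) {
        i <- 2:(length(b) - 1L)
        i[b[i] %in% c("A", "T") & b[i + 1L] == "G"]
      }),
      form_ins = sites(function(b) {
        i <- 2:(length(b) - 1L)
        i[b[i] %in% c("A", "T")]
      }),
      both_snv = sites(function(b) {
        i <- 2:(length(b) - 1L)
        i[b[i - 1L] == "C" & b[i] == "G" & b[i + 1L] == "G"]
      }),
      neut_snv = sites(function(b) {
        i <- 2:(length(b) - 1L)
        i[b[i] %in% c("A", "T") & b[i + 1L] != "G"]
      }),
      neut_ins = sites(function(b) {
        i <- 2:(length(b) - 1L)
        i[b[i] %in% c("A", "G")]
      })
    )

    take <- function(kind, n, class_name) {
      if (n == 0L) return(NULL)
      tab <- cand[[kind]]
      if (is.null(tab)) tab <- data.frame(k = integer(), i = integer())
      tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
      picked <- list()
      for (r in seq_len(nrow(tab))) {
        if (length(picked) == n) break
        k <- tab$k[r]; i <- tab$i[r]
        win <- max(1L, i - 4L):min(length(used[[k]]), i + 5L)
        if (any(used[[k]][win])) next
        used[[k]][win] <<- TRUE
        picked[[length(picked) + 1L]] <- c(k, i)
      }
      if (length(picked) < n) {
        stop("not enough eligible positions for class '", class_name, "'")
      }
      do.call(rbind, picked)
    }

    n_ind <- function(class) {
      as.integer(round(classes[[class]] * indel_fraction))
    }
    plan <- list(
      dis_del = take("dis_del", n_ind("disruptive"), "disruptive"),
      dis_snv = take("dis_snv", classes[["disruptive"]] - n_ind("disruptive"),
                     "disruptive"),
      form_ins = take("form_ins", n_ind("forming"), "forming"),
      form_snv = take("form_snv", classes[["forming"]] - n_ind("forming"),
                      "forming"),
      both_snv = take("both_snv", classes[["both"]], "both"),
      neut_ins = take("neut_ins", n_ind("neutral"), "neutral"),
      neut_snv = take("neut_snv", classes[["neutral"]] - n_ind("neutral"),
                      "neutral")
    )

    rows <- list()
    emit <- function(k, pos, ref, alt, label, is_indel) {
      stopifnot(brute_force_delta(reference[[k]], pos, ref, alt) == label)
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = names(reference)[k], pos = pos, ref = ref, alt = alt,
        rsid = NA_character_, gene = NA_character_,
        consequences = sample(conseq_pool, 1L),
        region_features = sample(region_pool, 1L),
        maf = round(runif(1, 0.01, 0.5), 3),
        true_label = label, is_indel = is_indel,
        stringsAsFactors = FALSE
      )
    }
    for (kind in names(plan)) {
      sel <- plan[[kind]]
      if (is.null(sel)) next
      for (r in seq_len(nrow(sel))) {
        k <- sel[r, 1L]; i <- sel[r, 2L]
        b <- chars[[k]]
        switch(kind,
          dis_snv = {
            opts <- setdiff(c("A", "T", "G"), if (b[i - 1L] == "C") "G")
            emit(k, i, "C", sample(opts, 1L), "disruptive", FALSE)
          },
          dis_del = emit(k, i, "CG", "C", "disruptive", TRUE),
          form_snv = emit(k, i, b[i], "C", "forming", FALSE),
          form_ins = emit(k, i, b[i], paste0(b[i], "CG"), "forming", TRUE),
          both_snv = emit(k, i, "G", "C", "both", FALSE),
          neut_snv = emit(k, i, b[i], if (b[i] == "A") "T" else "A",
                          "neutral", FALSE),
          neut_ins = emit(k, i, b[i], paste0(b[i], "T"), "neutral", TRUE)
        )
      }
    }
    variants <- if (length(rows)) do.call(rbind, rows) else {
      cbind(empty_variant_table(),
            data.frame(true_label = character(), is_indel = logical()))
    }
    if (nrow(variants)) {
      variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
      variants$rsid <- sprintf("simrs%04d", seq_len(nrow(variants)))
      if (!is.null(genes) && length(genes)) {
        variants$gene <- sample(genes, nrow(variants), replace = TRUE)
      }
      rownames(variants) <- NULL
    }
    list(variants = variants, vcf = render_vcf(variants, reference))
  })
}

# Render a variant table as VCF 4.3 text lines.
render_vcf <- function(variants, reference) {
  header <- c(
    "##fileformat=VCFv4.3",
    sprintf("##contig=<ID=%s,length=%d>", names(reference), nchar(reference)),
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=MAF,Number=A,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence labels\">",
    "##INFO=<ID=REG,Number=.,Type=String,Description=\"Regulatory region features\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  if (nrow(variants) == 0L) return(header)
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    if (!is.na(variants$gene[i])) {
      parts <- c(parts, paste0("GENE=", variants$gene[i]))
    }
    if (!is.na(variants$maf[i])) {
      parts <- c(parts, paste0("MAF=", format(variants$maf[i], scientific = FALSE)))
    }
    if (!is.na(variants$consequences[i]) && nzchar(variants$consequences[i])) {
      parts <- c(parts, paste0("CSQ=", gsub(";", "&", variants$consequences[i])))
    }
    if (!is.na(variants$region_features[i]) && nzchar(variants$region_features[i])) {
      parts <- c(parts, paste0("REG=", gsub(";", "&", variants$region_features[i])))
    }
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))
  body <- paste(variants$chrom, variants$pos, variants$rsid, variants$ref,
                variants$alt, ".", "PASS", info, sep = "\t")
  c(header, body)
}

#' Generate PGx and GWAS annotation tables with planted significance
#'
#' Variants of `pgx_genes` receive one to three variant-drug annotations
#' each; a planted fraction are significant, with p-values drawn uniformly
#' below the 0.05 threshold (non-significant ones uniformly above).
#' Variants of `gwas_genes` receive variant-trait associations whose
#' significant p-values are drawn log-uniformly below the genome-wide
#' 5e-8 threshold; association MAFs reuse each variant's MAF, which is
#' uniform on [0.01, 0.5] so the MAF filter has bite.  When
#' `plant_boundaries` is set, one annotation is planted exactly at each
#' threshold (p = 0.05 and p = 5e-8, both non-significant by the strict
#' filters) and one significant association exactly at MAF = 0.05 (kept by
#' the default inclusive filter).
#'
#' @param variants Variant table from [spike_variants()] (with `gene` and
#'   `maf` columns).
#' @param pgx_genes,gwas_genes Gene symbols routed to each pathway.
#' @param frac_pgx_significant,frac_gwas_significant Planted significant
#'   fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @param plant_boundaries Plant exact-threshold rows.  Default `TRUE`.
#' @return List with `pgx` and `gwas` tables; each carries truth columns
#'   (`significant` for pgx; `significant_p`, `maf_pass`, `refined` for
#'   gwas) alongside the schema columns.
#' @export
synth_annotation_tables <- function(variants, pgx_genes, gwas_genes,
                                    frac_pgx_significant = 0.7,
                                    frac_gwas_significant = 0.6,
                                    seed = 1L, plant_boundaries = TRUE) {
  stopifnot(frac_pgx_significant >= 0, frac_pgx_significant <= 1,
            frac_gwas_significant >= 0, frac_gwas_significant <= 1)
  withr::with_seed(as.integer(seed), {
    drugs <- paste0("drug_", letters[1:12])
    traits <- paste0("trait_", letters[1:12])
    pgx_rows <- list()
    gwas_rows <- list()
    for (i in seq_len(nrow(variants))) {
      g <- variants$gene[i]
      if (is.na(g)) next
      if (g %in% pgx_genes) {
        for (a in seq_len(sample(1:3, 1L))) {
          sig <- runif(1) < frac_pgx_significant
          p <- if (sig) runif(1, 1e-12, 0.05) else runif(1, 0.05, 1)
          pgx_rows[[length(pgx_rows) + 1L]] <- data.frame(
            rsid = variants$rsid[i], gene = g,
            drug = sample(drugs, 1L), p_value = p, significant = sig,
            stringsAsFactors = FALSE
          )
        }
      }
      if (g %in% gwas_genes) {
        for (a in seq_len(sample(1:2, 1L))) {
          sig <- runif(1) < frac_gwas_significant
          p <- if (sig) 10^runif(1, -20, log10(5e-8)) else 10^runif(1, log10(5e-8), 0)
          maf <- variants$maf[i]
          gwas_rows[[length(gwas_rows) + 1L]] <- data.frame(
            rsid = variants$rsid[i], gene = g,
            trait = sample(traits, 1L), p_value = p, maf = maf,
            significant_p = sig, maf_pass = maf >= 0.05,
            stringsAsFactors = FALSE
          )
        }
      }
    }
    pgx <- if (length(pgx_rows)) do.call(rbind, pgx_rows) else
      data.frame(rsid = character(), gene = character(), drug = character(),
                 p_value = numeric(), significant = logical(),
                 stringsAsFactors = FALSE)
    gwas <- if (length(gwas_rows)) do.call(rbind, gwas_rows) else
      data.frame(rsid = character(), gene = character(), trait = character(),
                 p_value = numeric(), maf = numeric(),
                 significant_p = logical(), maf_pass = logical(),
                 stringsAsFactors = FALSE)

    if (isTRUE(plant_boundaries)) {
      vp <- variants[!is.na(variants$gene) & variants$gene %in% pgx_genes, ]
      if (nrow(vp)) {
        pgx <- rbind(pgx, data.frame(
          rsid = vp$rsid[1L], gene = vp$gene[1L], drug = "drug_boundary",
          p_value = 0.05, significant = FALSE, stringsAsFactors = FALSE
        ))
      }
      vg <- variants[!is.na(variants$gene) & variants$gene %in% gwas_genes, ]
      if (nrow(vg)) {
        gwas <- rbind(gwas,
          data.frame(rsid = vg$rsid[1L], gene = vg$gene[1L],
                     trait = "trait_boundary_p", p_value = 5e-8,
                     maf = 0.3, significant_p = FALSE, maf_pass = TRUE,
                     stringsAsFactors = FALSE))
      }
      if (nrow(vg) >= 2L) {
        gwas <- rbind(gwas,
          data.frame(rsid = vg$rsid[2L], gene = vg$gene[2L],
                     trait = "trait_boundary_maf", p_value = 1e-9,
                     maf = 0.05, significant_p = TRUE, maf_pass = TRUE,
                     stringsAsFactors = FALSE))
      }
      if (nrow(vg) >= 3L) {
        gwas <- rbind(gwas,
          data.frame(rsid = vg$rsid[3L], gene = vg$gene[3L],
                     trait = "trait_low_maf", p_value = 1e-9,
                     maf = 0.049, significant_p = TRUE, maf_pass = FALSE,
                     stringsAsFactors = FALSE))
      }
    }
    gwas$refined <- gwas$significant_p & gwas$maf_pass
    rownames(pgx) <- rownames(gwas) <- NULL
    list(pgx = pgx, gwas = gwas)
  })
}

#' Generate a complete desk-scale screening scenario
#'
#' Bundles a reference, spiked variants, annotation tables and a gene
#' panel, together with the planted truth every pipeline output can be
#' compared against.  The default scenario uses two 12 kb sequences,
#' 88 variants (30 disruptive, 30 forming, 3 both, 25 neutral; a quarter
#' of the non-`both` classes as indels) and a 12-gene panel split evenly
#' between the two pathways.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function
#'   of it.
#' @param dir Optional directory: when given, the scenario is written as
#'   `reference.fa`, `variants.vcf`, `pgx.tsv`, `gwas.tsv`, `panel.tsv`
#'   and a `truth.json` sidecar, and the paths are returned in the bundle.
#' @return List with `reference`, `variants`, `pgx`, `gwas`, `panel`,
#'   `truth` (see Details) and, when `dir` is given, `paths`.
#' @details `truth` contains `labels` (rsid to true delta label),
#'   `pathway1_genes`, `pathway2_genes`, `per_gene_pgx` (gene,
#'   n_significant_annotations, n_cpg_pgx_snps), `per_gene_gwas` (gene,
#'   n_refined_snps, n_cpg_snps) and `delta_split` (disruptive / forming /
#'   both counts among pathway-2 candidates).
#' @export
make_scenario <- function(seed = 1L, dir = NULL) {
  seed <- as.integer(seed)
  panel_genes <- sprintf("EPG%02d", 1:12)
  panel <- data.frame(
    gene = c(panel_genes, panel_genes[c(2, 5, 8, 11)]),
    process = c(rep(PROCESS_LEVELS, 3L), PROCESS_LEVELS),
    stringsAsFactors = FALSE
  )
  panel$relevance_score <- withr::with_seed(seed, round(runif(nrow(panel), 1, 40), 4))

  reference <- synth_reference(n_seqs = 2L, length = 12000L, gc = 0.45,
                               cpg_rate = 0.02, seed = seed)
  sv <- spike_variants(reference,
                       n_per_class = c(disruptive = 30L, forming = 30L,
                                       both = 3L, neutral = 25L),
                       indel_fraction = 0.25, seed = seed + 1L,
                       genes = panel_genes)
  pgx_genes <- panel_genes[1:6]
  gwas_genes <- panel_genes[7:12]
  ann <- synth_annotation_tables(sv$variants, pgx_genes, gwas_genes,
                                 frac_pgx_significant = 0.7,
                                 frac_gwas_significant = 0.6,
                                 seed = seed + 2L)

  v <- sv$variants
  nonneutral <- v$rsid[v$true_label != "neutral"]
  sig_pgx <- ann$pgx[ann$pgx$significant, , drop = FALSE]
  pathway1_genes <- sort(unique(sig_pgx$gene))
  pathway2_genes <- sort(setdiff(unique(panel$gene), pathway1_genes))

  cand1 <- unique(sig_pgx$rsid[sig_pgx$rsid %in% nonneutral])
  per_gene_pgx <- data.frame(
    gene = pathway1_genes,
    n_significant_annotations = vapply(pathway1_genes, function(g)
      sum(sig_pgx$gene == g), integer(1)),
    n_cpg_pgx_snps = vapply(pathway1_genes, function(g)
      length(unique(sig_pgx$rsid[sig_pgx$gene == g &
                                   sig_pgx$rsid %in% nonneutral])),
      integer(1)),
    stringsAsFactors = FALSE
  )

  refined <- ann$gwas[ann$gwas$refined & ann$gwas$gene %in% pathway2_genes, ,
                      drop = FALSE]
  # per-gene truth mirrors the summary contract: one row per gene with at
  # least one non-neutral variant among its refined associations
  gwas_genes_seen <- sort(unique(
    refined$gene[refined$rsid %in% nonneutral]))
  per_gene_gwas <- data.frame(
    gene = gwas_genes_seen,
    n_refined_snps = vapply(gwas_genes_seen, function(g)
      sum(refined$gene == g), integer(1)),
    n_cpg_snps = vapply(gwas_genes_seen, function(g)
      length(unique(refined$rsid[refined$gene == g &
                                   refined$rsid %in% nonneutral])),
      integer(1)),
    stringsAsFactors = FALSE
  )
  cand2 <- unique(refined$rsid[refined$rsid %in% nonneutral])
  lab2 <- v$true_label[match(cand2, v$rsid)]
  truth <- list(
    labels = setNames(v$true_label, v$rsid),
    pathway1_genes = pathway1_genes,
    pathway2_genes = pathway2_genes,
    per_gene_pgx = per_gene_pgx,
    per_gene_gwas = per_gene_gwas,
    n_cpg_pgx_snps = length(cand1),
    delta_split = c(disruptive = sum(lab2 == "disruptive"),
                    forming = sum(lab2 == "forming"),
                    both = sum(lab2 == "both"))
  )

  bundle <- list(reference = reference, variants = v,
                 pgx = ann$pgx, gwas = ann$gwas, panel = panel,
                 truth = truth, seed = seed)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      fasta = file.path(dir, "reference.fa"),
      vcf = file.path(dir, "variants.vcf"),
      pgx = file.path(dir, "pgx.tsv"),
      gwas = file.path(dir, "gwas.tsv"),
      panel = file.path(dir, "panel.tsv"),
      truth = file.path(dir, "truth.json")
    )
    write_fasta(reference, paths$fasta)
    writeLines(sv$vcf, paths$vcf)
    write_table(ann$pgx[, c("rsid", "gene", "drug", "p_value")], paths$pgx)
    write_table(ann$gwas[, c("rsid", "gene", "trait", "p_value", "maf")],
                paths$gwas)
    write_table(panel, paths$panel)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    bundle$paths <- paths
  }
  bundle
}
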