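# Seeded generators and their planted ground truth.

test_that("synth_reference is seed-deterministic and hits the CpG rate", {
  a <- synth_reference(2, 500, gc = 0.5, cpg_rate = 0.03, seed = 5)
  b <- synth_reference(2, 500, gc = 0.5, cpg_rate = 0.03, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, synth_reference(2, 500, 0.5, 0.03, seed = 6)))

  none <- synth_reference(1, 2000, gc = 0.5, cpg_rate = 0, seed = 1)
  expect_equal(count_cpg(none[[1]]), 0L)

  # observed CpG frequency within 3 binomial standard errors of the target
  target <- 0.02
  len <- 10000L
  s <- synth_reference(1, len, gc = 0.42, cpg_rate = target, seed = 9)
  obs <- count_cpg(s[[1]]) / (len - 1)
  se <- sqrt(target * (1 - target) / (len - 1))
  expect_lt(abs(obs - target), 3 * se)

  expect_error(synth_reference(1, 1000, gc = 0.2, cpg_rate = 0.5, seed = 1),
               "infeasible")
})

test_that("spike_variants plants recoverable labels for SNVs and indels", {
  ref <- synth_reference(1, 8000, gc = 0.45, cpg_rate = 0.025, seed = 2)
  sv <- spike_variants(ref, c(disruptive = 10, forming = 10, both = 1,
                              neutral = 20),
                       indel_fraction = 0.3, seed = 3)
  v <- sv$variants
  expect_equal(nrow(v), 41L)
  expect_equal(sum(v$true_label == "disruptive"), 10L)
  expect_equal(sum(v$true_label == "forming"), 10L)
  expect_equal(sum(v$true_label == "both"), 1L)
  expect_equal(sum(v$true_label == "neutral"), 20L)
  expect_equal(sum(v$is_indel), 3L + 3L + 6L)  # 30% of 10/10/20

  # classify_batch recovers every truth label exactly
  out <- classify_batch(v, ref, screen_config())
  expect_true(all(is.na(out$error)))
  expect_equal(out$label, v$true_label)

  # and the independent full-sequence oracle agrees
  for (i in seq_len(nrow(v))) {
    expect_equal(oracle_delta(ref[[v$chrom[i]]], v$pos[i], v$ref[i],
                              v$alt[i])$label,
                 v$true_label[i])
  }
})

test_that("spike_variants is deterministic and validates feasibility", {
  ref <- synth_reference(1, 4000, gc = 0.45, cpg_rate = 0.02, seed = 2)
  a <- spike_variants(ref, c(disruptive = 5, forming = 5), seed = 8)
  b <- spike_variants(ref, c(disruptive = 5, forming = 5), seed = 8)
  expect_identical(a, b)

  zero <- spike_variants(ref, c(disruptive = 0), seed = 1)
  expect_equal(nrow(zero$variants), 0L)

  tiny <- c(s = "ATATATATATATATAT")  # no CpG sites at all
  expect_error(spike_variants(tiny, c(disruptive = 3), seed = 1),
               "disruptive")
})

test_that("synth_annotation_tables plants significance that the filters recover", {
  ref <- synth_reference(1, 8000, gc = 0.45, cpg_rate = 0.025, seed = 4)
  sv <- spike_variants(ref, c(disruptive = 8, forming = 8, neutral = 8),
                       seed = 5, genes = c("GP1", "GP2", "GW1", "GW2"))
  ann <- synth_annotation_tables(sv$variants, pgx_genes = c("GP1", "GP2"),
                                 gwas_genes = c("GW1", "GW2"), seed = 6)
  # truth flags match the filters exactly, including boundaries
  sig <- filter_significant_pgx(ann$pgx)
  expect_setequal(which(ann$pgx$significant),
                  which(ann$pgx$p_value < 0.05))
  expect_equal(nrow(sig), sum(ann$pgx$significant))
  expect_true(any(ann$pgx$p_value == 0.05))  # planted boundary, excluded

  refined <- filter_gwas(ann$gwas)
  expect_equal(sort(refined$rsid), sort(ann$gwas$rsid[ann$gwas$refined]))
  expect_true(any(ann$gwas$p_value == 5e-8))   # excluded boundary
  expect_true(any(ann$gwas$maf == 0.05 &
                    ann$gwas$refined))         # retained boundary

  # no significant fraction -> nothing survives
  none <- synth_annotation_tables(sv$variants, pgx_genes = c("GP1", "GP2"),
                                  gwas_genes = c("GW1", "GW2"),
                                  frac_gwas_significant = 0,
                                  seed = 7, plant_boundaries = FALSE)
  expect_equal(nrow(filter_gwas(none$gwas)), 0L)

  # determinism
  again <- synth_annotation_tables(sv$variants, pgx_genes = c("GP1", "GP2"),
                                   gwas_genes = c("GW1", "GW2"), seed = 6)
  expect_identical(ann, again)
})

test_that("make_scenario writes a self-consistent bundle deterministically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- make_scenario(seed = 3, dir = d1)
  s2 <- make_scenario(seed = 3, dir = d2)
  for (f in c("reference.fa", "variants.vcf", "pgx.tsv", "gwas.tsv",
              "panel.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  expect_false(identical(s1$variants, make_scenario(seed = 4)$variants))

  # planted per-gene counts equal the sums of per-variant truths
  tr <- s1$truth
  expect_equal(sum(tr$per_gene_pgx$n_cpg_pgx_snps), tr$n_cpg_pgx_snps)
  expect_equal(sum(tr$delta_split),
               sum(tr$per_gene_gwas$n_cpg_snps) -
                 0L)  # same unique variants, gene-disjoint by construction

  # files parse back through the package readers
  expect_identical(read_fasta(s1$paths$fasta), s1$reference)
  v <- read_vcf(s1$paths$vcf)
  expect_equal(nrow(v), nrow(s1$variants))
  expect_setequal(v$rsid, s1$variants$rsid)
})
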