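# The CpG delta classifier and its supporting primitives.

test_that("count_cpg counts non-overlapping CG dinucleotides, N matches nothing", {
  expect_equal(count_cpg("ACGT"), 1L)
  expect_equal(count_cpg("CGCG"), 2L)
  expect_equal(count_cpg("CCGG"), 1L)
  expect_equal(count_cpg("GC"), 0L)
  expect_equal(count_cpg("CNG"), 0L)
  expect_equal(count_cpg("C"), 0L)
  expect_error(count_cpg("ACGU"), "A, C, G, T, N")
})

test_that("normalize_variant trims, left-aligns, and validates", {
  # SNV: identity
  ref <- c(s = "ACGTAGA")
  v <- normalize_variant(variant_record("s", 5, "A", "G"), ref)
  expect_equal(c(v$pos, v$ref, v$alt), c("5", "A", "G"))

  # deletion in a homopolymer left-aligns to the run's leftmost anchor
  v <- normalize_variant(variant_record("s", 3, "TT", "T"), c(s = "GTTTTC"))
  expect_equal(v$pos, 1L)
  expect_equal(v$ref, "GT")
  expect_equal(v$alt, "G")
  # both representations reconstruct the same haplotype
  apply_var <- function(s, pos, ref, alt) {
    paste0(substr(s, 1, pos - 1), alt, substr(s, pos + nchar(ref), nchar(s)))
  }
  expect_equal(apply_var("GTTTTC", 3, "TT", "T"),
               apply_var("GTTTTC", v$pos, v$ref, v$alt))

  # shared-prefix/suffix trimming of a padded SNV
  v <- normalize_variant(variant_record("s", 2, "CGT", "CTT"), c(s = "ACGTA"))
  expect_equal(v$pos, 3L)
  expect_equal(c(v$ref, v$alt), c("G", "T"))

  expect_error(normalize_variant(variant_record("s", 5, "AT", "AT"),
                                 c(s = "ACGTATA")),
               "differ")
  expect_error(normalize_variant(variant_record("s", 2, "G", "T"),
                                 c(s = "ACGTA")),
               "mismatch")
  expect_error(normalize_variant(variant_record("x", 1, "A", "T"),
                                 c(s = "ACGTA")),
               "unknown sequence")
})

test_that("normalized representation is stable and haplotype-preserving on random indels", {
  withr::local_seed(421)
  apply_var <- function(s, pos, ref, alt) {
    paste0(substr(s, 1, pos - 1), alt, substr(s, pos + nchar(ref), nchar(s)))
  }
  for (rep in 1:200) {
    case <- random_variant_case()
    v0 <- variant_record("s", case$pos, case$ref, case$alt)
    v1 <- normalize_variant(v0, setNames(case$seq, "s"))
    # same haplotype from both representations
    expect_equal(apply_var(case$seq, case$pos, case$ref, case$alt),
                 apply_var(case$seq, v1$pos, v1$ref, v1$alt))
    # idempotent
    v2 <- normalize_variant(v1, setNames(case$seq, "s"))
    expect_identical(v1, v2)
  }
})

test_that("build_windows covers the affected span plus the effective flank", {
  # SNV, flank 1
  w <- build_windows(variant_record("s", 3, "G", "T"), c(s = "ACGTA"), 1)
  expect_equal(w$context$ref_window, "CGT")
  expect_equal(w$alt_window, "CTT")
  expect_equal(w$context$variant_offset, 1L)
  expect_equal(w$context$window_start, 2L)

  # SNV at position 1: truncated left flank
  w <- build_windows(variant_record("s", 1, "A", "T"), c(s = "ACGTA"), 1)
  expect_equal(w$context$window_start, 1L)
  expect_equal(w$context$variant_offset, 0L)

  # deletion: effective flank max(flank, |ref|, |alt|) = 2
  w <- build_windows(variant_record("s", 2, "AC", "A"), c(s = "TACGA"), 1)
  expect_equal(w$context$ref_window, "TACGA")
  expect_equal(w$alt_window, "TAGA")
  # the alternate window is the windowed slice of the full mutated sequence
  full_alt <- paste0(substr("TACGA", 1, 1), "A", substr("TACGA", 4, 5))
  expect_equal(w$alt_window, full_alt)
})

test_that("classify_cpg_delta reproduces the four delta classes", {
  cls <- function(seq, pos, ref, alt, flank = 1) {
    classify_case(list(seq = seq, pos = pos, ref = ref, alt = alt), flank)
  }
  d <- cls("ACGT", 2, "C", "T")  # breaks the CpG
  expect_equal(d$label, "disruptive")
  expect_equal(c(d$n_lost, d$n_gained), c(1L, 0L))

  d <- cls("ATGT", 2, "T", "C")  # TpG -> CpG
  expect_equal(d$label, "forming")
  expect_equal(c(d$n_lost, d$n_gained), c(0L, 1L))

  d <- cls("ACGG", 3, "G", "C")  # between two CpG sites: breaks one, forms one
  expect_equal(d$label, "both")
  expect_equal(c(d$n_lost, d$n_gained), c(1L, 1L))

  d <- cls("CATG", 1, "CAT", "C")  # deletion creates a junction CpG
  expect_equal(d$label, "forming")

  d <- cls("AATT", 2, "A", "T")
  expect_equal(d$label, "neutral")
  expect_equal(d$n_ref_cpg, d$n_alt_cpg)
})

test_that("conservation identity holds for every classified variant", {
  withr::local_seed(77)
  for (rep in 1:200) {
    case <- random_variant_case()
    d <- classify_case(case)
    expect_equal(d$n_alt_cpg - d$n_ref_cpg, d$n_gained - d$n_lost)
  }
})

test_that("all 192 SNV-in-3-mer cases map to the rule-derived label", {
  bases <- c("A", "C", "G", "T")
  trimers <- expand.grid(b1 = bases, b2 = bases, b3 = bases,
                         stringsAsFactors = FALSE)
  n_cases <- 0L
  for (r in seq_len(nrow(trimers))) {
    b <- unlist(trimers[r, ])
    s <- paste(b, collapse = "")
    for (alt in setdiff(bases, b[2])) {
      n_cases <- n_cases + 1L
      d <- classify_case(list(seq = s, pos = 2, ref = b[2], alt = alt))
      # direct dinucleotide comparison at the two positions the middle
      # base touches
      ref_left <- b[1] == "C" && b[2] == "G"
      ref_right <- b[2] == "C" && b[3] == "G"
      alt_left <- b[1] == "C" && alt == "G"
      alt_right <- alt == "C" && b[3] == "G"
      lost <- sum(ref_left && !alt_left, ref_right && !alt_right)
      gained <- sum(alt_left && !ref_left, alt_right && !ref_right)
      expected <- if (lost > 0 && gained > 0) "both"
                  else if (lost > 0) "disruptive"
                  else if (gained > 0) "forming"
                  else "neutral"
      expect_equal(d$label, expected,
                   info = paste0(s, " ", b[2], ">", alt))
      expect_equal(c(d$n_lost, d$n_gained), c(lost, gained),
                   ignore_attr = TRUE,
                   info = paste0(s, " ", b[2], ">", alt))
    }
  }
  expect_equal(n_cases, 192L)
})

test_that("an adjacent N lowers confidence but still classifies", {
  d <- classify_case(list(seq = "NCGT", pos = 2, ref = "C", alt = "T"))
  expect_equal(d$label, "disruptive")
  expect_true(d$low_confidence)
  d <- classify_case(list(seq = "ACGT", pos = 2, ref = "C", alt = "T"))
  expect_false(d$low_confidence)
})

test_that("classify_batch preserves order and isolates per-row failures", {
  ref <- c(s1 = "AACGTTAGGTT", s2 = "TTTTTTTT")
  v <- rbind(
    variant_record("s1", 3, "C", "T", rsid = "v1"),   # breaks the CpG at 3-4
    variant_record("s1", 7, "A", "C", rsid = "v2"),   # forms a CpG at 7-8
    variant_record("nope", 1, "A", "T", rsid = "v3"), # unknown chrom
    variant_record("s2", 2, "T", "A", rsid = "v4")    # neutral
  )
  out <- classify_batch(v, ref, screen_config())
  expect_equal(out$rsid, c("v1", "v2", "v3", "v4"))
  expect_equal(out$label[1], "disruptive")
  expect_equal(out$label[2], "forming")
  expect_match(out$error[3], "unknown sequence")
  expect_true(is.na(out$label[3]))
  expect_equal(out$label[4], "neutral")
  # failed row does not abort: all other rows classified
  expect_equal(sum(is.na(out$label)), 1L)

  empty <- classify_batch(v[0, ], ref, screen_config())
  expect_equal(nrow(empty), 0L)
})
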