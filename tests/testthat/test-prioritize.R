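# MAF-based ranking and the hub-gene comparison.

test_that("rank_by_maf sorts by MAF then function class then rsid", {
  cand <- data.frame(
    rsid = c("rs9", "rs1", "rs5"),
    maf = c(0.5, 0.47, 0.5),
    consequences = c("intronic", "missense", "synonymous"),
    region_features = c("", "", "EMAR"),
    stringsAsFactors = FALSE
  )
  r <- rank_by_maf(cand)
  # the two MAF-0.5 variants lead; the intronic-only one yields to the
  # synonymous/EMAR one
  expect_equal(r$rsid, c("rs5", "rs9", "rs1"))
  expect_equal(r$priority_rank, 1:3)

  single <- rank_by_maf(cand[2, ])
  expect_equal(single$priority_rank, 1L)

  # pure rsid tie-break, stable across runs
  tie <- data.frame(rsid = c("rsB", "rsA"), maf = 0.3,
                    consequences = "missense", region_features = "",
                    stringsAsFactors = FALSE)
  expect_equal(rank_by_maf(tie)$rsid, c("rsA", "rsB"))
  expect_identical(rank_by_maf(tie), rank_by_maf(tie))

  # missing MAF goes last, flagged
  cand$maf[1] <- NA
  r <- rank_by_maf(cand)
  expect_equal(r$rsid[3], "rs9")
  expect_true(r$missing_maf[3])
  expect_false(any(r$missing_maf[1:2]))
})

test_that("rank_by_maf is a permutation with gap-free ranks", {
  withr::local_seed(11)
  cand <- data.frame(
    rsid = sprintf("rs%03d", sample(999, 40)),
    maf = round(runif(40, 0.01, 0.5), 2),
    consequences = sample(c("missense", "intronic", "synonymous"), 40, TRUE),
    region_features = sample(c("", "enhancer"), 40, TRUE),
    stringsAsFactors = FALSE
  )
  r <- rank_by_maf(cand)
  expect_setequal(r$rsid, cand$rsid)
  expect_equal(sort(r$priority_rank), 1:40)
  expect_true(all(diff(rank(-r$maf, ties.method = "min")) >= 0))
})

test_that("count_variant_types counts distinct function-label combinations", {
  t2 <- load_fixture("table2")
  cyp2d6 <- t2[t2$gene == "CYP2D6", ]
  expect_equal(count_variant_types(cyp2d6), 5L)
  expect_equal(count_variant_types(t2[t2$gene == "CYP2C19", ]), 3L)
  expect_equal(count_variant_types(t2[t2$gene == "CYP2B6", ]), 3L)

  mono <- data.frame(consequences = rep("missense", 4), region_features = "",
                     stringsAsFactors = FALSE)
  expect_equal(count_variant_types(mono), 1L)
  planted <- data.frame(consequences = c("missense", "intronic", "splice"),
                        region_features = "", stringsAsFactors = FALSE)
  expect_equal(count_variant_types(planted), 3L)
})

test_that("formations/disruptions double-count dual-impact variants", {
  t2 <- load_fixture("table2")
  fd <- count_formations_disruptions(t2[t2$gene == "CYP2D6", ])
  expect_equal(fd, c(n_formations = 10L, n_disruptions = 10L))
  fd <- count_formations_disruptions(t2[t2$gene == "CYP2C19", ])
  expect_equal(fd, c(n_formations = 7L, n_disruptions = 14L))
  fd <- count_formations_disruptions(
    data.frame(label = "both", stringsAsFactors = FALSE))
  expect_equal(fd, c(n_formations = 1L, n_disruptions = 1L))
  # identity: formations + disruptions = candidates + both
  for (g in unique(t2$gene)) {
    cg <- t2[t2$gene == g, ]
    fd <- count_formations_disruptions(cg)
    expect_equal(sum(fd), nrow(cg) + sum(cg$label == "both"))
  }
})

test_that("hub_comparison finds the published hub gene", {
  hub <- hub_comparison(load_fixture("table3"))
  expect_equal(hub$overall_winner, "CYP2D6")
  expect_equal(hub$winner_factor_count, 4L)
  expect_false(hub$tie)
  expect_length(hub$per_factor, 7L)
  # the four factors won: relevance, variant types, formations, PubMed
  won <- names(hub$per_factor)[vapply(hub$per_factor,
                                      function(w) "CYP2D6" %in% w, logical(1))]
  expect_setequal(won, c("relevance_score", "n_variant_types",
                         "n_formations", "n_pubmed_titles"))
  expect_equal(hub$per_factor$n_significant_pgx, "CYP2C19")
  expect_equal(hub$per_factor$n_cpg_pgx_snp, "CYP2B6")
})

test_that("hub_comparison handles sweeps, ties, and degenerate input", {
  sweep <- data.frame(gene = c("A", "B"), f1 = c(2, 1), f2 = c(5, 0),
                      f3 = c(1, 0), f4 = c(9, 2), f5 = c(3, 1),
                      f6 = c(2, 0), f7 = c(8, 7), stringsAsFactors = FALSE)
  hub <- hub_comparison(sweep)
  expect_equal(hub$overall_winner, "A")
  expect_equal(hub$winner_factor_count, 7L)

  tied <- data.frame(gene = c("A", "B"), f1 = c(1, 2), f2 = c(2, 1),
                     stringsAsFactors = FALSE)
  hub <- hub_comparison(tied)
  expect_true(hub$tie)
  expect_setequal(hub$overall_winner, c("A", "B"))

  expect_error(hub_comparison(sweep[1, ]), "at least 2")
})

test_that("hub_comparison agrees with brute-force argmax on random tables", {
  withr::local_seed(31)
  for (rep in 1:50) {
    tab <- data.frame(gene = c("A", "B", "C"),
                      matrix(sample(0:5, 21, TRUE), nrow = 3))
    hub <- hub_comparison(tab)
    # brute force: per-gene wins counted column by column
    wins <- sapply(c("A", "B", "C"), function(g) {
      sum(vapply(2:8, function(j) {
        tab[tab$gene == g, j] == max(tab[, j])
      }, logical(1)))
    })
    expect_equal(sort(hub$overall_winner), sort(names(wins)[wins == max(wins)]))
    expect_equal(hub$winner_factor_count, max(wins))
    expect_equal(unname(hub$factor_wins), unname(wins))
  }
})
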