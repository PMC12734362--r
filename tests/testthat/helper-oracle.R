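# Independent brute-force oracle for the CpG delta classifier: apply the
# variant to the FULL sequence (no windows, no normalization), locate every
# CpG in both haplotypes with gregexpr, and match reference CpGs to
# alternate CpGs positionally (same coordinate, or coordinate shifted by
# the allele-length difference) using igraph's maximum bipartite matching.

oracle_cpg_positions <- function(s) {
  hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
  as.integer(hits[hits > 0])
}

oracle_delta <- function(seqstr, pos, ref, alt) {
  stopifnot(substr(seqstr, pos, pos + nchar(ref) - 1L) == ref)
  altseq <- paste0(substr(seqstr, 1L, pos - 1L), alt,
                   substr(seqstr, pos + nchar(ref), nchar(seqstr)))
  R <- oracle_cpg_positions(seqstr)
  A <- oracle_cpg_positions(altseq)
  d <- nchar(alt) - nchar(ref)
  m <- 0L
  if (length(R) && length(A)) {
    edges <- integer(0)
    for (ii in seq_along(R)) {
      for (jj in seq_along(A)) {
        if (A[jj] == R[ii] || A[jj] == R[ii] + d) {
          edges <- c(edges, ii, length(R) + jj)
        }
      }
    }
    if (length(edges)) {
      g <- igraph::make_bipartite_graph(
        c(rep(FALSE, length(R)), rep(TRUE, length(A))), edges,
        directed = FALSE
      )
      m <- igraph::max_bipartite_match(g)$matching_size
    }
  }
  n_lost <- length(R) - m
  n_gained <- length(A) - m
  label <- if (n_lost > 0 && n_gained > 0) "both"
           else if (n_lost > 0) "disruptive"
           else if (n_gained > 0) "forming"
           else "neutral"
  list(n_ref_cpg = length(R), n_alt_cpg = length(A),
       n_lost = n_lost, n_gained = n_gained, label = label)
}

# Independent reverse complement used by the strand-invariance checks.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# Random (sequence, variant) pair generator for property suites.
random_variant_case <- function() {
  len <- sample(20:50, 1L)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  type <- sample(c("snv", "del", "ins"), 1L, prob = c(0.5, 0.25, 0.25))
  if (type == "snv") {
    pos <- sample(len, 1L)
    rb <- substr(s, pos, pos)
    ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
    list(seq = s, pos = pos, ref = rb, alt = ab)
  } else if (type == "del") {
    k <- sample(1:3, 1L)
    pos <- sample(len - k, 1L)
    list(seq = s, pos = pos, ref = substr(s, pos, pos + k), alt = substr(s, pos, pos))
  } else {
    pos <- sample(len, 1L)
    ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1L), replace = TRUE),
                 collapse = "")
    rb <- substr(s, pos, pos)
    list(seq = s, pos = pos, ref = rb, alt = paste0(rb, ins))
  }
}

# Classify one ad-hoc case through the package's full path.
classify_case <- function(case, flank = 1L) {
  ref <- setNames(case$seq, "s")
  v <- variant_record("s", case$pos, case$ref, case$alt)
  v <- normalize_variant(v, ref)
  w <- build_windows(v, ref, flank = flank)
  classify_cpg_delta(w$context, w$alt_window)
}
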