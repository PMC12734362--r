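# The core classifier: does a reference->alternate allele change destroy
# and/or create CpG dinucleotides?  SNVs reduce to direct positional
# comparison of CpG sites in a small window; indels are handled by
# flank-anchored positional diffing, in which a CpG that merely shifts
# position (same location relative to the unchanged flank) is neither lost
# nor gained.

#' Count CpG dinucleotides in a sequence
#'
#' Counts offsets `i` with `seq[i] == "C"` and `seq[i+1] == "G"`.  `N`
#' matches nothing.
#'
#' @param seq A nucleotide string over A, C, G, T, N.
#' @return Non-negative integer count.
#' @examples
#' count_cpg("CGCG")  # 2
#' @export
count_cpg <- function(seq) {
  length(cpg_starts(seq))
}

# 1-based start positions of CpG dinucleotides.
cpg_starts <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (!grepl("^[ACGTN]*$", seq)) {
    stop("sequence contains characters other than A, C, G, T, N")
  }
  n <- nchar(seq)
  if (n < 2L) return(integer(0))
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  which(chars[-n] == "C" & chars[-1L] == "G")
}

# Reverse complement (A<->T, C<->G, N fixed).
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(seq, "", fixed = TRUE),
                function(x) paste(rev(x), collapse = ""), character(1)))
}

#' Normalize a variant to its canonical left-aligned representation
#'
#' Shared suffix then shared prefix bases are trimmed and indels are shifted
#' left through repetitive sequence until the preceding base no longer
#' permits a shift; empty-allele representations are restored to VCF style
#' by retaining an anchor base.  SNVs are returned unchanged.
#'
#' @param v A one-row variant `data.frame` (see [variant_record()]).
#' @param reference Named character vector of reference sequences.
#' @return The variant with possibly updated `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(v, reference) {
  stopifnot(is.data.frame(v), nrow(v) == 1L)
  if (!v$chrom %in% names(reference)) {
    stop("unknown sequence '", v$chrom, "'")
  }
  s <- reference[[v$chrom]]
  pos <- v$pos
  ref <- toupper(v$ref)
  alt <- toupper(v$alt)
  if (pos + nchar(ref) - 1L > nchar(s) ||
      substr(s, pos, pos + nchar(ref) - 1L) != ref) {
    stop("reference mismatch at ", v$chrom, ":", pos,
         " (expected '", ref, "', found '",
         substr(s, pos, min(nchar(s), pos + nchar(ref) - 1L)), "')")
  }
  if (ref == alt) stop("null change at ", v$chrom, ":", pos)

  # Extend-and-trim left alignment: while the alleles share their last base,
  # drop it, borrowing a base from the reference on the left whenever an
  # allele would otherwise become empty.
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (substr(ref, nr, nr) != substr(alt, na, na)) break
    if (nr == 1L || na == 1L) {
      if (pos == 1L) break
      b <- substr(s, pos - 1L, pos - 1L)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
      nr <- nr + 1L; na <- na + 1L
    }
    ref <- substr(ref, 1L, nr - 1L)
    alt <- substr(alt, 1L, na - 1L)
  }
  # Trim shared leading bases while both alleles keep at least one base.
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) stop("null change at ", v$chrom, ":", v$pos)
  v$pos <- as.integer(pos); v$ref <- ref; v$alt <- alt
  v
}

#' Build reference and alternate sequence windows around a variant
#'
#' The reference window covers the variant's affected reference span
#' extended by `max(flank, nchar(ref), nchar(alt))` bases on each side
#' (truncated at the sequence ends), which guarantees that every
#' dinucleotide the change can touch lies inside the window.  The alternate
#' window is the reference window with the reference allele replaced by the
#' alternate allele.
#'
#' @param v A one-row, normalized variant `data.frame`.
#' @param reference Named character vector of reference sequences.
#' @param flank Context half-width in bases (at least 1).
#' @return A list with `context` (fields `chrom`, `window_start`,
#'   `ref_window`, `variant_offset` (0-based), `ref_len`, `alt_len`) and
#'   `alt_window`.
#' @export
build_windows <- function(v, reference, flank = 1L) {
  stopifnot(is.data.frame(v), nrow(v) == 1L, flank >= 1)
  s <- reference[[v$chrom]]
  if (is.null(s)) stop("unknown sequence '", v$chrom, "'")
  nr <- nchar(v$ref); na <- nchar(v$alt)
  eff <- max(as.integer(flank), nr, na)
  span_end <- v$pos + nr - 1L
  if (span_end > nchar(s)) stop("variant extends past end of ", v$chrom)
  w_start <- max(1L, v$pos - eff)
  w_end <- min(nchar(s), span_end + eff)
  ref_window <- substr(s, w_start, w_end)
  if (!nzchar(ref_window)) stop("empty window at ", v$chrom, ":", v$pos)
  offset <- v$pos - w_start  # 0-based offset of first affected base
  alt_window <- paste0(substr(ref_window, 1L, offset),
                       v$alt,
                       substr(ref_window, offset + nr + 1L, nchar(ref_window)))
  context <- list(chrom = v$chrom, window_start = w_start,
                  ref_window = ref_window, variant_offset = offset,
                  ref_len = nr, alt_len = na)
  list(context = context, alt_window = alt_window)
}

# Maximum bipartite matching between reference CpG start positions `R` and
# alternate CpG start positions `A`, where a reference CpG at i may pair
# with an alternate CpG at the same coordinate i (unchanged left flank /
# substitution) or at i + d (right flank shifted by the allele length
# difference d).  Kuhn's augmenting-path algorithm; the maximum cardinality
# is unique, so lost/gained counts do not depend on processing order.
match_cpg_sets <- function(R, A, d) {
  if (length(R) == 0L || length(A) == 0L) return(0L)
  adj <- lapply(R, function(i) {
    unique(c(match(i, A), match(i + d, A)))
  })
  adj <- lapply(adj, function(x) x[!is.na(x)])
  match_alt <- integer(length(A))  # 0 = free, else index into R
  n_matched <- 0L
  for (u in seq_along(R)) {
    visited <- logical(length(A))
    augment <- function(u) {
      for (j in adj[[u]]) {
        if (!visited[j]) {
          visited[j] <<- TRUE
          if (match_alt[j] == 0L || augment(match_alt[j])) {
            match_alt[j] <<- u
            return(TRUE)
          }
        }
      }
      FALSE
    }
    if (augment(u)) n_matched <- n_matched + 1L
  }
  n_matched
}

#' Classify the CpG delta of a variant
#'
#' Compares the CpG dinucleotide sets of the reference and alternate
#' windows.  CpG sites are matched positionally: at identical window
#' coordinates (which covers all substitutions and the unchanged left
#' flank) or, for indels, shifted by the allele length difference (which
#' covers the unchanged right flank, so a CpG that only changes coordinates
#' is preserved).  Unmatched reference CpGs are lost; unmatched alternate
#' CpGs are gained.
#'
#' @param context Context list from [build_windows()].
#' @param alt_window Alternate window string from [build_windows()].
#' @return A list with `n_ref_cpg`, `n_alt_cpg`, `n_lost`, `n_gained`,
#'   `label` (`disruptive`, `forming`, `both` or `neutral`) and
#'   `low_confidence` (`TRUE` when an N base makes a dinucleotide
#'   unresolvable).
#' @examples
#' w <- build_windows(variant_record("s", 2, "C", "T"),
#'                    c(s = "ACGT"), flank = 1)
#' classify_cpg_delta(w$context, w$alt_window)$label  # "disruptive"
#' @export
classify_cpg_delta <- function(context, alt_window) {
  ref_window <- context$ref_window
  d <- context$alt_len - context$ref_len
  if (nchar(alt_window) != nchar(ref_window) + d) {
    stop("alt_window is inconsistent with the context")
  }
  R <- cpg_starts(ref_window)
  A <- cpg_starts(alt_window)
  n_matched <- match_cpg_sets(R, A, d)
  n_lost <- length(R) - n_matched
  n_gained <- length(A) - n_matched
  label <- if (n_lost > 0L && n_gained > 0L) "both"
           else if (n_lost > 0L) "disruptive"
           else if (n_gained > 0L) "forming"
           else "neutral"
  list(n_ref_cpg = length(R), n_alt_cpg = length(A),
       n_lost = n_lost, n_gained = as.integer(n_gained), label = label,
       low_confidence = grepl("N", ref_window, fixed = TRUE) ||
         grepl("N", alt_window, fixed = TRUE))
}

#' Classify a batch of variants against a reference
#'
#' Applies [normalize_variant()], [build_windows()] and
#' [classify_cpg_delta()] to each variant.  Per-variant failures (unknown
#' sequence, reference mismatch, null change) are recorded in the `error`
#' column and never abort the batch; input order is preserved.
#'
#' @param variants Variant `data.frame` (see [variant_record()]).
#' @param reference Named character vector of reference sequences.
#' @param config A [screen_config()] (supplies `flank`).
#' @return A `data.frame` with the input columns plus `n_ref_cpg`,
#'   `n_alt_cpg`, `n_lost`, `n_gained`, `label`, `low_confidence`, `error`.
#' @export
classify_batch <- function(variants, reference, config = screen_config()) {
  n <- nrow(variants)
  res <- data.frame(
    n_ref_cpg = rep(NA_integer_, n), n_alt_cpg = rep(NA_integer_, n),
    n_lost = rep(NA_integer_, n), n_gained = rep(NA_integer_, n),
    label = rep(NA_character_, n), low_confidence = rep(NA, n),
    error = rep(NA_character_, n), stringsAsFactors = FALSE
  )
  out <- cbind(variants, res)
  for (i in seq_len(n)) {
    delta <- tryCatch({
      v <- normalize_variant(variants[i, , drop = FALSE], reference)
      w <- build_windows(v, reference, flank = config$flank)
      c(classify_cpg_delta(w$context, w$alt_window),
        list(pos = v$pos, ref = v$ref, alt = v$alt))
    }, error = function(e) conditionMessage(e))
    if (is.character(delta)) {
      out$error[i] <- delta
    } else {
      out$pos[i] <- delta$pos
      out$ref[i] <- delta$ref
      out$alt[i] <- delta$alt
      out$n_ref_cpg[i] <- delta$n_ref_cpg
      out$n_alt_cpg[i] <- delta$n_alt_cpg
      out$n_lost[i] <- delta$n_lost
      out$n_gained[i] <- delta$n_gained
      out$label[i] <- delta$label
      out$low_confidence[i] <- delta$low_confidence
    }
  }
  rownames(out) <- NULL
  out
}
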