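#' Alignment scoring scheme
#'
#' Default scoring used for part annotation and marker orientation:
#' match +2, mismatch -3, gap open -4, gap extend -2 (a gap of length L costs
#' `gap_open + (L - 1) * gap_extend`). The penalties tolerate roughly 10%
#' read error while rejecting cross-part hits between unrelated parts.
#'
#' @param match,mismatch,gap_open,gap_extend Non-negative magnitudes; mismatch
#'   and gaps are applied as penalties.
#' @return A named list.
#' @export
align_scoring <- function(match = 2, mismatch = 3, gap_open = 4, gap_extend = 2) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend))
}

#' Local (Smith-Waterman) alignment of a part against a read
#'
#' Affine-gap local alignment. A score-only pass locates the optimal local
#' alignment and its start cell; a traceback restricted to that rectangle then
#' yields match counts for identity. All coordinates are 0-based half-open.
#'
#' @param subject Read sequence (character scalar).
#' @param pattern Part/marker sequence (character scalar).
#' @param scoring See [align_scoring()].
#' @return One-row tibble: `score`, `subject_start`, `subject_end`,
#'   `pattern_start`, `pattern_end`, `matches`, `aln_len`, `identity`.
#' @export
sw_align <- function(subject, pattern, scoring = align_scoring()) {
  b <- cpp_sw_best(subject, pattern, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
  if (b$score <= 0) {
    return(tibble(score = 0L, subject_start = NA_integer_,
                  subject_end = NA_integer_, pattern_start = NA_integer_,
                  pattern_end = NA_integer_, matches = 0L, aln_len = 0L,
                  identity = NA_real_))
  }
  pad <- 25L
  ss <- max(0L, b$subject_start - pad)
  se <- min(nchar(subject), b$subject_end + pad)
  ps <- max(0L, b$pattern_start - pad)
  pe <- min(nchar(pattern), b$pattern_end + pad)
  tb <- cpp_sw_traceback(substr(subject, ss + 1L, se), substr(pattern, ps + 1L, pe),
                         scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
  tibble(
    score = tb$score,
    subject_start = ss + tb$subject_start, subject_end = ss + tb$subject_end,
    pattern_start = ps + tb$pattern_start, pattern_end = ps + tb$pattern_end,
    matches = tb$matches, aln_len = tb$aln_len,
    identity = tb$matches / tb$aln_len
  )
}

# seed-guided banded local alignment: k-mer seeds estimate the alignment
# diagonal, a banded Gotoh pass with traceback does the rest. Returns NULL
# when the pattern shares fewer than min_seeds k-mers with the subject.
# An exact substring occurrence short-circuits the DP entirely.
# Returns a plain list (hot path; callers build tibbles in bulk).
seeded_align <- function(subject, pattern, scoring = align_scoring(),
                         band = 100L, k = 11L, min_seeds = 1L) {
  exact <- regexpr(pattern, subject, fixed = TRUE)[1]
  plen <- nchar(pattern)
  if (exact > 0) {
    return(list(score = scoring$match * plen,
                subject_start = exact - 1L, subject_end = exact - 1L + plen,
                pattern_start = 0L, pattern_end = plen,
                matches = plen, aln_len = plen, identity = 1))
  }
  sd <- cpp_seed_diags(subject, pattern, as.integer(k))
  if (sd$count[1] < min_seeds) return(NULL)
  b <- cpp_sw_banded(subject, pattern, scoring$match, scoring$mismatch,
                     scoring$gap_open, scoring$gap_extend,
                     sd$diag[1], as.integer(band))
  if (b$score <= 0) return(NULL)
  b$identity <- b$matches / b$aln_len
  b
}
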