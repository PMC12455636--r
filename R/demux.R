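#' Error-tolerant barcode matching at a read end
#'
#' Finds the best infix (semi-global) alignment of a barcode within a search
#' window at the head or tail of a read, under unit-cost edit distance. Ties
#' are broken toward the smaller edit distance, then the smaller start
#' coordinate. Windows larger than the read are clipped, not an error.
#'
#' @param read Read sequence (character scalar).
#' @param barcode Barcode sequence.
#' @param end `"head"` (first `window` bases) or `"tail"` (last `window`).
#' @param max_dist Maximum edit distance accepted.
#' @param window Search window length; must be >= the barcode length.
#' @return One-row tibble (`end`, `edit_distance`, `read_start`, `read_end`;
#'   coordinates 0-based half-open on the read), or a zero-row tibble when no
#'   hit is within `max_dist`.
#' @export
match_barcode <- function(read, barcode, end = c("head", "tail"),
                          max_dist = 4, window = 150) {
  end <- match.arg(end)
  if (window < nchar(barcode)) abort("window must be >= barcode length")
  if (max_dist < 0) abort("max_dist must be >= 0")
  L <- nchar(read)
  w <- min(window, L)
  offset <- if (end == "head") 0L else L - w
  region <- substr(read, offset + 1L, offset + w)
  h <- cpp_infix_edit(region, barcode)
  empty <- tibble(end = character(), edit_distance = integer(),
                  read_start = integer(), read_end = integer())
  if (h$dist > max_dist) return(empty)
  tibble(end = end, edit_distance = h$dist,
         read_start = offset + h$start, read_end = offset + h$end)
}

#' Demultiplex reads by dual barcodes
#'
#' A read is assigned to the (ORF library, sort gate) pool named by its
#' forward barcode (head) and reverse barcode (tail). Both read orientations
#' are tested: a minus-strand read carries the reverse complement of the
#' forward barcode at its tail and of the reverse barcode at its head. A read
#' is `assigned` iff exactly one forward and exactly one reverse barcode
#' match within `max_dist`; two or more matches of either role give
#' `ambiguous`, a missing forward `no_fwd`, a missing reverse `no_rev`.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param barcodes Barcode manifest (`barcode_id`, `role`, `pool`,
#'   `sequence`); ids must be unique, roles `fwd`/`rev`.
#' @param max_dist Maximum edit distance per barcode (default 4, ~len/6 for
#'   24-nt barcodes).
#' @param window Search window at each read end (nt).
#' @return Assignment tibble: `read_id`, `status`, `orf_pool`, `gate_pool`,
#'   `fwd_dist`, `rev_dist`, `length`, `strand`.
#' @export
demultiplex <- function(reads, barcodes, max_dist = 4, window = 150) {
  if (nrow(barcodes) == 0) abort("empty barcode manifest")
  if (anyDuplicated(barcodes$barcode_id)) abort("duplicate barcode ids")
  if (!all(barcodes$role %in% c("fwd", "rev"))) abort("barcode role must be fwd/rev")
  fwd <- filter(barcodes, .data$role == "fwd")
  rev_ <- filter(barcodes, .data$role == "rev")
  fwd_rc <- revcomp(fwd$sequence)
  rev_rc <- revcomp(rev_$sequence)

  scan_read <- function(seq) {
    L <- nchar(seq)
    w <- min(window, L)
    head_rgn <- substr(seq, 1L, w)
    tail_rgn <- substr(seq, L - w + 1L, L)
    dist_in <- function(region, bc) {
      vapply(bc, function(b) cpp_infix_edit(region, b)$dist, integer(1),
             USE.NAMES = FALSE)
    }
    # plus orientation: fwd at head, rev at tail
    f_plus <- dist_in(head_rgn, fwd$sequence)
    r_plus <- dist_in(tail_rgn, rev_$sequence)
    # minus orientation: rc(fwd) at tail, rc(rev) at head
    f_minus <- dist_in(tail_rgn, fwd_rc)
    r_minus <- dist_in(head_rgn, rev_rc)
    f_best <- pmin(f_plus, f_minus)
    r_best <- pmin(r_plus, r_minus)
    f_hit <- which(f_best <= max_dist)
    r_hit <- which(r_best <= max_dist)
    status <- if (length(f_hit) == 0) "no_fwd"
      else if (length(r_hit) == 0) "no_rev"
      else if (length(f_hit) > 1 || length(r_hit) > 1) "ambiguous"
      else "assigned"
    if (status == "assigned") {
      plus_sum <- f_plus[f_hit] + r_plus[r_hit]
      minus_sum <- f_minus[f_hit] + r_minus[r_hit]
      strand <- if (plus_sum <= minus_sum) "+" else "-"
      list(status = status, orf_pool = fwd$pool[f_hit],
           gate_pool = rev_$pool[r_hit],
           fwd_dist = f_best[f_hit], rev_dist = r_best[r_hit],
           strand = strand)
    } else {
      list(status = status, orf_pool = NA_character_,
           gate_pool = NA_character_,
           fwd_dist = if (length(f_hit) == 1) f_best[f_hit] else NA_integer_,
           rev_dist = if (length(r_hit) == 1) r_best[r_hit] else NA_integer_,
           strand = NA_character_)
    }
  }

  res <- purrr::map(reads$sequence, scan_read)
  tibble(
    read_id = reads$read_id,
    status = purrr::map_chr(res, "status"),
    orf_pool = purrr::map_chr(res, "orf_pool"),
    gate_pool = purrr::map_chr(res, "gate_pool"),
    fwd_dist = purrr::map_int(res, ~ as.integer(.x$fwd_dist)),
    rev_dist = purrr::map_int(res, ~ as.integer(.x$rev_dist)),
    length = nchar(reads$sequence),
    strand = purrr::map_chr(res, "strand")
  )
}

#' Full-amplicon length filter
#'
#' Reads shorter than `min_len` are flagged `too_short`; the threshold is
#' inclusive ("at least 2 kb": a 2,000-nt read is kept, a 1,999-nt read is
#' not). Only currently `assigned` reads are re-flagged.
#'
#' @param assignments Tibble from [demultiplex()].
#' @param min_len Minimum read length in nt (default 2000).
#' @return The assignment tibble with updated `status`.
#' @export
filter_length <- function(assignments, min_len = 2000) {
  if (min_len < 0) abort("min_len must be >= 0")
  mutate(assignments,
         status = ifelse(.data$status == "assigned" & .data$length < min_len,
                         "too_short", .data$status))
}

#' Unify read orientation with a 3' marker sequence
#'
#' Locally aligns the marker (the CBM fusion-module sequence, which sits near
#' the 3' end of every sense-strand amplicon) against each read and its
#' reverse complement. The orientation carrying the sense marker is kept, so
#' oriented reads place the marker nearer their 3' end. Reads with no
#' acceptable marker hit are flagged `no_marker`; reads with two disjoint
#' acceptable hits on the same strand (double-marker templates) are flagged
#' `chimeric`. When both strands carry an equally good hit, the plus strand
#' is kept with a warning.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param marker Marker DNA sequence (>= 30 nt).
#' @param min_identity Minimum alignment identity for a marker hit.
#' @param min_marker_coverage Minimum fraction of the marker that must align.
#' @return Tibble: `read_id`, `sequence` (oriented), `strand` (strand of the
#'   input read relative to the sense amplicon), `status`
#'   (`oriented`/`no_marker`/`chimeric`), `marker_start`, `marker_end`
#'   (0-based half-open on the oriented read).
#' @export
orient_reads <- function(reads, marker, min_identity = 0.8,
                         min_marker_coverage = 0.5) {
  if (nchar(marker) < 30) abort("marker must be at least 30 nt")
  marker_rc <- revcomp(marker)
  mlen <- nchar(marker)
  ok_hit <- function(a) {
    !is.null(a) && !is.na(a$identity) && a$identity >= min_identity &&
      (a$pattern_end - a$pattern_start) / mlen >= min_marker_coverage
  }
  one <- function(read_id, seq) {
    ap <- seeded_align(seq, marker, min_seeds = 2L)
    am <- seeded_align(seq, marker_rc, min_seeds = 2L)
    okp <- ok_hit(ap); okm <- ok_hit(am)
    if (!okp && !okm) {
      return(list(sequence = seq, strand = NA_character_,
                  status = "no_marker", marker_start = NA_integer_,
                  marker_end = NA_integer_))
    }
    if (okp && okm && ap$score == am$score) {
      warn(sprintf("read %s: marker hit on both strands with equal score; keeping +",
                   read_id))
      okm <- FALSE
    }
    plus <- okp && (!okm || ap$score >= am$score)
    L <- nchar(seq)
    if (plus) {
      oriented <- seq
      ms <- ap$subject_start; me <- ap$subject_end
    } else {
      oriented <- revcomp(seq)
      ms <- L - am$subject_end; me <- L - am$subject_start
    }
    # second disjoint sense-marker hit on the oriented read => chimeric
    before <- substr(oriented, 1, ms)
    after <- substr(oriented, me + 1, L)
    second <- FALSE
    if (nchar(before) >= mlen * min_marker_coverage) {
      second <- second || ok_hit(seeded_align(before, marker, min_seeds = 2L))
    }
    if (!second && nchar(after) >= mlen * min_marker_coverage) {
      second <- second || ok_hit(seeded_align(after, marker, min_seeds = 2L))
    }
    list(sequence = oriented, strand = if (plus) "+" else "-",
         status = if (second) "chimeric" else "oriented",
         marker_start = as.integer(ms), marker_end = as.integer(me))
  }
  res <- purrr::map2(reads$read_id, reads$sequence, one)
  tibble(
    read_id = reads$read_id,
    sequence = vapply(res, `[[`, "", "sequence"),
    strand = vapply(res, `[[`, "", "strand"),
    status = vapply(res, `[[`, "", "status"),
    marker_start = vapply(res, `[[`, 0L, "marker_start"),
    marker_end = vapply(res, `[[`, 0L, "marker_end")
  )
}
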