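# Synthetic demonstration fixtures. Real toolkit part sequences are not
# redistributed here; these parts are random DNA with internally consistent
# overhangs, generated once under fixed seeds so that every session sees the
# same registry. Lengths are chosen so that full barcoded amplicons span
# ~2.2-3.3 kb, the regime the >= 2 kb full-amplicon filter expects.

DEMO_JUNCTIONS <- c("CCCT", "AACG", "TATG", "ATCC", "TGGC", "GCTT")

#' Synthetic demonstration part registry
#'
#' Twenty promoters (`pYTK009`-`pYTK028`; strength classes: strong
#' `pYTK009`-`pYTK015`, the rest split into medium and weak), four signal
#' peptide-3xFLAG parts (`MF`, `STA1`, `SUC2`, `AMY`), coding sequences
#' `ELP2`/`ELP4` (built from the ELP repeat formula via [elp_dna()]),
#' `BLA` and `MEL1`, the `CBM` fusion module (4a, also the 3' orientation
#' marker) and the two terminator cassettes `4b_display`/`4b_secrete`.
#' All sequences are synthetic; bodies are random DNA under a fixed seed
#' except the ELP parts, which use the deterministic repeat encoding.
#'
#' @return A `part_registry` tibble.
#' @export
demo_registry <- function() {
  J <- DEMO_JUNCTIONS
  withr::with_seed(7141L, {
    wrap <- function(body, oh5, oh3) paste0(oh5, body, oh3)
    prom_ids <- sprintf("pYTK%03d", 9:28)
    prom_len <- sample(300:700, 20)
    strength <- dplyr::case_when(
      prom_ids %in% sprintf("pYTK%03d", 9:15) ~ "strong",
      prom_ids %in% c("pYTK016", "pYTK018", "pYTK020", "pYTK021",
                      "pYTK022", "pYTK023") ~ "medium",
      TRUE ~ "weak"
    )
    proms <- tibble(
      part_id = prom_ids, role = "promoter",
      sequence = purrr::map_chr(prom_len, ~ wrap(random_dna(.x - 8), J[1], J[2])),
      overhang_5 = J[1], overhang_3 = J[2], strength_class = strength
    )
    sps <- tibble(
      part_id = c("MF", "STA1", "SUC2", "AMY"), role = "sp_flag",
      sequence = purrr::map_chr(1:4, ~ wrap(random_dna(142), J[2], J[3])),
      overhang_5 = J[2], overhang_3 = J[3], strength_class = NA_character_
    )
    cds <- tibble(
      part_id = c("ELP2", "ELP4", "BLA", "MEL1"), role = "cds",
      sequence = c(
        wrap(elp_dna(2), J[3], J[4]),
        wrap(elp_dna(4), J[3], J[4]),
        wrap(random_dna(856), J[3], J[4]),
        wrap(random_dna(1092), J[3], J[4])
      ),
      overhang_5 = J[3], overhang_3 = J[4], strength_class = NA_character_
    )
    cbm <- tibble(
      part_id = "CBM", role = "fusion_4a",
      sequence = wrap(random_dna(346), J[4], J[5]),
      overhang_5 = J[4], overhang_3 = J[5], strength_class = NA_character_
    )
    gs8 <- random_dna(48)
    aga2 <- random_dna(300)
    ha <- random_dna(27)
    ttdh1 <- random_dna(417)
    cassettes <- tibble(
      part_id = c("4b_display", "4b_secrete"), role = "cassette_4b",
      sequence = c(
        wrap(paste0(gs8, aga2, ha, ttdh1), J[5], J[6]),
        wrap(paste0(gs8, ha, ttdh1), J[5], J[6])
      ),
      overhang_5 = J[5], overhang_3 = J[6], strength_class = NA_character_
    )
    part_registry(bind_rows(proms, sps, cds, cbm, cassettes))
  })
}

#' Design a crosstalk-resistant barcode set
#'
#' Random barcodes accepted greedily so that every pair (including each
#' barcode against the reverse complements of the others and of itself) is at
#' least `min_dist` edits apart. Forward barcodes tag the ORF library of the
#' amplicon pool, reverse barcodes the sort gate.
#'
#' @param fwd_pools,rev_pools Pool labels; one barcode is designed per label.
#' @param bc_length Barcode length in nt.
#' @param min_dist Minimum pairwise edit distance.
#' @param seed Integer seed; the default reproduces the shipped manifest.
#' @return Barcode manifest tibble: `barcode_id`, `role` (`fwd`/`rev`),
#'   `pool`, `sequence`.
#' @export
make_barcode_set <- function(fwd_pools = c("BLA", "ELP2", "ELP4", "MEL1"),
                             rev_pools = c("low", "medium", "high"),
                             bc_length = 24, min_dist = 8, seed = 99L) {
  n <- length(fwd_pools) + length(rev_pools)
  withr::with_seed(as.integer(seed), {
    accepted <- character(0)
    tries <- 0L
    while (length(accepted) < n) {
      tries <- tries + 1L
      if (tries > 5000L) abort("could not design barcode set; relax min_dist")
      cand <- random_dna(bc_length)
      pool <- c(accepted, revcomp(accepted), revcomp(cand))
      d <- vapply(pool, function(b) cpp_edit_dist(cand, b), integer(1))
      if (all(d >= min_dist)) accepted <- c(accepted, cand)
    }
    tibble(
      barcode_id = c(paste0("bcF_", fwd_pools), paste0("bcR_", rev_pools)),
      role = rep(c("fwd", "rev"), c(length(fwd_pools), length(rev_pools))),
      pool = c(fwd_pools, rev_pools),
      sequence = accepted
    )
  })
}

#' @rdname demo_registry
#' @export
demo_barcodes <- function() make_barcode_set()

#' Write the demonstration fixtures to disk
#'
#' Emits `parts.fasta`, `parts_manifest.tsv` and `barcodes.tsv` for
#' [demo_registry()] and [demo_barcodes()]; these are the files shipped under
#' `inst/extdata`.
#'
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_demo_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- demo_registry()
  paths <- list(
    parts_fasta = file.path(dir, "parts.fasta"),
    parts_manifest = file.path(dir, "parts_manifest.tsv"),
    barcodes = file.path(dir, "barcodes.tsv")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(reg$sequence, reg$part_id)),
    paths$parts_fasta)
  readr::write_tsv(select(reg, -"sequence", -"length"), paths$parts_manifest)
  readr::write_tsv(demo_barcodes(), paths$barcodes)
  invisible(paths)
}
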