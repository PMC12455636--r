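#' Load a part registry from FASTA + manifest
#'
#' A registry is a tibble of modular genetic parts in the positional grammar
#' used for the integration cassette: promoters (part 2), signal
#' peptide-3xFLAG fusions (3a), coding sequences (3b), the fusion module
#' carrying the cellulose-binding module (modified 4a) and the terminator
#' cassette with or without the Aga2 anchor (modified 4b). Each part carries
#' its 4-nt assembly overhangs; the part sequence includes both overhangs as
#' its first and last four bases.
#'
#' @param parts_fasta FASTA file of part sequences (ids = part ids).
#' @param manifest TSV with columns `part_id`, `role`, `overhang_5`,
#'   `overhang_3` and optional `strength_class` (promoters only).
#' @return A validated `part_registry` tibble with columns `part_id`, `role`,
#'   `sequence`, `overhang_5`, `overhang_3`, `strength_class`, `length`.
#' @export
read_parts_registry <- function(parts_fasta, manifest) {
  seqs <- Biostrings::readDNAStringSet(parts_fasta)
  man <- readr::read_tsv(manifest, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (!"strength_class" %in% names(man)) man$strength_class <- NA_character_
  ids <- names(seqs)
  missing <- setdiff(ids, man$part_id)
  if (length(missing) > 0) {
    abort(sprintf("FASTA records missing from manifest: %s",
                  paste(missing, collapse = ", ")))
  }
  orphan <- setdiff(man$part_id, ids)
  if (length(orphan) > 0) {
    abort(sprintf("manifest entries without a FASTA record: %s",
                  paste(orphan, collapse = ", ")))
  }
  reg <- tibble(part_id = ids, sequence = unname(toupper(as.character(seqs)))) |>
    left_join(select(man, "part_id", "role", "overhang_5", "overhang_3",
                     "strength_class"),
              by = "part_id")
  part_registry(reg)
}

#' Construct/validate a part registry
#'
#' @param parts Tibble with columns `part_id`, `role`, `sequence`,
#'   `overhang_5`, `overhang_3` and optional `strength_class`.
#' @return The validated registry (class `part_registry`).
#' @export
part_registry <- function(parts) {
  req <- c("part_id", "role", "sequence", "overhang_5", "overhang_3")
  miss <- setdiff(req, names(parts))
  if (length(miss) > 0) abort(paste("registry missing columns:", paste(miss, collapse = ", ")))
  if (!"strength_class" %in% names(parts)) parts$strength_class <- NA_character_
  if (anyDuplicated(parts$part_id)) {
    abort(sprintf("duplicate part_id: %s",
                  paste(unique(parts$part_id[duplicated(parts$part_id)]), collapse = ", ")))
  }
  bad_role <- setdiff(unique(parts$role), PART_ROLES)
  if (length(bad_role) > 0) abort(paste("unknown part role:", paste(bad_role, collapse = ", ")))
  if (any(nchar(parts$sequence) == 0)) abort("empty part sequence")
  assert_dna(parts$sequence, "part sequence")
  is_bc <- parts$role %in% c("barcode_fwd", "barcode_rev")
  oh <- c(parts$overhang_5[!is_bc], parts$overhang_3[!is_bc])
  if (any(is.na(oh)) || any(nchar(oh) != 4)) {
    abort("overhangs must be exactly 4 nt for all non-barcode parts")
  }
  assert_dna(oh, "overhang")
  # the stored sequence must begin/end with its declared overhangs
  mism <- !is_bc & (substr(parts$sequence, 1, 4) != parts$overhang_5 |
    substr(parts$sequence, nchar(parts$sequence) - 3, nchar(parts$sequence)) !=
      parts$overhang_3)
  if (any(mism)) {
    abort(sprintf("part sequence does not start/end with its overhangs: %s",
                  paste(parts$part_id[mism], collapse = ", ")))
  }
  sc <- parts$strength_class
  if (any(!is.na(sc) & !sc %in% STRENGTH_CLASSES)) abort("invalid strength_class")
  out <- parts |>
    mutate(length = nchar(.data$sequence)) |>
    select("part_id", "role", "sequence", "overhang_5", "overhang_3",
           "strength_class", "length")
  class(out) <- c("part_registry", class(tibble()))
  out
}

registry_parts <- function(registry, role) {
  registry$part_id[registry$role == role]
}

registry_get <- function(registry, part_id) {
  i <- match(part_id, registry$part_id)
  if (anyNA(i)) {
    abort(sprintf("part not in registry: %s",
                  paste(part_id[is.na(i)], collapse = ", ")))
  }
  registry[i, ]
}

#' Build an elastin-like polypeptide sequence from the repeat formula
#'
#' One ELP unit (ELP1) spans 100 amino acids, structured as
#' (VPGVG)5-(VPGAG)2-(VPGGG)3-(VPGVG)5-(VPGAG)2-(VPGGG)3. `build_elp()`
#' repeats that unit; `elp_dna()` back-translates it with one fixed codon per
#' amino acid so that DNA-level fixtures are deterministic.
#'
#' @param n_units Number of ELP1 units (>= 1); ELP2 = 2 units, ELP4 = 4, ...
#' @param codons Named codon map used by `elp_dna()`.
#' @return `build_elp()`: amino-acid string of length `100 * n_units`;
#'   `elp_dna()`: DNA string of length `300 * n_units`.
#' @export
build_elp <- function(n_units) {
  if (length(n_units) != 1 || is.na(n_units) || n_units < 1 ||
      n_units != as.integer(n_units)) {
    abort("n_units must be a single integer >= 1")
  }
  half <- paste0(strrep("VPGVG", 5), strrep("VPGAG", 2), strrep("VPGGG", 3))
  strrep(strrep(half, 2), as.integer(n_units))
}

#' @rdname build_elp
#' @export
elp_dna <- function(n_units, codons = c(V = "GTT", P = "CCA", G = "GGT", A = "GCT")) {
  aa <- strsplit(build_elp(n_units), "")[[1]]
  paste(codons[aa], collapse = "")
}

#' Assemble a construct design from one part per grammar slot
#'
#' Validates that adjacent parts share their 4-nt junction overhang
#' (`overhang_3` of part i equals `overhang_5` of part i+1) and joins part
#' bodies scarlessly: each shared junction appears once in the assembled
#' sequence, so the assembled length is the sum of part lengths minus
#' 4 x (number of junctions).
#'
#' @param registry A `part_registry`.
#' @param promoter,sp,cds Part ids filling the promoter, signal-peptide (3a)
#'   and CDS (3b) slots.
#' @param mode `"display"` (4b cassette with the Aga2 anchor) or `"secrete"`
#'   (without it).
#' @param fusion_4a Part id of the 4a fusion module (default: the registry's
#'   single `fusion_4a` part).
#' @param cassette_display,cassette_secrete Part ids of the two 4b cassettes.
#' @return One-row tibble: `promoter`, `sp`, `cds`, `mode`, `genotype_key`,
#'   `sequence`, `length`, plus `cds_start`/`cds_len` (0-based coordinates of
#'   the CDS part within the assembly, used by the read simulator to model
#'   CDS-less truncation).
#' @export
assemble_construct <- function(registry, promoter, sp, cds,
                               mode = c("display", "secrete"),
                               fusion_4a = NULL,
                               cassette_display = "4b_display",
                               cassette_secrete = "4b_secrete") {
  mode <- match.arg(mode)
  if (is.null(fusion_4a)) {
    fusion_4a <- registry_parts(registry, "fusion_4a")[1]
  }
  cassette <- if (mode == "display") cassette_display else cassette_secrete
  ids <- c(promoter, sp, cds, fusion_4a, cassette)
  parts <- registry_get(registry, ids)
  wrong <- parts$role != GRAMMAR_SLOTS
  if (any(wrong)) {
    abort(sprintf(
      "part in wrong slot: %s (role %s) offered for slot %s",
      paste(parts$part_id[wrong], collapse = ","),
      paste(parts$role[wrong], collapse = ","),
      paste(GRAMMAR_SLOTS[wrong], collapse = ",")))
  }
  for (i in seq_len(nrow(parts) - 1)) {
    if (parts$overhang_3[i] != parts$overhang_5[i + 1]) {
      abort(sprintf(
        "overhang mismatch at junction %d: %s (3' %s) vs %s (5' %s)",
        i - 1L, parts$part_id[i], parts$overhang_3[i],
        parts$part_id[i + 1], parts$overhang_5[i + 1]))
    }
  }
  assembled <- paste0(parts$sequence[1],
                      paste(substr(parts$sequence[-1], 5,
                                   nchar(parts$sequence[-1])), collapse = ""))
  cds_start <- sum(parts$length[1:2] - 4L)
  tibble(
    promoter = promoter, sp = sp, cds = cds, mode = mode,
    fusion_4a = fusion_4a, cassette_4b = cassette,
    genotype_key = paste(promoter, sp, cds, sep = "__"),
    sequence = assembled, length = nchar(assembled),
    cds_start = cds_start, cds_len = parts$length[3]
  )
}

#' Enumerate the combinatorial promoter x signal-peptide design space
#'
#' Builds one construct per (promoter, signal peptide) pair for a fixed CDS,
#' e.g. 20 promoters x 4 signal peptides = 80 constructs per library.
#'
#' @inheritParams assemble_construct
#' @param promoters,sps Part id vectors; default to every registry part with
#'   the matching role, in registry order.
#' @param cds Single CDS part id.
#' @return Tibble of construct designs, one row per combination; all
#'   `genotype_key`s are distinct.
#' @export
enumerate_design_space <- function(registry, cds, promoters = NULL, sps = NULL,
                                   mode = "display") {
  promoters <- promoters %||% registry_parts(registry, "promoter")
  sps <- sps %||% registry_parts(registry, "sp_flag")
  if (length(promoters) == 0 || length(sps) == 0) {
    abort("need at least one promoter and one signal peptide")
  }
  stopifnot(length(cds) == 1)
  grid <- tidyr::expand_grid(promoter = promoters, sp = sps)
  purrr::pmap(grid, function(promoter, sp) {
    assemble_construct(registry, promoter, sp, cds, mode = mode)
  }) |> bind_rows()
}

#' Export construct designs as FASTA
#'
#' Record ids encode the genotype key as `<promoter>__<sp>__<cds>`.
#'
#' @param designs Tibble from [enumerate_design_space()] or
#'   [assemble_construct()].
#' @param path Output FASTA path.
#' @export
write_constructs_fasta <- function(designs, path) {
  x <- Biostrings::DNAStringSet(setNames(designs$sequence, designs$genotype_key))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
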