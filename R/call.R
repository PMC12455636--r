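#' Call the (promoter, signal peptide, CDS) genotype of one read
#'
#' Accepted part hits are mapped to grammar slots by their registry role. A
#' `full` call requires exactly one promoter, one signal peptide, one CDS and
#' one 4a hit in left-to-right grammar order (neighbouring hits may share the
#' 4-nt assembly junction; overlaps up to `junction_tol` nt are tolerated).
#' Two accepted hits in any one of those slots, or a slot-order violation,
#' give `ambiguous`. A read carrying promoter + signal peptide + 4a but no
#' CDS is the truncated, "false-high" species: `truncated_no_cds`. Fewer
#' slots give `partial`; no accepted hits give `uncallable`. Ambiguity is
#' never rescued by abundance priors.
#'
#' @param hits Part-hit tibble for one read ([annotate_read()]).
#' @param junction_tol Maximum tolerated overlap (nt) between consecutive
#'   slot hits.
#' @return One-row tibble: `call_status`, `promoter`, `sp`, `cds`,
#'   `genotype_key` (`NA` unless `full`), `n_hits`.
#' @export
call_genotype <- function(hits, junction_tol = 12) {
  r <- call_genotype_impl(hits, junction_tol)
  tibble(call_status = r$call_status, promoter = r$promoter, sp = r$sp,
         cds = r$cds, genotype_key = r$genotype_key, n_hits = r$n_hits)
}

call_genotype_impl <- function(hits, junction_tol = 12) {
  out <- function(status, promoter = NA_character_, sp = NA_character_,
                  cds = NA_character_) {
    list(call_status = status, promoter = promoter, sp = sp, cds = cds,
         genotype_key = if (status == "full")
           paste(promoter, sp, cds, sep = "__") else NA_character_,
         n_hits = nrow(hits))
  }
  if (nrow(hits) == 0) return(out("uncallable"))
  slots <- c("promoter", "sp_flag", "cds", "fusion_4a")
  idx <- lapply(slots, function(s) which(hits$role == s))
  names(idx) <- slots
  n_per <- lengths(idx)
  if (any(n_per > 1)) return(out("ambiguous"))
  # order check over the slots that are present
  present <- unlist(idx[n_per == 1], use.names = FALSE)
  if (length(present) > 1) {
    rs <- hits$read_start[present]
    re <- hits$read_end[present]
    for (i in seq_along(present)[-1]) {
      if (rs[i] < rs[i - 1] || re[i] < re[i - 1] ||
          rs[i] < re[i - 1] - junction_tol) {
        return(out("ambiguous"))
      }
    }
  }
  ids <- vapply(idx, function(i) if (length(i) == 1) hits$part_id[i]
                else NA_character_, "")
  if (all(n_per == 1)) {
    return(out("full", ids[["promoter"]], ids[["sp_flag"]], ids[["cds"]]))
  }
  if (n_per[["promoter"]] == 1 && n_per[["sp_flag"]] == 1 &&
      n_per[["fusion_4a"]] == 1 && n_per[["cds"]] == 0) {
    return(out("truncated_no_cds", ids[["promoter"]], ids[["sp_flag"]]))
  }
  out("partial", ids[["promoter"]], ids[["sp_flag"]], ids[["cds"]])
}

#' Call genotypes for a set of annotated reads
#'
#' @param hits Part-hit tibble with `read_id` ([annotate_reads()]).
#' @param read_ids Optional vector of all read ids, so that reads without any
#'   accepted hit appear as `uncallable` rows.
#' @inheritParams call_genotype
#' @return Tibble with one row per read: `read_id`, `call_status`,
#'   `promoter`, `sp`, `cds`, `genotype_key`, `n_hits`.
#' @export
call_genotypes <- function(hits, read_ids = NULL, junction_tol = 12) {
  ids <- read_ids %||% unique(hits$read_id)
  by_read <- split(as.data.frame(hits), factor(hits$read_id, levels = ids))
  res <- purrr::map(by_read, call_genotype_impl, junction_tol = junction_tol)
  tibble(
    read_id = ids,
    call_status = vapply(res, `[[`, "", "call_status"),
    promoter = vapply(res, `[[`, "", "promoter"),
    sp = vapply(res, `[[`, "", "sp"),
    cds = vapply(res, `[[`, "", "cds"),
    genotype_key = vapply(res, `[[`, "", "genotype_key"),
    n_hits = vapply(res, `[[`, 0L, "n_hits")
  )
}

#' Write / read a genotype-call table
#'
#' @param calls Tibble from [call_genotypes()].
#' @param path TSV path.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(calls, path)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(n_hits = "i", .default = "c"))
}
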