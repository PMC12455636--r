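#' Count unique genotypes in one pool
#'
#' Builds the promoter x signal-peptide abundance matrix of a sorted pool
#' from its genotype calls. Only `full` calls are counted; fractions are
#' relative to the number of full calls in the pool (the denominator used
#' throughout, since only full-amplicon reads enter the analysis).
#'
#' @param calls Genotype-call tibble ([call_genotypes()]) for one pool.
#' @param registry Part registry fixing the row (promoter) and column
#'   (signal peptide) order.
#' @param pool Pool label, e.g. `c(orf = "BLA", gate = "high")` or a string.
#' @return An `abundance_matrix`: counts and fractions matrices (promoters x
#'   signal peptides in registry order) plus `pool`, `cds` and
#'   `n_full_reads`.
#' @export
count_genotypes <- function(calls, registry, pool = NA) {
  promoters <- registry_parts(registry, "promoter")
  sps <- registry_parts(registry, "sp_flag")
  full <- filter(calls, .data$call_status == "full")
  counts <- table(factor(full$promoter, levels = promoters),
                  factor(full$sp, levels = sps))
  counts <- matrix(as.integer(counts), nrow = length(promoters),
                   dimnames = list(promoter = promoters, sp = sps))
  n <- nrow(full)
  if (n == 0) {
    warn("pool has no full genotype calls; returning an all-zero matrix")
  }
  structure(
    list(counts = counts,
         fractions = if (n > 0) counts / n else counts * 0,
         pool = pool,
         cds = if (n > 0) unique(full$cds) else character(0),
         n_full_reads = n),
    class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> pool: %s | %d full reads | %d x %d genotypes\n",
              paste(x$pool, collapse = "/"), x$n_full_reads,
              nrow(x$counts), ncol(x$counts)))
  print(utils::head(x$counts, 10))
  invisible(x)
}

#' @export
as.matrix.abundance_matrix <- function(x, which = c("fraction", "count"), ...) {
  which <- match.arg(which)
  if (which == "fraction") x$fractions else x$counts
}

#' Tidy an abundance matrix into a long tibble
#'
#' @param x An `abundance_matrix`.
#' @param ... Unused.
#' @return Tibble: `promoter`, `sp`, `count`, `fraction`.
#' @export
tidy.abundance_matrix <- function(x, ...) {
  tibble(
    promoter = rep(rownames(x$counts), times = ncol(x$counts)),
    sp = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.integer(x$counts),
    fraction = as.numeric(x$fractions)
  )
}

#' @rdname tidy.abundance_matrix
#' @export
glance.abundance_matrix <- function(x, ...) {
  top <- top_genotypes(x, 1)
  tibble(
    pool = paste(x$pool, collapse = "/"),
    n_full_reads = x$n_full_reads,
    n_genotypes_observed = sum(x$counts > 0),
    top_genotype = if (nrow(top) > 0) paste0(top$promoter, "_", top$sp) else NA_character_,
    top_fraction = if (nrow(top) > 0) top$fraction else NA_real_
  )
}

#' Most abundant genotypes of a pool
#'
#' Ranked by descending fraction; ties broken lexicographically by promoter
#' id then signal-peptide id. At most `min(n, nonzero cells)` rows are
#' returned.
#'
#' @param x An `abundance_matrix`.
#' @param n Number of entries (>= 1).
#' @return Tibble: `promoter`, `sp`, `genotype` (promoter_sp), `count`,
#'   `fraction`.
#' @export
top_genotypes <- function(x, n = 5) {
  if (n < 1) abort("n must be >= 1")
  tidy(x) |>
    filter(.data$count > 0) |>
    arrange(desc(.data$fraction), .data$promoter, .data$sp) |>
    head(n) |>
    mutate(genotype = paste0(.data$promoter, "_", .data$sp)) |>
    select("promoter", "sp", "genotype", "count", "fraction")
}

#' Per-genotype gate profile and secretion rank score
#'
#' Joins the low/medium/high abundance matrices of one ORF library and
#' summarises each genotype's distribution across gates as a scalar rank
#' score: the gate-weighted mean of its per-gate fractions, with weights
#' low = 0, medium = 1, high = 2, normalised by the genotype's total
#' fraction mass. The score ranges from 0 (only seen in the low gate) to 2
#' (only in the high gate) and is invariant to per-gate read depth.
#' Genotypes absent from all three gates are omitted.
#'
#' @param low,medium,high `abundance_matrix` objects sharing axes.
#' @return Tibble: `promoter`, `sp`, `genotype`, `f_low`, `f_medium`,
#'   `f_high`, `score`.
#' @export
enrichment_across_gates <- function(low, medium, high) {
  mats <- list(low = low, medium = medium, high = high)
  dims <- purrr::map(mats, ~ dimnames(.x$counts))
  if (!all(purrr::map_lgl(dims[-1], identical, dims[[1]]))) {
    abort("abundance matrices must share row/column order")
  }
  out <- tidy(low) |>
    select("promoter", "sp", f_low = "fraction") |>
    mutate(f_medium = as.numeric(medium$fractions),
           f_high = as.numeric(high$fractions)) |>
    filter(.data$f_low + .data$f_medium + .data$f_high > 0) |>
    mutate(
      genotype = paste0(.data$promoter, "_", .data$sp),
      score = (.data$f_medium + 2 * .data$f_high) /
        (.data$f_low + .data$f_medium + .data$f_high)
    ) |>
    select("promoter", "sp", "genotype", "f_low", "f_medium", "f_high", "score")
  class(out) <- c("gate_profile", class(out))
  out
}

#' Export / read a heatmap-ready abundance table
#'
#' Wide TSV with one promoter row per line and one column per signal
#' peptide, in fixed registry order.
#'
#' @param x An `abundance_matrix`.
#' @param path TSV path.
#' @param values `"fraction"` (default) or `"count"`.
#' @export
export_heatmap_table <- function(x, path, values = c("fraction", "count")) {
  values <- match.arg(values)
  m <- as.matrix(x, which = values)
  df <- tibble::as_tibble(m, rownames = "promoter")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname export_heatmap_table
#' @param pool Pool label attached to the re-read matrix.
#' @export
read_heatmap_table <- function(path, values = c("fraction", "count"),
                               pool = NA) {
  values <- match.arg(values)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$promoter
  names(dimnames(m)) <- c("promoter", "sp")
  if (values == "count") {
    n <- as.integer(sum(m))
    structure(list(counts = m, fractions = if (n > 0) m / n else m,
                   pool = pool, cds = character(0), n_full_reads = n),
              class = "abundance_matrix")
  } else {
    structure(list(counts = matrix(NA_integer_, nrow(m), ncol(m),
                                   dimnames = dimnames(m)),
                   fractions = m, pool = pool, cds = character(0),
                   n_full_reads = NA_integer_),
              class = "abundance_matrix")
  }
}

#' Heatmap of an abundance matrix
#'
#' @param object An `abundance_matrix`.
#' @param values `"fraction"` or `"count"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.abundance_matrix <- function(object, values = c("fraction", "count"), ...) {
  values <- match.arg(values)
  df <- tidy(object) |>
    mutate(promoter = factor(.data$promoter, levels = rev(rownames(object$counts))),
           sp = factor(.data$sp, levels = colnames(object$counts)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sp, y = .data$promoter,
                                   fill = .data[[values]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "signal peptide", y = "promoter", fill = values,
                  title = paste("pool:", paste(object$pool, collapse = "/"))) +
    ggplot2::theme_minimal()
}

#' Gate-profile plot of per-genotype rank scores
#'
#' @param object A `gate_profile` tibble ([enrichment_across_gates()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gate_profile <- function(object, ...) {
  df <- arrange(object, .data$score) |>
    mutate(genotype = factor(.data$genotype, levels = .data$genotype))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$genotype)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "gate rank score (0 = low only, 2 = high only)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
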