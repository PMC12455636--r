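#' Gate model for FACS sorting
#'
#' Three increasing thresholds on log10 fluorescence define four intervals:
#' low `(-Inf, t_low)`, an intentionally excluded band `[t_low, t_mid)` that
#' separates low from medium expression, medium `[t_mid, t_high)` and high
#' `[t_high, Inf)`. Intervals are left-closed; cells falling in the excluded
#' band are discarded. Defaults sit inside the 1e2-1e5 span of the
#' display-fluorescence scale.
#'
#' @param t_low,t_mid,t_high Increasing log10-fluorescence thresholds.
#' @return A `gate_model` list.
#' @export
gate_model <- function(t_low = 2.7, t_mid = 3.2, t_high = 4.2) {
  if (!(t_low < t_mid && t_mid < t_high)) abort("need t_low < t_mid < t_high")
  structure(list(t_low = t_low, t_mid = t_mid, t_high = t_high),
            class = "gate_model")
}

#' Nanopore-like read error model
#'
#' Per-base substitution/insertion/deletion probabilities (defaults total
#' ~8%, typical of current long-read chemistry), plus the probability that a
#' template lacks its CDS part entirely (the truncated, "false-high" species)
#' and the probability of a chimeric template formed by concatenating two
#' barcoded amplicons.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities in \[0, 0.2\].
#' @param truncation_prob,chimera_prob Per-template probabilities in \[0, 1\].
#' @return An `error_model` list.
#' @export
error_model <- function(sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.03,
                        truncation_prob = 0, chimera_prob = 0) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.2)) abort("error rates must lie in [0, 0.2]")
  if (truncation_prob < 0 || truncation_prob > 1 ||
      chimera_prob < 0 || chimera_prob > 1) {
    abort("truncation_prob and chimera_prob must lie in [0, 1]")
  }
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
                 truncation_prob = truncation_prob, chimera_prob = chimera_prob),
            class = "error_model")
}

#' Default promoter-strength x signal-peptide expression map
#'
#' Mean log10 display fluorescence per (promoter strength class, signal
#' peptide). Calibrated qualitatively to the screening pattern of the system
#' this models: strong promoters with the MF (and to a lesser degree STA1)
#' signal peptide give the brightest display, weak promoters sit just above
#' the ~1e2 background regardless of signal peptide.
#'
#' @return Tibble with columns `strength_class`, `sp`, `mu`.
#' @export
default_strength_mu <- function() {
  tidyr::expand_grid(
    strength_class = STRENGTH_CLASSES,
    sp = c("MF", "STA1", "SUC2", "AMY")
  ) |>
    mutate(mu = c(
      4.8, 4.3, 3.4, 3.1,   # strong
      3.6, 3.4, 2.9, 2.7,   # medium
      2.4, 2.35, 2.3, 2.25  # weak
    ))
}

#' Assign per-genotype fluorescence means
#'
#' Each genotype's mean log10 fluorescence is the (strength class, signal
#' peptide) base value plus a small genotype-specific offset (normal with sd
#' `jitter_sd`, clamped to +/- 3 sd so that the class ordering - strong above
#' weak for the same signal peptide - is preserved by construction), clamped
#' to the observable \[2, 5\] span.
#'
#' @param designs Construct designs ([enumerate_design_space()]).
#' @param registry Part registry supplying promoter strength classes.
#' @param strength_mu Map of (strength_class, sp) to mean log10 fluorescence;
#'   see [default_strength_mu()].
#' @param sigma Shared per-cell log10 sd (biological + measurement spread).
#' @param jitter_sd Sd of the deterministic per-genotype offset.
#' @param background_mu Mean log10 fluorescence of non-displaying cells.
#' @param seed Integer seed; the model is deterministic given the seed.
#' @return A `fluorescence_model` tibble (`genotype_key`, `promoter`, `sp`,
#'   `cds`, `strength_class`, `mu`) with `sigma` and `background_mu`
#'   attributes.
#' @export
assign_fluorescence <- function(designs, registry,
                                strength_mu = default_strength_mu(),
                                sigma = 0.3, jitter_sd = 0.1,
                                background_mu = 2.0, seed = 1L) {
  if (nrow(designs) == 0) {
    out <- tibble(genotype_key = character(), promoter = character(),
                  sp = character(), cds = character(),
                  strength_class = character(), mu = double())
    return(structure(out, sigma = sigma, background_mu = background_mu,
                     class = c("fluorescence_model", class(tibble()))))
  }
  cls <- registry |>
    filter(.data$role == "promoter") |>
    select(promoter = "part_id", "strength_class")
  out <- designs |>
    select("genotype_key", "promoter", "sp", "cds") |>
    left_join(cls, by = "promoter")
  if (anyNA(out$strength_class)) {
    abort(sprintf("promoter without strength_class: %s",
                  paste(unique(out$promoter[is.na(out$strength_class)]),
                        collapse = ", ")))
  }
  out <- left_join(out, strength_mu, by = c("strength_class", "sp"))
  if (anyNA(out$mu)) {
    bad <- out[is.na(out$mu), c("strength_class", "sp")]
    abort(sprintf("no expression value mapped for: %s",
                  paste(unique(paste(bad$strength_class, bad$sp)), collapse = ", ")))
  }
  withr::with_seed(as.integer(seed), {
    jit <- rnorm(nrow(out), 0, jitter_sd)
    jit <- pmin(pmax(jit, -3 * jitter_sd), 3 * jitter_sd)
    out$mu <- pmin(pmax(out$mu + jit, 2), 5)
  })
  structure(out, sigma = sigma, background_mu = background_mu,
            class = c("fluorescence_model", class(tibble())))
}

#' Sort cells into fluorescence gates
#'
#' Draws `n_cells` cells from the library composition, gives each a log10
#' fluorescence ~ Normal(mu_genotype, sigma) and bins it by the gate model.
#' Cells in the excluded band between low and medium are discarded, so the
#' returned counts sum to at most `n_cells`.
#'
#' @param model A `fluorescence_model`.
#' @param gates A [gate_model()].
#' @param composition Tibble (`genotype_key`, `frequency`) or named numeric;
#'   frequencies must sum to 1 (tolerance 1e-9).
#' @param n_cells Number of cells sorted (>= 1).
#' @param seed Integer seed.
#' @param sigma Per-cell log10 sd; defaults to the model's. `sigma = 0` is
#'   allowed as the degenerate noise-free limit.
#' @return Tibble (`gate`, `genotype_key`, `count`) with attributes
#'   `n_cells` and `n_excluded`.
#' @export
sort_cells <- function(model, gates, composition, n_cells, seed = 1L,
                       sigma = NULL) {
  sigma <- sigma %||% attr(model, "sigma")
  if (is.numeric(composition) && !is.null(names(composition))) {
    composition <- tibble(genotype_key = names(composition),
                          frequency = unname(composition))
  }
  if (abs(sum(composition$frequency) - 1) > 1e-9) {
    abort("composition frequencies must sum to 1")
  }
  if (n_cells < 1) abort("n_cells must be >= 1")
  mu <- setNames(model$mu, model$genotype_key)
  if (!all(composition$genotype_key %in% names(mu))) {
    abort("composition contains genotypes absent from the fluorescence model")
  }
  breaks <- c(gates$t_low, gates$t_mid, gates$t_high)
  withr::with_seed(as.integer(seed), {
    counts <- rmultinom(1, n_cells, composition$frequency)[, 1]
    per <- purrr::map2(composition$genotype_key, counts, function(g, k) {
      if (k == 0) return(NULL)
      x <- rnorm(k, mu[[g]], sigma)
      bin <- findInterval(x, breaks)  # 0 low, 1 excluded, 2 medium, 3 high
      tibble(genotype_key = g, bin = bin)
    })
  })
  cells <- bind_rows(per)
  n_excluded <- sum(cells$bin == 1)
  out <- cells |>
    filter(.data$bin != 1) |>
    mutate(gate = c("low", NA, "medium", "high")[.data$bin + 1L]) |>
    dplyr::count(.data$gate, .data$genotype_key, name = "count") |>
    mutate(gate = factor(.data$gate, levels = GATES)) |>
    arrange(.data$gate, .data$genotype_key)
  attr(out, "n_cells") <- n_cells
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Uniform library composition over a design set
#'
#' @param designs Construct designs.
#' @return Tibble (`genotype_key`, `frequency`).
#' @export
uniform_composition <- function(designs) {
  tibble(genotype_key = designs$genotype_key,
         frequency = 1 / nrow(designs))
}

# apply per-base substitution/insertion/deletion noise to one sequence
mutate_sequence <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  keep <- runif(length(b)) >= del_rate
  surv <- b[keep]
  do_sub <- runif(length(surv)) < sub_rate
  if (any(do_sub)) {
    # substitute with one of the three other bases
    cur <- match(surv[do_sub], DNA_BASES)
    shift <- sample(1:3, sum(do_sub), replace = TRUE)
    surv[do_sub] <- DNA_BASES[((cur - 1 + shift) %% 4) + 1]
  }
  ins_at <- which(runif(length(surv) + 1) < ins_rate)  # gap g precedes base g
  if (length(ins_at) > 0) {
    vals <- c(surv, sample(DNA_BASES, length(ins_at), replace = TRUE))
    keys <- c(seq_along(surv), ins_at - 0.5)
    surv <- vals[order(keys)]
  }
  paste(surv, collapse = "")
}

#' Simulate nanopore-like reads from sorted gate pools
#'
#' Each read is a forward (ORF library) barcode, the amplicon of a genotype
#' sampled in proportion to its gate count, and a reverse (gate) barcode,
#' mutated under the error model and reverse-complemented with probability
#' 0.5. Truncated templates lack the CDS part (one junction copy retained, so
#' they are shorter by `cds length - 4`); chimeric templates concatenate a
#' second barcoded amplicon. The hidden truth is carried alongside each read.
#'
#' @param pools Output of [sort_cells()] for one ORF library.
#' @param designs Construct designs of that library (single CDS).
#' @param barcodes Barcode manifest ([make_barcode_set()]); the forward
#'   barcode is looked up by the library's CDS id, reverse barcodes by gate.
#' @param errors An [error_model()].
#' @param reads_per_pool Reads to emit per gate pool (>= 1).
#' @param seed Integer seed; identical inputs and seed give identical reads.
#' @return Tibble: `read_id`, `sequence`, `quality` (constant placeholder),
#'   and truth columns `genotype_key`, `gate`, `strand`, `truncated`,
#'   `chimeric`.
#' @export
simulate_reads <- function(pools, designs, barcodes, errors = error_model(),
                           reads_per_pool = 500, seed = 1L) {
  if (reads_per_pool < 1) abort("reads_per_pool must be >= 1")
  orf <- unique(designs$cds)
  if (length(orf) != 1) abort("designs must share a single CDS (one ORF library)")
  fwd <- barcodes$sequence[barcodes$role == "fwd" & barcodes$pool == orf]
  if (length(fwd) != 1) abort(sprintf("missing forward barcode for pool '%s'", orf))
  dindex <- setNames(seq_len(nrow(designs)), designs$genotype_key)
  gates_present <- as.character(unique(pools$gate))
  out <- withr::with_seed(as.integer(seed), {
    purrr::map(gates_present, function(g) {
      rev_bc <- barcodes$sequence[barcodes$role == "rev" & barcodes$pool == g]
      if (length(rev_bc) != 1) abort(sprintf("missing reverse barcode for gate '%s'", g))
      cnt <- filter(pools, .data$gate == g)
      gkeys <- sample(cnt$genotype_key, reads_per_pool, replace = TRUE,
                      prob = cnt$count)
      truncated <- runif(reads_per_pool) < errors$truncation_prob
      chimeric <- runif(reads_per_pool) < errors$chimera_prob
      strand <- ifelse(runif(reads_per_pool) < 0.5, "+", "-")
      seqs <- vapply(seq_len(reads_per_pool), function(i) {
        d <- designs[dindex[[gkeys[i]]], ]
        amp <- d$sequence
        if (truncated[i]) {
          # drop the CDS but keep one copy of the shared junction
          amp <- paste0(substr(amp, 1, d$cds_start),
                        substr(amp, d$cds_start + d$cds_len - 4 + 1, nchar(amp)))
        }
        tmpl <- paste0(fwd, amp, rev_bc)
        if (chimeric[i]) {
          d2 <- designs[sample.int(nrow(designs), 1), ]
          tmpl <- paste0(tmpl, fwd, d2$sequence, rev_bc)
        }
        mutate_sequence(tmpl, errors$sub_rate, errors$ins_rate, errors$del_rate)
      }, character(1))
      tibble(
        read_id = sprintf("%s_%s_%05d", orf, g, seq_len(reads_per_pool)),
        sequence = seqs, genotype_key = gkeys, gate = g,
        strand = strand, truncated = truncated, chimeric = chimeric
      )
    }) |> bind_rows()
  })
  minus <- out$strand == "-"
  if (any(minus)) out$sequence[minus] <- revcomp(out$sequence[minus])
  out$quality <- strrep("I", nchar(out$sequence))
  select(out, "read_id", "sequence", "quality", "genotype_key", "gate",
         "strand", "truncated", "chimeric")
}

#' Write the hidden truth table of a simulated read set
#'
#' @param reads Tibble from [simulate_reads()].
#' @param path Output TSV path.
#' @export
write_truth_table <- function(reads, path) {
  readr::write_tsv(select(reads, "read_id", "genotype_key", "gate", "strand",
                          "truncated", "chimeric"), path)
  invisible(path)
}
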