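#' Default pipeline configuration
#'
#' @param parts_fasta,parts_manifest,barcodes,out_dir File paths.
#' @return Nested configuration list (see [validate_config()] for the
#'   schema); scalar values are the package defaults.
#' @export
default_config <- function(parts_fasta = NULL, parts_manifest = NULL,
                           barcodes = NULL, out_dir = NULL) {
  list(
    paths = list(parts_fasta = parts_fasta, parts_manifest = parts_manifest,
                 barcodes = barcodes, out_dir = out_dir),
    simulate = list(
      orfs = c("BLA", "ELP2", "ELP4"),
      mode = "display",
      reads_per_pool = 500L,
      n_cells = 20000L,
      sigma = 0.3,
      jitter_sd = 0.1,
      gates = list(t_low = 2.7, t_mid = 3.2, t_high = 4.2),
      errors = list(sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.03,
                    truncation_prob = 0, chimera_prob = 0)
    ),
    demux = list(max_dist = 4L, window = 150L, min_len = 2000L),
    call = list(min_identity = 0.8, min_coverage = 0.8),
    quantify = list(top_n = 5L, min_full_reads = 1000L),
    marker = "CBM",
    seed = 1L
  )
}

check_keys <- function(user, def, prefix = "") {
  if (!is.list(user)) return(invisible(NULL))
  for (k in names(user)) {
    if (!nzchar(k)) abort("config entries must be named")
    if (!k %in% names(def)) {
      sugg <- agrep(k, names(def), max.distance = 2, value = TRUE)
      hint <- if (length(sugg) > 0) sprintf(" (did you mean '%s'?)", sugg[1]) else ""
      abort(sprintf("unknown config key '%s%s'%s", prefix, k, hint))
    }
    if (is.list(def[[k]]) && length(names(def[[k]])) > 0) {
      check_keys(user[[k]], def[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(NULL)
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills defaults, rejects unknown
#' keys (with a nearest-key suggestion), checks ranges and verifies that all
#' referenced input paths exist.
#'
#' @param config YAML path or list (see [default_config()] for the schema).
#' @return Validated `run_config` list with all defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  def <- default_config()
  check_keys(config, def)
  cfg <- utils::modifyList(def, config)
  for (p in c("parts_fasta", "parts_manifest", "barcodes")) {
    if (is.null(cfg$paths[[p]])) abort(sprintf("paths.%s is required", p))
    if (!file.exists(cfg$paths[[p]])) {
      abort(sprintf("paths.%s does not exist: %s", p, cfg$paths[[p]]))
    }
  }
  if (is.null(cfg$paths$out_dir)) abort("paths.out_dir is required")
  if (cfg$demux$max_dist < 0) abort("demux.max_dist must be >= 0")
  if (cfg$demux$min_len < 0) abort("demux.min_len must be >= 0")
  if (cfg$demux$window < 1) abort("demux.window must be >= 1")
  for (t in c("min_identity", "min_coverage")) {
    v <- cfg$call[[t]]
    if (v <= 0 || v > 1) abort(sprintf("call.%s must lie in (0, 1]", t))
  }
  if (cfg$simulate$reads_per_pool < 1) abort("simulate.reads_per_pool must be >= 1")
  if (cfg$simulate$n_cells < 1) abort("simulate.n_cells must be >= 1")
  g <- cfg$simulate$gates
  if (!(g$t_low < g$t_mid && g$t_mid < g$t_high)) {
    abort("simulate.gates must satisfy t_low < t_mid < t_high")
  }
  do.call(error_model, cfg$simulate$errors)  # range checks
  structure(cfg, class = "run_config")
}

#' Run the full screening pipeline
#'
#' Simulate -> demultiplex -> length-filter -> orient -> annotate/call ->
#' quantify, as one reproducible run. Every stage writes its outputs under
#' `paths.out_dir` and logs its filter attrition; a per-pool summary table
#' records the conservation chain reads_total >= assigned >= length_ok >=
#' oriented >= full_calls. Identical configs (including seed) give
#' byte-identical summaries.
#'
#' @param config YAML path, list, or validated `run_config`.
#' @return A `gatecall_run` object: `summary` tibble, matrices per pool,
#'   gate profiles per ORF, the echoed config and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out <- cfg$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  registry <- stage("load", read_parts_registry(cfg$paths$parts_fasta,
                                                cfg$paths$parts_manifest))
  barcodes <- stage("load", readr::read_tsv(cfg$paths$barcodes,
                                            show_col_types = FALSE))
  orfs <- cfg$simulate$orfs
  seeds <- derive_seeds(cfg$seed, 2L + 3L * length(orfs))
  gates <- do.call(gate_model, cfg$simulate$gates)
  errors <- do.call(error_model, cfg$simulate$errors)

  reads <- stage("simulate", {
    per_orf <- purrr::imap(orfs, function(orf, i) {
      designs <- enumerate_design_space(registry, cds = orf,
                                        mode = cfg$simulate$mode)
      fl <- assign_fluorescence(designs, registry, sigma = cfg$simulate$sigma,
                                jitter_sd = cfg$simulate$jitter_sd,
                                seed = seeds[3 * i])
      pools <- sort_cells(fl, gates, uniform_composition(designs),
                          cfg$simulate$n_cells, seed = seeds[3 * i + 1])
      simulate_reads(pools, designs, barcodes, errors,
                     reads_per_pool = cfg$simulate$reads_per_pool,
                     seed = seeds[3 * i + 2])
    })
    r <- bind_rows(per_orf)
    r <- withr::with_seed(seeds[1], r[sample.int(nrow(r)), ])
    message(sprintf("[simulate] %d reads from %d ORF libraries", nrow(r),
                    length(orfs)))
    write_fastq(r, file.path(out, "reads.fastq"))
    write_truth_table(r, file.path(out, "truth.tsv"))
    r
  })

  assignments <- stage("demux", {
    a <- demultiplex(select(reads, "read_id", "sequence"), barcodes,
                     max_dist = cfg$demux$max_dist, window = cfg$demux$window)
    message(sprintf("[demux] %d/%d reads assigned to pools",
                    sum(a$status == "assigned"), nrow(a)))
    a
  })

  assignments <- stage("length_filter", {
    a <- filter_length(assignments, min_len = cfg$demux$min_len)
    message(sprintf("[length_filter] %d reads >= %d nt retained",
                    sum(a$status == "assigned"), cfg$demux$min_len))
    a
  })

  marker_seq <- registry$sequence[registry$part_id == cfg$marker]
  if (length(marker_seq) != 1) {
    abort(sprintf("stage 'orient' failed: marker part '%s' not in registry",
                  cfg$marker))
  }
  oriented <- stage("orient", {
    keep <- assignments$read_id[assignments$status == "assigned"]
    o <- orient_reads(filter(reads, .data$read_id %in% keep), marker_seq,
                      min_identity = cfg$call$min_identity)
    message(sprintf("[orient] %d/%d reads oriented by the %s marker",
                    sum(o$status == "oriented"), nrow(o), cfg$marker))
    o
  })
  # propagate orientation failures into the assignment status
  st <- setNames(oriented$status, oriented$read_id)
  assignments <- mutate(assignments, status = ifelse(
    .data$status == "assigned" & st[.data$read_id] != "oriented",
    st[.data$read_id], .data$status))
  readr::write_tsv(assignments, file.path(out, "assignments.tsv"))

  # per-pool FASTQ of the oriented, fully filtered reads
  ok_ids <- assignments$read_id[assignments$status == "assigned"]
  pool_of <- setNames(paste(assignments$orf_pool, assignments$gate_pool,
                            sep = "_"), assignments$read_id)
  okr <- filter(oriented, .data$read_id %in% ok_ids)
  for (pool in split(okr, pool_of[okr$read_id])) {
    write_fastq(pool, file.path(out, sprintf("pool_%s.fastq",
                                             pool_of[[pool$read_id[1]]])))
  }

  calls <- stage("call", {
    keep <- filter(oriented, .data$status == "oriented")
    hits <- annotate_reads(
      select(keep, "read_id", "sequence", "marker_start", "marker_end"),
      registry, min_identity = cfg$call$min_identity,
      min_coverage = cfg$call$min_coverage)
    cl <- call_genotypes(hits, read_ids = keep$read_id)
    cl <- left_join(cl, select(assignments, "read_id", "orf_pool", "gate_pool"),
                    by = "read_id")
    message(sprintf("[call] %d/%d reads with full genotype calls",
                    sum(cl$call_status == "full"), nrow(cl)))
    write_calls(cl, file.path(out, "calls.tsv"))
    for (orf in orfs) {
      ids <- cl$read_id[cl$orf_pool == orf]
      write_gff3(filter(hits, .data$read_id %in% ids),
                 file.path(out, sprintf("annotation_%s.gff3", orf)))
    }
    cl
  })

  result <- stage("quantify", {
    pools <- tidyr::expand_grid(orf = orfs, gate = GATES)
    mats <- purrr::pmap(pools, function(orf, gate) {
      pc <- filter(calls, .data$orf_pool == orf, .data$gate_pool == gate)
      m <- suppressWarnings(count_genotypes(pc, registry,
                                            pool = c(orf = orf, gate = gate)))
      if (m$n_full_reads < cfg$quantify$min_full_reads) {
        warn(sprintf("pool %s/%s has %d full reads (< %d)", orf, gate,
                     m$n_full_reads, cfg$quantify$min_full_reads))
      }
      export_heatmap_table(m, file.path(out, sprintf("matrix_%s_%s.tsv", orf, gate)))
      readr::write_tsv(top_genotypes(m, cfg$quantify$top_n),
                       file.path(out, sprintf("top_%s_%s.tsv", orf, gate)))
      m
    })
    names(mats) <- paste(pools$orf, pools$gate, sep = "_")
    profiles <- purrr::map(orfs, function(orf) {
      p <- enrichment_across_gates(mats[[paste0(orf, "_low")]],
                                   mats[[paste0(orf, "_medium")]],
                                   mats[[paste0(orf, "_high")]])
      readr::write_tsv(p, file.path(out, sprintf("profile_%s.tsv", orf)))
      p
    })
    names(profiles) <- orfs
    list(matrices = mats, profiles = profiles, pools = pools)
  })

  summary <- purrr::pmap(result$pools, function(orf, gate) {
    in_pool <- assignments$orf_pool == orf & assignments$gate_pool == gate &
      !is.na(assignments$orf_pool)
    m <- result$matrices[[paste(orf, gate, sep = "_")]]
    top <- top_genotypes(m, 1)
    tibble(
      orf_pool = orf, gate_pool = gate,
      reads_total = nrow(reads),
      assigned = sum(in_pool & assignments$status %in%
                       c("assigned", "too_short", "no_marker", "chimeric")),
      length_ok = sum(in_pool & assignments$status %in%
                        c("assigned", "no_marker", "chimeric")),
      oriented = sum(in_pool & assignments$status == "assigned"),
      full_calls = m$n_full_reads,
      top_genotype = if (nrow(top) > 0) top$genotype else NA_character_,
      top_fraction = if (nrow(top) > 0) top$fraction else NA_real_
    )
  }) |> bind_rows()
  readr::write_tsv(summary, file.path(out, "summary.tsv"))
  cfg_echo <- unclass(cfg)
  yaml::write_yaml(cfg_echo, file.path(out, "config.yaml"))
  files <- sort(list.files(out))
  readr::write_tsv(tibble(file = files), file.path(out, "manifest.tsv"))

  structure(list(summary = summary, matrices = result$matrices,
                 profiles = result$profiles, config = cfg, out_dir = out),
            class = "gatecall_run")
}

#' @export
print.gatecall_run <- function(x, ...) {
  cat(sprintf("<gatecall_run> %d pools | outputs in %s\n",
              nrow(x$summary), x$out_dir))
  print(x$summary)
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `gatecall_run`.
#' @param ... Unused.
#' @return Tibble with read totals and the overall full-call rate.
#' @export
glance.gatecall_run <- function(x, ...) {
  tibble(
    n_pools = nrow(x$summary),
    reads_total = x$summary$reads_total[1],
    assigned = sum(x$summary$assigned),
    full_calls = sum(x$summary$full_calls),
    full_call_rate = sum(x$summary$full_calls) / x$summary$reads_total[1]
  )
}

#' Write a ready-to-run demonstration configuration
#'
#' Emits the demo fixtures ([write_demo_files()]) and a YAML config running
#' three ORF libraries at a small read depth.
#'
#' @param dir Directory for fixtures, outputs and `config.yaml`.
#' @param reads_per_pool Read depth per pool.
#' @param ... Overrides merged into the config (e.g. `seed = 7`).
#' @return Path to the written YAML config.
#' @export
demo_config <- function(dir, reads_per_pool = 100, ...) {
  paths <- write_demo_files(dir)
  cfg <- default_config(parts_fasta = paths$parts_fasta,
                        parts_manifest = paths$parts_manifest,
                        barcodes = paths$barcodes,
                        out_dir = file.path(dir, "out"))
  cfg$simulate$reads_per_pool <- as.integer(reads_per_pool)
  cfg <- utils::modifyList(cfg, list(...))
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  path
}
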