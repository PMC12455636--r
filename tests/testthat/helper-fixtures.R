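# shared fixtures, built once per test run
.fix <- new.env()

fix_registry <- function() {
  if (is.null(.fix$reg)) .fix$reg <- demo_registry()
  .fix$reg
}

fix_barcodes <- function() {
  if (is.null(.fix$bc)) .fix$bc <- demo_barcodes()
  .fix$bc
}

fix_marker <- function() {
  reg <- fix_registry()
  reg$sequence[reg$part_id == "CBM"]
}

fix_designs <- function(orf = "ELP2") {
  key <- paste0("designs_", orf)
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- enumerate_design_space(fix_registry(), cds = orf)
  }
  .fix[[key]]
}

# small simulated read set with truth attached
fix_reads <- function(orf = "ELP2", errors = error_model(),
                      reads_per_pool = 40, seed = 11, n_cells = 20000) {
  d <- fix_designs(orf)
  fl <- assign_fluorescence(d, fix_registry(), seed = seed)
  pools <- sort_cells(fl, gate_model(), uniform_composition(d), n_cells,
                      seed = seed + 1)
  simulate_reads(pools, d, fix_barcodes(), errors,
                 reads_per_pool = reads_per_pool, seed = seed + 2)
}
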