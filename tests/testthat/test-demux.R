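test_that("barcode matching finds exact and mutated hits with correct coordinates", {
  withr::local_seed(42)
  bc <- rand_dna(24)
  read <- paste0(bc, rand_dna(300))
  h <- match_barcode(read, bc, end = "head")
  expect_equal(h$edit_distance, 0)
  expect_equal(h$read_start, 0)
  expect_equal(h$read_end, 24)

  # one substitution
  read1 <- paste0(rand_dna(10), mutate_subs(bc, 1), rand_dna(200))
  h1 <- match_barcode(read1, bc, end = "head", max_dist = 2)
  expect_equal(h1$edit_distance, 1)
  expect_equal(h1$read_start, 10)

  # tail end: coordinates land in the final window
  read2 <- paste0(rand_dna(400), bc)
  h2 <- match_barcode(read2, bc, end = "tail")
  expect_equal(h2$read_start, 400)
  expect_equal(h2$read_end, 424)

  # an unrelated 2 kb read has no hit within distance 4
  read3 <- rand_dna(2000)
  expect_equal(nrow(match_barcode(read3, bc, end = "head", max_dist = 4,
                                  window = 2000)), 0)
  expect_gt(oracle_infix_edit(substr(read3, 1, 150), bc), 4)

  expect_error(match_barcode(read, bc, end = "head", window = 10),
               "window")
})

test_that("infix matcher agrees with the brute-force substring oracle", {
  withr::local_seed(7)
  for (case in 1:200) {
    read <- rand_dna(sample(30:120, 1))
    bc <- rand_dna(sample(6:12, 1))
    got <- gatecall:::cpp_infix_edit(read, bc)
    expect_equal(got$dist, oracle_infix_edit(read, bc))
    # reported window really achieves the reported distance
    expect_equal(as.integer(adist(substr(read, got$start + 1, got$end), bc)),
                 got$dist)
  }
})

test_that("dual-barcode demultiplexing recovers truth pools and flags failures", {
  reads <- fix_reads("ELP2", errors = error_model(0, 0, 0), reads_per_pool = 15)
  bc <- fix_barcodes()
  a <- demultiplex(dplyr::select(reads, read_id, sequence), bc)
  expect_true(all(a$status == "assigned"))
  expect_true(all(a$orf_pool == "ELP2"))
  expect_equal(a$gate_pool, reads$gate)
  expect_equal(a$strand, reads$strand)
  expect_true(all(a$fwd_dist == 0) && all(a$rev_dist == 0))

  # forward barcode only -> no_rev; no barcode -> no_fwd
  withr::local_seed(1)
  fwd <- bc$sequence[bc$barcode_id == "bcF_ELP2"]
  rev_bc <- bc$sequence[bc$barcode_id == "bcR_low"]
  naked <- tibble::tibble(
    read_id = c("fwd_only", "none", "rev_only"),
    sequence = c(paste0(fwd, rand_dna(2100)),
                 rand_dna(2100),
                 paste0(rand_dna(2100), rev_bc)))
  an <- demultiplex(naked, bc)
  expect_equal(an$status, c("no_rev", "no_fwd", "no_fwd"))

  # a read carrying two different forward barcodes is ambiguous
  fwd2 <- bc$sequence[bc$barcode_id == "bcF_BLA"]
  amb <- tibble::tibble(read_id = "amb",
                        sequence = paste0(fwd, fwd2, rand_dna(2000), rev_bc))
  expect_equal(demultiplex(amb, bc)$status, "ambiguous")

  expect_error(demultiplex(naked, bc[0, ]), "empty barcode manifest")
})

test_that("the full-amplicon length filter is inclusive at the threshold", {
  bc <- fix_barcodes()
  withr::local_seed(2)
  fwd <- bc$sequence[bc$barcode_id == "bcF_ELP2"]
  rev_bc <- bc$sequence[bc$barcode_id == "bcR_high"]
  mk <- function(id, L) tibble::tibble(
    read_id = id, sequence = paste0(fwd, rand_dna(L - 48), rev_bc))
  reads <- dplyr::bind_rows(mk("r1999", 1999), mk("r2000", 2000))
  a <- filter_length(demultiplex(reads, bc), min_len = 2000)
  expect_equal(a$status[a$read_id == "r1999"], "too_short")
  expect_equal(a$status[a$read_id == "r2000"], "assigned")
  # min_len 0 keeps everything
  a0 <- filter_length(demultiplex(reads, bc), min_len = 0)
  expect_true(all(a0$status == "assigned"))
})

test_that("orientation places the marker near the 3' end and flags chimeras", {
  reads <- fix_reads("ELP4", reads_per_pool = 8, seed = 21)
  o <- orient_reads(dplyr::select(reads, read_id, sequence), fix_marker())
  expect_true(all(o$status == "oriented"))
  expect_equal(o$strand, reads$strand)
  L <- nchar(o$sequence)
  expect_true(all((o$marker_start + o$marker_end) / 2 > L / 2))

  # minus-strand reads come back reverse-complemented to the sense strand
  minus <- which(reads$strand == "-")
  expect_true(length(minus) > 0)
  expect_equal(o$sequence[minus], revcomp(reads$sequence[minus]))

  # unrelated sequence: no marker
  withr::local_seed(3)
  stray <- tibble::tibble(read_id = "x", sequence = rand_dna(2500))
  expect_equal(orient_reads(stray, fix_marker())$status, "no_marker")

  # chimeric templates carry two disjoint sense markers
  chim <- fix_reads("ELP2", errors = error_model(chimera_prob = 1),
                    reads_per_pool = 6, seed = 9)
  oc <- orient_reads(dplyr::select(chim, read_id, sequence), fix_marker())
  expect_true(all(oc$status == "chimeric"))

  expect_error(orient_reads(stray, "ACGTACGT"), "at least 30")
})
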