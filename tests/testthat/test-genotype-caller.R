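test_that("noise-free reads annotate perfectly and in grammar order", {
  reads <- fix_reads("ELP2", errors = error_model(0, 0, 0), reads_per_pool = 4)
  o <- orient_reads(dplyr::select(reads, read_id, sequence), fix_marker())
  h <- annotate_reads(o, fix_registry())
  d <- fix_designs("ELP2")
  for (id in o$read_id) {
    hi <- dplyr::filter(h, read_id == id)
    expect_gte(nrow(hi), 4)
    expect_true(all(hi$identity == 1))
    expect_true(all(hi$coverage == 1))
    tr <- reads[reads$read_id == id, ]
    des <- d[d$genotype_key == tr$genotype_key, ]
    expect_equal(hi$part_id[hi$role == "promoter"], des$promoter)
    expect_equal(hi$part_id[hi$role == "sp_flag"], des$sp)
    expect_equal(hi$part_id[hi$role == "cds"], des$cds)
    # sorted by read start, grammar order
    expect_equal(hi$read_start, sort(hi$read_start))
    expect_equal(hi$role[1:4], c("promoter", "sp_flag", "cds", "fusion_4a"))
  }
})

test_that("annotation at nanopore-like error still recovers the true parts", {
  reads <- fix_reads("ELP4", reads_per_pool = 6, seed = 31)
  o <- orient_reads(dplyr::select(reads, read_id, sequence), fix_marker())
  h <- annotate_reads(o, fix_registry())
  d <- fix_designs("ELP4")
  for (id in o$read_id) {
    hi <- dplyr::filter(h, read_id == id)
    des <- d[d$genotype_key == reads$genotype_key[reads$read_id == id], ]
    expect_setequal(hi$part_id[hi$role %in% c("promoter", "sp_flag", "cds")],
                    c(des$promoter, des$sp, des$cds))
    expect_true(all(hi$identity >= 0.8))
  }
})

test_that("random DNA yields zero accepted part hits", {
  withr::local_seed(13)
  h <- annotate_read(rand_dna(2500), fix_registry())
  expect_equal(nrow(h), 0)
})

test_that("alignment scores agree with the quadratic-time oracle", {
  withr::local_seed(17)
  # generic local alignment on unrelated short sequences
  for (i in 1:15) {
    s <- rand_dna(sample(80:300, 1))
    p <- rand_dna(sample(20:60, 1))
    expect_equal(sw_align(s, p)$score, oracle_sw_score(s, p))
  }
  # part-in-read annotation path (seeded banded kernel) on mutated embeddings
  reg <- fix_registry()
  for (i in 1:15) {
    part <- reg$sequence[reg$part_id == "MF"]
    read <- paste0(rand_dna(60), mutate_subs(part, sample(3:10, 1)), rand_dna(80))
    got <- annotate_read(read, reg, min_identity = 0.5, min_coverage = 0.5)
    got <- got[got$part_id == "MF", ]
    expect_equal(got$score, oracle_sw_score(read, part))
  }
})

test_that("GFF3 output round-trips losslessly through the package reader", {
  reads <- fix_reads("BLA", reads_per_pool = 4, seed = 41)
  o <- orient_reads(dplyr::select(reads, read_id, sequence), fix_marker())
  h <- annotate_reads(o, fix_registry())
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(h, path)
  # 1-based inclusive on disk
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), nrow(h))
  first <- dplyr::arrange(h, read_id, read_start)[1, ]
  expect_true(any(grepl(sprintf("\t%d\t%d\t", first$read_start + 1, first$read_end),
                        body, fixed = TRUE)))
  back <- read_gff3(path)
  key <- function(x) dplyr::arrange(x, read_id, read_start, part_id)
  expect_equal(key(back)$part_id, key(h)$part_id)
  expect_equal(key(back)$read_start, key(h)$read_start)
  expect_equal(key(back)$read_end, key(h)$read_end)
  expect_equal(key(back)$identity, key(h)$identity, tolerance = 1e-5)
  expect_equal(key(back)$coverage, key(h)$coverage, tolerance = 1e-5)
  expect_equal(key(back)$clipped, key(h)$clipped)

  # empty hit set -> valid header-only GFF3
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(h[0, ], p2)
  expect_true(startsWith(readLines(p2)[1], "##gff-version 3"))
  expect_equal(nrow(read_gff3(p2)), 0)
})

test_that("genotype calling maps hit patterns to call statuses", {
  mk <- function(part_id, role, s, e) tibble::tibble(
    part_id = part_id, role = role, read_start = s, read_end = e,
    strand = "+", identity = 0.95, coverage = 0.95,
    score = as.integer((e - s) * 2), clipped = FALSE)
  full <- dplyr::bind_rows(
    mk("pYTK010", "promoter", 24, 524), mk("MF", "sp_flag", 520, 670),
    mk("ELP2", "cds", 666, 1270), mk("CBM", "fusion_4a", 1266, 1620))
  c1 <- call_genotype(full)
  expect_equal(c1$call_status, "full")
  expect_equal(c1$genotype_key, "pYTK010__MF__ELP2")

  # no CDS: the false-high truncation signature
  c2 <- call_genotype(full[c(1, 2, 4), ])
  expect_equal(c2$call_status, "truncated_no_cds")
  expect_equal(c2$promoter, "pYTK010")
  expect_true(is.na(c2$cds))

  # promoter downstream of the signal peptide violates the grammar
  swapped <- full
  swapped$read_start[1] <- 700; swapped$read_end[1] <- 1200
  expect_equal(call_genotype(swapped)$call_status, "ambiguous")

  # two accepted promoters
  two <- dplyr::bind_rows(full, mk("pYTK011", "promoter", 1700, 2200))
  expect_equal(call_genotype(two)$call_status, "ambiguous")

  # missing slots and empty hit sets
  expect_equal(call_genotype(full[c(1, 2), ])$call_status, "partial")
  expect_equal(call_genotype(full[0, ])$call_status, "uncallable")
})

test_that("calls are invariant to input orientation", {
  reads <- fix_reads("ELP2", reads_per_pool = 5, seed = 51)
  o <- orient_reads(dplyr::select(reads, read_id, sequence), fix_marker())
  calls_pipeline <- call_genotypes(annotate_reads(o, fix_registry()),
                                   read_ids = o$read_id)
  # hand the annotator pre-sense-strand reads instead
  sense <- dplyr::mutate(reads,
    sequence = ifelse(strand == "-", revcomp(sequence), sequence))
  o2 <- orient_reads(dplyr::select(sense, read_id, sequence), fix_marker())
  expect_true(all(o2$strand == "+"))
  calls_direct <- call_genotypes(annotate_reads(o2, fix_registry()),
                                 read_ids = o2$read_id)
  expect_equal(calls_pipeline, calls_direct)
})

test_that("clipped 5' promoters are rescued at relaxed coverage", {
  reg <- fix_registry()
  d <- assemble_construct(reg, "pYTK012", "STA1", "BLA")
  # cut half of the promoter off the 5' end, as a primer-clipped read would be
  plen <- reg$length[reg$part_id == "pYTK012"]
  read <- substr(d$sequence, plen %/% 2, nchar(d$sequence))
  h <- annotate_read(read, reg)
  ph <- h[h$role == "promoter", ]
  expect_equal(ph$part_id, "pYTK012")
  expect_true(ph$clipped)
  expect_lt(ph$coverage, 0.8)
  expect_gte(ph$coverage, 0.5)
  expect_equal(call_genotype(h)$call_status, "full")
})
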