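test_that("fluorescence assignment respects strength classes and the seed", {
  reg <- fix_registry()
  d <- fix_designs("ELP2")
  fl <- assign_fluorescence(d, reg, seed = 3)
  expect_equal(nrow(fl), 80)
  expect_true(all(fl$mu >= 2 & fl$mu <= 5))
  # strong-promoter genotypes above weak-promoter genotypes for the same sp
  by_sp <- dplyr::group_by(fl, sp) |>
    dplyr::summarise(strong = min(mu[strength_class == "strong"]),
                     weak = max(mu[strength_class == "weak"]))
  expect_true(all(by_sp$strong > by_sp$weak))
  # weak promoters sit near background, strong + MF near the top of the span
  expect_lt(max(fl$mu[fl$strength_class == "weak"]), 2.8)
  expect_gt(min(fl$mu[fl$strength_class == "strong" & fl$sp == "MF"]), 4.4)
  # deterministic under the seed
  expect_identical(fl, assign_fluorescence(d, reg, seed = 3))
  expect_false(identical(fl$mu, assign_fluorescence(d, reg, seed = 4)$mu))
  # empty designs -> empty model
  expect_equal(nrow(assign_fluorescence(d[0, ], reg)), 0)
  # unmapped (class, sp) combination
  expect_error(
    assign_fluorescence(d, reg, strength_mu = default_strength_mu()[1:3, ]),
    "no expression value"
  )
})

test_that("degenerate sorts respect gate boundaries (left-closed intervals)", {
  reg <- fix_registry()
  d <- fix_designs("ELP2")[1, ]
  g <- gate_model()
  comp <- uniform_composition(d)
  fl <- assign_fluorescence(d, reg, seed = 1)

  fl$mu <- 2.1  # far below t_low
  s <- sort_cells(fl, g, comp, 500, seed = 1, sigma = 0)
  expect_equal(as.character(unique(s$gate)), "low")
  expect_equal(sum(s$count), 500)

  fl$mu <- g$t_mid  # exactly on the medium gate edge
  s <- sort_cells(fl, g, comp, 500, seed = 1, sigma = 0)
  expect_equal(as.character(unique(s$gate)), "medium")

  fl$mu <- (g$t_low + g$t_mid) / 2  # inside the excluded band
  s <- sort_cells(fl, g, comp, 500, seed = 1, sigma = 0)
  expect_equal(nrow(s), 0)
  expect_equal(attr(s, "n_excluded"), 500)

  expect_error(sort_cells(fl, g, dplyr::mutate(comp, frequency = 0.9), 100),
               "sum to 1")
  expect_error(sort_cells(fl, g, comp, 0), "n_cells")
})

test_that("gate fractions converge to the normal-CDF band probabilities", {
  reg <- fix_registry()
  d <- fix_designs("ELP2")[1:2, ]
  fl <- assign_fluorescence(d, reg, seed = 1)
  fl$mu <- c(2.5, 4.8)
  sigma <- 0.3
  g <- gate_model()
  n <- 1e5
  s <- sort_cells(fl, g, uniform_composition(d), n, seed = 7, sigma = sigma)
  expected_bands <- function(mu) {
    c(low = stats::pnorm(g$t_low, mu, sigma),
      medium = stats::pnorm(g$t_high, mu, sigma) - stats::pnorm(g$t_mid, mu, sigma),
      high = 1 - stats::pnorm(g$t_high, mu, sigma))
  }
  for (i in 1:2) {
    exp_p <- expected_bands(fl$mu[i]) / 2  # each genotype holds half the cells
    got <- s |> dplyr::filter(genotype_key == fl$genotype_key[i])
    for (gate in names(exp_p)) {
      obs <- sum(got$count[as.character(got$gate) == gate]) / n
      sd3 <- 3 * sqrt(exp_p[[gate]] * (1 - exp_p[[gate]]) / n)
      expect_lt(abs(obs - exp_p[[gate]]), sd3 + 1e-12)
    }
  }
})

test_that("raising a genotype's mean never decreases its high-gate share", {
  reg <- fix_registry()
  d <- fix_designs("ELP2")[1:2, ]
  g <- gate_model()
  mus <- seq(2.5, 4.9, by = 0.4)
  high_frac <- vapply(mus, function(m) {
    fl <- assign_fluorescence(d, reg, seed = 1)
    fl$mu <- c(m, 3.0)
    s <- sort_cells(fl, g, uniform_composition(d), 4e4, seed = 3)
    kept <- s$count[s$genotype_key == fl$genotype_key[1]]
    high <- s$count[s$genotype_key == fl$genotype_key[1] &
                      as.character(s$gate) == "high"]
    (if (length(high) == 0) 0 else high) / max(sum(kept), 1)
  }, 0)
  # allow 3-sigma binomial wiggle at ~2e4 draws per point
  expect_true(all(diff(high_frac) > -0.02))
})

test_that("simulated reads are exact barcoded amplicons in the noise-free limit", {
  reads <- fix_reads("ELP2", errors = error_model(0, 0, 0), reads_per_pool = 15)
  d <- fix_designs("ELP2")
  bc <- fix_barcodes()
  fwd <- bc$sequence[bc$pool == "ELP2"]
  for (i in seq_len(nrow(reads))) {
    seq <- if (reads$strand[i] == "-") revcomp(reads$sequence[i]) else reads$sequence[i]
    rev_bc <- bc$sequence[bc$role == "rev" & bc$pool == reads$gate[i]]
    amp <- d$sequence[d$genotype_key == reads$genotype_key[i]]
    expect_identical(seq, paste0(fwd, amp, rev_bc))
  }
  expect_true(all(reads$quality == strrep("I", nchar(reads$sequence))))
})

test_that("truncated templates lose exactly the CDS minus one junction", {
  d <- fix_designs("ELP2")
  reads <- fix_reads("ELP2", errors = error_model(0, 0, 0, truncation_prob = 1),
                     reads_per_pool = 10)
  expect_true(all(reads$truncated))
  cds_len <- fix_registry()$length[fix_registry()$part_id == "ELP2"]
  full_len <- d$length[match(reads$genotype_key, d$genotype_key)] + 48
  expect_equal(nchar(reads$sequence), full_len - (cds_len - 4))
})

test_that("read simulation is byte-identical under a fixed seed", {
  r1 <- fix_reads("BLA", reads_per_pool = 10, seed = 5)
  r2 <- fix_reads("BLA", reads_per_pool = 10, seed = 5)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1, f1)
  write_fastq(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # and FASTQ IO round-trips
  back <- read_fastq(f1)
  expect_equal(back$sequence, r1$sequence)
  expect_equal(back$read_id, r1$read_id)
})

test_that("barcode sets respect the pairwise edit-distance floor", {
  bc <- fix_barcodes()
  expect_equal(nrow(bc), 7)
  expect_true(all(nchar(bc$sequence) == 24))
  seqs <- c(bc$sequence, revcomp(bc$sequence))
  for (i in seq_len(nrow(bc))) {
    others <- setdiff(seq_along(seqs), c(i, i + nrow(bc)))
    d <- vapply(seqs[others], function(b) as.integer(adist(bc$sequence[i], b)), 0L)
    expect_true(all(d >= 8))
  }
})
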