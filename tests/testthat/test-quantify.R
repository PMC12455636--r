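mk_calls <- function(keys, status = "full") {
  parts <- strsplit(keys, "__", fixed = TRUE)
  tibble::tibble(
    read_id = sprintf("r%05d", seq_along(keys)),
    call_status = status,
    promoter = vapply(parts, `[[`, "", 1),
    sp = vapply(parts, `[[`, "", 2),
    cds = vapply(parts, `[[`, "", 3),
    genotype_key = keys,
    n_hits = 5L
  )
}

test_that("genotype counting and fractions mirror the call table", {
  reg <- fix_registry()
  keys <- c(rep("pYTK010__MF__BLA", 868), rep("pYTK009__MF__BLA", 28),
            rep("pYTK015__STA1__BLA", 104))
  m <- count_genotypes(mk_calls(keys), reg, pool = c(orf = "BLA", gate = "high"))
  expect_equal(m$n_full_reads, 1000)
  expect_equal(sum(m$counts), 1000)
  expect_equal(m$fractions["pYTK010", "MF"], 0.868)
  expect_equal(dim(m$counts), c(20, 4))
  expect_equal(sum(m$fractions), 1, tolerance = 1e-9)

  # order invariance under read shuffling
  shuf <- mk_calls(sample(keys))
  m2 <- count_genotypes(shuf, reg, pool = "x")
  expect_equal(m2$counts, m$counts)

  # non-full calls are never counted
  mixed <- dplyr::bind_rows(mk_calls(keys),
                            mk_calls(rep("pYTK009__MF__BLA", 50), "partial"))
  expect_equal(sum(count_genotypes(mixed, reg)$counts), 1000)

  # empty pool: warning, all-zero matrix
  expect_warning(m0 <- count_genotypes(mk_calls(character(0)), reg), "no full")
  expect_equal(sum(m0$counts), 0)
  expect_equal(m0$n_full_reads, 0)

  # tidy/glance accessors
  td <- tidy(m)
  expect_equal(nrow(td), 80)
  expect_equal(sum(td$count), 1000)
  g <- glance(m)
  expect_equal(g$top_genotype, "pYTK010_MF")
  expect_equal(g$n_genotypes_observed, 3)
})

test_that("top-genotype ranking is fraction-descending with lexicographic ties", {
  reg <- fix_registry()
  keys <- c(rep("pYTK010__MF__BLA", 5), rep("pYTK009__STA1__BLA", 3),
            rep("pYTK011__SUC2__BLA", 2))
  m <- count_genotypes(mk_calls(keys), reg)
  top <- top_genotypes(m, 2)
  expect_equal(top$genotype, c("pYTK010_MF", "pYTK009_STA1"))
  # fewer nonzero cells than n
  expect_equal(nrow(top_genotypes(m, 10)), 3)
  # tie at 0.4: lexicographically smaller promoter first
  keys2 <- c(rep("pYTK012__MF__BLA", 4), rep("pYTK009__AMY__BLA", 4),
             rep("pYTK010__MF__BLA", 2))
  top2 <- top_genotypes(count_genotypes(mk_calls(keys2), reg), 2)
  expect_equal(top2$genotype, c("pYTK009_AMY", "pYTK012_MF"))
  # idempotent / stable
  expect_identical(top2, top_genotypes(count_genotypes(mk_calls(keys2), reg), 2))
})

test_that("gate profiles weight fractions into a 0-2 rank score", {
  reg <- fix_registry()
  lo <- count_genotypes(mk_calls(rep("pYTK020__SUC2__BLA", 10)), reg, "low")
  me <- count_genotypes(mk_calls(rep("pYTK014__STA1__BLA", 10)), reg, "medium")
  hi <- count_genotypes(mk_calls(rep("pYTK010__MF__BLA", 10)), reg, "high")
  p <- enrichment_across_gates(lo, me, hi)
  expect_equal(nrow(p), 3)
  expect_equal(p$score[p$genotype == "pYTK010_MF"], 2)
  expect_equal(p$score[p$genotype == "pYTK020_SUC2"], 0)
  expect_equal(p$score[p$genotype == "pYTK014_STA1"], 1)

  # depth invariance: replicating reads in one gate leaves scores unchanged
  hi2 <- count_genotypes(mk_calls(rep("pYTK010__MF__BLA", 500)), reg, "high")
  p2 <- enrichment_across_gates(lo, me, hi2)
  expect_equal(p2$score, p$score)

  # mismatched axes
  reg2 <- fix_registry()[-1, ]
  class(reg2) <- class(fix_registry())
  bad <- count_genotypes(mk_calls(rep("pYTK010__MF__BLA", 5)), reg2, "high")
  expect_error(enrichment_across_gates(lo, me, bad), "share row/column")
})

test_that("heatmap tables export and re-import intact", {
  reg <- fix_registry()
  keys <- c(rep("pYTK010__MF__BLA", 7), rep("pYTK028__SUC2__BLA", 3))
  m <- count_genotypes(mk_calls(keys), reg)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_heatmap_table(m, path)
  lines <- readLines(path)
  expect_equal(length(lines), 21)  # header + 20 promoters
  expect_equal(length(strsplit(lines[1], "\t")[[1]]), 5)
  back <- read_heatmap_table(path)
  expect_equal(back$fractions, m$fractions)

  # counts round-trip too
  export_heatmap_table(m, path, values = "count")
  backc <- read_heatmap_table(path, values = "count")
  expect_equal(backc$counts, m$counts, ignore_attr = TRUE)
  expect_equal(backc$n_full_reads, 10)

  # degenerate all-zero matrix
  suppressWarnings(m0 <- count_genotypes(mk_calls(character(0)), reg))
  export_heatmap_table(m0, path)
  expect_equal(sum(read_heatmap_table(path)$fractions), 0)
})

test_that("autoplot methods return ggplot objects", {
  reg <- fix_registry()
  m <- count_genotypes(mk_calls(rep("pYTK010__MF__BLA", 5)), reg, "high")
  expect_s3_class(autoplot(m), "ggplot")
  lo <- count_genotypes(mk_calls(rep("pYTK020__SUC2__BLA", 5)), reg, "low")
  me <- count_genotypes(mk_calls(rep("pYTK014__STA1__BLA", 5)), reg, "medium")
  p <- enrichment_across_gates(lo, me, m)
  expect_s3_class(autoplot(p), "ggplot")
})
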