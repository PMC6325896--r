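test_that("read_vcf encodes diploid GT fields as alt dosages", {
  path <- write_manual_vcf(c(
    vcf_header(c("s1", "s2", "s3", "s4")),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0/0\t0/1"
  ))
  gm <- read_vcf(path)
  expect_equal(unname(gm$calls[, 1]), c(0L, 1L, 2L, NA))
  expect_equal(unname(gm$calls[, 2]), c(1L, 2L, 0L, 1L))
  expect_equal(gm$individuals, c("s1", "s2", "s3", "s4"))
  expect_equal(gm$loci$pos, c(100L, 200L))
  expect_equal(gm$loci$ref, c("A", "C"))
})

test_that("multi-allelic records error in strict mode and can be dropped", {
  path <- write_manual_vcf(c(
    vcf_header(c("s1", "s2")),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2"
  ))
  expect_error(read_vcf(path), "chr1:200")
  gm <- read_vcf(path, multiallelic = "drop")
  expect_equal(nrow(gm$loci), 1L)
})

test_that("non-diploid GT fields are rejected", {
  path <- write_manual_vcf(c(
    vcf_header(c("s1", "s2")),
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0/1\t0/1"
  ))
  expect_error(read_vcf(path), "non-diploid")
})

test_that("VCF round-trip is the identity on calls, loci and missingness", {
  gm <- random_genotypes(5, 12, miss = 0.2, seed = 42)
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path, total_length = gm$total_length)
  expect_identical(unname(back$calls), unname(gm$calls))
  expect_equal(back$loci$chrom, gm$loci$chrom)
  expect_equal(back$loci$pos, gm$loci$pos)
  expect_equal(back$individuals, gm$individuals)
})

test_that("population map IO validates and round-trips", {
  pm <- tibble::tibble(individual = c("a", "b", "c"),
                       population = c("p1", "p1", "p2"),
                       group = c("G", "G", "G"))
  path <- tempfile(fileext = ".tsv")
  write_popmap(pm, path)
  back <- read_popmap(path)
  expect_equal(back, pm)

  dup <- tempfile()
  writeLines(c("a\tp1\tG", "a\tp2\tG"), dup)
  expect_error(read_popmap(dup), "more than once")

  twog <- tempfile()
  writeLines(c("a\tp1\tG1", "b\tp1\tG2"), twog)
  expect_error(read_popmap(twog), "more than one group")

  empty <- tempfile()
  writeLines(character(), empty)
  expect_error(read_popmap(empty), "empty")
})

test_that("joining a map that misses individuals names them", {
  gm <- random_genotypes(3, 4)
  pm <- tibble::tibble(individual = c("i1", "i2"), population = "p",
                       group = "G")
  expect_error(group_summary(gm, pm), "i3")
})

test_that("filter_loci keeps loci called in enough populations", {
  # 3 populations x 20 individuals; per-population call rates per locus:
  # 1.0, 0.6, 0.7, 0.65, 0.9 -> with -p 3 -r 0.66 only rates >= 0.66 pass
  # in every population: loci 1, 3, 5 (hand enumeration)
  rates <- c(1.0, 0.6, 0.7, 0.65, 0.9)
  calls <- matrix(1L, nrow = 60, ncol = 5)
  set.seed(9)
  for (p in 0:2) {
    for (l in seq_along(rates)) {
      rows <- p * 20 + seq_len(20)
      n_miss <- round(20 * (1 - rates[l]))
      calls[sample(rows, n_miss), l] <- NA_integer_
    }
  }
  rownames(calls) <- paste0("i", 1:60)
  gm <- genotypes(calls, tibble::tibble(chrom = "chr1",
                                        pos = as.integer(1:5 * 100),
                                        ref = "A", alt = "G"))
  pm <- tibble::tibble(individual = paste0("i", 1:60),
                       population = rep(c("p1", "p2", "p3"), each = 20),
                       group = rep(c("g1", "g2", "g3"), each = 20))
  kept <- filter_loci(gm, pm, min_populations = 3, min_fraction = 0.66)
  expect_equal(kept$loci$pos, c(100L, 300L, 500L))

  # locus in 2/3 pops at p=3 is removed
  calls2 <- calls
  calls2[1:20, 1] <- NA_integer_  # locus 1 fully missing in p1
  gm2 <- genotypes(calls2, gm$loci)
  kept2 <- filter_loci(gm2, pm, 3, 0.66)
  expect_false(100L %in% kept2$loci$pos)

  expect_error(filter_loci(gm, pm, 4, 0.5), "exceeds")
})

test_that("filter_loci is idempotent, monotone and has an identity limit", {
  gm <- random_genotypes(12, 30, miss = 0.3, seed = 7)
  pm <- even_popmap(gm, 3)
  pm$population <- pm$group  # three 4-individual populations
  f1 <- filter_loci(gm, pm, 3, 0.7)
  f2 <- filter_loci(f1, pm, 3, 0.7)
  expect_identical(f1$loci, f2$loci)
  expect_lte(nrow(f1$loci), nrow(gm$loci))
  # min_fraction -> 0, min_populations = 1: identity on loci with >= 1 call
  f0 <- filter_loci(gm, pm, 1, 1e-9)
  expect_equal(nrow(f0$loci), sum(colSums(!is.na(gm$calls)) >= 1))
  # grouping level is switchable
  fg <- filter_loci(gm, pm, 1, 0.5, by = "group")
  expect_s3_class(fg, "gbs_genotypes")
})
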