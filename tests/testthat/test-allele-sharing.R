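test_that("classify_site identifies the sharing states", {
  expect_equal(classify_site(1, 1, 0), "AB")
  expect_equal(classify_site(1, 0, 1), "AC")
  expect_equal(classify_site(0, 1, 1), "BC")
  expect_equal(classify_site(1, 0.5, 0), "unclassified")
  expect_equal(classify_site(1, 1, 1), "unclassified")  # trio-invariant
  expect_equal(classify_site(NA, 1, 0), "unclassified")
})

test_that("classify_site matches the enumeration oracle on all configurations", {
  vals <- c(0, 0.5, 1, NA)
  grid <- expand.grid(a = vals, b = vals, c = vals)
  got <- classify_site(grid$a, grid$b, grid$c)
  want <- vapply(seq_len(nrow(grid)),
                 function(i) oracle_classify(grid$a[i], grid$b[i], grid$c[i]),
                 character(1))
  expect_equal(got, want)
})

test_that("classify_site permutes consistently under group relabelling", {
  set.seed(4)
  f <- matrix(sample(c(0, 0.25, 0.5, 1), 300, replace = TRUE), ncol = 3)
  base <- classify_site(f[, 1], f[, 2], f[, 3])
  swapped <- classify_site(f[, 2], f[, 1], f[, 3])  # swap A and B
  remap <- c(AB = "AB", AC = "BC", BC = "AC", unclassified = "unclassified")
  expect_equal(swapped, unname(remap[base]))
})

test_that("sharing_table reproduces engineered state counts and proportions", {
  fx <- make_fixture("sharing-811")
  st <- sharing_table(fx$genotypes, fx$popmap, fx$expected$groups)
  expect_equal(st$totals$count, fx$expected$counts)
  expect_equal(st$totals$proportion, fx$expected$proportions)
  expect_equal(st$n_classified, 10L)
  expect_equal(st$n_input_snps, 10L)
  # per-chromosome counts sum to the totals
  sums <- colSums(st$by_chromosome[, -1])
  expect_equal(unname(sums), st$totals$count)
  expect_equal(sum(st$totals$count), st$n_classified)
  expect_equal(tidy(st), st$totals)
})

test_that("sharing_table handles no-fixed-difference input and missing-data rules", {
  gm <- random_genotypes(6, 12, seed = 3)
  gm$calls[] <- 1L  # everyone heterozygous: nothing fixed
  pm <- tibble::tibble(individual = gm$individuals,
                       population = rep(c("p1", "p2", "p3"), each = 2),
                       group = rep(c("A", "B", "C"), each = 2))
  st <- sharing_table(gm, pm, c("A", "B", "C"))
  expect_equal(st$n_classified, 0L)
  expect_equal(st$totals$proportion, c(0, 0, 0))

  # a group whose only call count falls below min_alleles is unclassified
  fx <- make_fixture("sharing-811")
  gm2 <- fx$genotypes
  gm2$calls[1:2, 1] <- NA_integer_  # group A uncalled at site 1
  st2 <- sharing_table(gm2, fx$popmap, fx$expected$groups)
  expect_equal(st2$n_classified, 9L)
  expect_error(sharing_table(gm2, fx$popmap, c("A", "B")), "exactly three")
  expect_error(sharing_table(gm2, fx$popmap, c("A", "B", "Z")), "absent")
})

test_that("relaxed fixation mode classifies near-fixed sites", {
  fx <- make_fixture("sharing-811")
  gm <- fx$genotypes
  gm$calls[1, 1] <- 1L  # group A now at frequency 0.75 at site 1
  strict <- sharing_table(gm, fx$popmap, fx$expected$groups)
  expect_equal(strict$n_classified, 9L)
  relaxed <- sharing_table(gm, fx$popmap, fx$expected$groups, delta = 0.3)
  expect_equal(relaxed$n_classified, 10L)
})
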