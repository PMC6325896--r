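single_pop_scenario <- function(N, n_diploid) {
  demographic_scenario(
    "single", populations = c(A = N),
    events = data.frame(time = numeric(0), type = character(0),
                        a = character(0), b = character(0)),
    samples = c(A = as.integer(n_diploid))
  )
}

test_that("scenario templates match their described topologies", {
  sc <- build_scenarios()
  expect_named(sc, c("I", "II", "III", "IV", "out_of_nk"))
  # III: 4 sampled populations + ancestor, splits only
  expect_equal(length(sc$III$populations), 5L)
  expect_equal(sum(sc$III$samples), 20L)
  expect_true(all(sc$III$events$type == "split"))
  expect_equal(sort(unique(sc$III$events$time)), c("t1", "t2", "t3"))
  # IV: exactly one admixture event with free rate r
  adm <- sc$IV$events[sc$IV$events$type == "admixture", ]
  expect_equal(nrow(adm), 1L)
  expect_equal(adm$rate, "r")
  expect_true("r" %in% scenario_parameters(sc$IV))
  expect_false("r" %in% scenario_parameters(sc$III))
  # two-deme split model
  expect_equal(length(sc$out_of_nk$populations), 2L)
  expect_equal(nrow(sc$out_of_nk$events), 1L)
  expect_equal(unname(sc$out_of_nk$samples), c(6L, 6L))
})

test_that("prior draws respect bounds, truncation and joint constraints", {
  ps <- default_priors()
  d <- sample_prior(ps, n = 10000, seed = 2)
  for (i in seq_len(nrow(ps$params))) {
    p <- ps$params[i, ]
    expect_gte(min(d[[p$parameter]]), p$min)
    expect_lte(max(d[[p$parameter]]), p$max)
  }
  expect_true(all(d$t3 > d$t2))
  expect_true(all(d$t3 > d$t1))
  expect_true(all(d$t2 >= d$t1))
  # deterministic given seed
  expect_identical(d, sample_prior(ps, n = 10000, seed = 2))
  # a constraint with ~zero mass errors out instead of spinning
  bad <- prior_set(ps$params, constraints = c("t1 > t2", "t2 > t1"))
  expect_error(sample_prior(bad, n = 10, seed = 1, max_rejections = 50),
               "consecutive")
})

test_that("single-population TMRCA matches the coalescent expectation", {
  N <- 1000
  n_hap <- 4
  sc <- single_pop_scenario(N, n_hap / 2)
  set.seed(10)
  out <- gbsabc:::simulate_counts(sc, list(), 10000, tmrca = TRUE)
  expected <- sum(4 * N / (2:n_hap * (2:n_hap - 1)))  # 3N for n = 4
  se <- sd(out$tmrca) / sqrt(length(out$tmrca))
  expect_lt(abs(mean(out$tmrca) - expected), 3 * se)
})

test_that("derived-allele counts follow the neutral 1/i spectrum", {
  # conditioning on one SNP per locus length-biases the raw spectrum
  # (P(size i) = E[L_i/L_tot], which overweights singletons); weighting each
  # locus by its total tree length recovers the neutral E[L_i] proportional
  # to 1/i, which is what the chi-square checks
  sc <- single_pop_scenario(10000, 5)
  for (seed in c(3, 17)) {
    set.seed(seed)
    out <- gbsabc:::simulate_counts(sc, list(), 8000, tmrca = TRUE)
    w <- out$tree_length / mean(out$tree_length)
    counts <- tapply(w, factor(out$counts[, 1], levels = 1:9), sum)
    counts[is.na(counts)] <- 0
    probs <- (1 / (1:9)) / sum(1 / (1:9))
    p <- suppressWarnings(chisq.test(counts, p = probs)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("a split at time ~0 leaves no population structure", {
  sc <- demographic_scenario(
    "flat", populations = c(A = 10000, B = 10000),
    events = data.frame(time = 1e-9, type = "split", a = "B", b = "A"),
    samples = c(A = 4L, B = 4L)
  )
  set.seed(8)
  out <- gbsabc:::simulate_counts(sc, list(), 4000)
  pA <- out$counts[, "A"] / 8
  pB <- out$counts[, "B"] / 8
  d <- nei_distance(pA, pB)
  # split halves of a single panmictic sample as the no-structure reference:
  # same per-half sample size (4 diploids = 8 alleles)
  sc1 <- single_pop_scenario(10000, 8)
  hap <- simulate_snps(sc1, list(), 4000, seed = 9)$genotypes$calls
  pA1 <- colSums(hap[1:4, ]) / 8
  pB1 <- colSums(hap[5:8, ]) / 8
  diff_split <- mean(abs(pA - pB))
  diff_pan <- mean(abs(pA1 - pB1))
  expect_lt(abs(diff_split - diff_pan), 0.02)
})

test_that("identical seeds give identical matrices, loci are exchangeable", {
  sc <- build_scenarios()$III
  draw <- list(N_NJPN = 8e5, N_TajimaTango = 6e5, N_Kyushu = 1.2e6,
               N_Honshu = 1.5e6, N_Ancestor = 4e5,
               t1 = 5e5, t2 = 1e6, t3 = 4.5e6)
  a <- simulate_snps(sc, draw, 300, seed = 42)
  b <- simulate_snps(sc, draw, 300, seed = 42)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$popmap, b$popmap)
  c <- simulate_snps(sc, draw, 300, seed = 43)
  expect_false(identical(a$genotypes$calls, c$genotypes$calls))
  # every locus polymorphic in the pooled sample
  ac <- colSums(a$genotypes$calls)
  expect_true(all(ac > 0 & ac < 2 * length(a$genotypes$individuals)))
})

test_that("scenario IV collapses to III as the admixture pulse vanishes", {
  draw3 <- list(N_NJPN = 4e5, N_TajimaTango = 9e5, N_Kyushu = 1.2e6,
                N_Honshu = 1.5e6, N_Ancestor = 5e5,
                t1 = 4e5, t2 = 1.2e6, t3 = 5e6)
  draw4 <- c(draw3, list(r = 0.999))
  sc <- build_scenarios()
  layout <- stat_layout(names(sc$III$samples))
  stats_for <- function(scenario, draw, seeds) {
    t(vapply(seeds, function(s) {
      sim <- simulate_snps(scenario, draw, 1000, seed = s)
      summary_stats(sim$genotypes, sim$popmap, layout)
    }, numeric(length(gbsabc:::stat_names(layout)))))
  }
  seeds <- 1:8
  s3 <- stats_for(sc$III, draw3, seeds)
  s4 <- stats_for(sc$IV, draw4, seeds + 100)
  # mean statistic vectors agree within Monte-Carlo error (4 SE of the diff)
  se <- sqrt(apply(s3, 2, var) / nrow(s3) + apply(s4, 2, var) / nrow(s4))
  diff <- abs(colMeans(s3) - colMeans(s4))
  expect_true(all(diff <= 4 * se + 1e-8))
})
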