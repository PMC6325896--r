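# small end-to-end runs; sizes chosen so each completes in seconds

test_that("the two-deme dating workflow produces a coherent scaled report", {
  d <- generate_dataset(study_template("local", n_loci = 200L), seed = 21)
  gm <- d$genotypes
  gm$total_length <- 50000L
  rep <- run_out_of_nk(gm, d$popmap, n_sims = 800L, tolerance = 0.02,
                       seed = 31)
  expect_s3_class(rep$posterior, "abc_posterior")
  expect_true(all(c("N_SSaga", "N_NSaga", "t") %in%
                    rep$posterior$summary$parameter))
  # provenance: the Ne used for scaling is reported with its pi inputs
  expect_equal(nrow(rep$ne_inputs), 2L)
  expect_equal(rep$mean_ne, mean(rep$ne_inputs$Ne))
  expect_equal(unique(rep$ne_inputs$mu), 1e-9)
  # credible bounds ordered
  expect_true(all(rep$posterior$summary$q2.5 <= rep$posterior$summary$q97.5))
  expect_true(all(rep$posterior_scaled$q2.5 <= rep$posterior_scaled$q97.5))
  expect_true(nzchar(rep$config$hash))
})

test_that("seeded workflows are end-to-end deterministic", {
  d <- generate_dataset(study_template("local", n_loci = 120L), seed = 22)
  gm <- d$genotypes
  a <- run_out_of_nk(gm, d$popmap, n_sims = 400L, tolerance = 0.05,
                     mean_ne = 1275000, seed = 7)
  b <- run_out_of_nk(gm, d$popmap, n_sims = 400L, tolerance = 0.05,
                     mean_ne = 1275000, seed = 7)
  expect_identical(a$posterior$summary, b$posterior$summary)
  expect_identical(a$posterior_scaled, b$posterior_scaled)
  expect_identical(a$config$hash, b$config$hash)
})

test_that("the scenario-comparison workflow reports both estimators and a posterior", {
  d <- generate_dataset(study_template("hz2", n_loci = 150L), seed = 23)
  rep <- suppressWarnings(run_tajima_tango(
    d$genotypes, d$popmap, n_per_scenario = 600L, tolerance = 0.05,
    n_closest = 50L, seed = 41
  ))
  expect_setequal(unique(rep$model_choice$method), c("direct", "logistic"))
  expect_equal(sort(unique(rep$model_choice$scenario)),
               c("I", "II", "III", "IV"))
  probs <- rep$model_choice
  expect_true(all(probs$probability >= 0 & probs$probability <= 1))
  by_method <- tapply(probs$probability, probs$method, sum)
  expect_equal(unname(by_method["direct"]), 1, tolerance = 1e-9)
  expect_gte(length(rep$posteriors), 1L)
  for (p in rep$posteriors) expect_s3_class(p, "abc_posterior")
  # the observed vector follows the declared layout
  expect_equal(length(rep$observed), 2 * 4 + 2 * 6 + 4 * 1)
})

test_that("accuracy metrics are finite, non-negative and zero for a perfect estimator", {
  rt <- build_reference_table(build_scenarios()$out_of_nk, out_of_nk_priors(),
                              n_per_scenario = 400L, n_loci = 100L, seed = 3)
  acc <- accuracy_metrics(rt, n_test = 10L, tolerance = 0.05, seed = 4)
  expect_setequal(acc$parameter, c("N_SSaga", "N_NSaga", "t"))
  expect_true(all(is.finite(acc$RRMISE) & acc$RRMISE >= 0))
  expect_true(all(is.finite(acc$RMeanAD) & acc$RMeanAD >= 0))
  expect_true(all(is.finite(acc$RRMSE) & acc$RRMSE >= 0))
  # posterior-based test draws run through the same machinery
  d <- generate_dataset(study_template("local", n_loci = 100L), seed = 6)
  obs <- summary_stats(d$genotypes, d$popmap,
                       stat_layout(c("S.Saga", "N.Saga")))
  post <- regression_adjust(abc_reject(rt, obs, 0.05))
  accp <- accuracy_metrics(rt, n_test = 10L, tolerance = 0.05,
                           from = "posterior", posterior = post, seed = 5)
  expect_equal(accp$from[1], "posterior")
  expect_true(all(is.finite(accp$RRMSE)))
})
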