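# hand-built reference table for the conjugate-Gaussian toy:
# theta ~ N(0,1) (wide truncation), one statistic s = theta + N(0, noise_sd)
gaussian_reftable <- function(n, noise_sd = 0.1, seed = 1,
                              informative = TRUE) {
  set.seed(seed)
  theta <- rnorm(n)
  theta <- pmin(pmax(theta, -6), 6)
  s <- if (informative) theta + rnorm(n, 0, noise_sd) else rnorm(n)
  priors <- prior_set(tibble::tibble(
    parameter = "theta", dist = "norm", min = -6, max = 6, mean = 0, sd = 1
  ))
  structure(
    list(
      records = tibble::tibble(scenario = "toy", theta = theta, s = s),
      stat_names = "s", param_names = "theta",
      stat_sd = c(s = sd(s)),
      layout = NULL, priors = list(toy = priors), scenarios = NULL,
      n_loci = NA_integer_
    ),
    class = "abc_reftable"
  )
}

test_that("rejection keeps the prescribed closest fraction", {
  rt <- gaussian_reftable(1000)
  rej <- abc_reject(rt, c(s = 1), tolerance = 0.01)
  expect_equal(nrow(rej$accepted), 10L)
  # observed equal to a record's statistics ranks that record first
  obs <- c(s = rt$records$s[123])
  rej2 <- abc_reject(rt, obs, tolerance = 0.05)
  expect_equal(rej2$accepted$distance[1], 0)
  expect_equal(rej2$accepted$theta[1], rt$records$theta[123])
  expect_error(abc_reject(rt, c(s = 1), tolerance = 0), "tolerance")
})

test_that("rejection + regression recovers the conjugate-Gaussian posterior", {
  rt <- gaussian_reftable(20000, noise_sd = 0.1, seed = 2)
  rej <- abc_reject(rt, c(s = 1), tolerance = 0.01)
  post <- regression_adjust(rej)
  # analytic posterior: mean s_obs/(1 + noise^2), sd ~ 0.0995
  analytic_mean <- 1 / (1 + 0.1^2)
  analytic_sd <- sqrt(0.1^2 / (1 + 0.1^2))
  mc_err <- analytic_sd / sqrt(post$n_accepted) * 5
  expect_lt(abs(post$summary$mean - analytic_mean), max(mc_err, 0.04))
  expect_lt(post$summary$q2.5, analytic_mean)
  expect_gt(post$summary$q97.5, analytic_mean)
  expect_true(post$adjusted)
  expect_s3_class(tidy(post), "tbl_df")
  expect_equal(glance(post)$n_accepted, post$n_accepted)
})

test_that("regression adjustment lowers RMSE versus plain rejection", {
  rt <- gaussian_reftable(5000, noise_sd = 0.1, seed = 3)
  set.seed(99)
  errs <- t(vapply(1:50, function(i) {
    truth <- rnorm(1)
    obs <- c(s = truth + rnorm(1, 0, 0.1))
    rej <- abc_reject(rt, obs, tolerance = 0.02)
    post <- regression_adjust(rej)
    est_adj <- post$summary$mean
    est_rej <- mean(rej$accepted$theta)
    c(adj = est_adj - truth, rej = est_rej - truth)
  }, c(adj = 0, rej = 0)))
  rmse <- sqrt(colMeans(errs^2))
  expect_lte(rmse["adj"], rmse["rej"])
})

test_that("uninformative statistics leave the rejection sample unchanged", {
  rt <- gaussian_reftable(10000, seed = 4, informative = FALSE)
  rej <- abc_reject(rt, c(s = 0.5), tolerance = 0.05)
  post <- regression_adjust(rej)
  rej_mean <- mean(rej$accepted$theta)
  se <- sd(rej$accepted$theta) / sqrt(nrow(rej$accepted))
  expect_lt(abs(post$summary$mean - rej_mean), 4 * se)
})

test_that("parameter scaling is exact and invertible", {
  rt <- gaussian_reftable(2000, seed = 5)
  post <- regression_adjust(abc_reject(rt, c(s = 0), tolerance = 0.05))
  up <- scale_parameters(post, 1275000, "to_natural")
  expect_equal(up$draws$theta, post$draws$theta * 1275000)
  expect_equal(up$summary$mean, post$summary$mean * 1275000)
  back <- scale_parameters(up, 1275000, "to_scaled")
  expect_equal(back$draws$theta, post$draws$theta, tolerance = 1e-12)
  # identity at mean_ne = 1
  same <- scale_parameters(post, 1)
  expect_equal(same$summary, post$summary)
  expect_error(scale_parameters(post, -1), "positive")
})
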