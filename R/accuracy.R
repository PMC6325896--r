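#' Accuracy metrics for ABC posterior estimation
#'
#' Simulates `n_test` pseudo-observed datasets with known parameters drawn
#' from the scenario's prior (or from a supplied posterior), runs the full
#' rejection + regression estimation against the given reference table for
#' each, and reports per parameter, over test datasets `j` with posterior
#' draws `k` (weights `w_k`):
#'
#' * RRMISE: \eqn{\sqrt{\mathrm{mean}_j\, \sum_k w_k ((\theta^*_{jk}-\theta_j)/\theta_j)^2}}
#' * RMeanAD: \eqn{\mathrm{mean}_j\, \sum_k w_k |\theta^*_{jk}-\theta_j|/\theta_j}
#' * RRMSE: \eqn{\sqrt{\mathrm{mean}_j ((\hat\theta_j-\theta_j)/\theta_j)^2}}
#'   with \eqn{\hat\theta_j} the weighted posterior mean.
#'
#' Test datasets with a true parameter value of exactly 0 are excluded from
#' that parameter's relative metrics with a warning.
#'
#' @param rt a single-scenario [build_reference_table()] result.
#' @param n_test number of pseudo-observed datasets (>= 10).
#' @param tolerance rejection tolerance for each estimation (default 0.01).
#' @param from draw the true test parameters from the `"prior"` (default)
#'   or from a `"posterior"` supplied via `posterior`.
#' @param posterior an [regression_adjust()] result supplying test-parameter
#'   draws when `from = "posterior"`.
#' @param seed optional integer seed.
#' @return A tibble of class `abc_accuracy`: columns `parameter`, `RRMISE`,
#'   `RMeanAD`, `RRMSE`, `from`, `n_test`.
#' @export
accuracy_metrics <- function(rt, n_test = 100L, tolerance = 0.01,
                             from = c("prior", "posterior"), posterior = NULL,
                             seed = NULL) {
  from <- match.arg(from)
  stopifnot(inherits(rt, "abc_reftable"), n_test >= 10L)
  scen_name <- unique(rt$records$scenario)
  if (length(scen_name) != 1L) {
    stop("accuracy metrics need a single-scenario reference table",
         call. = FALSE)
  }
  sc <- rt$scenarios[[scen_name]]
  run <- function() {
    truths <- if (from == "prior") {
      sample_prior(rt$priors[[scen_name]], n = n_test)
    } else {
      stopifnot(inherits(posterior, "abc_posterior"))
      idx <- sample.int(nrow(posterior$draws), n_test, replace = TRUE,
                        prob = posterior$draws$weight)
      posterior$draws[idx, posterior$summary$parameter, drop = FALSE]
    }
    params <- intersect(names(truths), scenario_parameters(sc))
    per_test <- vector("list", n_test)
    for (j in seq_len(n_test)) {
      sim <- simulate_counts(sc, truths[j, ], rt$n_loci)
      an <- matrix(sim$an, nrow = rt$n_loci, ncol = length(sim$an),
                   byrow = TRUE, dimnames = list(NULL, names(sim$an)))
      obs <- stats_from_counts(sim$counts, an, rt$layout)
      post <- regression_adjust(abc_reject(rt, obs, tolerance))
      per_test[[j]] <- purrr::map_dfr(params, function(p) {
        theta <- truths[[p]][j]
        x <- post$draws[[p]]
        w <- post$draws$weight
        tibble::tibble(
          parameter = p, truth = theta,
          mise = sum(w * ((x - theta) / theta)^2),
          mad = sum(w * abs(x - theta) / abs(theta)),
          sqerr = ((sum(w * x) - theta) / theta)^2
        )
      })
    }
    all <- dplyr::bind_rows(per_test)
    if (any(all$truth == 0)) {
      warning(sum(all$truth == 0),
              " test value(s) of exactly 0 excluded from relative metrics",
              call. = FALSE)
      all <- all[all$truth != 0, , drop = FALSE]
    }
    out <- all |>
      dplyr::group_by(.data$parameter) |>
      dplyr::summarise(
        RRMISE = sqrt(mean(.data$mise)),
        RMeanAD = mean(.data$mad),
        RRMSE = sqrt(mean(.data$sqerr)),
        .groups = "drop"
      )
    out$from <- from
    out$n_test <- n_test
    class(out) <- c("abc_accuracy", class(out))
    out
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}
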