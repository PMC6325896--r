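#' Weighted local-linear regression adjustment of an ABC rejection sample
#'
#' Implements the classic post-rejection correction: accepted records get
#' Epanechnikov weights \eqn{w_i = 1 - (d_i/d_{max})^2} (bandwidth = the
#' largest accepted distance); each parameter is mapped to an unbounded
#' scale by a logit on its prior bounds, regressed on the standardized
#' summary statistics by weighted least squares, and replaced by its fitted
#' value at the observed vector plus its residual; the back-transform clamps
#' the adjusted values to the prior support. Point estimates (weighted
#' mean/median/mode) and central 95% credible intervals are reported per
#' parameter.
#'
#' @param rej an [abc_reject()] result.
#' @param scenario which scenario's records to adjust when the table mixed
#'   several (default: the only scenario present; an error if ambiguous).
#' @return A list of class `abc_posterior`: `draws` (tibble of accepted
#'   parameter values, columns `<param>` adjusted and `<param>_rej`
#'   unadjusted, plus `weight` and `distance`), `summary` (tibble:
#'   `parameter`, `mean`, `median`, `mode`, `q2.5`, `q97.5`), `scenario`,
#'   `n_accepted`, `adjusted` (FALSE when the design was singular and the
#'   plain rejection sample was returned).
#' @export
regression_adjust <- function(rej, scenario = NULL) {
  stopifnot(inherits(rej, "abc_rejection"))
  acc <- rej$accepted
  scen_present <- unique(acc$scenario)
  if (is.null(scenario)) {
    if (length(scen_present) > 1L) {
      stop("accepted set mixes scenarios (", paste(scen_present, collapse = ", "),
           "); pass `scenario =` to pick one", call. = FALSE)
    }
    scenario <- scen_present
  }
  acc <- acc[acc$scenario == scenario, , drop = FALSE]
  params <- rej$param_names[colSums(!is.na(acc[rej$param_names])) > 0]
  priors <- rej$priors[[scenario]]$params
  n <- nrow(acc)
  if (n < length(rej$stat_names) + 2L) {
    stop("need at least dim(stats) + 2 = ", length(rej$stat_names) + 2L,
         " accepted records, got ", n, call. = FALSE)
  }
  dmax <- max(acc$distance)
  w <- if (dmax > 0) 1 - (acc$distance / dmax)^2 else rep(1, n)
  w[w <= 0] <- min(w[w > 0], 1) * 1e-6  # the farthest record keeps a token weight
  rtlike <- list(stat_sd = rej$stat_sd)
  S <- standardize_stats(rtlike, acc[rej$stat_names])
  o <- standardize_stats(rtlike, rej$observed)
  X <- cbind(1, sweep(S, 2L, o, "-"))
  adjusted <- TRUE
  draws <- tibble::tibble(.rows = n)
  for (p in params) {
    pr <- priors[priors$parameter == p, ]
    y <- bounded_logit(acc[[p]], pr$min, pr$max)
    fit <- tryCatch(stats::lm.wfit(x = X, y = y, w = w), error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients[1])) {
      warning("singular regression design; returning unadjusted sample for '",
              p, "'", call. = FALSE)
      adj <- acc[[p]]
      adjusted <- FALSE
    } else {
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0  # collinear statistics contribute nothing
      resid <- y - as.vector(X %*% coefs)
      adj <- bounded_expit(coefs[1] + resid, pr$min, pr$max)
    }
    draws[[p]] <- adj
    draws[[paste0(p, "_rej")]] <- acc[[p]]
  }
  draws$weight <- w / sum(w)
  draws$distance <- acc$distance
  summary <- purrr::map_dfr(params, function(p) {
    x <- draws[[p]]
    tibble::tibble(
      parameter = p,
      mean = sum(draws$weight * x),
      median = weighted_quantile(x, draws$weight, 0.5),
      mode = weighted_mode(x, draws$weight),
      q2.5 = weighted_quantile(x, draws$weight, 0.025),
      q97.5 = weighted_quantile(x, draws$weight, 0.975)
    )
  })
  structure(list(draws = draws, summary = summary, scenario = scenario,
                 n_accepted = n, adjusted = adjusted, priors = priors,
                 observed = rej$observed, tolerance = rej$tolerance),
            class = "abc_posterior")
}

# logit mapped to [lo, hi]; values squeezed off the boundary so the
# transform stays finite
bounded_logit <- function(x, lo, hi) {
  u <- (x - lo) / (hi - lo)
  eps <- 1e-9
  u <- pmin(pmax(u, eps), 1 - eps)
  log(u / (1 - u))
}

bounded_expit <- function(z, lo, hi) lo + (hi - lo) / (1 + exp(-z))

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

weighted_mode <- function(x, w) {
  if (length(unique(x)) == 1L) return(x[1])
  # weighted bandwidth selection is not defined; nrd0 on the raw sample is fine
  d <- suppressWarnings(stats::density(x, weights = w / sum(w)))
  d$x[which.max(d$y)]
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("<abc_posterior> scenario ", x$scenario, ", ", x$n_accepted,
      " accepted draws",
      if (!x$adjusted) " (regression adjustment skipped: singular design)",
      "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname regression_adjust
#' @param x an `abc_posterior`.
#' @param ... unused.
#' @export
tidy.abc_posterior <- function(x, ...) x$summary

#' @rdname regression_adjust
#' @export
glance.abc_posterior <- function(x, ...) {
  tibble::tibble(scenario = x$scenario, n_accepted = x$n_accepted,
                 tolerance = x$tolerance, adjusted = x$adjusted)
}

#' Convert posterior parameters between coalescent-scaled and natural units
#'
#' Multiplies (direction `"to_natural"`) or divides (`"to_scaled"`) every
#' size and time parameter by a reference mean effective population size —
#' the device used to report a scale-free SNP-mode posterior in years /
#' individuals. Proportion-type parameters (prior support inside \[0, 1\],
#' e.g. an admixture rate) are left untouched. The two directions are exact
#' inverses.
#'
#' @param post an [regression_adjust()] result.
#' @param mean_ne reference diploid effective size (> 0), e.g. from
#'   [ne_from_pi()] on the observed data.
#' @param direction `"to_natural"` or `"to_scaled"`.
#' @return An `abc_posterior` with draws and summary rescaled.
#' @export
scale_parameters <- function(post, mean_ne,
                             direction = c("to_natural", "to_scaled")) {
  direction <- match.arg(direction)
  stopifnot(inherits(post, "abc_posterior"))
  if (!is.numeric(mean_ne) || mean_ne <= 0) {
    stop("mean_ne must be a positive number", call. = FALSE)
  }
  fac <- if (direction == "to_natural") mean_ne else 1 / mean_ne
  params <- post$summary$parameter
  pr <- post$priors
  # a parameter whose prior support sits inside [0,1] is a proportion
  rates <- pr$parameter[pr$min >= 0 & pr$max <= 1]
  scalable <- setdiff(params, rates)
  for (p in scalable) {
    post$draws[[p]] <- post$draws[[p]] * fac
    rj <- paste0(p, "_rej")
    if (rj %in% names(post$draws)) post$draws[[rj]] <- post$draws[[rj]] * fac
  }
  num_cols <- c("mean", "median", "mode", "q2.5", "q97.5")
  idx <- post$summary$parameter %in% scalable
  post$summary[idx, num_cols] <- post$summary[idx, num_cols] * fac
  post
}
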