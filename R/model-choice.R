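#' Scenario choice by direct estimation
#'
#' The direct (rejection) estimator of scenario posterior probabilities:
#' among the `n_closest` reference-table records nearest to the observed
#' statistics (standardized Euclidean distance), each scenario's probability
#' is its share, with a normal-approximation binomial 95% CI on that share.
#'
#' @param rt an [build_reference_table()] result containing >= 2 scenarios.
#' @param observed named statistic vector from [summary_stats()].
#' @param n_closest number of nearest records used (default 500).
#' @return A tibble of class `abc_model_choice`: columns `scenario`,
#'   `probability`, `conf.low`, `conf.high`, `method`, `n_used`.
#' @export
select_model_direct <- function(rt, observed, n_closest = 500L) {
  stopifnot(inherits(rt, "abc_reftable"))
  scen <- unique(rt$records$scenario)
  if (length(scen) < 2L) stop("need >= 2 scenarios in the table", call. = FALSE)
  if (n_closest > nrow(rt$records)) {
    stop("n_closest exceeds the table size (", nrow(rt$records), ")",
         call. = FALSE)
  }
  S <- standardize_stats(rt, rt$records[rt$stat_names])
  o <- standardize_stats(rt, observed[rt$stat_names])
  d <- sqrt(rowSums(sweep(S, 2L, o, "-")^2))
  nearest <- rt$records$scenario[order(d)[seq_len(n_closest)]]
  out <- purrr::map_dfr(scen, function(s) {
    p <- mean(nearest == s)
    half <- 1.96 * sqrt(p * (1 - p) / n_closest)
    tibble::tibble(scenario = s, probability = p,
                   conf.low = max(0, p - half), conf.high = min(1, p + half))
  })
  out$method <- "direct"
  out$n_used <- n_closest
  class(out) <- c("abc_model_choice", class(out))
  out
}

#' Scenario choice by multinomial logistic regression
#'
#' Fits a weighted multinomial logistic regression of the scenario label on
#' the standardized summary statistics over the records accepted at
#' `tolerance` (Epanechnikov weights on distance), and evaluates it at the
#' observed vector. 95% CIs come from the fit's coefficient covariance by
#' the delta method. A fit that fails to converge or separates perfectly is
#' refitted with a small ridge penalty, with a warning.
#'
#' @inheritParams select_model_direct
#' @param tolerance accepted fraction of the table (default 0.01).
#' @return A tibble of class `abc_model_choice` (same columns as
#'   [select_model_direct()]).
#' @export
select_model_logistic <- function(rt, observed, tolerance = 0.01) {
  stopifnot(inherits(rt, "abc_reftable"))
  scen <- unique(rt$records$scenario)
  if (length(scen) < 2L) stop("need >= 2 scenarios in the table", call. = FALSE)
  rej <- abc_reject(rt, observed, tolerance)
  acc <- rej$accepted
  present <- unique(acc$scenario)
  if (length(present) < 2L) {
    warning("all accepted records come from scenario ", present,
            "; probabilities are degenerate", call. = FALSE)
    out <- tibble::tibble(
      scenario = scen, probability = as.numeric(scen == present),
      conf.low = as.numeric(scen == present),
      conf.high = as.numeric(scen == present)
    )
    out$method <- "logistic"
    out$n_used <- nrow(acc)
    class(out) <- c("abc_model_choice", class(out))
    return(out)
  }
  rtlike <- list(stat_sd = rej$stat_sd)
  S <- standardize_stats(rtlike, acc[rej$stat_names])
  o <- standardize_stats(rtlike, rej$observed)
  colnames(S) <- paste0("s", seq_len(ncol(S)))  # syntactic names for the fit
  names(o) <- colnames(S)
  dmax <- max(acc$distance)
  w <- if (dmax > 0) 1 - (acc$distance / dmax)^2 else rep(1, nrow(acc))
  w[w <= 0] <- min(w[w > 0]) * 1e-6
  dat <- data.frame(.scenario = factor(acc$scenario, levels = scen), S)
  fit_multinom <- function(decay) {
    suppressWarnings(nnet::multinom(
      .scenario ~ ., data = dat, weights = w, decay = decay,
      Hess = TRUE, trace = FALSE, maxit = 500
    ))
  }
  m <- fit_multinom(0)
  V <- tryCatch(stats::vcov(m), error = function(e) NULL)
  if (is.null(V) || anyNA(V) || !m$convergence %in% 0L ||
      any(!is.finite(V)) || any(diag(V) > 1e8)) {
    warning("logistic model-choice fit unstable (separation?); ",
            "refitting with a small ridge penalty", call. = FALSE)
    m <- fit_multinom(1e-3)
    V <- tryCatch(stats::vcov(m), error = function(e) NULL)
  }
  newdat <- as.data.frame(as.list(o), check.names = FALSE)
  probs <- as.numeric(stats::predict(m, newdata = newdat, type = "probs"))
  if (length(probs) == 1L) probs <- c(1 - probs, probs)  # K = 2 case
  names(probs) <- levels(dat$.scenario)
  se <- rep(NA_real_, length(probs))
  if (!is.null(V) && all(is.finite(V))) {
    wts_vec <- as.vector(t(stats::coef(m)))
    if (is.null(dim(stats::coef(m)))) wts_vec <- as.numeric(stats::coef(m))
    xo <- c(1, as.numeric(o))
    K <- length(probs)
    pred_from_coef <- function(beta) {
      B <- matrix(beta, nrow = K - 1L, byrow = TRUE)
      eta <- c(0, as.vector(B %*% xo))
      exp(eta) / sum(exp(eta))
    }
    J <- numeric_jacobian(pred_from_coef, wts_vec)
    se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
  }
  out <- tibble::tibble(
    scenario = names(probs), probability = unname(probs),
    conf.low = pmax(0, unname(probs) - 1.96 * se),
    conf.high = pmin(1, unname(probs) + 1.96 * se)
  )
  out$method <- "logistic"
  out$n_used <- nrow(acc)
  class(out) <- c("abc_model_choice", class(out))
  out
}

numeric_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (i in seq_along(x)) {
    h <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    J[, i] <- (f(xp) - f0) / h
  }
  J
}
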