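#' Define a demographic scenario
#'
#' A scenario is a set of constant-size populations joined, looking backward
#' in time, by split events (all lineages of `a` move into `b` at `time`)
#' and admixture pulses (each lineage of `a` moves to `b` with probability
#' `rate`, else to `c`; `c = a` means "stay"). Population sizes, event times
#' and admixture rates may be given as numbers or as names of parameters to
#' be resolved against a parameter draw at simulation time. Times are in
#' generations.
#'
#' @param name scenario identifier.
#' @param populations named character/numeric vector: population name ->
#'   diploid effective size (number or parameter name).
#' @param events data frame with columns `time`, `type`
#'   (`"split"`/`"admixture"`), `a`, `b`, `c` (NA for splits), `rate`
#'   (NA for splits); `time` and `rate` may be parameter names. Ties in
#'   `time` are applied in row order.
#' @param samples named integer vector: diploids sampled per population
#'   (populations omitted are unsampled).
#' @return A list of class `demographic_scenario`.
#' @export
demographic_scenario <- function(name, populations, events, samples) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("time", "type", "a", "b") %in% names(events)))
  if (!"c" %in% names(events)) events$c <- NA_character_
  if (!"rate" %in% names(events)) events$rate <- NA
  stopifnot(all(events$type %in% c("split", "admixture")),
            all(events$a %in% names(populations)),
            all(events$b %in% names(populations)),
            all(names(samples) %in% names(populations)))
  structure(list(name = name, populations = populations, events = events,
                 samples = samples),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("<demographic_scenario> ", x$name, ": ", length(x$populations),
      " populations, ", nrow(x$events), " event(s), ",
      sum(x$samples), " diploids sampled\n", sep = "")
  invisible(x)
}

#' Parameters referenced by a scenario
#' @param sc a `demographic_scenario`.
#' @return Character vector of parameter names.
#' @export
scenario_parameters <- function(sc) {
  vals <- c(unname(sc$populations), sc$events$time, sc$events$rate)
  vals <- vals[!is.na(vals)]
  unique(vals[is.na(suppressWarnings(as.numeric(vals)))])
}

#' The study's divergence/admixture scenario templates
#'
#' Returns the four competing histories for the Tajima-Tango boundary group
#' plus the two-deme "out of northern Kyushu" split model, parameterised
#' with the names used by [default_priors()] / [out_of_nk_priors()]. In all
#' four Tajima-Tango scenarios the N.JPN-side and S.JPN-side stems diverge
#' from the ancestor at t3 and Honshu diverges from Kyushu at t2:
#'
#' * I  — Tajima-Tango diverges from N.JPN at t1.
#' * II — Tajima-Tango is created at t1 by admixture between N.JPN
#'   (fraction `r`) and Honshu (fraction `1-r`).
#' * III — N.JPN diverges from Tajima-Tango at t1 (Tajima-Tango is the
#'   stem lineage).
#' * IV — as III, but at t1 the Tajima-Tango stem also receives the Honshu
#'   pulse: each Tajima-Tango lineage stays with probability `r` and traces
#'   to Honshu with probability `1-r` (applied before the N.JPN merge at
#'   the same time, so sampled N.JPN is unaffected by the pulse). With
#'   `r` near 1, IV collapses to III, as II collapses to I.
#' * out_of_nk — N.Saga diverges from S.Saga at time t.
#'
#' Default samples: 5 diploids per boundary group (one per constituent
#' population); 6 diploids per Saga deme.
#'
#' @return Named list of `demographic_scenario` objects
#'   (`I`, `II`, `III`, `IV`, `out_of_nk`).
#' @export
build_scenarios <- function() {
  pops4 <- c("N.JPN" = "N_NJPN", "Tajima-Tango" = "N_TajimaTango",
             "Kyushu" = "N_Kyushu", "Honshu" = "N_Honshu",
             "Ancestor" = "N_Ancestor")
  samp4 <- c("N.JPN" = 5L, "Tajima-Tango" = 5L, "Kyushu" = 5L, "Honshu" = 5L)
  ev <- function(...) tibble::tribble(...)
  list(
    I = demographic_scenario(
      "I", pops4, samples = samp4,
      events = ev(
        ~time, ~type, ~a, ~b, ~c, ~rate,
        "t1", "split", "Tajima-Tango", "N.JPN", NA, NA,
        "t2", "split", "Honshu", "Kyushu", NA, NA,
        "t3", "split", "N.JPN", "Ancestor", NA, NA,
        "t3", "split", "Kyushu", "Ancestor", NA, NA
      )
    ),
    II = demographic_scenario(
      "II", pops4, samples = samp4,
      events = ev(
        ~time, ~type, ~a, ~b, ~c, ~rate,
        "t1", "admixture", "Tajima-Tango", "N.JPN", "Honshu", "r",
        "t2", "split", "Honshu", "Kyushu", NA, NA,
        "t3", "split", "N.JPN", "Ancestor", NA, NA,
        "t3", "split", "Kyushu", "Ancestor", NA, NA
      )
    ),
    III = demographic_scenario(
      "III", pops4, samples = samp4,
      events = ev(
        ~time, ~type, ~a, ~b, ~c, ~rate,
        "t1", "split", "N.JPN", "Tajima-Tango", NA, NA,
        "t2", "split", "Honshu", "Kyushu", NA, NA,
        "t3", "split", "Tajima-Tango", "Ancestor", NA, NA,
        "t3", "split", "Kyushu", "Ancestor", NA, NA
      )
    ),
    IV = demographic_scenario(
      "IV", pops4, samples = samp4,
      events = ev(
        ~time, ~type, ~a, ~b, ~c, ~rate,
        "t1", "admixture", "Tajima-Tango", "Tajima-Tango", "Honshu", "r",
        "t1", "split", "N.JPN", "Tajima-Tango", NA, NA,
        "t2", "split", "Honshu", "Kyushu", NA, NA,
        "t3", "split", "Tajima-Tango", "Ancestor", NA, NA,
        "t3", "split", "Kyushu", "Ancestor", NA, NA
      )
    ),
    out_of_nk = demographic_scenario(
      "out_of_nk",
      populations = c("S.Saga" = "N_SSaga", "N.Saga" = "N_NSaga"),
      samples = c("S.Saga" = 6L, "N.Saga" = 6L),
      events = ev(
        ~time, ~type, ~a, ~b, ~c, ~rate,
        "t", "split", "N.Saga", "S.Saga", NA, NA
      )
    )
  )
}

#' Prior distributions for the demographic parameters
#'
#' `default_priors()` returns the priors shared by the four Tajima-Tango
#' scenarios: truncated normals on the four present-day diploid sizes
#' (e.g. N.JPN: Normal(450,000; 500,000) on \[10,000, 3,000,000\]), a
#' Uniform(10,000; 30,000,000) ancestor size, Uniform(10; 4,000,000) times
#' t1 and t2, Normal(4,000,000; 5,000,000) on \[1,000,000, 30,000,000\] for
#' the deep split t3, Uniform(0.001, 0.999) admixture rate, and the joint
#' constraints t3 > t2, t3 > t1 and t2 >= t1. `out_of_nk_priors()` returns
#' the two-deme model's priors (Saga sizes, split time
#' Uniform(1,000; 4,000,000)).
#'
#' @return A `prior_set`: list with a `params` tibble (columns `parameter`,
#'   `dist`, `min`, `max`, `mean`, `sd`) and a `constraints` character
#'   vector of inequalities over parameter names.
#' @export
default_priors <- function() {
  params <- tibble::tribble(
    ~parameter, ~dist, ~min, ~max, ~mean, ~sd,
    "N_NJPN", "norm", 1e4, 3e6, 450000, 500000,
    "N_TajimaTango", "norm", 1e4, 3e6, 600000, 500000,
    "N_Kyushu", "norm", 1e4, 3e6, 1225000, 500000,
    "N_Honshu", "norm", 1e4, 3e6, 1050000, 500000,
    "N_Ancestor", "unif", 1e4, 3e7, NA, NA,
    "t1", "unif", 10, 4e6, NA, NA,
    "t2", "unif", 10, 4e6, NA, NA,
    "t3", "norm", 1e6, 3e7, 4e6, 5e6,
    "r", "unif", 0.001, 0.999, NA, NA
  )
  prior_set(params, constraints = c("t3 > t2", "t3 > t1", "t2 >= t1"))
}

#' @rdname default_priors
#' @export
out_of_nk_priors <- function() {
  params <- tibble::tribble(
    ~parameter, ~dist, ~min, ~max, ~mean, ~sd,
    "N_SSaga", "norm", 1e4, 3e6, 1300000, 500000,
    "N_NSaga", "norm", 1e4, 3e6, 1250000, 500000,
    "t", "unif", 1e3, 4e6, NA, NA
  )
  prior_set(params, constraints = character())
}

#' @rdname default_priors
#' @param params tibble with columns `parameter`, `dist` (`"unif"` or
#'   `"norm"`, the normal truncated to \[min, max\]), `min`, `max`, `mean`,
#'   `sd`.
#' @param constraints character vector of inequality expressions over the
#'   parameter names (e.g. `"t3 > t2"`).
#' @export
prior_set <- function(params, constraints = character()) {
  params <- tibble::as_tibble(params)
  stopifnot(all(c("parameter", "dist", "min", "max") %in% names(params)),
            all(params$dist %in% c("unif", "norm")),
            all(params$min < params$max),
            all(is.na(params$sd) | params$sd > 0))
  used <- unique(unlist(lapply(constraints, function(s) all.vars(str2lang(s)))))
  if (!all(used %in% params$parameter)) {
    stop("constraint references undeclared parameter(s): ",
         paste(setdiff(used, params$parameter), collapse = ", "),
         call. = FALSE)
  }
  structure(list(params = params, constraints = constraints),
            class = "prior_set")
}

# n draws from one marginal prior (truncated normal by rejection)
draw_marginal <- function(row, n) {
  if (row$dist == "unif") {
    stats::runif(n, row$min, row$max)
  } else {
    out <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      x <- stats::rnorm(length(todo), row$mean, row$sd)
      ok <- x >= row$min & x <= row$max
      out[todo[ok]] <- x[ok]
      todo <- todo[!ok]
    }
    out
  }
}

#' Draw parameters from a prior set
#'
#' Independent marginal draws (uniform, or normal truncated to its bounds by
#' rejection), with joint draws violating any declared constraint rejected
#' and redrawn. Deterministic given `seed`.
#'
#' @param ps a [prior_set()].
#' @param n number of joint draws.
#' @param seed optional integer seed (uses the current RNG state when NULL).
#' @param max_rejections error out after this many consecutive all-rejected
#'   rounds (guards constraints of vanishing prior mass).
#' @return A tibble of `n` rows, one column per parameter.
#' @export
sample_prior <- function(ps, n = 1L, seed = NULL, max_rejections = 10000L) {
  stopifnot(inherits(ps, "prior_set"))
  run <- function() {
    draws <- purrr::map(seq_len(nrow(ps$params)), function(i) {
      draw_marginal(ps$params[i, ], n)
    })
    names(draws) <- ps$params$parameter
    draws <- tibble::as_tibble(draws)
    bad <- constraint_violations(draws, ps$constraints)
    tries <- 0L
    while (any(bad)) {
      idx <- which(bad)
      redraw <- purrr::map(seq_len(nrow(ps$params)), function(i) {
        draw_marginal(ps$params[i, ], length(idx))
      })
      names(redraw) <- ps$params$parameter
      draws[idx, ] <- tibble::as_tibble(redraw)
      newbad <- constraint_violations(draws[idx, , drop = FALSE], ps$constraints)
      tries <- if (all(newbad)) tries + 1L else 0L
      if (tries >= max_rejections) {
        stop("prior constraints rejected ", max_rejections,
             " consecutive redraws; constraint set may have ~zero mass",
             call. = FALSE)
      }
      bad[idx] <- newbad
    }
    draws
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

constraint_violations <- function(draws, constraints) {
  if (!length(constraints) || nrow(draws) == 0L) {
    return(rep(FALSE, nrow(draws)))
  }
  viol <- rep(FALSE, nrow(draws))
  for (s in constraints) {
    viol <- viol | !eval(str2lang(s), envir = draws)
  }
  viol
}
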