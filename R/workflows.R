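# single-scenario view of a multi-scenario reference table (standardization
# constants kept from the full table so distances stay comparable)
reftable_subset <- function(rt, scenario) {
  stopifnot(inherits(rt, "abc_reftable"), scenario %in% rt$records$scenario)
  rt$records <- rt$records[rt$records$scenario == scenario, , drop = FALSE]
  rt$scenarios <- rt$scenarios[scenario]
  rt
}

#' Scenario comparison and parameter estimation for the Tajima-Tango history
#'
#' Runs the full boundary-group analysis on a four-group dataset: builds a
#' reference table over the competing scenarios, performs model choice by
#' both the direct and the logistic estimator, and estimates posterior
#' parameters (rejection + weighted local-linear regression) for each
#' scenario that wins under either method. Optional accuracy metrics
#' (prior- and posterior-based) are computed for the estimated scenarios.
#'
#' The population map's groups must be named like the scenarios' sampled
#' populations (N.JPN, Tajima-Tango, Kyushu, Honshu).
#'
#' @param gm a `gbs_genotypes` dataset (e.g. an LD-pruned HZ-2-like set).
#' @param pm population map with the four boundary groups.
#' @param scenarios named list of competing [demographic_scenario()]s
#'   (default: templates I-IV).
#' @param priors shared [prior_set()] (default [default_priors()]).
#' @param n_per_scenario simulations per scenario (default 10,000 — sized so
#'   the whole workflow runs in minutes on one CPU; raise towards the
#'   million-per-scenario regime for production inference).
#' @param tolerance rejection tolerance (default 0.01).
#' @param n_closest records for the direct estimator (default 500).
#' @param trio (admixed, parent1, parent2) group names entering the
#'   admixture summary statistics (default Tajima-Tango given N.JPN and
#'   Honshu, the admixture hypothesis under test).
#' @param n_accuracy_test pseudo-observed datasets per accuracy evaluation
#'   (0, the default, skips accuracy metrics).
#' @param seed integer seed driving every stochastic stage.
#' @return A list of class `tt_report`: `observed` (statistic vector),
#'   `model_choice` (tibble, both methods), `posteriors` (named list of
#'   `abc_posterior` for the winning scenarios), `accuracy` (tibble or
#'   NULL), `config` (sizes, seed, config hash).
#' @export
run_tajima_tango <- function(gm, pm,
                             scenarios = build_scenarios()[c("I", "II", "III", "IV")],
                             priors = default_priors(),
                             n_per_scenario = 10000L, tolerance = 0.01,
                             n_closest = 500L,
                             trio = c("Tajima-Tango", "N.JPN", "Honshu"),
                             n_accuracy_test = 0L, seed = 1L) {
  pm <- join_popmap(gm, pm)
  groups <- names(scenarios[[1]]$samples)
  missing <- setdiff(groups, pm$group)
  if (length(missing)) {
    stop("dataset lacks group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  layout <- stat_layout(groups, trios = list(trio))
  observed <- summary_stats(gm, pm, layout)
  rt <- build_reference_table(scenarios, priors, n_per_scenario,
                              n_loci = nrow(gm$loci), layout = layout,
                              seed = seed)
  direct <- select_model_direct(rt, observed, n_closest = n_closest)
  logistic <- select_model_logistic(rt, observed, tolerance = tolerance)
  model_choice <- dplyr::bind_rows(direct, logistic)
  winners <- unique(c(
    direct$scenario[which.max(direct$probability)],
    logistic$scenario[which.max(logistic$probability)]
  ))
  posteriors <- stats::setNames(lapply(winners, function(s) {
    regression_adjust(abc_reject(reftable_subset(rt, s), observed, tolerance))
  }), winners)
  accuracy <- NULL
  if (n_accuracy_test > 0L) {
    accuracy <- dplyr::bind_rows(lapply(winners, function(s) {
      sub <- reftable_subset(rt, s)
      acc_p <- accuracy_metrics(sub, n_test = n_accuracy_test,
                                tolerance = tolerance, from = "prior",
                                seed = seed + 101L)
      acc_q <- accuracy_metrics(sub, n_test = n_accuracy_test,
                                tolerance = tolerance, from = "posterior",
                                posterior = posteriors[[s]],
                                seed = seed + 102L)
      dplyr::bind_rows(acc_p, acc_q) |>
        dplyr::mutate(scenario = s, .before = 1L)
    }))
  }
  config <- list(
    n_per_scenario = n_per_scenario, n_loci = nrow(gm$loci),
    tolerance = tolerance, n_closest = n_closest, trio = trio,
    scenarios = names(scenarios), seed = seed
  )
  config$hash <- rlang::hash(config)
  structure(list(observed = observed, model_choice = model_choice,
                 posteriors = posteriors, accuracy = accuracy,
                 config = config),
            class = "tt_report")
}

#' @export
print.tt_report <- function(x, ...) {
  cat("<tt_report> scenario comparison over (",
      paste(x$config$scenarios, collapse = ", "), "), ",
      x$config$n_per_scenario, " sims/scenario, seed ", x$config$seed,
      "\n\nModel choice:\n", sep = "")
  print(x$model_choice)
  for (s in names(x$posteriors)) {
    cat("\nPosterior (scenario ", s, "):\n", sep = "")
    print(x$posteriors[[s]]$summary)
  }
  invisible(x)
}

#' Date the "out of northern Kyushu" split from a two-deme dataset
#'
#' Single-split ABC on a dataset of two deme samples: estimates the
#' divergence time (and the two deme sizes) by rejection + regression, then
#' reports the posterior both non-scaled (simulation units: generations /
#' individuals) and scaled — each accepted draw's sizes and times divided
#' by that draw's own mean deme size and multiplied by the observed mean
#' effective size, the standard device for reporting a scale-free SNP-mode
#' posterior in natural units. The observed mean Ne comes from
#' [ne_from_pi()] on the per-group nucleotide diversities of the input
#' (requires `total_length` on `gm`) unless supplied directly.
#'
#' @param gm two-deme `gbs_genotypes` dataset.
#' @param pm population map whose two groups match the scenario populations.
#' @param scenario the split scenario (default template `out_of_nk`).
#' @param priors a [prior_set()] (default [out_of_nk_priors()]).
#' @param n_sims reference-table size (default 10,000).
#' @param tolerance rejection tolerance (default 0.01).
#' @param mu mutation rate per site per generation for the Ne conversion
#'   (default 1e-9; 1 generation = 1 year at the reporting layer).
#' @param mean_ne observed mean effective size; computed from the data when
#'   NULL.
#' @param seed integer seed.
#' @return A list of class `oonk_report`: `posterior` (non-scaled
#'   `abc_posterior`), `posterior_scaled` (tibble summary of the scaled
#'   posterior), `mean_ne`, `ne_inputs` (per-group pi and Ne used), and
#'   `config`.
#' @export
run_out_of_nk <- function(gm, pm, scenario = build_scenarios()$out_of_nk,
                          priors = out_of_nk_priors(), n_sims = 10000L,
                          tolerance = 0.01, mu = 1e-9, mean_ne = NULL,
                          seed = 1L) {
  pm <- join_popmap(gm, pm)
  groups <- names(scenario$samples)
  missing <- setdiff(groups, pm$group)
  if (length(missing)) {
    stop("dataset lacks group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ne_inputs <- NULL
  if (is.null(mean_ne)) {
    gs <- group_summary(gm, pm, groups)
    ne_inputs <- ne_from_pi(gs$nucleotide_diversity, mu = mu)
    ne_inputs$group <- gs$group
    mean_ne <- mean(ne_inputs$Ne)
  }
  layout <- stat_layout(groups)
  observed <- summary_stats(gm, pm, layout)
  rt <- build_reference_table(scenario, priors, n_sims,
                              n_loci = nrow(gm$loci), layout = layout,
                              seed = seed)
  post <- regression_adjust(abc_reject(rt, observed, tolerance))
  # scaled route: normalise each draw by its own mean deme size, then put on
  # the observed-Ne scale
  size_params <- priors$params$parameter[priors$params$max > 1 &
                                           grepl("^N_", priors$params$parameter)]
  nbar <- rowMeans(post$draws[size_params])
  scaled <- post
  scalable <- priors$params$parameter[priors$params$max > 1]
  for (p in scalable) scaled$draws[[p]] <- scaled$draws[[p]] / nbar
  scaled$summary <- purrr::map_dfr(scalable, function(p) {
    x <- scaled$draws[[p]]
    w <- scaled$draws$weight
    tibble::tibble(parameter = p, mean = sum(w * x),
                   median = weighted_quantile(x, w, 0.5),
                   mode = weighted_mode(x, w),
                   q2.5 = weighted_quantile(x, w, 0.025),
                   q97.5 = weighted_quantile(x, w, 0.975))
  })
  scaled <- scale_parameters(scaled, mean_ne, "to_natural")
  config <- list(n_sims = n_sims, n_loci = nrow(gm$loci),
                 tolerance = tolerance, mu = mu, seed = seed)
  config$hash <- rlang::hash(config)
  structure(list(posterior = post, posterior_scaled = scaled$summary,
                 mean_ne = mean_ne, ne_inputs = ne_inputs, config = config),
            class = "oonk_report")
}

#' @export
print.oonk_report <- function(x, ...) {
  cat("<oonk_report> two-deme split ABC, ", x$config$n_sims,
      " simulations, seed ", x$config$seed, "\n", sep = "")
  cat("mean observed Ne used for scaling: ", format(x$mean_ne, big.mark = ","),
      " (mu = ", x$config$mu, ")\n", sep = "")
  if (!is.null(x$ne_inputs)) {
    cat("per-group pi and Ne inputs:\n")
    print(x$ne_inputs)
  }
  cat("\nScaled posterior (natural units):\n")
  print(x$posterior_scaled)
  invisible(x)
}
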