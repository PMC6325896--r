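#' Build an ABC reference table
#'
#' Draws parameters from the priors, simulates a SNP dataset of `n_loci`
#' loci under each draw for each scenario, and summarises every dataset with
#' the layout's statistic vector. Also records per-statistic standardization
#' constants (standard deviations across the whole table) used by the
#' rejection step. Deterministic given `seed`.
#'
#' The layout's group names must match the scenarios' sampled population
#' names.
#'
#' @param scenarios named list of [demographic_scenario()] objects (one
#'   entry is fine for plain parameter estimation).
#' @param priors a single [prior_set()] shared by all scenarios, or a named
#'   list parallel to `scenarios`.
#' @param n_per_scenario simulations per scenario.
#' @param n_loci loci per simulated dataset.
#' @param layout a [stat_layout()]; default: all singles and pairs over the
#'   sampled populations of the first scenario, no trios.
#' @param seed optional integer seed.
#' @return A list of class `abc_reftable`: `records` (tibble with columns
#'   `scenario`, the parameters, and the statistics), `stat_names`,
#'   `param_names`, `stat_sd`, `layout`, `priors`, `n_loci`.
#' @export
build_reference_table <- function(scenarios, priors, n_per_scenario, n_loci,
                                  layout = NULL, seed = NULL) {
  if (inherits(scenarios, "demographic_scenario")) {
    scenarios <- stats::setNames(list(scenarios), scenarios$name)
  }
  stopifnot(length(scenarios) >= 1L)
  if (inherits(priors, "prior_set")) {
    priors <- stats::setNames(rep(list(priors), length(scenarios)),
                              names(scenarios))
  }
  if (is.null(layout)) {
    layout <- stat_layout(names(scenarios[[1]]$samples))
  }
  run <- function() {
    blocks <- purrr::imap(scenarios, function(sc, nm) {
      draws <- sample_prior(priors[[nm]], n = n_per_scenario)
      keep <- intersect(names(draws), scenario_parameters(sc))
      stats <- matrix(NA_real_, n_per_scenario, length(stat_names(layout)))
      an <- NULL
      for (i in seq_len(n_per_scenario)) {
        sim <- simulate_counts(sc, draws[i, ], n_loci)
        if (is.null(an)) {
          an <- matrix(sim$an, nrow = n_loci, ncol = length(sim$an),
                       byrow = TRUE, dimnames = list(NULL, names(sim$an)))
        }
        stats[i, ] <- stats_from_counts(sim$counts, an, layout)
      }
      colnames(stats) <- stat_names(layout)
      dplyr::bind_cols(tibble::tibble(scenario = nm), draws[keep],
                       tibble::as_tibble(stats))
    })
    records <- dplyr::bind_rows(blocks)
    sn <- stat_names(layout)
    pn <- setdiff(names(records), c("scenario", sn))
    structure(
      list(records = records, stat_names = sn, param_names = pn,
           stat_sd = vapply(records[sn], stats::sd, numeric(1)),
           layout = layout, priors = priors, scenarios = scenarios,
           n_loci = n_loci),
      class = "abc_reftable"
    )
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}

#' @export
print.abc_reftable <- function(x, ...) {
  cat("<abc_reftable> ", nrow(x$records), " simulations (",
      paste(unique(x$records$scenario), collapse = ", "), "), ",
      length(x$stat_names), " summary statistics, ", x$n_loci,
      " loci each\n", sep = "")
  invisible(x)
}

# standardize a stats matrix/vector by the table's constants; zero-sd
# statistics carry no ranking information and are dropped
standardize_stats <- function(rt, stats) {
  sdv <- rt$stat_sd
  keep <- which(is.finite(sdv) & sdv > 0)
  if (is.null(dim(stats))) {
    stats[names(sdv)[keep]] / sdv[keep]
  } else {
    sweep(as.matrix(stats[, names(sdv)[keep], drop = FALSE]), 2L,
          sdv[keep], "/")
  }
}

#' ABC rejection step
#'
#' Ranks the reference-table records by Euclidean distance between their
#' standardized summary-statistic vectors and the observed vector
#' (standardization constants: per-statistic standard deviations across the
#' table), and keeps the closest `ceiling(tolerance * N)`.
#'
#' @param rt an [build_reference_table()] result.
#' @param observed named statistic vector, as from [summary_stats()], in the
#'   table's layout.
#' @param tolerance accepted fraction of simulations, in (0, 1\]; the
#'   study-standard value is 0.01.
#' @return A list of class `abc_rejection`: `accepted` (tibble of accepted
#'   records with a `distance` column, closest first), `observed`,
#'   `tolerance`, plus the parent table's metadata.
#' @export
abc_reject <- function(rt, observed, tolerance = 0.01) {
  stopifnot(inherits(rt, "abc_reftable"),
            tolerance > 0, tolerance <= 1)
  if (nrow(rt$records) == 0L) stop("empty reference table", call. = FALSE)
  obs <- observed[rt$stat_names]
  if (anyNA(obs)) {
    stop("observed vector lacks statistic(s): ",
         paste(rt$stat_names[is.na(obs)], collapse = ", "), call. = FALSE)
  }
  S <- standardize_stats(rt, rt$records[rt$stat_names])
  o <- standardize_stats(rt, obs)
  d <- sqrt(rowSums(sweep(S, 2L, o, "-")^2))
  n_keep <- ceiling(tolerance * nrow(S))
  ord <- order(d)[seq_len(n_keep)]
  structure(
    list(accepted = dplyr::bind_cols(rt$records[ord, ],
                                     tibble::tibble(distance = d[ord])),
         observed = obs, tolerance = tolerance,
         stat_names = rt$stat_names, param_names = rt$param_names,
         stat_sd = rt$stat_sd, priors = rt$priors, layout = rt$layout),
    class = "abc_rejection"
  )
}

#' @export
print.abc_rejection <- function(x, ...) {
  cat("<abc_rejection> ", nrow(x$accepted), " accepted records (tolerance ",
      x$tolerance, "), max distance ", signif(max(x$accepted$distance), 4),
      "\n", sep = "")
  invisible(x)
}
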