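#' Plot an ABC posterior
#'
#' Weighted posterior density per parameter with the weighted mean (solid)
#' and central 95% credible bounds (dashed).
#'
#' @param object an `abc_posterior`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.abc_posterior <- function(object, ...) {
  params <- object$summary$parameter
  long <- object$draws |>
    dplyr::select(dplyr::all_of(c(params, "weight"))) |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                        values_to = "value")
  marks <- object$summary |>
    tidyr::pivot_longer(c("mean", "q2.5", "q97.5"), names_to = "stat",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(ggplot2::aes(weight = .data$weight),
                          fill = "grey80", colour = "grey30") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$value,
                                     linetype = .data$stat),
                        colour = "firebrick") +
    ggplot2::scale_linetype_manual(
      values = c(mean = "solid", q2.5 = "dashed", q97.5 = "dashed"),
      guide = "none") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = paste("Scenario", object$scenario)) +
    ggplot2::theme_minimal()
}

#' Plot scenario posterior probabilities
#'
#' @param object an `abc_model_choice` tibble (possibly both methods bound
#'   together, as in a `tt_report`).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.abc_model_choice <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$scenario, y = .data$probability,
                               fill = .data$method)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(y = "posterior probability", x = "scenario") +
    ggplot2::theme_minimal()
}

#' Plot a fixed-allele sharing table by chromosome
#'
#' @param object a [sharing_table()] result.
#' @param ... unused.
#' @return A ggplot of per-chromosome stacked counts of the three states.
#' @export
autoplot.sharing_table <- function(object, ...) {
  long <- object$by_chromosome |>
    tidyr::pivot_longer(-"chrom", names_to = "state", values_to = "count")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$chrom, y = .data$count,
                               fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "chromosome", y = "fixed-difference SNPs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
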