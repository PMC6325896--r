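#' Read or validate a population map
#'
#' A population map assigns each individual to a population and each
#' population to a group (here, a mitochondrial-lineage group such as N.JPN,
#' Tajima-Tango or S.JPN). On disk it is a 3-column tab-separated file
#' (individual, population, group) with optional `#` comment lines.
#'
#' @param path path to a tab-delimited file with >= 3 columns.
#' @return A tibble with columns `individual`, `population`, `group`,
#'   row order preserved.
#' @export
read_popmap <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (nrow(df) == 0L) stop("empty population map: ", path, call. = FALSE)
  if (ncol(df) < 3L) {
    stop("population map needs >= 3 columns (individual, population, group), got ",
         ncol(df), call. = FALSE)
  }
  pm <- tibble::tibble(
    individual = df[[1]],
    population = df[[2]],
    group = df[[3]]
  )
  validate_popmap(pm)
}

#' @rdname read_popmap
#' @param pm a data frame with columns `individual`, `population`, `group`.
#' @export
validate_popmap <- function(pm) {
  pm <- tibble::as_tibble(pm)
  need <- c("individual", "population", "group")
  if (!all(need %in% names(pm))) {
    stop("population map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dup <- pm$individual[duplicated(pm$individual)]
  if (length(dup)) {
    stop("individuals assigned more than once: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  two <- pm |>
    dplyr::distinct(.data$population, .data$group) |>
    dplyr::count(.data$population) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(two)) {
    stop("population(s) mapped to more than one group: ",
         paste(two$population, collapse = ", "), call. = FALSE)
  }
  pm[need]
}

#' @rdname read_popmap
#' @export
write_popmap <- function(pm, path) {
  pm <- validate_popmap(pm)
  readr::write_tsv(pm, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

popmap_group_individuals <- function(pm, group) {
  pm <- validate_popmap(pm)
  if (!group %in% pm$group) stop("unknown group: ", group, call. = FALSE)
  pm$individual[pm$group == group]
}

# check every matrix individual is mapped; returns pm restricted to matrix order
join_popmap <- function(gm, pm) {
  pm <- validate_popmap(pm)
  missing <- setdiff(gm$individuals, pm$individual)
  if (length(missing)) {
    stop("individuals absent from population map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  pm[match(gm$individuals, pm$individual), ]
}
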