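#' Classify a SNP by fixed-allele sharing among three groups
#'
#' Given the alt-allele frequencies of three groups at one site, returns
#' which two groups are fixed for the same allele while the third is fixed
#' for the other allele. Sites where any group is not fixed (frequency
#' strictly between 0 and 1), where all three agree (invariant in the trio),
#' or where a frequency is undefined, are `"unclassified"`.
#'
#' @param freq_a,freq_b,freq_c within-group alt-allele frequencies
#'   (vectorised; `NA` allowed).
#' @return Character vector with values `"AB"`, `"AC"`, `"BC"` (the pair
#'   sharing the allele, positions referring to the argument order) or
#'   `"unclassified"`.
#' @export
#' @examples
#' classify_site(1, 1, 0)    # "AB"
#' classify_site(1, 0, 1)    # "AC": a B-specific allele
#' classify_site(1, 0.5, 0)  # "unclassified"
classify_site <- function(freq_a, freq_b, freq_c) {
  f <- cbind(freq_a, freq_b, freq_c)
  fixed <- !is.na(f) & (f == 0 | f == 1)
  all_fixed <- rowSums(fixed) == 3L
  out <- rep("unclassified", nrow(f))
  idx <- which(all_fixed)
  if (length(idx)) {
    fa <- f[idx, 1L]; fb <- f[idx, 2L]; fc <- f[idx, 3L]
    out[idx][fa == fb & fa != fc] <- "AB"
    out[idx][fa == fc & fa != fb] <- "AC"
    out[idx][fb == fc & fb != fa] <- "BC"
    # three-way agreement stays "unclassified" (invariant in the trio)
  }
  out
}

#' Fixed-allele sharing table for three groups
#'
#' Applies [classify_site()] to every SNP using within-group alt-allele
#' frequencies over called genotypes, and tabulates the three sharing states
#' per chromosome and overall. "Fixed" means frequency exactly 0 or 1 over
#' called alleles; a group additionally needs at least `min_alleles` called
#' alleles at the site for its frequency to count (missing-data guard).
#' A relaxed fixation threshold is available via `delta`: a group is then
#' treated as fixed when its frequency is within `delta` of 0 or 1
#' (`delta = 0`, the default, is the strict definition).
#'
#' @param gm a `gbs_genotypes` object.
#' @param pm population map.
#' @param groups ordered character vector of exactly three group names; the
#'   states are named after pairs of these.
#' @param min_alleles minimum called alleles per group per site (default 2).
#' @param delta relaxed fixation margin in \[0, 0.5); default 0 (strict).
#' @return A list of class `sharing_table` with elements
#'   `by_chromosome` (tibble: chrom x three state counts), `totals` (tibble
#'   with counts and proportions per state), `n_classified`, `n_input_snps`,
#'   and `groups`.
#' @export
sharing_table <- function(gm, pm, groups, min_alleles = 2L, delta = 0) {
  validate_genotypes(gm)
  pm <- join_popmap(gm, pm)
  if (length(groups) != 3L) stop("exactly three groups required", call. = FALSE)
  if (!all(groups %in% pm$group)) {
    stop("group(s) absent from map: ",
         paste(setdiff(groups, pm$group), collapse = ", "), call. = FALSE)
  }
  stopifnot(delta >= 0, delta < 0.5)
  cm <- group_count_matrices(gm, pm, groups)
  f <- ifelse(cm$an >= min_alleles, cm$ac / cm$an, NA_real_)
  if (delta > 0) f <- ifelse(f <= delta, 0, ifelse(f >= 1 - delta, 1, f))
  state <- classify_site(f[, 1L], f[, 2L], f[, 3L])
  labels <- c(
    AB = paste0("shared(", groups[1], ",", groups[2], ")"),
    AC = paste0("shared(", groups[1], ",", groups[3], ")"),
    BC = paste0("shared(", groups[2], ",", groups[3], ")")
  )
  df <- tibble::tibble(chrom = gm$loci$chrom, state = state) |>
    dplyr::filter(.data$state != "unclassified") |>
    dplyr::mutate(state = labels[.data$state])
  by_chrom <- df |>
    dplyr::count(.data$chrom, .data$state) |>
    tidyr::pivot_wider(names_from = "state", values_from = "n",
                       values_fill = 0L)
  for (lab in labels) {
    if (!lab %in% names(by_chrom)) by_chrom[[lab]] <- 0L
  }
  by_chrom <- by_chrom[, c("chrom", unname(labels))]
  n_classified <- nrow(df)
  counts <- vapply(labels, function(l) sum(df$state == l), integer(1))
  totals <- tibble::tibble(
    state = unname(labels),
    count = unname(counts),
    proportion = if (n_classified > 0) unname(counts) / n_classified else 0
  )
  structure(
    list(by_chromosome = by_chrom, totals = totals,
         n_classified = n_classified, n_input_snps = nrow(gm$loci),
         groups = groups),
    class = "sharing_table"
  )
}

#' @export
print.sharing_table <- function(x, ...) {
  cat("<sharing_table> ", x$n_classified, " of ", x$n_input_snps,
      " SNPs classified among (", paste(x$groups, collapse = ", "), ")\n",
      sep = "")
  print(x$totals)
  invisible(x)
}

#' @rdname sharing_table
#' @param x a `sharing_table`.
#' @param ... unused.
#' @export
tidy.sharing_table <- function(x, ...) x$totals
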