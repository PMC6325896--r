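#' Group summary statistics for a filtered SNP dataset
#'
#' Computes, for each group of a population map, the classic GBS summary
#' table: mean number of genotyped individuals per locus, number of variant
#' sites (variable across all groups jointly), polymorphic sites within the
#' group, private alleles, mean major-allele frequency, mean observed
#' heterozygosity, and per-bp nucleotide diversity with across-site standard
#' errors.
#'
#' Per site the within-group gene diversity uses the small-sample unbiased
#' form \eqn{(n/(n-1))(1 - \sum p^2)} with `n` the number of called alleles;
#' nucleotide diversity is the sum of per-site gene diversities divided by
#' the total surveyed sequence length (invariant sites included), so
#' `total_length` must be set on `gm`. Missing calls are excluded
#' throughout; sites with fewer than 2 called alleles in a group contribute
#' nothing to that group's sums.
#'
#' Standard errors are across-site: \eqn{\sigma/\sqrt{sites}} for the two
#' means, and the correspondingly propagated \eqn{\sqrt{sites}\,\sigma/L}
#' for the diversity sum.
#'
#' @param gm a `gbs_genotypes` object, typically after [filter_loci()].
#' @param pm population map covering the individuals of `gm`.
#' @param groups groups to summarise; default all groups in `pm`.
#' @return A tibble with one row per group and columns `group`,
#'   `n_individuals`, `mean_individuals`, `mean_individuals_se`,
#'   `total_length`, `n_variant`, `n_polymorphic`, `n_private`,
#'   `major_allele_freq`, `major_allele_freq_se`, `obs_heterozygosity`,
#'   `obs_heterozygosity_se`, `nucleotide_diversity`,
#'   `nucleotide_diversity_se`.
#' @export
group_summary <- function(gm, pm, groups = NULL) {
  validate_genotypes(gm)
  pm <- join_popmap(gm, pm)
  if (is.null(groups)) groups <- unique(pm$group)
  if (!all(groups %in% pm$group)) {
    stop("unknown group(s): ", paste(setdiff(groups, pm$group), collapse = ", "),
         call. = FALSE)
  }
  all_groups <- unique(pm$group)
  cm <- group_count_matrices(gm, pm, all_groups)
  ac_tot <- rowSums(cm$ac)
  an_tot <- rowSums(cm$an)
  variant <- ac_tot > 0L & ac_tot < an_tot  # variable across all groups jointly
  n_variant <- sum(variant)
  # allele presence per group at variant sites
  alt_present <- cm$ac > 0L
  ref_present <- cm$ac < cm$an
  purrr::map_dfr(groups, function(g) {
    gi <- match(g, all_groups)
    ids <- pm$individual[pm$group == g]
    called <- !is.na(gm$calls[match(ids, gm$individuals), , drop = FALSE])
    n_called_ind <- colSums(called)
    ac <- cm$ac[, gi]
    an <- cm$an[, gi]
    others <- setdiff(seq_along(all_groups), gi)
    priv_alt <- alt_present[, gi] & !apply(alt_present[, others, drop = FALSE], 1L, any)
    priv_ref <- ref_present[, gi] & !apply(ref_present[, others, drop = FALSE], 1L, any)
    v <- variant
    use <- v & an > 0L          # variant sites with >= 1 call in group
    p <- ac[use] / an[use]
    maf <- pmax(p, 1 - p)
    het_rate <- {
      h <- colSums(gm$calls[match(ids, gm$individuals), , drop = FALSE] == 1L,
                   na.rm = TRUE)
      (h / pmax(n_called_ind, 1L))[use]
    }
    use2 <- v & an >= 2L
    gd <- gene_diversity(ac[use2] / an[use2], an[use2])
    L <- gm$total_length
    if (is.na(L)) {
      pi_val <- NA_real_
      pi_se <- NA_real_
    } else {
      pi_val <- sum(gd) / L
      pi_se <- sqrt(length(gd)) * stats::sd(gd) / L
    }
    se <- function(x) stats::sd(x) / sqrt(length(x))
    tibble::tibble(
      group = g,
      n_individuals = length(ids),
      mean_individuals = mean(n_called_ind[v]),
      mean_individuals_se = se(n_called_ind[v]),
      total_length = L,
      n_variant = n_variant,
      n_polymorphic = sum(v & ac > 0L & ac < an),
      n_private = sum(v & (priv_alt | priv_ref)),
      major_allele_freq = mean(maf),
      major_allele_freq_se = se(maf),
      obs_heterozygosity = mean(het_rate),
      obs_heterozygosity_se = se(het_rate),
      nucleotide_diversity = pi_val,
      nucleotide_diversity_se = pi_se
    )
  })
}

#' Per-individual heterozygosity per site
#'
#' Nucleotide diversity of a single diploid individual: the count of
#' heterozygous calls divided by the total surveyed sequence length
#' (invariant sites included). Missing calls are excluded from the
#' numerator. An individual with no calls at all gets 0 with a warning.
#'
#' @param gm a `gbs_genotypes` object with `total_length` set.
#' @param individuals identifiers to report; default all.
#' @return A tibble with columns `individual`, `n_het`, `n_called`,
#'   `heterozygosity`.
#' @export
individual_heterozygosity <- function(gm, individuals = NULL) {
  validate_genotypes(gm)
  if (is.na(gm$total_length)) {
    stop("total_length must be set to compute per-bp heterozygosity",
         call. = FALSE)
  }
  if (is.null(individuals)) individuals <- gm$individuals
  idx <- match(individuals, gm$individuals)
  if (anyNA(idx)) {
    stop("unknown individual(s): ",
         paste(individuals[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  d <- gm$calls[idx, , drop = FALSE]
  n_called <- rowSums(!is.na(d))
  if (any(n_called == 0L)) {
    warning("individual(s) with no called genotypes reported as 0: ",
            paste(individuals[n_called == 0L], collapse = ", "), call. = FALSE)
  }
  n_het <- unname(rowSums(d == 1L, na.rm = TRUE))
  tibble::tibble(
    individual = individuals,
    n_het = n_het,
    n_called = unname(n_called),
    heterozygosity = n_het / gm$total_length
  )
}

#' Effective population size from nucleotide diversity
#'
#' Inverts the neutral equilibrium relationship \eqn{\pi = 4 N_e \mu} for a
#' Wright-Fisher population of constant size under the infinite-sites model.
#'
#' @param pi per-bp nucleotide diversity (>= 0); vectorised.
#' @param mu mutation rate per site per generation; default `1e-9`.
#' @param generation_years years per generation (used only by reporting
#'   layers; the returned Ne is in individuals). Default 1.
#' @return A tibble with columns `pi`, `mu`, `generation_years`, `Ne`.
#' @export
#' @examples
#' ne_from_pi(0.0036)  # Ne = 900,000
ne_from_pi <- function(pi, mu = 1e-9, generation_years = 1) {
  if (any(mu <= 0)) stop("mu must be > 0", call. = FALSE)
  if (any(pi < 0)) stop("pi must be >= 0", call. = FALSE)
  tibble::tibble(
    pi = pi, mu = mu, generation_years = generation_years,
    Ne = pi / (4 * mu)
  )
}
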