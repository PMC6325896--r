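#' Per-locus gene diversity
#'
#' Unbiased expected heterozygosity of a biallelic locus,
#' \eqn{(n/(n-1))(1 - p^2 - (1-p)^2)}, with `n` the number of called alleles.
#'
#' @param p alt-allele frequency (vectorised).
#' @param n number of called alleles (>= 2; `NA` returned otherwise).
#' @return Gene diversity >= 0; exactly 0 for a monomorphic locus.
#' @export
#' @examples
#' gene_diversity(0.5, 4)  # 2/3
gene_diversity <- function(p, n) {
  out <- (n / (n - 1)) * (1 - p^2 - (1 - p)^2)
  out[n < 2] <- NA_real_
  out
}

#' Per-locus Nei's standard genetic distance
#'
#' \eqn{-\ln(J_{XY}/\sqrt{J_X J_Y})} from the two biallelic allele
#' frequencies, where \eqn{J_X = p_X^2 + (1-p_X)^2} and
#' \eqn{J_{XY} = p_X p_Y + (1-p_X)(1-p_Y)}. Exactly 0 when the frequencies
#' are identical. When the two samples share no alleles (\eqn{J_{XY}=0})
#' the distance is infinite and is capped at `cap`.
#'
#' @param freq_x,freq_y alt-allele frequencies (vectorised).
#' @param cap finite stand-in for infinite distances (default 10).
#' @return Distance >= 0 (`NA` when a frequency is `NA`).
#' @export
#' @examples
#' nei_distance(0.8, 0.5)  # 0.1542
nei_distance <- function(freq_x, freq_y, cap = 10) {
  jx <- freq_x^2 + (1 - freq_x)^2
  jy <- freq_y^2 + (1 - freq_y)^2
  jxy <- freq_x * freq_y + (1 - freq_x) * (1 - freq_y)
  d <- -log(jxy / sqrt(jx * jy))
  d[!is.na(d) & is.infinite(d)] <- cap
  # identical frequencies give exactly 0 despite floating-point log
  d[!is.na(freq_x) & !is.na(freq_y) & freq_x == freq_y] <- 0
  d
}

#' Per-locus admixture estimate from an (admixed, parent1, parent2) trio
#'
#' The classic frequency-based admixture coefficient
#' \eqn{(p_{adm} - p_{2})/(p_{1} - p_{2})}: 1 when the admixed group matches
#' parent 1, 0 when it matches parent 2. Undefined (`NA`) when the parental
#' frequencies differ by less than `tol`.
#'
#' @param freq_adm,freq_p1,freq_p2 alt-allele frequencies (vectorised).
#' @param tol minimum parental frequency difference (default 1e-9).
#' @return Admixture estimate (may fall outside \[0,1\]), or `NA`.
#' @export
#' @examples
#' admixture_estimate(0.6, 1, 0.5)  # 0.2
admixture_estimate <- function(freq_adm, freq_p1, freq_p2, tol = 1e-9) {
  denom <- freq_p1 - freq_p2
  out <- (freq_adm - freq_p2) / denom
  out[!is.na(denom) & abs(denom) < tol] <- NA_real_
  out
}

#' Declare a summary-statistic layout
#'
#' Fixes which one-sample, two-sample and three-sample statistics make up a
#' summary vector, so observed and simulated vectors align component by
#' component. Per single group: proportion of loci with null (zero) gene
#' diversity and mean gene diversity across polymorphic loci. Per pair:
#' proportion of loci with null Nei's distance and variance of the non-null
#' distances. Per (admixed, parent1, parent2) trio: proportion of null
#' admixture estimates, mean and variance of the non-null estimates, and the
#' mean over all loci with a defined estimate.
#'
#' @param groups character vector naming the groups, fixing column order.
#' @param singles groups entering one-sample statistics (default all).
#' @param pairs list of 2-vectors of group names (default all unordered
#'   pairs of `groups`).
#' @param trios list of 3-vectors `(admixed, parent1, parent2)`; default
#'   none.
#' @param nei_cap cap for infinite Nei distances (default 10).
#' @param adm_tol tolerance below which parental frequencies count as equal
#'   (default 1e-9).
#' @return A list of class `stat_layout`.
#' @export
stat_layout <- function(groups, singles = groups, pairs = NULL, trios = list(),
                        nei_cap = 10, adm_tol = 1e-9) {
  if (is.null(pairs)) {
    pairs <- if (length(groups) >= 2L) {
      utils::combn(groups, 2L, simplify = FALSE)
    } else list()
  }
  stopifnot(all(singles %in% groups),
            all(unlist(pairs) %in% groups),
            all(unlist(trios) %in% groups))
  structure(list(groups = groups, singles = singles, pairs = pairs,
                 trios = trios, nei_cap = nei_cap, adm_tol = adm_tol),
            class = "stat_layout")
}

stat_names <- function(layout) {
  c(
    unlist(lapply(layout$singles, function(g) {
      paste0(c("prop_null_gd.", "mean_gd_poly."), g)
    })),
    unlist(lapply(layout$pairs, function(p) {
      key <- paste(p, collapse = "-")
      paste0(c("prop_null_nei.", "var_nei_nonnull."), key)
    })),
    unlist(lapply(layout$trios, function(t) {
      key <- paste(t, collapse = "-")
      paste0(c("prop_null_adm.", "mean_adm_nonnull.", "var_adm_nonnull.",
               "mean_adm_all."), key)
    }))
  )
}

# variance/mean that return 0 instead of NA on degenerate input, so summary
# vectors stay finite and comparable
var0 <- function(x) if (length(x) >= 2L) stats::var(x) else 0
mean0 <- function(x) if (length(x) >= 1L) mean(x) else 0

#' Summary-statistic vector from per-group allele counts
#'
#' Lower-level workhorse behind [summary_stats()], shared with the
#' reference-table builder: takes per-locus alt-allele counts and called
#' allele totals per group and aggregates them into the layout's vector.
#'
#' @param ac,an numeric matrices (loci x groups, columns named by group) of
#'   alt-allele counts and called allele totals.
#' @param layout a [stat_layout()].
#' @return Named numeric vector, one element per configured statistic.
#' @export
stats_from_counts <- function(ac, an, layout) {
  p <- ac / an
  p[an == 0] <- NA_real_
  out <- numeric(0)
  for (g in layout$singles) {
    gd <- gene_diversity(p[, g], an[, g])
    gd <- gd[!is.na(gd)]
    out <- c(out,
             if (length(gd)) mean(gd == 0) else 0,
             mean0(gd[gd > 0]))
  }
  for (pr in layout$pairs) {
    d <- nei_distance(p[, pr[1]], p[, pr[2]], cap = layout$nei_cap)
    d <- d[!is.na(d)]
    out <- c(out,
             if (length(d)) mean(d == 0) else 0,
             var0(d[d > 0]))
  }
  for (tr in layout$trios) {
    a <- admixture_estimate(p[, tr[1]], p[, tr[2]], p[, tr[3]],
                            tol = layout$adm_tol)
    a <- a[!is.na(a)]  # undefined estimates excluded from all aggregates
    out <- c(out,
             if (length(a)) mean(a == 0) else 0,
             mean0(a[a != 0]),
             var0(a[a != 0]),
             mean0(a))
  }
  stats::setNames(out, stat_names(layout))
}

#' Observed summary-statistic vector of a genotype dataset
#'
#' Computes the configured one-, two- and three-sample statistics from
#' within-group allele frequencies over called genotypes, per locus, and
#' aggregates them exactly as the simulated reference-table vectors are
#' aggregated.
#'
#' @param gm a `gbs_genotypes` object.
#' @param pm population map.
#' @param layout a [stat_layout()] whose groups all appear in `pm`.
#' @return Named numeric vector (see [stats_from_counts()]).
#' @export
summary_stats <- function(gm, pm, layout) {
  validate_genotypes(gm)
  pm <- join_popmap(gm, pm)
  missing <- setdiff(layout$groups, pm$group)
  if (length(missing)) {
    stop("layout group(s) absent from map: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cm <- group_count_matrices(gm, pm, layout$groups)
  colnames(cm$ac) <- colnames(cm$an) <- layout$groups
  stats_from_counts(cm$ac, cm$an, layout)
}
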