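#' Diploid biallelic genotype matrix
#'
#' Light container for GBS-style SNP calls: an individuals-by-loci integer
#' matrix of alt-allele dosages (0, 1, 2 or `NA` for a missing call) plus a
#' locus table and an optional total surveyed sequence length. The total
#' length (bp, including invariant sites) is the denominator used for
#' nucleotide diversity, matching how reduced-representation datasets report
#' per-bp diversity.
#'
#' Internally "allele frequency" always means alt-allele frequency; reporting
#' functions convert to major/minor where a table calls for it.
#'
#' @param calls integer matrix, individuals x loci, values in {0,1,2,NA}.
#'   Row names are taken as individual identifiers if `individuals` is NULL.
#' @param loci data frame with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (single characters, distinct). One row per column of `calls`.
#' @param individuals character vector of unique individual identifiers.
#' @param total_length optional integer, bp of surveyed sequence including
#'   invariant sites.
#'
#' @return An object of class `gbs_genotypes`: a list with elements
#'   `calls`, `loci` (tibble), `individuals`, `total_length`.
#' @export
#' @examples
#' gm <- genotypes(
#'   calls = rbind(a = c(0L, 1L), b = c(2L, NA)),
#'   loci = data.frame(chrom = "chr1", pos = c(100L, 200L),
#'                     ref = "A", alt = c("G", "T"))
#' )
#' gm
genotypes <- function(calls, loci, individuals = NULL, total_length = NA_integer_) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(individuals)) individuals <- rownames(calls)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(nrow(calls)))
  loci <- tibble::as_tibble(loci)
  rownames(calls) <- individuals
  colnames(calls) <- locus_ids(loci)
  x <- structure(
    list(
      calls = calls,
      loci = loci,
      individuals = as.character(individuals),
      total_length = if (is.na(total_length)) NA_integer_ else as.integer(total_length)
    ),
    class = "gbs_genotypes"
  )
  validate_genotypes(x)
}

locus_ids <- function(loci) paste0(loci$chrom, ":", loci$pos)

#' @rdname genotypes
#' @param x a `gbs_genotypes` object.
#' @export
validate_genotypes <- function(x) {
  stopifnot(inherits(x, "gbs_genotypes"))
  calls <- x$calls
  loci <- x$loci
  if (nrow(loci) != ncol(calls)) {
    stop("locus table has ", nrow(loci), " rows but calls matrix has ",
         ncol(calls), " columns", call. = FALSE)
  }
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(loci))) {
    stop("locus table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(calls)), c(0L, 1L, 2L, NA_integer_))
  if (length(bad)) {
    stop("dosage values outside {0,1,2,NA}: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$individuals)) {
    stop("duplicated individual identifiers", call. = FALSE)
  }
  if (anyDuplicated(locus_ids(loci))) {
    stop("duplicated loci (same chrom:pos)", call. = FALSE)
  }
  multi <- nchar(loci$ref) != 1L | nchar(loci$alt) != 1L | loci$ref == loci$alt
  if (any(multi)) {
    stop("non-biallelic SNP records at loci: ",
         paste(utils::head(locus_ids(loci)[multi], 5L), collapse = ", "),
         call. = FALSE)
  }
  nondec <- loci |>
    dplyr::mutate(.i = dplyr::row_number()) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::filter(c(FALSE, diff(.data$pos) <= 0)) |>
    dplyr::ungroup()
  if (nrow(nondec)) {
    stop("positions not strictly increasing within chromosome ",
         nondec$chrom[1], " near position ", nondec$pos[1], call. = FALSE)
  }
  x
}

#' @export
print.gbs_genotypes <- function(x, ...) {
  cat("<gbs_genotypes> ", length(x$individuals), " individuals x ",
      nrow(x$loci), " loci on ", length(unique(x$loci$chrom)),
      " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat("  missing calls: ", sprintf("%.1f%%", 100 * miss), sep = "")
  if (!is.na(x$total_length)) cat("; total surveyed length: ", x$total_length, " bp", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.gbs_genotypes <- function(x) c(length(x$individuals), nrow(x$loci))

#' Subset a genotype matrix
#'
#' @param gm a `gbs_genotypes` object.
#' @param loci integer or logical index over loci (columns).
#' @param individuals integer, logical or character index over individuals.
#' @return A `gbs_genotypes` with the selected rows/columns.
#' @export
subset_genotypes <- function(gm, loci = NULL, individuals = NULL) {
  validate_genotypes(gm)
  if (is.null(loci)) loci <- seq_len(nrow(gm$loci))
  if (is.null(individuals)) individuals <- seq_along(gm$individuals)
  if (is.character(individuals)) {
    individuals <- match(individuals, gm$individuals)
    if (anyNA(individuals)) stop("unknown individuals requested", call. = FALSE)
  }
  genotypes(
    calls = gm$calls[individuals, loci, drop = FALSE],
    loci = gm$loci[loci, , drop = FALSE],
    individuals = gm$individuals[individuals],
    total_length = gm$total_length
  )
}

#' Alt-allele frequency of one group at one locus
#'
#' The shared frequency primitive: alt-dosage sum over called individuals in
#' the group, divided by twice the number of called individuals. `NA` (not an
#' error) when no individual in the group is called at the locus.
#'
#' @param gm a `gbs_genotypes` object.
#' @param pm a population map (see [read_popmap()]).
#' @param group group name present in `pm`.
#' @param locus locus index (column of `gm$calls`).
#' @return Frequency in \[0,1\], or `NA` if the group has no calls there.
#' @export
#' @examples
#' gm <- genotypes(rbind(a = 0L, b = 1L),
#'                 data.frame(chrom = "chr1", pos = 1L, ref = "A", alt = "C"))
#' pm <- data.frame(individual = c("a", "b"), population = "p", group = "g")
#' group_allele_freq(gm, pm, "g", 1)  # 1/4
group_allele_freq <- function(gm, pm, group, locus) {
  ids <- popmap_group_individuals(pm, group)
  d <- gm$calls[match(ids, gm$individuals), locus]
  n <- sum(!is.na(d))
  if (n == 0L) return(NA_real_)
  sum(d, na.rm = TRUE) / (2 * n)
}

# alt-allele count and called-allele count per locus for a set of individuals;
# returns list(ac, an) of length-n_loci integer vectors
group_counts <- function(gm, ids) {
  d <- gm$calls[match(ids, gm$individuals), , drop = FALSE]
  an <- 2L * colSums(!is.na(d))
  ac <- colSums(d, na.rm = TRUE)
  list(ac = as.integer(ac), an = as.integer(an))
}

# per-group alt counts (ac) and called allele numbers (an): loci x groups
group_count_matrices <- function(gm, pm, groups) {
  pm <- validate_popmap(pm)
  counts <- lapply(groups, function(g) group_counts(gm, popmap_group_individuals(pm, g)))
  list(
    ac = vapply(counts, `[[`, integer(nrow(gm$loci)), "ac"),
    an = vapply(counts, `[[`, integer(nrow(gm$loci)), "an")
  )
}
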