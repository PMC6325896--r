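# Resolve a scenario's symbolic sizes/times/rates against a parameter draw
# and flatten to the numeric arrays the C++ simulator takes.
resolve_scenario <- function(sc, draw) {
  stopifnot(inherits(sc, "demographic_scenario"))
  draw <- as.list(draw)
  val <- function(x) {
    num <- suppressWarnings(as.numeric(x))
    out <- ifelse(is.na(num), NA_real_, num)
    for (i in which(is.na(num) & !is.na(x))) {
      if (is.null(draw[[x[i]]])) {
        stop("parameter '", x[i], "' not in draw", call. = FALSE)
      }
      out[i] <- draw[[x[i]]]
    }
    out
  }
  pop_names <- names(sc$populations)
  pop_size <- val(unname(sc$populations))
  if (any(!is.finite(pop_size) | pop_size <= 0)) {
    stop("population sizes must be positive", call. = FALSE)
  }
  ev <- sc$events
  time <- val(ev$time)
  rate <- val(ev$rate)
  if (any(time <= 0)) stop("event times must be > 0", call. = FALSE)
  is_adm <- ev$type == "admixture"
  if (any(is_adm & (is.na(rate) | rate <= 0 | rate >= 1))) {
    stop("admixture rates must lie in (0, 1)", call. = FALSE)
  }
  ord <- order(time)  # stable: ties keep row order
  events <- cbind(
    time = time,
    type = ifelse(is_adm, 1, 0),
    a = match(ev$a, pop_names) - 1L,
    b = match(ev$b, pop_names) - 1L,
    c = ifelse(is.na(ev$c), -1L, match(ev$c, pop_names) - 1L),
    rate = ifelse(is.na(rate), 0, rate)
  )[ord, , drop = FALSE]
  n_hap <- integer(length(pop_names))
  n_hap[match(names(sc$samples), pop_names)] <- 2L * as.integer(sc$samples)
  list(pop_names = pop_names, pop_size = pop_size,
       events = matrix(events, ncol = 6), n_hap = n_hap)
}

# per-locus derived-allele counts per sampled population (current RNG state);
# returns list(counts = loci x sampled-pops matrix, an = haploid sample sizes,
# tmrca optional)
simulate_counts <- function(sc, draw, n_loci, tmrca = FALSE) {
  rs <- resolve_scenario(sc, draw)
  out <- cpp_simulate_loci(rs$pop_size, rs$events, rs$n_hap, as.integer(n_loci),
                           FALSE, tmrca)
  sampled <- rs$n_hap > 0L
  counts <- out$counts[, sampled, drop = FALSE]
  colnames(counts) <- rs$pop_names[sampled]
  res <- list(counts = counts,
              an = stats::setNames(rs$n_hap[sampled], rs$pop_names[sampled]))
  if (tmrca) {
    res$tmrca <- out$tmrca
    res$tree_length <- out$tree_length
  }
  res
}

#' Simulate SNP genotypes under a demographic scenario
#'
#' For each locus independently, simulates a coalescent genealogy of all
#' sampled lineages under the scenario (times in generations) and places
#' exactly one mutation on a branch chosen with probability proportional to
#' its length, so every locus is polymorphic in the pooled sample —
#' mirroring how SNP-ascertained GBS loci behave and making the simulation
#' mutation-rate-free. Diploids are formed by pairing consecutive simulated
#' haplotypes within a population.
#'
#' Loci are placed at distinct uniform positions across `n_chrom`
#' chromosomes of length `chrom_length` (positions only matter for I/O and
#' LD windows; loci are unlinked by construction).
#'
#' @param sc a [demographic_scenario()].
#' @param draw named list / one-row data frame of parameter values
#'   resolving every parameter the scenario references.
#' @param n_loci number of SNP loci.
#' @param seed optional integer seed.
#' @param n_chrom,chrom_length genome layout for the emitted positions
#'   (defaults: 24 chromosomes of 30 Mb).
#' @return A list with `genotypes` (a [genotypes()] object, individuals
#'   named `<population>_<i>`) and `popmap` (tibble; population and group
#'   both set to the scenario population name).
#' @export
simulate_snps <- function(sc, draw, n_loci, seed = NULL,
                          n_chrom = 24L, chrom_length = 3e7) {
  run <- function() {
    rs <- resolve_scenario(sc, draw)
    if (sum(rs$n_hap) == 0L) stop("scenario samples no lineages", call. = FALSE)
    out <- cpp_simulate_loci(rs$pop_size, rs$events, rs$n_hap,
                             as.integer(n_loci), TRUE, FALSE)
    hap <- out$haplotypes  # loci x haploids, 0/1 derived
    sampled <- which(rs$n_hap > 0L)
    pops <- rep(rs$pop_names[sampled], rs$n_hap[sampled] / 2L)
    ind_ids <- paste0(gsub("[^A-Za-z0-9]", "", pops), "_",
                      unlist(lapply(table(factor(pops, unique(pops))), seq_len)))
    # pair consecutive haplotypes into diploids
    odd <- seq(1L, ncol(hap), by = 2L)
    calls <- t(hap[, odd, drop = FALSE] + hap[, odd + 1L, drop = FALSE])
    chrom <- sort(sample.int(n_chrom, n_loci, replace = TRUE))
    pos <- integer(n_loci)
    for (ch in unique(chrom)) {
      k <- sum(chrom == ch)
      pos[chrom == ch] <- sort(sample.int(chrom_length, k))
    }
    loci <- tibble::tibble(
      chrom = paste0("chr", chrom), pos = pos, ref = "A", alt = "G"
    )
    gm <- genotypes(calls, loci, individuals = ind_ids)
    pm <- tibble::tibble(individual = ind_ids, population = pops, group = pops)
    list(genotypes = gm, popmap = pm)
  }
  if (is.null(seed)) run() else withr_seed(seed, run())
}
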