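#' Small hand-constructed fixtures with known expectations
#'
#' Returns tiny genotype matrices whose statistics are known by
#' construction, for exercising the statistics and classification code
#' without any simulation:
#'
#' * `"sharing-811"` — 10 SNPs, three groups of 2 diploids, engineered so
#'   the three fixed-allele sharing states occur 8, 1 and 1 times.
#' * `"mono"` — an all-monomorphic matrix (nucleotide diversity 0).
#' * `"het23"` — two individuals over 1,000 bp of surveyed sequence, the
#'   first with exactly 23 heterozygous sites.
#'
#' @param name fixture name.
#' @return A list with `genotypes`, `popmap` and `expected` (a list of the
#'   fixture's precomputed expectations).
#' @export
make_fixture <- function(name) {
  fixtures <- c("sharing-811", "mono", "het23")
  if (!name %in% fixtures) {
    stop("unknown fixture '", name, "'; available: ",
         paste(fixtures, collapse = ", "), call. = FALSE)
  }
  loci_tbl <- function(n) {
    chrom <- rep(c("chr1", "chr2"), each = ceiling(n / 2))[seq_len(n)]
    tibble::tibble(chrom = chrom,
                   pos = as.integer(stats::ave(seq_len(n), chrom, FUN = seq_along) * 100L),
                   ref = "A", alt = "G")
  }
  if (name == "sharing-811") {
    # groups A, B, C of 2 diploids; per site all individuals homozygous
    site <- function(a, b, c) as.integer(rep(c(a, b, c) * 2, each = 2L))
    calls <- cbind(
      # 8 sites: A and B fixed for alt, C for ref -> shared(A,B)
      vapply(1:8, function(i) site(1, 1, 0), integer(6)),
      site(1, 0, 1),  # shared(A,C)
      site(0, 1, 1)   # shared(B,C)
    )
    rownames(calls) <- paste0(rep(c("a", "b", "c"), each = 2L), 1:2)
    gm <- genotypes(calls, loci_tbl(10), total_length = 1000L)
    pm <- tibble::tibble(
      individual = rownames(calls),
      population = rep(c("popA", "popB", "popC"), each = 2L),
      group = rep(c("A", "B", "C"), each = 2L)
    )
    expected <- list(counts = c(8L, 1L, 1L), proportions = c(0.8, 0.1, 0.1),
                     groups = c("A", "B", "C"))
  } else if (name == "mono") {
    calls <- matrix(0L, nrow = 4, ncol = 6,
                    dimnames = list(paste0("i", 1:4), NULL))
    gm <- genotypes(calls, loci_tbl(6), total_length = 1000L)
    pm <- tibble::tibble(individual = paste0("i", 1:4),
                         population = rep(c("p1", "p2"), each = 2L),
                         group = "G")
    expected <- list(pi = 0, n_polymorphic = 0L)
  } else {
    calls <- rbind(
      het = c(rep(1L, 23L), rep(0L, 7L)),
      hom = c(rep(2L, 15L), rep(0L, 15L))
    )
    gm <- genotypes(calls, loci_tbl(30), total_length = 1000L)
    pm <- tibble::tibble(individual = c("het", "hom"),
                         population = "p", group = "G")
    expected <- list(het_heterozygosity = 0.023, hom_heterozygosity = 0)
  }
  list(genotypes = gm, popmap = pm, expected = expected)
}

#' Study-shaped synthetic dataset templates
#'
#' Describes a synthetic dataset emulating one of the study designs the
#' package targets, with a generating scenario and true parameters so
#' recovery experiments know the truth:
#'
#' * `"hz2"` — four boundary groups (N.JPN, Tajima-Tango, Kyushu, Honshu)
#'   of 5 populations with one diploid each, 1,014 SNPs; generated under
#'   scenario III with the study's posterior-mean parameters as truth.
#' * `"local"` — two Saga demes of 6 diploids each, 698 SNPs, generated
#'   under the two-deme split model (truth: split 510,000 generations ago).
#' * `"popstat"` — like `"hz2"` but 2,453 SNPs and a 45,968 bp total
#'   surveyed length attached, for summary-statistics work.
#'
#' @param name template name.
#' @param n_loci,missingness,truth,scenario overrides of the template
#'   defaults. `missingness` is the probability a call is dropped,
#'   uniformly over cells (`dropout = "uniform"`), or with per-locus rates
#'   drawn from a Beta distribution with this mean (`dropout = "beta"`,
#'   shape `beta_shape`), emulating locus-structured GBS dropout.
#' @param dropout missingness structure (see above).
#' @param beta_shape first Beta shape parameter for `dropout = "beta"`.
#' @return A list of class `study_template`.
#' @export
study_template <- function(name = c("hz2", "local", "popstat"),
                           n_loci = NULL, missingness = 0,
                           truth = NULL, scenario = NULL,
                           dropout = c("uniform", "beta"), beta_shape = 2) {
  name <- match.arg(name)
  dropout <- match.arg(dropout)
  stopifnot(missingness >= 0, missingness < 1)
  scenarios <- build_scenarios()
  if (name %in% c("hz2", "popstat")) {
    def_scenario <- scenarios$III
    def_truth <- list(N_NJPN = 825000, N_TajimaTango = 613000,
                      N_Kyushu = 1210000, N_Honshu = 1490000,
                      N_Ancestor = 432000,
                      t1 = 566000, t2 = 1050000, t3 = 4560000)
    def_loci <- if (name == "hz2") 1014L else 2453L
    populations <- list(
      "N.JPN" = c("Kaga", "Maiduru", "Miyadu", "Obama", "Sabae"),
      "Tajima-Tango" = c("Amino", "Hamasaka", "Kinosaki", "Kumihama", "Toyooka"),
      "Kyushu" = c("Fukue", "Hiwaki", "Izumi", "Kadusa", "Kikai"),
      "Honshu" = c("Ayabe", "Iwami", "Kasumi", "Matsue", "Tottori")
    )
    total_length <- if (name == "popstat") 45968L else NA_integer_
  } else {
    def_scenario <- scenarios$out_of_nk
    def_truth <- list(N_SSaga = 1326000, N_NSaga = 1224000, t = 510000)
    def_loci <- 698L
    populations <- list("S.Saga" = "Ogi", "N.Saga" = "Umejiro")
    total_length <- NA_integer_
  }
  structure(list(
    name = name,
    scenario = scenario %||% def_scenario,
    truth = truth %||% def_truth,
    n_loci = as.integer(n_loci %||% def_loci),
    missingness = missingness, dropout = dropout, beta_shape = beta_shape,
    populations = populations, total_length = total_length
  ), class = "study_template")
}

#' Generate a synthetic dataset from a template
#'
#' Simulates genotypes under the template's scenario and true parameters
#' via the coalescent SNP simulator, relabels individuals with the
#' template's population names, applies missingness, and (optionally)
#' writes VCF + popmap + a JSON truth record to `out_dir`. Deterministic
#' given `seed`.
#'
#' @param template a [study_template()] (or a template name).
#' @param seed integer seed.
#' @param out_dir optional directory; when given, writes
#'   `genotypes.vcf`, `popmap.tsv` and `truth.json` there.
#' @return A list with `genotypes`, `popmap` and `truth` (the template's
#'   true parameters plus generation metadata).
#' @export
generate_dataset <- function(template, seed = 1L, out_dir = NULL) {
  if (is.character(template)) template <- study_template(template)
  stopifnot(inherits(template, "study_template"))
  sim <- simulate_snps(template$scenario, template$truth, template$n_loci,
                       seed = seed)
  gm <- sim$genotypes
  pm <- sim$popmap
  # relabel: individuals of group g spread over the template's populations
  pops <- template$populations
  pm$population <- unlist(lapply(unique(pm$group), function(g) {
    n <- sum(pm$group == g)
    rep_len(pops[[g]], n)
  }))
  gm$total_length <- template$total_length
  if (template$missingness > 0) {
    gm <- withr_seed(seed + 1L, {
      apply_missingness(gm, template$missingness, template$dropout,
                        template$beta_shape)
    })
  }
  truth <- c(template$truth,
             list(scenario = template$scenario$name, template = template$name,
                  n_loci = template$n_loci, seed = seed,
                  missingness = template$missingness))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(gm, file.path(out_dir, "genotypes.vcf"))
    write_popmap(pm, file.path(out_dir, "popmap.tsv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(genotypes = gm, popmap = pm, truth = truth)
}

apply_missingness <- function(gm, rate, dropout, beta_shape) {
  n_ind <- length(gm$individuals)
  n_loci <- nrow(gm$loci)
  if (dropout == "uniform") {
    drop <- matrix(stats::runif(n_ind * n_loci) < rate, n_ind, n_loci)
  } else {
    # per-locus dropout rates ~ Beta(a, b) with mean `rate`
    a <- beta_shape
    b <- a * (1 - rate) / rate
    locus_rate <- stats::rbeta(n_loci, a, b)
    drop <- matrix(stats::runif(n_ind * n_loci), n_ind, n_loci) <
      matrix(locus_rate, n_ind, n_loci, byrow = TRUE)
  }
  gm$calls[drop] <- NA_integer_
  gm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
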