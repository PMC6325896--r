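# Independent brute-force oracles used to check the package's statistics.
# These deliberately recompute everything by direct enumeration, not through
# the package's own aggregation paths.

# random small genotype matrix with optional missingness
random_genotypes <- function(n_ind, n_loci, miss = 0, seed = 1,
                             total_length = 1000L) {
  set.seed(seed)
  calls <- matrix(sample(0:2, n_ind * n_loci, replace = TRUE), n_ind, n_loci)
  if (miss > 0) calls[runif(n_ind * n_loci) < miss] <- NA_integer_
  rownames(calls) <- paste0("i", seq_len(n_ind))
  genotypes(
    calls,
    tibble::tibble(chrom = "chr1", pos = as.integer(seq_len(n_loci) * 50L),
                   ref = "A", alt = "G"),
    total_length = total_length
  )
}

even_popmap <- function(gm, n_groups = 2) {
  n <- length(gm$individuals)
  g <- rep_len(paste0("G", seq_len(n_groups)), n)
  g <- sort(g)
  tibble::tibble(individual = gm$individuals, population = paste0("p", g),
                 group = g)
}

# per-site mean pairwise allele difference, enumerated over all allele pairs
# (equals the unbiased gene diversity), summed and divided by total length
oracle_pi <- function(gm, pm, group) {
  ids <- pm$individual[pm$group == group]
  d <- gm$calls[match(ids, gm$individuals), , drop = FALSE]
  an_all <- colSums(!is.na(gm$calls)) * 2
  ac_all <- colSums(gm$calls, na.rm = TRUE)
  variant <- ac_all > 0 & ac_all < an_all
  total <- 0
  for (l in which(variant)) {
    alleles <- unlist(lapply(d[, l], function(x) {
      if (is.na(x)) NULL else c(rep(1, x), rep(0, 2 - x))
    }))
    n <- length(alleles)
    if (n < 2) next
    diff_sum <- 0
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      diff_sum <- diff_sum + (alleles[a] != alleles[b])
    }
    total <- total + diff_sum / choose(n, 2)
  }
  unname(total / gm$total_length)
}

# straight-line per-locus recomputation of the full summary vector
oracle_summary_stats <- function(gm, pm, layout) {
  freq_of <- function(group, l) {
    ids <- pm$individual[pm$group == group]
    d <- gm$calls[match(ids, gm$individuals), l]
    n <- sum(!is.na(d))
    if (n == 0) return(c(p = NA, an = 0))
    c(p = sum(d, na.rm = TRUE) / (2 * n), an = 2 * n)
  }
  n_loci <- nrow(gm$loci)
  out <- numeric(0)
  for (g in layout$singles) {
    gd <- c()
    for (l in seq_len(n_loci)) {
      f <- freq_of(g, l)
      if (f["an"] >= 2) {
        p <- f["p"]
        gd <- c(gd, (f["an"] / (f["an"] - 1)) * (1 - p^2 - (1 - p)^2))
      }
    }
    out <- c(out, if (length(gd)) mean(gd == 0) else 0,
             if (any(gd > 0)) mean(gd[gd > 0]) else 0)
  }
  for (pr in layout$pairs) {
    dv <- c()
    for (l in seq_len(n_loci)) {
      fx <- freq_of(pr[1], l); fy <- freq_of(pr[2], l)
      if (fx["an"] == 0 || fy["an"] == 0) next
      px <- fx["p"]; py <- fy["p"]
      if (px == py) { dv <- c(dv, 0); next }
      jxy <- px * py + (1 - px) * (1 - py)
      jx <- px^2 + (1 - px)^2
      jy <- py^2 + (1 - py)^2
      d <- if (jxy == 0) layout$nei_cap else -log(jxy / sqrt(jx * jy))
      dv <- c(dv, d)
    }
    nn <- dv[dv > 0]
    out <- c(out, if (length(dv)) mean(dv == 0) else 0,
             if (length(nn) >= 2) var(nn) else 0)
  }
  for (tr in layout$trios) {
    av <- c()
    for (l in seq_len(n_loci)) {
      fa <- freq_of(tr[1], l); f1 <- freq_of(tr[2], l); f2 <- freq_of(tr[3], l)
      if (fa["an"] == 0 || f1["an"] == 0 || f2["an"] == 0) next
      if (abs(f1["p"] - f2["p"]) < layout$adm_tol) next
      av <- c(av, (fa["p"] - f2["p"]) / (f1["p"] - f2["p"]))
    }
    nn <- av[av != 0]
    out <- c(out, if (length(av)) mean(av == 0) else 0,
             if (length(nn)) mean(nn) else 0,
             if (length(nn) >= 2) var(nn) else 0,
             if (length(av)) mean(av) else 0)
  }
  unname(out)
}

# enumeration oracle for the three-state fixed-allele classification
oracle_classify <- function(fa, fb, fc) {
  is_fixed <- function(f) !is.na(f) && (f == 0 || f == 1)
  if (!is_fixed(fa) || !is_fixed(fb) || !is_fixed(fc)) return("unclassified")
  if (fa == fb && fb == fc) return("unclassified")
  if (fa == fb) return("AB")
  if (fa == fc) return("AC")
  "BC"
}

# write a VCF by hand (independent of write_vcf) for parser tests
write_manual_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
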