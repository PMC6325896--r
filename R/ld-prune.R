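#' Pairwise genotypic r-squared between two loci
#'
#' Squared Pearson correlation of alt-allele dosages over individuals called
#' at both loci — the composite LD measure plink's `--indep-pairwise` uses.
#' `NA` when either locus is monomorphic on the pairwise-complete set (the
#' correlation is undefined there).
#'
#' @param gm a `gbs_genotypes` object.
#' @param i,j locus indices; must lie on the same chromosome.
#' @return r^2 in \[0,1\], or `NA`.
#' @export
pairwise_r2 <- function(gm, i, j) {
  if (gm$loci$chrom[i] != gm$loci$chrom[j]) {
    stop("loci ", i, " and ", j, " are on different chromosomes", call. = FALSE)
  }
  x <- gm$calls[, i]
  y <- gm$calls[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' LD pruning configuration
#'
#' @param window_kb physical window width in kb (default 12.5).
#' @param step number of variants to slide the window by (default 5).
#' @param r2_max r^2 threshold above which a pair is pruned (default 0.2).
#' @param seed integer seed controlling which member of an offending pair is
#'   removed.
#' @param removal `"random"` (default; one member of the pair removed
#'   uniformly at random, as described for the study's pruning step) or
#'   `"maf"` (remove the member with the lower minor-allele frequency,
#'   plink's behaviour).
#' @return A list of class `prune_config`.
#' @export
prune_config <- function(window_kb = 12.5, step = 5L, r2_max = 0.2,
                         seed = 1L, removal = c("random", "maf")) {
  removal <- match.arg(removal)
  stopifnot(window_kb > 0, step >= 1, r2_max >= 0, r2_max <= 1)
  structure(list(window_kb = window_kb, step = as.integer(step),
                 r2_max = r2_max, seed = as.integer(seed), removal = removal),
            class = "prune_config")
}

# anchored windows over the retained loci of one chromosome: list of integer
# vectors of (original) locus indices. Anchors step over retained variants.
prune_windows <- function(pos, retained_idx, window_kb, step) {
  out <- list()
  s <- 1L
  n <- length(retained_idx)
  while (s <= n) {
    anchor <- retained_idx[s]
    in_win <- retained_idx[retained_idx >= anchor &
                             pos[retained_idx] - pos[anchor] <= window_kb * 1000]
    if (length(in_win) >= 2L) out[[length(out) + 1L]] <- in_win
    s <- s + step
  }
  out
}

#' Windowed LD pruning of a genotype matrix
#'
#' Reproduces plink's `--indep-pairwise <window kb> <step> <r2>` scheme at the
#' genotype level: within each physical window (anchored at every `step`-th
#' retained variant along a chromosome), pairs of retained SNPs with
#' r^2 above `r2_max` are broken by removing one member — chosen uniformly at
#' random under the configured seed (or by lower minor-allele frequency in
#' `"maf"` mode) — until no offending pair remains. Deterministic given the
#' seed; output locus order is preserved.
#'
#' @param gm a `gbs_genotypes` object with loci sorted by chromosome and
#'   position (as produced by [read_vcf()]).
#' @param cfg a [prune_config()].
#' @return The pruned `gbs_genotypes`.
#' @seealso [prune_audit()] to verify the post-condition on the output.
#' @export
ld_prune <- function(gm, cfg = prune_config()) {
  validate_genotypes(gm)
  stopifnot(inherits(cfg, "prune_config"))
  keep <- rep(TRUE, nrow(gm$loci))
  pos <- gm$loci$pos
  maf <- locus_maf(gm)
  withr_seed(cfg$seed, {
    for (chr in unique(gm$loci$chrom)) {
      chr_idx <- which(gm$loci$chrom == chr)
      s <- 1L
      repeat {
        retained <- chr_idx[keep[chr_idx]]
        if (s > length(retained)) break
        anchor <- retained[s]
        win <- retained[retained >= anchor &
                          pos[retained] - pos[anchor] <= cfg$window_kb * 1000]
        if (length(win) >= 2L) {
          repeat {
            win <- win[keep[win]]
            off <- offending_pair(gm, win, cfg$r2_max)
            if (is.null(off)) break
            drop <- pick_removal(off, maf, cfg$removal)
            keep[drop] <- FALSE
          }
        }
        s <- s + cfg$step
      }
    }
  })
  subset_genotypes(gm, loci = keep)
}

# first pair (in index order) among `idx` with r2 > r2_max, or NULL
offending_pair <- function(gm, idx, r2_max) {
  if (length(idx) < 2L) return(NULL)
  for (a in seq_len(length(idx) - 1L)) {
    for (b in seq(a + 1L, length(idx))) {
      r2 <- pairwise_r2(gm, idx[a], idx[b])
      if (!is.na(r2) && r2 > r2_max) return(c(idx[a], idx[b]))
    }
  }
  NULL
}

pick_removal <- function(pair, maf, removal) {
  if (removal == "maf") {
    if (maf[pair[1]] == maf[pair[2]]) pair[2] else pair[which.min(maf[pair])]
  } else {
    pair[sample.int(2L, 1L)]
  }
}

locus_maf <- function(gm) {
  ac <- colSums(gm$calls, na.rm = TRUE)
  an <- 2 * colSums(!is.na(gm$calls))
  p <- ifelse(an > 0, ac / an, NA_real_)
  pmin(p, 1 - p)
}

#' Audit the LD-pruning post-condition
#'
#' Exhaustively re-enumerates the same anchored windows [ld_prune()] uses on
#' the pruned matrix and returns every retained same-window pair whose r^2
#' exceeds the threshold. An empty result certifies the pruning
#' post-condition.
#'
#' @inheritParams ld_prune
#' @return A tibble with columns `chrom`, `i`, `j`, `r2` (zero rows when the
#'   post-condition holds).
#' @export
prune_audit <- function(gm, cfg = prune_config()) {
  validate_genotypes(gm)
  out <- list()
  for (chr in unique(gm$loci$chrom)) {
    chr_idx <- which(gm$loci$chrom == chr)
    wins <- prune_windows(gm$loci$pos, chr_idx, cfg$window_kb, cfg$step)
    for (win in wins) {
      for (a in seq_len(length(win) - 1L)) {
        for (b in seq(a + 1L, length(win))) {
          r2 <- pairwise_r2(gm, win[a], win[b])
          if (!is.na(r2) && r2 > cfg$r2_max) {
            out[[length(out) + 1L]] <- tibble::tibble(
              chrom = chr, i = win[a], j = win[b], r2 = r2
            )
          }
        }
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(chrom = character(), i = integer(), j = integer(),
                   r2 = double())
  }
}

# run code with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}
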