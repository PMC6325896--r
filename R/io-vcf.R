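#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF (v4.x) with diploid GT fields into a [genotypes()] object of
#' alt-allele dosages. Only biallelic SNP records are representable; what to
#' do with multi-allelic records is configurable.
#'
#' Within each chromosome, records are sorted by position (chromosome blocks
#' keep their order of first appearance).
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @param multiallelic `"error"` (default) to fail listing the offending
#'   records, or `"drop"` to silently discard them.
#' @param total_length optional surveyed sequence length (bp) to attach.
#' @return A `gbs_genotypes` object.
#' @export
read_vcf <- function(path, multiallelic = c("error", "drop"),
                     total_length = NA_integer_) {
  multiallelic <- match.arg(multiallelic)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path, call. = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | nchar(fix$REF) != 1L |
    nchar(fix$ALT) != 1L
  if (any(multi)) {
    if (multiallelic == "error") {
      stop("non-biallelic-SNP record(s) at ",
           paste(utils::head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 5L),
                 collapse = ", "),
           " (use multiallelic = \"drop\" to discard)", call. = FALSE)
    }
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  inds <- colnames(gt)
  dosage <- gt_to_dosage(gt)  # loci x individuals
  loci <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  ord <- order(match(loci$chrom, unique(loci$chrom)), loci$pos)
  genotypes(
    calls = t(dosage[ord, , drop = FALSE]),
    loci = loci[ord, ],
    individuals = inds,
    total_length = total_length
  )
}

# GT strings (loci x individuals) -> integer dosage matrix, NA for missing
gt_to_dosage <- function(gt) {
  gt <- as.matrix(gt)
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  alleles <- strsplit(u, "[/|]")
  n_all <- lengths(alleles)
  missing_codes <- vapply(alleles, function(a) all(a == "."), logical(1))
  if (any(n_all != 2L & !missing_codes)) {
    stop("non-diploid GT field(s): ",
         paste(utils::head(u[n_all != 2L & !missing_codes], 5L), collapse = ", "),
         call. = FALSE)
  }
  dos <- vapply(seq_along(u), function(i) {
    a <- alleles[[i]]
    if (any(a == ".")) return(NA_integer_)
    if (!all(a %in% c("0", "1"))) {
      stop("GT allele index outside {0,1} in '", u[i],
           "' (record not biallelic?)", call. = FALSE)
    }
    sum(a == "1")
  }, integer(1))
  out <- dos[match(gt, u)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal GT-only VCFv4.2 file (plain text). Together with
#' [read_vcf()] this round-trips calls, loci and individual order exactly.
#'
#' @param gm a `gbs_genotypes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  validate_genotypes(gm)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(gm$loci), ncol = length(gm$individuals))
  d <- t(gm$calls)  # loci x individuals
  ok <- !is.na(d)
  gt[ok] <- gt_code[as.character(d[ok])]
  body <- paste(
    gm$loci$chrom, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt, ".", "PASS", ".",
    "GT", apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gbsabc",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$individuals), collapse = "\t")
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Stacks-style locus filtering on genotype call rates
#'
#' Keeps a locus when it is genotyped (non-missing) in at least
#' `min_fraction` of the individuals of each of at least `min_populations`
#' populations — the genotype-level analogue of the Stacks `populations`
#' `-p`/`-r` options used to build GBS SNP datasets. The counting unit is the
#' population by default; set `by = "group"` for datasets defined as "loci
#' sequenced in one or more populations in each group".
#'
#' @param gm a `gbs_genotypes` object.
#' @param pm population map covering all individuals of `gm`.
#' @param min_populations minimum number of units (populations or groups)
#'   that must each reach the call-rate threshold (`-p`).
#' @param min_fraction minimum fraction of called individuals within a unit
#'   (`-r`), in (0, 1].
#' @param by counting unit, `"population"` (default) or `"group"`.
#' @return A `gbs_genotypes` containing the retained loci, order preserved.
#' @export
filter_loci <- function(gm, pm, min_populations, min_fraction,
                        by = c("population", "group")) {
  by <- match.arg(by)
  validate_genotypes(gm)
  pm <- join_popmap(gm, pm)
  unit <- if (by == "population") pm$population else pm$group
  units <- unique(unit)
  if (min_populations > length(units)) {
    stop("min_populations = ", min_populations, " exceeds the ",
         length(units), " available ", by, "(s)", call. = FALSE)
  }
  if (min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]", call. = FALSE)
  }
  called <- !is.na(gm$calls)
  n_ok <- rowSums(vapply(units, function(u) {
    rows <- unit == u
    colMeans(called[rows, , drop = FALSE]) >= min_fraction - 1e-12
  }, logical(ncol(called))) |> matrix(ncol = length(units)))
  keep <- n_ok >= min_populations
  subset_genotypes(gm, loci = keep)
}
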