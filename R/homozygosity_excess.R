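#' Tally allele and homozygote counts for one variant
#'
#' @param genotypes integer vector of alternate-allele dosages (0, 1, 2) with
#'   `NA` for missing calls, over the analyzed sample subset.
#' @return list with `n` (called individuals), `c` (minor allele count among
#'   the `2n` called alleles), `hom` (minor-allele homozygote count) and
#'   `maf` (`c / 2n`; `NA` when `n == 0`).
#' @export
tally_variant <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  if (length(g) && !all(g %in% 0:2)) stop("genotypes must be dosages in {0, 1, 2, NA}")
  n <- length(g)
  if (n == 0L) return(list(n = 0L, c = 0L, hom = 0L, maf = NA_real_))
  alt <- sum(g)
  if (alt <= n) {           # alt is the minor allele (ties go to alt)
    cc <- alt
    hom <- sum(g == 2L)
  } else {
    cc <- 2L * n - alt
    hom <- sum(g == 0L)
  }
  list(n = as.integer(n), c = as.integer(cc), hom = as.integer(hom),
       maf = cc / (2 * n))
}

#' Expected number of minor-allele homozygotes under random mating
#'
#' Two estimators are provided. The default `"pairing"` form
#' `n * c * (c - 1) / (2n * (2n - 1))` is the expectation under random union
#' of the `2n` observed gametes without replacement: it is exact for the
#' finite sample and gives 0 for singletons (a lone allele cannot pair with
#' itself). The `"p2"` plug-in `n * (c / 2n)^2` is the textbook
#' Hardy-Weinberg expectation; it is biased upward for rare variants.
#'
#' @param n number of called individuals (>= 1).
#' @param c minor allele count (0..2n). Both arguments are vectorised.
#' @param method `"pairing"` (default) or `"p2"`.
#' @return expected homozygote count(s).
#' @examples
#' expected_homozygotes(4, 2)            # 4 * 2 * 1 / (8 * 7) = 1/7
#' expected_homozygotes(4, 2, "p2")      # 4 * (2/8)^2 = 0.25
#' @export
expected_homozygotes <- function(n, c, method = c("pairing", "p2")) {
  method <- match.arg(method)
  if (any(n < 1)) stop("n must be >= 1")
  if (any(c < 0 | c > 2 * n)) stop("allele count c must be in 0..2n")
  if (method == "pairing") {
    n * c * (c - 1) / (2 * n * (2 * n - 1))
  } else {
    n * (c / (2 * n))^2
  }
}

# Tally every row of a dosage matrix (variants x individuals) over a column
# subset; returns a data.table, one row per variant. Multi-allelic rows must
# have been removed upstream (the VCF reader does this).
tally_matrix <- function(geno, cols = NULL) {
  if (!is.null(cols)) geno <- geno[, cols, drop = FALSE]
  called <- !is.na(geno)
  n <- as.integer(rowSums(called))
  alt <- as.integer(rowSums(geno, na.rm = TRUE))
  n_alt_hom <- as.integer(rowSums(geno == 2L & called))
  n_ref_hom <- as.integer(rowSums(geno == 0L & called))
  minor_is_alt <- alt <= n
  cc <- ifelse(minor_is_alt, alt, 2L * n - alt)
  hom <- ifelse(minor_is_alt, n_alt_hom, n_ref_hom)
  data.table::data.table(n = n, c = as.integer(cc), hom = as.integer(hom),
                         maf = ifelse(n > 0, cc / (2 * n), NA_real_))
}

#' Default MAF bin edges
#'
#' Half-decade edges 0.0005, 0.001, 0.002, 0.005, 0.01, 0.02, 0.05 with an
#' open top bin to 0.5, binning variants from rarest to common.
#'
#' @return numeric vector of bin edges spanning (0, 0.5].
#' @export
default_maf_bins <- function() {
  c(0, 0.0005, 0.001, 0.002, 0.005, 0.01, 0.02, 0.05, 0.5)
}

#' Observed/expected rare-homozygote ratio table
#'
#' For each MAF bin (and optionally each inbreeding stratum) sums observed
#' minor-allele homozygote counts and their random-mating expectations over
#' all variants whose within-subset MAF falls in the bin, and reports the
#' ratio. MAF, allele counts and expectations are recomputed within each
#' stratum's sample subset, so a variant may fall in different bins in
#' different strata. Under random mating the ratio is ~1 in every bin;
#' consanguinity inflates it, increasingly so at rarer MAF.
#'
#' @param geno integer dosage matrix, variants in rows, individuals in
#'   columns (colnames = individual ids); values 0/1/2/NA.
#' @param maf_bins bin edges covering (0, 0.5]; default [default_maf_bins()].
#' @param strata optional named character vector mapping individual id to
#'   stratum label (e.g. from [stratify_calls()]); when omitted a single
#'   `"all"` stratum over every column is used.
#' @param method expectation estimator, see [expected_homozygotes()].
#' @param min_call_rate variants with a lower within-stratum call rate are
#'   excluded (default 0.7).
#' @return data.table with columns `stratum`, `bin_low`, `bin_high`,
#'   `n_variants`, `observed`, `expected`, `ratio` (`NA` where the summed
#'   expectation is 0: undefined, not zero).
#' @export
ratio_table <- function(geno, maf_bins = default_maf_bins(), strata = NULL,
                        method = c("pairing", "p2"), min_call_rate = 0.7) {
  method <- match.arg(method)
  maf_bins <- sort(unique(maf_bins))
  if (min(maf_bins) > 0 || max(maf_bins) < 0.5) {
    stop("maf_bins must cover (0, 0.5]")
  }
  if (is.null(strata)) {
    groups <- list(all = colnames(geno) %||% seq_len(ncol(geno)))
  } else {
    if (is.null(names(strata))) stop("strata must be a named vector (iid -> stratum)")
    ids <- intersect(colnames(geno), names(strata))
    groups <- split(ids, factor(strata[ids], levels = sort(unique(strata))))
  }
  out <- lapply(names(groups), function(gname) {
    cols <- groups[[gname]]
    if (!length(cols)) {
      warning("empty stratum: ", gname)
      return(NULL)
    }
    tv <- tally_matrix(geno, cols)
    keep <- tv$n >= pmax(1, ceiling(min_call_rate * length(cols))) &
      !is.na(tv$maf) & tv$maf > 0
    tv <- tv[keep]
    if (!nrow(tv)) {
      warning("no analyzable variants in stratum: ", gname)
      return(NULL)
    }
    tv[, expected := expected_homozygotes(n, c, method = method)]
    tv[, bin := as.character(cut(maf, breaks = maf_bins, right = TRUE,
                                 include.lowest = FALSE))]
    agg <- tv[!is.na(bin),
              .(n_variants = .N, observed = sum(hom), expected = sum(expected)),
              by = bin]
    lo <- maf_bins[-length(maf_bins)]
    hi <- maf_bins[-1L]
    full <- data.table::data.table(
      bin = as.character(cut((lo + hi) / 2, breaks = maf_bins, right = TRUE)),
      bin_low = lo, bin_high = hi
    )
    agg <- agg[full, on = "bin"]
    agg[is.na(n_variants), `:=`(n_variants = 0L, observed = 0, expected = 0)]
    agg[, ratio := ifelse(expected > 0, observed / expected, NA_real_)]
    agg[, stratum := gname]
    agg[, .(stratum, bin_low, bin_high, n_variants, observed, expected, ratio)]
  })
  out <- data.table::rbindlist(out[!vapply(out, is.null, logical(1))])
  out[]
}

#' Read genotype dosages from a VCF
#'
#' Reads a (possibly bgzipped) VCF with vcfR and returns an integer dosage
#' matrix (variants x individuals) of alternate-allele counts. Multi-allelic
#' records are skipped with a warning; only the GT field is used.
#'
#' @param path VCF path.
#' @return integer matrix with `NA` for missing genotypes; rownames are
#'   `chrom:pos`, colnames sample ids.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = list(paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v)),
                                colnames(gt)))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean == "0/1" | clean == "1/0"] <- 1L
  dos[clean == "1/1"] <- 2L
  dos
}

#' Write a ratio table to long-format TSV
#'
#' @param tab output of [ratio_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(tab, path) {
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
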