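# Merge possibly-overlapping intervals (cM) into a disjoint union.
merge_intervals <- function(start, end) {
  if (!length(start)) return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  data.frame(start = c(out_s, ms), end = c(out_e, me))
}

#' Specify a synthetic cohort
#'
#' Describes a cohort of diploid individuals whose parents have known degrees
#' of relatedness, for end-to-end testing of the ROH machinery without any
#' external data. Autozygous tracts follow the block-inheritance model;
#' genotypes are Hardy-Weinberg outside tracts and forced homozygous inside;
#' physical coordinates come from a constant bp-per-cM embedding.
#'
#' @param n_individuals cohort size.
#' @param mixture named numeric weights over the parental-relatedness
#'   categories `"unrelated"` and `"2"`..`"6"`; must sum to 1. The default
#'   emulates a strongly consanguineous population in which roughly one in
#'   four individuals is the offspring of first cousins or closer relatives.
#' @param n_variants number of bi-allelic SNV sites.
#' @param freq_range allele-frequency spectrum: frequencies are drawn
#'   log-uniformly over this range (default 5e-4 to 0.5, enriching rare
#'   variants), or supply `freqs` directly.
#' @param freqs optional explicit per-site frequency vector (length
#'   `n_variants`), overriding `freq_range`.
#' @param lengths_cM chromosome genetic-length table.
#' @param bp_per_cM physical embedding scale (default 1 Mb per cM).
#' @param background_rate expected number of short background ROH per genome
#'   (Poisson), mimicking endogamy; lengths drawn uniformly on 1-3 cM.
#' @param min_emit_cM emission floor: tracts shorter than this are genuinely
#'   autozygous but produce no ROH record (a crude detectability limit).
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_individuals = 100,
                        mixture = c(unrelated = 0.55, `5` = 0.10, `4` = 0.10,
                                    `3` = 0.20, `2` = 0.05),
                        n_variants = 20000,
                        freq_range = c(5e-4, 0.5),
                        freqs = NULL,
                        lengths_cM = default_chrom_lengths(),
                        bp_per_cM = 1e6,
                        background_rate = 2,
                        min_emit_cM = 0.5,
                        seed = 1L) {
  if (n_individuals < 1 || n_variants < 1) stop("counts must be positive")
  allowed <- c("unrelated", "2", "3", "4", "5", "6")
  if (is.null(names(mixture)) || !all(names(mixture) %in% allowed)) {
    stop("mixture must be named with categories among: ",
         paste(allowed, collapse = ", "))
  }
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (any(mixture < 0)) stop("mixture weights must be non-negative")
  if (!is.null(freqs) && length(freqs) != n_variants) {
    stop("freqs must have length n_variants")
  }
  if (background_rate < 0) stop("background_rate must be >= 0")
  structure(list(n_individuals = as.integer(n_individuals), mixture = mixture,
                 n_variants = as.integer(n_variants), freq_range = freq_range,
                 freqs = freqs, lengths_cM = lengths_cM, bp_per_cM = bp_per_cM,
                 background_rate = background_rate, min_emit_cM = min_emit_cM,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws, per individual, a parental-relatedness category from the mixture;
#' simulates autozygous loop tracts with [simulate_genome()] (none for
#' `"unrelated"`); adds short background tracts at the configured Poisson
#' rate to every individual; and emits genotypes at each site - Hardy-Weinberg
#' from the site frequency outside tracts, a single allele drawn and doubled
#' inside tracts. ROH records are the disjoint union of an individual's
#' tracts at genetic length >= the emission floor.
#'
#' @param spec a [cohort_spec()].
#' @return a `synthetic_cohort` list: `spec`; `truth` (data.table `iid`,
#'   `true_degree`); `tracts` (merged per-individual tracts: `iid`, `chrom`,
#'   `start_cM`, `end_cM`); `sites` (`chrom`, `pos_bp`, `freq`); `geno`
#'   (integer dosage matrix, variants x individuals); `roh` (records in the
#'   layout of [read_plink_hom()] plus `cm`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_individuals
  L <- spec$lengths_cM
  iids <- sprintf("F%04d:I%04d", seq_len(n), seq_len(n))
  cats <- names(spec$mixture)
  true_degree <- sample(cats, n, replace = TRUE, prob = spec$mixture)

  # variant sites: placed uniformly in genetic coordinates, embedded linearly
  site_chrom <- sample(names(L), spec$n_variants, replace = TRUE, prob = L)
  site_cm <- stats::runif(spec$n_variants, 0, L[site_chrom])
  o <- order(match(site_chrom, names(L)), site_cm)
  site_chrom <- site_chrom[o]; site_cm <- site_cm[o]
  site_bp <- pmax(1, round(site_cm * spec$bp_per_cM))
  if (is.null(spec$freqs)) {
    lr <- log(spec$freq_range)
    freq <- exp(stats::runif(spec$n_variants, lr[1], lr[2]))
  } else {
    freq <- spec$freqs
  }

  tract_list <- vector("list", n)
  geno <- matrix(NA_integer_, nrow = spec$n_variants, ncol = n)
  for (i in seq_len(n)) {
    segs <- NULL
    if (true_degree[i] != "unrelated") {
      g <- simulate_genome(as.integer(true_degree[i]), lengths_cM = L)
      if (nrow(g)) segs <- data.frame(chrom = g$chrom, start = g$start_cM,
                                      end = g$start_cM + g$length_cM)
    }
    nb <- stats::rpois(1, spec$background_rate)
    if (nb > 0) {
      blen <- stats::runif(nb, 1, 3)
      bchrom <- sample(names(L), nb, replace = TRUE, prob = L)
      ok <- blen < L[bchrom]
      if (any(ok)) {
        bstart <- stats::runif(sum(ok), 0, L[bchrom[ok]] - blen[ok])
        segs <- rbind(segs, data.frame(chrom = bchrom[ok], start = bstart,
                                       end = bstart + blen[ok]))
      }
    }
    merged <- NULL
    if (!is.null(segs) && nrow(segs)) {
      merged <- do.call(rbind, lapply(split(segs, segs$chrom), function(d) {
        m <- merge_intervals(d$start, d$end)
        cbind(chrom = d$chrom[1], m)
      }))
      rownames(merged) <- NULL
    }
    tract_list[i] <- list(merged)   # [[<- NULL would delete the element

    in_tract <- rep(FALSE, spec$n_variants)
    if (!is.null(merged)) {
      for (ch in unique(merged$chrom)) {
        idx <- which(site_chrom == ch)
        if (!length(idx)) next
        mm <- merged[merged$chrom == ch, , drop = FALSE]
        bounds <- as.vector(rbind(mm$start, mm$end))
        in_tract[idx] <- findInterval(site_cm[idx], bounds) %% 2L == 1L
      }
    }
    g <- integer(spec$n_variants)
    out_i <- !in_tract
    g[out_i] <- stats::rbinom(sum(out_i), 2L, freq[out_i])
    g[in_tract] <- 2L * stats::rbinom(sum(in_tract), 1L, freq[in_tract])
    geno[, i] <- g
  }

  truth <- data.table::data.table(iid = iids, true_degree = true_degree)
  tr <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    m <- tract_list[[i]]
    if (is.null(m)) return(NULL)
    data.table::data.table(iid = iids[i], chrom = m$chrom,
                           start_cM = m$start, end_cM = m$end)
  }))
  if (!nrow(tr)) {
    tr <- data.table::data.table(iid = character(0), chrom = character(0),
                                 start_cM = numeric(0), end_cM = numeric(0))
  }
  emit <- tr[end_cM - start_cM >= spec$min_emit_cM]
  roh <- data.table::data.table(
    iid = emit$iid, chrom = emit$chrom,
    start_bp = pmax(1, round(emit$start_cM * spec$bp_per_cM) + 1),
    end_bp = round(emit$end_cM * spec$bp_per_cM),
    cm = emit$end_cM - emit$start_cM
  )
  roh[, kb := (end_bp - start_bp + 1) / 1000]
  colnames(geno) <- iids
  rownames(geno) <- paste0(site_chrom, ":", site_bp)
  structure(list(spec = spec, truth = truth, tracts = tr,
                 sites = data.table::data.table(chrom = site_chrom,
                                                pos_bp = site_bp,
                                                cm = site_cm, freq = freq),
                 geno = geno, roh = roh),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d individuals, %d variants, %d ROH records\n",
              x$spec$n_individuals, x$spec$n_variants, nrow(x$roh)))
  print(table(x$truth$true_degree))
  invisible(x)
}

#' Write cohort files
#'
#' Writes, under `outdir`: `cohort.vcf` (GT-only, bi-allelic SNVs),
#' `cohort.hom` (PLINK `.hom` layout; SNP/quality columns are placeholders),
#' `tracts.bed` (true merged tracts, 0-based half-open) and `truth.tsv`
#' (`iid`, `true_degree`). All files round-trip through the package readers.
#'
#' @param cohort a `synthetic_cohort`.
#' @param outdir output directory (created if absent).
#' @return named character vector of the four paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(outdir, "cohort.vcf"),
             hom = file.path(outdir, "cohort.hom"),
             bed = file.path(outdir, "tracts.bed"),
             truth = file.path(outdir, "truth.tsv"))

  ids <- cohort$truth$iid
  samp <- sub("^.*:", "", ids)
  gt <- matrix(".", nrow = nrow(cohort$geno), ncol = ncol(cohort$geno))
  gt[cohort$geno == 0L] <- "0/0"
  gt[cohort$geno == 1L] <- "0/1"
  gt[cohort$geno == 2L] <- "1/1"
  gt[is.na(cohort$geno)] <- "./."
  L <- cohort$spec$lengths_cM
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=autozyg-synthetic-cohort",
    sprintf("##contig=<ID=%s,length=%d>", names(L),
            as.integer(ceiling(L * cohort$spec$bp_per_cM)) + 1L),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samp), collapse = "\t")
  )
  body <- paste(cohort$sites$chrom, cohort$sites$pos_bp,
                sprintf("var%06d", seq_len(nrow(cohort$sites))),
                "A", "G", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), paths[["vcf"]])

  fid <- sub(":.*$", "", cohort$roh$iid)
  iid2 <- sub("^.*:", "", cohort$roh$iid)
  hom <- data.table::data.table(
    FID = fid, IID = iid2, PHE = -9, CHR = cohort$roh$chrom,
    SNP1 = ".", SNP2 = ".",
    POS1 = as.integer(cohort$roh$start_bp), POS2 = as.integer(cohort$roh$end_bp),
    KB = sprintf("%.3f", cohort$roh$kb), NSNP = 0, DENSITY = 0,
    PHOM = 1, PHET = 0
  )
  data.table::fwrite(hom, paths[["hom"]], sep = " ")

  bed <- data.table::data.table(
    chrom = cohort$tracts$chrom,
    start = as.integer(round(cohort$tracts$start_cM * cohort$spec$bp_per_cM)),
    end = as.integer(round(cohort$tracts$end_cM * cohort$spec$bp_per_cM)),
    name = cohort$tracts$iid
  )
  data.table::fwrite(bed, paths[["bed"]], sep = "\t", col.names = FALSE)

  data.table::fwrite(cohort$truth, paths[["truth"]], sep = "\t")
  invisible(paths)
}
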