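#' Construct a genetic map
#'
#' A genetic map is a set of per-chromosome anchor points relating physical
#' position (bp, 1-based) to cumulative genetic position (cM). Physical
#' positions between anchors are interpolated linearly; positions outside the
#' anchored range clamp to the terminal anchors.
#'
#' @param chrom character or integer vector of chromosome identifiers.
#' @param pos_bp integer vector of physical positions (bp).
#' @param cm numeric vector of cumulative genetic positions (cM).
#' @return An object of class `genetic_map`: a named list of data.frames
#'   (one per chromosome) with columns `pos_bp` and `cm`, sorted by position.
#' @examples
#' gm <- genetic_map(chrom = c(1, 1), pos_bp = c(0, 100e6), cm = c(0, 100))
#' interpolate_cM(gm, 1, 5e6)
#' @export
genetic_map <- function(chrom, pos_bp, cm) {
  if (length(chrom) != length(pos_bp) || length(pos_bp) != length(cm)) {
    stop("chrom, pos_bp and cm must have equal length")
  }
  if (any(is.na(pos_bp)) || any(is.na(cm))) stop("map anchors must not be NA")
  chrom <- as.character(chrom)
  sp <- split(data.frame(pos_bp = as.numeric(pos_bp), cm = as.numeric(cm)), chrom)
  sp <- lapply(sp, function(d) {
    d <- d[order(d$pos_bp), , drop = FALSE]
    if (anyDuplicated(d$pos_bp)) stop("duplicate physical positions within a chromosome")
    if (is.unsorted(d$cm)) stop("cumulative cM must be non-decreasing along each chromosome")
    if (d$cm[1] < 0) stop("cumulative cM must be >= 0")
    rownames(d) <- NULL
    d
  })
  structure(sp, class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", length(x), " chromosome(s): ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a genetic map from a plain-text file
#'
#' Expects at least three whitespace- or tab-delimited columns: chromosome,
#' physical position (bp), cumulative genetic position (cM). Extra columns
#' (e.g. a rate column between position and cM in 4-column map dialects) are
#' handled via `cols`. A header line is auto-detected.
#'
#' @param path path to the map file.
#' @param cols integer vector of length 3 giving the column indices of
#'   chromosome, bp position and cumulative cM. Default `c(1, 2, 3)`.
#' @return A `genetic_map`.
#' @export
read_genetic_map <- function(path, cols = c(1L, 2L, 3L)) {
  if (!file.exists(path)) stop("genetic map file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*\\S+\\s+[0-9]+(\\.[0-9]*)?\\s", first)
  d <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(d) < max(cols)) stop("map file has fewer columns than expected")
  chrom <- sub("^chr", "", as.character(d[[cols[1]]]))
  genetic_map(chrom = chrom, pos_bp = d[[cols[2]]], cm = d[[cols[3]]])
}

#' Interpolate genetic position at a physical coordinate
#'
#' Piecewise-linear interpolation between map anchors. Positions before the
#' first anchor take the first anchor's cM; positions past the last anchor
#' take the last anchor's cM.
#'
#' @param map a `genetic_map`.
#' @param chromosome chromosome identifier.
#' @param position physical position(s) in bp (vectorised).
#' @return numeric cM value(s).
#' @export
interpolate_cM <- function(map, chromosome, position) {
  stopifnot(inherits(map, "genetic_map"))
  chromosome <- as.character(chromosome)
  d <- map[[chromosome]]
  if (is.null(d)) stop("chromosome not present in genetic map: ", chromosome)
  if (nrow(d) == 1L) return(rep(d$cm, length(position)))
  stats::approx(d$pos_bp, d$cm, xout = position, rule = 2, ties = "ordered")$y
}

#' Genetic length of a physical interval
#'
#' @param map a `genetic_map`.
#' @param chromosome chromosome identifier.
#' @param start,end interval endpoints in bp, `start <= end` (vectorised).
#' @return genetic length(s) in cM, always >= 0.
#' @export
genetic_length <- function(map, chromosome, start, end) {
  if (any(start > end)) stop("interval start must not exceed end")
  interpolate_cM(map, chromosome, end) - interpolate_cM(map, chromosome, start)
}

#' Default autosomal genetic-length table
#'
#' Approximate sex-averaged genetic lengths (cM) of the 22 human autosomes,
#' on the deCODE scale (~35.4 Morgans in total). These are rounded literature
#' approximations intended as a sensible default for the block-inheritance
#' simulator; supply your own table (e.g. from [read_chrom_lengths()]) for
#' map-exact work.
#'
#' @return named numeric vector, names `"1"`..`"22"`, values in cM.
#' @export
default_chrom_lengths <- function() {
  c(`1` = 286, `2` = 269, `3` = 223, `4` = 214, `5` = 204,
    `6` = 192, `7` = 187, `8` = 168, `9` = 166, `10` = 181,
    `11` = 158, `12` = 175, `13` = 126, `14` = 119, `15` = 141,
    `16` = 134, `17` = 128, `18` = 117, `19` = 108, `20` = 108,
    `21` = 62, `22` = 74)
}

#' Read a chromosome genetic-length table
#'
#' Two-column TSV: chromosome identifier, genetic length in cM.
#'
#' @param path file path.
#' @return named numeric vector of cM lengths.
#' @export
read_chrom_lengths <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2) stop("chromosome length table needs two columns (chrom, cM)")
  len <- suppressWarnings(as.numeric(d[[2]]))
  if (any(is.na(len)) || any(len <= 0)) stop("all chromosome lengths must be positive numbers")
  names(len) <- sub("^chr", "", as.character(d[[1]]))
  len
}

#' Constant-rate genetic map
#'
#' Builds a two-anchor linear map per chromosome at a fixed bp-per-cM scale.
#' Used by the synthetic cohort generator to embed genetic coordinates in
#' physical space, and convenient for tests.
#'
#' @param lengths_cM named numeric vector of chromosome genetic lengths (cM).
#' @param bp_per_cM physical bp per cM (default 1 Mb/cM).
#' @return a `genetic_map`.
#' @export
constant_map <- function(lengths_cM = default_chrom_lengths(), bp_per_cM = 1e6) {
  chrom <- rep(names(lengths_cM), each = 2L)
  pos <- as.numeric(rbind(0, lengths_cM * bp_per_cM))
  cm <- as.numeric(rbind(0, lengths_cM))
  genetic_map(chrom = chrom, pos_bp = pos, cm = cm)
}
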