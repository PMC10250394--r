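#' Read PLINK .hom ROH calls
#'
#' Parses the whitespace-delimited `.hom` output of PLINK's `--homozyg`
#' caller. Requires at least the FID, IID, CHR, POS1, POS2 and KB columns;
#' any other columns are ignored. Individual id is formed as `FID:IID`.
#'
#' @param path path to a `.hom` file.
#' @return data.table with columns `iid`, `chrom`, `start_bp`, `end_bp`,
#'   `kb` (physical length), and `cm` (genetic length, `NA` until filled by
#'   [add_genetic_lengths()]).
#' @export
read_plink_hom <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty .hom file: ", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  required <- c("FID", "IID", "CHR", "POS1", "POS2", "KB")
  missing_cols <- setdiff(required, header)
  if (length(missing_cols)) {
    stop("missing required .hom column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (length(lines) == 1L) {
    return(data.table::data.table(iid = character(0), chrom = character(0),
                                  start_bp = numeric(0), end_bp = numeric(0),
                                  kb = numeric(0), cm = numeric(0)))
  }
  fields <- strsplit(trimws(lines[-1L]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    stop("malformed .hom line ", bad + 1L, ": expected ", length(header),
         " fields, found ", nf[bad])
  }
  m <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  num <- function(col) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop("non-numeric ", col, " at .hom line ", which(is.na(v))[1L] + 1L)
    }
    v
  }
  out <- data.table::data.table(
    iid = paste(m[, "FID"], m[, "IID"], sep = ":"),
    chrom = sub("^chr", "", m[, "CHR"]),
    start_bp = num("POS1"),
    end_bp = num("POS2"),
    kb = num("KB"),
    cm = NA_real_
  )
  if (any(out$end_bp < out$start_bp)) stop("ROH with end before start in ", path)
  out
}

#' Fill genetic lengths of ROH records from a genetic map
#'
#' @param records ROH records from [read_plink_hom()] (or any data.frame with
#'   `chrom`, `start_bp`, `end_bp`).
#' @param map a [genetic_map()].
#' @return the records with the `cm` column filled.
#' @export
add_genetic_lengths <- function(records, map) {
  records <- data.table::as.data.table(records)
  records[, cm := genetic_length(map, .BY[[1L]], start_bp, end_bp), by = chrom]
  records[]
}

#' Apply the ROH inclusion filters
#'
#' Retains calls with physical length >= `min_kb` kb AND genetic length
#' >= `min_cM` cM (defaults 500 kb and 1 cM), preserving input order.
#'
#' @param records ROH records with the `cm` column filled.
#' @param min_kb minimum physical length (kb).
#' @param min_cM minimum genetic length (cM).
#' @return the retained records.
#' @export
apply_roh_filters <- function(records, min_kb = 500, min_cM = 1.0) {
  records <- data.table::as.data.table(records)
  if (!("cm" %in% names(records)) || anyNA(records$cm)) {
    stop("genetic lengths must be filled (add_genetic_lengths) before filtering")
  }
  records[kb >= min_kb & cm >= min_cM]
}

#' Per-individual ROH summaries
#'
#' For each individual computes the classifier statistics: `n10`, the number
#' of ROHs with genetic length strictly greater than 10 cM; `s10`, the summed
#' genetic length of the 10 longest ROHs (all of them when fewer than 10);
#' and `total_ge1`, the summed genetic length of all retained ROHs. Apply
#' [apply_roh_filters()] first so that only calls >= 1 cM and >= 500 kb enter.
#'
#' @param records filtered ROH records with `iid` and `cm` columns.
#' @param ids optional character vector of individuals to report even when
#'   they have no ROH (summaries all zero).
#' @param n10_cM threshold for the long-ROH count (cM; strict inequality).
#' @param top_k how many longest ROHs enter the sum (default 10).
#' @return data.table with columns `iid`, `n10`, `s10`, `total_ge1`.
#' @examples
#' rec <- data.table::data.table(iid = "A:A", cm = c(12, 11, 3, 2))
#' summarize_roh(rec)   # n10 = 2, s10 = 28, total_ge1 = 28
#' @export
summarize_roh <- function(records, ids = NULL, n10_cM = 10, top_k = 10L) {
  records <- data.table::as.data.table(records)
  if (nrow(records) && anyNA(records$cm)) stop("genetic lengths must be filled")
  if (nrow(records)) {
    s <- records[, .(iid, cm)]
    data.table::setorder(s, iid, -cm)
    s[, idx := seq_len(.N), by = iid]
    out <- s[, .(n10 = sum(cm > n10_cM),
                 s10 = sum(cm[idx <= top_k]),
                 total_ge1 = sum(cm)), by = iid]
  } else {
    out <- data.table::data.table(iid = character(0), n10 = integer(0),
                                  s10 = numeric(0), total_ge1 = numeric(0))
  }
  if (!is.null(ids)) {
    all_ids <- data.table::data.table(iid = unique(as.character(ids)))
    out <- out[all_ids, on = "iid"]
    out[is.na(n10), `:=`(n10 = 0L, s10 = 0, total_ge1 = 0)]
  }
  out[, n10 := as.integer(n10)]
  out[]
}

#' Write per-individual summaries to TSV
#'
#' @param summaries output of [summarize_roh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roh_summaries <- function(summaries, path) {
  d <- data.table::copy(data.table::as.data.table(summaries))
  data.table::setnames(d, c("s10", "total_ge1"), c("s10_cM", "total_ge1_cM"),
                       skip_absent = TRUE)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}
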