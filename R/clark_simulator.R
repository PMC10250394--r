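# Resolve a degree specification into block-model parameters (G, F).
# Accepts an integer degree in 2..6, or a list/one-row data.frame with
# elements G and F (allowing degenerate test degrees such as F = 0 or 1).
as_degree_params <- function(degree) {
  if (is.numeric(degree) && length(degree) == 1L && degree %in% 2:6) {
    row <- consanguinity_degrees(degree)
    return(list(degree = row$degree, label = row$label, G = row$G, F = row$F))
  }
  if (is.data.frame(degree)) degree <- as.list(degree[1L, ])
  if (is.list(degree) && !is.null(degree$G) && !is.null(degree$F)) {
    if (degree$G < 2) stop("G must be >= 2")
    if (degree$F < 0 || degree$F > 1) stop("F must be in [0, 1]")
    return(list(degree = degree$degree %||% NA_integer_,
                label = degree$label %||% NA_character_,
                G = degree$G, F = degree$F))
  }
  stop("degree must be an integer in 2..6 or a list with elements G and F")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate autozygous segments along one chromosome
#'
#' Partitions a chromosome of given genetic length into consecutive ancestry
#' blocks with i.i.d. Exponential(mean = 100/G cM) lengths (the last block is
#' truncated at the chromosome end), marks each block autozygous independently
#' with probability F, and merges adjacent autozygous blocks into maximal
#' segments. Uses R's global RNG; call `set.seed()` for reproducibility.
#'
#' @param length_cM chromosome genetic length in cM (> 0).
#' @param degree an integer degree in 2..6 (see [consanguinity_degrees()]) or
#'   a list with elements `G` and `F`.
#' @return data.frame with columns `start_cM` and `length_cM`, one row per
#'   maximal autozygous segment (possibly zero rows).
#' @examples
#' set.seed(1)
#' simulate_chromosome(200, degree = 3)
#' @export
simulate_chromosome <- function(length_cM, degree) {
  if (!is.numeric(length_cM) || length(length_cM) != 1L || length_cM <= 0) {
    stop("length_cM must be a single positive number")
  }
  p <- as_degree_params(degree)
  mu <- 100 / p$G
  # draw blocks until the chromosome is covered
  lens <- numeric(0)
  while (sum(lens) < length_cM) {
    lens <- c(lens, stats::rexp(max(8L, ceiling(length_cM / mu)), rate = 1 / mu))
  }
  ends <- pmin(cumsum(lens), length_cM)
  starts <- c(0, ends[-length(ends)])
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  aut <- stats::runif(length(starts)) < p$F
  if (!any(aut)) {
    return(data.frame(start_cM = numeric(0), length_cM = numeric(0)))
  }
  r <- rle(aut)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  i <- which(r$values)
  data.frame(start_cM = starts[run_start[i]],
             length_cM = ends[run_end[i]] - starts[run_start[i]])
}

#' Simulate autozygous segments across a genome
#'
#' Runs [simulate_chromosome()] independently for every chromosome in a
#' genetic-length table and concatenates the results.
#'
#' @param lengths_cM named numeric vector: chromosome genetic lengths in cM
#'   (default the bundled autosome table).
#' @param degree degree specification as in [simulate_chromosome()].
#' @return data.frame with columns `chrom`, `start_cM`, `length_cM`.
#' @export
simulate_genome <- function(degree, lengths_cM = default_chrom_lengths()) {
  if (length(lengths_cM) == 0L) stop("chromosome length table is empty")
  out <- lapply(names(lengths_cM), function(ch) {
    seg <- simulate_chromosome(lengths_cM[[ch]], degree)
    if (nrow(seg)) cbind(chrom = ch, seg, stringsAsFactors = FALSE) else NULL
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(chrom = character(0), start_cM = numeric(0),
                      length_cM = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Vectorised engine: autozygous segments for n_reps genomes on one chromosome.
# Returns a data.table (rep, start_cM, length_cM). Blocks are laid out
# replicate-major so that run-length merging can be done with one cumsum.
sim_chrom_many <- function(length_cM, G, F, n_reps) {
  mu <- 100 / G
  if (F <= 0) {
    return(data.table::data.table(rep = integer(0), start_cM = numeric(0),
                                  length_cM = numeric(0)))
  }
  m <- length_cM / mu
  K <- max(4L, ceiling(m + 10 * sqrt(m) + 20))
  E <- matrix(stats::rexp(n_reps * K, rate = 1 / mu), nrow = n_reps)
  CS <- E
  for (j in seq_len(K)[-1L]) CS[, j] <- CS[, j - 1L] + E[, j]
  while (any(CS[, ncol(CS)] < length_cM)) {
    add <- matrix(stats::rexp(n_reps * 8L, rate = 1 / mu), nrow = n_reps)
    add[, 1L] <- CS[, ncol(CS)] + add[, 1L]
    for (j in 2:8) add[, j] <- add[, j - 1L] + add[, j]
    CS <- cbind(CS, add)
  }
  Kf <- ncol(CS)
  ends <- pmin(t(CS), length_cM)             # Kf x n, column = one replicate
  starts <- rbind(0, ends[-Kf, , drop = FALSE])
  len <- as.vector(ends - starts)            # replicate-major flattening
  rep_id <- rep.int(seq_len(n_reps), rep(Kf, n_reps))
  keep <- len > 0
  len <- len[keep]
  st <- as.vector(starts)[keep]
  rep_id <- rep_id[keep]
  aut <- stats::runif(length(len)) < F
  nb <- length(len)
  if (nb == 0L || !any(aut)) {
    return(data.table::data.table(rep = integer(0), start_cM = numeric(0),
                                  length_cM = numeric(0)))
  }
  new_run <- c(TRUE, rep_id[-1L] != rep_id[-nb] | aut[-1L] != aut[-nb])
  run_id <- cumsum(new_run)
  first <- which(new_run)
  run_len <- rowsum(len, run_id, reorder = FALSE)[, 1L]
  run_aut <- aut[first]
  data.table::data.table(rep = rep_id[first][run_aut],
                         start_cM = st[first][run_aut],
                         length_cM = unname(run_len[run_aut]))
}

#' Simulate many genomes under the block-inheritance model
#'
#' Vectorised replicate engine behind [build_reference()]. Each replicate is
#' an independent genome; per chromosome the model of [simulate_chromosome()]
#' applies.
#'
#' @param degree degree specification (integer 2..6 or list with `G`, `F`).
#' @param n_reps number of genomes to simulate.
#' @param lengths_cM named chromosome genetic-length vector (cM).
#' @return data.table with columns `rep` (1..n_reps), `chrom`, `start_cM`,
#'   `length_cM`; replicates with no autozygous segment have no rows.
#' @export
simulate_genomes <- function(degree, n_reps, lengths_cM = default_chrom_lengths()) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  p <- as_degree_params(degree)
  parts <- lapply(names(lengths_cM), function(ch) {
    d <- sim_chrom_many(lengths_cM[[ch]], p$G, p$F, n_reps)
    if (nrow(d)) d[, chrom := ch]
    d
  })
  out <- data.table::rbindlist(parts, fill = TRUE)
  if (!nrow(out)) {
    return(data.table::data.table(rep = integer(0), chrom = character(0),
                                  start_cM = numeric(0), length_cM = numeric(0)))
  }
  data.table::setcolorder(out, c("rep", "chrom", "start_cM", "length_cM"))
  data.table::setorder(out, rep)
  out[]
}

# Reduce simulated segments to per-replicate (n10, s10) with the same rules
# applied to observed ROH: segments >= min_cM retained, n10 counts those
# strictly longer than 10 cM, s10 sums the 10 longest.
segments_to_summaries <- function(segs, n_reps, min_cM = 1) {
  s <- segs[length_cM >= min_cM]
  if (nrow(s)) {
    data.table::setorder(s, rep, -length_cM)
    s[, idx := seq_len(.N), by = rep]
    agg <- s[, .(n10 = sum(length_cM > 10), s10 = sum(length_cM[idx <= 10L])),
             by = rep]
  } else {
    agg <- data.table::data.table(rep = integer(0), n10 = integer(0), s10 = numeric(0))
  }
  out <- data.table::data.table(rep = seq_len(n_reps), n10 = 0L, s10 = 0)
  if (nrow(agg)) {
    out[agg, on = "rep", `:=`(n10 = as.integer(i.n10), s10 = i.s10)]
  }
  out[]
}

#' Build a reference (N10, S10) distribution for one degree
#'
#' Simulates `n_sims` genomes for a given degree of parental relatedness and
#' reduces each to the two classifier summaries using the same rules applied
#' to observed ROH calls: segments >= `min_cM` are retained, `n10` counts
#' segments strictly longer than 10 cM, and `s10` sums the genetic lengths of
#' the 10 longest retained segments.
#'
#' @param degree integer degree in 2..6 or list with `G`, `F`.
#' @param n_sims number of simulated genomes (the production default is
#'   2e6; use smaller values for exploration).
#' @param lengths_cM named chromosome genetic-length vector (cM).
#' @param seed optional integer seed; stored with the reference.
#' @param min_cM retention threshold applied to simulated segments (cM),
#'   matching the observed-ROH filter.
#' @param chunk replicates simulated per memory chunk.
#' @return an object of class `roh_reference`: list with elements `samples`
#'   (data.table of `n10`, `s10` per replicate), `degree`, `G`, `F`,
#'   `n_sims`, `min_cM`, `seed`, `lengths_cM`.
#' @examples
#' ref <- build_reference(3, n_sims = 1000, seed = 1)
#' colMeans(ref$samples[, .(n10, s10)])
#' @export
build_reference <- function(degree, n_sims = 2e6,
                            lengths_cM = default_chrom_lengths(),
                            seed = NULL, min_cM = 1, chunk = 1e5) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  p <- as_degree_params(degree)
  if (!is.null(seed)) set.seed(seed)
  n_sims <- as.integer(n_sims)
  pieces <- vector("list", ceiling(n_sims / chunk))
  done <- 0L
  for (i in seq_along(pieces)) {
    n_here <- min(as.integer(chunk), n_sims - done)
    segs <- simulate_genomes(p, n_here, lengths_cM)
    pieces[[i]] <- segments_to_summaries(segs, n_here, min_cM = min_cM)
    done <- done + n_here
  }
  samples <- data.table::rbindlist(pieces)
  samples[, rep := seq_len(.N)]
  structure(list(samples = samples, degree = p$degree, label = p$label,
                 G = p$G, F = p$F, n_sims = n_sims, min_cM = min_cM,
                 seed = seed, lengths_cM = lengths_cM),
            class = "roh_reference")
}

#' @export
print.roh_reference <- function(x, ...) {
  cat(sprintf("<roh_reference> degree %s (G=%s, F=%.5g), %d replicates\n",
              x$degree, x$G, x$F, x$n_sims))
  cat(sprintf("  mean n10 = %.3f, mean s10 = %.2f cM\n",
              mean(x$samples$n10), mean(x$samples$s10)))
  invisible(x)
}

#' Build references for all degrees 2..6
#'
#' Per-degree RNG streams are derived deterministically from the master seed
#' so that each degree's reference is reproducible in isolation.
#'
#' @param n_sims replicates per degree.
#' @param lengths_cM chromosome genetic-length vector.
#' @param seed master integer seed.
#' @param ... further arguments to [build_reference()].
#' @return named list of `roh_reference` objects, names `"2"`..`"6"`.
#' @export
build_all_references <- function(n_sims = 2e6,
                                 lengths_cM = default_chrom_lengths(),
                                 seed = 1L, ...) {
  refs <- lapply(2:6, function(d) {
    build_reference(d, n_sims = n_sims, lengths_cM = lengths_cM,
                    seed = (seed + 7919L * d) %% .Machine$integer.max, ...)
  })
  names(refs) <- as.character(2:6)
  refs
}

#' Write / read a reference distribution
#'
#' The replicate summaries go to a two-column TSV (`n10`, `s10`) and the
#' provenance (degree parameters, replicate count, seed, retention threshold,
#' chromosome-length table) to a JSON sidecar at `<path>.json`.
#'
#' @param ref an `roh_reference`.
#' @param path TSV path.
#' @return `write_reference` returns `path` invisibly; `read_reference`
#'   returns an `roh_reference`.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "roh_reference"))
  data.table::fwrite(ref$samples[, .(n10, s10)], path, sep = "\t")
  meta <- list(degree = ref$degree, label = ref$label, G = ref$G, F = ref$F,
               n_sims = ref$n_sims, min_cM = ref$min_cM, seed = ref$seed,
               lengths_cM = as.list(ref$lengths_cM))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  samples <- data.table::fread(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  samples[, rep := seq_len(.N)]
  lengths <- unlist(meta$lengths_cM)
  structure(list(samples = samples, degree = meta$degree, label = meta$label,
                 G = meta$G, F = meta$F, n_sims = meta$n_sims,
                 min_cM = meta$min_cM, seed = meta$seed, lengths_cM = lengths),
            class = "roh_reference")
}
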