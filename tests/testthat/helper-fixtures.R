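# Shared fixtures and independent oracles for the test suite.

# Two-segment map: 2 cM/Mb up to 10 Mb, then 0.5 cM/Mb to 20 Mb.
fixture_map <- function() {
  genetic_map(chrom = rep("1", 3), pos_bp = c(0, 10e6, 20e6), cm = c(0, 20, 25))
}

# 1 cM/Mb linear map on one chromosome of 100 cM.
linear_map <- function() {
  genetic_map(chrom = c("1", "1"), pos_bp = c(0, 100e6), cm = c(0, 100))
}

# Naive, independent reimplementation of the block model for one chromosome:
# sample block boundaries one at a time, label each block, scan-merge by
# explicit loop. Deliberately structured differently from the package engine.
naive_simulate_chromosome <- function(length_cM, G, F) {
  mu <- 100 / G
  pos <- 0
  blocks <- list()
  while (pos < length_cM) {
    len <- stats::rexp(1, rate = 1 / mu)
    end <- min(pos + len, length_cM)
    blocks[[length(blocks) + 1L]] <- c(start = pos, end = end,
                                       aut = as.numeric(stats::runif(1) < F))
    pos <- pos + len
  }
  segs <- NULL
  cur <- NULL
  for (b in blocks) {
    if (b[["aut"]] == 1) {
      if (is.null(cur)) cur <- c(b[["start"]], b[["end"]])
      else cur[2] <- b[["end"]]
    } else if (!is.null(cur)) {
      segs <- rbind(segs, cur); cur <- NULL
    }
  }
  if (!is.null(cur)) segs <- rbind(segs, cur)
  if (is.null(segs)) return(numeric(0))
  segs[, 2] - segs[, 1]
}

# Naive genome-level (N10, S10) with the observed-ROH reduction rules.
naive_genome_summary <- function(lengths_cM, G, F, min_cM = 1) {
  lens <- unlist(lapply(lengths_cM,
                        function(L) naive_simulate_chromosome(L, G, F)))
  lens <- lens[lens >= min_cM]
  lens <- sort(lens, decreasing = TRUE)
  c(n10 = sum(lens > 10), s10 = sum(utils::head(lens, 10)))
}

# Write a .hom file from a data.frame of FID/IID/CHR/POS1/POS2/KB.
write_hom_fixture <- function(d, path = tempfile(fileext = ".hom")) {
  hdr <- c("FID", "IID", "PHE", "CHR", "SNP1", "SNP2", "POS1", "POS2",
           "KB", "NSNP", "DENSITY", "PHOM", "PHET")
  lines <- paste(d$FID, d$IID, -9, d$CHR, "rs1", "rs2", d$POS1, d$POS2,
                 d$KB, 10, 1, 1, 0)
  writeLines(c(paste(hdr, collapse = " "), lines), path)
  path
}

# Toy reference distribution with explicit (n10, s10) samples.
toy_reference <- function(n10, s10, degree = 6, lengths = c(`1` = 100)) {
  structure(list(
    samples = data.table::data.table(rep = seq_along(n10),
                                     n10 = as.integer(n10), s10 = s10),
    degree = degree,
    label = consanguinity_degrees(degree)$label,
    G = consanguinity_degrees(degree)$G,
    F = consanguinity_degrees(degree)$F,
    n_sims = length(n10), min_cM = 1, seed = NULL, lengths_cM = lengths
  ), class = "roh_reference")
}

# Brute-force expected homozygotes: enumerate all pairings of 2n observed
# alleles into n individuals and average the homozygote count. Feasible for
# 2n <= 12. Equivalent formulation: for each individual slot, probability
# both alleles are minor under sampling without replacement.
brute_force_expected_hom <- function(n, c) {
  alleles <- c(rep(1, c), rep(0, 2 * n - c))
  # expectation by exhaustive enumeration over distinct ordered draws of the
  # first pair times n (exchangeability): enumerate all unordered pairs.
  total <- 0
  npair <- 0
  for (i in seq_along(alleles)) {
    for (j in seq_along(alleles)) {
      if (i == j) next
      total <- total + (alleles[i] == 1 && alleles[j] == 1)
      npair <- npair + 1
    }
  }
  n * total / npair
}
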