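test_that("variant tallies identify the minor allele within the subset", {
  # all heterozygotes: 10 minor alleles, no minor homozygote
  t1 <- tally_variant(rep(1L, 10))
  expect_equal(t1[c("n", "c", "hom")], list(n = 10L, c = 10L, hom = 0L))

  # one alt homozygote among four: alt is minor with c = 2
  t2 <- tally_variant(c(2L, 0L, 0L, 0L))
  expect_equal(t2$c, 2L)
  expect_equal(t2$hom, 1L)
  expect_equal(t2$maf, 0.25)

  # alt is the major allele: minor homozygotes are the ref homozygotes
  t3 <- tally_variant(c(2L, 2L, 2L, 0L))
  expect_equal(t3$c, 2L)
  expect_equal(t3$hom, 1L)

  # missing genotypes drop out of n; all-missing yields n = 0
  t4 <- tally_variant(c(1L, NA, 2L, NA))
  expect_equal(t4$n, 2L)
  t5 <- tally_variant(c(NA_integer_, NA_integer_))
  expect_equal(t5$n, 0L)
  expect_true(is.na(t5$maf))

  expect_error(tally_variant(c(0L, 3L)), "dosages")
})

test_that("expected homozygotes: pairing estimator matches brute-force enumeration", {
  # hand example: n = 4, c = 2 -> 4 * 2 * 1 / (8 * 7) = 1/7
  expect_equal(expected_homozygotes(4, 2), 1 / 7)
  # singletons cannot form a homozygote under pairing
  expect_equal(expected_homozygotes(10, 1), 0)
  # fully minor: every individual homozygous
  expect_equal(expected_homozygotes(5, 10), 5)
  # the p2 plug-in differs for rare alleles
  expect_equal(expected_homozygotes(4, 2, "p2"), 0.25)
  expect_gt(expected_homozygotes(10, 1, "p2"), 0)

  # exhaustive enumeration over all fixtures with 2n <= 12
  for (n in 1:6) {
    for (c in 0:(2 * n)) {
      expect_equal(expected_homozygotes(n, c), brute_force_expected_hom(n, c),
                   info = sprintf("n=%d c=%d", n, c))
    }
  }
  expect_error(expected_homozygotes(4, 9), "0..2n")
})

test_that("HWE cohorts give observed/expected ratios near 1 in every bin", {
  sp <- cohort_spec(n_individuals = 400, n_variants = 15000,
                    mixture = c(unrelated = 1), background_rate = 0,
                    seed = 21)
  co <- generate_cohort(sp)
  rt <- ratio_table(co$geno)
  defined <- rt[!is.na(rt$ratio) & rt$expected >= 5, ]
  expect_gt(nrow(defined), 3)
  # 99% Monte-Carlo band: observed totals are sums of many near-independent
  # Bernoulli counts, approximately Poisson around the expectation
  for (i in seq_len(nrow(defined))) {
    z <- (defined$observed[i] - defined$expected[i]) / sqrt(defined$expected[i])
    expect_lt(abs(z), qnorm(0.995) + 1,
              label = sprintf("bin [%g, %g] z", defined$bin_low[i],
                              defined$bin_high[i]))
  }
  expect_equal(mean(defined$ratio), 1, tolerance = 0.1)
})

test_that("fully autozygous cohort matches exhaustive enumeration on a tiny fixture", {
  # 5 individuals, every genome fully autozygous: each carrier is homozygous,
  # so per variant observed = number of minor-allele carriers
  set.seed(33)
  n <- 5; m <- 20
  freq <- runif(m, 0.1, 0.5)
  geno <- matrix(0L, nrow = m, ncol = n,
                 dimnames = list(NULL, paste0("s", 1:n)))
  for (v in 1:m) geno[v, ] <- 2L * rbinom(n, 1, freq[v])
  bins <- c(0, 0.5)
  rt <- ratio_table(geno, maf_bins = bins)
  # exhaustive recomputation with scalar tallies
  obs <- 0; exp_tot <- 0
  for (v in 1:m) {
    tv <- tally_variant(geno[v, ])
    if (tv$maf == 0) next
    obs <- obs + tv$hom
    exp_tot <- exp_tot + brute_force_expected_hom(tv$n, tv$c)
  }
  expect_equal(rt$observed, obs)
  expect_equal(rt$expected, exp_tot, tolerance = 1e-12)
  expect_equal(rt$ratio, obs / exp_tot)
})

test_that("all-heterozygote data yield zero observed and ratio 0", {
  geno <- matrix(1L, nrow = 50, ncol = 20,
                 dimnames = list(NULL, paste0("s", 1:20)))
  rt <- ratio_table(geno, maf_bins = c(0, 0.5))
  expect_equal(rt$observed, 0L)
  expect_equal(rt$ratio, 0)
})

test_that("bins with zero expectation are undefined, not zero", {
  # two singletons only: pairing expectation is exactly 0
  geno <- matrix(0L, nrow = 2, ncol = 30,
                 dimnames = list(NULL, paste0("s", 1:30)))
  geno[1, 1] <- 1L
  geno[2, 2] <- 1L
  rt <- ratio_table(geno, maf_bins = c(0, 0.05, 0.5))
  low <- rt[rt$bin_low == 0, ]
  expect_equal(low$observed, 0L)
  expect_true(is.na(low$ratio))
})

test_that("consanguineous mixtures show elevated, MAF-decreasing excess and
           inbred strata exceed outbred strata", {
  sp <- cohort_spec(n_individuals = 350, n_variants = 15000,
                    mixture = c(unrelated = 0.4, `2` = 0.2, `3` = 0.4),
                    background_rate = 1, seed = 99)
  co <- generate_cohort(sp)
  rt <- ratio_table(co$geno)
  defined <- rt[!is.na(rt$ratio) & rt$n_variants >= 50, ]
  # excess overall, growing toward rare variants
  expect_gt(defined$ratio[1], utils::tail(defined$ratio, 1))
  expect_lte(stats::cor(defined$ratio, defined$bin_low, method = "spearman"), 0)
  expect_gt(max(defined$ratio), 1.5)

  strata <- ifelse(co$truth$true_degree %in% c("2", "3"), "inbred", "outbred")
  names(strata) <- co$truth$iid
  rts <- ratio_table(co$geno, strata = strata)
  byb <- merge(rts[rts$stratum == "inbred", ],
               rts[rts$stratum == "outbred", ],
               by = c("bin_low", "bin_high"), suffixes = c("_in", "_out"))
  byb <- byb[!is.na(byb$ratio_in) & !is.na(byb$ratio_out) &
               byb$expected_in >= 5 & byb$expected_out >= 5, ]
  expect_gt(nrow(byb), 2)
  expect_true(all(byb$ratio_in > byb$ratio_out))
})

test_that("empty strata warn and are omitted", {
  geno <- matrix(1L, nrow = 5, ncol = 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  strata <- c(s1 = "a", s2 = "a", s3 = "a", s4 = "a", ghost = "b")
  expect_warning(rt <- ratio_table(geno, maf_bins = c(0, 0.5), strata = strata),
                 "empty stratum")
  expect_equal(unique(rt$stratum), "a")
})
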