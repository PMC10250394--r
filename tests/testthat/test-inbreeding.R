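make_toy_refs <- function() {
  # distinct supports so every degree is identifiable
  list(`2` = toy_reference(n10 = c(8, 8, 9), s10 = c(300, 310, 320), degree = 2),
       `3` = toy_reference(n10 = c(5, 5, 6), s10 = c(200, 205, 210), degree = 3),
       `4` = toy_reference(n10 = c(3, 3), s10 = c(100, 101), degree = 4),
       `5` = toy_reference(n10 = c(1, 1), s10 = c(40, 41), degree = 5),
       `6` = toy_reference(n10 = c(0, 0, 1), s10 = c(0, 0, 12), degree = 6))
}

test_that("empirical likelihood counts matching replicates", {
  all_zero <- toy_reference(n10 = rep(0, 5), s10 = rep(0, 5))
  expect_equal(empirical_likelihood(0, 0, all_zero), 1.0)

  # 10 replicates, exactly two with n10 = 3 and s10 within 1% of 60
  ref <- toy_reference(n10 = c(3, 3, 3, 2, 2, 4, 3, 1, 0, 5),
                       s10 = c(59.5, 60.5, 70, 60, 60, 60, 59.39, 60, 0, 61))
  expect_equal(empirical_likelihood(3, 60, ref, s_tol = 0.01), 0.2)

  # unreachable observation
  expect_equal(empirical_likelihood(50, 900, ref), 0)

  # zero s10 matches only replicates at exactly zero
  ref0 <- toy_reference(n10 = c(0, 0), s10 = c(0, 0.4))
  expect_equal(empirical_likelihood(0, 0, ref0), 0.5)

  # likelihood is invariant to replicate permutation
  perm <- toy_reference(n10 = rev(c(3, 3, 3, 2, 2, 4, 3, 1, 0, 5)),
                        s10 = rev(c(59.5, 60.5, 70, 60, 60, 60, 59.39, 60, 0, 61)))
  expect_equal(empirical_likelihood(3, 60, perm), 0.2)
})

test_that("classification picks the max-likelihood degree, distant on ties", {
  refs <- make_toy_refs()
  sm <- data.table::data.table(iid = c("a", "b", "c"),
                               n10 = c(0L, 5L, 8L), s10 = c(0, 205, 310))
  calls <- classify_inbreeding(sm, refs)
  expect_equal(calls$label, c("unrelated", "third", "second"))
  expect_equal(calls$tolerance_used, rep(0.01, 3))
  expect_equal(calls$L6[1], 2 / 3)

  # exact tie between degrees 2 and 3 -> the more distant degree wins
  tie <- list(`2` = toy_reference(n10 = c(4, 0), s10 = c(100, 0), degree = 2),
              `3` = toy_reference(n10 = c(4, 1), s10 = c(100, 5), degree = 3),
              `4` = toy_reference(n10 = c(9, 9), s10 = c(500, 501), degree = 4),
              `5` = toy_reference(n10 = c(9, 9), s10 = c(500, 501), degree = 5),
              `6` = toy_reference(n10 = c(9, 9), s10 = c(500, 501), degree = 6))
  tcall <- classify_inbreeding(data.table::data.table(iid = "t", n10 = 4L,
                                                      s10 = 100), tie)
  expect_equal(tcall$label, "third")
})

test_that("missing or inconsistent references are refused", {
  refs <- make_toy_refs()
  sm <- data.table::data.table(iid = "a", n10 = 0L, s10 = 0)
  expect_error(classify_inbreeding(sm, refs[c("2", "3", "4", "5")]), "missing: 6")
  refs$`4`$lengths_cM <- c(`1` = 999)
  expect_error(classify_inbreeding(sm, refs), "length table")
})

test_that("zero-likelihood fallback widens deterministically and terminates", {
  refs <- make_toy_refs()
  # n10 = 5 matches degree 3's support, but s10 = 150 is far outside the
  # 1% window: tolerance doubles until 205 * (1 - tol) <= 150
  sm <- data.table::data.table(iid = "w", n10 = 5L, s10 = 150)
  call <- classify_inbreeding(sm, refs)
  expect_gt(call$tolerance_used, 0.01)
  expect_true(any(unlist(call[, c("L2", "L3", "L4", "L5", "L6")]) > 0))
  # first widening with positive likelihood is recorded: at tol the window
  # must actually reach a reference point, one halving earlier must not
  tol <- call$tolerance_used
  expect_true(tol %in% (0.01 * 2^(1:30)))
  prev <- tol / 2
  reachable_prev <- any(vapply(refs, function(r) {
    empirical_likelihood(5, 150, r, s_tol = prev,
                         n_window = max(0, log2(prev / 0.01) - 2)) > 0
  }, logical(1)))
  expect_false(reachable_prev)

  # observation entirely outside every support still terminates via the
  # N10 window growth
  far <- data.table::data.table(iid = "f", n10 = 60L, s10 = 5000)
  fcall <- classify_inbreeding(far, refs)
  expect_true(fcall$label %in% c("second", "third", "fourth", "fifth", "unrelated"))
})

test_that("strata map labels to inbred / intermediate / outbred", {
  expect_equal(stratify_calls(c("second", "third", "fourth", "fifth", "unrelated")),
               c("inbred", "inbred", "intermediate", "intermediate", "outbred"))
  expect_error(stratify_calls("seventh"), "unknown")
})

test_that("simulated degree-2 offspring are mostly recalled as second degree", {
  lens <- default_chrom_lengths()
  refs <- build_all_references(n_sims = 20000, seed = 202)
  set.seed(303)
  n <- 150
  segs <- simulate_genomes(2, n, lens)
  sm <- autozyg:::segments_to_summaries(segs, n)
  sm[, iid := paste0("i", rep)]
  calls <- classify_inbreeding(sm, refs)
  expect_gt(mean(calls$label == "second"), 0.5)
  # misclassifications concentrate in the adjacent degree
  wrong <- calls$label[calls$label != "second"]
  if (length(wrong)) expect_gt(mean(wrong == "third"), 0.5)
})

test_that("recall declines toward distant degrees and unrelated cohorts stay outbred", {
  lens <- default_chrom_lengths()
  refs <- build_all_references(n_sims = 20000, seed = 404)
  recall <- vapply(c(2L, 3L, 5L, 6L), function(d) {
    set.seed(500 + d)
    n <- 120
    segs <- simulate_genomes(d, n, lens)
    sm <- autozyg:::segments_to_summaries(segs, n)
    sm[, iid := paste0("i", rep)]
    calls <- classify_inbreeding(sm, refs)
    truth_label <- consanguinity_degrees(d)$label
    mean(calls$label == truth_label)
  }, numeric(1))
  # close relationships are easier to recover than distant ones
  expect_gt(min(recall[1:2]), max(recall[3:4]) - 1e-9)

  # a 100% unrelated cohort (no autozygous loop tracts at all) is almost
  # never called inbred
  sm0 <- data.table::data.table(iid = paste0("u", 1:100), n10 = 0L, s10 = 0)
  calls0 <- classify_inbreeding(sm0, refs)
  expect_lt(mean(stratify_calls(calls0) == "inbred"), 0.05)
})
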