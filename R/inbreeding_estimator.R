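#' Empirical likelihood of an (N10, S10) observation under a reference
#'
#' The likelihood is the fraction of simulated reference replicates whose
#' `n10` matches the observation exactly (optionally within `n_window`) and
#' whose `s10` lies within a relative window `s10 * (1 +/- s_tol)` of the
#' observed value. When the observed `s10` is 0 the window is the single
#' point 0 (no simulated genome can match a zero top-10 sum except exactly).
#'
#' @param n10 observed count of ROHs longer than 10 cM.
#' @param s10 observed summed genetic length of the 10 longest ROHs (cM).
#' @param ref an `roh_reference` from [build_reference()].
#' @param s_tol relative tolerance on `s10` (default 1%).
#' @param n_window non-negative integer: accept reference `n10` within
#'   `+/- n_window` of the observation (0 = exact match, the default).
#' @param s_abs when `s10 == 0` and `s_abs > 0`, accept reference `s10` in
#'   `[0, s_abs]` cM instead of requiring exactly 0 (used by the classifier's
#'   widening fallback).
#' @return the likelihood, a fraction in [0, 1].
#' @export
empirical_likelihood <- function(n10, s10, ref, s_tol = 0.01,
                                 n_window = 0L, s_abs = 0) {
  stopifnot(inherits(ref, "roh_reference"), nrow(ref$samples) > 0)
  sm <- ref$samples
  n_ok <- abs(sm$n10 - n10) <= n_window
  if (s10 > 0) {
    s_ok <- sm$s10 >= s10 * (1 - s_tol) & sm$s10 <= s10 * (1 + s_tol)
  } else {
    s_ok <- sm$s10 <= s_abs
  }
  mean(n_ok & s_ok)
}

#' Classify the degree of parental relatedness of individuals
#'
#' For each individual, computes the empirical likelihood of its (N10, S10)
#' summary under reference distributions simulated at degrees 2..6 and
#' assigns the degree with the highest likelihood, reporting degree 6 as
#' `"unrelated"`. Ties are broken toward the more distant degree
#' (conservative against over-calling consanguinity).
#'
#' If all five likelihoods are zero the S10 tolerance is doubled and the
#' evaluation repeated; from the third widening onward the N10 match is also
#' relaxed to a growing `+/- k` window, so the schedule always terminates.
#' The tolerance at which a positive likelihood was first found is recorded.
#'
#' @param summaries per-individual summaries from [summarize_roh()] (columns
#'   `iid`, `n10`, `s10`).
#' @param refs named list of `roh_reference` objects for degrees `"2"`..`"6"`
#'   (e.g. from [build_all_references()]). All five must be present and built
#'   on the same chromosome-length table.
#' @param s_tol starting relative tolerance on S10 (default 1%).
#' @return data.table with one row per individual: `iid`, `label`
#'   (`second`/`third`/`fourth`/`fifth`/`unrelated`), likelihood columns
#'   `L2`..`L6`, and `tolerance_used`.
#' @export
classify_inbreeding <- function(summaries, refs, s_tol = 0.01) {
  need <- as.character(2:6)
  if (!all(need %in% names(refs))) {
    stop("references for all degrees 2..6 are required; missing: ",
         paste(setdiff(need, names(refs)), collapse = ", "))
  }
  refs <- refs[need]
  tabs <- lapply(refs, function(r) {
    stopifnot(inherits(r, "roh_reference"))
    r
  })
  base_len <- tabs[[1L]]$lengths_cM
  same <- vapply(tabs, function(r) {
    isTRUE(all.equal(unname(r$lengths_cM[names(base_len)]), unname(base_len)))
  }, logical(1))
  if (!all(same)) {
    stop("reference distributions were built on different chromosome-length tables")
  }
  summaries <- data.table::as.data.table(summaries)
  labels <- vapply(tabs, function(r) r$label, character(1))
  res <- lapply(seq_len(nrow(summaries)), function(i) {
    n10 <- summaries$n10[i]
    s10 <- summaries$s10[i]
    k <- 0L
    repeat {
      tol <- s_tol * 2^k
      nw <- max(0L, k - 2L)
      sa <- if (k == 0L) 0 else tol * 100
      L <- vapply(tabs, empirical_likelihood, numeric(1),
                  n10 = n10, s10 = s10, s_tol = tol, n_window = nw, s_abs = sa)
      if (any(L > 0)) break
      k <- k + 1L
    }
    best <- max(which(L == max(L)))  # ties -> more distant degree
    c(list(label = labels[best], tolerance_used = tol), as.list(L))
  })
  out <- data.table::data.table(
    iid = summaries$iid,
    label = vapply(res, `[[`, character(1), "label"),
    L2 = vapply(res, `[[`, numeric(1), "2"),
    L3 = vapply(res, `[[`, numeric(1), "3"),
    L4 = vapply(res, `[[`, numeric(1), "4"),
    L5 = vapply(res, `[[`, numeric(1), "5"),
    L6 = vapply(res, `[[`, numeric(1), "6"),
    tolerance_used = vapply(res, `[[`, numeric(1), "tolerance_used")
  )
  out[]
}

#' Stratify inbreeding calls into inbred / intermediate / outbred
#'
#' `inbred`: parents estimated to be third-degree relatives or more closely
#' related (labels `second`, `third`). `outbred`: sixth-degree or more
#' distant (`unrelated`). Everything else (`fourth`, `fifth`) is
#' `intermediate`.
#'
#' @param labels character vector of labels as produced by
#'   [classify_inbreeding()] (a data.frame with a `label` column is also
#'   accepted).
#' @return character vector of strata, same length as `labels`.
#' @export
stratify_calls <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  ok <- c("second", "third", "fourth", "fifth", "unrelated")
  if (!all(labels %in% ok)) {
    stop("unknown label(s): ", paste(setdiff(labels, ok), collapse = ", "))
  }
  out <- rep("intermediate", length(labels))
  out[labels %in% c("second", "third")] <- "inbred"
  out[labels == "unrelated"] <- "outbred"
  out
}
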