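# Shared fixtures and independent oracles. Oracles deliberately use a
# different computational route than the package code they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build an axiom_calls object directly from matrices, bypassing the caller,
# so QC/rescue logic can be tested on hand-crafted inputs.
make_calls_object <- function(raw_calls, confidence,
                              resolved = rep(TRUE, ncol(raw_calls)),
                              size = NULL, threshold = 0.15) {
  stopifnot(identical(dim(raw_calls), dim(confidence)))
  calls <- raw_calls
  calls[is.na(confidence) | confidence > threshold] <- "NC"
  if (is.null(size))
    size <- matrix(10, nrow(raw_calls), ncol(raw_calls),
                   dimnames = dimnames(raw_calls))
  diags <- data.table::data.table(
    probeset_id = colnames(raw_calls), n_components = 3L, means = "",
    sds = "", weights = "", separation = 10, resolved = resolved,
    n_informative = nrow(raw_calls))
  structure(list(calls = calls, raw_calls = raw_calls,
                 confidence = confidence, diagnostics = diags, size = size,
                 config = axiomsnp::caller_config(confidence_threshold = threshold)),
            class = "axiom_calls")
}

# Simple sample sheet: one plate, perfect DQC.
simple_samples <- function(sample_ids, population = "C1") {
  data.frame(sample_id = sample_ids,
             tree_id = sample_ids,
             population = population,
             plate_id = "plate001",
             dqc = 0.95)
}

# Independent G2 oracle: multinomial log-likelihood difference between the
# saturated and independence models (not the direct O*ln(O/E) formula).
g2_oracle <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  ll_sat <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0) ll_sat <- ll_sat + tab[i, j] * log(tab[i, j] / n)
  ll_ind <- 0
  rs <- rowSums(tab); cs <- colSums(tab)
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0)
      ll_ind <- ll_ind + tab[i, j] * (log(rs[i] / n) + log(cs[j] / n))
  unname(2 * (ll_sat - ll_ind))
}

# Independent HWE chi-square oracle: explicit expected counts, scalar loop.
hwe_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  p <- (2 * nAA + nAB) / (2 * n)
  if (p == 0 || p == 1) return(list(chi2 = 0, p = 1))
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  observed <- c(nAA, nAB, nBB)
  chi2 <- 0
  for (k in 1:3) chi2 <- chi2 + (observed[k] - expected[k])^2 / expected[k]
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Brute-force protocol reclassifier: recomputes every call rate from the
# raw confidence matrix with nested loops and if-chains, independent of the
# vectorized package path. Returns per-probeset category.
brute_force_classify <- function(raw_calls, confidence, resolved,
                                 otv_fraction, thresholds) {
  out <- character(ncol(raw_calls))
  names(out) <- colnames(raw_calls)
  for (j in seq_len(ncol(raw_calls))) {
    calls <- character(nrow(raw_calls))
    for (i in seq_len(nrow(raw_calls))) {
      calls[i] <- if (raw_calls[i, j] == "NC" || is.na(confidence[i, j]) ||
                      confidence[i, j] > thresholds$confidence_threshold)
        "NC" else raw_calls[i, j]
    }
    cr <- sum(calls != "NC") / length(calls)
    nAA <- sum(calls == "AA"); nAB <- sum(calls == "AB"); nBB <- sum(calls == "BB")
    cat_j <- if (otv_fraction[j] >= 0.1) "OTV"
    else if (!resolved[j]) "Other"
    else if (cr < thresholds$snp_cr_cutoff) "CallRateBelowThreshold"
    else if ((nAA > 0) + (nAB > 0) + (nBB > 0) <= 1) "MonoHighResolution"
    else if (min(nAA, nBB) == 0) "NoMinorHom"
    else "PolyHighResolution"
    if (cat_j %in% c("Other", "CallRateBelowThreshold") &&
        !is.null(thresholds$rescue_cr_cutoff)) {
      calls2 <- character(nrow(raw_calls))
      for (i in seq_len(nrow(raw_calls))) {
        calls2[i] <- if (raw_calls[i, j] == "NC" || is.na(confidence[i, j]) ||
                         confidence[i, j] > thresholds$phase2_confidence)
          "NC" else raw_calls[i, j]
      }
      cr2 <- sum(calls2 != "NC") / length(calls2)
      k2 <- (sum(calls2 == "AA") > 0) + (sum(calls2 == "AB") > 0) +
        (sum(calls2 == "BB") > 0)
      if (cr2 >= thresholds$rescue_cr_cutoff && k2 >= 2) cat_j <- "Rescued"
    }
    out[j] <- cat_j
  }
  out
}

# Random raw-call/confidence matrices for property tests.
random_calls_fixture <- function(n_samples, n_probesets, seed) {
  set.seed(seed)
  raw <- matrix(sample(c("AA", "AB", "BB"), n_samples * n_probesets, TRUE,
                       prob = c(0.4, 0.4, 0.2)),
                n_samples, n_probesets,
                dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                                sprintf("ps%03d", seq_len(n_probesets))))
  conf <- matrix(rbeta(n_samples * n_probesets, 0.4, 4), n_samples, n_probesets,
                 dimnames = dimnames(raw))
  list(raw = raw, conf = conf)
}
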