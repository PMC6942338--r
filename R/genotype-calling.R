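# Stand-in genotype caller. The vendor's clustering algorithm is
# proprietary; this module substitutes a transparent 1-D Gaussian mixture
# on the contrast coordinate, with BIC model selection over 1-3 components,
# genotype labels assigned from component means, and a per-call confidence
# score of 1 - max posterior (lower = better, so the conventional 0.15 /
# 0.10 confidence thresholds apply verbatim).

#' Contrast/size transform of two-channel intensities
#'
#' contrast = log2(A/B), size = (log2 A + log2 B)/2. Non-positive signals
#' are marked missing (NA), not an error: zeroed signals are how corrupted
#' assays present.
#'
#' @param signal_a,signal_b numeric matrices (samples x probesets) of
#'   channel intensities
#' @return list of matrices `contrast`, `size`
#' @export
transform_intensities <- function(signal_a, signal_b) {
  stopifnot(identical(dim(signal_a), dim(signal_b)))
  bad <- !(signal_a > 0 & signal_b > 0)
  la <- log2(ifelse(bad, NA_real_, signal_a))
  lb <- log2(ifelse(bad, NA_real_, signal_b))
  out <- list(contrast = la - lb, size = (la + lb) / 2)
  dimnames(out$contrast) <- dimnames(out$size) <- dimnames(signal_a)
  out
}

#' Caller configuration
#'
#' @param confidence_threshold calls with confidence above this become
#'   NoCall (default 0.15, the conventional default)
#' @param min_samples probesets with fewer informative samples are marked
#'   unresolved (default 20)
#' @param separation_min minimum between-cluster separation
#'   |mean difference| / pooled SD for a probeset to count as resolved
#'   (default 3.6)
#' @param max_cluster_sd largest within-cluster contrast SD compatible
#'   with a resolved probeset (default 0.5 log2 units); a single broad
#'   fused component -- confident calls but no genotype structure -- fails
#'   this cap and lands in `Other`
#' @param het_band component-mean band (+/-) labelled heterozygote
#'   (default 0.75, half the nominal homozygote contrast)
#' @param var_floor ridge floor on component variances
#' @param max_k maximum number of mixture components (3 = AA/AB/BB)
#' @return a `caller_config` list
#' @export
caller_config <- function(confidence_threshold = 0.15, min_samples = 20L,
                          separation_min = 3.6, max_cluster_sd = 0.5,
                          het_band = 0.75, var_floor = 1e-4, max_k = 3L) {
  assert_fraction(confidence_threshold, "confidence_threshold")
  structure(list(confidence_threshold = confidence_threshold,
                 min_samples = as.integer(min_samples),
                 separation_min = separation_min,
                 max_cluster_sd = max_cluster_sd, het_band = het_band,
                 var_floor = var_floor, max_k = as.integer(max_k)),
            class = "caller_config")
}

# Deterministic initialization (component means equally spaced over the
# observed contrast range) keeps the fit reproducible and channel-swap
# symmetric (no random restarts), and is robust to very unequal cluster
# weights (e.g. a low-MAF SNP with 95% of samples in one homozygote
# cluster, where quantile initialization would collapse).
fit_gmm_1d <- function(x, k, var_floor = 1e-4, max_iter = 60, tol = 1e-6) {
  n <- length(x)
  if (k == 1) {
    mu <- mean(x); s2 <- max(var(x) * (n - 1) / n, var_floor)
    ll <- sum(dnorm(x, mu, sqrt(s2), log = TRUE))
    return(list(k = 1L, w = 1, mu = mu, sd = sqrt(s2), loglik = ll,
                bic = -2 * ll + 2 * log(n),
                posterior = matrix(1, n, 1)))
  }
  r <- range(x)
  mu <- r[1] + diff(r) * (seq_len(k) - 0.5) / k
  if (anyDuplicated(mu)) mu <- mu + seq_len(k) * 1e-6
  s2 <- rep(max(var(x) / k^2, var_floor), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  post <- NULL
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      dnorm(x, mu[j], sqrt(s2[j]), log = TRUE) + log(w[j]), numeric(n))
    m <- apply(logd, 1, max)
    p <- exp(logd - m)
    tot <- rowSums(p)
    post <- p / tot
    ll <- sum(m + log(tot))
    nk <- colSums(post)
    w <- nk / n
    mu <- colSums(post * x) / nk
    s2 <- pmax(colSums(post * (outer(x, mu, "-")^2)) / nk, var_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  ord <- order(mu)
  list(k = as.integer(k), w = w[ord], mu = mu[ord], sd = sqrt(s2[ord]),
       loglik = ll, bic = -2 * ll + (3 * k - 1) * log(n),
       posterior = post[, ord, drop = FALSE])
}

label_components <- function(mu, het_band) {
  ifelse(mu > het_band, "AA", ifelse(mu < -het_band, "BB", "AB"))
}

# A 1-component fit separates nothing: its separation score is 0 by
# definition (resolution of such probesets is judged on the cluster SD cap
# instead, so tight monomorphic clusters still count as resolved).
min_separation <- function(mu, sdv) {
  if (length(mu) < 2) return(0)
  mu <- sort(mu)
  seps <- vapply(seq_len(length(mu) - 1), function(i)
    abs(mu[i + 1] - mu[i]) / sqrt((sdv[i]^2 + sdv[i + 1]^2) / 2), numeric(1))
  min(seps)
}

#' Call genotypes from contrast/size coordinates
#'
#' Per probeset, fits 1-, 2-, and 3-component Gaussian mixtures to the
#' contrast values (deterministic quantile initialization, EM with a
#' variance ridge floor), selects the component count by BIC, labels
#' components by mean (above `het_band` = AA, below `-het_band` = BB,
#' otherwise AB), and assigns each sample the label of its
#' maximum-posterior component with confidence `1 - max posterior`. Calls
#' whose confidence exceeds the threshold, and samples with missing
#' contrast, are NoCall. A probeset is `resolved` when every component SD
#' is within `max_cluster_sd`, no two components share a genotype label,
#' and (for multi-component fits) the minimum pairwise cluster separation
#' reaches `separation_min`.
#'
#' @param cs output of [transform_intensities()]
#' @param config a [caller_config()]
#' @return object of class `axiom_calls`: list with character matrix
#'   `calls` (`AA`/`AB`/`BB`/`NC`), matrix `raw_calls` (labels ignoring the
#'   confidence threshold), matrix `confidence`, data.table `diagnostics`,
#'   and the `config`
#' @export
call_genotypes <- function(cs, config = caller_config()) {
  stopifnot(inherits(config, "caller_config"))
  contrast <- cs$contrast
  ns <- nrow(contrast); np <- ncol(contrast)
  calls <- matrix(NA_character_, ns, np, dimnames = dimnames(contrast))
  conf <- matrix(NA_real_, ns, np, dimnames = dimnames(contrast))
  diags <- vector("list", np)
  for (j in seq_len(np)) {
    x <- contrast[, j]
    ok <- which(!is.na(x))
    if (length(ok) < config$min_samples) {
      diags[[j]] <- data.table::data.table(
        probeset_id = colnames(contrast)[j], n_components = 0L,
        means = "", sds = "", weights = "", separation = NA_real_,
        resolved = FALSE, n_informative = length(ok))
      next
    }
    xo <- x[ok]
    if (sd(xo) < 1e-9) {
      # all samples at one point: a single tight cluster
      fit <- list(k = 1L, w = 1, mu = mean(xo), sd = sqrt(config$var_floor),
                  posterior = matrix(1, length(ok), 1))
    } else {
      fits <- lapply(seq_len(config$max_k), function(k)
        fit_gmm_1d(xo, k, config$var_floor))
      fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
    }
    labels <- label_components(fit$mu, config$het_band)
    sep <- min_separation(fit$mu, fit$sd)
    resolved <- all(fit$sd <= config$max_cluster_sd) &&
      !anyDuplicated(labels) &&
      (fit$k == 1L || sep >= config$separation_min)
    comp <- max.col(fit$posterior, ties.method = "first")
    pmax_ <- fit$posterior[cbind(seq_along(ok), comp)]
    calls[ok, j] <- labels[comp]
    conf[ok, j] <- 1 - pmax_
    diags[[j]] <- data.table::data.table(
      probeset_id = colnames(contrast)[j], n_components = fit$k,
      means = paste(signif(fit$mu, 6), collapse = ","),
      sds = paste(signif(fit$sd, 6), collapse = ","),
      weights = paste(signif(fit$w, 6), collapse = ","),
      separation = sep, resolved = resolved, n_informative = length(ok))
  }
  raw <- calls
  calls[is.na(calls) | conf > config$confidence_threshold] <- "NC"
  raw[is.na(raw)] <- "NC"
  structure(list(calls = calls, raw_calls = raw, confidence = conf,
                 diagnostics = data.table::rbindlist(diags),
                 size = cs$size, config = config),
            class = "axiom_calls")
}

#' Re-apply a confidence threshold to raw calls
#'
#' @param calls an `axiom_calls` object
#' @param threshold new confidence threshold
#' @return character matrix of calls under the new threshold
#' @export
apply_confidence_threshold <- function(calls, threshold) {
  assert_fraction(threshold, "threshold")
  out <- calls$raw_calls
  out[is.na(calls$confidence) | calls$confidence > threshold] <- "NC"
  out
}

#' Rebuild an `axiom_calls` object from a long-format calls table
#'
#' Used by the command-line QC stage when calling and QC run as separate
#' invocations. The raw (pre-threshold) genotype of a NoCall is not
#' recoverable from the table, so Phase-2 re-thresholding can only turn
#' calls *off*, never recover them; cluster diagnostics default to
#' resolved unless supplied.
#'
#' @param calls_long data.table with `sample_id`, `probeset_id`, `call`,
#'   `confidence`
#' @param diagnostics optional caller diagnostics table
#' @param threshold the confidence threshold the table was written with
#' @return an `axiom_calls` object
#' @export
calls_object_from_long <- function(calls_long, diagnostics = NULL,
                                   threshold = 0.15) {
  cl <- data.table::as.data.table(calls_long)
  samples <- unique(cl$sample_id); probes <- unique(cl$probeset_id)
  ij <- cbind(match(cl$sample_id, samples), match(cl$probeset_id, probes))
  cm <- matrix("NC", length(samples), length(probes),
               dimnames = list(samples, probes))
  conf <- matrix(NA_real_, length(samples), length(probes),
                 dimnames = list(samples, probes))
  cm[ij] <- cl$call
  conf[ij] <- cl$confidence
  if (is.null(diagnostics))
    diagnostics <- data.table::data.table(
      probeset_id = probes, n_components = NA_integer_, means = "", sds = "",
      weights = "", separation = NA_real_, resolved = TRUE,
      n_informative = colSums(cm != "NC"))
  size <- matrix(NA_real_, length(samples), length(probes),
                 dimnames = list(samples, probes))
  structure(list(calls = cm, raw_calls = cm, confidence = conf,
                 diagnostics = diagnostics, size = size,
                 config = caller_config(confidence_threshold = threshold)),
            class = "axiom_calls")
}

#' Detect off-target-variant (OTV) clusters
#'
#' OTV SNPs show an extra low-intensity cluster caused by probe/target
#' mismatch; such samples hybridize weakly on both channels and sit well
#' below the main cluster in size. A sample is flagged when its size falls
#' more than `size_offset` log2 units below the per-probeset median size.
#'
#' @param calls an `axiom_calls` object (carries the size matrix)
#' @param size_offset downward offset from the median size (log2 units)
#'   defining "low-size"; default 2
#' @return list: `otv_fraction` named per-probeset fractions, `flags`
#'   logical matrix (samples x probesets)
#' @export
detect_otv <- function(calls, size_offset = 2) {
  size <- calls$size
  med <- apply(size, 2, median, na.rm = TRUE)
  flags <- sweep(size, 2, med - size_offset, "<")
  flags[is.na(flags)] <- FALSE
  frac <- colMeans(flags)
  list(otv_fraction = frac, flags = flags)
}
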