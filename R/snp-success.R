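# Predictors of SNP conversion: BLAST-derived feature engineering,
# univariate association tests, stepwise logistic regression with
# cross-validated ROC, and the marker-detection sample-size calculator.

#' Engineer success-prediction features from BLAST tabular hits
#'
#' Two modes, matching the two reference-genome passes of a typical array
#' project. `v05` counts one hit per alignment of at least 65 nt between
#' the 71-nt SNP sequence and the reference, and counts "perfect alleles"
#' (alignments with 100% identity over the full 71 nt); query ids of the
#' form `snp|allele` are grouped per SNP with distinct alleles counted.
#' `v10` extracts the best and second-best percent identity per query
#' (missing hits floored at PID 80), the three-class category of the top
#' two hits, and the number of hits at PID > 90 binned as
#' `one`/`gt1`/`zero`.
#'
#' @param blast data.frame of standard 12-column BLAST tabular rows (see
#'   [read_blast_tabular()]) or a path to such a file
#' @param mode `"v05"` or `"v10"`
#' @param queries optional character vector of all query ids, so queries
#'   with no hits appear in the output (zero hits / PID 80 floor)
#' @return data.table keyed by `query`; `v05`: `n_hits`,
#'   `n_perfect_alleles`; `v10`: `pid_best`, `pid_second`,
#'   `pid_pair_category`, `hit_bin`
#' @export
blast_features <- function(blast, mode = c("v05", "v10"), queries = NULL) {
  mode <- match.arg(mode)
  if (is.character(blast) && length(blast) == 1) blast <- read_blast_tabular(blast)
  b <- data.table::as.data.table(blast)
  if (is.null(queries)) queries <- unique(b$qseqid)
  if (mode == "v05") {
    has_allele <- grepl("|", b$qseqid, fixed = TRUE)
    b[, snp := ifelse(has_allele, sub("\\|[^|]*$", "", qseqid), qseqid)]
    b[, allele := ifelse(has_allele, sub("^.*\\|", "", qseqid), "A")]
    qsnp <- unique(ifelse(grepl("|", queries, fixed = TRUE),
                          sub("\\|[^|]*$", "", queries), queries))
    hits <- b[length >= 65, .(n_hits = .N), by = snp]
    perf <- b[pident == 100 & length == 71,
              .(n_perfect_alleles = data.table::uniqueN(allele)), by = snp]
    out <- data.table::data.table(query = qsnp)
    out <- merge(out, hits, by.x = "query", by.y = "snp", all.x = TRUE)
    out <- merge(out, perf, by.x = "query", by.y = "snp", all.x = TRUE)
    out[is.na(n_hits), n_hits := 0L]
    out[is.na(n_perfect_alleles), n_perfect_alleles := 0L]
    return(out[])
  }
  # v10
  per <- b[, {
    pid <- sort(pident, decreasing = TRUE)
    .(pid_best = max(pid[1], 80), pid_second = max(pid[2], 80, na.rm = TRUE),
      n_gt90 = sum(pident > 90))
  }, by = qseqid]
  out <- data.table::data.table(query = queries)
  out <- merge(out, per, by.x = "query", by.y = "qseqid", all.x = TRUE)
  out[is.na(pid_best), `:=`(pid_best = 80, pid_second = 80, n_gt90 = 0L)]
  out[, pid_second := pmin(pid_second, pid_best)]
  out[, pid_pair_category := pid_pair_category(pid_best, pid_second)]
  out[, hit_bin := ifelse(n_gt90 == 1, "one", ifelse(n_gt90 > 1, "gt1", "zero"))]
  out[]
}

#' Likelihood-ratio chi-square (G-squared) test of independence
#'
#' G2 = 2 sum O ln(O / E) over all cells, with expected counts from the
#' row/column margins; zero observed cells contribute 0. Degrees of
#' freedom (r-1)(k-1); rows or columns with zero margin are dropped with a
#' warning and df reduced accordingly.
#'
#' @param tab matrix of nonnegative counts (typically 2 x k:
#'   success/failure by category)
#' @return list: `g2`, `df`, `p`
#' @export
g2_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stopf("negative counts")
  rz <- rowSums(tab) == 0; cz <- colSums(tab) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero rows/columns; df reduced")
    tab <- tab[!rz, !cz, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) stopf("table must be at least 2 x 2 after dropping")
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  terms <- ifelse(tab > 0, tab * log(tab / e), 0)
  g2 <- 2 * sum(terms)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(g2 = g2, df = df, p = pchisq(g2, df, lower.tail = FALSE))
}

#' Two-group comparison: Welch t or Monte-Carlo Wilcoxon
#'
#' `welch_t` is the unequal-variance t test with Satterthwaite degrees of
#' freedom. `wilcoxon_mc` is the rank-sum test with a Monte-Carlo
#' two-sided p-value, p = (exceedances + 1) / (permutations + 1), suited
#' to rank-valued variables whose null distribution is awkward at scale.
#'
#' @param values numeric vector
#' @param labels two-level grouping vector, same length
#' @param test `"welch_t"` or `"wilcoxon_mc"`
#' @param n_perm Monte-Carlo permutation count (default 10000)
#' @param seed seed for the permutation draw
#' @return list: `statistic`, `p`, plus `df` for Welch
#' @export
group_compare <- function(values, labels, test = c("welch_t", "wilcoxon_mc"),
                          n_perm = 10000, seed = 1L) {
  test <- match.arg(test)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stopf("labels must have exactly two levels")
  x <- values[labels == levels(labels)[1]]
  y <- values[labels == levels(labels)[2]]
  if (length(x) < 2 || length(y) < 2) stopf("each group needs n >= 2")
  if (test == "welch_t") {
    vx <- var(x); vy <- var(y)
    if (vx == 0 && vy == 0) {
      if (mean(x) == mean(y)) return(list(statistic = 0, p = 1, df = NA_real_))
      stopf("constant values in both groups with different means: t undefined")
    }
    se2 <- vx / length(x) + vy / length(y)
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / length(x))^2 / (length(x) - 1) +
                     (vy / length(y))^2 / (length(y) - 1))
    return(list(statistic = t, p = 2 * stats::pt(-abs(t), df), df = df))
  }
  # Monte-Carlo Wilcoxon rank-sum
  r <- rank(values)
  obs <- sum(r[labels == levels(labels)[1]])
  mu <- length(x) * (length(values) + 1) / 2
  exceed <- with_stream(seed, 99L, {
    sum(vapply(seq_len(n_perm), function(i) {
      w <- sum(r[sample.int(length(values), length(x))])
      abs(w - mu) >= abs(obs - mu)
    }, logical(1)))
  })
  list(statistic = obs, p = (exceed + 1) / (n_perm + 1))
}

lr_chisq <- function(fit_small, fit_big) {
  chi <- fit_small$deviance - fit_big$deviance
  df <- fit_small$df.residual - fit_big$df.residual
  list(chi2 = max(chi, 0), df = df,
       p = pchisq(max(chi, 0), df, lower.tail = FALSE))
}

#' Stepwise logistic regression with cross-validated ROC
#'
#' Forward-entry/backward-removal stepwise selection on a binary outcome:
#' at each step the candidate with the largest likelihood-ratio chi-square
#' enters if its p-value is at most `sle`; after each entry, included
#' variables whose removal p-value exceeds `sls` are dropped. After
#' selection, the selected model is refit on stratified cross-validation
#' folds and the out-of-fold predicted probabilities are pooled into a
#' single ROC curve with trapezoidal AUC and an operating point at the
#' given probability threshold. Quasi-separation is flagged when any
#' coefficient exceeds 15 in absolute value.
#'
#' @param features data.frame of numeric candidate predictors
#' @param label binary outcome (0/1 or logical)
#' @param sle significance level to enter (default 0.05)
#' @param sls significance level to stay (default 0.05)
#' @param folds cross-validation fold count (default 10)
#' @param threshold probability threshold for the reported operating point
#' @param seed seed for the fold assignment
#' @return list: `steps` (variable, step, chi2, p at entry), `selected`,
#'   `model` (the full-data glm fit), `roc` (data.table fpr/tpr),
#'   `auc`, `operating_point`, `separation_flag`
#' @export
stepwise_logistic_roc <- function(features, label, sle = 0.05, sls = 0.05,
                                  folds = 10, threshold = 0.5, seed = 1L) {
  x <- as.data.frame(features)
  if (ncol(x) < 2) stopf("need at least 2 candidate variables")
  if (!all(vapply(x, is.numeric, logical(1))))
    stopf("all candidate variables must be numeric")
  y <- as.integer(label)
  if (!all(y %in% 0:1)) stopf("label must be binary")
  dat <- cbind(y = y, x)

  fit_with <- function(vars) {
    f <- if (length(vars)) stats::reformulate(vars, "y") else y ~ 1
    suppressWarnings(glm(f, data = dat, family = binomial()))
  }

  included <- character(0)
  steps <- list()
  current <- fit_with(included)
  step_no <- 0L
  repeat {
    remaining <- setdiff(names(x), included)
    if (!length(remaining)) break
    trials <- lapply(remaining, function(v) {
      lr_chisq(current, fit_with(c(included, v)))
    })
    ps <- vapply(trials, `[[`, numeric(1), "p")
    best <- which.min(ps)
    if (ps[best] > sle) break
    step_no <- step_no + 1L
    included <- c(included, remaining[best])
    steps[[step_no]] <- data.table::data.table(
      step = step_no, variable = remaining[best],
      chi2 = trials[[best]]$chi2, p = ps[best])
    current <- fit_with(included)
    # backward pass
    repeat {
      if (length(included) < 1) break
      drops <- vapply(included, function(v)
        lr_chisq(fit_with(setdiff(included, v)), current)$p, numeric(1))
      worst <- which.max(drops)
      if (drops[worst] <= sls) break
      included <- included[-worst]
      current <- fit_with(included)
    }
  }

  sep_flag <- length(included) > 0 &&
    any(abs(stats::coef(current)[-1]) > 15, na.rm = TRUE)

  # stratified k-fold CV of the selected model
  prob <- rep(NA_real_, length(y))
  if (length(included)) {
    fold <- integer(length(y))
    with_stream(seed, 98L, {
      for (cl in 0:1) {
        idx <- which(y == cl)
        fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      }
    })
    for (f in seq_len(folds)) {
      test <- fold == f
      fit <- suppressWarnings(glm(stats::reformulate(included, "y"),
                                  data = dat[!test, , drop = FALSE],
                                  family = binomial()))
      prob[test] <- predict(fit, newdata = dat[test, , drop = FALSE],
                            type = "response")
    }
  } else {
    prob[] <- mean(y)
  }
  roc <- roc_curve(prob, y)
  op <- list(threshold = threshold,
             tpr = sum(prob >= threshold & y == 1) / sum(y == 1),
             fpr = sum(prob >= threshold & y == 0) / sum(y == 0))
  list(steps = if (length(steps)) data.table::rbindlist(steps) else
         data.table::data.table(step = integer(), variable = character(),
                                chi2 = numeric(), p = numeric()),
       selected = included, model = current, roc = roc$points,
       auc = roc$auc, operating_point = op, separation_flag = sep_flag,
       cv_probabilities = prob)
}

#' ROC curve and trapezoidal AUC
#'
#' @param scores numeric predictions (higher = more likely positive)
#' @param labels binary outcomes
#' @return list: `points` (data.table `threshold`, `fpr`, `tpr`,
#'   monotone nondecreasing), `auc`
#' @export
roc_curve <- function(scores, labels) {
  y <- as.integer(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  keep <- c(diff(s) != 0, TRUE)  # one point per distinct threshold
  tpr <- c(0, tp[keep] / sum(y))
  fpr <- c(0, fp[keep] / sum(1 - y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.table::data.table(
    threshold = c(Inf, s[keep]), fpr = fpr, tpr = tpr), auc = auc)
}

#' Minimum number of trees to detect a SNP
#'
#' Under the one-informative-allele-per-tree model, the probability that a
#' SNP with minor allele frequency `maf` goes undetected in n trees is
#' (1 - maf)^n; the smallest n with (1 - maf)^n <= 1 - success_rate
#' guarantees detection with probability at least `success_rate`. This is
#' the model that reproduces the conventional 59 / 90 trees for MAF 0.05
#' at 95% / 99% detection.
#'
#' @param maf minor allele frequency, in (0, 1)
#' @param success_rate required detection probability, in (0, 1)
#' @return integer number of trees
#' @export
#' @examples
#' detection_sample_size(0.05, 0.95)  # 59
#' detection_sample_size(0.05, 0.99)  # 90
detection_sample_size <- function(maf, success_rate) {
  if (!is.numeric(maf) || maf <= 0 || maf >= 1)
    stopf("maf must lie in (0, 1)")
  if (!is.numeric(success_rate) || success_rate <= 0 || success_rate >= 1)
    stopf("success_rate must lie in (0, 1)")
  n <- max(1L, as.integer(ceiling(log(1 - success_rate) / log(1 - maf))))
  # guard against floating-point edge: verify the defining inequality
  while ((1 - maf)^n > 1 - success_rate) n <- n + 1L
  while (n > 1L && (1 - maf)^(n - 1L) <= 1 - success_rate) n <- n - 1L
  n
}
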