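# Per-SNP, per-population statistics: call rate, MAF, observed/expected
# heterozygosity, PIC, and a Hardy-Weinberg chi-square goodness-of-fit test.

#' Per-SNP population genetic statistics from genotype counts
#'
#' With allele frequency p = (2 nAA + nAB) / 2n estimated from the called
#' genotypes: MAF = min(p, 1-p); call rate = called / (called + nNC);
#' HETobs = nAB / n; HETexp = 2pq (plain product estimator, no
#' small-sample correction); PIC = 1 - (p^2 + q^2) - 2 p^2 q^2 (biallelic
#' Botstein form). Vectorized over count vectors.
#'
#' @param nAA,nAB,nBB,nNC genotype counts (A is the reference allele;
#'   vectors recycle to a common length)
#' @return data.table with columns `cr`, `maf`, `het_obs`, `het_exp`,
#'   `pic`, `hwe_chi2`, `hwe_p`, `n_called`; rows with zero called
#'   genotypes carry NA statistics
#' @export
#' @examples
#' snp_stats(25, 50, 25, 0)  # maf 0.5, het_obs 0.5, pic 0.375
snp_stats <- function(nAA, nAB, nBB, nNC = 0) {
  m <- max(length(nAA), length(nAB), length(nBB), length(nNC))
  nAA <- rep_len(nAA, m); nAB <- rep_len(nAB, m)
  nBB <- rep_len(nBB, m); nNC <- rep_len(nNC, m)
  if (any(c(nAA, nAB, nBB, nNC) < 0)) stopf("negative genotype counts")
  n <- nAA + nAB + nBB
  p <- ifelse(n > 0, (2 * nAA + nAB) / (2 * n), NA_real_)
  q <- 1 - p
  maf <- pmin(p, q)
  het_exp <- 2 * p * q
  pic <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
  hwe <- hwe_test(nAA, nAB, nBB)
  data.table::data.table(
    cr = ifelse(n + nNC > 0, n / (n + nNC), NA_real_),
    maf = maf,
    het_obs = ifelse(n > 0, nAB / n, NA_real_),
    het_exp = het_exp, pic = pic,
    hwe_chi2 = hwe$chi2, hwe_p = hwe$p, n_called = n)
}

#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' Pearson chi-square of the observed genotype counts against the
#' Hardy-Weinberg expectations n p^2, 2npq, n q^2 computed from the
#' estimated allele frequency; 1 degree of freedom, no continuity
#' correction. Monomorphic SNPs have no testable departure and return
#' chi2 = 0, p = 1 by convention.
#'
#' @param nAA,nAB,nBB genotype counts (vectorized)
#' @return list of vectors `chi2`, `p`
#' @export
#' @examples
#' hwe_test(25, 50, 25)  # chi2 = 0, p = 1 (exact HWE)
#' hwe_test(50, 0, 50)   # chi2 = 100 (complete heterozygote deficit)
hwe_test <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stopf("negative genotype counts")
  n <- nAA + nAB + nBB
  p <- ifelse(n > 0, (2 * nAA + nAB) / (2 * n), NA_real_)
  q <- 1 - p
  e_aa <- n * p^2; e_ab <- 2 * n * p * q; e_bb <- n * q^2
  chi2 <- ifelse(n == 0, NA_real_,
                 ifelse(p == 0 | p == 1, 0,
                        (nAA - e_aa)^2 / e_aa + (nAB - e_ab)^2 / e_ab +
                          (nBB - e_bb)^2 / e_bb))
  pval <- ifelse(is.na(chi2), NA_real_, pchisq(chi2, df = 1, lower.tail = FALSE))
  list(chi2 = chi2, p = pval)
}

#' Per-SNP statistics from a call matrix
#'
#' @param call_matrix character matrix samples x probesets
#'   (`AA`/`AB`/`BB`/`NC`)
#' @param population_id label attached to the output
#' @return data.table of [snp_stats()] rows with `probeset_id` and
#'   `population_id`
#' @export
call_matrix_stats <- function(call_matrix, population_id = "C1") {
  nAA <- colSums(call_matrix == "AA")
  nAB <- colSums(call_matrix == "AB")
  nBB <- colSums(call_matrix == "BB")
  nNC <- colSums(call_matrix == "NC")
  st <- snp_stats(nAA, nAB, nBB, nNC)
  st[, probeset_id := colnames(call_matrix)]
  st[, population_id := population_id]
  data.table::setcolorder(st, c("probeset_id", "population_id"))
  st[]
}

#' Cross-population medians and MAF histogram
#'
#' Per population, keeps SNPs that are polymorphic and in Hardy-Weinberg
#' equilibrium (p >= `hwe_alpha`), computes the medians of call rate, MAF,
#' observed heterozygosity, expected heterozygosity and PIC, and then
#' averages the per-population medians arithmetically. Also bins MAF into
#' 0.05-wide classes for two series: all polymorphic SNPs ("open") and the
#' HWE-filtered subset.
#'
#' @param stats data.table of per-SNP stats with a `population_id` column
#'   (rows from [call_matrix_stats()], one per SNP x population)
#' @param hwe_alpha HWE exclusion level (default 0.01: SNPs with
#'   p < 0.01 are excluded)
#' @return list: `per_population` medians, `averaged` (mean of the
#'   per-population medians), `n_snps` per population, `maf_histogram`
#'   (bin, population, series, count)
#' @export
population_summary <- function(stats, hwe_alpha = 0.01) {
  st <- data.table::as.data.table(stats)
  pops <- sort(unique(st$population_id))
  med <- list(); hist_rows <- list()
  breaks <- seq(0, 0.5, by = 0.05)
  for (p in pops) {
    sp <- st[population_id == p & !is.na(maf) & maf > 0]
    keep <- sp[hwe_p >= hwe_alpha]
    if (!nrow(keep))
      stopf("population %s: no polymorphic SNP passes the HWE filter (p >= %g)",
            p, hwe_alpha)
    med[[p]] <- keep[, .(population_id = p, n_snps = .N,
                         cr = median(cr), maf = median(maf),
                         het_obs = median(het_obs), het_exp = median(het_exp),
                         pic = median(pic))]
    for (series in c("open", "hwe")) {
      d <- if (series == "open") sp else keep
      cnt <- table(cut(d$maf, breaks, include.lowest = TRUE, right = FALSE))
      hist_rows[[paste(p, series)]] <- data.table::data.table(
        population_id = p, series = series,
        bin = names(cnt), count = as.integer(cnt))
    }
  }
  med <- data.table::rbindlist(med)
  averaged <- med[, lapply(.SD, mean), .SDcols = c("cr", "maf", "het_obs",
                                                   "het_exp", "pic")]
  list(per_population = med[], averaged = averaged[],
       n_snps = setNames(med$n_snps, med$population_id),
       maf_histogram = data.table::rbindlist(hist_rows))
}
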