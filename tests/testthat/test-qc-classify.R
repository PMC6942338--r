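test_that("qc_thresholds encodes the named protocols", {
  th <- qc_thresholds("default")
  expect_equal(th$dqc_min, 0.82)
  expect_equal(th$sample_cr_min, 0.97)
  expect_equal(th$plate_pass_fraction_min, 0.95)
  expect_equal(th$plate_cr_min, 0.985)
  expect_equal(th$snp_cr_cutoff, 0.97)
  expect_null(th$rescue_cr_cutoff)
  expect_equal(qc_thresholds("rescue70")$rescue_cr_cutoff, 0.70)
  mod <- qc_thresholds("modified")
  expect_equal(mod$dqc_min, 0.50)
  expect_equal(mod$snp_cr_cutoff, 0.95)
  expect_equal(mod$rescue_cr_cutoff, 0.80)
  expect_error(qc_thresholds("bogus"), "unknown protocol")
})

test_that("sample and plate QC apply Dish-QC, sample-CR, and plate rules", {
  # 100 samples on one plate; 4 fail on call rate, 1 on dqc
  n <- 100; np <- 50
  raw <- matrix("AA", n, np, dimnames = list(sprintf("s%03d", 1:n),
                                             sprintf("ps%02d", 1:np)))
  conf <- matrix(0.01, n, np, dimnames = dimnames(raw))
  conf[1:4, 1:10] <- 0.9  # 20% NoCall for samples 1-4 -> CR 0.80
  calls <- make_calls_object(raw, conf)
  samples <- simple_samples(rownames(raw))
  samples$dqc[5] <- 0.80  # below default 0.82
  th <- qc_thresholds("default")
  q <- sample_plate_qc(samples, calls$calls, th)
  expect_setequal(setdiff(rownames(raw), q$passing), sprintf("s%03d", 1:5))
  # plate: 95/100 passing = 0.95 >= 0.95 and plate CR 1.0 -> plate passes
  expect_true(q$plates$pass_plate)
  # under the modified protocol dqc 0.80 passes and CR 0.80 passes
  q2 <- sample_plate_qc(samples, calls$calls, qc_thresholds("modified"))
  expect_length(q2$passing, 100)
  # failing plate CR drags the whole plate down
  conf[, 1:2] <- 0.9  # every sample loses 4% CR -> 0.96 < 0.97
  callsB <- make_calls_object(raw, conf)
  qB <- sample_plate_qc(samples, callsB$calls, th)
  expect_length(qB$passing, 0)
})

test_that("classify_snp follows the category decision order", {
  th <- qc_thresholds("default")
  mono <- rep("AA", 100)
  expect_identical(classify_snp(mono, TRUE, th)$category, "MonoHighResolution")
  nmh <- c(rep("AA", 80), rep("AB", 15), rep("NC", 1))
  cl <- classify_snp(nmh, TRUE, th)
  expect_identical(cl$category, "NoMinorHom")
  expect_equal(cl$call_rate, 95 / 96)
  low <- c(rep("AA", 60), rep("AB", 20), rep("BB", 10), rep("NC", 10))
  expect_identical(classify_snp(low, TRUE, th)$category, "CallRateBelowThreshold")
  poly <- c(rep("AA", 60), rep("AB", 30), rep("BB", 10))
  expect_identical(classify_snp(poly, TRUE, th)$category, "PolyHighResolution")
  # unresolved dominates call-rate and polymorphism...
  expect_identical(classify_snp(poly, FALSE, th)$category, "Other")
  # ...and OTV dominates everything
  expect_identical(classify_snp(poly, FALSE, th, otv_fraction = 0.25)$category,
                   "OTV")
})

test_that("rescue re-thresholds confidences and requires polymorphism", {
  th <- qc_thresholds("rescue80")
  n <- 100
  mk <- function(geno, conf_vec) {
    raw <- matrix(geno, n, 1, dimnames = list(sprintf("s%03d", 1:n), "ps1"))
    conf <- matrix(conf_vec, n, 1, dimnames = dimnames(raw))
    make_calls_object(raw, conf)
  }
  # Other SNP whose calls are confident at 0.10: CR 0.85 >= 0.80, three
  # genotype classes -> Rescued
  geno <- c(rep("AA", 50), rep("AB", 25), rep("BB", 25))
  conf <- c(rep(0.05, 85), rep(0.5, 15))
  calls <- mk(geno, conf)
  cls <- classify_all(calls$calls, calls$diagnostics, th)
  cls$category <- "Other"  # force phase-1 category
  out <- rescue_snps(cls, calls, rownames(calls$calls), th)
  expect_identical(out$category, "Rescued")
  expect_true(out$successful)
  expect_equal(out$call_rate, 0.85)

  # boundary: phase-2 CR 0.55 below cutoff 0.60 -> unchanged
  th60 <- qc_thresholds("rescue60")
  conf2 <- c(rep(0.05, 55), rep(0.5, 45))
  calls2 <- mk(geno, conf2)
  cls2 <- classify_all(calls2$calls, calls2$diagnostics, th60)
  cls2$category <- "CallRateBelowThreshold"
  out2 <- rescue_snps(cls2, calls2, rownames(calls2$calls), th60)
  expect_identical(out2$category, "CallRateBelowThreshold")

  # monomorphic after re-threshold: not rescued (not successful)
  geno3 <- c(rep("AA", 95), rep("AB", 5))
  conf3 <- c(rep(0.05, 95), rep(0.12, 5))
  # at phase-1 0.15 there are AB calls; at phase-2 0.10 only AA remain
  calls3 <- mk(geno3, conf3)
  cls3 <- classify_all(calls3$calls, calls3$diagnostics, th)
  cls3$category <- "Other"
  out3 <- rescue_snps(cls3, calls3, rownames(calls3$calls), th)
  expect_identical(out3$category, "Other")
  expect_false(out3$successful)
  # unless monomorphic rescue is explicitly recorded (still unsuccessful)
  out3b <- rescue_snps(cls3, calls3, rownames(calls3$calls), th,
                       allow_monomorphic_rescue = TRUE)
  expect_identical(out3b$category, "Rescued")
  expect_false(out3b$successful)

  # other categories are untouched; missing cutoff errors
  cls4 <- data.table::copy(cls)
  cls4$category <- "PolyHighResolution"
  expect_identical(rescue_snps(cls4, calls, rownames(calls$calls), th)$category,
                   "PolyHighResolution")
  expect_error(rescue_snps(cls, calls, rownames(calls$calls),
                           qc_thresholds("default")), "rescue_cr_cutoff")
})

test_that("summarize_categories reproduces the converted/successful arithmetic", {
  counts <- c(PolyHighResolution = 31, NoMinorHom = 13, MonoHighResolution = 16,
              Rescued = 13, OTV = 1, Other = 24, CallRateBelowThreshold = 2)
  s <- summarize_categories(counts)
  expect_equal(s$total, 100)
  expect_equal(s$converted, 73)
  expect_equal(s$successful, 44)
  expect_equal(s$percent_successful, 44.0)
  # all SNPs Poly: successful fraction 1
  s2 <- summarize_categories(c(PolyHighResolution = 50))
  expect_equal(s2$percent_successful, 100)
  # partition: per-category counts sum to total
  expect_equal(sum(s$counts), s$total)
})

test_that("duplicate_accuracy counts genotype and allele concordance", {
  # 10 SNPs, one duplicated tree: 9 concordant, 1 pair AA vs AB
  calls <- rbind(s1 = c(rep("AA", 5), rep("AB", 4), "AA"),
                 s2 = c(rep("AA", 5), rep("AB", 4), "AB"))
  colnames(calls) <- sprintf("ps%02d", 1:10)
  st <- data.frame(sample_id = c("s1", "s2"), tree_id = "t1")
  acc <- duplicate_accuracy(calls, st)
  expect_equal(acc$genotype_accuracy, 0.9)
  expect_equal(acc$allele_accuracy, 0.95)
  expect_equal(acc$missing_fraction, 0)

  # opposite homozygotes share no alleles
  calls2 <- rbind(s1 = "AA", s2 = "BB")
  colnames(calls2) <- "ps1"
  acc2 <- duplicate_accuracy(calls2, st)
  expect_equal(acc2$genotype_accuracy, 0)
  expect_equal(acc2$allele_accuracy, 0)

  # NC excludes the pair and counts as missing
  calls3 <- rbind(s1 = c("AA", "NC"), s2 = c("AA", "AB"))
  colnames(calls3) <- c("ps1", "ps2")
  acc3 <- duplicate_accuracy(calls3, st)
  expect_equal(acc3$missing_fraction, 0.5)
  expect_equal(acc3$n_pairs_compared, 1)

  expect_error(duplicate_accuracy(calls, data.frame(sample_id = c("s1", "s2"),
                                                    tree_id = c("t1", "t2"))),
               "duplicate")
})

test_that("allele accuracy never falls below genotype accuracy", {
  for (seed in 1:5) {
    set.seed(seed)
    n_snps <- 40
    calls <- rbind(
      s1 = sample(c("AA", "AB", "BB", "NC"), n_snps, TRUE, prob = c(.4, .3, .2, .1)),
      s2 = sample(c("AA", "AB", "BB", "NC"), n_snps, TRUE, prob = c(.4, .3, .2, .1)))
    colnames(calls) <- sprintf("ps%02d", seq_len(n_snps))
    st <- data.frame(sample_id = c("s1", "s2"), tree_id = "t1")
    acc <- duplicate_accuracy(calls, st)
    expect_gte(acc$allele_accuracy, acc$genotype_accuracy)
  }
})

test_that("classification matches a brute-force reclassifier on small instances", {
  for (seed in c(101, 202, 303)) {
    fx <- random_calls_fixture(n_samples = 40, n_probesets = 50, seed = seed)
    set.seed(seed + 1)
    resolved <- runif(50) < 0.7
    otv_fraction <- ifelse(runif(50) < 0.1, 0.3, 0)
    th <- qc_thresholds(sample(c("rescue90", "rescue70", "rescue60"), 1))
    calls <- make_calls_object(fx$raw, fx$conf, resolved = resolved,
                               threshold = th$confidence_threshold)
    cls <- classify_all(calls$calls, calls$diagnostics, th,
                        otv_fraction = as.list(setNames(otv_fraction,
                                                        colnames(fx$raw))))
    cls <- rescue_snps(cls, calls, rownames(fx$raw), th)
    oracle <- brute_force_classify(fx$raw, fx$conf, resolved, otv_fraction, th)
    expect_identical(setNames(cls$category, cls$probeset_id), oracle)
    # category partition
    expect_equal(sum(table(cls$category)), 50)
  }
})
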