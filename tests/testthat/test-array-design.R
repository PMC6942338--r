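cand_row <- function(snp_id = "snpA", alleles = c("A", "C"), fv = "",
                     infinium = FALSE, source = "OSU", transcript = "tr1",
                     ps = 1e-5, conf = 2) {
  data.frame(snp_id = snp_id, source = source, transcript_id = transcript,
             transcript_confidence = conf, allele_a = alleles[1],
             allele_b = alleles[2],
             context_seq = strrep("A", 35) %+% alleles[1] %+% strrep("C", 35),
             target_snp_prob = if (source == "OSU") ps else NA_real_,
             n_detect_programs = if (source == "UH") 2L else NA_integer_,
             flanking_variants = fv, infinium_success = infinium)
}
`%+%` <- paste0

ps_row <- function(snp_id = "snpA", direction = "forward", pconvert = 0.8,
                   repetitive = FALSE, rec = NULL, match = TRUE, hits = 1L,
                   perfect = 1L, frank = 1L) {
  data.frame(probeset_id = paste0(snp_id, "-", substr(direction, 1, 1)),
             snp_id = snp_id, direction = direction, repetitive = repetitive,
             pconvert = pconvert,
             recommendation = rec %||% axiomsnp::pconvert_recommendation(pconvert),
             genome_match = match, n_scaffold_hits_v05 = hits,
             n_perfect_alleles = perfect, flanking_rank = frank)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("buildable applies the high-tier flank rule with exact boundaries", {
  none <- list(flanking_variants = "")
  expect_true(buildable(none, "forward"))
  expect_true(buildable(none, "reverse"))
  # high-tier variant at 35: blocks forward only (boundary)
  v35 <- list(flanking_variants = "35:high")
  expect_false(buildable(v35, "forward"))
  expect_true(buildable(v35, "reverse"))
  # position 37 blocks reverse only
  v37 <- list(flanking_variants = "37:high")
  expect_true(buildable(v37, "forward"))
  expect_false(buildable(v37, "reverse"))
  # low tier does not block
  expect_true(buildable(list(flanking_variants = "20:low"), "forward"))
  # the target position itself is an input error
  expect_error(buildable(list(flanking_variants = "36:high"), "forward"),
               "position 36")
})

test_that("filter_candidates implements the acceptability and A/T-C/G rules", {
  cands <- rbind(
    cand_row("snpAT", c("A", "T")),                     # A/T, not validated
    cand_row("snpATinf", c("A", "T"), infinium = TRUE), # A/T but validated
    cand_row("snpOK", c("A", "G")),
    cand_row("snpFlank", c("A", "C"), fv = "10:high"),  # forward flank blocked
    cand_row("snpRecInf", c("A", "C"), infinium = TRUE),
    cand_row("snpRec", c("A", "C")))
  probes <- rbind(
    ps_row("snpAT"), ps_row("snpATinf"), ps_row("snpOK"),
    ps_row("snpOK", "reverse"),
    ps_row("snpFlank", "forward", frank = NA_integer_),
    ps_row("snpFlank", "reverse"),
    ps_row("snpRecInf", rec = "not_recommended", pconvert = 0.3),
    ps_row("snpRec", rec = "not_recommended", pconvert = 0.3),
    ps_row("snpNoMatch", match = FALSE))
  expect_error(filter_candidates(cands, probes), "unknown SNPs")
  probes <- probes[probes$snp_id != "snpNoMatch", ]

  out <- filter_candidates(cands, probes)
  kept <- unique(out$probesets$snp_id)
  # A/T removed unless Infinium-validated
  expect_false("snpAT" %in% kept)
  expect_true("snpATinf" %in% kept)
  expect_true("at_cg" %in% out$rejections$reason[out$rejections$id == "snpAT"])
  # not_recommended removed, unless Infinium-validated with a buildable probeset
  expect_false("snpRec" %in% kept)
  expect_true("snpRecInf" %in% kept)
  # high-tier variant in one flank only: the other direction survives
  expect_identical(out$probesets[out$probesets$snp_id == "snpFlank", ]$direction,
                   "reverse")
})

test_that("rank_transcripts orders by hit category, confidence, SNP count", {
  tr <- data.frame(
    transcript_id = c("t_cat0", "t_cat1", "t_gt1", "t_conf", "t_snps", "t_uh"),
    mean_hits = c(0, 1, 2.5, 1, 1, 1),
    confidence_score = c(1, 2, 1, 1, 2, NA),
    n_snps = c(9, 5, 9, 2, 2, 9))
  rk <- rank_transcripts(tr)
  # category 1 beats gt1 beats 0
  expect_lt(which(rk$transcript_id == "t_cat1"),
            which(rk$transcript_id == "t_gt1"))
  expect_gt(which(rk$transcript_id == "t_cat0"),
            which(rk$transcript_id == "t_gt1"))
  # within category 1: lower confidence first
  expect_lt(which(rk$transcript_id == "t_conf"),
            which(rk$transcript_id == "t_cat1"))
  # equal category+confidence: more SNPs first
  expect_lt(which(rk$transcript_id == "t_cat1"),
            which(rk$transcript_id == "t_snps"))
  # fully tied pair is ordered deterministically (lexicographic)
  tied <- data.frame(transcript_id = c("b", "a"), mean_hits = 1,
                     confidence_score = 1, n_snps = 3)
  expect_identical(rank_transcripts(tied)$transcript_id, c("a", "b"))
})

test_that("rank_probesets applies the five within-transcript keys in order", {
  base <- function(id, ...) {
    row <- ps_row(id, ...)
    row$infinium_success <- FALSE
    row$target_snp_prob <- 1e-5
    row$n_detect_programs <- NA_integer_
    row
  }
  ps <- rbind(
    within(base("worstEverything", pconvert = 0.1, perfect = 0L, frank = 3L),
           infinium_success <- TRUE),
    base("flank1", frank = 1L, pconvert = 0.5),
    base("flank2", frank = 2L, pconvert = 0.9),
    base("perf1", perfect = 1L, pconvert = 0.2),
    base("perf2", perfect = 2L, pconvert = 0.9),
    base("perf0", perfect = 0L, pconvert = 0.9))
  rk <- rank_probesets(ps)
  # Infinium first even when everything else is worse
  expect_identical(rk$snp_id[1], "worstEverything")
  # flanking rank 1 before 2 despite lower pconvert
  expect_lt(which(rk$snp_id == "flank1"), which(rk$snp_id == "flank2"))
  # perfect-allele order 1, 2, 0
  expect_lt(which(rk$snp_id == "perf1"), which(rk$snp_id == "perf2"))
  expect_lt(which(rk$snp_id == "perf2"), which(rk$snp_id == "perf0"))
  # pconvert breaks remaining ties
  tie <- rbind(base("pcHi", pconvert = 0.8), base("pcLo", pconvert = 0.5))
  expect_identical(rank_probesets(tie)$snp_id[1], "pcHi")
})

test_that("select_array is a deterministic round-robin honoring capacity", {
  cands <- rbind(cand_row("s1a", transcript = "t1"),
                 cand_row("s1b", transcript = "t1"),
                 cand_row("s2", transcript = "t2"),
                 cand_row("s3", transcript = "t3"))
  probes <- rbind(ps_row("s1a"), ps_row("s1b"), ps_row("s2"), ps_row("s3"))
  flt <- filter_candidates(cands, probes)
  tr <- rank_transcripts(transcript_table(flt$probesets))

  # coverage before depth: capacity 3 takes one probeset per transcript
  sel <- select_array(tr, flt$probesets, capacity = 3)
  expect_equal(nrow(sel), 3)
  expect_setequal(sel$transcript_id, c("t1", "t2", "t3"))

  # capacity >= total: everything selected
  sel_all <- select_array(tr, flt$probesets, capacity = 100)
  expect_equal(nrow(sel_all), 4)

  # determinism
  expect_identical(select_array(tr, flt$probesets, 3),
                   select_array(tr, flt$probesets, 3))
  expect_error(select_array(tr, flt$probesets, 0), "capacity")
})

test_that("a lone SNP can contribute both strand probesets", {
  cands <- cand_row("solo", transcript = "t1")
  probes <- rbind(ps_row("solo", "forward"), ps_row("solo", "reverse"))
  flt <- filter_candidates(cands, probes)
  tr <- rank_transcripts(transcript_table(flt$probesets))
  sel <- select_array(tr, flt$probesets, capacity = 2)
  expect_setequal(sel$direction, c("forward", "reverse"))
})

test_that("A/T SNPs cost two capacity slots", {
  cands <- rbind(cand_row("at", c("A", "T"), infinium = TRUE, transcript = "t1"),
                 cand_row("cg", c("A", "C"), transcript = "t2"))
  probes <- rbind(ps_row("at"), ps_row("cg"))
  flt <- filter_candidates(cands, probes)
  tr <- rank_transcripts(transcript_table(flt$probesets))
  sel2 <- select_array(tr, flt$probesets, capacity = 2)
  # capacity 2 cannot hold the A/T (2 slots) plus the other; the round-robin
  # takes the A/T (2 slots) or, if it does not fit after the first pick, skips
  expect_lte(sum(ifelse(sel2$allele_b == "T", 2, 1)), 2)
  sel3 <- select_array(tr, flt$probesets, capacity = 3)
  expect_equal(nrow(sel3), 2)  # both SNPs fit in 3 slots (2 + 1)
})

test_that("coverage dominance holds on generated candidate sets", {
  cfg <- sim_config(n_snps = 150, n_samples_per_pop = 10, seed = 11)
  cand <- gen_candidates(cfg)
  des <- design_array(cand$candidates, cand$probesets, capacity = 120)
  sel <- des$selected
  # every selected probeset passed the filter
  expect_true(all(sel$probeset_id %in%
                    filter_candidates(cand$candidates,
                                      cand$probesets)$probesets$probeset_id))
  # no transcript receives a second SNP before every coverable transcript
  # has its first: find the selection index of each transcript's first and
  # second distinct SNP
  idx_first <- tapply(seq_len(nrow(sel)), sel$transcript_id, min)
  second_snp_idx <- c()
  for (tid in unique(sel$transcript_id)) {
    rows <- sel[sel$transcript_id == tid, ]
    snps <- unique(rows$snp_id)
    if (length(snps) > 1)
      second_snp_idx <- c(second_snp_idx,
                          min(which(sel$transcript_id == tid &
                                      sel$snp_id == snps[2])))
  }
  if (length(second_snp_idx))
    expect_true(max(idx_first) < min(second_snp_idx))
  # selection stays within capacity (A/T cost 2)
  cost <- sum(ifelse((sel$allele_a == "A" & sel$allele_b == "T") |
                       (sel$allele_a == "T" & sel$allele_b == "A") |
                       (sel$allele_a == "C" & sel$allele_b == "G") |
                       (sel$allele_a == "G" & sel$allele_b == "C"), 2, 1))
  expect_lte(cost, 120)
})
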