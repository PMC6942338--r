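# Synthetic array experiment generator.
#
# The real array intensities behind the published Douglas-fir-style results
# are proprietary and undeposited, so this module fabricates a full
# experiment -- candidate SNPs with 71-nt probe contexts, design features,
# genotype truth, two-channel intensities, and sample/plate metadata -- whose
# statistical structure matches what the downstream design/calling/QC stages
# assume. Every draw is seeded and stream-separated, so output is
# reproducible and ground truth is available for parameter-recovery tests.

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all `gen_*`
#' generators. Defaults describe a realistic two-population conifer array
#' experiment: latent SNP quality classes loosely calibrated to the category
#' percentages observed on a conifer Axiom array under default QC
#' (PolyHighResolution 31%, Other 30%, MonoHighResolution 16%, NoMinorHom
#' 13%, CallRateBelowThreshold 8%, OTV 1%), a flat minor-allele-frequency
#' spectrum on [0.01, 0.5] (arrays select for common SNPs), Dish-QC
#' concentrated near 0.95 with a small failing tail, and ~5% of trees
#' sampled twice from independent DNA isolations.
#'
#' @param n_snps number of SNPs to simulate
#' @param n_samples_per_pop number of distinct trees per population
#'   (duplicate samples are added on top, see `duplicate_fraction`)
#' @param n_pops number of populations (1 or 2)
#' @param maf_distribution named distribution for true minor allele
#'   frequencies, e.g. `list(name = "uniform", min = 0.01, max = 0.5)`
#' @param class_proportions named fractions over the six latent SNP quality
#'   classes `poly_resolved`, `no_minor_hom`, `monomorphic`, `low_cr`,
#'   `otv`, `unresolvable`; must sum to 1
#' @param duplicate_fraction fraction of trees with a second, independently
#'   assayed sample
#' @param dqc_distribution named distribution on \[0,1\] for per-sample
#'   Dish-QC
#' @param plate_size samples per 96-well plate
#' @param cluster list of intensity-model parameters: `delta` (homozygote
#'   contrast mean, log2 units), `sd_poly` (within-cluster contrast SD of
#'   well-behaved SNPs), `unres_blob_delta`/`unres_blob_sd` (compressed
#'   genotype means and inflated SD of `unresolvable` SNPs, whose clusters
#'   fuse into one broad blob -- calls stay confident, as on real arrays,
#'   but the cluster geometry fails resolution QC), `size_mean`, `size_sd`
#'   (log2 average intensity), `otv_size_shift` (downward size shift of the
#'   off-target cluster), `otv_sample_fraction` (fraction of samples in
#'   it), `lowcr_missing_range` and `lowcr_missing_shape` (range and beta
#'   shape of per-SNP corrupted-call fractions for `low_cr` SNPs; the
#'   default concentrates call rates just under the 97% cutoff with a thin
#'   tail toward 60%, the shape the rescue protocols exploit)
#' @param design list of design-feature parameters: `osu_fraction`,
#'   `infinium_fraction`, `at_cg_fraction`, `mean_snps_per_transcript`
#' @param success_model stated logistic model for the synthetic probeset
#'   success label: `list(intercept =, coefficients = c(...))`; see
#'   [gen_design_features()]
#' @param seed master integer seed
#' @return a validated `sim_config` list
#' @export
#' @examples
#' cfg <- sim_config(n_snps = 200, n_samples_per_pop = 50, seed = 1)
sim_config <- function(n_snps = 2000,
                       n_samples_per_pop = 200,
                       n_pops = 2,
                       maf_distribution = list(name = "uniform", min = 0.01, max = 0.5),
                       class_proportions = c(poly_resolved = 0.31,
                                             no_minor_hom  = 0.13,
                                             monomorphic   = 0.16,
                                             low_cr        = 0.08,
                                             otv           = 0.01,
                                             unresolvable  = 0.31),
                       duplicate_fraction = 0.05,
                       dqc_distribution = list(name = "beta", shape1 = 28, shape2 = 2),
                       plate_size = 96,
                       cluster = list(),
                       design = list(),
                       success_model = NULL,
                       seed = 1L) {
  if (!n_pops %in% 1:2) stopf("n_pops must be 1 or 2")
  if (n_snps < 1 || n_samples_per_pop < 1) stopf("n_snps and n_samples_per_pop must be >= 1")
  if (plate_size < 1) stopf("plate_size must be >= 1")
  missing_cls <- setdiff(LATENT_CLASSES, names(class_proportions))
  if (length(missing_cls))
    stopf("class_proportions missing classes: %s", paste(missing_cls, collapse = ", "))
  class_proportions <- class_proportions[LATENT_CLASSES]
  assert_fraction(class_proportions, "class_proportions")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stopf("class_proportions must sum to 1 (got %.12f)", sum(class_proportions))
  assert_fraction(duplicate_fraction, "duplicate_fraction")

  cluster_defaults <- list(delta = 1.5, sd_poly = 0.15,
                           unres_blob_delta = 0.375, unres_blob_sd = 0.75,
                           size_mean = 10, size_sd = 0.3,
                           otv_size_shift = 3, otv_sample_fraction = 0.3,
                           lowcr_missing_range = c(0.03, 0.40),
                           lowcr_missing_shape = c(1, 5))
  cluster <- utils::modifyList(cluster_defaults, cluster)
  design_defaults <- list(osu_fraction = 0.94, infinium_fraction = 0.03,
                          at_cg_fraction = 0.08, mean_snps_per_transcript = 2.5)
  design <- utils::modifyList(design_defaults, design)
  if (is.null(success_model))
    success_model <- list(intercept = 0,
                          coefficients = c(pid_gap = 0.05, pconvert = 1.2,
                                           scaffold_one = 0.5, neglog10_ps = 0.1,
                                           infinium = 1.0))
  structure(list(n_snps = as.integer(n_snps),
                 n_samples_per_pop = as.integer(n_samples_per_pop),
                 n_pops = as.integer(n_pops),
                 maf_distribution = maf_distribution,
                 class_proportions = class_proportions,
                 duplicate_fraction = duplicate_fraction,
                 dqc_distribution = dqc_distribution,
                 plate_size = as.integer(plate_size),
                 cluster = cluster, design = design,
                 success_model = success_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

random_context <- function(n, allele_a) {
  # 71-nt context; position 36 carries the A allele of the SNP
  flanks <- vapply(seq_len(n), function(i)
    paste0(sample(BASES, 70, replace = TRUE), collapse = ""), character(1))
  paste0(substr(flanks, 1, 35), allele_a, substr(flanks, 36, 70))
}

encode_variants <- function(pos, tier) {
  if (!length(pos)) return("")
  paste(sprintf("%d:%s", pos, tier), collapse = ";")
}

#' Parse an encoded flanking-variant string
#'
#' Flanking variants are stored as `"pos:tier;pos:tier"` with 1-based
#' positions in 1..71 (never 36, the target SNP itself) and tiers
#' `low`/`medium`/`high`.
#'
#' @param s encoded string (may be `""`)
#' @return data.frame with columns `position`, `tier`
#' @export
parse_flanking_variants <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(position = integer(), tier = character()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  out <- data.frame(position = as.integer(vapply(parts, `[`, "", 1)),
                    tier = vapply(parts, `[`, "", 2))
  if (any(out$position == 36L)) stopf("flanking variant at target position 36")
  if (any(out$position < 1L | out$position > 71L))
    stopf("flanking variant position outside 1..71")
  out
}

flank_window <- function(direction) {
  switch(direction, forward = 1:35, reverse = 37:71,
         stopf("direction must be 'forward' or 'reverse'"))
}

# Flanking-variant priority rank of one probeset direction: 1 = no variants
# at any confidence tier in the probe flank, 2 = only low-tier variants,
# 3 = low/medium but no high-tier; NA = high-tier variant present (the
# probeset is not buildable).
flanking_rank_for <- function(variants, direction) {
  win <- flank_window(direction)
  v <- variants[variants$position %in% win, , drop = FALSE]
  if (!nrow(v)) return(1L)
  if (any(v$tier == "high")) return(NA_integer_)
  if (any(v$tier == "medium")) return(3L)
  2L
}

#' Generate candidate SNPs and probeset designs
#'
#' Fabricates a candidate table in the shape produced by transcriptome-based
#' SNP discovery plus vendor probeset scoring: 71-nt contexts with the target
#' SNP at position 36, tiered flanking variants, a per-SNP target-SNP
#' p-value (OSU-style) or detection-program count (UH-style), an Infinium
#' validation flag, and per-direction probesets carrying pConvert,
#' Repetitive, recommendation bins, v0.5 scaffold-hit and perfect-allele
#' counts. Repetitive probesets get pConvert 0; recommendation bins follow
#' pConvert: recommended \[0.6, 1\], neutral \[0.4, 0.6), not_recommended
#' \[0, 0.4).
#'
#' @param config a [sim_config()]
#' @return list with data.tables `candidates` and `probesets`
#' @export
gen_candidates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  d <- config$design
  with_stream(config$seed, 1L, {
    snp_id <- sprintf("snp%06d", seq_len(n))
    source <- ifelse(runif(n) < d$osu_fraction, "OSU", "UH")

    # transcripts: 1 + Poisson sizes, assigned in order
    sizes <- integer(0)
    while (sum(sizes) < n)
      sizes <- c(sizes, 1L + stats::rpois(max(16L, n %/% 2L),
                                          max(0, d$mean_snps_per_transcript - 1)))
    sizes <- sizes[cumsum(sizes) - sizes < n]
    transcript_id <- rep(sprintf("tr%05d", seq_along(sizes)), times = sizes)[seq_len(n)]
    transcript_confidence <- round(runif(length(sizes), 0, 10), 3)[
      match(transcript_id, sprintf("tr%05d", seq_along(sizes)))]

    at_cg <- runif(n) < d$at_cg_fraction
    allele_a <- character(n); allele_b <- character(n)
    pairs_atcg <- list(c("A", "T"), c("C", "G"))
    pairs_other <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    for (i in seq_len(n)) {
      p <- if (at_cg[i]) pairs_atcg[[sample.int(2L, 1L)]] else
        pairs_other[[sample.int(4L, 1L)]]
      if (runif(1) < 0.5) p <- rev(p)
      allele_a[i] <- p[1]; allele_b[i] <- p[2]
    }
    context_seq <- random_context(n, allele_a)

    # tiered flanking variants: ~1.2 per SNP, positions uniform over 1..71 \ {36}
    fv <- character(n)
    positions <- setdiff(1:71, 36)
    for (i in seq_len(n)) {
      k <- stats::rpois(1, 1.2)
      if (k > 0) {
        pos <- sample(positions, min(k, 70))
        tier <- sample(c("low", "medium", "high"), length(pos),
                       replace = TRUE, prob = c(0.5, 0.3, 0.2))
        fv[i] <- encode_variants(pos, tier)
      }
    }

    target_snp_prob <- ifelse(source == "OSU", 10^runif(n, -8, -3), NA_real_)
    n_detect_programs <- ifelse(source == "UH",
                                sample(1:3, n, replace = TRUE,
                                       prob = c(0.2, 0.45, 0.35)), NA_integer_)
    infinium_success <- runif(n) < d$infinium_fraction

    candidates <- data.table::data.table(
      snp_id = snp_id, source = source, transcript_id = transcript_id,
      transcript_confidence = ifelse(source == "UH", NA_real_, transcript_confidence),
      allele_a = allele_a, allele_b = allele_b, context_seq = context_seq,
      target_snp_prob = target_snp_prob, n_detect_programs = n_detect_programs,
      flanking_variants = fv, infinium_success = infinium_success)

    # probesets: one per direction per SNP
    probesets <- data.table::CJ(snp_id = snp_id, direction = c("forward", "reverse"),
                                sorted = FALSE)
    data.table::setorder(probesets, snp_id, direction)
    m <- nrow(probesets)
    probesets[, probeset_id := sprintf("AX-%s-%s", sub("^snp", "", snp_id),
                                       ifelse(direction == "forward", "F", "R"))]
    probesets[, repetitive := runif(m) < 0.05]
    probesets[, pconvert := round(ifelse(repetitive, 0, rbeta(m, 6, 4)), 4)]
    probesets[, recommendation := ifelse(repetitive & runif(m) < 0.3, "not_possible",
                                         pconvert_recommendation(pconvert))]
    probesets[, genome_match := runif(m) < 0.95]
    probesets[, n_scaffold_hits_v05 := sample(c(0L, 1L, 2L, 3L), m, replace = TRUE,
                                              prob = c(0.05, 0.75, 0.15, 0.05))]
    probesets[, n_perfect_alleles := sample(c(0L, 1L, 2L), m, replace = TRUE,
                                            prob = c(0.12, 0.80, 0.08))]
    vlist <- lapply(fv, parse_flanking_variants)
    names(vlist) <- snp_id
    probesets[, flanking_rank := mapply(function(sid, dir)
      flanking_rank_for(vlist[[sid]], dir), snp_id, direction)]
    list(candidates = candidates, probesets = probesets[])
  })
}

#' pConvert recommendation bins
#'
#' @param pconvert numeric vector in \[0,1\]
#' @return character vector: `recommended` for pConvert in \[0.6, 1\],
#'   `neutral` for \[0.4, 0.6), `not_recommended` for \[0, 0.4)
#' @export
pconvert_recommendation <- function(pconvert) {
  assert_fraction(pconvert, "pconvert")
  ifelse(pconvert >= 0.6, "recommended",
         ifelse(pconvert >= 0.4, "neutral", "not_recommended"))
}

#' Generate genotype ground truth
#'
#' Assigns each SNP a latent quality class and per-population true MAF, then
#' draws per-sample genotypes: Hardy-Weinberg proportions for polymorphic
#' classes, all major-homozygote for `monomorphic`, and HWE conditioned on
#' "no minor homozygote" for `no_minor_hom`. Duplicate samples of a tree
#' copy its genotype vector exactly; discordance can only arise later from
#' the calling noise model. Also draws the sample/plate metadata (plate
#' assignment, Dish-QC).
#'
#' @param config a [sim_config()]
#' @return list of data.tables/matrix: `snps` (snp_id, class, maf per pop),
#'   `samples` (sample_id, tree_id, population, plate_id, dqc), and
#'   `genotypes`, an integer matrix samples x SNPs counting copies of the
#'   minor (B) allele: 0 = AA, 1 = AB, 2 = BB
#' @export
gen_genotype_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps

  snps <- with_stream(config$seed, 2L, {
    cls <- sample(LATENT_CLASSES, n, replace = TRUE, prob = config$class_proportions)
    dt <- data.table::data.table(snp_id = sprintf("snp%06d", seq_len(n)), class = cls)
    for (p in seq_len(config$n_pops)) {
      maf <- draw_distribution(n, config$maf_distribution)
      maf[cls == "monomorphic"] <- 0
      dt[, (sprintf("maf_pop%d", p)) := maf]
    }
    dt
  })

  samples <- with_stream(config$seed, 3L, {
    out <- list()
    for (p in seq_len(config$n_pops)) {
      ntree <- config$n_samples_per_pop
      tree_id <- sprintf("P%d_T%04d", p, seq_len(ntree))
      dup <- runif(ntree) < config$duplicate_fraction
      # paste0(character(0), x) yields x, not character(0): guard empty case
      dup_sid <- if (any(dup)) paste0(tree_id[dup], "_s2") else character(0)
      sid <- c(paste0(tree_id, "_s1"), dup_sid)
      out[[p]] <- data.table::data.table(
        sample_id = sid,
        tree_id = c(tree_id, tree_id[dup]),
        population = sprintf("C%d", p))
    }
    out <- data.table::rbindlist(out)
    out[, plate_id := sprintf("plate%03d", 1L + (seq_len(.N) - 1L) %/% config$plate_size)]
    out[, dqc := pmin(1, pmax(0, draw_distribution(.N, config$dqc_distribution)))]
    out
  })

  genotypes <- with_stream(config$seed, 4L, {
    G <- matrix(NA_integer_, nrow = nrow(samples), ncol = n,
                dimnames = list(samples$sample_id, snps$snp_id))
    first <- !duplicated(samples$tree_id)
    for (p in seq_len(config$n_pops)) {
      in_pop <- samples$population == sprintf("C%d", p) & first
      ntree <- sum(in_pop)
      maf <- snps[[sprintf("maf_pop%d", p)]]
      for (j in seq_len(n)) {
        q <- maf[j]
        probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)  # AA, AB, BB
        if (snps$class[j] == "monomorphic") {
          g <- rep(0L, ntree)
        } else if (snps$class[j] == "no_minor_hom") {
          pr <- probs[1:2] / sum(probs[1:2])
          g <- sample(0:1, ntree, replace = TRUE, prob = pr)
        } else {
          g <- sample(0:2, ntree, replace = TRUE, prob = probs)
        }
        G[in_pop, j] <- g
      }
    }
    # duplicates copy the tree's genotype row
    dup_rows <- which(duplicated(samples$tree_id))
    for (i in dup_rows) {
      src <- which(first & samples$tree_id == samples$tree_id[i])[1]
      G[i, ] <- G[src, ]
    }
    G
  })

  list(snps = snps, samples = samples, genotypes = genotypes)
}

#' Generate two-channel intensity data
#'
#' Draws log-normal channel signals from per-class cluster models in
#' contrast/size coordinates (contrast = log2 A/B, size = mean log2 signal).
#' `poly_resolved` SNPs give three well-separated contrast clusters centered
#' at +delta/0/-delta for AA/AB/BB; `unresolvable` SNPs compress the
#' genotype means and inflate the within-cluster SD so the clusters fuse
#' into one broad blob (the array analogue of SNPs whose cluster plot
#' cannot be partitioned; their calls remain confident but their geometry
#' fails resolution QC); `otv` SNPs shift a fraction of samples into a
#' low-size off-target cluster; `low_cr` SNPs zero a per-SNP fraction of
#' signal pairs (downstream these become missing/NoCall).
#'
#' @param truth output of [gen_genotype_truth()]
#' @param config the same [sim_config()]
#' @return list with matrices `signal_a`, `signal_b` (samples x probesets;
#'   probeset ids are the SNP ids) and the `truth` passthrough
#' @export
gen_intensity_data <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$cluster
  G <- truth$genotypes
  ns <- nrow(G); np <- ncol(G)
  with_stream(config$seed, 5L, {
    # genotype 0 = AA -> contrast +delta; 2 = BB -> -delta
    unres <- truth$snps$class == "unresolvable"
    delta <- ifelse(unres, cl$unres_blob_delta, cl$delta)
    mu <- sweep(1 - G, 2, delta, "*")
    sdv <- matrix(cl$sd_poly, ns, np)
    sdv[, unres] <- cl$unres_blob_sd
    contrast <- matrix(rnorm(ns * np, mu, sdv), ns, np)
    size <- matrix(rnorm(ns * np, cl$size_mean, cl$size_sd), ns, np)

    otv_cols <- which(truth$snps$class == "otv")
    for (j in otv_cols) {
      k <- which(runif(ns) < cl$otv_sample_fraction)
      size[k, j] <- size[k, j] - cl$otv_size_shift
      contrast[k, j] <- rnorm(length(k), 0, cl$sd_poly)
    }

    a <- 2^(size + contrast / 2)
    b <- 2^(size - contrast / 2)
    lc_cols <- which(truth$snps$class == "low_cr")
    for (j in lc_cols) {
      r <- cl$lowcr_missing_range; sh <- cl$lowcr_missing_shape
      f <- r[1] + diff(r) * rbeta(1, sh[1], sh[2])
      k <- which(runif(ns) < f)
      a[k, j] <- 0; b[k, j] <- 0
    }
    dimnames(a) <- dimnames(b) <- dimnames(G)
    list(signal_a = a, signal_b = b, truth = truth)
  })
}

#' Generate design features with a planted success model
#'
#' Emits, per probeset, BLAST-style v1.0 features (best and second-best
#' scaffold percent identity with an 80-floor for missing hits, binned hit
#' counts for scaffolds/singletons/gene models/transcripts) alongside the
#' design variables (pConvert, target-SNP probability, flanking rank,
#' Infinium flag, perfect-allele count), plus a Bernoulli `success` label
#' drawn from a stated logistic model so that feature-selection methods have
#' known signal to find. Model: logit P(success) = intercept +
#' sum(coefficients * features), with features `pid_gap` (pid_best -
#' pid_second, percent), `pconvert`, `scaffold_one` (indicator of exactly
#' one scaffold hit), `neglog10_ps` (-log10 target SNP p-value, 0 for UH),
#' `infinium` (indicator).
#'
#' @param candidates,probesets output of [gen_candidates()]
#' @param config the [sim_config()]; `config$success_model` holds the model
#' @return data.table of features plus `success` (0/1) and the latent
#'   `true_logit`
#' @export
gen_design_features <- function(candidates, probesets, config) {
  stopifnot(inherits(config, "sim_config"))
  with_stream(config$seed, 6L, {
    ft <- merge(probesets,
                candidates[, .(snp_id, source, target_snp_prob, infinium_success)],
                by = "snp_id", sort = FALSE)
    m <- nrow(ft)
    has_hit <- runif(m) < 0.9
    pid_best <- ifelse(has_hit, pmin(100, 100 - stats::rexp(m, 1 / 3)), 80)
    has_second <- has_hit & runif(m) < 0.6
    pid_second <- ifelse(has_second, pmax(80, pid_best - stats::rexp(m, 1 / 12)), 80)
    pid_second <- pmin(pid_second, pid_best)
    ft[, pid_best := round(pid_best, 2)]
    ft[, pid_second := round(pid_second, 2)]
    ft[, pid_pair_category := pid_pair_category(pid_best, pid_second)]
    for (tgt in c("scaffold", "singleton", "genemodel", "transcript"))
      ft[, (paste0("hits_", tgt)) := sample(c("one", "gt1", "zero"), m,
                                            replace = TRUE,
                                            prob = c(0.6, 0.3, 0.1))]
    x <- data.frame(
      pid_gap = ft$pid_best - ft$pid_second,
      pconvert = ft$pconvert,
      scaffold_one = as.numeric(ft$hits_scaffold == "one"),
      neglog10_ps = ifelse(is.na(ft$target_snp_prob), 0,
                           -log10(ft$target_snp_prob)),
      infinium = as.numeric(ft$infinium_success))
    sm <- config$success_model
    beta <- sm$coefficients
    unknown <- setdiff(names(beta), names(x))
    if (length(unknown)) stopf("success_model names unknown features: %s",
                               paste(unknown, collapse = ", "))
    eta <- sm$intercept + as.matrix(x[, names(beta), drop = FALSE]) %*% beta
    ft[, true_logit := as.numeric(eta)]
    ft[, success := as.integer(runif(m) < plogis(true_logit))]
    ft[]
  })
}

#' Three-class category for the top-two-hit percent identities
#'
#' @param pid_best,pid_second percent identities (80 floor applied upstream)
#' @return factor-like character: `both_gt80`, `best_gt80_second_le80`, or
#'   `both_le80`
#' @export
pid_pair_category <- function(pid_best, pid_second) {
  if (any(pid_second > pid_best, na.rm = TRUE))
    stopf("pid_second must not exceed pid_best")
  ifelse(pid_best > 80 & pid_second > 80, "both_gt80",
         ifelse(pid_best > 80, "best_gt80_second_le80", "both_le80"))
}
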