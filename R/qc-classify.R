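# Sample/plate quality control, seven-category SNP classification, rescue
# protocols, and duplicate-sample accuracy.

#' QC thresholds for a named protocol
#'
#' The `default` protocol uses the conventional diploid thresholds:
#' Dish-QC >= 0.82, sample call rate >= 97%, plate percent-samples-passing
#' >= 95%, plate call rate >= 98.5%, SNP call-rate cutoff >= 97%,
#' confidence threshold 0.15. `rescue90`..`rescue60` keep the defaults in
#' Phase 1 and add a Phase 2 step that re-thresholds confidences at 0.10
#' and admits Other/CallRateBelowThreshold SNPs at the lowered call-rate
#' cutoff. `modified` relaxes the sample/plate thresholds (Dish-QC 0.50,
#' sample CR 80%, plate passing 80%, plate CR 90%, SNP cutoff 95%) and uses
#' a Phase-2 call-rate threshold of 80% with confidence 0.10.
#'
#' @param protocol_name one of `default`, `rescue90`, `rescue80`,
#'   `rescue70`, `rescue60`, `modified`
#' @return a `qc_thresholds` list (all rates as fractions)
#' @export
qc_thresholds <- function(protocol_name = "default") {
  base <- list(dqc_min = 0.82, sample_cr_min = 0.97,
               plate_pass_fraction_min = 0.95, plate_cr_min = 0.985,
               snp_cr_cutoff = 0.97, confidence_threshold = 0.15,
               rescue_cr_cutoff = NULL, phase2_confidence = 0.10,
               protocol_name = protocol_name)
  th <- switch(protocol_name,
    default = base,
    rescue90 = utils::modifyList(base, list(rescue_cr_cutoff = 0.90)),
    rescue80 = utils::modifyList(base, list(rescue_cr_cutoff = 0.80)),
    rescue70 = utils::modifyList(base, list(rescue_cr_cutoff = 0.70)),
    rescue60 = utils::modifyList(base, list(rescue_cr_cutoff = 0.60)),
    modified = utils::modifyList(base, list(
      dqc_min = 0.50, sample_cr_min = 0.80, plate_pass_fraction_min = 0.80,
      plate_cr_min = 0.90, snp_cr_cutoff = 0.95, rescue_cr_cutoff = 0.80)),
    stopf("unknown protocol '%s'", protocol_name))
  if (!is.null(th$rescue_cr_cutoff) && th$rescue_cr_cutoff > th$snp_cr_cutoff)
    stopf("rescue_cr_cutoff must not exceed snp_cr_cutoff")
  structure(th, class = "qc_thresholds")
}

#' Sample and plate quality control
#'
#' Drops samples with Dish-QC below `dqc_min` or sample call rate (mean SNP
#' call rate for the sample) below `sample_cr_min`, then drops whole plates
#' whose fraction of passing samples falls below
#' `plate_pass_fraction_min` or whose plate call rate -- the average sample
#' call rate of the *passing* samples on the plate -- falls below
#' `plate_cr_min`.
#'
#' @param samples data.frame with `sample_id`, `plate_id`, `dqc`
#' @param call_matrix character matrix samples x probesets with entries
#'   `AA`/`AB`/`BB`/`NC`
#' @param thresholds a [qc_thresholds()]
#' @return list: `passing` (character vector of sample ids), `samples`
#'   (per-sample report with cr, dqc, pass flags), `plates` (per-plate
#'   report)
#' @export
sample_plate_qc <- function(samples, call_matrix, thresholds) {
  s <- data.table::as.data.table(samples)
  if (!all(c("sample_id", "plate_id", "dqc") %in% names(s)))
    stopf("samples must have sample_id, plate_id, dqc")
  cr <- rowMeans(call_matrix[s$sample_id, , drop = FALSE] != "NC")
  s[, sample_cr := cr]
  s[, pass_sample := dqc >= thresholds$dqc_min & sample_cr >= thresholds$sample_cr_min]
  plates <- s[, .(n_samples = .N, n_passing = sum(pass_sample),
                  pass_fraction = mean(pass_sample),
                  plate_cr = if (any(pass_sample)) mean(sample_cr[pass_sample]) else NA_real_),
              by = plate_id]
  plates[, pass_plate := pass_fraction >= thresholds$plate_pass_fraction_min &
           !is.na(plate_cr) & plate_cr >= thresholds$plate_cr_min]
  s[, pass := pass_sample & plate_id %in% plates$plate_id[plates$pass_plate]]
  list(passing = s$sample_id[s$pass], samples = s[], plates = plates[])
}

genotype_counts <- function(v) {
  c(nAA = sum(v == "AA"), nAB = sum(v == "AB"),
    nBB = sum(v == "BB"), nNC = sum(v == "NC"))
}

#' Classify one SNP (probeset) into the six base categories
#'
#' Decision order: `OTV` if the off-target fraction reaches
#' `otv_min_fraction`; else `Other` if the cluster fit is unresolved; else
#' `CallRateBelowThreshold` if the call rate is below the SNP cutoff; else
#' `MonoHighResolution` if only one genotype class was called; else
#' `NoMinorHom` if the minor homozygote was never called; else
#' `PolyHighResolution`.
#'
#' @param call_vec character vector of calls for one probeset (passing
#'   samples only)
#' @param resolved logical from the caller diagnostics
#' @param thresholds a [qc_thresholds()]
#' @param otv_fraction fraction of samples in a low-size cluster
#' @param otv_min_fraction minimum OTV fraction to classify as OTV
#'   (default 0.1)
#' @return list: `category`, `call_rate`, `counts`
#' @export
classify_snp <- function(call_vec, resolved, thresholds,
                         otv_fraction = 0, otv_min_fraction = 0.1) {
  if (!length(call_vec)) stopf("no passing samples for probeset")
  cnt <- genotype_counts(call_vec)
  called <- sum(cnt[c("nAA", "nAB", "nBB")])
  cr <- called / length(call_vec)
  n_classes <- sum(cnt[c("nAA", "nAB", "nBB")] > 0)
  category <-
    if (otv_fraction >= otv_min_fraction) "OTV"
    else if (!isTRUE(resolved)) "Other"
    else if (cr < thresholds$snp_cr_cutoff) "CallRateBelowThreshold"
    else if (n_classes <= 1) "MonoHighResolution"
    else if (min(cnt["nAA"], cnt["nBB"]) == 0) "NoMinorHom"
    else "PolyHighResolution"
  list(category = category, call_rate = cr, counts = cnt)
}

classify_all <- function(call_matrix, diagnostics, thresholds,
                         otv_fraction = NULL, otv_min_fraction = 0.1) {
  ids <- colnames(call_matrix)
  res <- lapply(ids, function(pid) {
    d <- diagnostics[diagnostics$probeset_id == pid, ]
    of <- if (is.null(otv_fraction)) 0 else otv_fraction[[pid]] %||% 0
    cl <- classify_snp(call_matrix[, pid], resolved = isTRUE(d$resolved[1]),
                       thresholds = thresholds, otv_fraction = of,
                       otv_min_fraction = otv_min_fraction)
    data.table::data.table(probeset_id = pid, category = cl$category,
                           call_rate = cl$call_rate,
                           nAA = cl$counts[["nAA"]], nAB = cl$counts[["nAB"]],
                           nBB = cl$counts[["nBB"]], nNC = cl$counts[["nNC"]])
  })
  out <- data.table::rbindlist(res)
  out[, successful := category %in% c("PolyHighResolution", "Rescued")]
  out[]
}

#' Phase-2 rescue of Other and CallRateBelowThreshold SNPs
#'
#' Re-thresholds the per-call confidences of Other and
#' CallRateBelowThreshold probesets at the tighter Phase-2 confidence
#' (default 0.10; stricter than the Phase-1 0.15, so the call rate can only
#' drop but accuracy improves), recomputes their call rates, and
#' reclassifies as `Rescued` those with call rate at or above the lowered
#' `rescue_cr_cutoff` *and* at least two called genotype classes
#' (successful SNPs must be polymorphic). Monomorphic rescue candidates
#' can optionally be recorded as `Rescued` too but are never counted
#' successful.
#'
#' @param classifications output of the Phase-1 classification
#' @param calls the `axiom_calls` object (raw calls + confidences)
#' @param passing sample ids that passed QC
#' @param thresholds a [qc_thresholds()] with a `rescue_cr_cutoff`
#' @param allow_monomorphic_rescue label monomorphic candidates `Rescued`
#'   as well (still not successful); default FALSE
#' @return updated classification data.table
#' @export
rescue_snps <- function(classifications, calls, passing, thresholds,
                        allow_monomorphic_rescue = FALSE) {
  if (is.null(thresholds$rescue_cr_cutoff))
    stopf("rescue requested but thresholds carry no rescue_cr_cutoff")
  cls <- data.table::copy(data.table::as.data.table(classifications))
  eligible <- cls$category %in% c("Other", "CallRateBelowThreshold")
  if (!any(eligible)) return(cls)
  phase2 <- apply_confidence_threshold(calls, thresholds$phase2_confidence)
  phase2 <- phase2[passing, , drop = FALSE]
  for (i in which(eligible)) {
    pid <- cls$probeset_id[i]
    v <- phase2[, pid]
    cnt <- genotype_counts(v)
    called <- sum(cnt[c("nAA", "nAB", "nBB")])
    cr <- called / length(v)
    polymorphic <- sum(cnt[c("nAA", "nAB", "nBB")] > 0) >= 2
    if (cr >= thresholds$rescue_cr_cutoff && (polymorphic || allow_monomorphic_rescue)) {
      cls[i, `:=`(category = "Rescued", call_rate = cr,
                  nAA = cnt[["nAA"]], nAB = cnt[["nAB"]], nBB = cnt[["nBB"]],
                  nNC = cnt[["nNC"]], successful = polymorphic)]
    }
  }
  cls[]
}

#' Category summary arithmetic
#'
#' Converted = PolyHighResolution + NoMinorHom + MonoHighResolution +
#' Rescued (SNPs that yielded genotype calls); successful =
#' PolyHighResolution + Rescued (reliably genotyped *and* polymorphic).
#'
#' @param counts named numeric vector of per-category counts (categories
#'   from `PolyHighResolution`, `NoMinorHom`, `MonoHighResolution`,
#'   `CallRateBelowThreshold`, `OTV`, `Other`, `Rescued`; missing = 0)
#' @return list with `counts`, `total`, `converted`, `successful`, and the
#'   corresponding percentages (1 decimal)
#' @export
summarize_categories <- function(counts) {
  full <- setNames(numeric(length(SNP_CATEGORIES)), SNP_CATEGORIES)
  full[names(counts)] <- counts
  total <- sum(full)
  converted <- sum(full[c("PolyHighResolution", "NoMinorHom",
                          "MonoHighResolution", "Rescued")])
  successful <- sum(full[c("PolyHighResolution", "Rescued")])
  list(counts = full, total = total, converted = converted,
       successful = successful,
       percent = round(100 * full / total, 1),
       percent_converted = round(100 * converted / total, 1),
       percent_successful = round(100 * successful / total, 1))
}

#' Run a full QC protocol
#'
#' Chains Phase-1 confidence thresholding, sample/plate QC, SNP
#' classification, OTV detection, and (for rescue/modified protocols) the
#' Phase-2 rescue, separately per population. Emits per-population
#' category summaries plus the across-population average and "sum"
#' (a SNP counts as successful in the sum when it is successful in at
#' least one population -- each population has successful SNPs that are
#' monomorphic in the other).
#'
#' @param calls an `axiom_calls` object over all samples
#' @param samples sample metadata (`sample_id`, `plate_id`, `dqc`, and
#'   optionally `population`)
#' @param protocol protocol name (see [qc_thresholds()]) or a
#'   `qc_thresholds` object
#' @param otv_size_offset passed to [detect_otv()]
#' @param otv_min_fraction minimum OTV fraction for the OTV category
#' @return list: `per_population` (classification tables),
#'   `summaries` (per-population [summarize_categories()] results),
#'   `average_successful`, `sum_successful`, `qc` (per-population sample
#'   QC reports), `thresholds`
#' @export
run_protocol <- function(calls, samples, protocol = "default",
                         otv_size_offset = 2, otv_min_fraction = 0.1) {
  th <- if (inherits(protocol, "qc_thresholds")) protocol else qc_thresholds(protocol)
  s <- data.table::as.data.table(samples)
  if (!"population" %in% names(s)) s[, population := "C1"]
  phase1 <- apply_confidence_threshold(calls, th$confidence_threshold)
  otv <- detect_otv(calls, size_offset = otv_size_offset)

  pops <- sort(unique(s$population))
  per_pop <- list(); qc <- list(); summ <- list()
  for (p in pops) {
    sp <- s[population == p]
    q <- sample_plate_qc(sp, phase1, th)
    if (!length(q$passing)) stopf("no samples pass QC in population %s", p)
    cm <- phase1[q$passing, , drop = FALSE]
    of <- colMeans(otv$flags[q$passing, , drop = FALSE])
    cls <- classify_all(cm, calls$diagnostics, th, otv_fraction = as.list(of),
                        otv_min_fraction = otv_min_fraction)
    if (!is.null(th$rescue_cr_cutoff))
      cls <- rescue_snps(cls, calls, q$passing, th)
    per_pop[[p]] <- cls
    qc[[p]] <- q
    summ[[p]] <- summarize_categories(table(cls$category))
  }
  avg_succ <- mean(vapply(per_pop, function(cl) sum(cl$successful), numeric(1)))
  succ_union <- unique(unlist(lapply(per_pop, function(cl)
    cl$probeset_id[cl$successful])))
  list(per_population = per_pop, summaries = summ,
       average_successful = avg_succ, sum_successful = length(succ_union),
       qc = qc, thresholds = th)
}

#' Duplicate-sample genotyping and allele accuracy
#'
#' Over all within-tree sample pairs and probesets: pairs with either call
#' missing are excluded (and counted in `missing_fraction`); among compared
#' pairs, `genotype_accuracy` is the fraction of concordant genotype pairs
#' and `allele_accuracy` the fraction of shared alleles (identical
#' genotypes share 2, homozygote vs heterozygote share 1, opposite
#' homozygotes share 0, out of 2).
#'
#' @param call_matrix character matrix samples x probesets
#' @param sample_tree data.frame with `sample_id`, `tree_id`
#' @return list: `genotype_accuracy`, `allele_accuracy`,
#'   `missing_fraction`, `n_pairs_compared`, `n_trees`
#' @export
duplicate_accuracy <- function(call_matrix, sample_tree) {
  st <- data.table::as.data.table(sample_tree)
  st <- st[sample_id %in% rownames(call_matrix)]
  trees <- st[, .N, by = tree_id][N >= 2, tree_id]
  if (!length(trees)) stopf("no tree has duplicate samples")
  dosage <- c(AA = 2, AB = 1, BB = 0)
  concord <- 0; shared <- 0; compared <- 0; excluded <- 0
  for (tr in trees) {
    sids <- st$sample_id[st$tree_id == tr]
    pairs <- utils::combn(sids, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- call_matrix[pairs[1, k], ]
      b <- call_matrix[pairs[2, k], ]
      ok <- a != "NC" & b != "NC"
      excluded <- excluded + sum(!ok)
      compared <- compared + sum(ok)
      concord <- concord + sum(a[ok] == b[ok])
      shared <- shared + sum(2 - abs(dosage[a[ok]] - dosage[b[ok]]))
    }
  }
  if (compared == 0) stopf("no comparable (both-called) pairs")
  list(genotype_accuracy = concord / compared,
       allele_accuracy = shared / (2 * compared),
       missing_fraction = excluded / (compared + excluded),
       n_pairs_compared = compared, n_trees = length(trees))
}
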