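# Candidate filtering, transcript/probeset ranking, and greedy
# coverage-maximizing selection of probesets for a fixed-content array.

#' Is a probe direction buildable for a SNP?
#'
#' A direction is buildable when its 35-nt flank (positions 1-35 of the
#' 71-nt context for `forward`, 37-71 for `reverse`) carries no
#' high-confidence non-target variant. Low- and medium-tier variants do not
#' block buildability; they only lower the flanking rank.
#'
#' @param snp one row of a candidates table (list or single-row data.frame)
#' @param direction `"forward"` or `"reverse"`
#' @return logical
#' @export
#' @examples
#' snp <- list(flanking_variants = "35:high")
#' buildable(snp, "forward")  # FALSE: high-tier variant in the 5' flank
#' buildable(snp, "reverse")  # TRUE
buildable <- function(snp, direction) {
  v <- parse_flanking_variants(snp$flanking_variants[[1]])
  win <- flank_window(direction)
  !any(v$position %in% win & v$tier == "high")
}

#' Filter candidate SNPs and probesets for array design
#'
#' Removes unacceptable probesets and then SNPs with none left. A probeset
#' is unacceptable when (1) it has no 71-nt match in the reference genome,
#' (2) its flank carries a high-confidence non-target variant (it is not
#' buildable), or (3) its vendor recommendation is `not_recommended` or
#' `not_possible`. SNPs already validated on an Infinium platform are
#' exempt from rule (3) as long as they keep at least one buildable
#' probeset. A/T and C/G SNPs are removed (they need two probesets each)
#' unless Infinium-validated.
#'
#' @param candidates,probesets tables as from [gen_candidates()]
#' @return list: `probesets` (retained, with candidate columns merged in)
#'   and `rejections` (item id, level, reason)
#' @export
filter_candidates <- function(candidates, probesets) {
  orphans <- setdiff(probesets$snp_id, candidates$snp_id)
  if (length(orphans))
    stopf("probesets reference unknown SNPs: %s",
          paste(head(orphans, 5), collapse = ", "))
  cand <- data.table::as.data.table(candidates)
  ps <- merge(data.table::as.data.table(probesets),
              cand[, .(snp_id, transcript_id, transcript_confidence, source,
                       allele_a, allele_b, flanking_variants, infinium_success,
                       target_snp_prob, n_detect_programs)],
              by = "snp_id", sort = FALSE)

  rej <- list()
  reject <- function(ids, level, reason) {
    if (length(ids)) rej[[length(rej) + 1L]] <<-
        data.table::data.table(id = ids, level = level, reason = reason)
  }

  # probeset-level rules; buildability comes from the precomputed flanking
  # rank (NA = high-tier variant in that flank)
  not_buildable <- is.na(ps$flanking_rank)
  no_match <- !isTRUE_vec(ps$genome_match)
  bad_rec <- ps$recommendation %in% c("not_recommended", "not_possible") &
    !(ps$infinium_success & !not_buildable)
  reject(ps$probeset_id[no_match], "probeset", "no_genome_match")
  reject(ps$probeset_id[!no_match & not_buildable], "probeset", "flank_variant")
  reject(ps$probeset_id[!no_match & !not_buildable & bad_rec],
         "probeset", "not_recommended")
  keep <- !(no_match | not_buildable | bad_rec)
  ps <- ps[keep]

  # SNP-level rules
  at_cg <- (ps$allele_a == "A" & ps$allele_b == "T") |
    (ps$allele_a == "T" & ps$allele_b == "A") |
    (ps$allele_a == "C" & ps$allele_b == "G") |
    (ps$allele_a == "G" & ps$allele_b == "C")
  drop_atcg <- at_cg & !ps$infinium_success
  reject(unique(ps$snp_id[drop_atcg]), "snp", "at_cg")
  ps <- ps[!drop_atcg]

  no_ps <- setdiff(cand$snp_id, ps$snp_id)
  already <- if (length(rej)) data.table::rbindlist(rej)[level == "snp", id] else character()
  reject(setdiff(no_ps, already), "snp", "no_acceptable_probeset")

  list(probesets = ps[],
       rejections = if (length(rej)) data.table::rbindlist(rej) else
         data.table::data.table(id = character(), level = character(),
                                reason = character()))
}

isTRUE_vec <- function(x) if (is.null(x)) TRUE else (!is.na(x) & x)

hit_category <- function(mean_hits) {
  ifelse(mean_hits == 0, "0", ifelse(mean_hits <= 1, "1", "gt1"))
}

#' Rank transcripts for array selection
#'
#' Orders transcripts by (1) the mean per-SNP 65-nt reference hit count,
#' binned best-to-worst as exactly one hit, more than one, then zero;
#' (2) the discovery confidence score, ascending (lower is better; absent
#' for UH transcripts, which are compared on the other two keys only);
#' (3) number of SNPs per transcript, descending (more probesets to choose
#' from). Full ties break lexicographically on transcript id, so the order
#' is a deterministic total order.
#'
#' @param transcripts data.frame with columns `transcript_id`, `mean_hits`
#'   (mean v0.5 scaffold hits across the transcript's SNPs),
#'   `confidence_score` (NA for UH), `n_snps`
#' @return the table with `hit_category` and `combined_rank` (1 = best),
#'   sorted by rank
#' @export
rank_transcripts <- function(transcripts) {
  tr <- data.table::as.data.table(transcripts)
  tr[, hit_category := hit_category(mean_hits)]
  cat_rank <- c("1" = 1L, "gt1" = 2L, "0" = 3L)
  conf <- tr$confidence_score
  conf[is.na(conf)] <- -Inf  # UH: no key; compare equal, fall through to n_snps
  ord <- order(cat_rank[tr$hit_category], conf, -tr$n_snps, tr$transcript_id)
  tr <- tr[ord]
  tr[, combined_rank := seq_len(.N)]
  tr[]
}

#' Rank probesets within one transcript
#'
#' Five keys, best first: Infinium-validated SNPs at the top; flanking rank
#' 1 < 2 < 3; perfect-allele count in order 1, 2, 0 (one match = unique
#' locus, two = duplicated locus, zero = missing from assembly); pConvert
#' descending; target-SNP evidence (OSU p-value ascending, or UH
#' detection-program count descending). Ties break on probeset id.
#'
#' @param probesets probesets of a single transcript, with candidate columns
#'   merged in (as returned by [filter_candidates()])
#' @return the table sorted best-first with `within_rank`
#' @export
rank_probesets <- function(probesets) {
  ps <- data.table::as.data.table(probesets)
  pa_rank <- c(2L, 1L, 3L)[match(ps$n_perfect_alleles, c(2L, 1L, 0L))]
  pa_rank[is.na(pa_rank)] <- 4L
  # target-evidence key: OSU P_S ascending, UH program count descending.
  # All probesets within a transcript share a discovery source, so the two
  # scales never actually compete; one numeric key suffices.
  evidence <- ifelse(!is.na(ps$target_snp_prob), ps$target_snp_prob,
                     ifelse(!is.na(ps$n_detect_programs),
                            -as.numeric(ps$n_detect_programs), 0))
  ord <- order(-as.integer(ps$infinium_success), ps$flanking_rank, pa_rank,
               -ps$pconvert, evidence, ps$probeset_id)
  ps <- ps[ord]
  ps[, within_rank := seq_len(.N)]
  ps[]
}

#' Build the transcript table from filtered probesets
#'
#' @param probesets filtered probesets with candidate columns
#' @return transcript table suitable for [rank_transcripts()]
#' @export
transcript_table <- function(probesets) {
  ps <- data.table::as.data.table(probesets)
  ps[, .(mean_hits = mean(n_scaffold_hits_v05),
         confidence_score = transcript_confidence[1],
         n_snps = data.table::uniqueN(snp_id)),
     by = transcript_id]
}

#' Greedy coverage-maximizing array selection
#'
#' Round-robins over transcripts in rank order. Each pass takes, from each
#' transcript in turn, the best not-yet-selected probeset of a SNP not yet
#' covered on the array; once all of a transcript's SNPs are covered, later
#' passes may add the opposite-direction probeset of its top-ranked SNP
#' (two probesets per SNP improve the odds that the transcript yields a
#' working assay). A/T and C/G SNPs cost two capacity units per probeset
#' (they need both strands). Selection stops exactly at capacity and is a
#' deterministic function of its inputs.
#'
#' @param ranked_transcripts output of [rank_transcripts()]
#' @param probesets filtered probesets (candidate columns merged)
#' @param capacity number of probeset slots on the array
#' @param second_probeset_per_snp allow a second, opposite-direction
#'   probeset for covered SNPs on later passes (default TRUE)
#' @return data.table of selected probesets with `final_rank` (selection
#'   order)
#' @export
select_array <- function(ranked_transcripts, probesets, capacity,
                         second_probeset_per_snp = TRUE) {
  if (!is.numeric(capacity) || capacity < 1) stopf("capacity must be >= 1")
  ps <- data.table::as.data.table(probesets)
  ranked <- lapply(split(ps, ps$transcript_id), rank_probesets)
  tr_order <- ranked_transcripts$transcript_id[
    ranked_transcripts$transcript_id %in% names(ranked)]

  at_cg_cost <- function(row) {
    if ((row$allele_a == "A" && row$allele_b == "T") ||
        (row$allele_a == "T" && row$allele_b == "A") ||
        (row$allele_a == "C" && row$allele_b == "G") ||
        (row$allele_a == "G" && row$allele_b == "C")) 2L else 1L
  }

  selected <- character(0)
  covered <- character(0)
  used <- 0L
  progress <- TRUE
  while (used < capacity && progress) {
    progress <- FALSE
    for (tid in tr_order) {
      if (used >= capacity) break
      rk <- ranked[[tid]]
      avail <- rk[!probeset_id %in% selected]
      if (!nrow(avail)) next
      pick <- avail[!snp_id %in% covered]
      if (!nrow(pick)) {
        if (!second_probeset_per_snp) next
        # all SNPs covered: take the opposite-direction probeset of the
        # transcript's top-ranked SNP, if present
        top_snp <- rk$snp_id[1]
        pick <- avail[snp_id == top_snp]
        if (!nrow(pick)) next
      }
      row <- pick[1]
      cost <- at_cg_cost(row)
      if (used + cost > capacity) next
      selected <- c(selected, row$probeset_id)
      covered <- union(covered, row$snp_id)
      used <- used + cost
      progress <- TRUE
    }
  }
  out <- ps[match(selected, probeset_id)]
  out[, final_rank := seq_len(.N)]
  out[]
}

#' One-call array design pipeline
#'
#' Filters candidates, ranks transcripts, and selects probesets up to
#' capacity.
#'
#' @inheritParams filter_candidates
#' @inheritParams select_array
#' @return list: `selected`, `rejections`, `transcripts`
#' @export
design_array <- function(candidates, probesets, capacity) {
  flt <- filter_candidates(candidates, probesets)
  tr <- rank_transcripts(transcript_table(flt$probesets))
  sel <- select_array(tr, flt$probesets, capacity)
  list(selected = sel, rejections = flt$rejections, transcripts = tr)
}
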