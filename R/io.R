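# Readers and writers for the pipeline's plain-text formats: schema-checked
# TSV tables, probe FASTA, standard BLAST tabular, VCF v4.2 export, and the
# reproducibility manifest. All tables are UTF-8, tab-separated, Unix
# newlines, with a mandatory header row.

TABLE_SCHEMAS <- list(
  candidates = list(
    columns = c(snp_id = "character", source = "character",
                transcript_id = "character", transcript_confidence = "numeric",
                allele_a = "character", allele_b = "character",
                context_seq = "character", target_snp_prob = "numeric",
                n_detect_programs = "integer", flanking_variants = "character",
                infinium_success = "logical")),
  probesets = list(
    columns = c(probeset_id = "character", snp_id = "character",
                direction = "character", repetitive = "logical",
                pconvert = "numeric", recommendation = "character",
                genome_match = "logical", n_scaffold_hits_v05 = "integer",
                n_perfect_alleles = "integer", flanking_rank = "integer")),
  intensities = list(
    columns = c(sample_id = "character", probeset_id = "character",
                signal_a = "numeric", signal_b = "numeric")),
  calls = list(
    columns = c(sample_id = "character", probeset_id = "character",
                call = "character", confidence = "numeric"),
    values = list(call = c("AA", "AB", "BB", "NC"))),
  samples = list(
    columns = c(sample_id = "character", tree_id = "character",
                population = "character", plate_id = "character",
                dqc = "numeric")),
  features = list(
    columns = c(probeset_id = "character", snp_id = "character",
                success = "integer")))

#' Read a schema-checked pipeline table
#'
#' Validates that every declared column is present with a coercible type
#' and, where a value domain is declared (e.g. genotype symbols
#' `AA`/`AB`/`BB`/`NC` in the calls table), that all values fall in it;
#' violations raise an error naming the column and the first offending row.
#' Extra columns are preserved.
#'
#' @param path TSV file path
#' @param schema one of `candidates`, `probesets`, `intensities`, `calls`,
#'   `samples`, `features`
#' @return a data.table
#' @export
read_table_checked <- function(path, schema) {
  if (!schema %in% names(TABLE_SCHEMAS)) stopf("unknown schema '%s'", schema)
  sc <- TABLE_SCHEMAS[[schema]]
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = "character", showProgress = FALSE)
  missing <- setdiff(names(sc$columns), names(dt))
  if (length(missing))
    stopf("table '%s' (%s): missing column(s) %s", schema, path,
          paste(sprintf("\"%s\"", missing), collapse = ", "))
  for (col in names(sc$columns)) {
    type <- sc$columns[[col]]
    raw <- dt[[col]]
    val <- switch(type,
      character = raw,
      numeric = suppressWarnings(as.numeric(raw)),
      integer = suppressWarnings(as.integer(raw)),
      logical = as.logical(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad))
      stopf("table '%s': column \"%s\" not %s at row %d (value \"%s\")",
            schema, col, type, bad[1], raw[bad[1]])
    data.table::set(dt, j = col, value = val)
  }
  for (col in names(sc$values %||% list())) {
    bad <- which(!is.na(dt[[col]]) & !dt[[col]] %in% sc$values[[col]])
    if (length(bad))
      stopf("table '%s': column \"%s\" has invalid symbol \"%s\" at row %d",
            schema, col, dt[[col]][bad[1]], bad[1])
  }
  dt
}

#' Write a pipeline table
#'
#' @param dt data.frame/data.table
#' @param path destination TSV path
#' @return `path`, invisibly
#' @export
write_table_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA", eol = "\n")
  invisible(path)
}

#' Matrix <-> long-format conversion for calls
#'
#' @param call_matrix character matrix samples x probesets
#' @param confidence optional matching confidence matrix
#' @return long data.table (`sample_id`, `probeset_id`, `call`,
#'   `confidence`)
#' @export
calls_to_long <- function(call_matrix, confidence = NULL) {
  out <- data.table::data.table(
    sample_id = rep(rownames(call_matrix), times = ncol(call_matrix)),
    probeset_id = rep(colnames(call_matrix), each = nrow(call_matrix)),
    call = as.vector(call_matrix),
    confidence = if (is.null(confidence)) NA_real_ else as.vector(confidence))
  out
}

#' @rdname calls_to_long
#' @param calls_long long-format calls table
#' @export
calls_to_matrix <- function(calls_long) {
  cl <- data.table::as.data.table(calls_long)
  samples <- unique(cl$sample_id); probes <- unique(cl$probeset_id)
  m <- matrix("NC", length(samples), length(probes),
              dimnames = list(samples, probes))
  m[cbind(match(cl$sample_id, samples), match(cl$probeset_id, probes))] <- cl$call
  m
}

#' Write probe contexts as FASTA
#'
#' One 71-mer per probeset, header = probeset id.
#'
#' @param ids,sequences character vectors
#' @param path destination
#' @return `path`, invisibly
#' @export
write_probe_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  writeLines(paste0(">", ids, "\n", sequences), path)
  invisible(path)
}

#' Read standard 12-column BLAST tabular output
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#' qend, sstart, send, evalue, bitscore. Malformed rows (wrong field
#' count or non-numeric pident/length) are skipped; their count is
#' reported as attribute `n_skipped` and a warning.
#'
#' @param path tab-separated BLAST outfmt-6 file
#' @return data.table with the 12 standard columns
#' @export
read_blast_tabular <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) == 12
  parts <- parts[ok]
  mat <- do.call(rbind, parts)
  dt <- if (is.null(mat)) {
    data.table::as.data.table(setNames(rep(list(character()), 12), cols))
  } else data.table::as.data.table(setNames(as.data.frame(mat,
                                                          stringsAsFactors = FALSE), cols))
  num_cols <- cols[3:12]
  for (cc in num_cols) data.table::set(dt, j = cc,
                                       value = suppressWarnings(as.numeric(dt[[cc]])))
  bad <- is.na(dt$pident) | is.na(dt$length)
  n_skipped <- sum(!ok) + sum(bad)
  dt <- dt[!bad]
  if (n_skipped > 0)
    warning(sprintf("skipped %d malformed BLAST row(s)", n_skipped))
  data.table::setattr(dt, "n_skipped", n_skipped)
  dt[]
}

#' Export genotype calls as VCF v4.2
#'
#' One record per SNP with per-sample GT fields; NoCall becomes `./.`.
#' REF is the A allele and ALT the B allele of the assay, so AA maps to
#' 0/0, AB to 0/1, BB to 1/1. SNPs without genome coordinates are emitted
#' on their transcript (contig = transcript id, POS = 36, the SNP's offset
#' in its 71-nt context).
#'
#' @param call_matrix character matrix samples x probesets
#' @param snp_meta data.frame with `probeset_id`, `allele_a`, `allele_b`,
#'   `transcript_id`, and optionally `chrom`/`pos`
#' @param path destination VCF path
#' @param source_label free-text for the `##source` header line
#' @return `path`, invisibly
#' @export
vcf_export <- function(call_matrix, snp_meta, path,
                       source_label = paste0("axiomsnp-", utils::packageVersion("axiomsnp"))) {
  meta <- data.table::as.data.table(snp_meta)
  missing <- setdiff(colnames(call_matrix), meta$probeset_id)
  if (length(missing))
    stopf("snp_meta lacks alleles for probeset(s): %s",
          paste(head(missing, 5), collapse = ", "))
  meta <- meta[match(colnames(call_matrix), probeset_id)]
  if (any(meta$allele_a == meta$allele_b))
    stopf("allele mismatch: REF and ALT identical for some probesets")
  chrom <- if ("chrom" %in% names(meta) && !all(is.na(meta$chrom)))
    meta$chrom else meta$transcript_id
  pos <- if ("pos" %in% names(meta) && !all(is.na(meta$pos))) meta$pos else
    rep(36L, nrow(meta))
  samples <- rownames(call_matrix)
  gt_map <- c(AA = "0/0", AB = "0/1", BB = "1/1", NC = "./.")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=%s", source_label),
           sprintf("##contig=<ID=%s>", unique(chrom)),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(ncol(call_matrix)), function(j) {
    paste(c(chrom[j], pos[j], colnames(call_matrix)[j],
            meta$allele_a[j], meta$allele_b[j], ".", "PASS", ".", "GT",
            unname(gt_map[call_matrix[, j]])), collapse = "\t")
  }, character(1))
  # sort records by contig then position, as VCF consumers expect
  ord <- order(chrom, pos)
  writeLines(c(hdr, body[ord]), path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records inputs, thresholds, seed and package version so a run can be
#' reproduced byte-for-byte.
#'
#' @param path destination JSON path
#' @param inputs named list or character vector of input paths
#' @param thresholds list of thresholds in force
#' @param seed integer seed
#' @param extra optional named list of additional fields
#' @return `path`, invisibly
#' @export
write_manifest <- function(path, inputs, thresholds, seed, extra = list()) {
  manifest <- c(list(
    package = "axiomsnp",
    version = as.character(utils::packageVersion("axiomsnp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed, inputs = as.list(inputs), thresholds = thresholds), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
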