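# Plain-text readers and writers for the pipeline's external formats.
# All positions in these files are 1-based inclusive.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Write a cohort fixture directory
#'
#' Emits the transcript CDS FASTA plus TSV sidecars (transcripts, variants,
#' germline calls, HLA typing, truth labels, planted binders) and a JSON
#' manifest.
#'
#' @param cohort From [generate_cohort()].
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::DNAStringSet(cohort$transcripts$cds_sequence)
  names(seqs) <- cohort$transcripts$transcript_id
  f <- file.path(dir, "transcripts.fasta")
  Biostrings::writeXStringSet(seqs, f)
  files <- c(f,
    write_tsv(cohort$transcripts[, c("transcript_id", "gene_symbol",
                                     "expression_rpkm")],
              file.path(dir, "transcripts.tsv")),
    write_tsv(cohort$variants, file.path(dir, "variants.tsv")),
    write_tsv(cohort$germline, file.path(dir, "germline.tsv")),
    write_tsv(cohort$hla, file.path(dir, "hla.tsv")),
    write_tsv(cohort$truth, file.path(dir, "truth.tsv")),
    write_tsv(cohort$planted_binders, file.path(dir, "planted_binders.tsv")))
  manifest <- list(patient_id = cohort$patient_id,
                   n_transcripts = nrow(cohort$transcripts),
                   n_variants = nrow(cohort$variants))
  jf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, jf, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, jf))
}

#' Read a cohort fixture directory
#'
#' @param dir Directory written by [write_cohort()].
#' @return A cohort list as returned by [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fasta"))
  transcripts <- read_tsv(file.path(dir, "transcripts.tsv"))
  transcripts$cds_sequence <-
    as.character(seqs)[match(transcripts$transcript_id, names(seqs))]
  hla <- read_tsv(file.path(dir, "hla.tsv"))
  list(patient_id = hla$patient_id[1],
       transcripts = transcripts,
       variants = read_tsv(file.path(dir, "variants.tsv")),
       germline = read_tsv(file.path(dir, "germline.tsv")),
       hla = hla,
       truth = read_tsv(file.path(dir, "truth.tsv")),
       planted_binders = read_tsv(file.path(dir, "planted_binders.tsv")))
}

#' Write/read ELISpot well tables
#'
#' Long TSV with columns patient_id, timepoint, day, assay_arm, antigen_id,
#' well_index, count, tntc, cells_per_well.
#' @param wells Data frame of wells.
#' @param path File path.
#' @export
write_elispot <- function(wells, path) invisible(write_tsv(wells, path))

#' @rdname write_elispot
#' @export
read_elispot <- function(path) {
  wells <- read_tsv(path)
  required <- c("patient_id", "timepoint", "day", "assay_arm", "antigen_id",
                "well_index", "count", "tntc", "cells_per_well")
  miss <- setdiff(required, names(wells))
  if (length(miss)) stopf("ELISpot table lacks columns: %s",
                          paste(miss, collapse = ", "))
  wells
}

#' Read an AIRR-style rearrangement TSV
#'
#' Requires at least `junction_aa` and `duplicate_count`; `locus` rows
#' other than TRB are dropped when present.
#' @param path File path.
#' @return Data frame ready for [merge_clonotypes()].
#' @export
read_airr <- function(path) {
  df <- read_tsv(path)
  if (is.null(df$junction_aa) || is.null(df$duplicate_count))
    stopf("not an AIRR rearrangement table: %s", path)
  if (!is.null(df$locus)) df <- df[df$locus == "TRB", , drop = FALSE]
  df
}

#' @rdname read_airr
#' @param df AIRR-style data frame.
#' @export
write_airr <- function(df, path) invisible(write_tsv(df, path))
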