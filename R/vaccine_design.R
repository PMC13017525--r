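# Staged MPS prioritization, target selection, two-string partition and
# SEC-concatemer-MITD construct assembly.
#
# Prioritization (up to 46 MPS) runs on mutations with RNA VAF > 0, each
# step drawing only from MPS not yet taken by an earlier step:
#   (1) up to 5 indel MPS by class I binding score;
#   (2) up to 20 SNV MPS by class II score, expression >= 10 RPKM;
#   (3) up to 20 SNV MPS by class I score, expression >= 1 RPKM;
#   (4) further SNV MPS by expression, to 46 in total;
# and if still short, mutations with RNA VAF = 0 are added
#   (5) by class I score where one exists, then (6) by expression.
# Up to 20 targets are then selected and dealt alternately onto two
# strings of at most 10, each assembled as SEC ++ targets with 10-aa G/S
# linkers ++ MITD and reverse-translated with a fixed codon table.

#' Vaccine construct flanking sequences
#'
#' Fixed amino-acid literals: the secretory signal peptide (SEC, 26 aa) and
#' the MHC class I trafficking domain (MITD, 55 aa) fused around the target
#' concatemer, and the FI RNA-stability element, which is carried as
#' construct metadata and not concatenated into the ORF.
#' @export
FLANK_SEQUENCES <- list(
  SEC  = "MRVMAPRTLILLLSGALALTETWAGS",
  MITD = "IVGIVAGLAVLAVVVIGAVVATVMCRRKSSGGKGGSYSQAASSDSAQGSDVSLTA",
  FI   = "LVLHARNASCPFPVLGTPSLPRPRVPGMLPPPPAPLTTSASSRHL")

#' Default prioritization / design configuration
#'
#' Caps and thresholds of the staged selection (5 indel picks, 20 + 20 SNV
#' picks, 46 prioritized, 20 selected, 10 per string; RPKM gates 10 and 1),
#' the default 10-aa glycine/serine linker (30 nt once encoded), and the
#' composite re-ranking weights (all zero = keep prioritized order).
#' @return A named list of design parameters.
#' @export
design_config <- function() {
  list(cap_indel = 5L, cap_snv_class2 = 20L, cap_snv_class1 = 20L,
       cap_prioritized = 46L, cap_selected = 20L, cap_per_string = 10L,
       rpkm_class2 = 10, rpkm_class1 = 1,
       linker = "GGSGGGGSGG",
       weights = c(best_class1 = 0, best_class2 = 0, rpkm = 0, dna_vaf = 0),
       min_targets_warn = 5L)
}

# Stable ordering: primary key ascending (a score) with ties broken
# by expression descending then variant_id lexicographic.
order_by <- function(df, primary, decreasing = FALSE) {
  o <- order(if (decreasing) -df[[primary]] else df[[primary]],
             -df$rpkm, df$variant_id, method = "radix")
  df[o, , drop = FALSE]
}

#' Prioritize MPS for vaccine design (staged filter, up to 46)
#'
#' @param candidates Data frame with one row per MPS: `mps_id`,
#'   `variant_id`, `variant_kind` ("snv"/"insertion"/"deletion"),
#'   `best_class1`, `best_class2`, `rpkm` (transcript expression),
#'   `rna_vaf`. Build it with [design_candidates()] or by joining
#'   [mps_table()] with a score summary.
#' @param config List from [design_config()].
#' @return The prioritized subset (<= 46 rows) in selection order, with
#'   columns `selection_step` and `rank_within_step` appended.
#' @export
prioritize_mps <- function(candidates, config = design_config()) {
  required <- c("mps_id", "variant_id", "variant_kind", "best_class1",
                "best_class2", "rpkm", "rna_vaf")
  miss <- setdiff(required, names(candidates))
  if (length(miss)) stopf("candidates lack columns: %s",
                          paste(miss, collapse = ", "))
  if (anyNA(candidates$best_class1) || anyNA(candidates$best_class2))
    stopf("MPS without scores: %s", paste(
      candidates$mps_id[is.na(candidates$best_class1) |
                        is.na(candidates$best_class2)], collapse = ", "))
  if (anyDuplicated(candidates$variant_id))
    stopf("duplicate variant_ids in candidate table")
  picked <- candidates[0, , drop = FALSE]
  picked$selection_step <- character(0)
  picked$rank_within_step <- integer(0)
  room <- function() config$cap_prioritized - nrow(picked)
  take <- function(pool, step, cap) {
    pool <- pool[!pool$mps_id %in% picked$mps_id, , drop = FALSE]
    n <- min(cap, nrow(pool), room())
    if (n <= 0L) return(invisible())
    sel <- pool[seq_len(n), , drop = FALSE]
    sel$selection_step <- step
    sel$rank_within_step <- seq_len(n)
    picked <<- rbind(picked, sel)
  }
  expressed <- candidates[candidates$rna_vaf > 0, , drop = FALSE]
  indel <- expressed[expressed$variant_kind %in% c("insertion", "deletion"), ,
                     drop = FALSE]
  snv <- expressed[expressed$variant_kind == "snv", , drop = FALSE]
  take(order_by(indel, "best_class1"), "s1_indel_hla1", config$cap_indel)
  take(order_by(snv[snv$rpkm >= config$rpkm_class2, , drop = FALSE],
                "best_class2"), "s2_snv_hla2", config$cap_snv_class2)
  take(order_by(snv[snv$rpkm >= config$rpkm_class1, , drop = FALSE],
                "best_class1"), "s3_snv_hla1", config$cap_snv_class1)
  take(order_by(snv, "rpkm", decreasing = TRUE), "s4_snv_expression", room())
  if (room() > 0L) {
    fallback <- candidates[candidates$rna_vaf <= 0, , drop = FALSE]
    # (5) those with an actual class I prediction, by score; (6) the rest
    # by expression.
    with_score <- fallback[fallback$best_class1 < SCORE_SENTINEL, ,
                           drop = FALSE]
    take(order_by(with_score, "best_class1"), "s5_fallback_hla1", room())
    take(order_by(fallback, "rpkm", decreasing = TRUE),
         "s6_fallback_expression", room())
  }
  rownames(picked) <- NULL
  picked
}

#' Join MPS, scores, transcripts and variants into a candidate table
#'
#' @param mps_list List of `mps` objects.
#' @param score_summary `summary` element of [score_mps_set()].
#' @param transcripts,variants Input tables (see [build_patient_mps()]).
#' @return Candidate data frame for [prioritize_mps()].
#' @export
design_candidates <- function(mps_list, score_summary, transcripts, variants) {
  df <- mps_table(mps_list, transcripts = transcripts, variants = variants)
  i <- match(df$mps_id, score_summary$mps_id)
  df$best_class1 <- score_summary$best_class1[i]
  df$best_class2 <- score_summary$best_class2[i]
  df$rpkm <- df$expression_rpkm
  df
}

#' Select up to 20 vaccine targets from the prioritized list
#'
#' Default policy keeps prioritized order and truncates at `cap`. With
#' non-zero `weights` (over negated class I/II best scores, expression and
#' DNA VAF) a composite score re-ranks the prioritized list first; the
#' stable sort makes all-zero weights the identity.
#'
#' @param prioritized Output of [prioritize_mps()].
#' @param cap Maximum number of targets (default 20).
#' @param weights Named numeric vector (`best_class1`, `best_class2`,
#'   `rpkm`, `dna_vaf`).
#' @return The selected rows in final order.
#' @export
select_targets <- function(prioritized, cap = 20L,
                           weights = c(best_class1 = 0, best_class2 = 0,
                                       rpkm = 0, dna_vaf = 0)) {
  if (!nrow(prioritized)) stopf("empty prioritized list")
  composite <- weights[["best_class1"]] * (-prioritized$best_class1) +
    weights[["best_class2"]] * (-prioritized$best_class2) +
    weights[["rpkm"]] * prioritized$rpkm +
    weights[["dna_vaf"]] * (prioritized$dna_vaf %||% 0)
  o <- order(-composite, method = "radix")  # stable: zero weights keep order
  out <- prioritized[o, , drop = FALSE]
  head(out, cap)
}

#' Deal selected targets onto two strings
#'
#' Targets are dealt alternately by selection rank (1st to string 1, 2nd to
#' string 2, ...), giving balanced strings of at most 10 targets each.
#'
#' @param selected Data frame of selected targets (<= 20 rows) in order.
#' @return `selected` with a `string` column (1 or 2).
#' @export
partition_targets <- function(selected) {
  n <- nrow(selected)
  if (n < 1L) stopf("no targets to partition")
  if (n > 20L) stopf("%d targets exceed the 20-target capacity", n)
  selected$string <- rep_len(c(1L, 2L), n)
  selected
}

#' Human-preferred codon table for reverse translation
#'
#' One fixed codon per amino acid (the most used codon in human coding
#' sequence), so reverse translation is deterministic and
#' `translate_cds(reverse_translate(x))` is the identity.
#' @export
CODON_TABLE_HUMAN <- c(
  A = "GCC", R = "AGA", N = "AAC", D = "GAC", C = "TGC", Q = "CAG",
  E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTG", K = "AAG",
  M = "ATG", F = "TTC", P = "CCC", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAC", V = "GTG")

#' Reverse-translate an amino-acid string
#'
#' @param aa Amino-acid string (one-letter code, no stop symbol).
#' @param codon_table Named character vector amino acid -> codon.
#' @return Nucleotide string of length `3 * nchar(aa)`.
#' @export
reverse_translate <- function(aa, codon_table = CODON_TABLE_HUMAN) {
  if (nchar(aa) == 0L) return("")
  res <- strsplit(aa, "")[[1]]
  bad <- setdiff(res, names(codon_table))
  if (length(bad)) stopf("no codon for residue(s): %s",
                         paste(unique(bad), collapse = ", "))
  paste(codon_table[res], collapse = "")
}

#' Assemble one vaccine string construct
#'
#' Builds `SEC ++ t1 ++ L ++ t2 ++ ... ++ L ++ tn ++ MITD` at the amino-acid
#' level, reverse-translates it with a fixed codon table, and returns
#' 1-based inclusive annotation spans that tile the ORF exactly. Each 10-aa
#' linker occupies 30 nt, and a single-target string has no linker.
#'
#' @param target_seqs Character vector of target peptide sequences (>= 1).
#' @param target_ids Identifiers for the annotation table.
#' @param linker Glycine/serine linker (exactly 10 aa of G/S).
#' @param codon_table Passed to [reverse_translate()].
#' @return List with `orf_aa`, `orf_nt`, `annotations` (element, id,
#'   start_aa, end_aa, start_nt, end_nt) and `fi_element` metadata.
#' @export
assemble_construct <- function(target_seqs, target_ids = NULL,
                               linker = "GGSGGGGSGG",
                               codon_table = CODON_TABLE_HUMAN) {
  n <- length(target_seqs)
  if (n < 1L) stopf("construct needs at least one target")
  if (nchar(linker) != 10L || grepl("[^GS]", linker))
    stopf("linker must be 10 residues of G/S only")
  if (is.null(target_ids)) target_ids <- paste0("target_", seq_len(n))
  elements <- c("SEC", rbind(target_ids,
                             c(rep("linker", n - 1L), ""))[-2L * n], "MITD")
  seqs <- c(FLANK_SEQUENCES$SEC,
            rbind(target_seqs, c(rep(linker, n - 1L), ""))[-2L * n],
            FLANK_SEQUENCES$MITD)
  kind <- c("SEC", rbind(rep("target", n),
                         c(rep("linker", n - 1L), ""))[-2L * n], "MITD")
  lens <- nchar(seqs)
  end_aa <- cumsum(lens)
  start_aa <- end_aa - lens + 1L
  orf_aa <- paste(seqs, collapse = "")
  orf_nt <- reverse_translate(orf_aa, codon_table)
  list(orf_aa = orf_aa, orf_nt = orf_nt,
       annotations = data.frame(
         element = kind, id = elements,
         start_aa = start_aa, end_aa = end_aa,
         start_nt = 3L * (start_aa - 1L) + 1L, end_nt = 3L * end_aa,
         stringsAsFactors = FALSE),
       fi_element = FLANK_SEQUENCES$FI)
}

#' Build the full vaccine design for one patient
#'
#' Chains prioritization, selection, partition and assembly.
#'
#' @inheritParams prioritize_mps
#' @param config From [design_config()].
#' @param patient_id Used in identifiers and report headers.
#' @return A `vaccine_design` list: `prioritized`, `selected` (with string
#'   assignment), `constructs` (one per non-empty string), `config`.
#' @export
build_vaccine_design <- function(candidates, config = design_config(),
                                 patient_id = "patient") {
  prioritized <- prioritize_mps(candidates, config)
  selected <- select_targets(prioritized, cap = config$cap_selected,
                             weights = config$weights)
  if (nrow(selected) < config$min_targets_warn)
    warning(sprintf("%s: only %d vaccine targets (eligibility threshold %d)",
                    patient_id, nrow(selected), config$min_targets_warn),
            call. = FALSE)
  selected <- partition_targets(selected)
  constructs <- lapply(split(selected, selected$string), function(s)
    assemble_construct(s$sequence, target_ids = s$mps_id,
                       linker = config$linker))
  structure(list(patient_id = patient_id, prioritized = prioritized,
                 selected = selected, constructs = constructs,
                 config = config),
            class = "vaccine_design")
}

#' @export
print.vaccine_design <- function(x, ...) {
  cat(sprintf("<vaccine_design %s> %d prioritized, %d selected on %d string(s)\n",
              x$patient_id, nrow(x$prioritized), nrow(x$selected),
              length(x$constructs)))
  invisible(x)
}

#' Write a vaccine design report
#'
#' Emits per-string FASTA (nucleotide and amino acid), a target TSV with
#' step provenance, scores, expression and VAFs, and a JSON manifest.
#' Re-running with the same inputs produces byte-identical files.
#'
#' @param design A `vaccine_design`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
emit_design_report <- function(design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pid <- design$patient_id
  files <- character(0)
  nt <- vapply(design$constructs, `[[`, character(1), "orf_nt")
  aa <- vapply(design$constructs, `[[`, character(1), "orf_aa")
  names(nt) <- names(aa) <- sprintf("%s|string%s", pid, names(design$constructs))
  f_nt <- file.path(dir, sprintf("%s_constructs_nt.fasta", pid))
  f_aa <- file.path(dir, sprintf("%s_constructs_aa.fasta", pid))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(nt), f_nt)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(aa), f_aa)
  files <- c(files, f_nt, f_aa)
  tgt <- design$selected
  keep <- intersect(c("mps_id", "variant_id", "sequence", "variant_kind",
                      "selection_step", "rank_within_step", "best_class1",
                      "best_class2", "rpkm", "dna_vaf", "rna_vaf", "string"),
                    names(tgt))
  f_tsv <- file.path(dir, sprintf("%s_targets.tsv", pid))
  utils::write.table(tgt[, keep, drop = FALSE], f_tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f_tsv)
  manifest <- list(patient_id = pid,
                   n_prioritized = nrow(design$prioritized),
                   n_selected = nrow(design$selected),
                   strings = lapply(design$constructs, function(cstr)
                     list(orf_aa_length = nchar(cstr$orf_aa),
                          orf_nt_length = nchar(cstr$orf_nt))),
                   fi_element = FLANK_SEQUENCES$FI,
                   config = design$config)
  f_json <- file.path(dir, sprintf("%s_manifest.json", pid))
  jsonlite::write_json(manifest, f_json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  files <- c(files, f_json)
  invisible(files)
}

#' Read a design report back (round-trip of targets and constructs)
#'
#' @param dir Report directory.
#' @param patient_id Patient identifier used at write time.
#' @return List with `targets` data frame and per-string `orf_nt`/`orf_aa`.
#' @export
read_design_report <- function(dir, patient_id) {
  targets <- utils::read.delim(
    file.path(dir, sprintf("%s_targets.tsv", patient_id)),
    stringsAsFactors = FALSE)
  nt <- Biostrings::readDNAStringSet(
    file.path(dir, sprintf("%s_constructs_nt.fasta", patient_id)))
  aa <- Biostrings::readAAStringSet(
    file.path(dir, sprintf("%s_constructs_aa.fasta", patient_id)))
  list(targets = targets,
       orf_nt = stats::setNames(as.character(nt), names(nt)),
       orf_aa = stats::setNames(as.character(aa), names(aa)))
}
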