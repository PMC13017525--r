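# Mutated peptide sequence (MPS) construction from transcripts and variants.
#
# A somatic variant on a coding transcript is turned into a vaccine-candidate
# peptide: for missense SNVs (and in-frame indels) a 27mer window with the
# changed residue in the centre, truncated at the protein termini; for
# frameshift indels the novel peptide tail from the first changed residue to
# the next stop codon, capped at 50 residues. Synonymous and nonsense
# variants are filtered. In-phase protein-changing germline variants that
# fall inside a window are incorporated into the peptide.

MPS_SNV_FLANK <- 13L        # residues each side of the mutation (27mer window)
MPS_FRAMESHIFT_CAP <- 50L   # maximum frameshift tail length (aa)

#' Translate a coding sequence to protein
#'
#' Standard-genetic-code translation of an in-frame nucleotide sequence.
#' The terminal stop codon, if present, is dropped. By default an internal
#' stop codon is an error; the frameshift path translates up to the first
#' stop instead.
#'
#' @param cds Nucleotide string (A/C/G/T), length divisible by 3 unless
#'   `partial = TRUE`.
#' @param allow_internal_stop If `TRUE`, translation ends at the first stop
#'   codon (exclusive) instead of erroring; a trailing partial codon is
#'   ignored when `partial = TRUE`.
#' @param partial Permit a sequence length not divisible by 3 (frameshifted
#'   tails); the incomplete final codon is dropped.
#' @return Amino-acid string (one-letter code, no stop symbol).
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
#' @export
translate_cds <- function(cds, allow_internal_stop = FALSE, partial = FALSE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stopf("non-ACGT symbol in CDS")
  n <- nchar(cds)
  if (!partial && n %% 3L != 0L) stopf("CDS length %d not divisible by 3", n)
  ncod <- n %/% 3L
  if (ncod == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = ncod)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(GENETIC_CODE_1[codons])
  stops <- which(aa == "*")
  if (length(stops)) {
    first <- stops[1L]
    if (first < ncod || any(stops != ncod)) {
      # a stop before the final codon
      if (!allow_internal_stop && stops[1L] != ncod)
        stopf("internal stop codon at codon %d", stops[1L])
    }
    aa <- aa[seq_len(stops[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

# Standard genetic code, codon -> one-letter amino acid ('*' = stop).
GENETIC_CODE_1 <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

#' Apply a somatic variant to a coding sequence
#'
#' Variants use VCF-style anchored coordinates: `cds_position` is 1-based
#' into the CDS; for SNVs `ref`/`alt` are single bases; for insertions and
#' deletions both alleles include the anchor base at `cds_position`.
#'
#' @param cds Reference CDS nucleotide string.
#' @param cds_position 1-based anchor position.
#' @param ref,alt Reference and alternate alleles.
#' @return Mutated CDS string.
#' @export
apply_variant <- function(cds, cds_position, ref, alt) {
  n <- nchar(cds)
  pos <- as.integer(cds_position)
  if (pos < 1L || pos + nchar(ref) - 1L > n)
    stopf("variant at %d with ref '%s' outside CDS of length %d", pos, ref, n)
  obs <- substr(cds, pos, pos + nchar(ref) - 1L)
  if (obs != toupper(ref))
    stopf("reference allele mismatch at %d: CDS has '%s', variant says '%s'",
          pos, obs, ref)
  paste0(substr(cds, 1L, pos - 1L), toupper(alt),
         substr(cds, pos + nchar(ref), n))
}

#' Classify the protein consequence of a somatic variant
#'
#' @param variant A list or one-row data frame with fields `kind`
#'   (`"snv"`, `"insertion"`, `"deletion"`), `cds_position`, `ref`, `alt`.
#' @param transcript A list with `cds_sequence`.
#' @return One of `"synonymous"`, `"nonsense"`, `"missense"`,
#'   `"frameshift"`, `"inframe_indel"`.
#' @export
classify_variant <- function(variant, transcript) {
  cds <- toupper(transcript$cds_sequence)
  pos <- as.integer(variant$cds_position)
  if (pos < 1L || pos > nchar(cds)) stopf("variant position outside CDS")
  kind <- variant$kind
  if (kind == "snv") {
    codon_idx <- (pos - 1L) %/% 3L + 1L
    cstart <- (codon_idx - 1L) * 3L + 1L
    ref_codon <- substr(cds, cstart, cstart + 2L)
    off <- pos - cstart + 1L
    alt_codon <- ref_codon
    substr(alt_codon, off, off) <- toupper(variant$alt)
    ref_aa <- GENETIC_CODE_1[[ref_codon]]
    alt_aa <- GENETIC_CODE_1[[alt_codon]]
    if (alt_aa == "*") return("nonsense")
    if (alt_aa == ref_aa) return("synonymous")
    return("missense")
  }
  if (!kind %in% c("insertion", "deletion")) stopf("unknown variant kind '%s'", kind)
  shift <- abs(nchar(variant$alt) - nchar(variant$ref))
  if (shift %% 3L != 0L) "frameshift" else "inframe_indel"
}

new_mps <- function(mps_id, variant_id, sequence, mutation_positions, kind,
                    incorporated_germline = character(0)) {
  stopifnot(nchar(sequence) >= 1L, length(mutation_positions) >= 1L,
            all(mutation_positions >= 1L),
            all(mutation_positions <= nchar(sequence)))
  if (grepl("\\*", sequence)) stopf("MPS contains a stop symbol")
  structure(list(mps_id = mps_id, variant_id = variant_id,
                 sequence = sequence,
                 mutation_positions = as.integer(mutation_positions),
                 kind = kind,
                 incorporated_germline = incorporated_germline),
            class = "mps")
}

#' @export
print.mps <- function(x, ...) {
  cat(sprintf("<mps %s> %s (%s, %d aa, mutated at %s)\n", x$mps_id,
              x$sequence, x$kind, nchar(x$sequence),
              paste(x$mutation_positions, collapse = ",")))
  invisible(x)
}

#' Build the 27mer window MPS for a missense SNV (or in-frame indel)
#'
#' Takes 13 residues of flank on each side of the changed residue. Near a
#' protein terminus all available flank on that side is kept (no padding),
#' so the mutation need not be central. In-phase germline amino-acid
#' substitutions falling inside the window are applied to the emitted
#' sequence and recorded.
#'
#' @param protein Somatically mutated protein (aa string).
#' @param mutated_index 1-based position of the changed residue.
#' @param germline_substitutions Named list/vector mapping protein position
#'   (as character) to replacement amino acid; names outside the window are
#'   ignored.
#' @param mps_id,variant_id Identifiers carried on the result.
#' @param extra_mutated Additional mutated protein positions (in-frame
#'   insertions contribute a run of novel residues).
#' @return An `mps` object.
#' @export
build_mps_snv <- function(protein, mutated_index,
                          germline_substitutions = list(),
                          mps_id = "mps", variant_id = "variant",
                          extra_mutated = integer(0)) {
  L <- nchar(protein)
  i <- as.integer(mutated_index)
  if (i < 1L || i > L) stopf("mutated_index %d out of range 1..%d", i, L)
  from <- max(1L, i - MPS_SNV_FLANK)
  to <- min(L, i + MPS_SNV_FLANK)
  seq <- substr(protein, from, to)
  incorporated <- character(0)
  if (length(germline_substitutions)) {
    gp <- as.integer(names(germline_substitutions))
    for (k in seq_along(gp)) {
      p <- gp[k]
      if (p >= from && p <= to && p != i) {
        local_pos <- p - from + 1L
        substr(seq, local_pos, local_pos) <-
          as.character(germline_substitutions[[k]])
        incorporated <- c(incorporated,
                          names(germline_substitutions)[k])
      }
    }
  }
  mut_local <- unique(pmax(pmin(c(i, extra_mutated), to), from)) - from + 1L
  new_mps(mps_id, variant_id, seq, sort(mut_local), "snv",
          incorporated_germline = incorporated)
}

#' Build the frameshift MPS from the novel peptide tail
#'
#' The tail runs from the first changed residue to the next stop codon in
#' the shifted frame (stop excluded) and is hard-capped at 50 residues.
#' Every emitted position is mutated. An empty tail (immediate stop) is an
#' error; `build_patient_mps()` discards such variants with a logged reason.
#'
#' @param mutated_tail Amino-acid string from the changed residue to the
#'   stop (exclusive).
#' @inheritParams build_mps_snv
#' @return An `mps` object of kind `"frameshift"`.
#' @export
build_mps_frameshift <- function(mutated_tail, mps_id = "mps",
                                 variant_id = "variant") {
  if (nchar(mutated_tail) == 0L) stopf("empty frameshift tail (immediate stop)")
  seq <- substr(mutated_tail, 1L, MPS_FRAMESHIFT_CAP)
  new_mps(mps_id, variant_id, seq, seq_len(nchar(seq)), "frameshift")
}

first_difference <- function(a, b) {
  # first position where proteins a (reference) and b (mutated) differ;
  # if b extends beyond a with no earlier change, the first novel position.
  n <- min(nchar(a), nchar(b))
  if (n > 0L) {
    av <- strsplit(a, "")[[1]][seq_len(n)]
    bv <- strsplit(b, "")[[1]][seq_len(n)]
    d <- which(av != bv)
    if (length(d)) return(d[1L])
  }
  if (nchar(b) > nchar(a)) return(nchar(a) + 1L)
  NA_integer_
}

#' Build all mutated peptide sequences for a patient
#'
#' Applies the construction rules over a variant table: synonymous and
#' nonsense variants are removed; missense SNVs and in-frame indels yield
#' 27mer-window peptides; frameshift indels yield the capped novel tail.
#' Variants on non-expressed transcripts are retained but flagged
#' (prioritization applies the expression thresholds). One MPS is emitted
#' per somatic variant on its designated canonical transcript.
#'
#' @param transcripts Data frame with columns `transcript_id`,
#'   `cds_sequence`, `expression_rpkm` (and optionally `gene_symbol`).
#' @param variants Data frame with columns `variant_id`, `transcript_id`,
#'   `kind`, `cds_position`, `ref`, `alt`, `dna_vaf`, `rna_vaf`.
#' @param germline_calls Optional data frame with columns `germline_id`,
#'   `transcript_id`, `cds_position`, `ref`, `alt`, `in_phase_with`
#'   (comma-separated somatic variant ids).
#' @return A list of `mps` objects with attribute `"log"`: a data frame of
#'   discarded variants and machine-readable reasons.
#' @export
build_patient_mps <- function(transcripts, variants, germline_calls = NULL) {
  missing_tx <- setdiff(variants$transcript_id, transcripts$transcript_id)
  if (length(missing_tx))
    stopf("variants reference missing transcripts: %s",
          paste(unique(missing_tx), collapse = ", "))
  tx_idx <- match(variants$transcript_id, transcripts$transcript_id)
  out <- list()
  log <- list()
  note <- function(variant_id, reason)
    log[[length(log) + 1L]] <<- data.frame(variant_id = variant_id,
                                           reason = reason)
  for (r in seq_len(nrow(variants))) {
    v <- as.list(variants[r, ])
    t <- as.list(transcripts[tx_idx[r], ])
    cds <- toupper(t$cds_sequence)
    cons <- classify_variant(v, t)
    if (cons %in% c("synonymous", "nonsense")) {
      note(v$variant_id, paste0("filtered_", cons))
      next
    }
    mut_cds <- apply_variant(cds, v$cds_position, v$ref, v$alt)
    ref_prot <- translate_cds(cds)
    mps_id <- paste0("MPS_", v$variant_id)
    if (cons == "frameshift") {
      mut_prot <- translate_cds(mut_cds, allow_internal_stop = TRUE,
                                partial = TRUE)
      fd <- first_difference(ref_prot, mut_prot)
      if (is.na(fd) || fd > nchar(mut_prot)) {
        note(v$variant_id, "frameshift_immediate_stop")
        next
      }
      tail <- substr(mut_prot, fd, nchar(mut_prot))
      out[[length(out) + 1L]] <-
        build_mps_frameshift(tail, mps_id = mps_id, variant_id = v$variant_id)
    } else {  # missense or inframe_indel: 27mer window at first change
      mut_prot <- tryCatch(translate_cds(mut_cds),
                           error = function(e) NULL)
      if (is.null(mut_prot)) {
        note(v$variant_id, "indel_introduces_stop")
        next
      }
      fd <- first_difference(ref_prot, mut_prot)
      if (is.na(fd)) {
        note(v$variant_id, "no_protein_change")
        next
      }
      ins_len <- max(0L, (nchar(v$alt) - nchar(v$ref)) %/% 3L)
      extra <- if (ins_len > 0L) fd + seq_len(ins_len) else integer(0)
      subs <- germline_substitutions_for(v, t, mut_cds, germline_calls)
      out[[length(out) + 1L]] <-
        build_mps_snv(mut_prot, fd, germline_substitutions = subs,
                      mps_id = mps_id, variant_id = v$variant_id,
                      extra_mutated = extra)
    }
  }
  attr(out, "log") <- if (length(log)) do.call(rbind, log) else
    data.frame(variant_id = character(0), reason = character(0))
  out
}

# Protein-level substitution map for germline calls phased with variant v.
# Germline calls are single-nucleotide; the replacement residue is read by
# translating the affected codon of the somatically mutated CDS. Only valid
# for missense SNVs, where somatic and germline coordinates stay in frame.
germline_substitutions_for <- function(v, t, mut_cds, germline_calls) {
  if (is.null(germline_calls) || !nrow(germline_calls)) return(list())
  g <- germline_calls[germline_calls$transcript_id == t$transcript_id, ,
                      drop = FALSE]
  if (!nrow(g)) return(list())
  in_phase <- vapply(strsplit(g$in_phase_with, ","), function(ids)
    v$variant_id %in% trimws(ids), logical(1))
  g <- g[in_phase, , drop = FALSE]
  if (!nrow(g)) return(list())
  subs <- list()
  for (k in seq_len(nrow(g))) {
    pos <- as.integer(g$cds_position[k])
    codon_idx <- (pos - 1L) %/% 3L + 1L
    cstart <- (codon_idx - 1L) * 3L + 1L
    codon <- substr(mut_cds, cstart, cstart + 2L)
    off <- pos - cstart + 1L
    substr(codon, off, off) <- toupper(g$alt[k])
    aa <- GENETIC_CODE_1[[codon]]
    if (aa == "*") next  # a stop-introducing germline call is never applied
    subs[[as.character(codon_idx)]] <- aa
  }
  subs
}

#' Tabulate a list of MPS objects
#'
#' @param mps_list List of `mps` objects (e.g. from `build_patient_mps()`).
#' @param transcripts,variants Optional tables used to join expression and
#'   VAF columns needed by prioritization.
#' @return Data frame with one row per MPS.
#' @export
mps_table <- function(mps_list, transcripts = NULL, variants = NULL) {
  df <- do.call(rbind, lapply(mps_list, function(m) data.frame(
    mps_id = m$mps_id, variant_id = m$variant_id, sequence = m$sequence,
    mutation_positions = paste(m$mutation_positions, collapse = ","),
    kind = m$kind,
    incorporated_germline = paste(m$incorporated_germline, collapse = ","),
    stringsAsFactors = FALSE)))
  if (is.null(df)) df <- data.frame(mps_id = character(0),
                                    variant_id = character(0),
                                    sequence = character(0),
                                    mutation_positions = character(0),
                                    kind = character(0),
                                    incorporated_germline = character(0))
  if (!is.null(variants)) {
    i <- match(df$variant_id, variants$variant_id)
    df$variant_kind <- variants$kind[i]
    df$dna_vaf <- variants$dna_vaf[i]
    df$rna_vaf <- variants$rna_vaf[i]
    df$gene_symbol <- variants$gene_symbol[i] %||% NA_character_
    df$transcript_id <- variants$transcript_id[i]
    if (!is.null(transcripts)) {
      j <- match(df$transcript_id, transcripts$transcript_id)
      df$expression_rpkm <- transcripts$expression_rpkm[j]
      df$not_expressed <- df$expression_rpkm <= 0
    }
  }
  df
}
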