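# RevImMo: TCR repertoire enrichment, paired-chain gating, candidate
# selection, reporter-assay specificity calls, and clone tracking.
#
# The clonotype identity key throughout is the TRB CDR3 amino-acid
# sequence; V/J gene calls are carried as annotations only.

#' Merge bulk clonotypes by TRB CDR3 amino-acid sequence
#'
#' Rows with identical CDR3 are merged, counts summed and frequencies
#' recomputed from the merged totals, so merging is idempotent.
#'
#' @param entries Data frame with columns `cdr3_aa` (or AIRR `junction_aa`)
#'   and `count` (or AIRR `duplicate_count`).
#' @return Data frame `cdr3_aa`, `count`, `frequency`, sorted by count
#'   descending then CDR3.
#' @export
merge_clonotypes <- function(entries) {
  cdr3 <- entries$cdr3_aa %||% entries$junction_aa
  count <- entries$count %||% entries$duplicate_count
  if (is.null(cdr3) || is.null(count) || !length(cdr3))
    stopf("empty clonotype input")
  if (any(count < 1)) stopf("clonotype counts must be >= 1")
  agg <- rowsum(as.numeric(count), group = cdr3)
  out <- data.frame(cdr3_aa = rownames(agg), count = agg[, 1],
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / sum(out$count)
  out <- out[order(-out$count, out$cdr3_aa, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Post-treatment clonal enrichment with de novo imputation
#'
#' For every clone observed post-treatment: clones also present
#' pre-treatment are `pre_existing` with fold = post/pre frequency; clones
#' absent pre-treatment are `de_novo` and their baseline is imputed as the
#' lowest frequency observed in the pre-treatment repertoire of the same
#' compartment. Enrichment is post-anchored: clones that contracted to
#' zero are not recorded.
#'
#' @param pre,post Merged repertoires ([merge_clonotypes()]) of the same
#'   patient and compartment.
#' @return Data frame `cdr3_aa`, `pre_frequency`, `post_frequency`,
#'   `fold_change`, `status`, `imputed_baseline`, sorted by fold change
#'   descending (ties: post frequency descending, then CDR3).
#' @export
compute_enrichment <- function(pre, post) {
  if (is.null(pre) || !nrow(pre))
    stopf("empty pre-treatment repertoire: no imputation floor definable")
  if (is.null(post) || !nrow(post)) stopf("empty post-treatment repertoire")
  floor_f <- min(pre$frequency)
  i <- match(post$cdr3_aa, pre$cdr3_aa)
  pre_f <- pre$frequency[i]
  imputed <- is.na(pre_f)
  pre_f[imputed] <- floor_f
  out <- data.frame(cdr3_aa = post$cdr3_aa,
                    pre_frequency = pre_f,
                    post_frequency = post$frequency,
                    fold_change = post$frequency / pre_f,
                    status = ifelse(imputed, "de_novo", "pre_existing"),
                    imputed_baseline = imputed,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fold_change, -out$post_frequency, out$cdr3_aa,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gate single-cell clonotypes on paired chains
#'
#' Keeps only clonotypes with both a TRA and a TRB chain; clonotypes with
#' two (or more) TRB chains are discarded. Clonotypes with several TRA
#' chains are retained and the TRA with the highest cell/read support is
#' designated primary.
#'
#' @param sc Data frame with one row per (clonotype, chain): columns
#'   `clonotype_id`, `chain` ("TRA"/"TRB"), `cdr3_aa`, `v_call`, `j_call`,
#'   `cell_count`.
#' @return Data frame with one row per surviving clonotype: `clonotype_id`,
#'   `trb_cdr3_aa`, `tra_cdr3_aa` (primary), `trb_v`, `trb_j`, `tra_v`,
#'   `tra_j`, `cell_count`, `n_tra`.
#' @export
gate_paired <- function(sc) {
  if (is.null(sc) || !nrow(sc))
    return(data.frame(clonotype_id = character(0),
                      trb_cdr3_aa = character(0), tra_cdr3_aa = character(0),
                      trb_v = character(0), trb_j = character(0),
                      tra_v = character(0), tra_j = character(0),
                      cell_count = numeric(0), n_tra = integer(0)))
  out <- lapply(split(sc, sc$clonotype_id), function(g) {
    trb <- g[g$chain == "TRB", , drop = FALSE]
    tra <- g[g$chain == "TRA", , drop = FALSE]
    if (nrow(trb) != 1L || nrow(tra) < 1L) return(NULL)
    tra <- tra[order(-tra$cell_count, tra$cdr3_aa, method = "radix"), ,
               drop = FALSE]
    data.frame(clonotype_id = g$clonotype_id[1],
               trb_cdr3_aa = trb$cdr3_aa, tra_cdr3_aa = tra$cdr3_aa[1],
               trb_v = trb$v_call, trb_j = trb$j_call,
               tra_v = tra$v_call[1], tra_j = tra$j_call[1],
               cell_count = max(g$cell_count), n_tra = nrow(tra),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(gate_paired(NULL))
  rownames(out) <- NULL
  out
}

#' Rank enriched clonotypes and select cloning candidates
#'
#' Only clonotypes with paired single-cell chain information are eligible.
#' Up to `per_class_max` of the most enriched de novo and pre-existing
#' clonotypes are taken (no borrowing between classes), then the total cap
#' is enforced.
#'
#' @param enrichments From [compute_enrichment()].
#' @param paired From [gate_paired()]; eligibility is membership of
#'   `trb_cdr3_aa`.
#' @param caps List with `per_class_min` (10), `per_class_max` (15),
#'   `total_max` (30).
#' @return Selected rows of `enrichments` with paired-chain annotations
#'   joined, in rank order.
#' @export
rank_and_select <- function(enrichments, paired,
                            caps = list(per_class_min = 10L,
                                        per_class_max = 15L,
                                        total_max = 30L)) {
  if (caps$per_class_max < caps$per_class_min)
    stopf("per_class_max < per_class_min")
  eligible <- enrichments[enrichments$cdr3_aa %in% paired$trb_cdr3_aa, ,
                          drop = FALSE]
  pick <- function(status) {
    sub <- eligible[eligible$status == status, , drop = FALSE]
    head(sub, caps$per_class_max)  # already in fold-descending order
  }
  out <- rbind(pick("de_novo"), pick("pre_existing"))
  out <- out[order(-out$fold_change, -out$post_frequency, out$cdr3_aa,
                   method = "radix"), , drop = FALSE]
  out <- head(out, caps$total_max)
  i <- match(out$cdr3_aa, paired$trb_cdr3_aa)
  out$tra_cdr3_aa <- paired$tra_cdr3_aa[i]
  out$trb_v <- paired$trb_v[i]; out$trb_j <- paired$trb_j[i]
  rownames(out) <- NULL
  out
}

#' Reporter-assay specificity calls
#'
#' For each TCR, luminescence in every (antigen, HLA) condition is divided
#' by that TCR's effectors-only control; a condition with fold >= 2 is
#' specific, and a TCR is neoantigen-specific if specific in at least one
#' condition.
#'
#' @param luminescence Data frame `tcr_id`, `condition_id`, `antigen_id`,
#'   `hla_allele`, `rlu`, `is_control` (logical; one control row per TCR).
#' @return List with `calls` (per condition: fold_over_control, specific)
#'   and `specific_tcrs` (character vector).
#' @export
call_reactivity <- function(luminescence) {
  ctl <- luminescence[as.logical(luminescence$is_control), , drop = FALSE]
  cond <- luminescence[!as.logical(luminescence$is_control), , drop = FALSE]
  ctl_rlu <- tapply(ctl$rlu, ctl$tcr_id, function(x) x[1])
  missing <- setdiff(unique(cond$tcr_id), names(ctl_rlu))
  if (length(missing))
    stopf("no effectors-only control for TCR(s): %s",
          paste(missing, collapse = ", "))
  base <- as.numeric(ctl_rlu[cond$tcr_id])
  if (any(base <= 0))
    stopf("non-positive control luminescence for TCR(s): %s",
          paste(unique(cond$tcr_id[base <= 0]), collapse = ", "))
  cond$fold_over_control <- cond$rlu / base
  cond$specific <- cond$fold_over_control >= 2
  list(calls = cond,
       specific_tcrs = sort(unique(cond$tcr_id[cond$specific])))
}

#' Track clones across timepoints and compartments
#'
#' Builds a clone-by-sample frequency matrix over merged repertoires, with
#' 0 where a clone is absent, plus the per-sample cumulative frequency of
#' the tracked set.
#'
#' @param clones Character vector of TRB CDR3 amino-acid sequences.
#' @param repertoires Named list of merged repertoires
#'   ([merge_clonotypes()]); names are sample labels.
#' @return List with `matrix` (clone x sample) and `cumulative` (named
#'   numeric, per sample).
#' @export
track_clones <- function(clones, repertoires) {
  m <- sapply(repertoires, function(rep) {
    f <- rep$frequency[match(clones, rep$cdr3_aa)]
    f[is.na(f)] <- 0
    f
  })
  m <- matrix(m, nrow = length(clones),
              dimnames = list(clones, names(repertoires)))
  list(matrix = m, cumulative = colSums(m))
}
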