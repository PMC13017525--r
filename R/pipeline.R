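# End-to-end orchestration: vaccine design, immunomonitoring, RevImMo.

#' Run the vaccine-design stage end to end
#'
#' Chains MPS construction, epitope scoring and design (prioritization,
#' selection, partition, assembly) for one patient.
#'
#' @param cohort List with `transcripts`, `variants`, `germline`, `hla`
#'   (from [generate_cohort()] or [read_cohort()]).
#' @param predictor Binding predictor; defaults to [mock_predictor()]
#'   seeded with `predictor_seed` and the cohort's planted binders.
#' @param predictor_seed Seed for the default mock predictor.
#' @param config From [design_config()].
#' @param out_dir Optional report directory for [emit_design_report()].
#' @return List with `mps`, `scores`, `candidates`, `design`, and the
#'   construction `log`.
#' @export
run_design <- function(cohort, predictor = NULL, predictor_seed = 42L,
                       config = design_config(), out_dir = NULL) {
  if (is.null(predictor))
    predictor <- mock_predictor(predictor_seed,
                                planted = if (nrow(cohort$planted_binders %||%
                                               data.frame())) {
                                  cohort$planted_binders
                                } else NULL)
  mps <- build_patient_mps(cohort$transcripts, cohort$variants,
                           cohort$germline)
  if (!length(mps)) stopf("antigen_model stage produced no MPS")
  scores <- score_mps_set(mps, cohort$hla$allele, predictor)
  candidates <- design_candidates(mps, scores$summary, cohort$transcripts,
                                  cohort$variants)
  design <- build_vaccine_design(candidates, config = config,
                                 patient_id = cohort$patient_id %||% "patient")
  if (!is.null(out_dir)) emit_design_report(design, out_dir)
  list(mps = mps, scores = scores, candidates = candidates, design = design,
       log = attr(mps, "log"))
}

#' Run ELISpot immunomonitoring over a well table
#'
#' Calls every (patient, day, arm, antigen) against its same-sample medium
#' control, classifies pre vs post responses, and computes the summed
#' multi-antigen kinetics over immunogenic antigens.
#'
#' @param wells Long data frame (see [read_elispot()]); the control rows
#'   have `antigen_id == control_id`.
#' @param policy From [call_policy()].
#' @param pre_day,post_day Days compared for classification; default the
#'   earliest and latest day present.
#' @param control_id Label of the medium-only condition.
#' @return List with `calls`, `classification`, `kinetics`.
#' @export
run_immunomonitoring <- function(wells, policy = call_policy(),
                                 pre_day = NULL, post_day = NULL,
                                 control_id = "medium") {
  groups <- unique(wells[, c("patient_id", "day", "assay_arm")])
  calls <- list()
  for (g in seq_len(nrow(groups))) {
    sub <- wells[wells$patient_id == groups$patient_id[g] &
                 wells$day == groups$day[g] &
                 wells$assay_arm == groups$assay_arm[g], , drop = FALSE]
    ctl_rows <- sub[sub$antigen_id == control_id, , drop = FALSE]
    if (!nrow(ctl_rows))
      stopf("no %s control for patient %s day %s", control_id,
            groups$patient_id[g], groups$day[g])
    control <- list(antigen_id = control_id, counts = ctl_rows$count,
                    tntc = ctl_rows$tntc,
                    cells_per_well = ctl_rows$cells_per_well[1])
    for (ag in setdiff(unique(sub$antigen_id), control_id)) {
      arows <- sub[sub$antigen_id == ag, , drop = FALSE]
      m <- list(antigen_id = ag, timepoint = arows$timepoint[1],
                day = arows$day[1], counts = arows$count, tntc = arows$tntc,
                cells_per_well = arows$cells_per_well[1])
      cl <- call_response(m, control, policy)
      cl$patient_id <- groups$patient_id[g]
      cl$assay_arm <- groups$assay_arm[g]
      calls[[length(calls) + 1L]] <- cl
    }
  }
  calls <- do.call(rbind, calls)
  pre_day <- pre_day %||% min(calls$day)
  post_day <- post_day %||% max(calls$day)
  classification <- do.call(rbind, lapply(
    split(calls, calls[, c("patient_id", "antigen_id")], drop = TRUE),
    function(cc) {
      pre <- cc[cc$day == pre_day, , drop = FALSE]
      post <- cc[cc$day == post_day, , drop = FALSE]
      if (!nrow(pre) || !nrow(post)) return(NULL)
      out <- classify_response(pre[1, ], post[1, ])
      out$patient_id <- cc$patient_id[1]
      out
    }))
  rownames(classification) <- NULL
  kinetics <- multiantigen_kinetics(calls, classification)
  list(calls = calls, classification = classification, kinetics = kinetics)
}

#' Run the RevImMo chain
#'
#' Merges bulk repertoires, computes post-treatment enrichment with de novo
#' imputation, gates single-cell clonotypes on paired chains, selects up to
#' 30 cloning candidates, calls reporter specificity, and tracks the
#' specific clones across all supplied repertoires.
#'
#' @param pre,post Bulk TRB tables (AIRR-style or `cdr3_aa`/`count`).
#' @param sc Single-cell chain table (see [gate_paired()]).
#' @param luminescence Optional reporter matrix (see [call_reactivity()]).
#' @param tumour Optional tumour-compartment bulk table.
#' @param caps Candidate caps (see [rank_and_select()]).
#' @return List with `enrichment`, `paired`, `candidates`, `reactivity`,
#'   `tracking`, and the merged `repertoires`.
#' @export
run_revimmo <- function(pre, post, sc, luminescence = NULL, tumour = NULL,
                        caps = list(per_class_min = 10L, per_class_max = 15L,
                                    total_max = 30L)) {
  if (is.null(pre) || !nrow(pre)) stopf("missing pre-treatment repertoire")
  reps <- list(pre = merge_clonotypes(pre), post = merge_clonotypes(post))
  if (!is.null(tumour)) reps$tumour <- merge_clonotypes(tumour)
  enrichment <- compute_enrichment(reps$pre, reps$post)
  paired <- gate_paired(sc)
  candidates <- rank_and_select(enrichment, paired, caps)
  reactivity <- NULL
  tracked <- candidates$cdr3_aa
  if (!is.null(luminescence)) {
    reactivity <- call_reactivity(luminescence)
    tracked <- intersect(candidates$cdr3_aa, reactivity$specific_tcrs)
  }
  tracking <- if (length(tracked)) track_clones(tracked, reps) else NULL
  list(enrichment = enrichment, paired = paired, candidates = candidates,
       reactivity = reactivity, tracking = tracking, repertoires = reps)
}
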