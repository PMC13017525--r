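# ELISpot response calling.
#
# Replicate-level well counts for an antigen are compared with the
# medium-only control of the same sample by two one-sided distribution-free
# resampling (DFR) tests of H0: mean(antigen) <= R * mean(control), with
# R = 1 ("eq") and R = 2 ("2x"). A response is positive when the configured
# test combination rejects at alpha AND the mean antigen count is at least
# 7 spots per well. Pre/post-vaccination calls are compared to classify
# responses as de novo or amplified; the post-IVS arm uses the at-least-
# twofold increase rule instead.

#' Normalize a mean spot count to spots per million cells
#'
#' @param mean_count Mean spots per well.
#' @param cells_per_well Effector cells plated per well (> 0).
#' @return Spots per 1e6 cells.
#' @export
normalize_spots <- function(mean_count, cells_per_well) {
  if (any(cells_per_well <= 0)) stopf("cells_per_well must be positive")
  mean_count / cells_per_well * 1e6
}

#' Distribution-free resampling (DFR) test for ELISpot wells
#'
#' One-sided test of H0: mean(antigen) <= R * mean(control) on well-level
#' counts, R = 1 (`"eq"`) or 2 (`"2x"`). Under the boundary null the
#' antigen wells scaled by 1/R are exchangeable with the control wells, so
#' the reference distribution of `T = mean(antigen)/R - mean(control)` is
#' built by resampling group labels over the pooled scaled wells. When the
#' split space `choose(n, n_antigen)` is at most 10^4 every split is
#' enumerated (the test is then exact and deterministic); otherwise B
#' random splits are drawn under the seed. The returned p-value carries
#' the mid-p correction for the discrete reference set,
#' `p = (#\{T* > T\} + 0.5 #\{T* = T\}) / N`, which is what makes
#' rejection at p < 0.05 attainable with triplicate wells: the observed
#' split must then be the strict maximizer of T among all 20 splits
#' (mid-p 0.025), so the test never exceeds the nominal level.
#'
#' @param antigen_wells,control_wells Numeric vectors of spot counts,
#'   at least 2 wells each.
#' @param variant `"eq"` or `"2x"`.
#' @param B Number of random splits when the space is too large to
#'   enumerate (>= 100).
#' @param seed RNG seed for the random-split path (the exact path is
#'   deterministic and ignores it).
#' @return A p-value in (0, 1].
#' @export
dfr_test <- function(antigen_wells, control_wells,
                     variant = c("eq", "2x"), B = 10000L, seed = 1L) {
  variant <- match.arg(variant)
  if (B < 100L) stopf("B must be at least 100")
  a <- as.numeric(antigen_wells); ctl <- as.numeric(control_wells)
  if (length(a) < 2L || length(ctl) < 2L)
    stopf("need at least 2 wells per group")
  R <- if (variant == "eq") 1 else 2
  pool <- c(a / R, ctl)
  na <- length(a); nc <- length(ctl); np <- na + nc
  t_obs <- mean(a) / R - mean(ctl)
  eps <- 1e-9
  midp <- function(tstar, n)
    (sum(tstar > t_obs + eps) + 0.5 * sum(abs(tstar - t_obs) <= eps)) / n
  if (choose(np, na) <= 1e4) {
    idx <- utils::combn(np, na)
    tstar <- colMeans(matrix(pool[idx], nrow = na)) * (1 + na / nc) -
      sum(pool) / nc  # mean(in) - mean(out), vectorised
    p <- midp(tstar, ncol(idx))
  } else {
    p <- with_seed(seed, {
      tstar <- vapply(seq_len(B), function(b) {
        i <- sample.int(np, na)
        mean(pool[i]) - mean(pool[-i])
      }, numeric(1))
      (0.5 + sum(tstar > t_obs + eps) +
         0.5 * sum(abs(tstar - t_obs) <= eps)) / (B + 1)
    })
  }
  max(p, .Machine$double.eps)
}

#' Default response-calling policy
#'
#' `rule` chooses how the two DFR tests combine: `"require_2x"` (default:
#' positive when the 2x test rejects; the eq p-value is reported),
#' `"require_both"`, or `"require_any"`. `min_count` is the spots-per-well
#' gate; `tntc_cap` is the imputed count for saturated (TNTC) wells.
#' @export
call_policy <- function(rule = c("require_2x", "require_both", "require_any"),
                        alpha = 0.05, min_count = 7, B = 10000L, seed = 1L,
                        tntc_cap = 2000) {
  list(rule = match.arg(rule), alpha = alpha, min_count = min_count,
       B = as.integer(B), seed = as.integer(seed), tntc_cap = tntc_cap)
}

impute_tntc <- function(counts, tntc, cap) {
  counts[which(as.logical(tntc))] <- cap
  counts
}

#' Call an ELISpot response for one antigen measurement
#'
#' @param measurement List with `antigen_id`, `timepoint`, `counts`
#'   (well-level), `cells_per_well`, and optionally `tntc` (logical per
#'   well) and `day`.
#' @param control_measurement Same-sample medium-only measurement.
#' @param policy From [call_policy()].
#' @return One-row data frame: antigen_id, timepoint, p_eq, p_2x, p_value
#'   (the policy-combined p), mean_count, spots_per_million, positive.
#' @export
call_response <- function(measurement, control_measurement,
                          policy = call_policy()) {
  if (is.null(control_measurement)) stopf("missing medium-only control")
  a <- impute_tntc(measurement$counts, measurement$tntc %||% FALSE,
                   policy$tntc_cap)
  ctl <- impute_tntc(control_measurement$counts,
                     control_measurement$tntc %||% FALSE, policy$tntc_cap)
  p_eq <- dfr_test(a, ctl, "eq", B = policy$B, seed = policy$seed)
  p_2x <- dfr_test(a, ctl, "2x", B = policy$B, seed = policy$seed)
  reject <- switch(policy$rule,
                   require_2x = p_2x < policy$alpha,
                   require_both = p_eq < policy$alpha & p_2x < policy$alpha,
                   require_any = p_eq < policy$alpha | p_2x < policy$alpha)
  p_value <- switch(policy$rule,
                    require_2x = p_2x,
                    require_both = max(p_eq, p_2x),
                    require_any = min(p_eq, p_2x))
  mean_count <- mean(a)
  data.frame(antigen_id = measurement$antigen_id,
             timepoint = measurement$timepoint %||% NA_character_,
             day = measurement$day %||% NA_integer_,
             p_eq = p_eq, p_2x = p_2x, p_value = p_value,
             mean_count = mean_count,
             spots_per_million = normalize_spots(
               mean_count, measurement$cells_per_well),
             positive = reject && mean_count >= policy$min_count,
             stringsAsFactors = FALSE)
}

#' Classify a pre/post pair of response calls
#'
#' (negative, positive) is a de novo response; (positive, positive) an
#' amplified one; (positive, negative) pre-existing unchanged; otherwise
#' none. The fold change compares normalized magnitudes with the
#' pre-vaccination value floored at one spot per well-equivalent.
#'
#' @param pre_call,post_call Rows from [call_response()] for the same
#'   antigen and assay arm.
#' @return One-row data frame with `class` and `fold_change_post_vs_pre`.
#' @export
classify_response <- function(pre_call, post_call) {
  if (pre_call$antigen_id != post_call$antigen_id)
    stopf("pre/post calls are for different antigens")
  cls <- if (!pre_call$positive && post_call$positive) "de_novo"
  else if (pre_call$positive && post_call$positive) "amplified"
  else if (pre_call$positive && !post_call$positive) "pre_existing_unchanged"
  else "none"
  floor_pre <- max(pre_call$spots_per_million,
                   normalize_spots(1, 1e6))  # 1 spot per well-equivalent
  data.frame(antigen_id = pre_call$antigen_id, class = cls,
             pre_positive = pre_call$positive,
             post_positive = post_call$positive,
             pre_spots_per_million = pre_call$spots_per_million,
             post_spots_per_million = post_call$spots_per_million,
             fold_change_post_vs_pre =
               post_call$spots_per_million / floor_pre,
             stringsAsFactors = FALSE)
}

#' Post-IVS vaccine-response call (twofold rule)
#'
#' Positive when the post-vaccination mean spot count is at least twice the
#' pre-vaccination mean and exceeds the control mean. At a zero
#' pre-vaccination baseline the twofold rule is undefined; positivity then
#' requires a post mean of at least 7 (the per-well count gate).
#'
#' @param pre_counts,post_counts,control_counts Well-level counts (post is
#'   required; the means are taken over replicates).
#' @return Logical.
#' @export
ivs_call <- function(pre_counts, post_counts, control_counts) {
  if (is.null(post_counts) || !length(post_counts))
    stopf("missing post-vaccination sample")
  pre <- mean(pre_counts); post <- mean(post_counts)
  ctl <- mean(control_counts)
  if (post <= ctl) return(FALSE)
  if (pre == 0) return(post >= 7)
  post >= 2 * pre
}

#' Summed multi-antigen response kinetics
#'
#' Per timepoint, sums normalized magnitudes over the immunogenic antigens
#' (those classified de novo or amplified). An antigen missing at a
#' timepoint contributes zero.
#'
#' @param calls Data frame of response calls across timepoints (columns
#'   `antigen_id`, `timepoint` or `day`, `spots_per_million`).
#' @param classification Data frame from [classify_response()] rows.
#' @return Data frame `timepoint`, `sum_spots_per_million`, `n_antigens`.
#' @export
multiantigen_kinetics <- function(calls, classification) {
  immunogenic <- classification$antigen_id[
    classification$class %in% c("de_novo", "amplified")]
  key <- if ("day" %in% names(calls) && !all(is.na(calls$day))) "day"
         else "timepoint"
  tps <- unique(calls[[key]])
  rows <- lapply(tps, function(tp) {
    sub <- calls[calls[[key]] == tp & calls$antigen_id %in% immunogenic, ,
                 drop = FALSE]
    data.frame(timepoint = tp,
               sum_spots_per_million = sum(sub$spots_per_million),
               n_antigens = nrow(sub))
  })
  out <- do.call(rbind, rows)
  out[order(out$timepoint), , drop = FALSE]
}

#' Immunogenic fraction of evaluable targets
#'
#' The percentage of evaluable antigens with a positive (or de novo /
#' amplified) call, as reported per assay across a cohort.
#'
#' @param n_positive,n_evaluable Counts of positive and evaluable targets.
#' @param digits Decimal places of the printed percentage.
#' @return Percentage on the 0-100 scale.
#' @export
immunogenic_fraction <- function(n_positive, n_evaluable, digits = 1) {
  if (n_evaluable <= 0) stopf("no evaluable targets")
  round(100 * n_positive / n_evaluable, digits)
}
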