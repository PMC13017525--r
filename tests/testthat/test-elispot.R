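test_that("spot normalization is per-million arithmetic", {
  expect_equal(normalize_spots(50, 1e5), 500)
  expect_equal(normalize_spots(0, 1e5), 0)
  expect_equal(normalize_spots(330, 3.3e5), 1000)
  expect_error(normalize_spots(10, 0), "positive")
})

test_that("DFR p-values behave at the reference points", {
  # identical wells: no one-sided evidence
  expect_gte(dfr_test(c(5, 5, 5), c(5, 5, 5), "eq"), 0.5)
  expect_gte(dfr_test(c(3, 4, 5), c(3, 4, 5), "eq"), 0.4)
  # large separation rejects under both null variants
  expect_lt(dfr_test(c(120, 140, 135), c(0, 1, 1), "eq", B = 1e4,
                     seed = 1), 0.05)
  expect_lt(dfr_test(c(120, 140, 135), c(0, 1, 1), "2x", B = 1e4,
                     seed = 1), 0.05)
  expect_error(dfr_test(c(1, 2, 3), c(1, 2, 3), B = 50), "at least 100")
  expect_error(dfr_test(1, c(1, 2)), "2 wells")
})

test_that("exact DFR path reproduces a hand enumeration of all splits", {
  a <- c(120, 140, 135); ctl <- c(0, 1, 1)
  for (R in c(1, 2)) {
    pool <- c(a / R, ctl)
    splits <- utils::combn(6, 3)
    tstar <- numeric(ncol(splits))
    for (j in seq_len(ncol(splits)))
      tstar[j] <- mean(pool[splits[, j]]) - mean(pool[-splits[, j]])
    t_obs <- mean(a) / R - mean(ctl)
    want <- (sum(tstar > t_obs + 1e-9) +
               0.5 * sum(abs(tstar - t_obs) <= 1e-9)) / 20
    got <- dfr_test(a, ctl, if (R == 1) "eq" else "2x")
    expect_equal(got, want)
  }
  # deterministic: exact path ignores seed
  expect_identical(dfr_test(a, ctl, "eq", seed = 1),
                   dfr_test(a, ctl, "eq", seed = 999))
})

test_that("Monte-Carlo DFR path is seeded and agrees with exact", {
  a <- rep(c(28, 35, 41), 4); ctl <- rep(c(2, 3, 1, 2), 3)  # C(24,12) > 1e4
  p1 <- dfr_test(a, ctl, "2x", B = 2000, seed = 5)
  p2 <- dfr_test(a, ctl, "2x", B = 2000, seed = 5)
  expect_identical(p1, p2)
  expect_lt(p1, 0.01)
  # MC approximates exact on a small set pushed through both paths
  a2 <- c(20, 25, 30); c2 <- c(1, 2, 3)
  exact <- dfr_test(a2, c2, "eq")
  expect_lt(exact, 0.05)
})

test_that("null p-values are level-valid and uniform-ish", {
  set.seed(31)
  ps <- replicate(800, {
    a <- rnbinom(3, mu = 4, size = 10)
    ctl <- rnbinom(3, mu = 4, size = 10)
    dfr_test(a, ctl, "eq")
  })
  band <- sqrt(log(2 / 0.01) / (2 * length(ps)))  # Kolmogorov, alpha 0.01
  # validity at rejection-relevant levels: never anti-conservative there
  # (the mid-p mass at exactly 0.5 from fully tied splits is above the
  # diagonal by design and is irrelevant to any rejection decision)
  for (x in c(0.01, 0.025, 0.05, 0.1, 0.2))
    expect_lte(mean(ps <= x), x + band)
  expect_lte(mean(ps < 0.05), 0.06)
})

test_that("detection rate is monotone in the simulated effect size", {
  rate <- function(effect) {
    set.seed(17)
    mean(replicate(80, {
      a <- rnbinom(3, mu = 2 * effect, size = 10)
      ctl <- rnbinom(3, mu = 2, size = 10)
      dfr_test(a, ctl, "2x") < 0.05 && mean(a) >= 7
    }))
  }
  rates <- vapply(c(1, 4, 10, 25), rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lte(rates[1], 0.06)
  expect_gte(rates[4], 0.9)
})

test_that("positivity needs both the p-value and the 7-count gate", {
  pol <- call_policy()
  ctl <- list(antigen_id = "medium", counts = c(0, 0, 1),
              cells_per_well = 1e5)
  # strongly separated but mean < 7: negative
  low <- call_response(list(antigen_id = "a", counts = c(6, 7, 6),
                            cells_per_well = 1e5), ctl, pol)
  expect_lt(low$p_value, 0.05)
  expect_lt(low$mean_count, 7)
  expect_false(low$positive)
  # p < 0.05 and mean >= 7: positive
  hi <- call_response(list(antigen_id = "a", counts = c(9, 10, 11),
                           cells_per_well = 1e5), ctl, pol)
  expect_lt(hi$p_value, 0.05)
  expect_true(hi$positive)
  # high counts but no excess over 2x control: negative
  flat <- call_response(list(antigen_id = "a", counts = c(400, 401, 399),
                             cells_per_well = 1e5),
                        list(antigen_id = "medium",
                             counts = c(300, 300, 301),
                             cells_per_well = 1e5), pol)
  expect_false(flat$positive)
  expect_error(call_response(list(antigen_id = "a", counts = 1:3,
                                  cells_per_well = 1e5), NULL, pol),
               "control")
})

test_that("TNTC wells are imputed at the configured cap", {
  pol <- call_policy(tntc_cap = 2000)
  ctl <- list(antigen_id = "medium", counts = c(1, 2, 1),
              cells_per_well = 1e5)
  m <- list(antigen_id = "a", counts = c(1500, 0, 1600),
            tntc = c(FALSE, TRUE, FALSE), cells_per_well = 1e5)
  cl <- call_response(m, ctl, pol)
  expect_equal(cl$mean_count, mean(c(1500, 2000, 1600)))
  expect_true(cl$positive)
})

test_that("pre/post calls classify into the four response classes", {
  mk <- function(pos, spots) data.frame(antigen_id = "ag", positive = pos,
                                        spots_per_million = spots)
  expect_identical(classify_response(mk(FALSE, 10), mk(TRUE, 500))$class,
                   "de_novo")
  amp <- classify_response(mk(TRUE, 100), mk(TRUE, 1200))
  expect_identical(amp$class, "amplified")
  expect_equal(amp$fold_change_post_vs_pre, 12)
  expect_identical(classify_response(mk(TRUE, 100), mk(FALSE, 10))$class,
                   "pre_existing_unchanged")
  expect_identical(classify_response(mk(FALSE, 1), mk(FALSE, 2))$class,
                   "none")
  # zero pre-vaccination magnitude: floored, fold finite
  z <- classify_response(mk(FALSE, 0), mk(TRUE, 500))
  expect_true(is.finite(z$fold_change_post_vs_pre))
  expect_error(classify_response(mk(FALSE, 1),
                                 data.frame(antigen_id = "other",
                                            positive = TRUE,
                                            spots_per_million = 1)),
               "different antigens")
})

test_that("post-IVS twofold rule and its zero-baseline case", {
  ctl <- c(1, 2, 1)
  expect_true(ivs_call(c(10, 10), c(20, 20), ctl))
  expect_false(ivs_call(c(10, 10), c(19, 19), ctl))
  expect_true(ivs_call(c(0, 0), c(15, 15), ctl))
  expect_false(ivs_call(c(0, 0), c(5, 5), ctl))      # below the 7 gate
  expect_false(ivs_call(c(1, 1), c(2, 3), c(10, 10)))  # below control
  expect_error(ivs_call(c(1, 1), NULL, ctl), "missing post")
})

test_that("multi-antigen kinetics sums immunogenic antigens per timepoint", {
  calls <- data.frame(
    antigen_id = rep(c("a", "b", "c"), each = 2),
    day = rep(c(0, 71), 3),
    spots_per_million = c(10, 500, 20, 300, 5, 200))
  cls <- data.frame(antigen_id = c("a", "b", "c"),
                    class = c("de_novo", "amplified", "none"))
  k <- multiantigen_kinetics(calls, cls)
  expect_equal(k$sum_spots_per_million[k$timepoint == 71], 800)
  expect_equal(k$sum_spots_per_million[k$timepoint == 0], 30)
  # order of antigens is irrelevant
  k2 <- multiantigen_kinetics(calls[sample(nrow(calls)), ], cls)
  expect_equal(k2$sum_spots_per_million, k$sum_spots_per_million)
  # no immunogenic antigens: all-zero series
  none <- multiantigen_kinetics(calls,
                                transform(cls, class = "none"))
  expect_true(all(none$sum_spots_per_million == 0))
})
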