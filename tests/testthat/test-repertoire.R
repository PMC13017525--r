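test_that("clonotypes merge by CDR3 with frequencies recomputed", {
  raw <- data.frame(cdr3_aa = c("CASSLGQYF", "CASSLGQYF", "CASSAPDTF"),
                    count = c(3, 7, 5))
  rep <- merge_clonotypes(raw)
  expect_identical(nrow(rep), 2L)
  expect_equal(rep$count[rep$cdr3_aa == "CASSLGQYF"], 10)
  expect_equal(sum(rep$frequency), 1)
  # idempotent
  again <- merge_clonotypes(rep)
  expect_equal(again, rep)
  # AIRR column names are accepted
  airr <- data.frame(junction_aa = raw$cdr3_aa, duplicate_count = raw$count)
  expect_equal(merge_clonotypes(airr), rep)
  expect_error(merge_clonotypes(raw[0, ]), "empty")
  expect_error(merge_clonotypes(data.frame(cdr3_aa = "X", count = 0)),
               ">= 1")
})

test_that("enrichment is post-anchored with de novo imputation at the pre minimum", {
  pre <- merge_clonotypes(data.frame(
    cdr3_aa = c("A", "B", "C"), count = c(100, 899, 1)))   # min freq 1e-3
  post <- merge_clonotypes(data.frame(
    cdr3_aa = c("A", "D"), count = c(500, 500)))
  enr <- compute_enrichment(pre, post)
  a <- enr[enr$cdr3_aa == "A", ]
  expect_identical(a$status, "pre_existing")
  expect_equal(a$fold_change, 0.5 / 0.1)
  d <- enr[enr$cdr3_aa == "D", ]
  expect_identical(d$status, "de_novo")
  expect_true(d$imputed_baseline)
  expect_equal(d$pre_frequency, 1e-3)
  expect_equal(d$fold_change, 0.5 / 1e-3)
  # clone present pre but absent post yields no record
  expect_false("B" %in% enr$cdr3_aa)
  expect_error(compute_enrichment(pre[0, ], post), "empty pre")
})

test_that("pre-existing enrichment is invariant to repertoire depth", {
  pre <- data.frame(cdr3_aa = c("A", "B", "C"), count = c(10, 30, 60))
  post <- data.frame(cdr3_aa = c("A", "B"), count = c(40, 10))
  f1 <- compute_enrichment(merge_clonotypes(pre), merge_clonotypes(post))
  pre10 <- transform(pre, count = count * 10)
  post7 <- transform(post, count = count * 7)
  f2 <- compute_enrichment(merge_clonotypes(pre10), merge_clonotypes(post7))
  expect_equal(f1$fold_change[f1$status == "pre_existing"],
               f2$fold_change[f2$status == "pre_existing"])
})

test_that("de novo fold decreases as the pre-repertoire minimum rises", {
  post <- merge_clonotypes(data.frame(cdr3_aa = c("X", "Y"),
                                      count = c(50, 50)))
  folds <- vapply(c(1, 5, 20), function(mincount) {
    pre <- merge_clonotypes(data.frame(cdr3_aa = c("A", "B"),
                                       count = c(1000, mincount)))
    enr <- compute_enrichment(pre, post)
    enr$fold_change[enr$cdr3_aa == "X"]
  }, numeric(1))
  expect_true(all(diff(folds) < 0))
})

test_that("paired-chain gating keeps TRA+TRB and discards two-TRB clonotypes", {
  sc <- data.frame(
    clonotype_id = c("c1", "c1", "c2", "c2", "c2", "c3", "c4", "c4", "c4"),
    chain = c("TRB", "TRA", "TRB", "TRB", "TRA", "TRB", "TRB", "TRA", "TRA"),
    cdr3_aa = c("B1", "A1", "B2", "B2b", "A2", "B3", "B4", "A4a", "A4b"),
    v_call = "V", j_call = "J",
    cell_count = c(5, 5, 9, 9, 9, 3, 7, 2, 6),
    stringsAsFactors = FALSE)
  g <- gate_paired(sc)
  expect_setequal(g$clonotype_id, c("c1", "c4"))  # c2 two TRB, c3 TRB-only
  # multi-TRA: highest-support TRA designated primary
  c4 <- g[g$clonotype_id == "c4", ]
  expect_identical(c4$tra_cdr3_aa, "A4b")
  expect_identical(c4$n_tra, 2L)
  expect_identical(nrow(gate_paired(sc[0, ])), 0L)
})

test_that("candidate selection honours pairing and the 15/15/30 caps", {
  mk_enr <- function(n, status, fold0) data.frame(
    cdr3_aa = sprintf("%s%03d", toupper(substr(status, 1, 1)), 1:n),
    pre_frequency = 1e-4, post_frequency = 1e-3,
    fold_change = fold0 - seq_len(n), status = status,
    imputed_baseline = status == "de_novo", stringsAsFactors = FALSE)
  enr <- rbind(mk_enr(50, "de_novo", 1000), mk_enr(50, "pre_existing", 500))
  paired <- data.frame(trb_cdr3_aa = enr$cdr3_aa, tra_cdr3_aa = "TRA",
                       trb_v = "V", trb_j = "J")
  sel <- rank_and_select(enr, paired)
  expect_identical(nrow(sel), 30L)
  expect_identical(as.integer(table(sel$status)), c(15L, 15L))
  # scarce de novo class: the other class does not borrow
  enr2 <- rbind(mk_enr(4, "de_novo", 1000), mk_enr(50, "pre_existing", 500))
  sel2 <- rank_and_select(enr2, paired)
  expect_identical(sum(sel2$status == "de_novo"), 4L)
  expect_identical(sum(sel2$status == "pre_existing"), 15L)
  # a highly enriched unpaired clone is never selected
  enr3 <- rbind(data.frame(cdr3_aa = "UNPAIRED", pre_frequency = 1e-5,
                           post_frequency = 0.2, fold_change = 2e4,
                           status = "de_novo", imputed_baseline = TRUE),
                enr)
  sel3 <- rank_and_select(enr3, paired)
  expect_false("UNPAIRED" %in% sel3$cdr3_aa)
  expect_error(rank_and_select(enr, paired,
                               caps = list(per_class_min = 10L,
                                           per_class_max = 5L,
                                           total_max = 30L)),
               "per_class_max")
})

test_that("reporter specificity uses the exact twofold cut-off", {
  lum <- data.frame(
    tcr_id = rep(c("t1", "t2", "t3"), each = 3),
    condition_id = rep(c("ctrl", "ag1", "ag2"), 3),
    antigen_id = rep(c(NA, "ag1", "ag2"), 3),
    hla_allele = rep(c(NA, "A*02:01", "B*07:02"), 3),
    rlu = c(1000, 2000, 900,    # t1: fold 2.0 -> specific
            1000, 1990, 500,    # t2: fold 1.99 -> not specific
            1000, 5000, 2600),  # t3: two specific conditions
    is_control = rep(c(TRUE, FALSE, FALSE), 3))
  rc <- call_reactivity(lum)
  expect_setequal(rc$specific_tcrs, c("t1", "t3"))
  t1 <- rc$calls[rc$calls$tcr_id == "t1" & rc$calls$antigen_id == "ag1", ]
  expect_equal(t1$fold_over_control, 2)
  expect_true(t1$specific)
  t2 <- rc$calls[rc$calls$tcr_id == "t2" & rc$calls$antigen_id == "ag1", ]
  expect_false(t2$specific)
  lum0 <- transform(lum, rlu = ifelse(is_control & tcr_id == "t1", 0, rlu))
  expect_error(call_reactivity(lum0), "non-positive control")
  expect_error(call_reactivity(lum[lum$tcr_id != "t1" | !lum$is_control, ]),
               "no effectors-only control")
})

test_that("clone tracking reports zeros for absent clones and bounded totals", {
  reps <- list(
    pre = merge_clonotypes(data.frame(cdr3_aa = c("A", "B", "C"),
                                      count = c(1, 10, 989))),
    post = merge_clonotypes(data.frame(cdr3_aa = c("A", "B"),
                                       count = c(20, 80))),
    tumour = merge_clonotypes(data.frame(cdr3_aa = "C", count = 5)))
  tr <- track_clones(c("A", "B"), reps)
  expect_identical(dim(tr$matrix), c(2L, 3L))
  expect_equal(tr$matrix["A", "pre"], 0.001)
  expect_equal(tr$matrix["A", "post"], 0.2)
  expect_equal(tr$matrix["A", "tumour"], 0)   # absent in tumour
  expect_true(all(tr$cumulative <= 1 + 1e-9))
  expect_equal(unname(tr$cumulative["post"]), 1)
})
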