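cand_row <- function(id, kind = "snv", c1 = 50, c2 = 50, rpkm = 20,
                     rna = 0.3, dna = 0.3) {
  data.frame(mps_id = paste0("MPS_", id), variant_id = id,
             variant_kind = kind, best_class1 = c1, best_class2 = c2,
             rpkm = rpkm, rna_vaf = rna, dna_vaf = dna,
             sequence = paste(rep("A", 27), collapse = ""),
             stringsAsFactors = FALSE)
}

test_that("staged prioritization enforces caps and RPKM gates", {
  # 7 expressed indels: exactly 5 enter via step 1, by class I score
  cand <- do.call(rbind, lapply(1:7, function(i)
    cand_row(sprintf("I%02d", i), kind = "deletion", c1 = i)))
  out <- prioritize_mps(cand)
  expect_identical(nrow(out), 5L)
  expect_true(all(out$selection_step == "s1_indel_hla1"))
  expect_identical(out$variant_id, sprintf("I%02d", 1:5))
  # RPKM 9.9 skipped by step 2, admitted by step 3 on class I score
  cand2 <- rbind(cand_row("A", rpkm = 9.9, c1 = 0.5, c2 = 0.5),
                 cand_row("B", rpkm = 50, c1 = 80, c2 = 1))
  out2 <- prioritize_mps(cand2)
  expect_identical(out2$selection_step[out2$variant_id == "A"],
                   "s3_snv_hla1")
  expect_identical(out2$selection_step[out2$variant_id == "B"],
                   "s2_snv_hla2")
  # RPKM 0.5 fails both gates, enters via step 4 on expression
  cand3 <- rbind(cand2, cand_row("C", rpkm = 0.5))
  out3 <- prioritize_mps(cand3)
  expect_identical(out3$selection_step[out3$variant_id == "C"],
                   "s4_snv_expression")
})

test_that("abundant pools cap at 46 and scarce pools keep everything", {
  big <- do.call(rbind, lapply(1:200, function(i)
    cand_row(sprintf("V%03d", i), c1 = i %% 97, c2 = (i * 7) %% 89,
             rpkm = (i * 13) %% 40)))
  out <- prioritize_mps(big)
  expect_identical(nrow(out), 46L)
  expect_false(anyDuplicated(out$variant_id) > 0)
  small <- big[1:40, ]
  out40 <- prioritize_mps(small)
  expect_identical(nrow(out40), 40L)
  steps <- unique(out40$selection_step)
  expect_identical(steps,
                   intersect(c("s1_indel_hla1", "s2_snv_hla2", "s3_snv_hla1",
                               "s4_snv_expression", "s5_fallback_hla1",
                               "s6_fallback_expression"), steps))
})

test_that("prioritization equals the independent brute-force oracle", {
  for (seed in 1:25) {
    cand <- random_candidates(sample(5:15, 1), seed = 100 + seed)
    got <- prioritize_mps(cand)
    want <- oracle_prioritize(cand)
    expect_identical(got$mps_id, want$mps_id, info = paste("seed", seed))
    expect_identical(got$selection_step, want$selection_step,
                     info = paste("seed", seed))
  }
  # larger instances: order and caps still agree
  for (seed in 1:5) {
    cand <- random_candidates(80, seed = 900 + seed)
    expect_identical(prioritize_mps(cand)$mps_id,
                     oracle_prioritize(cand)$mps_id)
  }
})

test_that("improving a winning class I score never drops the winner", {
  cand <- random_candidates(12, seed = 7)
  base <- prioritize_mps(cand)
  winners <- base$mps_id[base$selection_step %in%
                           c("s1_indel_hla1", "s3_snv_hla1")]
  for (w in winners) {
    cand2 <- cand
    cand2$best_class1[cand2$mps_id == w] <-
      cand2$best_class1[cand2$mps_id == w] / 2
    out2 <- prioritize_mps(cand2)
    expect_true(w %in% out2$mps_id)
  }
})

test_that("target selection truncates prioritized order; weights re-rank", {
  cand <- do.call(rbind, lapply(1:60, function(i)
    cand_row(sprintf("V%03d", i), c1 = i, c2 = i, rpkm = 60 - i)))
  pri <- prioritize_mps(cand)
  expect_identical(nrow(pri), 46L)
  sel <- select_targets(pri)
  expect_identical(nrow(sel), 20L)
  expect_identical(sel$mps_id, pri$mps_id[1:20])
  expect_identical(select_targets(pri[1:12, ])$mps_id, pri$mps_id[1:12])
  # all-zero weights are the identity configuration
  sel0 <- select_targets(pri, weights = c(best_class1 = 0, best_class2 = 0,
                                          rpkm = 0, dna_vaf = 0))
  expect_identical(sel0, sel)
  # weighting expression promotes high-RPKM targets
  selw <- select_targets(pri, weights = c(best_class1 = 0, best_class2 = 0,
                                          rpkm = 1, dna_vaf = 0))
  expect_identical(selw$mps_id[1], pri$mps_id[which.max(pri$rpkm)])
  expect_error(select_targets(pri[0, ]), "empty")
})

test_that("targets are dealt alternately onto two strings of at most 10", {
  sel <- do.call(rbind, lapply(1:20, function(i) cand_row(sprintf("V%02d", i))))
  p20 <- partition_targets(sel)
  expect_identical(as.integer(table(p20$string)), c(10L, 10L))
  expect_identical(p20$string[1:4], c(1L, 2L, 1L, 2L))
  p13 <- partition_targets(sel[1:13, ])
  expect_identical(as.integer(table(p13$string)), c(7L, 6L))
  p1 <- partition_targets(sel[1, ])
  expect_identical(p1$string, 1L)
  expect_error(partition_targets(rbind(sel, cand_row("V21"))), "exceed")
})

test_that("constructs assemble SEC-concatemer-MITD with 30-nt linkers", {
  t27 <- paste(rep("A", 27), collapse = "")
  cs <- assemble_construct(c(t27, t27), target_ids = c("t1", "t2"))
  expect_identical(nchar(cs$orf_aa), 26L + 27L + 10L + 27L + 55L)  # 145
  expect_identical(nchar(cs$orf_nt), 435L)
  expect_identical(translate_cds(cs$orf_nt), cs$orf_aa)
  ann <- cs$annotations
  expect_identical(ann$element,
                   c("SEC", "target", "linker", "target", "MITD"))
  link <- ann[ann$element == "linker", ]
  expect_identical(link$end_nt - link$start_nt + 1L, 30L)
  # spans tile the ORF exactly
  expect_identical(ann$start_aa[1], 1L)
  expect_identical(ann$end_aa[nrow(ann)], nchar(cs$orf_aa))
  expect_identical(ann$start_aa[-1], ann$end_aa[-nrow(ann)] + 1L)
  expect_identical(ann$start_nt[-1], ann$end_nt[-nrow(ann)] + 1L)
  # single target: no linker
  cs1 <- assemble_construct(t27)
  expect_false("linker" %in% cs1$annotations$element)
  expect_identical(nchar(cs1$orf_aa), 26L + 27L + 55L)
  expect_error(assemble_construct(t27, linker = "GGSGGGGSGA"), "G/S")
  expect_error(assemble_construct(t27, linker = "GGS"), "10 residues")
  expect_error(assemble_construct(character(0)), "at least one")
})

test_that("ORF length identity holds for any target set", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(1:10, 1)
    tgts <- vapply(seq_len(n), function(i)
      paste(sample(AA20, sample(14:50, 1), TRUE), collapse = ""),
      character(1))
    cs <- assemble_construct(tgts)
    expect_identical(nchar(cs$orf_aa),
                     81L + sum(nchar(tgts)) + 10L * (n - 1L))
    expect_identical(nchar(cs$orf_nt), 3L * nchar(cs$orf_aa))
    expect_identical(translate_cds(cs$orf_nt), cs$orf_aa)
  }
})

test_that("design reports round-trip and are byte-stable", {
  co <- generate_cohort(cohort_spec(seed = 3, n_missense = 30,
                                    n_frameshift = 3))
  res <- run_design(co)
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  emit_design_report(res$design, d1)
  emit_design_report(res$design, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  back <- read_design_report(d1, res$design$patient_id)
  expect_identical(sort(back$targets$mps_id),
                   sort(res$design$selected$mps_id))
  for (s in names(res$design$constructs)) {
    nm <- sprintf("%s|string%s", res$design$patient_id, s)
    expect_identical(unname(back$orf_nt[nm]),
                     res$design$constructs[[s]]$orf_nt)
    expect_identical(unname(back$orf_aa[nm]),
                     res$design$constructs[[s]]$orf_aa)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
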