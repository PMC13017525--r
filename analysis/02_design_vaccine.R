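#!/usr/bin/env Rscript
# Design the individualized vaccine for the simulated patient: build
# mutated peptide sequences, score variant-containing epitopes against the
# patient's HLA typing with the seeded mock predictor, prioritize up to 46
# MPS, select 20 targets, and assemble the two mRNA construct strings.

suppressPackageStartupMessages(library(neovax))

cohort <- read_cohort("results/cohort")
res <- run_design(cohort, predictor_seed = 42L, out_dir = "results/design")

cat(sprintf("%d MPS built (%d variants filtered):\n",
            length(res$mps), nrow(res$log)))
if (nrow(res$log)) print(table(res$log$reason))
pri <- res$design$prioritized
cat(sprintf("prioritized %d MPS by step:\n", nrow(pri)))
print(table(pri$selection_step))
sel <- res$design$selected
cat(sprintf("selected %d targets; strings carry %s targets\n",
            nrow(sel), paste(table(sel$string), collapse = " + ")))
for (s in names(res$design$constructs)) {
  cs <- res$design$constructs[[s]]
  cat(sprintf("string %s ORF: %d aa / %d nt (%d linkers of 30 nt)\n",
              s, nchar(cs$orf_aa), nchar(cs$orf_nt),
              sum(cs$annotations$element == "linker")))
}
planted <- cohort$planted_binders$variant_id
cat(sprintf("planted binders among selected targets: %d of %d\n",
            sum(sel$variant_id %in% planted), length(planted)))
cat("report written to results/design\n")
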