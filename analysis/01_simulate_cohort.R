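#!/usr/bin/env Rscript
# Simulate one patient's sequencing-derived inputs: expressed transcripts,
# somatic variants of every consequence class, in-phase germline calls,
# HLA typing, and two planted strong binders for the mock predictor.
# Writes the fixture directory consumed by 02_design_vaccine.R.

suppressPackageStartupMessages(library(neovax))

out <- "results/cohort"
spec <- cohort_spec(seed = 20260929L, n_missense = 60L, n_synonymous = 6L,
                    n_nonsense = 3L, n_frameshift = 6L, n_inframe = 2L,
                    n_germline_inphase = 4L, n_planted = 2L)
cohort <- generate_cohort(spec, patient_id = "SIM01")
write_cohort(cohort, out)

cat(sprintf("patient %s: %d transcripts, %d somatic variants\n",
            cohort$patient_id, nrow(cohort$transcripts),
            nrow(cohort$variants)))
print(table(cohort$truth$consequence))
cat(sprintf("%d variants with RNA VAF = 0 (expression-silent)\n",
            sum(cohort$variants$rna_vaf == 0)))
cat(sprintf("%d in-phase germline calls, %d planted binders\n",
            nrow(cohort$germline), nrow(cohort$planted_binders)))
cat("fixture written to", out, "\n")
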