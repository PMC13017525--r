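---
title: "Methods: neoantigen vaccine design and immunomonitoring with neovax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neoantigen vaccine design and immunomonitoring with neovax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovax)
```

# Scope

`neovax` implements the computational core of an individualized neoantigen
mRNA-vaccine workflow: somatic variants on coding transcripts are turned
into mutated peptide sequences (MPS), variant-containing epitopes are
scored against the patient's HLA typing, up to 20 vaccine targets are
prioritized and assembled into two concatemer mRNA constructs, vaccine-
induced T cell responses are called from replicate-level IFN-γ ELISpot
counts, and vaccine-expanded T cell clones are identified from bulk and
single-cell TCR repertoires (reverse immunomonitoring, RevImMo). Read
alignment, variant calling, expression quantification and real MHC-binding
predictors are out of scope: variants, expression values, phase flags and
binding scores are inputs, the latter through a pluggable predictor
interface with a deterministic mock.

# Mutated peptide construction

A missense SNV yields the 27mer window of the mutated protein with the
changed residue in the centre (13 residues of flank on each side). Two
interpretations were needed where the construction rule is under-specified:

* **Terminal truncation.** Within 13 residues of a protein terminus the
  window keeps all available flank on that side and is not padded, so the
  mutation need not be central and the MPS length ranges over 14–27.
* **In-frame indels** are windowed like SNVs, centred on the first changed
  residue, with inserted residues additionally marked as mutated.

A frameshift indel yields the novel peptide tail from the first changed
residue to the next stop codon in the shifted frame, hard-capped at 50
residues; a frameshift whose first novel codon is already a stop produces
nothing and is discarded with a logged reason. Synonymous and nonsense
variants are filtered. Variants on non-expressed transcripts are retained
but flagged; the expression thresholds act later, during prioritization.

Protein-changing germline variants arrive with phase flags (`in_phase_with`
somatic variant ids); read-level phasing is external. A phased germline
substitution falling inside an SNV window is applied to the emitted peptide
and recorded. One MPS is emitted per somatic variant on its designated
canonical transcript; isoform expansion and merging of overlapping somatic
variants into composite peptides are deliberately not performed.

Variant coordinates are VCF-style anchored (1-based CDS positions; indel
`ref`/`alt` include the anchor base). All file formats use 1-based
inclusive positions.

# Epitope enumeration and scoring

For HLA class I (A/B/C alleles) every 8–11mer window of the MPS that
overlaps at least one mutated residue is enumerated; for class II, every
15mer, restricted to HLA-DRB alleles as the class II loci actually used for
prediction. An MPS shorter than 15 residues has no class II queries.

Scores follow the IEDB consensus percentile-rank convention: lower is
stronger, and the per-MPS "best" score for a class is the minimum over that
class's (peptide, allele) rows. When a class has no rows the best score is
the sentinel 999, which sorts after every genuine percentile.

The shipped predictor is a deterministic mock: a polynomial hash of
(peptide, normalized allele, seed) mapped to [0, 100). It is not a binding
model — it exists so that the scoring, prioritization and selection
machinery can be exercised reproducibly, and so that simulations can plant
known strong binders (forced score 0.1) whose recovery downstream is
checkable. Allele names are normalized to the `A*02:01` / `DRB1*04:01`
form from common variant spellings.

# Prioritization, selection and construct assembly

Prioritization considers mutations with RNA variant-allele frequency
(VAF) > 0 and runs staged filters, each step drawing only from MPS not
taken by an earlier step, until 46 MPS are accumulated:

1. up to 5 indel-derived MPS by best class I score;
2. up to 20 SNV MPS with expression ≥ 10 RPKM by best class II score;
3. up to 20 SNV MPS with expression ≥ 1 RPKM by best class I score;
4. further SNV MPS by expression, to 46 in total.

If fewer than 46 accumulate, RNA-silent mutations (RNA VAF = 0) are added:
first those with an actual class I prediction, by that score; then the
remainder by expression. The source description labels both fallback
criteria with the same ordinal, so the split used here — score-bearing
candidates before expression-only ones — is a documented interpretation.
Step 4 is restricted to SNVs, as written. All sorts are stable, with ties
broken by expression (descending) then variant id, so results are exactly
reproducible.

Selection takes the first 20 prioritized MPS by default. An optional
composite re-ranking (configurable weights over best class I/II scores,
expression and DNA VAF) is available; all-zero weights reduce exactly to
the default. The review-board step that accompanied selection in practice
is a human process and is out of scope. Cohort eligibility required at
least five neoantigens; designs with fewer targets trigger a warning
rather than an error.

Targets are dealt alternately by rank onto two strings (at most 10 each) —
the actual split across the two RNA molecules was never specified, and
alternation balances both count and rank. Each string's open reading frame
is `SEC ++ t1 ++ L ++ t2 ++ ... ++ L ++ tn ++ MITD`, with the secretory
signal peptide (26 aa) and MHC class I trafficking domain (55 aa) as fixed
literals and 10-residue glycine/serine linkers (30 nt once encoded; the
exact G/S composition is configurable since it is not printed anywhere).
Reverse translation uses a fixed most-frequent-human-codon table, so
`translate_cds(reverse_translate(x))` is the identity and constructs are
byte-reproducible. The FI RNA-stability element and UTR/poly(A) designs
belong to the vector backbone, not the antigen-coding ORF, and are carried
as construct metadata only.

# ELISpot response calling

Antigen wells are compared with same-sample medium-only control wells by
two one-sided distribution-free resampling (DFR) tests of
H0: mean(antigen) ≤ R · mean(control), with R = 1 ("eq") and R = 2 ("2x").
Under the boundary null the antigen counts scaled by 1/R are exchangeable
with the control counts, so the reference distribution of
T = mean(antigen)/R − mean(control) is built by resampling group labels
over the pooled scaled wells: exhaustive enumeration of all
`choose(n, n_antigen)` splits when that space is ≤ 10⁴ (the test is then
exact and deterministic), seeded Monte-Carlo splits otherwise. The
returned p-value carries the mid-p correction for discrete reference
sets. This choice is load-bearing at the assay's replicate counts: with
triplicates there are only 20 splits, a plain permutation p can never fall
below 1/20 = 0.05, and rejection at p < 0.05 would be unattainable. With
mid-p, rejection requires the observed split to be the strict maximizer
of T (mid-p 0.025), which keeps the test exactly level-bounded — measured
type-I error 0.02–0.05 across negative-binomial null regimes — while
detection of a 20-fold effect with triplicates exceeds 0.99. With
duplicate wells even the mid-p cannot reach 0.05; duplicate-only data
cannot yield a positive ex vivo call, matching field guidance to run at
least three wells. A recentred-bootstrap variant was evaluated and
rejected: at 2–3 wells per group it is anti-conservative (measured type-I
0.11–0.17 at α = 0.05), and its studentized repair loses the 20× effect
about one time in five.

A response is positive when the configured test combination rejects at
α = 0.05 **and** the mean antigen count is at least 7 spots per well. The
7-count gate is applied to the raw per-well mean, not the normalized
magnitude (the source does not say which; raw counts are the scale on
which the threshold is integer-valued). The default combination rule is
`require_2x` — the 2x test must reject, with the eq p-value reported —
with `require_both` and `require_any` available. No cross-antigen
multiplicity correction is applied by default, matching per-antigen
reporting practice. "Too numerous to count" wells are imputed at a
configurable cap (default 2,000 spots/well) and flagged.

Magnitudes are normalized to spots per 10⁶ cells
(`mean_count / cells_per_well × 1e6`). Comparing pre- and post-vaccination
calls classifies each antigen: (negative, positive) → de novo;
(positive, positive) → amplified; (positive, negative) → pre-existing
unchanged; otherwise none. Amplification is classified on positivity
alone — the observed >11-fold expansions are descriptive, not a
threshold — and the reported fold change floors the pre-vaccination
magnitude at one spot per well-equivalent to stay finite. The post-IVS
arm instead uses the at-least-twofold increase rule over the
pre-vaccination mean, with positivity at a zero baseline requiring a post
mean ≥ 7 (reusing the count gate) and the post mean exceeding control.
Multi-antigen kinetics sum normalized magnitudes over the antigens
classified de novo or amplified, per timepoint, with absent antigens
contributing zero.

# Reverse immunomonitoring

Bulk TRB clonotypes are merged on the CDR3 amino-acid sequence — the
identity key throughout; V/J calls are annotations — with counts summed
and frequencies recomputed. Enrichment is post-anchored: for every clone
observed post-treatment, pre-existing clones get fold = post/pre
frequency, and clones absent pre-treatment are de novo with the baseline
imputed as the lowest frequency observed in the pre-treatment repertoire
of the same compartment. Clones that contracted to zero are not recorded;
the procedure exists to rank post-expanded candidates. Single-cell
clonotypes are gated to those with both a TRA and a TRB chain; two-TRB
clonotypes are discarded as probable doublets, while multi-TRA clonotypes
are kept with the best-supported TRA designated primary. Only paired
clonotypes are eligible for selection: up to 15 of the most enriched de
novo and up to 15 pre-existing clones (no borrowing between classes),
total capped at 30. Ties in fold change break by post frequency then
CDR3. Reporter specificity divides each (antigen, HLA) condition's
luminescence by the TCR's effectors-only control; fold ≥ 2 is specific,
exactly at the boundary. Tracking builds a clone × sample frequency
matrix over any set of merged repertoires (timepoints, compartments,
tumour), with zero where a clone is absent.

# Synthetic data

The generators produce inputs with the statistical structure the pipeline
assumes, plus truth labels sufficient to score every downstream call. All
randomness flows from a single seed and regeneration is identical.

* **Cohorts.** Template codons are planted into random coding sequences
  and mutated so each requested consequence class (missense, synonymous,
  nonsense, frameshift, in-frame) is realised exactly; frameshift
  positions are redrawn until the shifted frame yields a non-empty tail.
  Expression is log-normal (meanlog 2, sdlog 1.5 — median ≈ 7 RPKM, so
  both expression gates bind); DNA VAF ~ Beta(2, 6) (clonal-ish tumour
  fractions), RNA VAF ~ Beta(2, 2) with a configurable fraction forced to
  zero (default 10%) to exercise the fallback steps.
* **ELISpot.** Negative-binomial well counts, baseline mean 2 with
  dispersion (size) 10 — the noisy end of published replicate
  variability — in triplicate at 10⁵ cells/well. Responders gain a
  multiplicative 20× effect from day 22 (after the third dose);
  pre-existing responders start at the effect level and are further
  amplified 12-fold post-vaccination. Non-responders share the control
  distribution exactly.
* **Repertoires.** A power-law clone-size law (frequency ∝ rank^−1.2 over
  2,000 clones) sampled multinomially at depth 3 × 10⁴ pre and post; 20
  spiked clones from mid-repertoire ranks are expanded 50-fold post, half
  of them de novo (zero pre-treatment weight by construction); paired
  single-cell chains are observed with probability 0.8 for the largest
  post clones, alongside TRB-only and two-TRB decoys; the reporter matrix
  draws specific conditions at 3–30× control and non-specific ones at
  0.5–1.5×.

These generators emulate sampling noise and the pipeline's filter
structure, not biology: no real proteome or HLA frequencies, no binding
chemistry, no shared clones between unrelated processes, no batch or
plate effects. Passing tests therefore demonstrate the correctness and
calibration of the algorithms under the stated stochastic models, not
performance on real sequencing or assay data.

# Problem sizes and numerical choices

The test suite runs the full design chain on cohorts of 40–170 variants,
checks prioritization against an independent brute-force implementation
on instances of up to 15 candidates (and order-agreement at 80), measures
DFR type-I error on 1,000 simulated null antigens and detection on 200
simulated responders, and measures spiked-clone recovery on 100 seeded
repertoire replicates (recovery target ≥ 90% of paired spiked clones in
the top 30). Exact DFR enumeration makes the well-level tests
deterministic; Monte-Carlo resampling (B = 10⁴ by default, minimum 100)
applies only beyond `choose(n, n_a) ≤ 10⁴`. Floating-point tie detection
in the permutation statistic uses an absolute tolerance of 10⁻⁹ on count
scales, and repertoire frequency conservation is asserted at 10⁻⁹.

# Known limitations

The mock predictor shares no structure with real MHC-binding tools beyond
the score convention; planted binders are the only controllable signal.
Duplicate-well ELISpot data cannot produce positive ex vivo calls (see
above). The de novo imputation floor ties enrichment of unseen clones to
pre-treatment sequencing depth, so fold changes for de novo clones are
depth-dependent by construction. Manual review of target selection,
scRNA-seq phenotyping, and everything upstream of the variant table are
outside the package.
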