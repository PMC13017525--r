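# Seeded synthetic-data generators.
#
# These emulate the statistical structure of the pipeline's inputs --
# tumour variant calls on expressed transcripts with DNA/RNA VAF, mock
# binding-score landscapes, negative-binomial ELISpot well counts with a
# post-vaccination effect, and power-law TCR repertoires with spiked
# expansions -- together with ground-truth labels sufficient to score
# every downstream call. All randomness flows from a single seed;
# regeneration with the same spec is identical.

SENSE_CODONS <- local({
  all <- names(GENETIC_CODE_1)
  all[GENETIC_CODE_1 != "*"]
})

# Planted (ref_codon, position, alt_base) templates realising each
# requested consequence exactly.
VARIANT_TEMPLATES <- list(
  missense = list(c("GCT", 1, "C"),   # Ala -> Pro
                  c("AAA", 1, "G"),   # Lys -> Glu
                  c("TTC", 1, "A")),  # Phe -> Ile
  synonymous = list(c("GCT", 3, "C"), # Ala -> Ala
                    c("CTG", 3, "A")),# Leu -> Leu
  nonsense = list(c("TAC", 3, "G"),   # Tyr -> stop (TAG)
                  c("TGG", 2, "A")))  # Trp -> stop (TAG)

#' Specification for a synthetic patient cohort
#'
#' Counts of somatic variants by intended consequence, a coding-sequence
#' length range (in codons), a log-normal expression model, Beta VAF
#' models with a configurable fraction of RNA-silent mutations, the HLA
#' typing, and an optional number of planted strong binders.
#'
#' @param seed Master seed; every generated byte derives from it.
#' @param n_missense,n_synonymous,n_nonsense,n_frameshift,n_inframe Counts
#'   of variants of each consequence class (one variant per transcript).
#' @param cds_codons Range of CDS lengths in codons (excluding the stop).
#' @param expression_meanlog,expression_sdlog Log-normal RPKM model.
#' @param dna_vaf_shape,rna_vaf_shape Beta shape pairs.
#' @param frac_rna_zero Fraction of variants forced to RNA VAF 0.
#' @param hla Patient HLA typing (class I A/B/C and class II DRB alleles).
#' @param n_germline_inphase Number of missense variants that receive an
#'   in-phase protein-changing germline call inside the 27mer window.
#' @param n_planted Number of missense variants whose mutated 9mer is
#'   registered as a planted strong binder for the mock predictor.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(seed = 1L, n_missense = 20L, n_synonymous = 2L,
                        n_nonsense = 1L, n_frameshift = 3L, n_inframe = 0L,
                        cds_codons = c(60L, 120L),
                        expression_meanlog = 2, expression_sdlog = 1.5,
                        dna_vaf_shape = c(2, 6), rna_vaf_shape = c(2, 2),
                        frac_rna_zero = 0.1,
                        hla = c("A*01:01", "A*02:01", "B*07:02", "B*08:01",
                                "C*07:01", "C*07:02",
                                "DRB1*03:01", "DRB1*15:01"),
                        n_germline_inphase = 0L, n_planted = 0L) {
  structure(as.list(environment()), class = "cohort_spec")
}

random_cds <- function(n_codons) {
  body <- sample(SENSE_CODONS, n_codons - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

plant_codon <- function(cds, codon_idx, codon) {
  start <- (codon_idx - 1L) * 3L + 1L
  paste0(substr(cds, 1L, start - 1L), codon,
         substr(cds, start + 3L, nchar(cds)))
}

#' Generate a synthetic patient cohort
#'
#' Realises the requested consequence counts exactly: template codons are
#' planted into random coding sequences and mutated so that
#' [classify_variant()] reproduces the intended class, and frameshift
#' positions are redrawn until the shifted frame yields a non-empty novel
#' tail. One variant is placed per transcript.
#'
#' @param spec A [cohort_spec()].
#' @param patient_id Identifier carried on all outputs.
#' @return List with `transcripts`, `variants`, `germline`, `hla`, `truth`
#'   (variant_id, intended consequence) and `planted_binders` data frames.
#' @export
generate_cohort <- function(spec = cohort_spec(), patient_id = "P1") {
  with_seed(spec$seed, {
    kinds <- c(rep("missense", spec$n_missense),
               rep("synonymous", spec$n_synonymous),
               rep("nonsense", spec$n_nonsense),
               rep("frameshift", spec$n_frameshift),
               rep("inframe", spec$n_inframe))
    n <- length(kinds)
    if (n < 1L) stopf("cohort spec requests no variants")
    tx_ids <- sprintf("TX%04d", seq_len(n))
    var_ids <- sprintf("VAR%04d", seq_len(n))
    genes <- sprintf("GENE%04d", seq_len(n))
    ncod <- sample(seq(spec$cds_codons[1], spec$cds_codons[2]), n,
                   replace = TRUE)
    rpkm <- round(stats::rlnorm(n, spec$expression_meanlog,
                                spec$expression_sdlog), 3)
    dna_vaf <- round(stats::rbeta(n, spec$dna_vaf_shape[1],
                                  spec$dna_vaf_shape[2]), 4)
    rna_vaf <- round(stats::rbeta(n, spec$rna_vaf_shape[1],
                                  spec$rna_vaf_shape[2]), 4)
    zero <- sample.int(n, round(spec$frac_rna_zero * n))
    rna_vaf[zero] <- 0
    cds <- character(n)
    vrows <- vector("list", n)
    for (i in seq_len(n)) {
      kind <- kinds[i]
      cds_i <- random_cds(ncod[i])
      if (ncod[i] < 12L) stopf("CDS too short to place a variant")
      if (kind %in% c("missense", "synonymous", "nonsense")) {
        tpl <- VARIANT_TEMPLATES[[kind]][[
          sample.int(length(VARIANT_TEMPLATES[[kind]]), 1L)]]
        codon_idx <- sample(3:(ncod[i] - 2L), 1L)
        cds_i <- plant_codon(cds_i, codon_idx, tpl[1])
        pos <- (codon_idx - 1L) * 3L + as.integer(tpl[2])
        vrows[[i]] <- list(kind = "snv", cds_position = pos,
                           ref = substr(tpl[1], as.integer(tpl[2]),
                                        as.integer(tpl[2])),
                           alt = tpl[3])
      } else if (kind == "inframe") {
        pos <- 3L * sample(3:(ncod[i] - 2L), 1L)  # codon boundary anchor
        anchor <- substr(cds_i, pos, pos)
        ins <- paste(sample(SENSE_CODONS, 1L), collapse = "")
        vrows[[i]] <- list(kind = "insertion", cds_position = pos,
                           ref = anchor, alt = paste0(anchor, ins))
      } else {  # frameshift: 1-nt deletion, redrawn until the tail exists
        ok <- FALSE
        for (attempt in 1:50) {
          pos <- sample(6:(3L * (ncod[i] - 3L)), 1L)
          ref <- substr(cds_i, pos, pos + 1L)
          alt <- substr(cds_i, pos, pos)
          mut <- apply_variant(cds_i, pos, ref, alt)
          ref_prot <- translate_cds(cds_i)
          mut_prot <- translate_cds(mut, allow_internal_stop = TRUE,
                                    partial = TRUE)
          fd <- first_difference(ref_prot, mut_prot)
          if (!is.na(fd) && fd <= nchar(mut_prot)) { ok <- TRUE; break }
        }
        if (!ok) stopf("could not place frameshift on %s", tx_ids[i])
        vrows[[i]] <- list(kind = "deletion", cds_position = pos,
                           ref = ref, alt = alt)
      }
      cds[i] <- cds_i
    }
    variants <- data.frame(
      variant_id = var_ids, transcript_id = tx_ids,
      kind = vapply(vrows, `[[`, character(1), "kind"),
      cds_position = vapply(vrows, function(v)
        as.integer(v$cds_position), integer(1)),
      ref = vapply(vrows, `[[`, character(1), "ref"),
      alt = vapply(vrows, `[[`, character(1), "alt"),
      dna_vaf = dna_vaf, rna_vaf = rna_vaf, gene_symbol = genes,
      stringsAsFactors = FALSE)
    transcripts <- data.frame(
      transcript_id = tx_ids, gene_symbol = genes,
      expression_rpkm = rpkm, cds_sequence = cds, stringsAsFactors = FALSE)
    germline <- make_inphase_germline(transcripts, variants, kinds,
                                      spec$n_germline_inphase)
    truth <- data.frame(variant_id = var_ids, consequence = kinds,
                        stringsAsFactors = FALSE)
    hla <- data.frame(patient_id = patient_id,
                      locus = sub("\\*.*", "", spec$hla),
                      allele = spec$hla, stringsAsFactors = FALSE)
    planted <- make_planted_binders(transcripts, variants, kinds,
                                    spec$n_planted, spec$hla)
    list(patient_id = patient_id, transcripts = transcripts,
         variants = variants, germline = germline, hla = hla,
         truth = truth, planted_binders = planted)
  })
}

# In-phase germline SNVs placed a few codons from the somatic missense
# site, guaranteed protein-changing and non-stop.
make_inphase_germline <- function(transcripts, variants, kinds, n_germ) {
  empty <- data.frame(germline_id = character(0),
                      transcript_id = character(0),
                      cds_position = integer(0), ref = character(0),
                      alt = character(0), in_phase_with = character(0),
                      stringsAsFactors = FALSE)
  if (n_germ < 1L) return(empty)
  targets <- which(kinds == "missense")[seq_len(min(
    n_germ, sum(kinds == "missense")))]
  rows <- lapply(seq_along(targets), function(k) {
    i <- targets[k]
    cds <- transcripts$cds_sequence[i]
    som_codon <- (variants$cds_position[i] - 1L) %/% 3L + 1L
    g_codon <- som_codon + sample(c(-5L:-2L, 2L:5L), 1L)
    g_codon <- max(2L, min(nchar(cds) %/% 3L - 1L, g_codon))
    cstart <- (g_codon - 1L) * 3L + 1L
    codon <- substr(cds, cstart, cstart + 2L)
    for (b in c("A", "C", "G", "T")) {
      cand <- codon; substr(cand, 1L, 1L) <- b
      if (cand != codon && GENETIC_CODE_1[[cand]] != "*" &&
          GENETIC_CODE_1[[cand]] != GENETIC_CODE_1[[codon]]) {
        return(data.frame(germline_id = sprintf("GL%03d", k),
                          transcript_id = transcripts$transcript_id[i],
                          cds_position = cstart, ref = substr(codon, 1, 1),
                          alt = b,
                          in_phase_with = variants$variant_id[i],
                          stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# The mutated 9mer of the first n_planted missense MPS, paired with the
# first class I allele, so the planted score is the MPS best class I score
# by construction.
make_planted_binders <- function(transcripts, variants, kinds, n_planted,
                                 hla) {
  empty <- data.frame(peptide = character(0), allele = character(0),
                      variant_id = character(0), stringsAsFactors = FALSE)
  if (n_planted < 1L) return(empty)
  a1 <- hla[grepl("^[ABC]", hla)][1]
  idx <- which(kinds == "missense")[seq_len(min(
    n_planted, sum(kinds == "missense")))]
  rows <- lapply(idx, function(i) {
    mps <- build_patient_mps(transcripts[i, , drop = FALSE],
                             variants[i, , drop = FALSE])[[1]]
    m <- mps$mutation_positions[1]
    s <- max(1L, min(m - 4L, nchar(mps$sequence) - 8L))
    data.frame(peptide = substr(mps$sequence, s, s + 8L), allele = a1,
               variant_id = variants$variant_id[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Specification for a simulated ELISpot experiment
#'
#' Control wells and non-responder antigens share a negative-binomial
#' baseline; responder antigens receive a multiplicative post-vaccination
#' effect from `onset_day` onwards, and pre-existing responders start at
#' the effect level and are further amplified post-vaccination.
#'
#' @param n_antigens Antigens per patient.
#' @param n_responders,n_pre_existing Truth counts (pre-existing is a
#'   subset of immunogenic antigens, disjoint from de novo responders).
#' @param baseline_mean,dispersion Negative-binomial baseline (mean, size).
#' @param effect Multiplicative vaccine effect on the mean.
#' @param amplification Additional post/pre factor for pre-existing
#'   responses.
#' @param replicates Wells per condition (2 or 3).
#' @param cells_per_well Effector cells plated per well.
#' @param days Sampling days; `onset_day` is when the effect begins.
#' @return An `elispot_sim_spec` list.
#' @export
elispot_sim_spec <- function(n_antigens = 10L, n_responders = 4L,
                             n_pre_existing = 1L, baseline_mean = 2,
                             dispersion = 10, effect = 20,
                             amplification = 12, replicates = 3L,
                             cells_per_well = 1e5L,
                             days = c(0L, 71L), onset_day = 22L) {
  if (dispersion <= 0) stopf("dispersion must be positive")
  structure(as.list(environment()), class = "elispot_sim_spec")
}

#' Simulate replicate-level ELISpot well counts
#'
#' @param spec An [elispot_sim_spec()].
#' @param seed Seed for all draws.
#' @param patient_id Label on emitted rows.
#' @return List with `wells` (long data frame: patient_id, timepoint, day,
#'   assay_arm, antigen_id, well_index, count, tntc, cells_per_well; one
#'   `medium` control per day) and `truth` (antigen_id, label in
#'   responder/pre_existing/non_responder).
#' @export
simulate_elispot <- function(spec = elispot_sim_spec(), seed = 1L,
                             patient_id = "P1") {
  with_seed(seed, {
    antigens <- sprintf("AG%03d", seq_len(spec$n_antigens))
    label <- rep("non_responder", spec$n_antigens)
    if (spec$n_responders + spec$n_pre_existing > spec$n_antigens)
      stopf("more responders than antigens")
    label[seq_len(spec$n_responders)] <- "responder"
    if (spec$n_pre_existing > 0L)
      label[spec$n_responders + seq_len(spec$n_pre_existing)] <-
        "pre_existing"
    rows <- list()
    emit <- function(antigen_id, day, mu) {
      counts <- stats::rnbinom(spec$replicates, mu = mu,
                               size = spec$dispersion)
      rows[[length(rows) + 1L]] <<- data.frame(
        patient_id = patient_id,
        timepoint = sprintf("day%03d", day), day = day,
        assay_arm = "ex_vivo", antigen_id = antigen_id,
        well_index = seq_len(spec$replicates), count = counts,
        tntc = FALSE, cells_per_well = spec$cells_per_well,
        stringsAsFactors = FALSE)
    }
    for (day in spec$days) {
      post <- day >= spec$onset_day
      emit("medium", day, spec$baseline_mean)
      for (i in seq_len(spec$n_antigens)) {
        mu <- switch(label[i],
          non_responder = spec$baseline_mean,
          responder = if (post) spec$baseline_mean * spec$effect
                      else spec$baseline_mean,
          pre_existing = if (post)
            spec$baseline_mean * spec$effect * spec$amplification
          else spec$baseline_mean * spec$effect)
        emit(antigens[i], day, mu)
      }
    }
    list(wells = do.call(rbind, rows),
         truth = data.frame(antigen_id = antigens, label = label,
                            stringsAsFactors = FALSE))
  })
}

#' Specification for simulated TCR repertoires
#'
#' A power-law clone-size background (frequency of rank r proportional to
#' r^-alpha) sampled multinomially at the given depths, with a spike set
#' of clones expanded post-vaccination; de novo spikes have zero
#' pre-treatment weight by construction. Paired-chain annotations are
#' drawn per clone; the reporter truth maps specific TCRs to antigen/HLA
#' conditions.
#'
#' @param n_clones Background clone count.
#' @param alpha Power-law exponent of the clone-size law.
#' @param depth_pre,depth_post Sampled read depths.
#' @param n_spike Number of expanded clones.
#' @param spike_fold Expansion factor applied to spiked clone weights.
#' @param frac_de_novo Fraction of spikes with zero pre-treatment weight.
#' @param paired_prob Probability a clone has paired single-cell chains.
#' @param spike_rank_range Background ranks the spiked clones are drawn
#'   from (mid-repertoire, so pre-existing spikes are detectable pre).
#' @param antigens,hla_alleles Reporter-assay conditions.
#' @param specific_prob Probability a spiked TCR is truly specific for its
#'   assigned antigen.
#' @param control_rlu Effectors-only luminescence.
#' @return A `repertoire_sim_spec` list.
#' @export
repertoire_sim_spec <- function(n_clones = 2000L, alpha = 1.2,
                                depth_pre = 30000L, depth_post = 30000L,
                                n_spike = 20L, spike_fold = 50,
                                frac_de_novo = 0.5, paired_prob = 0.8,
                                spike_rank_range = c(100L, 500L),
                                antigens = sprintf("AG%03d", 1:4),
                                hla_alleles = c("A*02:01", "B*07:02"),
                                specific_prob = 0.8, control_rlu = 1000) {
  structure(as.list(environment()), class = "repertoire_sim_spec")
}

random_cdr3 <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mid <- vapply(seq_len(n), function(i)
    paste(sample(aa, 8, replace = TRUE), collapse = ""), character(1))
  paste0("CASS", mid, "EQYF")
}

#' Simulate pre/post (and tumour) TCR repertoires with spiked expansions
#'
#' @param spec A [repertoire_sim_spec()].
#' @param seed Seed for all draws.
#' @return List with `pre`, `post`, `tumour` (AIRR-style data frames:
#'   junction_aa, duplicate_count, v_call, j_call, locus), `sc`
#'   (single-cell chain table), `luminescence` (reporter matrix with
#'   control rows) and `truth` (per spiked clone: cdr3, de_novo, paired,
#'   antigen, specific).
#' @export
simulate_repertoires <- function(spec = repertoire_sim_spec(), seed = 1L) {
  with_seed(seed, {
    n <- spec$n_clones
    if (min(spec$depth_pre, spec$depth_post) < spec$n_spike)
      stopf("sampling depth below the number of spiked clones")
    cdr3 <- random_cdr3(n)
    stopifnot(!anyDuplicated(cdr3))
    w <- seq_len(n)^(-spec$alpha)
    spike_idx <- sample(seq(spec$spike_rank_range[1],
                            spec$spike_rank_range[2]), spec$n_spike)
    n_dn <- round(spec$frac_de_novo * spec$n_spike)
    de_novo_idx <- spike_idx[seq_len(n_dn)]
    w_pre <- w; w_pre[de_novo_idx] <- 0
    w_post <- w; w_post[spike_idx] <- w[spike_idx] * spec$spike_fold
    draw <- function(weights, depth) {
      counts <- as.vector(stats::rmultinom(1, depth, weights / sum(weights)))
      keep <- counts > 0
      data.frame(junction_aa = cdr3[keep], duplicate_count = counts[keep],
                 v_call = "TRBV19*01", j_call = "TRBJ2-7*01", locus = "TRB",
                 stringsAsFactors = FALSE)
    }
    pre <- draw(w_pre, spec$depth_pre)
    post <- draw(w_post, spec$depth_post)
    tumour <- draw(w_post, max(2000L, spec$depth_post %/% 10L))
    paired <- stats::runif(n) < spec$paired_prob
    sc <- simulate_sc_chains(cdr3, post, paired)
    spike_info <- data.frame(
      cdr3 = cdr3[spike_idx],
      de_novo = spike_idx %in% de_novo_idx,
      paired = paired[spike_idx],
      antigen = rep_len(spec$antigens, spec$n_spike),
      hla = rep_len(spec$hla_alleles, spec$n_spike),
      specific = stats::runif(spec$n_spike) < spec$specific_prob,
      stringsAsFactors = FALSE)
    lum <- simulate_luminescence(spike_info, spec)
    list(pre = pre, post = post, tumour = tumour, sc = sc,
         luminescence = lum, truth = spike_info)
  })
}

# Single-cell chain table: the capture follows post-treatment clone size
# (the largest clones are the ones seen in the single-cell experiment).
# Paired clones contribute a TRA and a TRB row; a sprinkle of TRB-only and
# two-TRB decoys exercises the gate.
simulate_sc_chains <- function(cdr3, post, paired) {
  post <- post[order(-post$duplicate_count, post$junction_aa,
                     method = "radix"), , drop = FALSE]
  seen <- post$junction_aa[seq_len(min(400L, nrow(post)))]
  idx <- match(seen, cdr3)
  rows <- list()
  for (k in seq_along(seen)) {
    cid <- sprintf("clonotype%04d", k)
    cells <- post$duplicate_count[k]
    if (paired[idx[k]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        clonotype_id = cid, chain = c("TRB", "TRA"),
        cdr3_aa = c(seen[k], paste0("CAV", substr(seen[k], 5, 12), "KLIF")),
        v_call = c("TRBV19*01", "TRAV12-1*01"),
        j_call = c("TRBJ2-7*01", "TRAJ33*01"),
        cell_count = cells, stringsAsFactors = FALSE)
    } else if (k %% 2L == 0L) {  # TRB-only clonotype
      rows[[length(rows) + 1L]] <- data.frame(
        clonotype_id = cid, chain = "TRB", cdr3_aa = seen[k],
        v_call = "TRBV19*01", j_call = "TRBJ2-7*01",
        cell_count = cells, stringsAsFactors = FALSE)
    } else {  # doublet-like two-TRB clonotype
      rows[[length(rows) + 1L]] <- data.frame(
        clonotype_id = cid, chain = c("TRB", "TRB", "TRA"),
        cdr3_aa = c(seen[k], paste0("CASS", substr(seen[k], 5, 12), "TQYF"),
                    paste0("CAV", substr(seen[k], 5, 12), "KLIF")),
        v_call = c("TRBV19*01", "TRBV6-5*01", "TRAV12-1*01"),
        j_call = c("TRBJ2-7*01", "TRBJ2-1*01", "TRAJ33*01"),
        cell_count = cells, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

simulate_luminescence <- function(spike_info, spec) {
  rows <- list()
  for (k in seq_len(nrow(spike_info))) {
    tcr <- spike_info$cdr3[k]
    rows[[length(rows) + 1L]] <- data.frame(
      tcr_id = tcr, condition_id = "effectors_only", antigen_id = NA,
      hla_allele = NA, rlu = spec$control_rlu, is_control = TRUE,
      stringsAsFactors = FALSE)
    for (ag in spec$antigens) for (hla in spec$hla_alleles) {
      hit <- spike_info$specific[k] && ag == spike_info$antigen[k] &&
        hla == spike_info$hla[k]
      fold <- if (hit) stats::runif(1, 3, 30) else stats::runif(1, 0.5, 1.5)
      rows[[length(rows) + 1L]] <- data.frame(
        tcr_id = tcr, condition_id = paste(ag, hla, sep = "|"),
        antigen_id = ag, hla_allele = hla,
        rlu = round(spec$control_rlu * fold, 1), is_control = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
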