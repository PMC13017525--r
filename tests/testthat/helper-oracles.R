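# Independent oracles used by the tests. These deliberately re-derive
# results by brute force or naive iteration, not by calling the package's
# own code paths.

# All substrings of lengths `lengths` that cover at least one mutated
# position, found by checking every window explicitly.
oracle_windows <- function(sequence, mutated, lengths) {
  out <- list()
  L <- nchar(sequence)
  for (k in lengths) {
    s <- 1L
    while (s + k - 1L <= L) {
      covered <- FALSE
      for (m in mutated) if (m >= s && m <= s + k - 1L) covered <- TRUE
      if (covered)
        out[[length(out) + 1L]] <- c(start = s, length = k)
      s <- s + 1L
    }
  }
  out
}

# Naive re-application of the staged prioritization: each step repeatedly
# scans its eligible pool and extracts the single best row by explicit
# tuple comparison (primary key, then RPKM descending, then variant_id).
oracle_prioritize <- function(cand, cap_total = 46L) {
  taken <- character(0)
  result <- list()
  better <- function(i, j, key, decreasing) {
    ki <- cand[[key]][i] * (if (decreasing) -1 else 1)
    kj <- cand[[key]][j] * (if (decreasing) -1 else 1)
    if (ki != kj) return(ki < kj)
    if (cand$rpkm[i] != cand$rpkm[j]) return(cand$rpkm[i] > cand$rpkm[j])
    cand$variant_id[i] < cand$variant_id[j]
  }
  grab <- function(rows, key, decreasing, cap, step) {
    n_taken <- 0L
    while (n_taken < cap && length(result) < cap_total) {
      pool <- setdiff(rows, match(taken, cand$mps_id))
      pool <- pool[!cand$mps_id[pool] %in% taken]
      if (!length(pool)) break
      best <- pool[1]
      for (i in pool[-1]) if (better(i, best, key, decreasing)) best <- i
      taken <<- c(taken, cand$mps_id[best])
      result[[length(result) + 1L]] <<-
        cbind(cand[best, ], selection_step = step,
              rank_within_step = n_taken + 1L)
      n_taken <- n_taken + 1L
    }
  }
  idx <- seq_len(nrow(cand))
  expressed <- cand$rna_vaf > 0
  is_indel <- cand$variant_kind %in% c("insertion", "deletion")
  grab(idx[expressed & is_indel], "best_class1", FALSE, 5L, "s1_indel_hla1")
  grab(idx[expressed & !is_indel & cand$rpkm >= 10], "best_class2", FALSE,
       20L, "s2_snv_hla2")
  grab(idx[expressed & !is_indel & cand$rpkm >= 1], "best_class1", FALSE,
       20L, "s3_snv_hla1")
  grab(idx[expressed & !is_indel], "rpkm", TRUE, cap_total,
       "s4_snv_expression")
  grab(idx[!expressed & cand$best_class1 < 999], "best_class1", FALSE,
       cap_total, "s5_fallback_hla1")
  grab(idx[!expressed], "rpkm", TRUE, cap_total, "s6_fallback_expression")
  if (!length(result)) return(NULL)
  out <- do.call(rbind, result)
  rownames(out) <- NULL
  out
}

# Random candidate tables for prioritization equivalence checks.
random_candidates <- function(n, seed) {
  set.seed(seed)
  kinds <- sample(c("snv", "insertion", "deletion"), n, replace = TRUE,
                  prob = c(0.7, 0.15, 0.15))
  data.frame(
    mps_id = sprintf("MPS_%02d", seq_len(n)),
    variant_id = sprintf("V%02d", seq_len(n)),
    variant_kind = kinds,
    best_class1 = round(stats::runif(n, 0, 100), 1),
    best_class2 = ifelse(stats::runif(n) < 0.2, 999,
                         round(stats::runif(n, 0, 100), 1)),
    rpkm = round(stats::rlnorm(n, 1.5, 1.5), 2),
    rna_vaf = ifelse(stats::runif(n) < 0.25, 0,
                     round(stats::runif(n, 0.01, 0.6), 3)),
    dna_vaf = round(stats::runif(n, 0.05, 0.6), 3),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 20,
                   replace = TRUE), collapse = ""), character(1)),
    stringsAsFactors = FALSE)
}

# Random mps-like objects for enumeration checks (plain lists satisfying
# the mps contract).
random_mps <- function(seed) {
  set.seed(seed)
  L <- sample(8:50, 1)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  nmut <- sample(1:min(4, L), 1)
  structure(list(
    mps_id = paste0("r", seed), variant_id = paste0("v", seed),
    sequence = paste(sample(aa, L, replace = TRUE), collapse = ""),
    mutation_positions = sort(sample.int(L, nmut)),
    kind = "snv", incorporated_germline = character(0)), class = "mps")
}

# One-line amino-acid alphabet for random proteins.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
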