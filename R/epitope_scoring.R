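# Variant-containing epitope enumeration and HLA-binding score tables.
#
# From each MPS, all 8-11mer windows (class I, HLA-A/B/C) and 15mer windows
# (class II, HLA-DRB) that overlap at least one mutated residue are scored
# against the patient's alleles by a pluggable predictor. Scores follow the
# IEDB consensus percentile-rank convention: lower = stronger binding; the
# per-MPS "best" score for a class is the minimum over its rows.

#' Sentinel score for an absent class
#'
#' An MPS too short to yield any 15mer has no class II rows; its best class
#' II score is this sentinel so it sorts after every real percentile score.
#' @export
SCORE_SENTINEL <- 999

CLASS1_LENGTHS <- 8:11
CLASS2_LENGTH <- 15L

enumerate_windows <- function(mps, lengths) {
  L <- nchar(mps$sequence)
  mut <- mps$mutation_positions
  out <- lapply(lengths, function(k) {
    if (k > L) return(NULL)
    nstart <- L - k + 1L
    # a window starting at s covers a mutation m iff m-k+1 <= s <= m
    ok <- logical(nstart)
    for (m in mut) ok[max(1L, m - k + 1L):min(nstart, m)] <- TRUE
    s <- which(ok)
    if (!length(s)) return(NULL)
    data.frame(start = s, length = k,
               peptide = substring(mps$sequence, s, s + k - 1L),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(start = integer(0), length = integer(0),
                      peptide = character(0)))
  unique(do.call(rbind, out))
}

#' Enumerate variant-containing class I peptides (8-11mers) of an MPS
#'
#' @param mps An `mps` object.
#' @return Data frame with columns `start`, `length`, `peptide`: exactly
#'   the windows of length 8-11 overlapping at least one mutated position.
#' @export
enumerate_class1 <- function(mps) enumerate_windows(mps, CLASS1_LENGTHS)

#' Enumerate variant-containing class II peptides (15mers) of an MPS
#'
#' An MPS shorter than 15 residues yields no class II peptides.
#' @inheritParams enumerate_class1
#' @export
enumerate_class2 <- function(mps) enumerate_windows(mps, CLASS2_LENGTH)

#' Normalize an HLA allele name
#'
#' Accepts common spellings ("HLA-A*02:01", "A*02:01", "HLA-A02:01",
#' "DRB104:01") and returns the normalized "A*02:01" / "DRB1*04:01" form.
#'
#' @param allele Character vector of allele names.
#' @return Normalized character vector.
#' @export
normalize_hla <- function(allele) {
  vapply(allele, function(a) {
    a <- gsub("^HLA-", "", toupper(trimws(a)))
    a <- gsub("\\*", "", a)
    m <- regmatches(a, regexec(
      "^(DRB[0-9]|DQB1|DPB1|DQA1|DPA1|[ABC])([0-9]{2,3}):?([0-9]{2,3})$", a))[[1]]
    if (length(m) != 4L) stopf("cannot parse HLA allele '%s'", a)
    sprintf("%s*%s:%s", m[2], m[3], m[4])
  }, character(1), USE.NAMES = FALSE)
}

hla_class_of <- function(allele) {
  ifelse(grepl("^[ABC]\\*", allele), "I",
         ifelse(grepl("^D", allele), "II", NA_character_))
}

#' Deterministic mock HLA-binding predictor
#'
#' Stands in for an external MHC-binding prediction service behind the
#' `predict(peptide, allele)` interface. The score is a deterministic hash
#' of (peptide, normalized allele, seed) mapped to a percentile-like value
#' in [0, 100); the same query always yields the same score within a run
#' configuration. Configured planted-binder pairs are forced to a strong
#' score so simulations can carry known ground truth.
#'
#' @param seed Integer; part of the hashed key, so different seeds give
#'   independent-looking score landscapes.
#' @param planted Optional data frame with columns `peptide`, `allele` (and
#'   optionally `score`, default 0.1) of forced strong binders.
#' @return A predictor object with elements `name` and
#'   `predict(peptide, allele)` (vectorised).
#' @export
mock_predictor <- function(seed = 1L, planted = NULL) {
  seed <- as.integer(seed)
  if (!is.null(planted)) {
    planted$allele <- normalize_hla(planted$allele)
    if (is.null(planted$score)) planted$score <- 0.1
  }
  predict_fun <- function(peptide, allele) {
    allele <- normalize_hla(allele)
    key <- paste(peptide, allele, seed, sep = "|")
    score <- round(string_hash01(key) * 100, 4)
    if (!is.null(planted)) {
      i <- match(paste(peptide, allele), paste(planted$peptide, planted$allele))
      hit <- !is.na(i)
      score[hit] <- planted$score[i[hit]]
    }
    score
  }
  structure(list(name = sprintf("mock(seed=%d)", seed),
                 planted = planted, predict = predict_fun),
            class = "binding_predictor")
}

#' Score all variant-containing peptides of one MPS
#'
#' @param mps An `mps` object.
#' @param patient_hla Character vector of the patient's HLA alleles
#'   (class I A/B/C and class II DRB, any accepted spelling).
#' @param predictor A predictor from [mock_predictor()] (or any object with
#'   a `predict(peptide, allele)` element).
#' @return List with `rows` (data frame: mps_id, peptide, allele,
#'   hla_class, score) and `best_class1` / `best_class2` (minimum score per
#'   class; `SCORE_SENTINEL` when the class has no rows).
#' @export
score_mps <- function(mps, patient_hla, predictor) {
  alleles <- normalize_hla(patient_hla)
  cls <- hla_class_of(alleles)
  a1 <- alleles[cls == "I"]
  a2 <- alleles[cls == "II" & grepl("^DRB", alleles)]
  rows <- list()
  add <- function(peps, als, hla_class) {
    if (!nrow(peps) || !length(als)) return()
    grid <- expand.grid(peptide = peps$peptide, allele = als,
                        stringsAsFactors = FALSE)
    grid <- unique(grid)
    score <- predictor$predict(grid$peptide, grid$allele)
    if (any(is.na(score) | score < 0))
      stopf("predictor failure on (%s, %s)",
            grid$peptide[which(is.na(score) | score < 0)[1]],
            grid$allele[which(is.na(score) | score < 0)[1]])
    rows[[length(rows) + 1L]] <<- data.frame(
      mps_id = mps$mps_id, peptide = grid$peptide, allele = grid$allele,
      hla_class = hla_class, score = score, stringsAsFactors = FALSE)
  }
  add(enumerate_class1(mps), a1, "I")
  add(enumerate_class2(mps), a2, "II")
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mps_id = character(0), peptide = character(0),
               allele = character(0), hla_class = character(0),
               score = numeric(0))
  best <- function(class) {
    s <- rows$score[rows$hla_class == class]
    if (length(s)) min(s) else SCORE_SENTINEL
  }
  list(rows = rows, best_class1 = best("I"), best_class2 = best("II"))
}

#' Score a set of MPS and summarise per-MPS best scores
#'
#' @param mps_list List of `mps` objects.
#' @inheritParams score_mps
#' @return List with `rows` (all per-peptide scores) and `summary` (one row
#'   per MPS: mps_id, best_class1, best_class2).
#' @export
score_mps_set <- function(mps_list, patient_hla, predictor) {
  scored <- lapply(mps_list, score_mps, patient_hla = patient_hla,
                   predictor = predictor)
  rows <- do.call(rbind, lapply(scored, `[[`, "rows"))
  summary <- data.frame(
    mps_id = vapply(mps_list, `[[`, character(1), "mps_id"),
    best_class1 = vapply(scored, `[[`, numeric(1), "best_class1"),
    best_class2 = vapply(scored, `[[`, numeric(1), "best_class2"),
    stringsAsFactors = FALSE)
  list(rows = rows, summary = summary)
}
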