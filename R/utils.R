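#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded helpers do not perturb an enclosing
#' simulation stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Deterministic string hash on [0, 1)
#'
#' Polynomial rolling hash (base 31, modulus 1000003) over the UTF-8 bytes
#' of `x`, mapped to the unit interval. All arithmetic stays below 2^31 so
#' the result is identical across platforms. Vectorised over `x`.
#'
#' @param x Character vector.
#' @return Numeric vector in [0, 1).
#' @keywords internal
string_hash01 <- function(x) {
  mod <- 1000003
  vapply(x, function(s) {
    codes <- utf8ToInt(s)
    h <- 7
    for (cc in codes) h <- (h * 31 + cc) %% mod
    h / mod
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
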