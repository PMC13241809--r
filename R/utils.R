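#' @keywords internal
"_PACKAGE"

#' Derive a child seed from a master seed and a stage label
#'
#' All randomness in the package flows from one explicit master seed. Each
#' stage (cohort design, LI draws, multi-start fitting, ...) derives its own
#' child seed from the master seed plus a stage label, so stages are
#' independently reproducible and inserting a new stage does not perturb the
#' draws of existing ones.
#'
#' @param seed master seed, a single integer.
#' @param label character stage label (e.g. `"li/AF/FA"`).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps the seed a valid R integer
  h <- as.double(seed %% m)
  for (b in utf8ToInt(as.character(label))) {
    # 31-bit multiplicative hash; doubles hold the intermediate exactly
    h <- (h * 131 + b) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

# run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# format numbers for CSV output: 9 significant digits so write/read
# round-trips are stable across platforms
fmt_num <- function(x) {
  out <- sprintf("%.9g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
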