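# Fractional-polynomial (FP) age smooths, Royston-Altman convention.
#
# An FP specification is a non-decreasing multiset of 1-3 powers from
# {-2, -1, -0.5, 0, 0.5, 1, 2, 3}. Power 0 maps to log(age); a power repeated
# k times contributes the base column multiplied by log(age)^(j-1) for its
# j-th occurrence. Ages are shifted by a positive offset before the
# transforms so that age 0 is admissible.

#' Canonical fractional-polynomial power set
#' @export
FP_POWER_SET <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Create a fractional-polynomial specification
#'
#' @param powers numeric vector of 1-3 powers, each from the canonical set
#'   `{-2, -1, -0.5, 0, 0.5, 1, 2, 3}` (repeats allowed); stored sorted.
#'   `numeric(0)` is permitted and denotes the constant (intercept-only)
#'   smooth, used as the degenerate baseline.
#' @param power_set permitted power values.
#' @return an object of class `fp_spec`.
#' @export
fp_spec <- function(powers, power_set = FP_POWER_SET) {
  powers <- as.numeric(powers)
  if (length(powers) > 3L) {
    stop("an FP specification has at most 3 powers")
  }
  if (!all(powers %in% power_set)) {
    stop("powers must come from {", paste(power_set, collapse = ", "), "}")
  }
  structure(list(powers = sort(powers)), class = "fp_spec")
}

#' @export
format.fp_spec <- function(x, ...) {
  paste0("FP(", paste(x$powers, collapse = ", "), ")")
}

#' @export
print.fp_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Evaluate the fractional-polynomial basis at given ages
#'
#' Builds one basis column per power of `spec` at the shifted ages
#' `a = age + age_offset`: `a^p` for `p != 0`, `log(a)` for `p == 0`, and for
#' the j-th occurrence of a repeated power, the base column times
#' `log(a)^(j-1)`.
#'
#' @param ages ages in years; `ages + age_offset` must be strictly positive.
#' @param spec an [fp_spec()].
#' @param age_offset years added to ages before the transforms (default 1).
#' @return numeric matrix, `length(ages)` rows, one column per power, with
#'   column names like `"age^0.5"` or `"age^1:log1"`.
#' @export
fp_basis <- function(ages, spec, age_offset = 1) {
  stopifnot(inherits(spec, "fp_spec"))
  a <- ages + age_offset
  if (any(!is.finite(a) | a <= 0)) {
    stop("ages + age_offset must be positive and finite")
  }
  p <- spec$powers
  la <- log(a)
  cols <- matrix(0, nrow = length(a), ncol = length(p))
  nm <- character(length(p))
  for (j in seq_along(p)) {
    rep_j <- if (j > 1L && p[j] == p[j - 1L]) {
      # count consecutive repeats of this power so far
      sum(p[seq_len(j - 1L)] == p[j])
    } else 0L
    base <- if (p[j] == 0) la else a^p[j]
    cols[, j] <- if (rep_j > 0L) base * la^rep_j else base
    nm[j] <- paste0(if (p[j] == 0) "log(age)" else paste0("age^", p[j]),
                    if (rep_j > 0L) paste0(":log", rep_j) else "")
  }
  colnames(cols) <- nm
  cols
}

#' Enumerate all fractional-polynomial specifications
#'
#' All multisets of sizes 1 to `max_order` drawn from `power_set`, in a
#' deterministic (size-major, lexicographic) order. For the canonical
#' 8-power set this yields 8, 44 and 164 specifications at orders 1-3.
#'
#' @param power_set permitted powers.
#' @param max_order largest multiset size, 1-3.
#' @return list of [fp_spec()] objects.
#' @export
enumerate_fp_specs <- function(power_set = FP_POWER_SET, max_order = 3) {
  stopifnot(max_order %in% 1:3)
  power_set <- sort(unique(as.numeric(power_set)))
  specs <- list()
  for (ord in seq_len(max_order)) {
    combs <- multisets(power_set, ord)
    specs <- c(specs, lapply(combs, fp_spec, power_set = power_set))
  }
  specs
}

# all non-decreasing tuples of length k over sorted vector v
multisets <- function(v, k) {
  if (k == 1L) return(as.list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in multisets(v[i:length(v)], k - 1L)) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}
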