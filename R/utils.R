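#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all printed percentages so that
#' e.g. a share of 56.45 prints as 56.5. Base R's `round()` rounds half to
#' even, which does not reproduce conventionally formatted claims tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Derive a child seed from a global seed and a stage tag
#'
#' A single global integer seed drives every generator; each stage derives
#' its own seed from the tag so modules can be regenerated independently
#' while remaining reproducible. Result is kept below 2^31.
#'
#' @param seed integer global seed.
#' @param tag character stage label.
#' @return integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 10007 + h * 97) %% 2147483629)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A probability vector: non-negative, sums to one within tolerance.
check_prob_vector <- function(p, what, tol = 1e-9) {
  if (!is.numeric(p) || length(p) < 1L || anyNA(p) || any(p < 0)) {
    stop("invalid probability vector for '", what,
         "': must be non-negative numeric", call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop("invalid probability vector for '", what, "': sums to ",
         format(sum(p), digits = 12), ", not 1", call. = FALSE)
  }
  invisible(p)
}

check_count <- function(n, what) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 ||
      n != trunc(n)) {
    stop("'", what, "' must be a single non-negative integer", call. = FALSE)
  }
  invisible(as.integer(n))
}
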