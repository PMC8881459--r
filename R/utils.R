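#' @keywords internal
"_PACKAGE"

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded draws inside the package
#' never disturb the caller's RNG stream ("no global state" contract).
#'
#' @param seed integer seed, or `NULL` to leave the RNG stream alone.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1000003 + 7919 * k) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Wrap angles to the interval (-pi, pi]
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi  # map -pi to +pi so the interval is (-pi, pi]
  y
}

#' Circular mean and resultant length
#'
#' @param theta angles in radians.
#' @return list with `mean` (radians in (-pi, pi]) and `r` (resultant length
#'   in \[0, 1\]; circular variance is `1 - r`).
#' @export
circ_stats <- function(theta) {
  theta <- theta[is.finite(theta)]
  if (!length(theta)) return(list(mean = NA_real_, r = NA_real_, n = 0L))
  z <- mean(exp(1i * theta))
  list(mean = Arg(z), r = Mod(z), n = length(theta))
}

# Maximum-likelihood von Mises concentration from a resultant length,
# solved on the exact Bessel ratio A1(kappa) = I1/I0.
vm_kappa_mle <- function(r) {
  if (!is.finite(r) || r <= 0) return(0)
  if (r >= 1 - 1e-12) return(Inf)
  a1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) a1(k) - r, c(1e-8, 1e4), tol = 1e-10)$root
}

# linear -> decibel power ratio
db10 <- function(p) 10 * log10(p)
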