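# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so that
#' seeded generators never perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-bit sub-seed from a base seed, a text label and an index.
# Polynomial rolling hash mod the prime 2147483629 (< 2^31), so derived seeds
# are valid R seeds and collisions across (label, index) are practically
# excluded for cohort-sized inputs.
derive_seed <- function(base_seed, label, index = 0L) {
  m <- 2147483629
  h <- as.numeric(base_seed) %% m
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% m
  h <- (h * 31 + as.numeric(index)) %% m
  as.integer(h) + 1L
}

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

# Symmetric Hann taper.
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Remove a least-squares linear trend.
detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

next_pow2 <- function(n) 2^ceiling(log2(n))

# Sample from a von Mises distribution (Best & Fisher 1979 rejection sampler).
# kappa = 0 degenerates to the uniform circular distribution; very large kappa
# approaches a point mass at `mu`.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      out[i] <- mu + sign(u3 - 0.5) * acos(pmin(1, pmax(-1, f)))
      i <- i + 1L
    }
  }
  ((out + pi) %% (2 * pi)) - pi
}

# Wrap angles into (-pi, pi].
wrap_phase <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
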