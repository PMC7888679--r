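#' First-passage-time distribution of the reversible two-step capture process
#'
#' A membrane protein that must capture a fluctuating DNA segment reaches its
#' bound state through a sequential scheme S1 <-> S2 -> S3: the DNA target
#' region first comes close to the membrane (rate `k1_plus`, reversed with
#' rate `k2_minus`), and the protein then binds it (rate `k2_plus`).  With all
#' probability initially in S1 the first-passage time to S3 is hypoexponential
#' with two timescales `alpha >= beta`,
#' \deqn{p(\tau) = \frac{e^{-\tau/\alpha} - e^{-\tau/\beta}}{\alpha - \beta}.}
#' A mixed initial condition, in which a fraction `x` of cells starts in the
#' intermediate state S2, adds the term
#' \eqn{c\,(\alpha e^{-\tau/\beta} - \beta e^{-\tau/\alpha})/(\alpha-\beta)}
#' with \eqn{c = x k_{2+}}.  `dfpt`, `pfpt`, `qfpt` and `rfpt` give the
#' density, distribution function, quantile function and random deviates.
#'
#' `alpha` is the long-time decay constant and `beta` the short-time delay;
#' the density is a valid probability density for `0 <= c <= 1/beta`.
#' The degenerate case `alpha == beta` is evaluated by the analytic limit
#' (for the pure case, \eqn{p(\tau) = \tau e^{-\tau/\alpha}/\alpha^2}).
#'
#' @param x,q vector of times (minutes), `>= 0`.
#' @param p vector of probabilities.
#' @param n number of deviates.
#' @param alpha,beta the two timescales (minutes), `alpha >= beta > 0`.
#'   Arguments are sorted internally, so the order does not matter.
#' @param c mixed-initial-condition parameter (1/min), `0 <= c <= 1/beta`;
#'   `c = 0` recovers the pure (all-in-S1) initial condition.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(T \le q)}.
#' @return `dfpt` a density (1/min), `pfpt` a probability, `qfpt` a time in
#'   minutes, `rfpt` a vector of random first-passage times in minutes.
#' @seealso [fpt_timescales()] to obtain `(alpha, beta)` from the microscopic
#'   rates, [fpt_moments()] for closed-form mean and variance,
#'   [fit_response()] to fit the CDF to response curves.
#' @examples
#' dfpt(1, alpha = 2, beta = 1)            # (e^-0.5 - e^-1) / 1
#' pfpt(2, alpha = 2, beta = 1)
#' qfpt(0.5, alpha = 4, beta = 0.5, c = 0.1)
#' @export
dfpt <- function(x, alpha, beta, c = 0) {
  check_timescales(alpha, beta, c)
  if (any(x < 0)) stop("times must be non-negative")
  ts <- sort_ab(alpha, beta)
  a <- ts[1L]; b <- ts[2L]
  if (degenerate_ab(a, b)) {
    # limit alpha -> beta of both the pure and the mixed density
    return(exp(-x / a) * (x / a^2 + c * (1 - x / a)))
  }
  (exp(-x / a) - exp(-x / b) + c * (a * exp(-x / b) - b * exp(-x / a))) /
    (a - b)
}

#' @rdname dfpt
#' @export
pfpt <- function(q, alpha, beta, c = 0, lower.tail = TRUE) {
  check_timescales(alpha, beta, c)
  if (any(q < 0)) stop("times must be non-negative")
  ts <- sort_ab(alpha, beta)
  a <- ts[1L]; b <- ts[2L]
  if (degenerate_ab(a, b)) {
    cdf <- 1 - exp(-q / a) * (1 + q / a - c * q)
  } else {
    cdf <- 1 - (a * exp(-q / a) - b * exp(-q / b) -
                  a * b * c * (exp(-q / a) - exp(-q / b))) / (a - b)
  }
  if (lower.tail) cdf else 1 - cdf
}

#' @rdname dfpt
#' @export
qfpt <- function(p, alpha, beta, c = 0) {
  check_timescales(alpha, beta, c)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  ts <- sort_ab(alpha, beta)
  a <- ts[1L]
  vapply(p, function(pi) {
    if (pi == 0) return(0)
    if (pi == 1) return(Inf)
    hi <- 2 * a
    while (pfpt(hi, alpha, beta, c) < pi) hi <- hi * 2
    stats::uniroot(function(t) pfpt(t, alpha, beta, c) - pi,
                   lower = 0, upper = hi, tol = 1e-10 * a)$root
  }, numeric(1))
}

#' @rdname dfpt
#' @export
rfpt <- function(n, alpha, beta, c = 0) {
  check_timescales(alpha, beta, c)
  # inverse-CDF sampling on a fine grid; interpolation error is far below
  # the sampling noise of any realistic cell count
  ts <- sort_ab(alpha, beta)
  a <- ts[1L]
  hi <- -log(1e-12) * a
  grid <- seq(0, hi, length.out = 10000L)
  cdf <- pfpt(grid, alpha, beta, c)
  u <- stats::runif(n)
  out <- stats::approx(cdf, grid, xout = u, ties = "ordered", rule = 2)$y
  out[u > max(cdf)] <- hi
  out
}

#' Timescales of the two-step process from its transition rates
#'
#' Converts the microscopic rates of the sequential reversible scheme
#' S1 <-> S2 -> S3 into the two timescales of the first-passage-time law,
#' \deqn{\alpha, \beta = 2\left(S \mp \sqrt{S^2 - 4 k_{1+} k_{2+}}\right)^{-1},}
#' with \eqn{S = k_{1+} + k_{2+} + k_{2-}}.  The pair satisfies the identities
#' \eqn{\alpha + \beta = S / (k_{1+} k_{2+})} and
#' \eqn{\alpha \beta = 1 / (k_{1+} k_{2+})}; the discriminant is non-negative
#' for any positive rates, and `alpha >= beta` always.
#'
#' @param k1_plus forward rate S1 -> S2 (1/min), `> 0`.
#' @param k2_plus binding rate S2 -> S3 (1/min), `> 0`.
#' @param k2_minus return rate S2 -> S1 (1/min), `>= 0`.
#' @return Named numeric vector `c(alpha = , beta = )` in minutes.
#' @examples
#' fpt_timescales(0.5, 0.2, 0.1)   # alpha ~ 6.449, beta ~ 1.551
#' @export
fpt_timescales <- function(k1_plus, k2_plus, k2_minus = 0) {
  if (k1_plus <= 0 || k2_plus <= 0) stop("k1_plus and k2_plus must be positive")
  if (k2_minus < 0) stop("k2_minus must be non-negative")
  s <- k1_plus + k2_plus + k2_minus
  disc <- s^2 - 4 * k1_plus * k2_plus
  disc <- max(disc, 0)  # provably >= 0; guard rounding
  r <- sqrt(disc)
  c(alpha = 2 / (s - r), beta = 2 / (s + r))
}

#' Transition rates compatible with a pair of timescales
#'
#' Inverts [fpt_timescales()]: given `(alpha, beta)` and a value for the
#' return rate `k2_minus`, solves for `(k1_plus, k2_plus)`.  The inversion is
#' a quadratic and is symmetric under exchanging the two forward rates, so
#' both roots are returned; the caller must disambiguate on external grounds.
#'
#' @param alpha,beta timescales (minutes), `alpha >= beta > 0`.
#' @param k2_minus assumed return rate (1/min), `>= 0`.
#' @return A 2 x 2 matrix with columns `k1_plus`, `k2_plus`; the two rows are
#'   the two roots (swapped assignments of the forward rates).
#' @examples
#' ts <- fpt_timescales(0.5, 0.2, 0.1)
#' fpt_rates(ts["alpha"], ts["beta"], k2_minus = 0.1)
#' @export
fpt_rates <- function(alpha, beta, k2_minus = 0) {
  if (beta <= 0 || alpha < beta) stop("need alpha >= beta > 0")
  if (k2_minus < 0) stop("k2_minus must be non-negative")
  s <- (alpha + beta) / (alpha * beta) - k2_minus  # k1+ + k2+
  p <- 1 / (alpha * beta)                          # k1+ * k2+
  disc <- s^2 - 4 * p
  if (s <= 0 || disc < -1e-12 * s^2)
    stop("no positive rates exist for this k2_minus")
  disc <- max(disc, 0)
  r <- sqrt(disc)
  k1 <- c((s + r) / 2, (s - r) / 2)
  out <- cbind(k1_plus = k1, k2_plus = p / k1)
  rownames(out) <- c("root1", "root2")
  out
}

#' Mean and variance of the first-passage-time distribution
#'
#' Closed-form moments of the two-step first-passage law.  For the pure
#' initial condition the mean is \eqn{\alpha + \beta} and the variance
#' \eqn{\alpha^2 + \beta^2}; with the mixed initial condition the mean is
#' \eqn{\alpha + \beta - \alpha\beta c} and the variance follows from the
#' second moment
#' \eqn{E[\tau^2] = 2(\alpha^2 + \alpha\beta + \beta^2)
#'      - 2 c \alpha\beta(\alpha + \beta)}.
#'
#' @inheritParams dfpt
#' @return Named numeric vector `c(mean = , var = )` (minutes, minutes^2).
#' @examples
#' fpt_moments(6.449, 1.551)            # mean = 8.0
#' fpt_moments(6.449, 1.551, c = 0.05)  # mean = 8 - 10 * 0.05
#' @export
fpt_moments <- function(alpha, beta, c = 0) {
  check_timescales(alpha, beta, c)
  ts <- sort_ab(alpha, beta)
  a <- ts[1L]; b <- ts[2L]
  m <- a + b - a * b * c
  m2 <- 2 * (a^2 + a * b + b^2) - 2 * c * a * b * (a + b)
  c(mean = m, var = m2 - m^2)
}

# ---- internal helpers ------------------------------------------------------

sort_ab <- function(alpha, beta) {
  if (length(alpha) != 1L || length(beta) != 1L)
    stop("alpha and beta must be scalars")
  c(max(alpha, beta), min(alpha, beta))
}

degenerate_ab <- function(a, b) (a - b) < 1e-9 * a

check_timescales <- function(alpha, beta, c) {
  if (!is.numeric(alpha) || !is.numeric(beta) || !is.numeric(c))
    stop("alpha, beta, c must be numeric")
  if (min(alpha, beta) <= 0) stop("timescales must be positive")
  if (c < 0) stop("c must be non-negative")
  if (c > 1 / min(alpha, beta) + 1e-12)
    stop("c exceeds 1/beta: the density would be negative (x > 1)")
  invisible(TRUE)
}
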