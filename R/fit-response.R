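#' Build a spot-response time series
#'
#' A response series records, for each imaging time point, the fraction
#' `nu` of cells showing at least one fluorescent protein-DNA spot, its
#' uncertainty, and the number of cells evaluated.  It is the common currency
#' between spot detection ([response_fraction()]), the synthetic generator
#' ([sim_response_counts()]) and model fitting ([fit_response()]).
#'
#' @param time_min time after receptor activation (minutes), strictly
#'   increasing.
#' @param nu fraction of spot-positive cells in `[0, 1]`.
#' @param nu_err standard deviation of `nu` (binomial error if counts are
#'   given and `nu_err` is missing).
#' @param n_cells number of cells evaluated per time point (optional).
#' @return A `data.frame` of class `"response_series"` with columns
#'   `time_min`, `nu`, `nu_err` and (if known) `n_cells`.
#' @export
response_series <- function(time_min, nu, nu_err = NULL, n_cells = NULL) {
  if (any(diff(time_min) <= 0)) stop("time_min must be strictly increasing")
  if (any(nu < 0 | nu > 1)) stop("nu must be in [0, 1]")
  if (is.null(nu_err)) {
    if (is.null(n_cells)) stop("supply nu_err or n_cells")
    nu_err <- sqrt(pmax(nu * (1 - nu), 0) / n_cells)
  }
  if (any(nu_err < 0)) stop("nu_err must be non-negative")
  out <- data.frame(time_min = time_min, nu = nu, nu_err = nu_err)
  if (!is.null(n_cells)) out$n_cells <- n_cells
  class(out) <- c("response_series", "data.frame")
  out
}

#' Read a response series from CSV
#'
#' Accepts either raw counts (`time_min`, `n_cells`, `n_cells_with_spot`),
#' from which `nu` and its binomial error are computed, or precomputed
#' columns (`time_min`, `nu`, `nu_err`).
#'
#' @param file path to a CSV file.
#' @return A [response_series()].
#' @export
read_response <- function(file) {
  d <- utils::read.csv(file)
  if (all(c("n_cells", "n_cells_with_spot") %in% names(d))) {
    nu <- d$n_cells_with_spot / d$n_cells
    response_series(d$time_min, nu, n_cells = d$n_cells)
  } else if (all(c("nu", "nu_err") %in% names(d))) {
    response_series(d$time_min, d$nu, d$nu_err,
                    n_cells = if ("n_cells" %in% names(d)) d$n_cells)
  } else {
    stop("need columns time_min + (n_cells, n_cells_with_spot) or (nu, nu_err)")
  }
}

#' Normalize a response series to the interval [0, 1]
#'
#' Spots are present in a baseline fraction `nu(0)` of cells before the
#' search starts (non-specific binding) and never appear in all cells
#' (`nu(Inf) < 1`, low copy number and detection misses), so the observable
#' identified with the first-passage CDF is the rescaled response
#' \deqn{R(t) = \frac{\nu(t) - \nu(0)}{\nu(\infty) - \nu(0)}.}
#' Errors are propagated to first order treating the normalization constants
#' as fixed.
#'
#' @param series a [response_series()].
#' @param nu_inf the plateau `nu(Inf)`: a number, or `"auto"` (default) for
#'   the mean of the last three time points.
#' @return A `data.frame` with columns `time_min`, `R`, `R_err` plus the
#'   attributes `nu0` and `nu_inf`.
#' @export
normalize_response <- function(series, nu_inf = "auto") {
  nu0 <- series$nu[1L]
  if (identical(nu_inf, "auto"))
    nu_inf <- mean(utils::tail(series$nu, 3L))
  if (!is.numeric(nu_inf) || nu_inf <= nu0)
    stop("degenerate normalization: nu_inf must exceed nu(0)")
  span <- nu_inf - nu0
  out <- data.frame(time_min = series$time_min,
                    R = (series$nu - nu0) / span,
                    R_err = series$nu_err / span)
  attr(out, "nu0") <- nu0
  attr(out, "nu_inf") <- nu_inf
  out
}

#' Fit the two-step first-passage model to a response curve
#'
#' Fits the cumulative first-passage-time distribution of the reversible
#' two-step capture process (see [pfpt()]) to a normalized response curve by
#' weighted least squares,
#' \deqn{\chi^2 = \sum_i \left(\frac{R_i - \mathrm{CDF}(t_i)}{\sigma_i}\right)^2,}
#' using bounded Levenberg-Marquardt minimization.  The `"fixed"` model has
#' parameters `(alpha, beta)` (all cells start with the DNA target away from
#' the membrane); the `"mixed"` model adds `c >= 0` for the fraction of cells
#' whose target region is already near the membrane at activation.  Mean and
#' variance of the search time are derived from the fitted parameters with
#' standard errors from the delta method using the full parameter covariance.
#'
#' Time points with zero (or missing) quoted error are given the fallback
#' weight `max(sigma)/2` so that the chi-square objective stays finite.
#'
#' @param data a [response_series()] (normalized internally), or a data frame
#'   with columns `time_min`, `R`, `R_err` as returned by
#'   [normalize_response()].
#' @param model `"mixed"` or `"fixed"`.
#' @param nu_inf plateau handling when `data` is an unnormalized response
#'   series: a number, `"auto"` (mean of the last three time points;
#'   adequate when the curve has saturated), or `"fit"` (the plateau is an
#'   additional free parameter, fitted on the raw `nu` scale with the
#'   baseline fixed at the first observation — use this when the last time
#'   points are still rising, where a plug-in plateau estimate biases the
#'   timescales low).
#' @param start optional named list of starting values (`alpha`, `beta`, `c`).
#' @return An object of class `"fpt_fit"`: a list with elements
#'   `coefficients`, `vcov`, `mean_tau`, `var_tau` (each value with standard
#'   error), `chisq`, `df`, `model`, `data`, `at_bound`, `converged`.
#'   Supported methods: `print`, `summary`, `coef`, `vcov`, `predict`,
#'   `fitted`, `residuals`, `simulate`, `plot`.
#' @examples
#' set.seed(1)
#' truth <- sim_response_counts(alpha = 4, beta = 0.5, c = 0.1,
#'                              nu0 = 0.2, nu_inf = 0.75,
#'                              times = 0:14, n_cells = 1500, seed = 7)
#' fit <- fit_response(truth$series, model = "mixed")
#' coef(fit)
#' @export
fit_response <- function(data, model = c("mixed", "fixed"), nu_inf = "auto",
                         start = NULL) {
  model <- match.arg(model)
  fit_plateau <- identical(nu_inf, "fit")
  nu0 <- NULL; nu_obs <- NULL
  if (inherits(data, "response_series")) {
    if (fit_plateau) {
      nu0 <- data$nu[1L]
      nu_obs <- data
    } else {
      data <- normalize_response(data, nu_inf)
    }
  } else if (fit_plateau) {
    stop("nu_inf = \"fit\" needs an unnormalized response_series")
  }
  if (!fit_plateau && !all(c("time_min", "R", "R_err") %in% names(data)))
    stop("data must have columns time_min, R, R_err")
  npar <- (if (model == "mixed") 3L else 2L) + fit_plateau
  n_time <- if (fit_plateau) nrow(nu_obs) else nrow(data)
  if (n_time < npar + 2L)
    stop("need at least ", npar + 2L, " time points for the ", model, " model")

  if (fit_plateau) {
    t <- nu_obs$time_min
    y <- nu_obs$nu
    sig <- nu_obs$nu_err
  } else {
    t <- data$time_min
    y <- data$R
    sig <- data$R_err
  }
  bad <- !is.finite(sig) | sig <= 0
  if (all(bad)) sig[] <- 1 else sig[bad] <- max(sig[!bad]) / 2

  cdf_fun <- function(p) {
    cc <- if (model == "mixed") p[3L] else 0
    a <- max(p[1L], p[2L]); b <- min(p[1L], p[2L])
    cc <- min(cc, 1 / b)  # stay inside the valid density region
    pfpt(t, a, b, cc)
  }
  model_fun <- function(p) {
    if (fit_plateau) {
      ninf <- p[npar]
      nu0 + (ninf - nu0) * cdf_fun(p)
    } else {
      cdf_fun(p)
    }
  }
  resid_fun <- function(p) (y - model_fun(p)) / sig

  if (is.null(start)) {
    # crude moment-style starts: alpha near the time to reach R ~ 0.63
    if (fit_plateau) {
      ninf0 <- max(mean(utils::tail(y, 3L)), nu0 + 0.05)
      Rs <- (y - nu0) / (ninf0 - nu0)
    } else {
      Rs <- y
    }
    a0 <- stats::approx(c(0, Rs, 1), c(0, t, max(t) * 2), xout = 0.632,
                        ties = "ordered")$y
    if (!is.finite(a0) || a0 <= 0) a0 <- mean(range(t[t > 0]))
    start <- list(alpha = a0, beta = a0 / 8, c = 0.25 / a0)
    if (fit_plateau) start$nu_inf <- min(ninf0 * 1.05, 1)
  } else if (fit_plateau && is.null(start$nu_inf)) {
    start$nu_inf <- min(max(mean(utils::tail(y, 3L)), nu0 + 0.05) * 1.05, 1)
  }
  p0 <- c(start$alpha, start$beta, if (model == "mixed") start$c,
          if (fit_plateau) start$nu_inf)
  lower <- c(1e-6, 1e-6, if (model == "mixed") 0,
             if (fit_plateau) nu0 + 1e-4)
  upper <- c(Inf, Inf, if (model == "mixed") Inf, if (fit_plateau) 1)

  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fun, lower = lower,
                            upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 9))
    stop("response fit failed to converge (final chi2 = ",
         signif(fit$deviance, 4), ")")
  p <- fit$par
  # enforce the alpha >= beta labelling (the CDF is symmetric in the pair)
  if (p[1L] < p[2L]) p[1L:2L] <- p[2L:1L]
  names(p) <- c("alpha", "beta", if (model == "mixed") "c",
                if (fit_plateau) "nu_inf")

  # covariance from the weighted Jacobian at the optimum (absolute errors)
  J <- num_jacobian(resid_fun, p)
  JtJ <- crossprod(J)
  vc <- tryCatch(solve(JtJ), error = function(e) {
    warning("singular Jacobian: covariance from pseudo-inverse")
    ev <- eigen(JtJ, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
  })
  dimnames(vc) <- list(names(p), names(p))

  cc <- if (model == "mixed") p[["c"]] else 0
  mom <- fpt_moments(p[["alpha"]], p[["beta"]], cc)
  gm <- moment_gradients(p[["alpha"]], p[["beta"]], cc)
  n_kin <- npar - fit_plateau          # kinetic parameters (plateau excluded)
  use <- seq_len(n_kin)
  se_mean <- sqrt(drop(gm$mean[use] %*% vc[use, use] %*% gm$mean[use]))
  se_var <- sqrt(drop(gm$var[use] %*% vc[use, use] %*% gm$var[use]))

  at_bound <- (model == "mixed" && p[["c"]] < 1e-10) ||
    any(p[1:2] <= 1.01e-6) ||
    (fit_plateau && p[["nu_inf"]] > 1 - 1e-8)

  if (fit_plateau) {
    span <- p[["nu_inf"]] - nu0
    rdata <- data.frame(time_min = t, R = (y - nu0) / span,
                        R_err = sig / span)
  } else {
    rdata <- data.frame(time_min = t, R = y, R_err = sig)
  }

  structure(list(
    coefficients = p,
    vcov = vc,
    mean_tau = c(estimate = unname(mom["mean"]), se = se_mean),
    var_tau = c(estimate = unname(mom["var"]), se = se_var),
    chisq = fit$deviance,
    df = length(t) - npar,
    model = model,
    data = rdata,
    nu0 = if (fit_plateau) nu0,
    at_bound = at_bound,
    converged = TRUE,
    niter = fit$niter
  ), class = "fpt_fit")
}

# Analytic gradients of the closed-form moments w.r.t. (alpha, beta, c);
# checked against finite differences in the test suite.
moment_gradients <- function(a, b, cc) {
  dmean <- c(alpha = 1 - b * cc, beta = 1 - a * cc, c = -a * b)
  dm2 <- c(alpha = 4 * a + 2 * b - 4 * cc * a * b - 2 * cc * b^2,
           beta = 2 * a + 4 * b - 2 * cc * a^2 - 4 * cc * a * b,
           c = -2 * a * b * (a + b))
  m <- a + b - a * b * cc
  list(mean = dmean, var = dm2 - 2 * m * dmean)
}

num_jacobian <- function(f, p, eps = 1e-6) {
  f0 <- f(p)
  J <- matrix(0, length(f0), length(p))
  for (k in seq_along(p)) {
    h <- eps * max(abs(p[k]), 1e-3)
    pp <- p; pp[k] <- p[k] + h
    pm <- p; pm[k] <- max(p[k] - h, 0)
    J[, k] <- (f(pp) - f(pm)) / (pp[k] - pm[k])
  }
  J
}

# ---- methods ---------------------------------------------------------------

#' @export
print.fpt_fit <- function(x, ...) {
  cat("Two-step first-passage fit (", x$model, " initial condition)\n", sep = "")
  cat("  parameters:\n")
  se <- sqrt(diag(x$vcov))
  for (nm in names(x$coefficients))
    cat(sprintf("    %-5s %8.4f +/- %.4f\n", nm, x$coefficients[[nm]], se[[nm]]))
  cat(sprintf("  mean search time: %.3f +/- %.3f min\n",
              x$mean_tau[["estimate"]], x$mean_tau[["se"]]))
  cat(sprintf("  variance:         %.3f +/- %.3f min^2\n",
              x$var_tau[["estimate"]], x$var_tau[["se"]]))
  cat(sprintf("  chi-square: %.3f on %d df\n", x$chisq, x$df))
  if (x$at_bound) cat("  note: a parameter sits at its bound\n")
  invisible(x)
}

#' @export
summary.fpt_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se)
  out <- list(model = object$model, coefficients = tab,
              mean_tau = object$mean_tau, var_tau = object$var_tau,
              chisq = object$chisq, df = object$df,
              at_bound = object$at_bound)
  class(out) <- "summary.fpt_fit"
  out
}

#' @export
print.summary.fpt_fit <- function(x, ...) {
  cat("Two-step first-passage fit (", x$model, " initial condition)\n\n", sep = "")
  print(x$coefficients)
  cat(sprintf("\nmean search time: %.3f +/- %.3f min\n",
              x$mean_tau[["estimate"]], x$mean_tau[["se"]]))
  cat(sprintf("variance:         %.3f +/- %.3f min^2\n",
              x$var_tau[["estimate"]], x$var_tau[["se"]]))
  cat(sprintf("chi-square: %.4f on %d degrees of freedom\n", x$chisq, x$df))
  invisible(x)
}

#' @export
coef.fpt_fit <- function(object, ...) object$coefficients

#' @export
vcov.fpt_fit <- function(object, ...) object$vcov

#' @export
fitted.fpt_fit <- function(object, ...) {
  predict(object, object$data$time_min)
}

#' Predicted response curve of a fitted first-passage model
#'
#' @param object an `fpt_fit`.
#' @param newdata times (minutes) at which to evaluate the fitted CDF;
#'   defaults to the fitted time points.
#' @param ... unused.
#' @return Numeric vector of model response values `R(t)` in `[0, 1]`.
#' @export
predict.fpt_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$time_min
  if (is.data.frame(newdata)) newdata <- newdata$time_min
  p <- object$coefficients
  cc <- if (object$model == "mixed") p[["c"]] else 0
  cc <- min(cc, 1 / min(p[["alpha"]], p[["beta"]]))
  pfpt(newdata, p[["alpha"]], p[["beta"]], cc)
}

#' @export
residuals.fpt_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  r <- object$data$R - fitted(object)
  if (type == "weighted") r / object$data$R_err else r
}

#' Simulate response counts from a fitted first-passage model
#'
#' Draws new per-cell spot-appearance data at the fitted parameters using the
#' same observation scheme as the original series (baseline fraction 0.2 and
#' plateau 0.95 unless overridden), via [sim_response_counts()].
#'
#' @param object an `fpt_fit`.
#' @param nsim number of replicate series.
#' @param seed integer seed.
#' @param n_cells cells per time point.
#' @param nu0,nu_inf baseline and plateau fractions of the observation model.
#' @param ... unused.
#' @return A list of `nsim` [response_series()] objects.
#' @export
simulate.fpt_fit <- function(object, nsim = 1, seed = NULL, n_cells = 1000,
                             nu0 = 0.2, nu_inf = 0.95, ...) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  p <- object$coefficients
  cc <- if (object$model == "mixed") p[["c"]] else 0
  lapply(seq_len(nsim), function(i) {
    sim_response_counts(alpha = p[["alpha"]], beta = p[["beta"]], c = cc,
                        nu0 = nu0, nu_inf = nu_inf,
                        times = object$data$time_min, n_cells = n_cells,
                        seed = seed + i - 1L)$series
  })
}

#' @export
plot.fpt_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$time_min, d$R, ylim = range(0, 1, d$R),
                 xlab = "time after activation (min)", ylab = "response R(t)",
                 pch = 16, ...)
  graphics::arrows(d$time_min, d$R - d$R_err, d$time_min, d$R + d$R_err,
                   angle = 90, code = 3, length = 0.03)
  tt <- seq(0, max(d$time_min), length.out = 200)
  graphics::lines(tt, predict(x, tt), col = "steelblue", lwd = 2)
  invisible(x)
}

#' Write a fitted response model to JSON
#'
#' Serializes parameters, covariance, derived moments and fit diagnostics.
#'
#' @param fit an `fpt_fit`.
#' @param file output path.
#' @export
write_fpt_fit <- function(fit, file) {
  obj <- list(model = fit$model,
              params = as.list(fit$coefficients),
              covariance = unname(apply(fit$vcov, 1, as.list)),
              mean_tau = as.list(fit$mean_tau),
              var_tau = as.list(fit$var_tau),
              chisq = fit$chisq, df = fit$df)
  writeLines(to_json(obj), file)
}

# Minimal JSON serializer for flat lists/vectors (avoids a hard dependency
# in the package itself; scripts may use jsonlite directly).
to_json <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      paste0("{", paste0('"', names(x), '":', vapply(x, to_json, ""),
                         collapse = ","), "}")
    } else {
      paste0("[", paste0(vapply(x, to_json, ""), collapse = ","), "]")
    }
  } else if (is.character(x)) {
    paste0('"', x, '"')
  } else if (length(x) == 1L) {
    format(x, digits = 15)
  } else {
    paste0("[", paste0(format(x, digits = 15), collapse = ","), "]")
  }
}
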