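#' Link per-frame spot detections into trajectories
#'
#' Within each cell, spots in consecutive frames are connected by greedy
#' nearest-neighbour assignment: each spot in frame `f + 1` is linked to the
#' closest unclaimed trajectory end in frame `f`, provided the displacement
#' does not exceed `max_disp`.  Unlinked spots start new trajectories; a spot
#' that finds no successor terminates its trajectory (a reappearing spot
#' starts a fresh one).
#'
#' @param spots data frame with columns `frame`, `cell_id`, `x_um`, `y_um`.
#' @param max_disp maximum frame-to-frame displacement (micrometres).  The
#'   default 0.5 is far above a chromosomal locus displacement per 30 s
#'   (~0.08 um) yet below typical inter-spot distances.
#' @return The input data frame with an added `track_id` column.
#' @export
link_spots <- function(spots, max_disp = 0.5) {
  need <- c("frame", "cell_id", "x_um", "y_um")
  if (!all(need %in% names(spots)))
    stop("spots needs columns ", paste(need, collapse = ", "))
  spots <- spots[order(spots$cell_id, spots$frame), , drop = FALSE]
  spots$track_id <- NA_integer_
  next_id <- 1L
  for (cell in unique(spots$cell_id)) {
    rows <- which(spots$cell_id == cell)
    frames <- sort(unique(spots$frame[rows]))
    active <- data.frame(track = integer(), x = numeric(), y = numeric(),
                         frame = integer())
    for (f in frames) {
      idx <- rows[spots$frame[rows] == f]
      cur <- active[active$frame == f - 1L, , drop = FALSE]
      claimed <- rep(FALSE, nrow(cur))
      for (i in idx) {
        tid <- NA_integer_
        if (nrow(cur) > 0) {
          d <- sqrt((cur$x - spots$x_um[i])^2 + (cur$y - spots$y_um[i])^2)
          d[claimed] <- Inf
          j <- which.min(d)
          if (length(j) && is.finite(d[j]) && d[j] <= max_disp) {
            tid <- cur$track[j]
            claimed[j] <- TRUE
          }
        }
        if (is.na(tid)) {
          tid <- next_id
          next_id <- next_id + 1L
        }
        spots$track_id[i] <- tid
        active <- active[active$track != tid, , drop = FALSE]
        active <- rbind(active, data.frame(track = tid, x = spots$x_um[i],
                                           y = spots$y_um[i], frame = f))
      }
      # drop stale ends: only frame f survivors may be extended at f + 1
      active <- active[active$frame >= f, , drop = FALSE]
    }
  }
  spots
}

#' Ensemble-averaged mean square displacement
#'
#' For each lag `tau = n * dt` the squared displacements over all
#' trajectories and all overlapping time origins are averaged:
#' \deqn{\mathrm{MSD}(\tau) = \langle (r(t) - r(t+\tau))^2 \rangle.}
#' The number of displacement pairs entering each lag is recorded so that
#' fits can down-weight the long, correlated lags.
#'
#' @param tracks data frame with `track_id`, `frame`, `x_um`, `y_um`
#'   (e.g. from [link_spots()] or [sim_locus_tracks()]).
#' @param max_lag largest lag in frames (default: longest track minus one).
#' @param dt frame interval in seconds (default 30).
#' @return A `data.frame` of class `"msd_curve"` with columns `lag_s`,
#'   `msd`, `n_pairs`; lags with no pairs are omitted.
#' @export
ensemble_msd <- function(tracks, max_lag = NULL, dt = 30) {
  if (!all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)))
    stop("tracks needs columns track_id, frame, x_um, y_um")
  split_tr <- split(tracks[c("frame", "x_um", "y_um")], tracks$track_id)
  if (is.null(max_lag))
    max_lag <- max(vapply(split_tr, nrow, 0L)) - 1L
  if (max_lag < 1L) stop("need at least one trajectory of length >= 2")
  sums <- numeric(max_lag)
  counts <- integer(max_lag)
  for (tr in split_tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    n <- nrow(tr)
    if (n < 2L) next
    for (lag in seq_len(min(max_lag, n - 1L))) {
      i <- seq_len(n - lag)
      ok <- (tr$frame[i + lag] - tr$frame[i]) == lag  # only contiguous pairs
      if (!any(ok)) next
      d2 <- (tr$x_um[i + lag] - tr$x_um[i])^2 +
        (tr$y_um[i + lag] - tr$y_um[i])^2
      sums[lag] <- sums[lag] + sum(d2[ok])
      counts[lag] <- counts[lag] + sum(ok)
    }
  }
  keep <- counts > 0L
  out <- data.frame(lag_s = (seq_len(max_lag) * dt)[keep],
                    msd = (sums / pmax(counts, 1L))[keep],
                    n_pairs = counts[keep])
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the subdiffusive scaling of an MSD curve
#'
#' Fits \eqn{\mathrm{MSD}(\tau) = \Gamma \tau^{1/2}} by weighted least
#' squares (weights proportional to the pair counts), as predicted by the
#' Rouse model for an internal chain segment at intermediate times.  With
#' `exponent = "free"` the scaling exponent is fitted as well, via log-log
#' regression, to check that the locus is in the Rouse regime.
#'
#' @param curve an [ensemble_msd()] result (or any data frame with `lag_s`,
#'   `msd` and optionally `n_pairs`).
#' @param exponent `"fixed"` (0.5) or `"free"`.
#' @param n_lags number of initial lags used (default 10); confinement bends
#'   the curve down at long lags.
#' @param weighted use `n_pairs` weights (default `TRUE`).
#' @return An object of class `"msd_fit"`: list with `Gamma`, `Gamma_se`,
#'   `exponent`, `exponent_se` (NA when fixed), `n_lags`, `curve`.
#' @export
fit_msd <- function(curve, exponent = c("fixed", "free"), n_lags = 10,
                    weighted = TRUE) {
  exponent <- match.arg(exponent)
  if (nrow(curve) < 3L) stop("need at least 3 lags to fit an MSD curve")
  d <- utils::head(curve[order(curve$lag_s), , drop = FALSE], n_lags)
  w <- if (weighted && "n_pairs" %in% names(d)) d$n_pairs else rep(1, nrow(d))
  if (exponent == "fixed") {
    X <- sqrt(d$lag_s)
    fit <- stats::lm(msd ~ 0 + X, data = d, weights = w)
    gamma <- unname(stats::coef(fit)[1L])
    gse <- unname(sqrt(diag(stats::vcov(fit)))[1L])
    ex <- 0.5; exse <- NA_real_
  } else {
    fit <- stats::lm(log(msd) ~ log(lag_s), data = d, weights = w)
    cf <- stats::coef(fit)
    gamma <- unname(exp(cf[1L]))
    ex <- unname(cf[2L])
    se <- sqrt(diag(stats::vcov(fit)))
    gse <- gamma * unname(se[1L])
    exse <- unname(se[2L])
  }
  structure(list(Gamma = gamma, Gamma_se = gse, exponent = ex,
                 exponent_se = exse, n_lags = nrow(d), curve = curve),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat("MSD scaling fit over", x$n_lags, "lags\n")
  cat(sprintf("  Gamma    = %.5f +/- %.5f um^2 s^-%0.2g\n",
              x$Gamma, x$Gamma_se, x$exponent))
  if (is.na(x$exponent_se)) {
    cat("  exponent = 0.5 (fixed)\n")
  } else {
    cat(sprintf("  exponent = %.3f +/- %.3f\n", x$exponent, x$exponent_se))
  }
  invisible(x)
}

#' @export
coef.msd_fit <- function(object, ...) {
  c(Gamma = object$Gamma, exponent = object$exponent)
}

#' @export
plot.msd_fit <- function(x, ...) {
  d <- x$curve
  graphics::plot(d$lag_s, d$msd, xlab = "lag (s)", ylab = "MSD (um^2)",
                 pch = 16, ...)
  tt <- seq(min(d$lag_s), max(d$lag_s), length.out = 200)
  graphics::lines(tt, x$Gamma * tt^x$exponent, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Rouse-model conversion between MSD prefactor and bead diffusivity
#'
#' The Rouse model predicts the 2D MSD of an internal chain segment,
#' \deqn{\mathrm{MSD}(\tau) = \sqrt{\frac{16\, l_K^2 D_0}{3\pi}}\ \tau^{1/2},}
#' so the measured prefactor \eqn{\Gamma} determines the diffusion constant
#' of one Kuhn segment as \eqn{D_0 = 3\pi \Gamma^2 / (16\, l_K^2)}.
#' `rouse_gamma` is the forward direction.
#'
#' @param Gamma MSD prefactor (micrometres^2 s^-0.5), `>= 0`.
#' @param D0 segment diffusion constant (micrometres^2 per second).
#' @param l_K Kuhn length (micrometres); default 0.1 (twice the 50 nm
#'   persistence length of double-stranded DNA).
#' @return `rouse_d0`: diffusion constant in micrometres^2 per second;
#'   `rouse_gamma`: MSD prefactor.
#' @examples
#' rouse_d0(Gamma = 0.0101)   # ~0.0060 um^2/s
#' @export
rouse_d0 <- function(Gamma, l_K = 0.1) {
  if (any(Gamma < 0)) stop("Gamma must be non-negative")
  if (l_K <= 0) stop("l_K must be positive")
  3 * pi * Gamma^2 / (16 * l_K^2)
}

#' @rdname rouse_d0
#' @export
rouse_gamma <- function(D0, l_K = 0.1) {
  if (any(D0 < 0)) stop("D0 must be non-negative")
  sqrt(16 * l_K^2 * D0 / (3 * pi))
}
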