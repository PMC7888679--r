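#' Simulate per-cell spot-response counts with known ground truth
#'
#' Emulates a single-cell response experiment: each simulated cell is,
#' independently, always spot-positive with probability `nu0` (non-specific
#' binding baseline), never positive with probability `1 - nu_inf` (too few
#' proteins, or the spot is missed), and otherwise becomes positive at a
#' random time drawn from the two-step first-passage distribution
#' (see [rfpt()]).  The expected response is therefore
#' `nu(t) = nu0 + (nu_inf - nu0) * CDF(t)`.  At each requested time a fresh
#' cohort of `n_cells` cells is scored, mirroring the sampling of separate
#' culture aliquots per time point.
#'
#' Defaults mimic the scales of the motivating experiments: mean search
#' times of a few minutes, a 20% baseline and a plateau well below 1.
#'
#' @param alpha,beta,c first-passage parameters (minutes, minutes, 1/min).
#' @param nu0 baseline spot fraction (`0 <= nu0 < nu_inf`).
#' @param nu_inf plateau fraction (`<= 1`).
#' @param times observation times (minutes).
#' @param n_cells cells evaluated per time point (scalar or per-time).
#' @param seed integer seed (deterministic output).
#' @return List with `series` (a [response_series()]), `appearance_times`
#'   (list, per time point, of the cohort's per-cell appearance times;
#'   `0` for always-positive, `Inf` for never-positive cells) and `truth`
#'   (the generating parameters).
#' @examples
#' g <- sim_response_counts(alpha = 4.5, beta = 0.3, c = 0.05, nu0 = 0.2,
#'                          nu_inf = 0.75, times = 0:14, n_cells = 1500,
#'                          seed = 1)
#' head(g$series)
#' @export
sim_response_counts <- function(alpha = 4.5, beta = 0.3, c = 0.05,
                                nu0 = 0.2, nu_inf = 0.75, times = 0:14,
                                n_cells = 1500, seed = 1) {
  if (nu0 < 0 || nu_inf > 1 || nu0 >= nu_inf)
    stop("need 0 <= nu0 < nu_inf <= 1")
  n_cells <- rep_len(n_cells, length(times))
  appearance <- withr_seed(seed, {
    lapply(seq_along(times), function(i) {
      n <- n_cells[i]
      u <- stats::runif(n)
      ap <- rep(Inf, n)
      ap[u < nu0] <- 0
      searching <- u >= nu0 & u < nu_inf
      ap[searching] <- rfpt(sum(searching), alpha, beta, c)
      ap
    })
  })
  nu <- vapply(seq_along(times), function(i)
    mean(appearance[[i]] <= times[i]), numeric(1))
  series <- response_series(times, nu, n_cells = n_cells)
  list(series = series, appearance_times = appearance,
       truth = list(alpha = alpha, beta = beta, c = c, nu0 = nu0,
                    nu_inf = nu_inf, seed = seed))
}

#' Simulate subdiffusive locus trajectories
#'
#' Generates 2D trajectories whose ensemble mean square displacement follows
#' the Rouse scaling `MSD(tau) = Gamma * tau^0.5`, as observed for
#' chromosomal loci, plus optional localization noise.  Each coordinate is
#' fractional Brownian motion with Hurst exponent 0.25, constructed exactly
#' from the Cholesky factor of the fractional-Gaussian-noise covariance
#' (`n_frames` is small, so the exact construction is cheap); the
#' per-coordinate variance is scaled so the two coordinates together give
#' the target prefactor.
#'
#' @param Gamma MSD prefactor (um^2 s^-0.5); the experimentally observed
#'   scale is ~0.01.
#' @param n_tracks number of trajectories.
#' @param n_frames frames per trajectory.
#' @param dt frame interval (seconds, default 30).
#' @param sigma_loc localization noise per coordinate and frame (um).
#' @param seed integer seed.
#' @return data.frame with `track_id`, `cell_id`, `frame`, `x_um`, `y_um`;
#'   attribute `truth` records the parameters.
#' @examples
#' tr <- sim_locus_tracks(Gamma = 0.0101, n_tracks = 50, n_frames = 20,
#'                        seed = 2)
#' fit_msd(ensemble_msd(tr))
#' @export
sim_locus_tracks <- function(Gamma = 0.0101, n_tracks = 500, n_frames = 20,
                             dt = 30, sigma_loc = 0, seed = 1) {
  if (Gamma < 0 || sigma_loc < 0 || n_frames < 2)
    stop("invalid track parameters")
  H <- 0.25
  n_inc <- n_frames - 1L
  Lc <- if (Gamma > 0) chol(fgn_covariance(n_inc, H, Gamma / 2, dt)) else NULL
  out <- withr_seed(seed, {
    lapply(seq_len(n_tracks), function(k) {
      if (is.null(Lc)) {
        x <- numeric(n_frames); y <- numeric(n_frames)
      } else {
        x <- c(0, cumsum(drop(crossprod(Lc, stats::rnorm(n_inc)))))
        y <- c(0, cumsum(drop(crossprod(Lc, stats::rnorm(n_inc)))))
      }
      if (sigma_loc > 0) {
        x <- x + stats::rnorm(n_frames, sd = sigma_loc)
        y <- y + stats::rnorm(n_frames, sd = sigma_loc)
      }
      data.frame(track_id = k, cell_id = k, frame = seq_len(n_frames) - 1L,
                 x_um = x, y_um = y)
    })
  })
  res <- do.call(rbind, out)
  attr(res, "truth") <- list(Gamma = Gamma, H = H, dt = dt,
                             sigma_loc = sigma_loc, seed = seed)
  res
}

#' Covariance matrix of fractional Gaussian noise increments
#'
#' Covariance of successive fBm increments with Hurst exponent `H` and
#' per-coordinate MSD `msd1 * tau^(2H)`:
#' `cov(k) = msd1 * dt^(2H) / 2 * ((k+1)^(2H) - 2 k^(2H) + |k-1|^(2H))`.
#' Exposed for construction checks of the track generator.
#'
#' @param n number of increments.
#' @param H Hurst exponent.
#' @param msd1 per-coordinate MSD prefactor (um^2 s^-2H).
#' @param dt frame interval (s).
#' @return `n` x `n` covariance matrix.
#' @export
fgn_covariance <- function(n, H = 0.25, msd1 = 1, dt = 1) {
  k <- abs(outer(seq_len(n), seq_len(n), "-"))
  0.5 * msd1 * dt^(2 * H) *
    ((k + 1)^(2 * H) - 2 * k^(2 * H) + abs(k - 1)^(2 * H))
}

#' Simulate fluorescence images of rod-shaped cells with planted spots
#'
#' Draws capsule-shaped (rod) cells on a dark background, fills their
#' interior with a uniform signal, plants 2D Gaussian spots at requested
#' positions along the cell axis, and adds Gaussian pixel noise.  The
#' returned ground truth makes the images usable as fixtures with known
#' answers for [detect_spots()] and [half_axis_localization()].
#'
#' @param n_cells number of cells (laid out on a grid).
#' @param cell_length_um,cell_width_um cell dimensions (defaults typical of
#'   *E. coli*: 2-4 um long, 1 um wide).
#' @param pixel_size micrometres per pixel (default 0.1).
#' @param spots_per_cell spots planted per cell (0 or more).
#' @param spot_rel_pos positions along the half long axis in `[0, 1]`
#'   (recycled); `NULL` draws uniformly.
#' @param amplitude,psf_sigma_um spot peak amplitude above the cell interior
#'   and Gaussian width.
#' @param bg_cell,bg_out interior and exterior background levels.
#' @param noise_sd Gaussian pixel noise.
#' @param seed integer seed.
#' @return List with `image` (numeric matrix), `outlines` (list of polygon
#'   outlines with `cell_id`), `truth` (data.frame of planted spots:
#'   `cell_id`, `x_px`, `y_px`, `half_axis_pos`).
#' @export
sim_cell_image <- function(n_cells = 4, cell_length_um = NULL,
                           cell_width_um = 1, pixel_size = 0.1,
                           spots_per_cell = 1, spot_rel_pos = NULL,
                           amplitude = 200, psf_sigma_um = 0.15,
                           bg_cell = 100, bg_out = 20, noise_sd = 10,
                           seed = 1) {
  withr_seed(seed, {
    if (is.null(cell_length_um))
      cell_length_um <- stats::runif(n_cells, 2, 4)
    cell_length_um <- rep_len(cell_length_um, n_cells)
    Lpx <- cell_length_um / pixel_size
    Wpx <- rep_len(cell_width_um, n_cells) / pixel_size
    pad <- 10
    cell_w <- max(Lpx) + 2 * pad
    ncol_img <- ceiling(max(Wpx)) + 2 * pad
    img <- matrix(bg_out, nrow = ceiling(cell_w),
                  ncol = n_cells * ncol_img)
    outlines <- vector("list", n_cells)
    truth <- list()
    for (k in seq_len(n_cells)) {
      L <- Lpx[k]; W <- Wpx[k]
      cx <- cell_w / 2
      cy <- (k - 1) * ncol_img + ncol_img / 2
      half <- (L - W) / 2  # half-length of the straight segment
      # interior: distance to the axis segment below W/2
      xr <- floor(cx - L / 2 - 1):ceiling(cx + L / 2 + 1)
      yr <- floor(cy - W / 2 - 1):ceiling(cy + W / 2 + 1)
      for (x in xr) for (y in yr) {
        dx <- max(abs(x - cx) - half, 0)
        if (dx^2 + (y - cy)^2 <= (W / 2)^2) img[x, y] <- bg_cell
      }
      # capsule outline polygon
      th <- seq(-pi / 2, pi / 2, length.out = 20)
      ox <- c(cx + half + (W / 2) * cos(th), cx - half - (W / 2) * cos(th))
      oy <- c(cy + (W / 2) * sin(th), cy - (W / 2) * sin(rev(th)))
      outlines[[k]] <- list(cell_id = paste0("cell", k), x = ox, y = oy)
      # plant spots along the axis
      if (spots_per_cell > 0) {
        rel <- if (is.null(spot_rel_pos)) {
          stats::runif(spots_per_cell, 0, 0.8)
        } else rep_len(spot_rel_pos, spots_per_cell)
        if (any(rel < 0 | rel > 1))
          stop("planted spot position outside its cell")
        side <- sample(c(-1, 1), spots_per_cell, replace = TRUE)
        for (j in seq_len(spots_per_cell)) {
          sx <- cx + side[j] * rel[j] * L / 2
          sy <- cy
          if (abs(sx - cx) > L / 2 - 1) sx <- cx + side[j] * (L / 2 - 1)
          s_px <- psf_sigma_um / pixel_size
          gx <- floor(sx - 4 * s_px):ceiling(sx + 4 * s_px)
          gy <- floor(sy - 4 * s_px):ceiling(sy + 4 * s_px)
          for (x in gx) for (y in gy)
            img[x, y] <- img[x, y] + amplitude *
              exp(-((x - sx)^2 + (y - sy)^2) / (2 * s_px^2))
          truth[[length(truth) + 1L]] <-
            data.frame(cell_id = paste0("cell", k), x_px = sx, y_px = sy,
                       half_axis_pos = abs(sx - cx) / (L / 2))
        }
      }
    }
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                          nrow = nrow(img))
    list(image = img, outlines = outlines,
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(cell_id = character(), x_px = numeric(),
                      y_px = numeric(), half_axis_pos = numeric()))
  })
}

#' Write an image matrix as TIFF
#'
#' Thin wrapper (intensities rescaled to `[0, 1]`); requires the `tiff`
#' package.
#'
#' @param image numeric matrix.
#' @param file output path.
#' @export
write_image_tiff <- function(image, file) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to write TIFF files")
  rng <- range(image)
  tiff::writeTIFF((image - rng[1L]) / diff(rng), file)
}

#' Read a TIFF image as intensity matrix
#'
#' @param file path to a TIFF file.
#' @return Numeric matrix.
#' @export
read_image_tiff <- function(file) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF files")
  img <- tiff::readTIFF(file)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
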