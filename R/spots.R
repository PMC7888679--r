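#' Detect fluorescent spots inside segmented cells
#'
#' For each cell outline, pixels inside the polygon with intensity above
#' `mean + f * sd` of the within-cell signal are thresholded; connected
#' components (8-connectivity) are filtered by size, and of any pair of
#' surviving components closer than `min_distance` (centroid to centroid)
#' only the brighter one is kept.  The threshold is relative to the
#' within-cell statistics, so detection is invariant under affine intensity
#' rescaling of the image.
#'
#' @param image numeric matrix of fluorescence intensities (row = x pixel,
#'   column = y pixel).
#' @param outlines a single outline (data frame / list with `x`, `y` polygon
#'   vertex coordinates in pixels and a `cell_id`) or a list of them.
#' @param f threshold factor (default 3).
#' @param min_size,max_size component size bounds in pixels.
#' @param min_distance minimum centroid separation in pixels.
#' @param pixel_size micrometres per pixel (default 0.1), for the reported
#'   physical coordinates.
#' @return data.frame with one row per spot: `cell_id`, `x_px`, `y_px`,
#'   `x_um`, `y_um`, `area_px`, `mean_intensity`, `half_axis_pos` (relative
#'   position along the half long axis: 0 = mid-cell, 1 = pole).
#' @export
detect_spots <- function(image, outlines, f = 3, min_size = 2,
                         max_size = 200, min_distance = 3,
                         pixel_size = 0.1) {
  if (f <= 0) stop("threshold factor f must be positive")
  if (min_size < 1 || max_size < min_size) stop("invalid size bounds")
  if (!is.null(outlines$x)) outlines <- list(outlines)
  out <- lapply(outlines, function(o)
    detect_spots_one(image, o, f, min_size, max_size, min_distance,
                     pixel_size))
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell_id = character(), x_px = numeric(),
                      y_px = numeric(), x_um = numeric(), y_um = numeric(),
                      area_px = numeric(), mean_intensity = numeric(),
                      half_axis_pos = numeric())
  rownames(res) <- NULL
  res
}

detect_spots_one <- function(image, outline, f, min_size, max_size,
                             min_distance, pixel_size) {
  px <- outline$x
  py <- outline$y
  if (min(px) < 1 || max(px) > nrow(image) ||
      min(py) < 1 || max(py) > ncol(image))
    stop("cell outline extends beyond the image")
  xr <- floor(min(px)):ceiling(max(px))
  yr <- floor(min(py)):ceiling(max(py))
  grid <- expand.grid(x = xr, y = yr)
  inside <- mgcv::in.out(cbind(c(px, px[1L]), c(py, py[1L])),
                         as.matrix(grid))
  gx <- grid$x[inside]
  gy <- grid$y[inside]
  if (length(gx) == 0) return(NULL)
  vals <- image[cbind(gx, gy)]
  thr <- mean(vals) + f * stats::sd(vals)
  if (!is.finite(thr)) return(NULL)
  hot <- vals > thr
  if (!any(hot)) return(NULL)

  # label the thresholded pixels inside the cell's bounding box
  mask <- matrix(FALSE, length(xr), length(yr))
  mask[cbind(gx[hot] - xr[1L] + 1L, gy[hot] - yr[1L] + 1L)] <- TRUE
  lab <- label8_cpp(mask)
  comps <- lapply(seq_len(max(lab)), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    cx <- w[, 1L] + xr[1L] - 1L
    cy <- w[, 2L] + yr[1L] - 1L
    list(x = mean(cx), y = mean(cy), area = nrow(w),
         intensity = mean(image[cbind(cx, cy)]))
  })
  comps <- Filter(function(cp) cp$area >= min_size && cp$area <= max_size,
                  comps)
  if (length(comps) == 0) return(NULL)

  # brightest-wins within min_distance
  ord <- order(vapply(comps, `[[`, 0, "intensity"), decreasing = TRUE)
  keep <- list()
  for (i in ord) {
    cp <- comps[[i]]
    clash <- any(vapply(keep, function(k)
      sqrt((k$x - cp$x)^2 + (k$y - cp$y)^2) < min_distance, logical(1)))
    if (!clash) keep <- c(keep, list(cp))
  }

  axis <- cell_long_axis(outline)
  do.call(rbind, lapply(keep, function(cp) {
    s <- (cp$x - axis$center[1L]) * axis$dir[1L] +
      (cp$y - axis$center[2L]) * axis$dir[2L]
    data.frame(cell_id = outline$cell_id, x_px = cp$x, y_px = cp$y,
               x_um = cp$x * pixel_size, y_um = cp$y * pixel_size,
               area_px = cp$area, mean_intensity = cp$intensity,
               half_axis_pos = min(abs(s) / (axis$L / 2), 1))
  }))
}

#' Principal long axis of a cell outline
#'
#' The long axis is the principal eigenvector of the second moments of the
#' outline interior (approximated by the polygon vertices weighted equally,
#' which is accurate for the densely sampled outlines produced by
#' segmentation tools); the axis length `L` is the extent of the outline
#' projected onto it, and the centre is the midpoint of that extent.
#'
#' @param outline list/data frame with `x`, `y` vertex coordinates (pixels).
#' @return List with `center` (x, y), `dir` (unit vector), `L` (length in
#'   pixels).
#' @export
cell_long_axis <- function(outline) {
  P <- cbind(outline$x, outline$y)
  cm <- colMeans(P)
  S <- stats::cov(P)
  e <- eigen(S, symmetric = TRUE)
  dir <- e$vectors[, 1L]
  s <- (P[, 1L] - cm[1L]) * dir[1L] + (P[, 2L] - cm[2L]) * dir[2L]
  L <- diff(range(s))
  if (L <= 0) stop("degenerate outline: zero long-axis length")
  center <- cm + dir * (min(s) + L / 2)
  list(center = center, dir = dir, L = L)
}

#' Fraction of spot-positive cells over time
#'
#' Computes the response observable nu(t): the fraction of cells with at
#' least one detected spot at each time point, with binomial standard
#' errors.  Feeds directly into [normalize_response()] and [fit_response()].
#'
#' @param cells data frame with one row per imaged cell: `time_min`,
#'   `cell_id` and either logical `has_spot` or integer `n_spots`.
#' @return A [response_series()].
#' @export
response_fraction <- function(cells) {
  if (!"has_spot" %in% names(cells)) {
    if (!"n_spots" %in% names(cells)) stop("need has_spot or n_spots column")
    cells$has_spot <- cells$n_spots > 0
  }
  tt <- sort(unique(cells$time_min))
  n <- vapply(tt, function(t) sum(cells$time_min == t), 0)
  if (any(n == 0)) {
    warning("time points without cells omitted")
    tt <- tt[n > 0]; n <- n[n > 0]
  }
  nu <- vapply(tt, function(t) mean(cells$has_spot[cells$time_min == t]), 0)
  response_series(tt, nu, n_cells = n)
}

#' Spot localization along the half long axis, by cell-length class
#'
#' Each spot position is projected onto its cell's long axis and expressed
#' as `|s - L/2| / (L/2)`, so mid-cell maps to 0 and the poles to 1.  Cells
#' are binned by length into `n_length_classes` equal classes over the
#' observed range, classes are pooled according to `groups`, and a position
#' histogram is returned per group.  When two spot populations are given
#' (e.g. protein-DNA complexes vs. a labelled chromosomal locus) the overlap
#' coefficient of their histograms measures colocalization along the axis.
#'
#' @param spots data frame from [detect_spots()] (needs `cell_id`,
#'   `half_axis_pos`).
#' @param outlines list of outlines with `cell_id`; lengths are computed via
#'   [cell_long_axis()].  Degenerate outlines are excluded with a warning.
#' @param n_length_classes number of equal cell-length classes (default 10).
#' @param groups list of inclusive class ranges to pool, default
#'   `list(c(1, 2), c(2, 6), c(6, 10))`.
#' @param breaks histogram breaks on `[0, 1]` (default 10 equal bins).
#' @param spots2 optional second spot population for the overlap
#'   coefficient.
#' @return List of per-group results: histogram `density`, `mids`, `n`;
#'   plus `overlap` per group when `spots2` is given.
#' @export
half_axis_localization <- function(spots, outlines, n_length_classes = 10,
                                   groups = list(c(1, 2), c(2, 6), c(6, 10)),
                                   breaks = seq(0, 1, by = 0.1),
                                   spots2 = NULL) {
  lens <- vapply(outlines, function(o) {
    tryCatch(cell_long_axis(o)$L, error = function(e) NA_real_)
  }, numeric(1))
  ids <- vapply(outlines, function(o) as.character(o$cell_id), character(1))
  if (anyNA(lens)) {
    warning(sum(is.na(lens)), " degenerate outline(s) excluded")
    ids <- ids[!is.na(lens)]; lens <- lens[!is.na(lens)]
  }
  cls <- cut(lens, breaks = seq(min(lens), max(lens),
                                length.out = n_length_classes + 1L),
             include.lowest = TRUE, labels = FALSE)
  names(cls) <- ids

  hist_group <- function(sp, g) {
    keep <- cls[as.character(sp$cell_id)] >= g[1L] &
      cls[as.character(sp$cell_id)] <= g[2L]
    keep[is.na(keep)] <- FALSE
    x <- pmin(pmax(sp$half_axis_pos[keep], 0), 1)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(density = h$density, mids = h$mids, n = length(x))
  }

  out <- lapply(groups, function(g) {
    res <- hist_group(spots, g)
    if (!is.null(spots2)) {
      res2 <- hist_group(spots2, g)
      w <- diff(breaks)
      res$overlap <- sum(pmin(res$density, res2$density) * w)
      res$density2 <- res2$density
    }
    res
  })
  names(out) <- vapply(groups, function(g) paste0("class", g[1L], "-", g[2L]),
                       character(1))
  out
}
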