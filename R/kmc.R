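#' Configuration for the lattice target-search simulation
#'
#' The cell is a cube with edge length `n_cell * a`, discretized into
#' `(n_cell + 1)^3` lattice sites with spacing `a` (the Kuhn length of
#' double-stranded DNA, 0.1 um, so the chromosome is a freely jointed chain
#' on the lattice).  The DNA is a phantom bead-spring chain of
#' `n_dna` beads moving anywhere in the box; the protein occupies a single
#' site on the box surface (the membrane) and hops to neighbouring surface
#' sites at rate `D_2D / a^2` per direction.  Bead moves are attempted at a
#' basal rate `k_dna` per direction and accepted with the Metropolis factor
#' `min(1, exp(-dU))` for the harmonic bond energy
#' `U = sum k_s (|r_{n+1} - r_n| - b)^2` (in kBT, lattice units).  `k_dna`
#' is calibrated so the free chain's centre of mass diffuses with `D_0 /
#' n_dna` (see [calibrate_k_dna()]).  The search ends when a binding-site
#' bead and the protein occupy the same lattice site.
#'
#' The default parameter values form the realistic parameter set for an
#' *E. coli* cell: `a = 0.1` um, 1 um^3 volume, a 100-bead chain (above the
#' length at which the search time plateaus), one protein dimer with
#' `D_2D = 0.20` um^2/s and a bead diffusivity `D_0 = 0.0060` um^2/s
#' measured from chromosomal locus tracking.
#'
#' @param a lattice constant (micrometres).
#' @param n_cell box edge length in lattice constants (cell volume
#'   `(n_cell * a)^3`; the lattice has `n_cell + 1` sites per edge).
#' @param n_dna number of DNA beads.
#' @param topology `"linear"` (default; `n_dna - 1` bonds) or `"ring"`
#'   (circular chromosome, used for multi-site placements).
#' @param n_b number of specific binding sites.
#' @param site_placement `"uniform"` (maximally spread along the chain/ring)
#'   or `"adjacent"` (consecutive beads centred mid-polymer).
#' @param sites explicit 1-based bead indices of the binding sites
#'   (overrides `n_b`/`site_placement`).
#' @param n_p number of independent proteins; capture by any of them.
#' @param D_2D protein surface diffusivity (um^2/s).
#' @param D_0 bead diffusivity (um^2/s).
#' @param k_s bond spring constant (kBT per a^2).
#' @param b equilibrium bond length (lattice units).
#' @param mode `"standard"` (both species move, capture on site
#'   coincidence); `"immobile_dna_membrane_target"` (DNA frozen with its
#'   binding-site bead placed at a random surface site, only the protein
#'   searches); `"membrane_as_target"` (the whole surface is the target:
#'   first touch of the binding-site bead on any surface site); or
#'   `"immobile_protein"` (protein frozen at a random surface site, DNA
#'   motion completes the search).
#' @param capture `"site"` (exact lattice-site coincidence, default) or
#'   `"chebyshev"` (distance <= 1 in every coordinate, for sensitivity
#'   checks of the capture rule).
#' @param init initial polymer placement: the confined lattice random walk
#'   is anchored at a uniformly drawn box site (`"uniform"`, default; the
#'   chain equilibrates across the whole cell, so some initial states
#'   already have the target region at the membrane, which is what gives
#'   rise to mixed-initial-condition response shapes), anchored at the cell
#'   centre (`"center"`), or confined to the interior sites (`"interior"`).
#' @param max_time simulated-seconds cap per run; `NULL` (default) lets
#'   [run_ensemble()] choose 10x the mean of a 50-run pilot.
#' @param k_dna basal bead move rate (1/s); `NULL` (default) triggers
#'   calibration.
#' @return A list of class `"kmc_config"`.
#' @export
kmc_config <- function(a = 0.1, n_cell = 10, n_dna = 100,
                       topology = c("linear", "ring"), n_b = 1,
                       site_placement = c("uniform", "adjacent"),
                       sites = NULL, n_p = 1, D_2D = 0.20, D_0 = 0.0060,
                       k_s = 3, b = 1,
                       mode = c("standard", "immobile_dna_membrane_target",
                                "membrane_as_target", "immobile_protein"),
                       capture = c("site", "chebyshev"),
                       init = c("uniform", "center", "interior"),
                       max_time = NULL, k_dna = NULL) {
  topology <- match.arg(topology)
  site_placement <- match.arg(site_placement)
  mode <- match.arg(mode)
  capture <- match.arg(capture)
  init <- match.arg(init)
  if (n_cell < 3) stop("n_cell must be >= 3")
  if (n_dna < 1) stop("n_dna must be >= 1")
  if (is.null(sites)) {
    sites <- place_binding_sites(n_b, n_dna, site_placement, topology)
  } else {
    if (any(sites < 1 | sites > n_dna)) stop("sites out of range")
    n_b <- length(sites)
  }
  if (D_2D < 0 || D_0 < 0) stop("diffusivities must be non-negative")
  if (mode == "standard" && D_2D == 0 && D_0 == 0)
    stop("at least one species must be mobile")
  structure(list(a = a, n_cell = n_cell, n_dna = n_dna, topology = topology,
                 n_b = n_b, site_placement = site_placement, sites = sites,
                 n_p = n_p, D_2D = D_2D, D_0 = D_0, k_s = k_s, b = b,
                 mode = mode, capture = capture, init = init,
                 max_time = max_time, k_dna = k_dna),
            class = "kmc_config")
}

#' @export
print.kmc_config <- function(x, ...) {
  cat("KMC target-search configuration\n")
  cat(sprintf("  box: %d^3 sites, a = %g um (V = %.3g um^3)\n",
              x$n_cell + 1L, x$a, (x$n_cell * x$a)^3))
  cat(sprintf("  DNA: %d beads (%s), k_s = %g, b = %g; sites: %s\n",
              x$n_dna, x$topology, x$k_s, x$b,
              paste(x$sites, collapse = ", ")))
  cat(sprintf("  protein: n_p = %d, D_2D = %g um^2/s; D_0 = %g um^2/s\n",
              x$n_p, x$D_2D, x$D_0))
  cat(sprintf("  mode: %s, capture: %s\n", x$mode, x$capture))
  invisible(x)
}

#' Place binding sites along the polymer
#'
#' `"uniform"` spreads `n_b` sites maximally: equidistant points on the ring
#' (antipodal for `n_b = 2`), segment centres on the linear chain.
#' `"adjacent"` uses `n_b` consecutive beads centred mid-polymer.
#'
#' @param n_b number of sites, `1 <= n_b <= n_dna`.
#' @param n_dna number of beads.
#' @param placement `"uniform"` or `"adjacent"`.
#' @param topology `"linear"` or `"ring"`.
#' @return Integer vector of 1-based bead indices.
#' @examples
#' place_binding_sites(2, 100, "uniform", "ring")    # 1, 51 (antipodal)
#' place_binding_sites(2, 100, "adjacent", "linear") # 50, 51
#' @export
place_binding_sites <- function(n_b, n_dna,
                                placement = c("uniform", "adjacent"),
                                topology = c("linear", "ring")) {
  placement <- match.arg(placement)
  topology <- match.arg(topology)
  if (n_b < 1 || n_b > n_dna) stop("need 1 <= n_b <= n_dna")
  if (placement == "adjacent") {
    start <- floor((n_dna - n_b) / 2) + 1L
    return(seq.int(start, start + n_b - 1L))
  }
  if (topology == "ring") {
    idx <- floor(seq(0, n_dna, length.out = n_b + 1L))[seq_len(n_b)] + 1L
  } else {
    idx <- round((seq_len(n_b) - 0.5) / n_b * n_dna + 0.5)
  }
  unique(as.integer(idx))
}

#' Conversion between dimensionless lattice time and seconds
#'
#' One lattice time unit corresponds to `a^2 / D_0` seconds; with the
#' realistic parameters (`a = 0.1` um, `D_0 = 0.0060` um^2/s) this is
#' approximately 1.66 s.
#'
#' @param a lattice constant (micrometres).
#' @param D_0 bead diffusivity (um^2/s).
#' @return Seconds per lattice time unit.
#' @export
lattice_time_scale <- function(a = 0.1, D_0 = 0.0060) {
  if (a <= 0 || D_0 <= 0) stop("a and D_0 must be positive")
  a^2 / D_0
}

#' Total bond-spring energy of a polymer configuration
#'
#' `U = sum_n k_s (|r_{n+1} - r_n| - b)^2` in kBT over the `n_dna - 1` bonds
#' of a linear chain (`n_dna` bonds on a ring); coordinates in lattice units.
#'
#' @param beads integer matrix (`n_dna` x 3) of lattice coordinates.
#' @param k_s spring constant (kBT per a^2).
#' @param b equilibrium bond length (lattice units).
#' @param ring circular chain?
#' @return Energy in kBT.
#' @export
spring_energy <- function(beads, k_s = 3, b = 1, ring = FALSE) {
  beads <- as.matrix(beads)
  storage.mode(beads) <- "integer"
  spring_energy_cpp(beads, k_s, b, ring)
}

# cache of calibrated basal move rates, keyed by chain parameters
.kmc_cache <- new.env(parent = emptyenv())

#' Calibrate the basal DNA move rate
#'
#' Adjusts `k_dna` so that the free chain (no confining box) has a
#' centre-of-mass diffusion coefficient `D_0 / n_dna`, the Rouse-model value
#' for a chain of beads with individual diffusivity `D_0`.  Because all bead
#' moves share the same Metropolis acceptance factors, the centre-of-mass
#' diffusivity is proportional to `k_dna`; a measurement at a reference rate
#' therefore gives the calibrated rate directly, which is then re-measured
#' and, if needed, rescaled until it matches the target within `tol`.
#' Results are cached per parameter combination.
#'
#' The centre-of-mass diffusivity is estimated from the time-averaged MSD of
#' replicate free chains at lags long enough for the bond-relaxation
#' anticorrelations to have decayed.
#'
#' @param n_dna,k_s,b,topology chain parameters (see [kmc_config()]).
#' @param D_0 target bead diffusivity (um^2/s).
#' @param a lattice constant (micrometres).
#' @param tol relative tolerance on the centre-of-mass diffusivity.
#' @param n_chains,t_total replicate chains and simulated time per
#'   measurement (time is expressed at the reference rate and rescaled).
#' @param max_iter iteration budget; exceeded means calibration error.
#' @param seed seed for the calibration simulations.
#' @return Calibrated `k_dna` in 1/s, with attribute `D_com_rel` giving the
#'   achieved relative deviation.
#' @export
calibrate_k_dna <- function(n_dna, k_s = 3, b = 1, D_0 = 0.0060, a = 0.1,
                            topology = "linear", tol = 0.05, n_chains = 60,
                            t_total = 3000, max_iter = 6, seed = 101) {
  d_tgt <- (D_0 / a^2) / n_dna  # lattice units^2 / s
  key <- paste(n_dna, k_s, b, topology, signif(d_tgt, 8), sep = "|")
  hit <- .kmc_cache[[key]]
  if (!is.null(hit)) return(hit)

  if (n_dna == 1 || k_s == 0) {
    # no springs: every in-range move is accepted, D_com = k a^2 / n exactly
    k <- D_0 / a^2
    attr(k, "D_com_rel") <- 0
    .kmc_cache[[key]] <- k
    return(k)
  }

  measure <- function(k, stream) {
    # keep the number of events comparable across k by rescaling time
    tt <- t_total / k
    dcoms <- vapply(seq_len(n_chains), function(i) {
      fc <- kmc_free_chain_cpp(n_dna, identical(topology, "ring"), k, k_s, b,
                               tt, tt / 1500, seed, stream * 10000L + i,
                               FALSE)
      com_diffusivity(fc$com, fc$dt)
    }, numeric(1))
    mean(dcoms)
  }

  k <- 1
  for (it in seq_len(max_iter)) {
    d_est <- measure(k, it)
    rel <- abs(d_est - d_tgt) / d_tgt
    if (it > 1 && rel < tol) {
      attr(k, "D_com_rel") <- rel
      .kmc_cache[[key]] <- k
      return(k)
    }
    k <- k * d_tgt / d_est
  }
  stop("k_dna calibration did not converge within ", max_iter, " iterations")
}

# Centre-of-mass diffusivity from a sampled trajectory: origin-pooled MSD at
# intermediate lags, slope of MSD = 6 D t through the origin.
com_diffusivity <- function(com, dt) {
  n <- nrow(com)
  # short lags: past the bond-relaxation anticorrelations but early enough
  # that the time-averaged MSD has small variance relative to the run length
  lags <- unique(round(seq(5, n %/% 20, length.out = 8)))
  msd <- vapply(lags, function(L) {
    i <- seq_len(n - L)
    mean(rowSums((com[i + L, , drop = FALSE] - com[i, , drop = FALSE])^2))
  }, numeric(1))
  tau <- lags * dt
  sum(msd * tau) / sum(tau * tau) / 6
}

resolve_k_dna <- function(config) {
  if (!is.null(config$k_dna)) return(config$k_dna)
  if (config$mode == "immobile_dna_membrane_target" || config$D_0 == 0)
    return(0)
  calibrate_k_dna(config$n_dna, config$k_s, config$b, config$D_0, config$a,
                  config$topology)
}

#' Run a single target-search simulation
#'
#' Simulates one search with the null-event kinetic Monte Carlo scheme and
#' returns its first-passage time.  The polymer is initialized as a confined
#' lattice random walk and the protein uniformly on the surface; in
#' `"immobile_dna_membrane_target"` mode the binding-site bead anchors the
#' (frozen) chain at a random surface site.  Identical `(seed, run)` pairs
#' give identical trajectories.
#'
#' @param config a [kmc_config()].
#' @param seed master seed (integer).
#' @param run run index; ensembles vary `run` at fixed `seed`.
#' @param k_dna basal bead rate; defaults to the calibrated value.
#' @param max_time override for the time cap (seconds).
#' @return A list: `fpt_s` (seconds, `NA` if censored), `fpt_lattice`
#'   (units of `a^2 / D_0`), `censored`, `attempts`, `accepted`.
#' @export
run_search <- function(config, seed = 1, run = 1, k_dna = NULL,
                       max_time = NULL) {
  stopifnot(inherits(config, "kmc_config"))
  if (is.null(k_dna)) k_dna <- resolve_k_dna(config)
  if (is.null(max_time))
    max_time <- if (is.null(config$max_time)) Inf else config$max_time
  mode <- config$mode
  dna_mobile <- mode != "immobile_dna_membrane_target" && config$D_0 > 0
  protein_mobile <- mode %in% c("standard", "immobile_dna_membrane_target") &&
    config$D_2D > 0
  capture_mode <- if (mode == "membrane_as_target") 1L
                  else if (config$capture == "chebyshev") 2L else 0L
  res <- kmc_search_cpp(config$n_cell + 1L, config$n_dna,
                        identical(config$topology, "ring"),
                        as.integer(config$sites) - 1L,
                        config$n_p, config$D_2D / config$a^2, k_dna,
                        config$k_s, config$b, dna_mobile, protein_mobile,
                        capture_mode,
                        mode == "immobile_dna_membrane_target",
                        match(config$init, c("uniform", "center",
                                             "interior")) - 1L,
                        max_time, seed, run)
  list(fpt_s = res$fpt,
       fpt_lattice = res$fpt / lattice_time_scale(config$a, config$D_0),
       censored = res$censored, attempts = res$attempts,
       accepted = res$accepted)
}

#' Run an ensemble of target-search simulations
#'
#' Runs `n_runs` independent searches (fresh initial configuration each, RNG
#' stream derived from `(seed, run index)`), and summarizes the
#' first-passage-time sample.  If no `max_time` is configured, a 50-run
#' pilot sets it to 10x the pilot mean.  Censored runs are reported and
#' excluded from the mean; more than 10% censoring raises a warning.
#'
#' @param config a [kmc_config()].
#' @param n_runs number of independent searches.
#' @param seed master seed.
#' @return An object of class `"kmc_ensemble"`: list with `fpt_s` (seconds,
#'   `NA` where censored), `censored`, `mean_s`, `sem_s`,
#'   `mean_positive_s`/`sem_positive_s` (mean over searches that do not
#'   start in the captured state — the proper first-passage mean when a
#'   fraction of initial configurations is already in contact, as happens
#'   with a whole-membrane target), `n_initial_capture`, `n_runs`,
#'   `n_censored`, `k_dna`, `max_time`, `config`, `seed`.  Methods:
#'   `print`, `summary`, `plot` (empirical CDF).
#' @export
run_ensemble <- function(config, n_runs = 1000, seed = 1) {
  stopifnot(inherits(config, "kmc_config"), n_runs >= 1)
  k_dna <- resolve_k_dna(config)
  max_time <- config$max_time
  if (is.null(max_time)) {
    pilot <- vapply(seq_len(50), function(i)
      run_search(config, seed, 1000000L + i, k_dna, 1e8)$fpt_s, numeric(1))
    # runs already captured at t = 0 carry no timescale information; basing
    # the cap on the positive passage times avoids truncating heavy tails
    # in modes where many initial states start in contact
    pos <- pilot[!is.na(pilot) & pilot > 0]
    max_time <- if (length(pos)) 10 * mean(pos) else 1e8
  }
  fpt <- numeric(n_runs)
  cen <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    r <- run_search(config, seed, i, k_dna, max_time)
    fpt[i] <- r$fpt_s
    cen[i] <- r$censored
  }
  n_cen <- sum(cen)
  if (n_cen > 0.1 * n_runs)
    warning(sprintf("%d of %d runs censored at max_time = %.3g s",
                    n_cen, n_runs, max_time))
  ok <- fpt[!cen]
  pos <- ok[ok > 0]
  structure(list(fpt_s = fpt, censored = cen,
                 mean_s = mean(ok),
                 sem_s = stats::sd(ok) / sqrt(max(length(ok), 1)),
                 mean_positive_s = mean(pos),
                 sem_positive_s = stats::sd(pos) / sqrt(max(length(pos), 1)),
                 n_initial_capture = sum(ok == 0),
                 n_runs = n_runs, n_censored = n_cen,
                 k_dna = k_dna, max_time = max_time,
                 config = config, seed = seed),
            class = "kmc_ensemble")
}

#' @export
print.kmc_ensemble <- function(x, ...) {
  cat(sprintf("KMC search ensemble: %d runs (%d censored)\n",
              x$n_runs, x$n_censored))
  cat(sprintf("  mean search time: %.4g s  (%.4g min), SEM %.3g s\n",
              x$mean_s, x$mean_s / 60, x$sem_s))
  if (x$n_initial_capture > 0)
    cat(sprintf("  %d runs started in contact; mean over the rest: %.4g s\n",
                x$n_initial_capture, x$mean_positive_s))
  invisible(x)
}

#' @export
summary.kmc_ensemble <- function(object, ...) {
  ok <- object$fpt_s[!object$censored]
  out <- list(mean_s = object$mean_s, sem_s = object$sem_s,
              median_s = stats::median(ok), sd_s = stats::sd(ok),
              n_runs = object$n_runs, n_censored = object$n_censored,
              quartiles = stats::quantile(ok, c(0.25, 0.75)))
  class(out) <- "summary.kmc_ensemble"
  out
}

#' @export
print.summary.kmc_ensemble <- function(x, ...) {
  cat(sprintf("runs: %d (censored: %d)\n", x$n_runs, x$n_censored))
  cat(sprintf("mean  %.4g s  (SEM %.3g), sd %.4g\n", x$mean_s, x$sem_s, x$sd_s))
  cat(sprintf("median %.4g s, IQR [%.4g, %.4g]\n",
              x$median_s, x$quartiles[1], x$quartiles[2]))
  invisible(x)
}

#' @export
plot.kmc_ensemble <- function(x, ..., unit = c("s", "min")) {
  unit <- match.arg(unit)
  ok <- x$fpt_s[!x$censored]
  if (unit == "min") ok <- ok / 60
  graphics::plot(stats::ecdf(ok), xlab = paste0("search time (", unit, ")"),
                 ylab = "empirical CDF", main = "", ...)
  invisible(x)
}

#' Empirical CDF of an ensemble on a time grid
#'
#' @param ensemble a [run_ensemble()] result.
#' @param times grid (seconds); default 100 points spanning the sample.
#' @return data.frame with `time_s` and `cdf`.
#' @export
ensemble_cdf <- function(ensemble, times = NULL) {
  ok <- ensemble$fpt_s[!ensemble$censored]
  if (is.null(times)) times <- seq(0, max(ok), length.out = 100)
  data.frame(time_s = times, cdf = stats::ecdf(ok)(times))
}

#' Sweep a simulation parameter
#'
#' Runs an ensemble per value of one parameter and tabulates mean and SEM of
#' the search time.  For binding-site-number sweeps the mean normalized to
#' the single-site value is added (`mean_ratio`).
#'
#' @param config base [kmc_config()].
#' @param param one of `"D_2D"`, `"D_0"`, `"n_b"`, `"n_dna"`, `"n_cell"`.
#' @param values numeric vector of parameter values.
#' @param n_runs runs per value.
#' @param seed master seed (offset per value for independent streams).
#' @return data.frame with `value`, `mean_s`, `sem_s`, `n_censored` (and
#'   `mean_ratio` for `n_b` sweeps containing 1).
#' @export
sweep_param <- function(config, param = c("D_2D", "D_0", "n_b", "n_dna",
                                          "n_cell"),
                        values, n_runs = 1000, seed = 1) {
  param <- match.arg(param)
  rows <- lapply(seq_along(values), function(i) {
    cfg <- config
    cfg[[param]] <- values[i]
    if (param %in% c("n_b", "n_dna"))
      cfg$sites <- place_binding_sites(cfg$n_b, cfg$n_dna,
                                       cfg$site_placement, cfg$topology)
    if (param == "D_2D" && values[i] == 0 && cfg$mode == "standard")
      cfg$mode <- "immobile_protein"
    ens <- run_ensemble(cfg, n_runs, seed + 7919L * (i - 1L))
    data.frame(value = values[i], mean_s = ens$mean_s, sem_s = ens$sem_s,
               n_censored = ens$n_censored)
  })
  out <- do.call(rbind, rows)
  if (param == "n_b" && any(values == 1))
    out$mean_ratio <- out$mean_s / out$mean_s[match(1, values)]
  out
}

#' Sampled initial state of the simulation
#'
#' Draws the initial polymer configuration (confined lattice random walk)
#' and protein surface position used by [run_search()]; exposed for
#' distributional tests of the initializer.
#'
#' @param config a [kmc_config()].
#' @param seed,run stream selectors as in [run_search()].
#' @return List with `beads` (matrix `n_dna` x 3) and `protein` (length-3).
#' @export
kmc_init <- function(config, seed = 1, run = 1) {
  res <- kmc_init_cpp(config$n_cell + 1L, config$n_dna,
                      config$mode == "immobile_dna_membrane_target",
                      match(config$init, c("uniform", "center",
                                           "interior")) - 1L,
                      as.integer(config$sites[1]) - 1L, seed, run)
  res
}

#' Candidate-move rate table for a lattice state
#'
#' Enumerates every candidate move of the current state with its transition
#' rate: the protein has rate `D_2D / a^2` to each neighbouring surface
#' site (moves leaving the box or the surface have rate zero), and each DNA
#' bead has rate `k_dna * min(1, exp(-dU))` to each of its 6 lattice
#' neighbours inside the box, with `dU` the bond-spring energy change of
#' that single-bead displacement.  This is the rate table the null-event
#' sampler draws from; it is exposed as a readable reference implementation
#' and for direct tests of detailed balance.
#'
#' @param beads integer matrix (`n_dna` x 3) of bead coordinates (0-based
#'   lattice units, as returned by [kmc_init()]).
#' @param protein integer vector of length 3 (a surface site).
#' @param config a [kmc_config()].
#' @param k_dna basal bead rate (1/s); defaults to the calibrated value.
#' @return data.frame with columns `species` ("protein"/"bead"), `index`
#'   (bead number, NA for the protein), `dx`, `dy`, `dz`, `rate`.
#' @export
move_rates <- function(beads, protein, config, k_dna = NULL) {
  stopifnot(inherits(config, "kmc_config"))
  if (is.null(k_dna)) k_dna <- resolve_k_dna(config)
  L <- config$n_cell + 1L
  k2d <- config$D_2D / config$a^2
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  in_box <- function(p) all(p >= 0 & p <= L - 1)
  on_surf <- function(p) any(p == 0 | p == L - 1)
  ring <- identical(config$topology, "ring")
  rows <- vector("list", 6L * (nrow(beads) + 1L))
  m <- 0L
  for (d in seq_len(6)) {
    q <- protein + dirs[d, ]
    m <- m + 1L
    rows[[m]] <- data.frame(species = "protein", index = NA_integer_,
                            dx = dirs[d, 1], dy = dirs[d, 2], dz = dirs[d, 3],
                            rate = if (in_box(q) && on_surf(q)) k2d else 0)
  }
  u0 <- spring_energy(beads, config$k_s, config$b, ring)
  for (i in seq_len(nrow(beads))) {
    for (d in seq_len(6)) {
      q <- beads[i, ] + dirs[d, ]
      m <- m + 1L
      if (!in_box(q)) {
        rate <- 0
      } else {
        nb <- beads
        nb[i, ] <- q
        du <- spring_energy(nb, config$k_s, config$b, ring) - u0
        rate <- k_dna * min(1, exp(-du))
      }
      rows[[m]] <- data.frame(species = "bead", index = i,
                              dx = dirs[d, 1], dy = dirs[d, 2],
                              dz = dirs[d, 3], rate = rate)
    }
  }
  do.call(rbind, rows)
}
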