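test_that("configuration and binding-site placement follow the geometry", {
  cfg <- kmc_config()
  expect_equal((cfg$n_cell * cfg$a)^3, 1)  # 1 um^3 cell
  expect_equal(kmc_config(n_cell = 11)$n_cell * 0.1, 1.1)  # 1.33 um^3

  expect_equal(place_binding_sites(2, 100, "uniform", "ring"), c(1L, 51L))
  expect_equal(place_binding_sites(2, 100, "adjacent", "linear"), c(50L, 51L))
  expect_equal(place_binding_sites(100, 100, "adjacent", "linear"), 1:100)
  expect_equal(length(place_binding_sites(4, 100, "uniform", "ring")), 4L)
  expect_error(place_binding_sites(5, 4), "n_b")
  expect_error(kmc_config(n_b = 1, sites = 200), "out of range")

  expect_equal(lattice_time_scale(0.1, 0.006), 1 / 0.6)
})

test_that("initial states: beads confined to the box, protein on the surface", {
  cfg <- kmc_config(n_dna = 50)
  L <- cfg$n_cell + 1
  for (i in 1:300) {
    st <- kmc_init(cfg, seed = 2, run = i)
    expect_true(all(st$beads >= 0 & st$beads <= L - 1))
    p <- st$protein
    expect_true(any(p == 0 | p == L - 1))
    # consecutive beads one lattice step apart in the initial walk
    steps <- abs(diff(st$beads))
    expect_true(all(rowSums(steps) == 1))
  }
  # frozen-DNA mode anchors the site bead on the membrane
  cfg7 <- kmc_config(mode = "immobile_dna_membrane_target")
  for (i in 1:100) {
    st <- kmc_init(cfg7, seed = 3, run = i)
    s <- st$beads[cfg7$sites[1], ]
    expect_true(any(s == 0 | s == L - 1))
  }
})

test_that("spring energy equals a brute-force bond sum", {
  brute <- function(beads, ks, b, ring) {
    n <- nrow(beads)
    idx <- if (ring) rbind(cbind(1:(n - 1), 2:n), c(n, 1)) else
      cbind(1:(n - 1), 2:n)
    sum(apply(idx, 1, function(ij) {
      d <- sqrt(sum((beads[ij[1], ] - beads[ij[2], ])^2))
      ks * (d - b)^2
    }))
  }
  # all bonds at length b -> zero energy
  straight <- cbind(1:5, rep(0, 5), rep(0, 5))
  expect_equal(spring_energy(straight, k_s = 3, b = 1), 0)
  # two beads at distance 2, b = 1, k_s = 3 -> 3 kBT
  expect_equal(spring_energy(rbind(c(0, 0, 0), c(2, 0, 0)), k_s = 3), 3)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    beads <- matrix(sample(0:6, 3 * n, replace = TRUE), ncol = 3)
    ring <- i %% 2 == 0
    expect_equal(spring_energy(beads, 2.5, 1, ring), brute(beads, 2.5, 1, ring))
  }
})

test_that("null-event stepping matches direct Gillespie sampling", {
  L <- 5; k2d <- 2; kdna <- 1
  ne <- memsearch:::kmc_event_trace_cpp(L, k2d, kdna, 40000, 11, 1)
  gi <- gillespie_toy(L, k2d, kdna, 40000, 12)
  # mean dwell time between accepted events
  se <- sqrt(stats::var(ne$dwell) / 40000 + stats::var(gi$dwell) / 40000)
  expect_lt(abs(mean(ne$dwell) - mean(gi$dwell)), 3 * se)
  # fraction of protein moves
  p1 <- mean(ne$type == 0); p2 <- mean(gi$type == 0)
  sp <- sqrt(p1 * (1 - p1) / 40000 + p2 * (1 - p2) / 40000)
  expect_lt(abs(p1 - p2), 3 * sp)
})

test_that("free single bead and surface protein diffuse at the imposed rates", {
  # single bead: MSD = 6 k a^2 t (lattice units, k = 1); many replicate
  # walkers and a lag well inside the run keep the estimator sd ~ 1%
  nrep <- 2000
  msd <- 0
  for (i in 1:nrep) {
    fc <- memsearch:::kmc_free_chain_cpp(1, FALSE, 1, 0, 1, 120, 3, 17, i,
                                         FALSE)
    com <- fc$com
    j <- seq_len(nrow(com) - 5)
    msd <- msd + mean(rowSums((com[j + 5, ] - com[j, ])^2))
  }
  expect_equal(msd / nrep, 6 * 15, tolerance = 0.02)

  # protein on one face away from the edges: MSD = 4 k a^2 t
  nrep <- 2000; msd <- 0; used <- 0
  for (i in 1:nrep) {
    pw <- memsearch:::kmc_protein_walk_cpp(121, 1, 120, 3, 19, i)
    if (pw$left_face) next
    pos <- pw$pos
    j <- seq_len(nrow(pos) - 5)
    msd <- msd + mean(rowSums((pos[j + 5, 1:2] - pos[j, 1:2])^2))
    used <- used + 1
  }
  expect_gt(used, 0.9 * nrep)
  expect_equal(msd / used, 4 * 15, tolerance = 0.02)
})

test_that("bead moves obey detailed balance: dimer bond-length Boltzmann", {
  ks <- 3; b <- 1
  fc <- memsearch:::kmc_free_chain_cpp(2, FALSE, 1, ks, b, 12000, 6, 23, 1,
                                       TRUE)
  d2 <- rowSums(fc$bond^2)
  # discrete Boltzmann weights over bond vectors, grouped by |d|^2
  grid <- as.matrix(expand.grid(-6:6, -6:6, -6:6))
  gd2 <- rowSums(grid^2)
  w <- exp(-ks * (sqrt(gd2) - b)^2)
  classes <- c(0, 1, 2, 3, 4, 5)
  p_exp <- vapply(classes, function(k) sum(w[gd2 == k]), numeric(1))
  p_exp <- c(p_exp, sum(w) - sum(p_exp))  # tail class
  p_exp <- p_exp / sum(w)
  obs <- c(vapply(classes, function(k) sum(d2 == k), numeric(1)),
           sum(!(d2 %in% classes)))
  keep <- p_exp > 5 / length(d2)
  chi <- stats::chisq.test(obs[keep], p = p_exp[keep] / sum(p_exp[keep]))
  expect_gt(chi$p.value, 1e-3)
})

test_that("seeded runs are deterministic and independent of call order", {
  cfg <- kmc_config(n_cell = 5, n_dna = 20)
  a1 <- run_search(cfg, seed = 7, run = 3, k_dna = 1)
  a2 <- run_search(cfg, seed = 7, run = 3, k_dna = 1)
  expect_identical(a1, a2)
  b1 <- run_search(cfg, seed = 7, run = 4, k_dna = 1)
  expect_false(isTRUE(all.equal(a1$fpt_s, b1$fpt_s)))
})

test_that("stalled configurations raise an error", {
  cfg <- kmc_config(n_cell = 5, n_dna = 5, mode = "immobile_protein",
                    D_0 = 0)
  expect_error(run_search(cfg, seed = 1, k_dna = 0), "zero")
})

test_that("calibration closed-form cases and caching", {
  k1 <- calibrate_k_dna(n_dna = 1, D_0 = 0.006, a = 0.1)
  expect_equal(as.numeric(k1), 0.6)  # D_0 / a^2, exactly
  k0 <- calibrate_k_dna(n_dna = 50, k_s = 0, D_0 = 0.006, a = 0.1)
  expect_equal(as.numeric(k0), 0.6)  # all moves accepted
  kc <- calibrate_k_dna(100)
  expect_identical(kc, calibrate_k_dna(100))  # cached
  expect_gt(as.numeric(kc), 0.6)  # Metropolis rejections must be compensated
})

test_that("ensembles report censoring and initial captures honestly", {
  cfg <- kmc_config(n_cell = 5, n_dna = 10, max_time = 0.5)
  expect_warning(ens <- run_ensemble(cfg, 50, seed = 2), "censored")
  expect_equal(ens$n_censored, sum(is.na(ens$fpt_s)))

  # whole-membrane target: some chains start in contact (fpt = 0)
  ens2 <- run_ensemble(kmc_config(n_cell = 5, n_dna = 30,
                                  mode = "membrane_as_target"), 100, seed = 3)
  expect_gt(ens2$n_initial_capture, 0)
  expect_gt(ens2$mean_positive_s, ens2$mean_s)
  expect_output(print(ens2), "started in contact")
})

test_that("single-site search is invariant under topology and site position", {
  # small system so the suite stays fast; CIs must overlap
  base <- list(n_cell = 5, n_dna = 30, D_2D = 0.2, D_0 = 0.006)
  e_chain <- run_ensemble(do.call(kmc_config, c(base, topology = "linear")),
                          300, seed = 5)
  e_ring <- run_ensemble(do.call(kmc_config, c(base, topology = "ring")),
                         300, seed = 6)
  expect_lt(abs(e_chain$mean_s - e_ring$mean_s),
            2 * sqrt(e_chain$sem_s^2 + e_ring$sem_s^2))

  e_s10 <- run_ensemble(do.call(kmc_config,
                                c(base, topology = "ring", list(sites = 10))),
                        300, seed = 7)
  e_s25 <- run_ensemble(do.call(kmc_config,
                                c(base, topology = "ring", list(sites = 25))),
                        300, seed = 8)
  expect_lt(abs(e_s10$mean_s - e_s25$mean_s),
            3 * sqrt(e_s10$sem_s^2 + e_s25$sem_s^2))
})

test_that("sweeps: search time decreases with protein diffusivity; n_b halves", {
  cfg <- kmc_config(n_cell = 5, n_dna = 30, topology = "ring")
  sw <- sweep_param(cfg, "D_2D", c(0.05, 0.2, 1), n_runs = 200, seed = 9)
  expect_true(all(diff(sw$mean_s) < 0))

  swb <- sweep_param(cfg, "n_b", c(1, 2), n_runs = 400, seed = 10)
  expect_true("mean_ratio" %in% names(swb))
  expect_equal(swb$mean_ratio[1], 1)
  expect_lt(swb$mean_ratio[2], 0.75)  # two antipodal sites: roughly half

  # D_2D = 0 in a sweep equals the immobile-protein mode
  e0 <- run_ensemble(kmc_config(n_cell = 5, n_dna = 30,
                                mode = "immobile_protein"), 200, seed = 11)
  sw0 <- sweep_param(kmc_config(n_cell = 5, n_dna = 30), "D_2D", 0,
                     n_runs = 200, seed = 11)
  expect_lt(abs(sw0$mean_s - e0$mean_s),
            3 * sqrt(sw0$sem_s^2 + e0$sem_s^2))
})

test_that("ensemble CDFs at realistic parameters fit the two-step model", {
  # both species mobile: mixed initial condition fits well
  ens <- run_ensemble(kmc_config(), 600, seed = 13)
  grid <- ensemble_cdf(ens)
  d <- data.frame(time_min = grid$time_s / 60, R = grid$cdf,
                  R_err = pmax(sqrt(grid$cdf * (1 - grid$cdf) / 600), 0.005))
  d <- d[d$time_min > 0, ]
  fit <- fit_response(d, model = "mixed")
  expect_lt(fit$chisq / fit$df, 2)

  # protein-only search: effectively one limiting step, fixed model fits
  ens2 <- run_ensemble(kmc_config(mode = "immobile_dna_membrane_target"),
                       600, seed = 14)
  g2 <- ensemble_cdf(ens2)
  d2 <- data.frame(time_min = g2$time_s / 60, R = g2$cdf,
                   R_err = pmax(sqrt(g2$cdf * (1 - g2$cdf) / 600), 0.005))
  d2 <- d2[d2$time_min > 0, ]
  fit2 <- fit_response(d2, model = "fixed")
  expect_lt(fit2$chisq / fit2$df, 2)
})

test_that("the move-rate table follows the kinetic scheme", {
  # single free bead away from walls: 6 directions at the basal rate
  cfg <- kmc_config(n_dna = 1, n_cell = 10)
  beads <- matrix(c(5L, 5L, 5L), 1)
  rt <- move_rates(beads, c(5L, 5L, 0L), cfg, k_dna = 1.3)
  bead_rates <- rt$rate[rt$species == "bead"]
  expect_equal(bead_rates, rep(1.3, 6))

  # protein at a face centre: exactly 4 allowed moves at D_2D / a^2
  prot <- rt[rt$species == "protein", ]
  expect_equal(sum(prot$rate > 0), 4L)
  expect_equal(max(prot$rate), cfg$D_2D / cfg$a^2)

  # stretching a bond: forward/backward rate ratio is exp(-dU)
  cfg2 <- kmc_config(n_dna = 2, n_cell = 10, k_s = 3)
  b0 <- rbind(c(5L, 5L, 5L), c(6L, 5L, 5L))       # bond length 1
  b1 <- rbind(c(5L, 5L, 5L), c(7L, 5L, 5L))       # bond length 2
  fwd <- move_rates(b0, c(0L, 5L, 5L), cfg2, k_dna = 1)  # move to length 2
  bwd <- move_rates(b1, c(0L, 5L, 5L), cfg2, k_dna = 1)  # move back
  r_fwd <- fwd$rate[fwd$species == "bead" & fwd$index == 2 & fwd$dx == 1]
  r_bwd <- bwd$rate[bwd$species == "bead" & bwd$index == 2 & bwd$dx == -1]
  dU <- spring_energy(b1, 3) - spring_energy(b0, 3)
  expect_equal(r_fwd / r_bwd, exp(-dU))

  # out-of-box moves carry rate zero
  edge <- matrix(c(0L, 5L, 5L), 1)
  rt3 <- move_rates(edge, c(10L, 5L, 5L), cfg, k_dna = 1)
  expect_equal(rt3$rate[rt3$species == "bead" & rt3$dx == -1], 0)
})
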