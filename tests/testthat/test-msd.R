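test_that("spot linking follows greedy nearest-neighbour rules", {
  # one drifting spot -> one full-length track
  sp <- data.frame(frame = 0:9, cell_id = 1,
                   x_um = seq(0, 0.9, by = 0.1), y_um = 0)
  tr <- link_spots(sp, max_disp = 0.5)
  expect_equal(length(unique(tr$track_id)), 1L)

  # a gap terminates the track and starts a new one
  sp2 <- sp[sp$frame != 4, ]
  tr2 <- link_spots(sp2, max_disp = 0.5)
  expect_equal(length(unique(tr2$track_id)), 2L)
  expect_equal(sort(as.integer(table(tr2$track_id))), c(4L, 5L))

  # a jump beyond max_disp starts a new track
  sp3 <- sp
  sp3$x_um[6:10] <- sp3$x_um[6:10] + 5
  tr3 <- link_spots(sp3, max_disp = 0.5)
  expect_equal(length(unique(tr3$track_id)), 2L)

  # two well-separated planted tracks are recovered exactly
  t1 <- data.frame(frame = 0:19, cell_id = 1,
                   x_um = cumsum(c(0, stats::rnorm(19, 0, 0.05))),
                   y_um = 0)
  t2 <- t1; t2$y_um <- 5
  both <- rbind(t1, t2)[sample(40), ]
  lk <- link_spots(both, max_disp = 0.5)
  expect_equal(length(unique(lk$track_id)), 2L)
  expect_true(all(tapply(lk$y_um > 2.5, lk$track_id,
                         function(z) all(z) || all(!z))))
})

test_that("ensemble MSD: closed forms and brute-force oracle", {
  # immobile spot
  still <- data.frame(track_id = 1, frame = 0:9, x_um = 1, y_um = 2)
  m <- ensemble_msd(still, dt = 30)
  expect_true(all(m$msd == 0))

  # deterministic drift: MSD(tau) = v^2 tau^2
  v <- 0.01  # um/s
  dr <- data.frame(track_id = 1, frame = 0:9, x_um = v * 30 * (0:9), y_um = 0)
  m2 <- ensemble_msd(dr, dt = 30)
  expect_equal(m2$msd, v^2 * m2$lag_s^2)
  expect_equal(m2$n_pairs, 9:1)

  # random small input vs brute-force double loop
  set.seed(5)
  tracks <- sim_locus_tracks(Gamma = 0.01, n_tracks = 3, n_frames = 8,
                             seed = 5)
  m3 <- ensemble_msd(tracks, dt = 30)
  bf <- bruteforce_msd(tracks, max_lag = 7, dt = 30)
  expect_equal(m3$msd, unname(bf[, "msd"]))
  expect_equal(m3$n_pairs, unname(as.integer(bf[, "n"])))
})

test_that("MSD fitting recovers exact and sampled scaling laws", {
  lag <- (1:10) * 30
  exact <- data.frame(lag_s = lag, msd = 0.0101 * sqrt(lag), n_pairs = 100)
  fit <- fit_msd(exact)
  expect_equal(fit$Gamma, 0.0101, tolerance = 1e-10)
  ffree <- fit_msd(exact, exponent = "free")
  expect_equal(ffree$exponent, 0.5, tolerance = 1e-8)
  expect_equal(ffree$Gamma, 0.0101, tolerance = 1e-6)
  expect_error(fit_msd(exact[1:2, ]), "3 lags")

  # recovery from generated subdiffusive tracks
  tracks <- sim_locus_tracks(Gamma = 0.010, n_tracks = 500, n_frames = 20,
                             seed = 31)
  curve <- ensemble_msd(tracks)
  f <- fit_msd(curve)
  expect_lt(abs(f$Gamma - 0.010), 2 * max(f$Gamma_se, 0.0005))
  ffr <- fit_msd(curve, exponent = "free")
  expect_lt(abs(ffr$exponent - 0.5), 0.05)
  expect_lt(abs(ffr$Gamma - 0.010) / 0.010, 0.10)

  # weighted and unweighted fits agree within errors on clean data
  fu <- fit_msd(curve, weighted = FALSE)
  expect_lt(abs(f$Gamma - fu$Gamma), 2 * (f$Gamma_se + fu$Gamma_se))
})

test_that("Rouse conversion between Gamma and D0 is exact and homogeneous", {
  expect_equal(rouse_d0(Gamma = (0.0111 + 0.0091) / 2, l_K = 0.1), 0.0060,
               tolerance = 0.01)
  expect_equal(rouse_d0(0), 0)
  set.seed(6)
  for (g in stats::runif(20, 1e-4, 1)) {
    expect_equal(rouse_gamma(rouse_d0(g)), g, tolerance = 1e-12)
    expect_equal(rouse_d0(3 * g), 9 * rouse_d0(g), tolerance = 1e-12)
  }
})

test_that("track generator has the exact fGn covariance and target MSD", {
  # construction check: accumulated increments must reproduce the fBm
  # position covariance 0.5 * msd1 * (s^2H + t^2H - |t-s|^2H)
  n <- 12; H <- 0.25; dt <- 30; msd1 <- 0.005
  C <- fgn_covariance(n, H, msd1, dt)
  A <- matrix(0, n, n)          # accumulation: X_k = sum of increments 1..k
  A[lower.tri(A, diag = TRUE)] <- 1
  P <- A %*% C %*% t(A)         # covariance of positions
  for (i in 1:n) for (j in 1:n) {
    s <- i * dt; t <- j * dt
    expect_equal(P[i, j],
                 0.5 * msd1 * (s^(2 * H) + t^(2 * H) - abs(t - s)^(2 * H)),
                 tolerance = 1e-10)
  }
  expect_equal(P[1, 1], msd1 * dt^(2 * H), tolerance = 1e-12)

  # localization noise adds an offset, Gamma = 0 gives static spots
  st <- sim_locus_tracks(Gamma = 0, n_tracks = 3, n_frames = 5,
                         sigma_loc = 0, seed = 2)
  expect_true(all(st$x_um == 0 & st$y_um == 0))
  stn <- sim_locus_tracks(Gamma = 0, n_tracks = 200, n_frames = 5,
                          sigma_loc = 0.02, seed = 2)
  mn <- ensemble_msd(stn)
  expect_equal(mean(mn$msd), 4 * 0.02^2, tolerance = 0.1)
})
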