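# Numerical-integration moments of the first-passage density: independent
# oracle for the closed forms.
numeric_fpt_moments <- function(alpha, beta, c = 0) {
  m0 <- stats::integrate(function(x) dfpt(x, alpha, beta, c), 0, Inf,
                         rel.tol = 1e-10)$value
  m1 <- stats::integrate(function(x) x * dfpt(x, alpha, beta, c), 0, Inf,
                         rel.tol = 1e-10)$value
  m2 <- stats::integrate(function(x) x^2 * dfpt(x, alpha, beta, c), 0, Inf,
                         rel.tol = 1e-10)$value
  list(norm = m0, mean = m1, var = m2 - m1^2)
}

# Direct Gillespie sampler for the toy system used to validate the
# null-event scheme: one free bead in an L^3 box plus one protein on the
# surface, no springs.  Enumerates the allowed moves in every state.
gillespie_toy <- function(L, k2d, kdna, n_events, seed) {
  set.seed(seed)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  on_surface <- function(p) any(p == 0 | p == L - 1)
  bead <- sample(0:(L - 1), 3, replace = TRUE)
  repeat {
    prot <- sample(0:(L - 1), 3, replace = TRUE)
    if (on_surface(prot)) break
  }
  dwell <- numeric(n_events)
  type <- integer(n_events)
  for (k in seq_len(n_events)) {
    pmoves <- which(apply(dirs, 1, function(d) {
      q <- prot + d
      all(q >= 0 & q < L) && on_surface(q)
    }))
    bmoves <- which(apply(dirs, 1, function(d) {
      q <- bead + d
      all(q >= 0 & q < L)
    }))
    rate <- length(pmoves) * k2d + length(bmoves) * kdna
    dwell[k] <- stats::rexp(1, rate)
    if (stats::runif(1) < length(pmoves) * k2d / rate) {
      prot <- prot + dirs[sample(pmoves, 1), ]
      type[k] <- 0L
    } else {
      bead <- bead + dirs[sample(bmoves, 1), ]
      type[k] <- 1L
    }
  }
  list(dwell = dwell, type = type)
}

# ensemble MSD oracle: brute-force double loop over all origin pairs
bruteforce_msd <- function(tracks, max_lag, dt = 30) {
  ids <- unique(tracks$track_id)
  out <- lapply(seq_len(max_lag), function(lag) {
    d2 <- c()
    for (id in ids) {
      tr <- tracks[tracks$track_id == id, ]
      tr <- tr[order(tr$frame), ]
      for (i in seq_len(nrow(tr))) for (j in seq_len(nrow(tr))) {
        if (tr$frame[j] - tr$frame[i] == lag)
          d2 <- c(d2, (tr$x_um[j] - tr$x_um[i])^2 +
                    (tr$y_um[j] - tr$y_um[i])^2)
      }
    }
    c(lag_s = lag * dt, msd = mean(d2), n = length(d2))
  })
  do.call(rbind, out)
}
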