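test_that("response normalization rescales linearly and catches degeneracy", {
  s <- response_series(c(0, 5, 10), c(0.2, 0.45, 0.7), c(0.01, 0.01, 0.01))
  r <- normalize_response(s, nu_inf = 0.7)
  expect_equal(r$R, c(0, 0.5, 1))
  expect_equal(r$R_err, c(0.01, 0.01, 0.01) / 0.5)
  expect_equal(attr(r, "nu0"), 0.2)

  flat <- response_series(c(0, 5, 10), c(0.3, 0.3, 0.3), c(0.01, 0.01, 0.01))
  expect_error(normalize_response(flat), "degenerate")
  expect_error(normalize_response(s, nu_inf = 0.1), "degenerate")
})

test_that("noise-free curves are recovered to high precision", {
  t <- 0:29
  truth <- c(alpha = 4, beta = 0.5, c = 0.1)
  d <- data.frame(time_min = t,
                  R = pfpt(t, truth["alpha"], truth["beta"], truth["c"]),
                  R_err = rep(0.01, length(t)))
  fit <- fit_response(d, model = "mixed")
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 1e-4)
  expect_lt(fit$chisq, 1e-10)

  # fixed model, noise-free
  d2 <- data.frame(time_min = t, R = pfpt(t, 4, 0.5),
                   R_err = rep(0.01, length(t)))
  fit2 <- fit_response(d2, model = "fixed")
  expect_equal(unname(coef(fit2)), c(4, 0.5), tolerance = 1e-4)
})

test_that("fit returns a sane covariance and delta-method moments", {
  g <- sim_response_counts(alpha = 4, beta = 0.5, c = 0.1, nu0 = 0.2,
                           nu_inf = 0.75, times = 0:19, n_cells = 2000,
                           seed = 4)
  fit <- fit_response(g$series, model = "mixed")
  vc <- vcov(fit)
  expect_true(isSymmetric(vc))
  expect_true(all(eigen(vc, symmetric = TRUE, only.values = TRUE)$values
                  > -1e-12))
  expect_gt(fit$mean_tau[["estimate"]], 0)
  expect_gt(fit$mean_tau[["se"]], 0)

  # analytic moment gradients match finite differences
  p <- c(4.2, 0.6, 0.08)
  g_an <- memsearch:::moment_gradients(p[1], p[2], p[3])
  h <- 1e-6
  for (k in 1:3) {
    pp <- p; pp[k] <- pp[k] + h
    pm <- p; pm[k] <- pm[k] - h
    fd_mean <- (fpt_moments(pp[1], pp[2], pp[3])["mean"] -
                  fpt_moments(pm[1], pm[2], pm[3])["mean"]) / (2 * h)
    fd_var <- (fpt_moments(pp[1], pp[2], pp[3])["var"] -
                 fpt_moments(pm[1], pm[2], pm[3])["var"]) / (2 * h)
    expect_equal(unname(g_an$mean[k]), unname(fd_mean), tolerance = 1e-5)
    expect_equal(unname(g_an$var[k]), unname(fd_var), tolerance = 1e-5)
  }
})

test_that("parameter recovery: generating mean within 2 SE in >= 90% of reps", {
  # the observation window (15 min) ends before full saturation, so the
  # plateau must be fitted rather than plugged in
  truth <- list(alpha = 4.5, beta = 0.3, c = 0.05)
  true_mean <- fpt_moments(truth$alpha, truth$beta, truth$c)["mean"]
  hits <- vapply(1:100, function(i) {
    g <- sim_response_counts(alpha = truth$alpha, beta = truth$beta,
                             c = truth$c, nu0 = 0.2, nu_inf = 0.75,
                             times = 0:14, n_cells = 1000, seed = 1000 + i)
    fit <- tryCatch(
      suppressWarnings(fit_response(g$series, model = "mixed",
                                    nu_inf = "fit")),
      error = function(e) NULL)
    if (is.null(fit)) return(NA)
    abs(fit$mean_tau[["estimate"]] - true_mean) <= 2 * fit$mean_tau[["se"]]
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("the mixed model nests the fixed model (chi-square ordering)", {
  g <- sim_response_counts(alpha = 4, beta = 0.4, c = 0.12, nu0 = 0.2,
                           nu_inf = 0.75, times = 0:14, n_cells = 3000,
                           seed = 9)
  fit_mixed <- fit_response(g$series, model = "mixed")
  fit_fixed <- fit_response(g$series, model = "fixed")
  expect_gt(fit_fixed$chisq, fit_mixed$chisq)
})

test_that("zero error bars get the documented fallback weight", {
  t <- 0:9
  d <- data.frame(time_min = t, R = pfpt(t, 3, 0.5),
                  R_err = c(0, rep(0.02, 9)))
  fit <- fit_response(d, model = "fixed")
  expect_equal(fit$data$R_err[1], 0.01)  # max(sigma)/2
  expect_equal(unname(coef(fit)), c(3, 0.5), tolerance = 1e-3)
})

test_that("fit object methods are consistent", {
  g <- sim_response_counts(seed = 21)
  fit <- fit_response(g$series, model = "mixed")
  expect_s3_class(fit, "fpt_fit")
  expect_equal(length(residuals(fit)), nrow(fit$data))
  expect_equal(predict(fit, 0), 0)
  expect_output(print(fit), "mean search time")
  expect_output(print(summary(fit)), "chi-square")
  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "response_series")

  # round trip through CSV and JSON writers
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time_min = g$series$time_min,
                              nu = g$series$nu,
                              nu_err = g$series$nu_err), tmp,
                   row.names = FALSE)
  s2 <- read_response(tmp)
  expect_equal(s2$nu, g$series$nu)
  tmpj <- tempfile(fileext = ".json")
  write_fpt_fit(fit, tmpj)
  expect_true(grepl("mean_tau", paste(readLines(tmpj), collapse = "")))
})
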