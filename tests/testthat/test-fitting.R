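make_hill_table <- function(ic50, h, n = 8, lo = 0.1, hi = 30) {
  cc <- 10^seq(log10(lo), log10(hi), length.out = n)
  data.frame(conc_uM = cc, inhibition = hill_inhibition(cc, hill_fit(ic50, h)))
}

test_that("Hill fitter recovers noiseless generating parameters", {
  fr <- fit_hill(make_hill_table(1.5, 2.8))
  expect_true(fr$converged)
  expect_lt(rel_err(fr$params$ic50, 1.5), 1e-6)
  expect_lt(rel_err(fr$params$h, 2.8), 1e-6)
  # fixed-slope variant
  fr2 <- fit_hill(make_hill_table(2.1, 3.4), fix_slope = 3.4)
  expect_lt(rel_err(fr2$params$ic50, 2.1), 1e-6)
  expect_true(fr2$params$fixed_slope)
  expect_identical(fr2$params$h, 3.4)
})

test_that("Hill fitter flags degenerate input instead of returning garbage", {
  flat <- data.frame(conc_uM = c(0.1, 1, 10), inhibition = c(0, 0, 0))
  fr <- fit_hill(flat)
  expect_false(fr$converged)
  expect_match(fr$diagnostic, "no concentration dependence")
  expect_error(fit_hill(data.frame(conc_uM = c(1, 10),
                                   inhibition = c(0.2, 0.8))),
               "3 distinct")
  expect_error(fit_hill(data.frame(conc_uM = c(1, 3, 10),
                                   inhibition = c(0.2, 0.5, 1.2))),
               "tolerance")
})

test_that("Boltzmann fitter recovers printed gating parameters from noiseless curves", {
  v <- seq(-120, 10, by = 5)
  avail <- boltzmann_fit(-69.7, 5.0, "availability")
  fr <- fit_boltzmann(data.frame(voltage_mV = v,
                                 response = boltzmann(v, avail)),
                      "availability")
  expect_lt(rel_err(fr$params$v_half, -69.7), 1e-6)
  expect_lt(rel_err(fr$params$k, 5.0), 1e-6)
  va <- seq(-100, 30, by = 5)
  act <- boltzmann_fit(-41.9, 3.6, "activation")
  fr2 <- fit_boltzmann(data.frame(voltage_mV = va,
                                  response = boltzmann(va, act)),
                       "activation")
  expect_lt(rel_err(fr2$params$v_half, -41.9), 1e-6)
  expect_lt(rel_err(fr2$params$k, 3.6), 1e-6)
  expect_error(fit_boltzmann(data.frame(voltage_mV = c(-80, -60),
                                        response = c(0.9, 0.1)),
                             "availability"),
               "4 distinct")
  flat <- fit_boltzmann(data.frame(voltage_mV = v, response = rep(0.5, length(v))),
                        "availability")
  expect_false(flat$converged)
})

test_that("biexponential fitter recovers taus and flags near-mono decays", {
  lg <- 10^seq(log10(1e-3), log10(60), length.out = 20)
  truth <- biexp_fit(0, 1, 1 / 0.272, 1 / 8.72, 50)
  fr <- fit_biexponential(lg, biexp_recovery(lg, truth))
  expect_true(fr$converged)
  expect_lt(rel_err(fr$params$tau_slow, 8.72), 1e-6)
  expect_lt(rel_err(fr$params$tau_fast, 0.272), 1e-6)
  expect_true(fr$params$k_fast >= fr$params$k_slow)
  # single-exponential data are flagged
  mono <- monoexp_fit(0, 1, 1 / 2)
  fr2 <- fit_biexponential(lg, monoexp(lg, mono))
  expect_true(fr2$converged)
  expect_match(fr2$diagnostic, "monoexponential")
  # constant data cannot converge
  fr3 <- fit_biexponential(lg, rep(0.7, 20))
  expect_false(fr3$converged)
  expect_error(fit_biexponential(1:4, 1:4), "6 lag points")
})

test_that("monoexponential fitter reports tau_obs and rejects non-decaying input", {
  t <- 0:120
  for (tau in c(21.6, 51.0)) {
    truth <- monoexp_fit(1, 0.1, 1 / tau)
    fr <- fit_monoexponential(t, monoexp(t, truth))
    expect_true(fr$converged)
    expect_lt(rel_err(fr$params$tau_obs, tau), 1e-6)
    expect_equal(fr$params$tau_obs * fr$params$k, 1)
  }
  fr2 <- fit_monoexponential(t, rep(0.5, length(t)))
  expect_false(fr2$converged)
  rising <- monoexp(t, monoexp_fit(0.1, 1, 1 / 20))
  fr3 <- fit_monoexponential(t, rising)
  expect_false(fr3$converged)
  expect_match(fr3$diagnostic, "decay")
})

test_that("state model fit matches NNLS oracle on measured holding-potential potencies", {
  avail <- boltzmann_fit(-69.7, 5.0, "availability")
  fr <- fit_state_model(c(-100, -90, -80, -70), c(12.7, 10.3, 6.7, 2.9), avail)
  expect_true(fr$converged)
  # frozen oracle values: non-negative linear least squares in 1/IC50 space
  expect_equal(fr$params$kd_rest, 11.8742186, tolerance = 1e-5)
  expect_equal(fr$params$kd_inact, 1.6033274, tolerance = 1e-5)
  expect_equal(fr$fold_ratio, 7.405985, tolerance = 1e-5)
})

test_that("state model fit is exact on self-generated apparent IC50s", {
  avail <- boltzmann_fit(-69.7, 5.0, "availability")
  truth <- state_block_model(12, 1.2, avail)
  vh <- c(-110, -95, -80, -65, -50)
  fr <- fit_state_model(vh, apparent_ic50(vh, truth), avail)
  expect_lt(rel_err(fr$params$kd_rest, 12), 1e-6)
  expect_lt(rel_err(fr$params$kd_inact, 1.2), 1e-6)
  expect_error(fit_state_model(-80, 6.7, avail), "underdetermined")
  expect_error(fit_state_model(c(-200, -190), c(12, 12), avail),
               "underdetermined")
})

test_that("temperature trend is the closed-form OLS line", {
  tr <- fit_ic50_temperature_trend(c(20, 28, 33), c(2.1, 3.4, 4.7))
  expect_gt(tr$slope_uM_per_C, 0)
  expect_equal(tr$slope_uM_per_C, 16.9 / 86, tolerance = 1e-12)
  exact <- fit_ic50_temperature_trend(c(10, 20, 30), c(1, 2, 3))
  expect_equal(exact$residual_ss, 0, tolerance = 1e-20)
  expect_error(fit_ic50_temperature_trend(25, 2), "2 distinct")
})

test_that("all fitters round-trip random parameter sets on noiseless data", {
  set.seed(101)
  for (i in 1:60) {
    ic <- 10^runif(1, -0.7, 1); h <- runif(1, 0.8, 4)
    fr <- fit_hill(make_hill_table(ic, h, n = 10, lo = ic / 30, hi = ic * 30))
    expect_lt(rel_err(fr$params$ic50, ic), 1e-6)
    expect_lt(rel_err(fr$params$h, h), 1e-6)
  }
  set.seed(102)
  v <- seq(-120, 10, by = 5)
  for (i in 1:60) {
    vh <- runif(1, -90, -40); k <- runif(1, 2, 10)
    pol <- sample(c("activation", "availability"), 1)
    fr <- fit_boltzmann(data.frame(voltage_mV = v,
                                   response = boltzmann(v, boltzmann_fit(vh, k, pol))),
                        pol)
    expect_lt(rel_err(fr$params$v_half, vh), 1e-6)
    expect_lt(rel_err(fr$params$k, k), 1e-6)
  }
  set.seed(103)
  lg <- 10^seq(log10(1e-3), log10(60), length.out = 24)
  for (i in 1:40) {
    tau_s <- runif(1, 0.5, 10); tau_f <- tau_s / runif(1, 10, 100)
    pf <- runif(1, 25, 75)
    truth <- biexp_fit(0, 1, 1 / tau_f, 1 / tau_s, pf)
    fr <- fit_biexponential(lg, biexp_recovery(lg, truth))
    expect_lt(rel_err(fr$params$tau_slow, tau_s), 1e-6)
    expect_lt(rel_err(fr$params$tau_fast, tau_f), 1e-6)
    expect_lt(abs(fr$params$percent_fast - pf), 1e-4)
  }
  set.seed(104)
  t <- 0:120
  for (i in 1:40) {
    tau <- runif(1, 5, 60); pl <- runif(1, 0, 0.5)
    truth <- monoexp_fit(1, pl, 1 / tau)
    fr <- fit_monoexponential(t, monoexp(t, truth))
    expect_lt(rel_err(fr$params$tau_obs, tau), 1e-6)
  }
})

test_that("IC50 bias stays small under measurement noise", {
  set.seed(2024)
  truth <- hill_fit(2.5, 2.0)
  cc <- 10^seq(log10(0.3), log10(30), length.out = 8)
  est <- replicate(100, {
    cells <- do.call(rbind, lapply(seq_along(cc), function(j) {
      y <- pmin(pmax(hill_inhibition(cc[j], truth) + rnorm(6, 0, 0.03), 0), 1)
      data.frame(cell_id = sprintf("c%d_%d", j, 1:6), conc_uM = cc[j],
                 inhibition = y)
    }))
    fr <- fit_hill(pool_concentration_response(cells))
    if (fr$converged) fr$params$ic50 else NA_real_
  })
  expect_lt(median(abs(est - 2.5) / 2.5, na.rm = TRUE), 0.10)
})

test_that("fits are deterministic for identical input", {
  tab <- make_hill_table(2.5, 2.0)
  expect_identical(fit_hill(tab), fit_hill(tab))
  lg <- 10^seq(-3, log10(60), length.out = 20)
  y <- biexp_recovery(lg, biexp_fit(0, 1, 4, 0.2, 60))
  expect_identical(fit_biexponential(lg, y), fit_biexponential(lg, y))
})

test_that("seeded bootstrap is reproducible and brackets the pooled fit", {
  set.seed(5)
  truth <- hill_fit(2.5, 2.0)
  cc <- 10^seq(log10(0.3), log10(30), length.out = 6)
  cells <- do.call(rbind, lapply(seq_along(cc), function(j) {
    data.frame(cell_id = sprintf("c%d_%d", j, 1:5), conc_uM = cc[j],
               inhibition = pmin(pmax(hill_inhibition(cc[j], truth) +
                                        rnorm(5, 0, 0.03), 0), 1))
  }))
  tab <- pool_concentration_response(cells)
  b1 <- hill_bootstrap(tab, n_boot = 30, seed = 9)
  b2 <- hill_bootstrap(tab, n_boot = 30, seed = 9)
  expect_identical(b1, b2)
  q <- quantile(b1$ic50, c(0.025, 0.975), na.rm = TRUE)
  expect_true(q[1] < 2.5 && 2.5 < q[2])
})
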