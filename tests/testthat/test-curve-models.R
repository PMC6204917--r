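test_that("Hill inhibition matches its defining properties", {
  f <- hill_fit(ic50 = 1.5, h = 3)
  expect_equal(hill_inhibition(1.5, f), 0.5)
  expect_equal(hill_inhibition(0, f), 0)
  expect_equal(hill_inhibition(3, f), 8 / 9, tolerance = 1e-12)
  # half-maximum is exact for any slope
  for (h in c(0.3, 1, 2.8, 5, 10))
    expect_identical(hill_inhibition(2.1, hill_fit(2.1, h)), 0.5)
  # monotone non-decreasing in concentration
  cc <- sort(runif(50, 0, 50))
  expect_true(all(diff(hill_inhibition(cc, f)) >= 0))
  expect_error(hill_inhibition(-1, f), "non-negative")
  expect_error(hill_fit(-2, 1), "positive")
  expect_error(hill_fit(2, 0), "positive")
})

test_that("Boltzmann curves respect polarity and midpoint", {
  act <- boltzmann_fit(-41.9, 3.6, "activation")
  avail <- boltzmann_fit(-62.0, 7.2, "availability")
  expect_equal(boltzmann(-41.9, act), 0.5)
  expect_equal(boltzmann(-62, avail), 0.5)
  expect_equal(boltzmann(-200, avail), 1, tolerance = 1e-8)
  # printed WT inactivation parameters leave ~8.6% available at -45 mV
  expect_equal(boltzmann(-45, avail), 1 / (1 + exp((-45 + 62) / 7.2)),
               tolerance = 1e-12)
  expect_equal(boltzmann(-45, avail), 0.086, tolerance = 0.01)
  v <- seq(-120, 20, by = 5)
  expect_true(all(diff(boltzmann(v, act)) > 0))
  expect_true(all(diff(boltzmann(v, avail)) < 0))
  expect_error(boltzmann_fit(-60, -1), "positive")
})

test_that("activation and availability with shared parameters are mirror images", {
  set.seed(11)
  for (i in 1:25) {
    vh <- runif(1, -90, -30); k <- runif(1, 1, 12)
    act <- boltzmann_fit(vh, k, "activation")
    avail <- boltzmann_fit(vh, k, "availability")
    vm <- runif(5, -120, 20)
    expect_equal(boltzmann(vm, act) + boltzmann(vm, avail), rep(1, 5),
                 tolerance = 1e-12)
    # reflection through the midpoint maps one onto the other
    expect_equal(boltzmann(2 * vh - vm, avail), boltzmann(vm, act),
                 tolerance = 1e-12)
  }
})

test_that("biexponential evaluation conserves spans and hits its limits", {
  f <- biexp_fit(0, 1, 1 / 0.00173, 1 / 0.0688, 70)
  expect_equal(biexp_recovery(0, f), 0)
  expect_equal(biexp_recovery(1e5, f), 1)
  expect_equal(biexp_recovery(0.01, f), 0.7384, tolerance = 1e-3)
  # span conservation for arbitrary percent_fast
  set.seed(7)
  for (i in 1:20) {
    pf <- runif(1, 0, 100)
    g <- biexp_fit(runif(1, -2, 2), runif(1, -2, 2),
                   runif(1, 1, 50), runif(1, 0.01, 1), pf)
    span <- g$y0 - g$plateau
    sf <- span * g$percent_fast / 100
    ss <- span * (100 - g$percent_fast) / 100
    expect_equal(sf + ss, span, tolerance = 1e-12)
  }
  # rate relabelling keeps k_fast >= k_slow
  g <- biexp_fit(0, 1, k_fast = 0.2, k_slow = 5, percent_fast = 30)
  expect_true(g$k_fast >= g$k_slow)
  expect_equal(g$percent_fast, 70)
  expect_error(biexp_fit(0, 1, 1, 0.1, 120), "0, 100")
  expect_error(biexp_recovery(-1, f), "non-negative")
})

test_that("monoexponential evaluation satisfies tau definition", {
  f <- monoexp_fit(1, 0.2, 1 / 21.6)
  expect_equal(f$tau_obs * f$k, 1)
  expect_equal(monoexp(0, f), 1)
  expect_equal(monoexp(21.6, f), 0.2 + 0.8 / exp(1), tolerance = 1e-12)
  expect_equal(monoexp(1e6, f), 0.2)
  expect_error(monoexp_fit(1, 0, -0.1), "positive")
})

test_that("apparent IC50 interpolates between state affinities", {
  avail <- boltzmann_fit(-69.7, 5.0, "availability")
  m <- state_block_model(12.7, 1.6, avail)
  # printed-parameter check: ~7.1 uM at -80 mV, near the measured 6.7
  expect_equal(apparent_ic50(-80, m), 7.1, tolerance = 0.01)
  expect_equal(apparent_ic50(-200, m), 12.7, tolerance = 1e-6)
  expect_equal(apparent_ic50(100, m), 1.6, tolerance = 1e-6)
  vh <- seq(-120, 0, by = 5)
  app <- apparent_ic50(vh, m)
  expect_true(all(app >= 1.6 - 1e-9 & app <= 12.7 + 1e-9))
  # monotone non-increasing as depolarization raises the inactivated fraction
  expect_true(all(diff(app) <= 1e-12))
  expect_error(state_block_model(12, 1.2, boltzmann_fit(-40, 4, "activation")),
               "availability")
})

test_that("evaluators agree with brute-force formula re-derivation", {
  set.seed(42)
  n <- 1000
  for (i in seq_len(n)) {
    cc <- runif(1, 0, 100); ic <- runif(1, 0.1, 50); h <- runif(1, 0.2, 8)
    expect_equal(hill_inhibition(cc, hill_fit(ic, h)), naive_hill(cc, ic, h),
                 tolerance = 1e-9)
  }
  set.seed(43)
  for (i in 1:250) {
    vm <- runif(1, -130, 40); vh <- runif(1, -90, -30); k <- runif(1, 1, 12)
    pol <- sample(c("activation", "availability"), 1)
    expect_equal(boltzmann(vm, boltzmann_fit(vh, k, pol)),
                 naive_boltzmann(vm, vh, k, pol), tolerance = 1e-12)
  }
  set.seed(44)
  for (i in 1:250) {
    t <- runif(1, 0, 60); kf <- runif(1, 1, 100); ks <- runif(1, 0.01, 1)
    pf <- runif(1, 0, 100); y0 <- runif(1, -1, 1); pl <- runif(1, -1, 1)
    expect_equal(biexp_recovery(t, biexp_fit(y0, pl, kf, ks, pf)),
                 naive_biexp(t, y0, pl, kf, ks, pf), tolerance = 1e-12)
    k <- runif(1, 0.01, 5)
    expect_equal(monoexp(t, monoexp_fit(y0, pl, k)),
                 naive_monoexp(t, y0, pl, k), tolerance = 1e-12)
  }
  set.seed(45)
  for (i in 1:250) {
    vh <- runif(1, -120, -40); kr <- runif(1, 5, 50); ki <- runif(1, 0.1, 5)
    v2 <- runif(1, -80, -50); k <- runif(1, 2, 10)
    m <- state_block_model(kr, ki, boltzmann_fit(v2, k, "availability"))
    expect_equal(apparent_ic50(vh, m), naive_apparent_ic50(vh, kr, ki, v2, k),
                 tolerance = 1e-12)
  }
})

test_that("fit objects round-trip through JSON with unit-bearing names", {
  fits <- list(hill_fit(2.5, 2.0), boltzmann_fit(-69.7, 5, "availability"),
               biexp_fit(0, 1, 1 / 0.272, 1 / 8.72, 50),
               monoexp_fit(1, 0.1, 1 / 21.6),
               state_block_model(12, 1.2,
                                 boltzmann_fit(-69.7, 5, "availability")))
  for (f in fits) {
    js <- write_fit_json(f)
    g <- read_fit_json(js)
    expect_equal(unclass(g)[sort(names(unclass(g)))],
                 unclass(f)[sort(names(unclass(f)))], tolerance = 1e-12)
  }
  expect_match(as.character(write_fit_json(fits[[1]])), "ic50_uM")
  expect_match(as.character(write_fit_json(fits[[2]])), "v_half_mV")
})
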