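#' Seeded synthetic voltage-clamp data generator
#'
#' Generates every table the pipeline consumes, with the statistical
#' structure the analysis assumes: concentration-response plates with one
#' concentration per cell, vehicle wells with exponential rundown and a
#' full-block reference epoch; I/V and steady-state fast-inactivation
#' prepulse families; two-pulse recovery series; block-onset time courses
#' at 1 Hz; and the 180-pulse-per-holding-potential state-dependence
#' protocol. All randomness is controlled by the config seed, so a given
#' config yields bit-identical tables.
#'
#' @name synthetic-data
NULL

#' Synthetic-data configuration
#'
#' The default "true" parameters are the study conditions the generator
#' emulates: low-micromolar Hill-type inhibition with a steep slope, an
#' availability midpoint near -70 mV shifting hyperpolarized ~8 mV under
#' drug, biexponential recovery slowing roughly tenfold under drug, and
#' block-onset equilibration time constants of tens of seconds that
#' saturate at high concentration.
#'
#' @param seed integer seed controlling all randomness
#' @param hill true [hill_fit()] for the compound
#' @param act_vehicle,act_drug activation [boltzmann_fit()] pair
#' @param avail_vehicle,avail_drug availability [boltzmann_fit()] pair
#' @param recovery_vehicle,recovery_drug true [biexp_fit()] pair (10-s
#'   prepulse conditions)
#' @param onset_tau table of block-onset time constants: data.frame with
#'   `temp_C`, `conc_uM`, `tau_s`
#' @param state true [state_block_model()]
#' @param state_h Hill slope applied to equilibrium block in the
#'   state-dependence protocol
#' @param noise_sd Gaussian noise s.d. on normalized currents
#' @param rundown_per_min fractional rundown rate on vehicle/drug wells
#' @param cells_per_conc cells per concentration on a plate
#' @param n_vehicle_cells vehicle wells per plate
#' @param cell_sdlog lognormal s.d. of cell-to-cell amplitude scatter
#' @param qc_fail_rate fraction of cells seeded with a QC failure
#' @param base_peak_pA typical baseline peak magnitude (pA; stored
#'   negative, inward)
#' @param leak_pA residual (full-block) current magnitude (pA)
#' @return an object of class `synth_config`
#' @export
synth_config <- function(
    seed = 1L,
    hill = hill_fit(ic50 = 2.5, h = 2.0),
    act_vehicle = boltzmann_fit(-41.9, 3.6, "activation"),
    act_drug = boltzmann_fit(-40.3, 7.2, "activation"),
    avail_vehicle = boltzmann_fit(-69.7, 5.0, "availability"),
    avail_drug = boltzmann_fit(-77.8, 5.8, "availability"),
    recovery_vehicle = biexp_fit(0, 1, 1 / 0.0715, 1 / 0.696, 50),
    recovery_drug = biexp_fit(0, 1, 1 / 0.272, 1 / 8.72, 50),
    onset_tau = data.frame(
      temp_C = rep(c(20, 28, 33), each = 4),
      conc_uM = rep(c(6.3, 12.5, 25, 50), 3),
      tau_s = c(51.0, 42.2, 21.6, 23.3,
                162.6, 87.7, 42.8, 30.4,
                299.0, 137.0, 79.2, 84.1)),
    state = state_block_model(12, 1.2, boltzmann_fit(-69.7, 5.0, "availability")),
    state_h = 3,
    noise_sd = 0.03,
    rundown_per_min = 0.02,
    cells_per_conc = 6L,
    n_vehicle_cells = 8L,
    cell_sdlog = 0.2,
    qc_fail_rate = 0.1,
    base_peak_pA = 1200,
    leak_pA = 25) {
  stopifnot(noise_sd >= 0, rundown_per_min >= 0, cells_per_conc >= 0,
            cell_sdlog >= 0, qc_fail_rate >= 0, qc_fail_rate <= 1)
  structure(as.list(environment()), class = "synth_config")
}

# column order of the sweep-record exchange table
sweep_columns <- c("cell_id", "well", "protocol", "sweep", "time_s",
                   "holding_mV", "test_mV", "prepulse_ms", "peak_pA",
                   "steady_pA", "temp_C", "compound", "conc_uM", "epoch")

new_sweep_rows <- function(cell_id, well, protocol, sweep, time_s,
                           holding_mV, test_mV, prepulse_ms, peak_pA,
                           steady_pA, temp_C, compound, conc_uM, epoch) {
  data.frame(cell_id = cell_id, well = well, protocol = protocol,
             sweep = sweep, time_s = time_s, holding_mV = holding_mV,
             test_mV = test_mV, prepulse_ms = prepulse_ms,
             peak_pA = peak_pA, steady_pA = steady_pA, temp_C = temp_C,
             compound = compound, conc_uM = conc_uM, epoch = epoch)
}

#' Generate a concentration-response plate
#'
#' Each drug cell receives a single concentration and is recorded through
#' three epochs: a 1-Hz baseline, a drug epoch relaxing exponentially
#' toward the Hill-predicted equilibrium block, and a full-block
#' reference epoch in which only the residual leak current remains.
#' Vehicle wells run the same schedule without block. Rundown acts
#' multiplicatively on the channel current; a leak pedestal is present in
#' every sweep so the full-block reference carries the correct zero of
#' the inhibition scale. Cell QC metrics are attached as attribute
#' `"cells"`, with a configured fraction seeded to fail QC.
#'
#' @param config a [synth_config()]
#' @param concentrations drug concentrations on the plate (uM)
#' @param drug_s duration of the drug epoch (s), sampled at 1 Hz
#' @param tau_s block-onset equilibration time constant (s)
#' @return sweep-record data.frame (see [read_sweep_table()]), with QC
#'   metrics in `attr(, "cells")`
#' @export
gen_plate <- function(config, concentrations = c(0.3, 1, 2, 3.3, 6.6, 10, 20),
                      drug_s = 240, tau_s = 20) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_base <- 10L
  t_base <- 0:(n_base - 1L)
  t_drug <- n_base + 0:(drug_s - 1L)
  t_fb <- max(t_drug) + 1:5
  rd_rate <- config$rundown_per_min / 60  # per second

  make_cell <- function(cell_id, well, conc, compound) {
    amp <- config$base_peak_pA * exp(stats::rnorm(1, 0, config$cell_sdlog))
    y_eq <- if (conc > 0) hill_inhibition(conc, config$hill) else 0
    onset <- monoexp_fit(1, 1 - y_eq, 1 / tau_s)
    frac_base <- rep(1, n_base)
    frac_drug <- monoexp(t_drug - n_base, onset)
    chan <- amp * c(frac_base, frac_drug) *
      exp(-rd_rate * c(t_base, t_drug))
    noise <- stats::rnorm(length(chan), 0, config$noise_sd) * amp
    peaks <- -(chan + config$leak_pA) + noise
    fb_peaks <- -(config$leak_pA) +
      stats::rnorm(length(t_fb), 0, config$noise_sd) * amp
    new_sweep_rows(
      cell_id = cell_id, well = well, protocol = "conc_response",
      sweep = seq_len(n_base + length(t_drug) + length(t_fb)),
      time_s = c(t_base, t_drug, t_fb),
      holding_mV = -45, test_mV = -20, prepulse_ms = 0,
      peak_pA = c(peaks, fb_peaks), steady_pA = 0, temp_C = 28,
      compound = compound, conc_uM = conc,
      epoch = c(rep("baseline", n_base), rep("drug", length(t_drug)),
                rep("full_block", length(t_fb))))
  }

  cells <- list(); qc <- list(); idx <- 0L
  for (conc in concentrations) {
    for (j in seq_len(config$cells_per_conc)) {
      idx <- idx + 1L
      id <- sprintf("C%03d", idx)
      cells[[idx]] <- make_cell(id, well = sprintf("W%03d", idx),
                                conc = conc, compound = "drug")
    }
  }
  for (j in seq_len(config$n_vehicle_cells)) {
    idx <- idx + 1L
    id <- sprintf("C%03d", idx)
    cells[[idx]] <- make_cell(id, well = sprintf("W%03d", idx),
                              conc = 0, compound = "vehicle")
  }
  tab <- do.call(rbind, cells)
  rownames(tab) <- NULL

  ids <- unique(tab$cell_id)
  fail <- stats::runif(length(ids)) < config$qc_fail_rate
  base_peak <- vapply(ids, function(id) {
    g <- tab[tab$cell_id == id & tab$epoch == "baseline", ]
    mean(g$peak_pA)
  }, numeric(1))
  qc <- data.frame(
    cell_id = ids,
    rm_MOhm = ifelse(fail, stats::runif(length(ids), 100, 450),
                     stats::runif(length(ids), 600, 2000)),
    rs_MOhm = stats::runif(length(ids), 3, 8),
    cap_pF = stats::runif(length(ids), 8, 20),
    baseline_peak_pA = base_peak)
  attr(tab, "cells") <- qc
  tab
}

#' Generate an I/V or SSFI gating family
#'
#' Activation families sweep test potentials -100 to +80 mV in 5-mV
#' steps; peak currents follow \eqn{G_{max} \cdot act(V) (V - E_{Na})}.
#' SSFI families precondition from -120 to +10 mV and report the test-
#' pulse current proportional to availability. Noise is additive Gaussian
#' on the normalized response.
#'
#' @param config a [synth_config()]
#' @param kind `"activation"` or `"ssfi"`
#' @param condition `"vehicle"` or `"drug"`
#' @param e_na_mV sodium reversal potential (mV)
#' @param gmax_nS maximal conductance (nS)
#' @param prepulse_ms SSFI prepulse duration (protocol metadata)
#' @return sweep-record data.frame
#' @export
gen_gating_family <- function(config, kind = c("activation", "ssfi"),
                              condition = c("vehicle", "drug"),
                              e_na_mV = 65, gmax_nS = 10,
                              prepulse_ms = 500) {
  kind <- match.arg(kind)
  condition <- match.arg(condition)
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  if (kind == "activation") {
    v <- seq(-100, 80, by = 5)
    act <- if (condition == "vehicle") config$act_vehicle else config$act_drug
    g <- gmax_nS * boltzmann(v, act)
    peaks <- g * (v - e_na_mV) +
      stats::rnorm(length(v), 0, config$noise_sd) * gmax_nS * abs(e_na_mV)
    new_sweep_rows(
      cell_id = "G001", well = "W001", protocol = "iv_family",
      sweep = seq_along(v), time_s = seq_along(v) - 1,
      holding_mV = -120, test_mV = v, prepulse_ms = 0,
      peak_pA = peaks, steady_pA = 0, temp_C = 22,
      compound = condition, conc_uM = if (condition == "drug") 3.3 else 0,
      epoch = "gating")
  } else {
    v <- seq(-120, 10, by = 5)
    avail <- if (condition == "vehicle") config$avail_vehicle else config$avail_drug
    imax <- -config$base_peak_pA
    peaks <- imax * boltzmann(v, avail) +
      stats::rnorm(length(v), 0, config$noise_sd) * abs(imax)
    new_sweep_rows(
      cell_id = "G001", well = "W001", protocol = "ssfi",
      sweep = seq_along(v), time_s = seq_along(v) - 1,
      holding_mV = -120, test_mV = -20, prepulse_ms = prepulse_ms,
      peak_pA = peaks, steady_pA = 0, temp_C = 22,
      compound = condition, conc_uM = if (condition == "drug") 3.3 else 0,
      epoch = "gating")
  }
}

#' Normalize an SSFI family to a gating curve
#'
#' @param sweeps output of [gen_gating_family()] with `protocol ==
#'   "ssfi"` (or any table with `test_mV`-tagged prepulse voltages; for
#'   SSFI rows the prepulse voltage is the sweep's conditioning voltage,
#'   reconstructed from the sweep order)
#' @param voltages the conditioning voltages, in sweep order
#' @return a `gating_curve` (availability)
#' @export
ssfi_curve <- function(sweeps, voltages = seq(-120, 10, by = 5)) {
  stopifnot(nrow(sweeps) == length(voltages))
  resp <- abs(sweeps$peak_pA)
  gating_curve(voltages, resp / max(resp), kind = "availability")
}

#' Generate a recovery-from-inactivation series
#'
#' Two-pulse protocol: recovered fraction at log-spaced lags (1 ms to
#' 60 s) follows the configured biexponential.
#'
#' @param config a [synth_config()]
#' @param condition `"vehicle"` or `"drug"`
#' @param prepulse_s conditioning prepulse duration (s), metadata
#' @param n_lags number of log-spaced lags
#' @return data.frame with `lag_s`, `fraction`, `prepulse_s`, `condition`
#' @export
gen_recovery_series <- function(config, condition = c("vehicle", "drug"),
                                prepulse_s = 10, n_lags = 20L) {
  condition <- match.arg(condition)
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  fit <- if (condition == "vehicle") config$recovery_vehicle else config$recovery_drug
  if (abs(fit$y0 - fit$plateau) < 1e-12)
    warning("degenerate recovery configuration: zero span")
  lags <- 10^seq(log10(1e-3), log10(60), length.out = n_lags)
  frac <- biexp_recovery(lags, fit) + stats::rnorm(n_lags, 0, config$noise_sd)
  data.frame(lag_s = lags, fraction = frac, prepulse_s = prepulse_s,
             condition = condition)
}

#' Generate block-onset time courses
#'
#' Normalized current sampled at 1 Hz after compound addition decays
#' monoexponentially toward the Hill-predicted equilibrium, with the
#' observed time constant drawn from the configured
#' temperature-by-concentration map (which saturates at a minimum at
#' high concentration rather than decreasing indefinitely).
#'
#' @param config a [synth_config()]
#' @param concentrations concentrations to simulate (uM); must appear in
#'   `config$onset_tau` for the chosen temperature
#' @param temp_C recording temperature (degrees C)
#' @param duration_s sampling duration (s)
#' @return data.frame with `time_s`, `norm_current`, `conc_uM`, `temp_C`
#' @export
gen_onset_series <- function(config, concentrations = c(6.3, 12.5, 25, 50),
                             temp_C = 20, duration_s = 120) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 3L)
  map <- config$onset_tau[config$onset_tau$temp_C == temp_C, , drop = FALSE]
  if (nrow(map) == 0L) stop("no onset tau map entries at ", temp_C, " C")
  out <- lapply(concentrations, function(cc) {
    i <- which(map$conc_uM == cc)
    if (length(i) == 0L)
      stop("no onset tau entry for ", cc, " uM at ", temp_C, " C")
    y_eq <- 1 - hill_inhibition(cc, config$hill)
    fit <- monoexp_fit(1, y_eq, 1 / map$tau_s[i])
    t <- 0:duration_s
    data.frame(time_s = t,
               norm_current = monoexp(t, fit) +
                 stats::rnorm(length(t), 0, config$noise_sd),
               conc_uM = cc, temp_C = temp_C)
  })
  do.call(rbind, out)
}

#' Generate a pulse-train state-dependence run
#'
#' 180 depolarizing pulses at 1 Hz at each of four holding potentials
#' (-100, -90, -80, -70 mV). At each holding potential the per-pulse peak
#' relaxes exponentially toward the equilibrium block given by the Hill
#' equation evaluated at the state model's apparent IC50 for that
#' voltage; with the default 30-s equilibration time constant the
#' 180th pulse sits within a fraction of a percent of equilibrium.
#'
#' @param config a [synth_config()]
#' @param concentrations compound concentrations simulated (uM)
#' @param holdings holding potentials (mV)
#' @param n_pulses pulses per holding potential (1 Hz)
#' @param tau_s equilibration time constant of block development (s)
#' @return data.frame with `holding_mV`, `conc_uM`, `pulse`, `time_s`,
#'   `norm_current`
#' @export
gen_state_dependence_run <- function(config,
                                     concentrations = c(1, 3.3, 10, 30),
                                     holdings = c(-100, -90, -80, -70),
                                     n_pulses = 180L, tau_s = 30) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 4L)
  out <- list(); k <- 0L
  for (vh in holdings) {
    ic50_app <- apparent_ic50(vh, config$state)
    for (cc in concentrations) {
      y_eq <- hill_inhibition(cc, hill_fit(ic50_app, config$state_h))
      t <- seq_len(n_pulses) - 1L
      frac <- 1 - y_eq * (1 - exp(-t / tau_s))
      k <- k + 1L
      out[[k]] <- data.frame(
        holding_mV = vh, conc_uM = cc, pulse = seq_len(n_pulses),
        time_s = t,
        norm_current = frac + stats::rnorm(n_pulses, 0, config$noise_sd))
    }
  }
  do.call(rbind, out)
}

#' Apparent IC50s from a state-dependence run
#'
#' For each (holding potential, concentration) pulse train, the
#' equilibrium fractional block is read from the plateau of a
#' monoexponential fit to the train (removing any residual
#' under-equilibration at the final pulse; if that fit fails, the final
#' pulse is used directly). The per-voltage blocks are then fit with a
#' Hill curve, yielding the apparent IC50 at each holding potential —
#' the measured input to [fit_state_model()].
#'
#' @param run output of [gen_state_dependence_run()]
#' @param fix_slope optional Hill slope to fix during the per-voltage fits
#' @return data.frame with `holding_mV` and `ic50_uM`
#' @export
state_run_ic50 <- function(run, fix_slope = NULL) {
  stopifnot(all(c("holding_mV", "conc_uM", "pulse", "time_s",
                  "norm_current") %in% names(run)))
  eq_block <- function(g) {
    y <- g$norm_current[order(g$pulse)]
    tail_mean <- mean(utils::tail(y, 30))
    fr <- tryCatch(fit_monoexponential(g$time_s, g$norm_current),
                   error = function(e) NULL)
    if (!is.null(fr) && fr$converged) {
      pl <- fr$params$plateau
      # guard against plateau extrapolation on noise-dominated flat trains
      margin <- 0.1 * diff(range(y))
      if (pl >= min(y) - margin && pl <= max(y) + margin) return(1 - pl)
    }
    1 - tail_mean
  }
  out <- lapply(split(run, run$holding_mV), function(h) {
    trains <- split(h, h$conc_uM)
    tab <- data.frame(
      conc_uM = vapply(trains, function(g) g$conc_uM[1], numeric(1)),
      inhibition = pmin(pmax(vapply(trains, eq_block, numeric(1)), 0), 1))
    g <- h
    fr <- fit_hill(tab, fix_slope = fix_slope)
    if (!fr$converged) stop("Hill fit failed at ", g$holding_mV[1], " mV")
    data.frame(holding_mV = g$holding_mV[1], ic50_uM = fr$params$ic50)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$holding_mV), , drop = FALSE]
}
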