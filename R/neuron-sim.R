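#' Modified Hodgkin-Huxley simulation of cortical-neuron excitability
#'
#' Single-compartment conductance-based model with the classic m^3 h
#' sodium and n^4 potassium current structure, but with the gating
#' steady states re-parameterized as Boltzmann functions so that
#' experimentally fitted midpoints and slopes (voltage dependence of
#' activation and steady-state fast inactivation) plug in directly.
#' Gating time constants use bell-shaped voltage dependences with
#' defaults in the cortical-pyramidal range. A drug condition is applied
#' as fractional conductance block plus a shift of the inactivation
#' midpoint.
#'
#' @name neuron-sim
NULL

#' Construct a cortical-neuron Hodgkin-Huxley model
#'
#' Defaults: conductance densities and reversals typical of a regular-
#' spiking cortical pyramidal cell; sodium activation and inactivation
#' midpoints/slopes from whole-cell measurements of neuronal Nav current
#' (activation V1/2 = -41.9 mV, k = 3.6 mV; inactivation V1/2 = -69.7 mV,
#' k = 5.0 mV).
#'
#' @param c_m membrane capacitance (uF/cm^2)
#' @param g_na,g_k,g_leak maximal conductance densities (mS/cm^2)
#' @param e_na,e_k,e_leak reversal potentials (mV)
#' @param na_act,na_inact sodium activation/inactivation steady states,
#'   `list(v_half, k)` in mV
#' @param k_act potassium activation steady state, `list(v_half, k)`
#' @param tau tau-curve parameters: each gate has a bell-shaped
#'   \eqn{\tau(V) = base + amp / \cosh((V - v_mid)/v_scale)} in ms
#' @return an object of class `neuron_model`
#' @export
neuron_model <- function(c_m = 1,
                         g_na = 56, g_k = 6, g_leak = 0.0205,
                         e_na = 50, e_k = -90, e_leak = -70.3,
                         na_act = list(v_half = -41.9, k = 3.6),
                         na_inact = list(v_half = -69.7, k = 5.0),
                         k_act = list(v_half = -25, k = 12),
                         tau = list(
                           m = list(base = 0.04, amp = 0.10, v_mid = -40, v_scale = 15),
                           h = list(base = 0.80, amp = 6.0, v_mid = -65, v_scale = 15),
                           n = list(base = 1.00, amp = 4.0, v_mid = -30, v_scale = 25))) {
  stopifnot(c_m > 0, g_na >= 0, g_k >= 0, g_leak >= 0)
  structure(list(c_m = c_m, g_na = g_na, g_k = g_k, g_leak = g_leak,
                 e_na = e_na, e_k = e_k, e_leak = e_leak,
                 na_act = na_act, na_inact = na_inact, k_act = k_act,
                 tau = tau),
            class = "neuron_model")
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("HH neuron model: gNa = %.3g, gK = %.3g, gL = %.3g mS/cm^2\n",
              x$g_na, x$g_k, x$g_leak))
  cat(sprintf("  Na act V1/2 = %.1f mV (k = %.1f); inact V1/2 = %.1f mV (k = %.1f)\n",
              x$na_act$v_half, x$na_act$k, x$na_inact$v_half, x$na_inact$k))
  invisible(x)
}

#' Apply a drug condition to a neuron model
#'
#' Scales the sodium and potassium conductances by the given block
#' fractions and shifts the sodium inactivation midpoint (negative =
#' hyperpolarizing, stabilizing inactivation). All other parameters are
#' untouched.
#'
#' @param model a [neuron_model()]
#' @param na_block,k_block fraction of conductance blocked, in [0, 1]
#' @param inact_shift_mV shift applied to the Na inactivation V1/2 (mV)
#' @return a modified `neuron_model`
#' @export
apply_drug_condition <- function(model, na_block = 0, k_block = 0,
                                 inact_shift_mV = 0) {
  stopifnot(inherits(model, "neuron_model"))
  if (na_block < 0 || na_block > 1 || k_block < 0 || k_block > 1)
    stop("block fractions must lie in [0, 1]")
  model$g_na <- model$g_na * (1 - na_block)
  model$g_k <- model$g_k * (1 - k_block)
  model$na_inact$v_half <- model$na_inact$v_half + inact_shift_mV
  model
}

#' Stepwise current-injection protocol
#'
#' A series of current steps of increasing intensity, each followed by a
#' recovery gap with no injected current.
#'
#' @param amplitudes step amplitudes (uA/cm^2)
#' @param step_ms step duration (ms)
#' @param gap_ms recovery period after each step (ms)
#' @return an object of class `stimulus_protocol`
#' @export
stimulus_protocol <- function(amplitudes = c(4, 6, 8, 10, 12),
                              step_ms = 100, gap_ms = 50) {
  stopifnot(step_ms > 0, gap_ms >= 0, length(amplitudes) >= 1)
  structure(list(amplitudes = amplitudes, step_ms = step_ms, gap_ms = gap_ms),
            class = "stimulus_protocol")
}

# steady state and tau helpers (vectorized over V)
gate_inf <- function(v, p) 1 / (1 + exp((p$v_half - v) / p$k))
gate_tau <- function(v, p) p$base + p$amp / cosh((v - p$v_mid) / p$v_scale)

#' Simulate the neuron's response to a stimulus protocol
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration. The state
#' starts at `v_init` with gates at their steady-state values there.
#'
#' @param model a [neuron_model()]
#' @param protocol a [stimulus_protocol()]
#' @param dt integration step (ms, <= 0.025)
#' @param v_init initial membrane potential (mV); defaults to `e_leak`
#' @param spike_threshold_mV,dvdt_criterion passed to [detect_spikes()]
#' @return an object of class `sim_result`: list with `time_ms`, `vm_mV`,
#'   `spikes` (data.frame of spike times, peaks, voltage thresholds),
#'   `per_step_counts`, and first-spike summaries
#' @export
simulate_neuron <- function(model, protocol, dt = 0.01, v_init = NULL,
                            spike_threshold_mV = 0, dvdt_criterion = 20) {
  stopifnot(inherits(model, "neuron_model"),
            inherits(protocol, "stimulus_protocol"))
  if (dt > 0.025) stop("fixed-step integrator requires dt <= 0.025 ms")
  if (is.null(v_init)) v_init <- model$e_leak

  period <- protocol$step_ms + protocol$gap_ms
  t_total <- period * length(protocol$amplitudes)
  n <- floor(t_total / dt) + 1L
  times <- (seq_len(n) - 1) * dt
  # piecewise-constant stimulus, precomputed per sample
  phase <- times %% period
  step_idx <- pmin(floor(times / period) + 1L, length(protocol$amplitudes))
  i_stim <- ifelse(phase < protocol$step_ms, protocol$amplitudes[step_idx], 0)

  m <- gate_inf(v_init, model$na_act)
  # h gate follows the availability convention: high at hyperpolarized V
  h <- 1 / (1 + exp((v_init - model$na_inact$v_half) / model$na_inact$k))
  nn <- gate_inf(v_init, model$k_act)
  v <- v_init
  vm <- numeric(n)
  vm[1] <- v

  # scalar parameters hoisted out of the loop; the RK4 stage derivative is
  # inlined for speed (this loop dominates the simulation cost)
  c_m <- model$c_m; g_na <- model$g_na; g_k <- model$g_k; g_l <- model$g_leak
  e_na <- model$e_na; e_k <- model$e_k; e_l <- model$e_leak
  vm_a <- model$na_act$v_half; km_a <- model$na_act$k
  vh_i <- model$na_inact$v_half; kh_i <- model$na_inact$k
  vn_a <- model$k_act$v_half; kn_a <- model$k_act$k
  tm <- model$tau$m; th <- model$tau$h; tn <- model$tau$n

  dstate <- function(v, m, h, nn, I) {
    dv <- (I - g_na * m * m * m * h * (v - e_na) -
             g_k * nn * nn * nn * nn * (v - e_k) - g_l * (v - e_l)) / c_m
    dm <- (1 / (1 + exp((vm_a - v) / km_a)) - m) /
      (tm$base + tm$amp / cosh((v - tm$v_mid) / tm$v_scale))
    dh <- (1 / (1 + exp((v - vh_i) / kh_i)) - h) /
      (th$base + th$amp / cosh((v - th$v_mid) / th$v_scale))
    dn <- (1 / (1 + exp((vn_a - v) / kn_a)) - nn) /
      (tn$base + tn$amp / cosh((v - tn$v_mid) / tn$v_scale))
    list(dv, dm, dh, dn)
  }

  half <- 0.5 * dt
  for (i in 2:n) {
    I <- i_stim[i - 1L]
    k1 <- dstate(v, m, h, nn, I)
    k2 <- dstate(v + half * k1[[1]], m + half * k1[[2]],
                 h + half * k1[[3]], nn + half * k1[[4]], I)
    k3 <- dstate(v + half * k2[[1]], m + half * k2[[2]],
                 h + half * k2[[3]], nn + half * k2[[4]], I)
    k4 <- dstate(v + dt * k3[[1]], m + dt * k3[[2]], h + dt * k3[[3]],
                 nn + dt * k3[[4]], i_stim[i])
    v <- v + dt * (k1[[1]] + 2 * k2[[1]] + 2 * k3[[1]] + k4[[1]]) / 6
    m <- m + dt * (k1[[2]] + 2 * k2[[2]] + 2 * k3[[2]] + k4[[2]]) / 6
    h <- h + dt * (k1[[3]] + 2 * k2[[3]] + 2 * k3[[3]] + k4[[3]]) / 6
    nn <- nn + dt * (k1[[4]] + 2 * k2[[4]] + 2 * k3[[4]] + k4[[4]]) / 6
    if (!is.finite(v))
      stop(sprintf("integration failure (non-finite state) at t = %.3f ms",
                   times[i]))
    vm[i] <- v
  }

  spikes <- detect_spikes(times, vm, threshold_mV = spike_threshold_mV,
                          dvdt_criterion = dvdt_criterion)
  step_of <- function(t) pmin(floor(t / period) + 1L, length(protocol$amplitudes))
  counts <- tabulate(step_of(spikes$time_ms), nbins = length(protocol$amplitudes))
  structure(list(time_ms = times, vm_mV = vm, spikes = spikes,
                 per_step_counts = counts,
                 first_spike_peak_mV = if (nrow(spikes)) spikes$peak_mV[1] else NA_real_,
                 first_spike_threshold_mV = if (nrow(spikes)) spikes$threshold_mV[1] else NA_real_,
                 protocol = protocol, dt = dt),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation: %.0f ms, %d spikes (per step: %s)\n",
              max(x$time_ms), nrow(x$spikes),
              paste(x$per_step_counts, collapse = ", ")))
  if (nrow(x$spikes))
    cat(sprintf("  first spike: peak %.1f mV, threshold %.1f mV\n",
                x$first_spike_peak_mV, x$first_spike_threshold_mV))
  invisible(x)
}

#' Detect action potentials in a voltage trace
#'
#' A spike is an upward crossing of the voltage threshold separated from
#' the previous spike by at least the refractory interval. The per-spike
#' voltage threshold is the membrane potential where dV/dt first exceeds
#' the criterion on the upstroke; the peak is the local maximum before
#' the trace falls back below the crossing threshold.
#'
#' @param time_ms uniformly sampled times (ms)
#' @param vm_mV membrane potential (mV)
#' @param threshold_mV crossing threshold for spike detection (mV)
#' @param dvdt_criterion upstroke criterion for the voltage threshold
#'   (mV/ms)
#' @param refractory_ms minimal separation between spikes (ms)
#' @return data.frame with `time_ms`, `peak_mV`, `threshold_mV`
#' @export
detect_spikes <- function(time_ms, vm_mV, threshold_mV = 0,
                          dvdt_criterion = 20, refractory_ms = 1) {
  stopifnot(length(time_ms) == length(vm_mV))
  n <- length(vm_mV)
  empty <- data.frame(time_ms = numeric(), peak_mV = numeric(),
                      threshold_mV = numeric())
  if (n < 3L) return(empty)
  dt <- time_ms[2] - time_ms[1]
  up <- which(vm_mV[-n] < threshold_mV & vm_mV[-1] >= threshold_mV) + 1L
  if (length(up) == 0L) return(empty)
  keep <- c(TRUE, diff(time_ms[up]) >= refractory_ms)
  up <- up[keep]
  dvdt <- c(diff(vm_mV) / dt, 0)
  out <- lapply(up, function(i) {
    # peak: local max until the trace falls back below threshold
    j <- i
    while (j < n && vm_mV[j + 1L] >= threshold_mV) j <- j + 1L
    peak <- max(vm_mV[i:j])
    # threshold: walk back to the start of the upstroke, then forward to
    # the first dV/dt crossing of the criterion
    a <- i
    while (a > 1L && dvdt[a - 1L] >= dvdt_criterion) a <- a - 1L
    thr <- vm_mV[a]
    data.frame(time_ms = time_ms[i], peak_mV = peak, threshold_mV = thr)
  })
  do.call(rbind, out)
}
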