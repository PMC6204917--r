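#' Parametric models for voltage-clamp pharmacology
#'
#' Constructors and evaluators for every parametric model used by the
#' analysis: the Hill-Langmuir concentration-response curve, Boltzmann
#' gating curves (activation and steady-state fast-inactivation
#' availability), mono- and biexponential time courses, and the
#' resting/inactivated two-receptor-state model of voltage-dependent
#' apparent potency.
#'
#' Units are fixed package-wide: membrane potentials in mV, concentrations
#' in uM, time in s for kinetics, currents in pA, capacitance in pF.
#' All fractions live in [0, 1]; percentages appear only at I/O boundaries.
#'
#' @name curve-models
NULL

#' Hill-Langmuir concentration-response parameters
#'
#' Describes fractional inhibition as a function of compound concentration,
#' \deqn{Y(C) = C^h / (IC_{50}^h + C^h),}
#' where \eqn{IC_{50}} is the half-maximal inhibitory concentration and
#' \eqn{h} the Hill coefficient. Steep slopes (\eqn{h > 1}) indicate that
#' more than one compound interaction contributes to inhibition.
#'
#' @param ic50 half-maximal inhibitory concentration (uM, > 0)
#' @param h Hill coefficient (dimensionless, > 0)
#' @param fixed_slope logical; was `h` held constant during fitting?
#' @return an object of class `hill_fit`
#' @export
#' @examples
#' f <- hill_fit(ic50 = 2.5, h = 2.0)
#' hill_inhibition(2.5, f)  # 0.5 by definition
hill_fit <- function(ic50, h, fixed_slope = FALSE) {
  stopifnot(is.numeric(ic50), length(ic50) == 1L, is.finite(ic50),
            is.numeric(h), length(h) == 1L, is.finite(h))
  if (ic50 <= 0) stop("`ic50` must be positive (uM)")
  if (h <= 0) stop("Hill coefficient `h` must be positive")
  structure(list(ic50 = ic50, h = h, fixed_slope = isTRUE(fixed_slope)),
            class = "hill_fit")
}

#' Fractional inhibition from the Hill-Langmuir equation
#'
#' @param conc compound concentration(s), uM, >= 0
#' @param fit a [hill_fit()] object
#' @return fraction inhibited in [0, 1], same length as `conc`
#' @export
hill_inhibition <- function(conc, fit) {
  stopifnot(inherits(fit, "hill_fit"), is.numeric(conc))
  if (any(conc < 0)) stop("concentration must be non-negative")
  out <- numeric(length(conc))
  pos <- conc > 0
  # logistic-in-log form is exact at conc = ic50 and overflow-safe
  out[pos] <- 1 / (1 + exp(fit$h * (log(fit$ic50) - log(conc[pos]))))
  out
}

#' Boltzmann gating-curve parameters
#'
#' Two-state voltage dependence \eqn{1 / (1 + \exp[(V_{1/2} - V_m)/k])}
#' with `polarity` fixing the sign convention: activation curves rise with
#' depolarization (normalized conductance G/Gmax), availability curves
#' (steady-state fast inactivation, I/Imax) fall with depolarization. The
#' slope factor `k` is always positive so fitted slopes stay comparable
#' between the two conventions.
#'
#' @param v_half midpoint voltage (mV)
#' @param k slope factor (mV, > 0)
#' @param polarity `"activation"` or `"availability"`
#' @return an object of class `boltzmann_fit`
#' @export
boltzmann_fit <- function(v_half, k, polarity = c("activation", "availability")) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(v_half), length(v_half) == 1L, is.finite(v_half),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (k <= 0) stop("slope factor `k` must be positive (mV)")
  structure(list(v_half = v_half, k = k, polarity = polarity),
            class = "boltzmann_fit")
}

#' Evaluate a Boltzmann gating curve
#'
#' @param vm membrane potential(s), mV
#' @param fit a [boltzmann_fit()] object
#' @return fraction in [0, 1]; 0.5 at `vm = v_half`
#' @export
boltzmann <- function(vm, fit) {
  stopifnot(inherits(fit, "boltzmann_fit"), is.numeric(vm))
  x <- (vm - fit$v_half) / fit$k
  if (fit$polarity == "availability") x <- -x
  1 / (1 + exp(-x))
}

#' Biexponential time-course parameters
#'
#' Two-component exponential relaxation used for recovery from
#' inactivation,
#' \deqn{Y(t) = Plateau + Span_{fast} e^{-K_{fast} t} + Span_{slow} e^{-K_{slow} t},}
#' with the spans partitioning the total amplitude:
#' \eqn{Span_{fast} = (Y_0 - Plateau) \cdot PercentFast/100} and
#' \eqn{Span_{slow} = (Y_0 - Plateau)(100 - PercentFast)/100}. Components
#' are labelled so that `k_fast >= k_slow`; time constants are
#' \eqn{\tau = 1/K}.
#'
#' @param y0 signal at t = 0
#' @param plateau asymptotic signal
#' @param k_fast fast rate constant (1/s, > 0)
#' @param k_slow slow rate constant (1/s, > 0)
#' @param percent_fast percent of the span in the fast component (0-100)
#' @return an object of class `biexp_fit`
#' @export
biexp_fit <- function(y0, plateau, k_fast, k_slow, percent_fast) {
  stopifnot(is.numeric(y0), is.numeric(plateau), is.numeric(k_fast),
            is.numeric(k_slow), is.numeric(percent_fast))
  if (k_fast <= 0 || k_slow <= 0) stop("rate constants must be positive (1/s)")
  if (percent_fast < 0 || percent_fast > 100)
    stop("`percent_fast` must lie in [0, 100]")
  if (k_fast < k_slow) {  # relabel so the fast component is the fast one
    tmp <- k_fast; k_fast <- k_slow; k_slow <- tmp
    percent_fast <- 100 - percent_fast
  }
  structure(list(y0 = y0, plateau = plateau, k_fast = k_fast,
                 k_slow = k_slow, percent_fast = percent_fast,
                 tau_fast = 1 / k_fast, tau_slow = 1 / k_slow),
            class = "biexp_fit")
}

#' Evaluate a biexponential recovery curve
#'
#' @param t time(s) since repolarization, s, >= 0
#' @param fit a [biexp_fit()] object
#' @return signal value(s); `y0` at t = 0, `plateau` as t grows
#' @export
biexp_recovery <- function(t, fit) {
  stopifnot(inherits(fit, "biexp_fit"), is.numeric(t))
  if (any(t < 0)) stop("time must be non-negative")
  span <- fit$y0 - fit$plateau
  span_fast <- span * fit$percent_fast * 0.01
  span_slow <- span * (100 - fit$percent_fast) * 0.01
  fit$plateau + span_fast * exp(-fit$k_fast * t) + span_slow * exp(-fit$k_slow * t)
}

#' Monoexponential time-course parameters
#'
#' Single exponential relaxation \eqn{Y(t) = (Y_0 - Plateau) e^{-Kt} + Plateau}
#' used for block-onset time courses; the observed equilibration time
#' constant is \eqn{\tau_{obs} = 1/K}.
#'
#' @param y0 signal at t = 0
#' @param plateau asymptote
#' @param k rate constant (1/s, > 0)
#' @return an object of class `monoexp_fit` with derived `tau_obs`
#' @export
monoexp_fit <- function(y0, plateau, k) {
  stopifnot(is.numeric(y0), is.numeric(plateau), is.numeric(k))
  if (k <= 0) stop("rate constant `k` must be positive (1/s)")
  structure(list(y0 = y0, plateau = plateau, k = k, tau_obs = 1 / k),
            class = "monoexp_fit")
}

#' Evaluate a monoexponential curve
#'
#' @param t time(s), s, >= 0
#' @param fit a [monoexp_fit()] object
#' @return signal value(s)
#' @export
monoexp <- function(t, fit) {
  stopifnot(inherits(fit, "monoexp_fit"), is.numeric(t))
  if (any(t < 0)) stop("time must be non-negative")
  (fit$y0 - fit$plateau) * exp(-fit$k * t) + fit$plateau
}

#' Resting/inactivated state-dependent block model
#'
#' Two-receptor-state equilibrium in which the compound binds resting
#' channels with dissociation constant `kd_rest` and inactivated channels
#' with `kd_inact`. The fraction of channels resting at a holding potential
#' is given by the availability Boltzmann; the apparent dissociation
#' constant is the availability-weighted harmonic combination
#' \deqn{1/K_{app}(V) = f_{rest}(V)/K_r + (1 - f_{rest}(V))/K_i,}
#' so the apparent potency at any voltage lies between the two state
#' affinities and tracks the inactivated fraction.
#'
#' @param kd_rest resting-state dissociation constant (uM, > 0)
#' @param kd_inact inactivated-state dissociation constant (uM, > 0)
#' @param availability a [boltzmann_fit()] with polarity `"availability"`
#' @return an object of class `state_block_model`
#' @export
state_block_model <- function(kd_rest, kd_inact, availability) {
  stopifnot(is.numeric(kd_rest), is.numeric(kd_inact),
            inherits(availability, "boltzmann_fit"))
  if (kd_rest <= 0 || kd_inact <= 0)
    stop("dissociation constants must be positive (uM)")
  kd_rest <- unname(kd_rest)
  kd_inact <- unname(kd_inact)
  if (availability$polarity != "availability")
    stop("`availability` must have polarity \"availability\"")
  structure(list(kd_rest = kd_rest, kd_inact = kd_inact,
                 availability = availability),
            class = "state_block_model")
}

#' Apparent IC50 at a holding potential
#'
#' @param vh holding potential(s), mV
#' @param model a [state_block_model()] object
#' @return apparent IC50 (uM), bounded by `kd_rest` and `kd_inact`
#' @export
apparent_ic50 <- function(vh, model) {
  stopifnot(inherits(model, "state_block_model"), is.numeric(vh))
  f_rest <- boltzmann(vh, model$availability)
  1 / (f_rest / model$kd_rest + (1 - f_rest) / model$kd_inact)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill-Langmuir fit: IC50 = %.4g uM, h = %.4g%s\n",
              x$ic50, x$h, if (x$fixed_slope) " (slope fixed)" else ""))
  invisible(x)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann %s curve: V1/2 = %.4g mV, k = %.4g mV\n",
              x$polarity, x$v_half, x$k))
  invisible(x)
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "Biexponential fit: tau_fast = %.4g s, tau_slow = %.4g s, %.1f%% fast\n",
    x$tau_fast, x$tau_slow, x$percent_fast))
  cat(sprintf("  y0 = %.4g, plateau = %.4g\n", x$y0, x$plateau))
  invisible(x)
}

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("Monoexponential fit: tau_obs = %.4g s (y0 = %.4g, plateau = %.4g)\n",
              x$tau_obs, x$y0, x$plateau))
  invisible(x)
}

#' @export
print.state_block_model <- function(x, ...) {
  cat(sprintf(
    "State-dependent block model: Kd(rest) = %.4g uM, Kd(inact) = %.4g uM (%.3g-fold)\n",
    x$kd_rest, x$kd_inact, x$kd_rest / x$kd_inact))
  cat(sprintf("  availability: V1/2 = %.4g mV, k = %.4g mV\n",
              x$availability$v_half, x$availability$k))
  invisible(x)
}
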