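# Brute-force re-derivations of the model formulas, written directly from
# their algebraic definitions and kept independent of the package
# evaluators they check.

naive_hill <- function(c, ic50, h) c^h / (ic50^h + c^h)

naive_boltzmann <- function(vm, v_half, k, polarity) {
  if (polarity == "activation") 1 / (1 + exp((v_half - vm) / k))
  else 1 / (1 + exp((vm - v_half) / k))
}

naive_biexp <- function(t, y0, plateau, k_fast, k_slow, percent_fast) {
  span_fast <- (y0 - plateau) * percent_fast * 0.01
  span_slow <- (y0 - plateau) * (100 - percent_fast) * 0.01
  plateau + span_fast * exp(-k_fast * t) + span_slow * exp(-k_slow * t)
}

naive_monoexp <- function(t, y0, plateau, k) {
  (y0 - plateau) * exp(-k * t) + plateau
}

naive_apparent_ic50 <- function(vh, kd_rest, kd_inact, v_half, k) {
  f_rest <- 1 / (1 + exp((vh - v_half) / k))
  1 / (f_rest / kd_rest + (1 - f_rest) / kd_inact)
}

# relative error helper
rel_err <- function(est, truth) abs(est - truth) / abs(truth)
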