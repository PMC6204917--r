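#' Plate pipeline: raw per-sweep records to pooled response tables
#'
#' Turns per-sweep peak-current records from automated patch-clamp plates
#' into QC-filtered, vehicle-corrected, pooled concentration-response and
#' gating tables. Inward sodium currents are stored negative; all block
#' fractions are computed on current magnitudes, so the pipeline is
#' invariant to an overall sign or scale change.
#'
#' @name plate-pipeline
NULL

#' Quality-control filter for recorded cells
#'
#' Applies the standard automated patch-clamp inclusion filters: membrane
#' resistance above 500 MOhm, series resistance below 10 MOhm, and a
#' baseline peak current magnitude above 500 pA. Each excluded cell is
#' labelled with every filter it failed.
#'
#' @param cells data.frame with columns `cell_id`, `rm_MOhm`, `rs_MOhm`,
#'   `baseline_peak_pA` (and optionally `cap_pF`)
#' @param rm_min_MOhm,rs_max_MOhm,min_peak_pA filter thresholds
#' @return list with data.frames `included` and `excluded`; `excluded`
#'   gains a `reason` column
#' @export
qc_filter <- function(cells, rm_min_MOhm = 500, rs_max_MOhm = 10,
                      min_peak_pA = 500) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "rm_MOhm", "rs_MOhm", "baseline_peak_pA") %in%
                  names(cells)))
  reasons <- vapply(seq_len(nrow(cells)), function(i) {
    r <- character()
    if (cells$rm_MOhm[i] <= rm_min_MOhm) r <- c(r, "membrane resistance")
    if (cells$rs_MOhm[i] >= rs_max_MOhm) r <- c(r, "series resistance")
    if (abs(cells$baseline_peak_pA[i]) <= min_peak_pA)
      r <- c(r, "current magnitude")
    paste(r, collapse = "; ")
  }, character(1))
  bad <- nzchar(reasons)
  excluded <- cells[bad, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reasons[bad]
  else excluded$reason <- character(0)
  list(included = cells[!bad, , drop = FALSE], excluded = excluded)
}

#' Fractional inhibition with vehicle-rundown correction
#'
#' Computes the inhibited fraction of the blockable current, referencing
#' the full-block current (e.g. saturating TTX) as the zero of the scale
#' and scaling the baseline by the time-matched fractional current
#' remaining on vehicle wells:
#' \deqn{Y = (|I_{base}| d - |I_{drug}|) / (|I_{base}| d - |I_{full}|),}
#' clipped to [0, 1]. Works on magnitudes, so it is invariant to current
#' sign and to any common scale factor.
#'
#' @param baseline_pA peak current before compound addition
#' @param drug_pA peak current at maximal inhibition
#' @param full_block_pA residual current in the full-block reference
#' @param vehicle_decay fractional current remaining on time-matched
#'   vehicle wells (1 = no rundown)
#' @param clip clip the result to [0, 1] (default); disable to study the
#'   unclipped estimator, e.g. when averaging vehicle wells whose true
#'   inhibition is zero
#' @return fraction inhibited (in [0, 1] when `clip = TRUE`)
#' @export
fraction_inhibition <- function(baseline_pA, drug_pA, full_block_pA,
                                vehicle_decay = 1, clip = TRUE) {
  b <- abs(baseline_pA) * vehicle_decay
  d <- abs(drug_pA)
  fb <- abs(full_block_pA)
  if (any(b <= fb))
    stop("baseline (after vehicle correction) must exceed the full-block reference")
  y <- (b - d) / (b - fb)
  if (clip) pmin(pmax(y, 0), 1) else y
}

#' Pool per-cell inhibition into a concentration-response table
#'
#' Each cell contributes a single concentration (the single-concentration-
#' per-cell plate design); per-concentration means and the per-cell
#' provenance points are both retained, sorted by concentration.
#'
#' @param records data.frame with columns `cell_id`, `conc_uM`,
#'   `inhibition`
#' @return an object of class `conc_response`: list with `pooled`
#'   (`conc_uM`, `mean_inhibition`, `n_cells`) and `cells` data.frames
#' @export
pool_concentration_response <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    out <- list(pooled = data.frame(conc_uM = numeric(), mean_inhibition = numeric(),
                                    n_cells = integer()),
                cells = records)
    return(structure(out, class = "conc_response"))
  }
  stopifnot(all(c("cell_id", "conc_uM", "inhibition") %in% names(records)))
  per_cell <- tapply(records$conc_uM, records$cell_id,
                     function(x) length(unique(x)))
  if (any(per_cell > 1L))
    stop("each cell must carry exactly one concentration; offending cell(s): ",
         paste(names(per_cell)[per_cell > 1L], collapse = ", "))
  cells <- records[order(records$conc_uM, records$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  agg <- stats::aggregate(inhibition ~ conc_uM, data = cells, FUN = mean)
  n <- stats::aggregate(inhibition ~ conc_uM, data = cells, FUN = length)
  pooled <- data.frame(conc_uM = agg$conc_uM, mean_inhibition = agg$inhibition,
                       n_cells = as.integer(n$inhibition))
  pooled <- pooled[order(pooled$conc_uM), , drop = FALSE]
  rownames(pooled) <- NULL
  structure(list(pooled = pooled, cells = cells), class = "conc_response")
}

#' @export
print.conc_response <- function(x, ...) {
  cat(sprintf("Concentration-response table: %d concentrations, %d cells\n",
              nrow(x$pooled), nrow(x$cells)))
  print(x$pooled)
  invisible(x)
}

#' Construct a gating curve
#'
#' @param voltage_mV voltages (mV)
#' @param response normalized response (max 1)
#' @param kind `"activation"` or `"availability"`
#' @return a `gating_curve` data.frame with attribute `kind`
#' @export
gating_curve <- function(voltage_mV, response,
                         kind = c("activation", "availability")) {
  kind <- match.arg(kind)
  stopifnot(length(voltage_mV) == length(response))
  if (abs(max(response) - 1) > 1e-9)
    stop("response must be normalized to a maximum of 1")
  structure(data.frame(voltage_mV = voltage_mV, response = response),
            kind = kind, class = c("gating_curve", "data.frame"))
}

#' Conductance transform of an I/V family
#'
#' Converts peak currents to chord conductances, \eqn{G = I/(V - E_{rev})},
#' drops any point at the reversal potential with a warning, and
#' normalizes to the maximum conductance, yielding an activation gating
#' curve.
#'
#' @param voltage_mV test potentials (mV)
#' @param current_pA peak currents (pA)
#' @param e_rev_mV reversal (Nernst) potential (mV)
#' @return a `gating_curve` (activation) with extra column `g_nS`
#' @export
conductance_transform <- function(voltage_mV, current_pA, e_rev_mV) {
  stopifnot(length(voltage_mV) == length(current_pA))
  at_rev <- voltage_mV == e_rev_mV
  if (any(at_rev)) {
    warning("dropping ", sum(at_rev), " point(s) at the reversal potential")
    voltage_mV <- voltage_mV[!at_rev]
    current_pA <- current_pA[!at_rev]
  }
  g <- current_pA / (voltage_mV - e_rev_mV)  # pA/mV = nS
  if (all(abs(g) < 1e-12)) stop("all-zero currents: no conductance to normalize")
  gc <- gating_curve(voltage_mV, g / max(g), kind = "activation")
  gc$g_nS <- g
  gc
}

#' Current density
#'
#' @param peak_pA peak current (pA)
#' @param cap_pF membrane capacitance (pF, > 0)
#' @return current density (pA/pF)
#' @export
current_density <- function(peak_pA, cap_pF) {
  if (any(cap_pF <= 0)) stop("capacitance must be positive (pF)")
  peak_pA / cap_pF
}

#' Percent block from mean current densities
#'
#' @param vehicle_density,drug_density mean current densities (pA/pF)
#' @return percent block, \eqn{100 (1 - drug/vehicle)}
#' @export
percent_block_from_densities <- function(vehicle_density, drug_density) {
  if (any(vehicle_density == 0)) stop("vehicle density must be non-zero")
  100 * (1 - drug_density / vehicle_density)
}

#' Signed midpoint shift between two Boltzmann fits
#'
#' @param fit_a,fit_b [boltzmann_fit()] objects of the same polarity
#'   (e.g. vehicle and drug conditions)
#' @return `fit_b$v_half - fit_a$v_half` (mV); negative values are
#'   hyperpolarizing shifts
#' @export
v_half_shift <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "boltzmann_fit"), inherits(fit_b, "boltzmann_fit"))
  if (fit_a$polarity != fit_b$polarity)
    stop("cannot compare fits of different polarity")
  fit_b$v_half - fit_a$v_half
}

#' Peak and persistent current from a depolarizing-step trace
#'
#' Peak is the extremum (largest magnitude) within the first 10 ms of the
#' step; persistent current is the mean over the final 10% of the step, a
#' standard window for the non-inactivating component.
#'
#' @param time_ms sample times within the step (ms, from 0)
#' @param current_pA current samples (pA)
#' @param peak_window_ms window for the peak search (ms)
#' @param persist_fraction trailing fraction of the step averaged for the
#'   persistent current
#' @return list with `peak_pA` and `persistent_pA`
#' @export
measure_peak_and_persistent <- function(time_ms, current_pA,
                                        peak_window_ms = 10,
                                        persist_fraction = 0.1) {
  stopifnot(length(time_ms) == length(current_pA))
  dur <- max(time_ms) - min(time_ms)
  if (dur < 100)
    stop("depolarizing step must be at least 100 ms for persistent-current analysis")
  t0 <- min(time_ms)
  early <- time_ms <= t0 + peak_window_ms
  peak <- current_pA[early][which.max(abs(current_pA[early]))]
  late <- time_ms >= t0 + (1 - persist_fraction) * dur
  list(peak_pA = peak, persistent_pA = mean(current_pA[late]))
}

#' Per-cell inhibition from a raw sweep table
#'
#' Reduces a concentration-response plate's sweep records to one
#' inhibition fraction per drug cell: the baseline is the mean magnitude
#' of the last 5 baseline-epoch sweeps, maximal inhibition the mean of the
#' last 3 drug-epoch sweeps, the full-block reference the mean of the
#' cell's full-block epoch, and the vehicle rundown correction is the
#' pooled fractional current remaining on vehicle wells, linearly
#' interpolated at the drug cell's measurement time.
#'
#' @param sweeps a sweep-record data.frame (see [read_sweep_table()] for
#'   the schema); vehicle wells are rows with `compound == "vehicle"`
#' @param n_baseline,n_drug number of trailing sweeps averaged per epoch
#' @param clip clip per-cell fractions to [0, 1] (default)
#' @return data.frame with columns `cell_id`, `conc_uM`, `inhibition`
#' @export
plate_inhibition <- function(sweeps, n_baseline = 5, n_drug = 3, clip = TRUE) {
  stopifnot(is.data.frame(sweeps),
            all(c("cell_id", "time_s", "peak_pA", "compound", "conc_uM",
                  "epoch") %in% names(sweeps)))
  tail_mean <- function(x, n) mean(utils::tail(x, n))
  per_cell <- function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    base <- g[g$epoch == "baseline", , drop = FALSE]
    drug <- g[g$epoch == "drug", , drop = FALSE]
    fb <- g[g$epoch == "full_block", , drop = FALSE]
    if (nrow(base) == 0L || nrow(drug) == 0L)
      stop("cell ", g$cell_id[1], " lacks baseline or drug epoch")
    data.frame(cell_id = g$cell_id[1],
               compound = g$compound[1],
               conc_uM = g$conc_uM[1],
               baseline_pA = tail_mean(abs(base$peak_pA), n_baseline),
               drug_pA = tail_mean(abs(drug$peak_pA), n_drug),
               t_meas_s = tail_mean(drug$time_s, n_drug),
               full_block_pA = if (nrow(fb)) mean(abs(fb$peak_pA)) else 0)
  }
  summ <- do.call(rbind, lapply(split(sweeps, sweeps$cell_id), per_cell))
  veh <- summ[summ$compound == "vehicle", , drop = FALSE]
  drug <- summ[summ$compound != "vehicle", , drop = FALSE]
  if (nrow(drug) == 0L)
    return(data.frame(cell_id = character(), conc_uM = numeric(),
                      inhibition = numeric()))
  decay_at <- vehicle_decay_curve(sweeps, veh)
  out <- data.frame(cell_id = drug$cell_id, conc_uM = drug$conc_uM,
                    inhibition = NA_real_)
  for (i in seq_len(nrow(drug))) {
    out$inhibition[i] <- fraction_inhibition(
      drug$baseline_pA[i], drug$drug_pA[i], drug$full_block_pA[i],
      vehicle_decay = decay_at(drug$t_meas_s[i]), clip = clip)
  }
  rownames(out) <- NULL
  out
}

# pooled fractional current remaining on vehicle wells as a function of
# time; returns an interpolator (constant 1 when no vehicle wells exist)
vehicle_decay_curve <- function(sweeps, veh_summary) {
  if (nrow(veh_summary) == 0L) return(function(t) 1)
  veh_rows <- sweeps[sweeps$compound == "vehicle" & sweeps$epoch == "drug", ,
                     drop = FALSE]
  base <- veh_summary$baseline_pA[match(veh_rows$cell_id, veh_summary$cell_id)]
  frac <- abs(veh_rows$peak_pA) / base
  tt <- veh_rows$time_s
  agg <- stats::aggregate(frac, by = list(t = round(tt, 6)), FUN = mean)
  function(t) stats::approx(agg$t, agg$x, xout = t, rule = 2)$y
}

#' Vehicle-corrected pooled inhibition for a whole plate
#'
#' Convenience wrapper: [plate_inhibition()] then
#' [pool_concentration_response()] on the drug wells.
#'
#' @inheritParams plate_inhibition
#' @return a `conc_response` object
#' @export
analyze_plate <- function(sweeps) {
  pool_concentration_response(plate_inhibition(sweeps))
}
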