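#' Nonlinear least-squares estimation of the parametric models
#'
#' Every fitter uses deterministic, data-derived initial values (no random
#' starts), Levenberg-Marquardt least squares with strictly positive
#' parameters handled on the log scale, and returns a [fit_result()]
#' carrying the fitted model, residual sum of squares and diagnostics.
#' Identical inputs therefore produce identical outputs.
#'
#' @name fitting
NULL

#' Container for a fit outcome
#'
#' @param params fitted model object (or NULL when not converged)
#' @param residual_ss residual sum of squares
#' @param n_points number of data points used
#' @param converged logical
#' @param init named list, the deterministic initial guess
#' @param diagnostic character; reason when `converged` is FALSE, or flags
#'   such as `"effectively monoexponential"`
#' @return an object of class `fit_result`
#' @export
fit_result <- function(params, residual_ss, n_points, converged,
                       init = NULL, diagnostic = NA_character_) {
  stopifnot(is.logical(converged), length(converged) == 1L)
  if (!converged && is.na(diagnostic))
    stop("non-converged results must carry a diagnostic")
  structure(list(params = params, residual_ss = residual_ss,
                 n_points = n_points, converged = converged,
                 init = init, diagnostic = diagnostic),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Converged fit (n = %d, RSS = %.4g)\n", x$n_points, x$residual_ss))
    print(x$params)
    if (!is.na(x$diagnostic)) cat("note:", x$diagnostic, "\n")
  } else {
    cat(sprintf("Fit did not converge (n = %d): %s\n", x$n_points, x$diagnostic))
  }
  invisible(x)
}

# Levenberg-Marquardt on a residual function with optim(BFGS) fallback.
# `par` is the unconstrained (log-transformed where needed) parameter vector.
lm_minimize <- function(resid_fun, par) {
  ans <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-15, ptol = 1e-15, maxiter = 500)),
    error = function(e) NULL)
  if (!is.null(ans) && all(is.finite(ans$par)))
    return(list(par = ans$par, rss = sum(resid_fun(ans$par)^2), ok = TRUE))
  obj <- function(p) sum(resid_fun(p)^2)
  ans <- tryCatch(
    stats::optim(par, obj, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 2000)),
    error = function(e) NULL)
  if (!is.null(ans) && all(is.finite(ans$par)))
    return(list(par = ans$par, rss = obj(ans$par), ok = TRUE))
  list(par = par, rss = NA_real_, ok = FALSE)
}

# deterministic half-crossing initializer: x where y crosses `level`,
# by linear interpolation on the (optionally log-transformed) x axis
half_crossing <- function(x, y, level = 0.5, logx = FALSE) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (logx) x <- log(x)
  s <- y - level
  idx <- which(s[-length(s)] * s[-1] <= 0 & s[-length(s)] != s[-1])
  if (length(idx) == 0L) {
    est <- mean(range(x))
  } else {
    i <- idx[1]
    est <- x[i] + (level - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
  }
  if (logx) exp(est) else est
}

#' Fit the Hill-Langmuir equation to pooled concentration-response data
#'
#' Minimizes squared error of the Hill equation against normalized
#' inhibition fractions, pooling either per-concentration means (default,
#' matching analysis of single-concentration-per-cell plate data) or all
#' per-cell points. IC50 is initialized by log-interpolating the
#' concentration bracketing 50% inhibition; the slope starts at 1 unless
#' fixed.
#'
#' @param table a `conc_response` object from
#'   [pool_concentration_response()], or a data.frame with columns
#'   `conc_uM` and `inhibition`
#' @param fix_slope optional Hill coefficient to hold constant
#' @param use_cells logical; fit all per-cell points instead of
#'   per-concentration means (only meaningful for `conc_response` input)
#' @return a [fit_result()] containing a [hill_fit()]
#' @export
#' @examples
#' tt <- hill_fit(ic50 = 1.5, h = 2.8)
#' cc <- 10^seq(log10(0.1), log10(30), length.out = 8)
#' fit_hill(data.frame(conc_uM = cc, inhibition = hill_inhibition(cc, tt)))
fit_hill <- function(table, fix_slope = NULL, use_cells = FALSE) {
  if (inherits(table, "conc_response")) {
    df <- if (use_cells) table$cells else table$pooled
    y <- if (use_cells) df$inhibition else df$mean_inhibition
    conc <- df$conc_uM
  } else {
    stopifnot(is.data.frame(table), all(c("conc_uM", "inhibition") %in% names(table)))
    conc <- table$conc_uM
    y <- table$inhibition
  }
  keep <- conc > 0
  conc <- conc[keep]; y <- y[keep]
  n <- length(y)
  need <- if (is.null(fix_slope)) 3L else 2L
  if (length(unique(conc)) < need)
    stop(sprintf("need at least %d distinct positive concentrations", need))
  if (any(y < -0.02 | y > 1.02))
    stop("inhibition values outside [0, 1] beyond the 0.02 clipping tolerance")
  y <- pmin(pmax(y, 0), 1)

  init_list <- list(ic50 = half_crossing(conc, y, 0.5, logx = TRUE),
                    h = if (is.null(fix_slope)) 1 else fix_slope)
  # degenerate input: no concentration dependence to fit
  means <- tapply(y, conc, mean)
  if (diff(range(means)) < 0.05 ||
      stats::cor(log(conc), y) < 0.1) {
    return(fit_result(NULL, NA_real_, n, FALSE, init_list,
                      "no concentration dependence"))
  }

  if (is.null(fix_slope)) {
    resid <- function(p) {
      f <- hill_fit(exp(p[1]), exp(p[2]))
      y - hill_inhibition(conc, f)
    }
    par0 <- c(log(init_list$ic50), log(init_list$h))
  } else {
    stopifnot(fix_slope > 0)
    resid <- function(p) {
      f <- hill_fit(exp(p[1]), fix_slope)
      y - hill_inhibition(conc, f)
    }
    par0 <- log(init_list$ic50)
  }
  ans <- lm_minimize(resid, par0)
  if (!ans$ok)
    return(fit_result(NULL, NA_real_, n, FALSE, init_list, "optimizer failure"))
  fit <- if (is.null(fix_slope))
    hill_fit(exp(ans$par[1]), exp(ans$par[2]))
  else
    hill_fit(exp(ans$par[1]), fix_slope, fixed_slope = TRUE)
  fit_result(fit, ans$rss, n, TRUE, init_list)
}

#' Fit a Boltzmann function to a gating curve
#'
#' Initial midpoint from the half-maximum crossing; initial slope from the
#' 10-90% transition width (which equals \eqn{k \ln 81} for a Boltzmann).
#'
#' @param curve a `gating_curve` object or data.frame with columns
#'   `voltage_mV` and `response` (normalized, 0-1)
#' @param polarity `"activation"` or `"availability"`; defaults to the
#'   curve's own `kind` when present
#' @param free_scale fit a free amplitude in front of the Boltzmann
#'   (default TRUE): max-normalized curves from protocols that do not fully
#'   saturate are then recovered without truncation bias; the amplitude is
#'   reported as `scale` on the result
#' @return a [fit_result()] containing a [boltzmann_fit()]
#' @export
fit_boltzmann <- function(curve, polarity = NULL, free_scale = TRUE) {
  if (inherits(curve, "gating_curve") && is.null(polarity))
    polarity <- attr(curve, "kind")
  polarity <- match.arg(polarity, c("activation", "availability"))
  stopifnot(is.data.frame(curve),
            all(c("voltage_mV", "response") %in% names(curve)))
  v <- curve$voltage_mV
  y <- curve$response
  n <- length(y)
  if (length(unique(v)) < 4L)
    stop("need at least 4 distinct voltages spanning the transition")
  init <- list(v_half = half_crossing(v, y, 0.5),
               k = max(abs(half_crossing(v, y, 0.9) -
                           half_crossing(v, y, 0.1)) / log(81), 0.5))
  if (diff(range(y)) < 0.1)
    return(fit_result(NULL, NA_real_, n, FALSE, init, "flat gating curve"))
  if (free_scale) {
    resid <- function(p)
      y - exp(p[3]) * boltzmann(v, boltzmann_fit(p[1], exp(p[2]), polarity))
    par0 <- c(init$v_half, log(init$k), 0)
  } else {
    resid <- function(p)
      y - boltzmann(v, boltzmann_fit(p[1], exp(p[2]), polarity))
    par0 <- c(init$v_half, log(init$k))
  }
  ans <- lm_minimize(resid, par0)
  if (!ans$ok)
    return(fit_result(NULL, NA_real_, n, FALSE, init, "optimizer failure"))
  res <- fit_result(boltzmann_fit(ans$par[1], exp(ans$par[2]), polarity),
                    ans$rss, n, TRUE, init)
  res$scale <- if (free_scale) exp(ans$par[3]) else 1
  res
}

#' Fit a biexponential recovery-from-inactivation time course
#'
#' Parameterized as (y0, plateau, log rates, logit fraction-fast) with the
#' rates relabelled after convergence so `k_fast >= k_slow`. Initial rates
#' come from a log-linear regression on the tail (slow component) with the
#' fast rate started an order of magnitude above. When the span of the
#' minor component is under 1% of the total, the result is flagged
#' `"effectively monoexponential"`.
#'
#' @param lags recovery lag times (s), >= 6 points, ideally log-spaced
#' @param fractions recovered fraction at each lag
#' @return a [fit_result()] containing a [biexp_fit()]
#' @export
fit_biexponential <- function(lags, fractions) {
  stopifnot(is.numeric(lags), is.numeric(fractions),
            length(lags) == length(fractions))
  o <- order(lags)
  t <- lags[o]; y <- fractions[o]
  n <- length(y)
  if (n < 6L) stop("need at least 6 lag points")
  init <- biexp_init(t, y)
  if (diff(range(y)) < 1e-8)
    return(fit_result(NULL, NA_real_, n, FALSE, init, "constant signal"))
  resid <- function(p) {
    pf <- 100 / (1 + exp(-p[5]))  # logit-parameterized percent fast
    y - biexp_recovery(t, biexp_fit(p[1], p[2], exp(p[3]), exp(p[4]), pf))
  }
  par0 <- c(init$y0, init$plateau, log(init$k_fast), log(init$k_slow),
            stats::qlogis(min(max(init$percent_fast / 100, 0.05), 0.95)))
  ans <- lm_minimize(resid, par0)
  if (!ans$ok)
    return(fit_result(NULL, NA_real_, n, FALSE, init, "optimizer failure"))
  pf <- 100 / (1 + exp(-ans$par[5]))
  fit <- biexp_fit(ans$par[1], ans$par[2], exp(ans$par[3]), exp(ans$par[4]), pf)
  flag <- NA_character_
  minor <- min(fit$percent_fast, 100 - fit$percent_fast)
  if (minor < 1 || fit$k_fast / fit$k_slow < 1 + 1e-6)
    flag <- "effectively monoexponential"
  fit_result(fit, ans$rss, n, TRUE, init, flag)
}

# deterministic biexponential initializer: plateau from the longest lag,
# slow rate from a log-linear regression on the tail of |y - plateau|
biexp_init <- function(t, y) {
  plateau <- y[length(y)]
  y0 <- y[1]
  dev <- abs(y - plateau)
  tail_idx <- which(t > stats::median(t) & dev > 1e-6 * max(dev, 1e-12))
  k_slow <- if (length(tail_idx) >= 2) {
    sl <- stats::coef(stats::lm(log(dev[tail_idx]) ~ t[tail_idx]))[2]
    max(-as.numeric(sl), 1e-3)
  } else 1 / max(t)
  list(y0 = y0, plateau = plateau, k_fast = 10 * k_slow, k_slow = k_slow,
       percent_fast = 50)
}

#' Fit a single-exponential block-onset time course
#'
#' @param times time since compound addition (s), >= 5 points
#' @param signal normalized current (or any exponentially relaxing signal)
#' @return a [fit_result()] containing a [monoexp_fit()]; the observed
#'   equilibration time constant is `params$tau_obs = 1/k`
#' @export
fit_monoexponential <- function(times, signal) {
  stopifnot(is.numeric(times), is.numeric(signal),
            length(times) == length(signal))
  o <- order(times)
  t <- times[o]; y <- signal[o]
  n <- length(y)
  if (n < 5L) stop("need at least 5 time points")
  plateau0 <- y[length(y)]
  dev <- abs(y - plateau0)
  init <- list(y0 = y[1], plateau = plateau0,
               k = {
                 idx <- which(dev > 1e-6 * max(dev, 1e-12))
                 if (length(idx) >= 2) {
                   sl <- stats::coef(stats::lm(log(dev[idx]) ~ t[idx]))[2]
                   max(-as.numeric(sl), 1e-4)
                 } else 1 / max(t[t > 0], 1)
               })
  if (diff(range(y)) < 1e-8)
    return(fit_result(NULL, NA_real_, n, FALSE, init, "constant signal"))
  resid <- function(p) y - monoexp(t, monoexp_fit(p[1], p[2], exp(p[3])))
  ans <- lm_minimize(resid, c(init$y0, init$plateau, log(init$k)))
  if (!ans$ok)
    return(fit_result(NULL, NA_real_, n, FALSE, init, "optimizer failure"))
  fit <- monoexp_fit(ans$par[1], ans$par[2], exp(ans$par[3]))
  if (fit$y0 < fit$plateau)
    return(fit_result(NULL, ans$rss, n, FALSE, init, "signal does not decay"))
  fit_result(fit, ans$rss, n, TRUE, init)
}

#' Fit the resting/inactivated state-dependent block model
#'
#' Linear least squares in inverse-IC50 space: with resting fraction
#' \eqn{f(V)} from the supplied availability Boltzmann,
#' \eqn{1/IC_{50}(V) = f(V)/K_r + (1-f(V))/K_i}, solved for the positive
#' inverse affinities. When the unconstrained solution leaves the positive
#' orthant, the fit is repeated on log-transformed affinities.
#'
#' @param holding_mV holding potentials (mV)
#' @param ic50_uM apparent IC50 measured at each holding potential (uM)
#' @param availability a [boltzmann_fit()] with polarity `"availability"`
#' @return a [fit_result()] containing a [state_block_model()]; the
#'   resting/inactivated affinity ratio is reported as `fold_ratio`
#' @export
fit_state_model <- function(holding_mV, ic50_uM, availability) {
  stopifnot(is.numeric(holding_mV), is.numeric(ic50_uM),
            length(holding_mV) == length(ic50_uM),
            inherits(availability, "boltzmann_fit"),
            availability$polarity == "availability")
  if (any(ic50_uM <= 0)) stop("apparent IC50 values must be positive")
  n <- length(ic50_uM)
  f <- boltzmann(holding_mV, availability)
  if (length(unique(round(f, 10))) < 2L)
    stop("underdetermined: all holding potentials give the same availability")
  yinv <- 1 / ic50_uM
  X <- cbind(rest = f, inact = 1 - f)
  beta <- stats::lm.fit(X, yinv)$coefficients
  init <- list(kd_rest = NA_real_, kd_inact = NA_real_)
  if (all(is.finite(beta)) && all(beta > 0)) {
    rss <- sum((yinv - X %*% beta)^2)
    par <- log(1 / beta)
  } else {
    par <- log(c(max(ic50_uM), min(ic50_uM)))
    rss <- NA_real_
  }
  # polish (or rescue) on the log scale to guarantee positivity
  resid <- function(p) yinv - (f * exp(-p[1]) + (1 - f) * exp(-p[2]))
  ans <- lm_minimize(resid, par)
  if (!ans$ok)
    return(fit_result(NULL, NA_real_, n, FALSE, init, "optimizer failure"))
  model <- state_block_model(exp(ans$par[1]), exp(ans$par[2]), availability)
  res <- fit_result(model, ans$rss, n, TRUE,
                    list(kd_rest = exp(par[1]), kd_inact = exp(par[2])))
  res$fold_ratio <- model$kd_rest / model$kd_inact
  res
}

#' Linear trend of potency with temperature
#'
#' Ordinary least-squares line of IC50 against recording temperature.
#'
#' @param temp_C temperatures (degrees C)
#' @param ic50_uM IC50 at each temperature (uM)
#' @return list with `slope_uM_per_C`, `intercept_uM`, `residual_ss`
#' @export
fit_ic50_temperature_trend <- function(temp_C, ic50_uM) {
  stopifnot(is.numeric(temp_C), is.numeric(ic50_uM),
            length(temp_C) == length(ic50_uM))
  if (length(unique(temp_C)) < 2L)
    stop("need at least 2 distinct temperatures")
  fit <- stats::lm(ic50_uM ~ temp_C)
  list(slope_uM_per_C = unname(stats::coef(fit)[2]),
       intercept_uM = unname(stats::coef(fit)[1]),
       residual_ss = sum(stats::residuals(fit)^2))
}

#' Seeded bootstrap of a pooled Hill fit
#'
#' Pooled plate fits carry no standard errors; this resamples cells with
#' replacement within each concentration and refits, giving percentile
#' intervals for IC50 and slope.
#'
#' @param table a `conc_response` object (per-cell points required)
#' @param n_boot number of bootstrap replicates
#' @param seed integer seed (required; no wall-clock seeding)
#' @param fix_slope optional fixed Hill coefficient
#' @return data.frame of bootstrap `ic50` and `h` estimates
#' @export
hill_bootstrap <- function(table, n_boot = 200, seed, fix_slope = NULL) {
  stopifnot(inherits(table, "conc_response"), !missing(seed))
  cells <- table$cells
  set.seed(as.integer(seed))
  out <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    res <- do.call(rbind, lapply(split(cells, cells$conc_uM), function(g) {
      g[sample.int(nrow(g), replace = TRUE), , drop = FALSE]
    }))
    fr <- tryCatch(fit_hill(pool_concentration_response(res),
                            fix_slope = fix_slope),
                   error = function(e) NULL)
    out[[b]] <- if (!is.null(fr) && fr$converged)
      data.frame(ic50 = fr$params$ic50, h = fr$params$h)
    else data.frame(ic50 = NA_real_, h = NA_real_)
  }
  do.call(rbind, out)
}
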