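#' @importFrom minpack.lm nlsLM
NULL

.fit_result <- function(amplitude, decay_constant, offset, rms_residual, n,
                        kind, flag = NULL) {
  structure(list(amplitude = amplitude, decay_constant = decay_constant,
                 offset = offset, rms_residual = rms_residual, n = n,
                 kind = kind, flag = flag), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  unit <- if (x$kind == "spatial") "um" else "ms"
  if (!is.null(x$flag)) {
    cat("<fit_result> flagged: ", x$flag, " (rms residual ",
        format(x$rms_residual), ")\n", sep = "")
    return(invisible(x))
  }
  cat("<fit_result> ", x$kind, ": amplitude ", format(x$amplitude),
      ", decay constant ", format(x$decay_constant), " ", unit,
      ", offset ", format(x$offset), ", rms residual ",
      format(x$rms_residual), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Peak-to-baseline amplitude of a response
#'
#' Peak membrane potential minus the mean over the pre-stimulus baseline
#' window; invariant under a constant offset of the whole trace.
#'
#' @param time time grid, ms.
#' @param vm membrane potential trace, mV.
#' @param baseline_window \code{c(t0, t1)} window (ms) whose mean defines
#'   the baseline.
#' @return Amplitude in mV.
#' @export
measure_ap_amplitude <- function(time, vm, baseline_window) {
  sel <- time >= baseline_window[1] & time <= baseline_window[2]
  if (!any(sel)) stop("empty baseline window")
  max(vm) - mean(vm[sel])
}

#' Single-exponential fit of spatial decay
#'
#' Least-squares fit of \code{A * exp(-x / lambda)} (optionally plus an
#' offset) to amplitude-versus-distance data, with log-linear
#' initialization. \code{lambda} is the distance over which the amplitude
#' falls to 1/e (37 percent).
#'
#' @param distance distances, um (>= 3 distinct values).
#' @param amplitude amplitudes, mV (positive, decaying).
#' @param offset fit an additive offset as well.
#' @return A \code{fit_result} with \code{decay_constant} = lambda (um);
#'   non-decaying data are flagged and no lambda is reported.
#' @export
fit_spatial_decay <- function(distance, amplitude, offset = FALSE) {
  if (length(distance) != length(amplitude))
    stop("distance and amplitude must have equal length")
  if (length(distance) < 3) stop("need at least 3 points")
  if (anyDuplicated(distance)) stop("distances must be distinct")
  pos <- amplitude > 0
  init <- stats::lm(log(amplitude[pos]) ~ distance[pos])
  slope <- stats::coef(init)[2]
  if (!is.finite(slope) || slope >= 0) {
    res <- amplitude - mean(amplitude)
    return(.fit_result(NA_real_, NA_real_, NA_real_,
                       sqrt(mean(res^2)), length(distance), "spatial",
                       flag = "non_decaying"))
  }
  start <- list(A = exp(unname(stats::coef(init)[1])),
                lambda = unname(-1 / slope))
  df <- data.frame(x = distance, y = amplitude)
  fit <- if (offset) {
    start$c0 <- 0
    nlsLM(y ~ c0 + A * exp(-x / lambda), data = df, start = start,
          control = stats::nls.control(maxiter = 200))
  } else {
    nlsLM(y ~ A * exp(-x / lambda), data = df, start = start,
          control = stats::nls.control(maxiter = 200))
  }
  cf <- stats::coef(fit)
  .fit_result(unname(cf["A"]), unname(cf["lambda"]),
              if (offset) unname(cf["c0"]) else 0,
              sqrt(mean(stats::resid(fit)^2)), length(distance), "spatial")
}

#' Single-exponential fit of temporal relaxation
#'
#' Least-squares fit of \code{V(t) = V_inf + B * exp(-(t - t0)/tau)} over a
#' window of a monotonically relaxing trace; \code{tau} is returned as the
#' decay constant.
#'
#' @param time time grid, ms.
#' @param vm trace, mV.
#' @param window \code{c(t0, t1)} fit window, ms (within the trace).
#' @return A \code{fit_result} with \code{decay_constant} = tau (ms),
#'   \code{amplitude} = B and \code{offset} = V_inf; a non-convergent fit is
#'   flagged with its residual report.
#' @export
fit_temporal_decay <- function(time, vm, window) {
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 5) stop("fit window must contain at least 5 samples")
  t <- time[sel] - window[1]
  y <- vm[sel]
  v_inf <- mean(y[t >= 0.9 * max(t)])
  dev <- y - v_inf
  sgn <- sign(dev[1])
  usable <- sgn * dev > 0 & t < 0.9 * max(t)
  tau0 <- if (sum(usable) >= 3) {
    sl <- unname(stats::coef(stats::lm(log(sgn * dev[usable]) ~ t[usable]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else diff(window) / 3
  } else diff(window) / 3
  fit <- tryCatch(
    nlsLM(y ~ vinf + B * exp(-t / tau), data = data.frame(t = t, y = y),
          start = list(vinf = v_inf, B = dev[1], tau = tau0),
          control = stats::nls.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || stats::coef(fit)["tau"] <= 0) {
    res <- y - mean(y)
    return(.fit_result(NA_real_, NA_real_, NA_real_, sqrt(mean(res^2)),
                       sum(sel), "temporal", flag = "non_convergent"))
  }
  cf <- stats::coef(fit)
  .fit_result(unname(cf["B"]), unname(cf["tau"]), unname(cf["vinf"]),
              sqrt(mean(stats::resid(fit)^2)), sum(sel), "temporal")
}

#' Align traces by baseline subtraction
#'
#' Shifts each trace so its mean over the pre-response window is zero;
#' idempotent.
#'
#' @param time shared time grid, ms.
#' @param traces numeric vector, matrix or data.frame of traces (one column
#'   each) on that grid.
#' @param baseline_window \code{c(t0, t1)} pre-response window, ms.
#' @return The aligned traces, same shape as the input.
#' @export
align_baseline <- function(time, traces, baseline_window) {
  sel <- time >= baseline_window[1] & time <= baseline_window[2]
  if (!any(sel)) stop("empty baseline window")
  if (is.null(dim(traces))) return(traces - mean(traces[sel]))
  sweep(as.matrix(traces), 2, colMeans(as.matrix(traces)[sel, , drop = FALSE]))
}

#' Decompose a propagating action potential into components
#'
#' Given the three baseline-aligned bouton traces of
#' \code{\link{protocol_component_decomposition}} (control, K+ conductance
#' removed, Na+ and K+ removed), computes by subtraction the
#' voltage components due to Na+ channels (\code{v_mna = noK - noNaK}),
#' K+ channels (\code{v_mk = control - noK}) and the capacitive component
#' (\code{v_cap = noNaK}); their sum reconstructs the control deviation
#' exactly by construction.
#'
#' @param time shared time grid, ms (all three traces must be on this
#'   grid).
#' @param control,noK,noNaK membrane-potential traces, mV.
#' @param baseline_window pre-response window used for alignment, ms.
#' @return An object of class \code{component_traces} with the component
#'   traces and \code{reconstruction_error} (identically 0 up to rounding).
#' @export
decompose_components <- function(time, control, noK, noNaK,
                                 baseline_window) {
  n <- length(time)
  if (length(control) != n || length(noK) != n || length(noNaK) != n)
    stop("grid mismatch: all traces must share the time grid")
  control <- align_baseline(time, control, baseline_window)
  noK <- align_baseline(time, noK, baseline_window)
  noNaK <- align_baseline(time, noNaK, baseline_window)
  v_mk <- control - noK
  v_mna <- noK - noNaK
  v_cap <- noNaK
  structure(list(time = time, v_mna = v_mna, v_mk = v_mk, v_cap = v_cap,
                 control = control,
                 reconstruction_error =
                   max(abs(v_cap + v_mna + v_mk - control))),
            class = "component_traces")
}

#' @export
print.component_traces <- function(x, ...) {
  cat("<component_traces> ", length(x$time), " samples; reconstruction error ",
      format(x$reconstruction_error), " mV\n", sep = "")
  invisible(x)
}

.onset_time <- function(time, x, frac, baseline_n) {
  base <- stats::median(x[seq_len(baseline_n)])
  d <- abs(x - base)
  thr <- frac * max(d)
  if (thr == 0) return(NA_real_)
  i <- which(d >= thr)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(time[1])
  # linear interpolation of the crossing
  time[i - 1] + (thr - d[i - 1]) / (d[i] - d[i - 1]) * (time[i] - time[i - 1])
}

#' Onset delay between capacitive and Na+ current
#'
#' Onset is the first crossing of a fraction (default 5 percent) of the peak
#' magnitude, after baseline subtraction; the delay is
#' \code{onset(I_Na) - onset(I_cap)}, positive when the capacitive current
#' precedes the Na+ current (propagated action potentials) and approximately
#' zero for locally evoked ones.
#'
#' @param time shared time grid, ms.
#' @param i_cap,i_na current traces, nA.
#' @param frac onset threshold as a fraction of the peak magnitude.
#' @param baseline_frac leading fraction of the trace whose median defines
#'   the current baseline.
#' @return Delay in ms; \code{NA} (with a warning) if either trace never
#'   crosses its threshold.
#' @export
onset_delay <- function(time, i_cap, i_na, frac = 0.05,
                        baseline_frac = 0.05) {
  nb <- max(1L, as.integer(baseline_frac * length(time)))
  on_cap <- .onset_time(time, i_cap, frac, nb)
  on_na <- .onset_time(time, i_na, frac, nb)
  if (is.na(on_cap) || is.na(on_na)) {
    warning("no threshold crossing found; onset delay undefined")
    return(NA_real_)
  }
  on_na - on_cap
}

#' After-potential and relaxation measurements at a recorded site
#'
#' \code{measure_step_tau} fits the single-exponential time constant of the
#' membrane-potential relaxation following a current-step onset;
#' \code{measure_afterpotential_tau} does the same for the late phase of the
#' after potential following the action-potential peak. Both use a matched
#' fit window starting \code{fit_start} ms after the perturbation (step onset
#' or spike peak) and ending \code{fit_end} ms after it: the first few ms of
#' either relaxation are multi-exponential (fast charge redistribution along
#' the cable), and the slow single-exponential phase that the time constant
#' describes dominates beyond ~10 ms. Sensitivity to the window start should
#' be reported alongside the fit (see the package vignette).
#'
#' @param ts a \code{trace_set}.
#' @param site recorded site name (default \code{"bouton10"}).
#' @param onset step onset time, ms.
#' @param fit_start,fit_end fit window relative to the perturbation, ms.
#' @return A \code{fit_result} with \code{decay_constant} = tau in ms.
#' @export
measure_step_tau <- function(ts, site = "bouton10", onset,
                             fit_start = 10, fit_end = 40) {
  tr <- get_trace(ts, site)
  fit_temporal_decay(tr$time, tr$value, onset + c(fit_start, fit_end))
}

#' @rdname measure_step_tau
#' @export
measure_afterpotential_tau <- function(ts, site = "bouton10",
                                       fit_start = 10, fit_end = 40) {
  tr <- get_trace(ts, site)
  peak_t <- tr$time[which.max(tr$value)]
  fit_temporal_decay(tr$time, tr$value, peak_t + c(fit_start, fit_end))
}

#' Early after-potential level
#'
#' Mean membrane potential relative to the resting potential over a window
#' after the action-potential peak (default 2-5 ms, inside the "initial
#' 5 ms" early phase that converges near E_K). Negative values indicate a
#' hyperpolarizing after potential, positive a depolarizing one.
#'
#' @param ts a \code{trace_set}.
#' @param site recorded site name.
#' @param resting resting potential the level is referenced to, mV.
#' @param window window after the spike peak, ms.
#' @return Level in mV.
#' @export
measure_afterpotential_level <- function(ts, site = "bouton10", resting,
                                         window = c(2, 5)) {
  tr <- get_trace(ts, site)
  peak_t <- tr$time[which.max(tr$value)]
  sel <- tr$time > peak_t + window[1] & tr$time <= peak_t + window[2]
  if (!any(sel)) stop("after-potential window lies outside the trace")
  mean(tr$value[sel]) - resting
}

#' Peak-amplitude decay profile beyond a section
#'
#' Per-segment peak depolarization amplitudes (peak minus per-segment
#' baseline) at all segments distal to the distal end of \code{from}, with
#' distances measured along the chain midline from that end. This is the
#' input of \code{\link{fit_spatial_decay}} for the passive-propagation
#' analysis.
#'
#' @param ts a \code{trace_set} (its per-segment peak table is used).
#' @param chain the chain the trace set was computed on (geometry source).
#' @param from section whose distal end is the distance origin (default
#'   \code{"bouton7"}, the last compartment with normal conductances in the
#'   standard knockout).
#' @return data.frame with columns \code{distance} (um), \code{amplitude}
#'   (mV), \code{section}.
#' @export
decay_profile <- function(ts, chain, from = "bouton7") {
  x0 <- section_end(chain, from)
  p <- ts$peaks[ts$peaks$x > x0, , drop = FALSE]
  data.frame(distance = p$x - x0, amplitude = p$amplitude,
             section = p$section, row.names = NULL)
}

#' Amplitude at a given distance beyond a section
#'
#' Convenience accessor: the peak amplitude at the segment whose center is
#' nearest to \code{distance} um beyond the distal end of \code{from}.
#'
#' @inheritParams decay_profile
#' @param distance distance along the chain midline, um.
#' @return Amplitude in mV.
#' @export
amplitude_at_distance <- function(ts, chain, distance, from = "bouton7") {
  prof <- decay_profile(ts, chain, from)
  prof$amplitude[which.min(abs(prof$distance - distance))]
}
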