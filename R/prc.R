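#' Normalised stimulus phase
#'
#' Phase of a stimulus relative to the last reference peak before it, in
#' units of the free-running period: `phi = (t_delta - t_r)/Tp`, with
#' `t_r <= t_delta <= t_r + Tp`.
#'
#' @param t_delta stimulus time (h).
#' @param t_r reference peak time immediately before the stimulus (h).
#' @param Tp free-running period (h).
#' @return `phi` in `[0, 1]`.
#' @export
normalized_phase <- function(t_delta, t_r, Tp) {
  stopifnot(Tp > 0)
  if (any(t_delta < t_r - 1e-9) || any(t_delta > t_r + Tp + 1e-9))
    stop("t_delta must lie within [t_r, t_r + Tp]")
  (t_delta - t_r) / Tp
}

#' Phase shift between a stimulated and a reference rhythm
#'
#' Compares CL mRNA peak times long after the stimulus (by default at the
#' 18th post-stimulus cycle, where transients have decayed). The phase
#' shift is `delta_phi = (t_ref - t_stim)/Tp` wrapped into `(-0.5, 0.5]`;
#' positive values are phase advances (the stimulated rhythm peaks
#' earlier). The stimulated peak compared is the one nearest the reference
#' peak, which avoids mispairing when a large shift reorders peak indices.
#'
#' @param stimulated_trace,reference_trace `pcs_trace` objects covering at
#'   least `cycle_index + 2` cycles beyond `stimulus_time`.
#' @param Tp free-running period of the reference rhythm (h).
#' @param stimulus_time onset of the stimulus (h).
#' @param cycle_index which post-stimulus reference cycle to compare at.
#' @param species trace column to compare.
#' @return normalised phase shift in `(-0.5, 0.5]`.
#' @export
phase_shift <- function(stimulated_trace, reference_trace, Tp,
                        stimulus_time, cycle_index = 18,
                        species = "CL_m") {
  stopifnot(Tp > 0, cycle_index >= 1)
  ref <- estimate_period(reference_trace, species,
                         transient_cutoff = stimulus_time)
  stim <- estimate_period(stimulated_trace, species,
                          transient_cutoff = stimulus_time)
  if (!ref$rhythmic) stop("reference trace is arrhythmic")
  if (!stim$rhythmic) stop("stimulated trace is arrhythmic")
  ref_pk <- ref$peak_times[ref$peak_times > stimulus_time]
  stim_pk <- stim$peak_times[stim$peak_times > stimulus_time]
  if (length(ref_pk) < cycle_index)
    stop("reference trace too short: ", length(ref_pk), " post-stimulus peaks")
  t_ref <- ref_pk[cycle_index]
  if (!length(stim_pk)) stop("no post-stimulus peaks in stimulated trace")
  t_stim <- stim_pk[which.min(abs(stim_pk - t_ref))]
  d <- (t_ref - t_stim) / Tp
  d <- d - round(d)            # wrap to (-0.5, 0.5]
  if (d <= -0.5) d <- d + 1
  d
}

#' Compute a phase-response curve
#'
#' Runs one of the six light-stimulus tests over a grid of stimulus onsets
#' spanning one free-running cycle. The reference simulation runs the
#' background program alone; `t_r` is its first CL mRNA peak after
#' `settle` hours, and stimulus onsets sweep `[t_r, t_r + Tp)`. For each
#' onset the spliced program is simulated and the phase shift measured at
#' the `cycle_index`-th post-stimulus cycle.
#'
#' @param params a `pcs_params` object.
#' @param test_id `"I"`..`"VI"` (see [build_protocol()]).
#' @param phase_grid number of onset points per cycle.
#' @param settle hours of undisturbed rhythm before the stimulus sweep.
#' @param cycle_index see [phase_shift()].
#' @param ... passed to [pcs_simulate()] (e.g. solver tolerances, `dt`).
#' @return an object of class `prc_result`: data frame with columns `phi`,
#'   `delta_phi`; attributes `Tp`, `test_id`, `ad_ratio` and the sign
#'   convention.
#' @export
compute_prc <- function(params, test_id, phase_grid = 48, settle = 200,
                        cycle_index = 18, ...) {
  params <- validate_params(params)
  proto0 <- build_protocol(test_id, onset = settle)  # validates test_id
  t_end <- settle + (cycle_index + 6) * 26
  ref_tr <- pcs_simulate(params, proto0$background, t_end, ...)
  ref <- estimate_period(ref_tr, "CL_m", transient_cutoff = settle)
  if (!ref$rhythmic)
    stop("background program does not admit a free-running rhythm")
  Tp <- ref$period
  t_r <- ref$peak_times[1]
  # the horizon must hold the full onset sweep plus cycle_index + margin
  # cycles of the measured period; extend and re-simulate if it does not
  need <- t_r + Tp + proto0$stimulus$duration + (cycle_index + 4) * Tp
  if (need > t_end) {
    t_end <- ceiling(need)
    ref_tr <- pcs_simulate(params, proto0$background, t_end, ...)
    ref <- estimate_period(ref_tr, "CL_m", transient_cutoff = settle)
    Tp <- ref$period
    t_r <- ref$peak_times[1]
  }
  onsets <- t_r + (seq_len(phase_grid) - 1) / phase_grid * Tp
  delta <- vapply(onsets, function(on) {
    proto <- build_protocol(test_id, onset = on)
    prog <- compose_protocol(proto, t_end)
    tr <- pcs_simulate(params, prog, t_end, ...)
    phase_shift(tr, ref_tr, Tp, stimulus_time = on,
                cycle_index = cycle_index)
  }, numeric(1))
  res <- data.frame(phi = normalized_phase(onsets, t_r, Tp),
                    delta_phi = delta)
  structure(res,
            class = c("prc_result", "data.frame"),
            Tp = Tp, test_id = test_id,
            ad_ratio = ad_ratio(res),
            sign_convention = "advance positive")
}

#' Advance/delay area ratio of a PRC
#'
#' Splits the curve into phase-advance (`delta_phi > 0`) and phase-delay
#' (`delta_phi < 0`) regions, locating region boundaries by linear
#' interpolation at zero crossings, and integrates each region with the
#' trapezoidal rule. Returns advance area divided by delay area; a purely
#' advancing PRC gives `Inf`, a purely delaying one `0`.
#'
#' @param prc a `prc_result` or any data frame with `phi` and `delta_phi`.
#' @return scalar A/D ratio.
#' @export
ad_ratio <- function(prc) {
  phi <- prc$phi
  y <- prc$delta_phi
  if (!length(phi)) stop("empty PRC")
  stopifnot(!is.unsorted(phi), all(is.finite(y)))
  # insert interpolated zero crossings so each trapezoid is single-signed
  xx <- phi[1]; yy <- y[1]
  for (i in seq_len(length(phi) - 1)) {
    if (y[i] * y[i + 1] < 0) {
      x0 <- phi[i] + (phi[i + 1] - phi[i]) * y[i] / (y[i] - y[i + 1])
      xx <- c(xx, x0); yy <- c(yy, 0)
    }
    xx <- c(xx, phi[i + 1]); yy <- c(yy, y[i + 1])
  }
  seg_area <- diff(xx) * (head(yy, -1) + yy[-1]) / 2
  adv <- sum(seg_area[seg_area > 0])
  del <- -sum(seg_area[seg_area < 0])
  if (del == 0 && adv == 0) return(NaN)
  if (del == 0) return(Inf)
  adv / del
}

#' @export
print.prc_result <- function(x, ...) {
  cat(sprintf("<prc_result> test %s: %d phases, Tp = %.2f h, A/D = %.3g\n",
              attr(x, "test_id"), nrow(x), attr(x, "Tp"),
              attr(x, "ad_ratio")))
  invisible(x)
}

#' @importFrom utils head tail
NULL
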