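#' Simulate the plant circadian system over a light program
#'
#' Integrates the 18-state model with a stiff-capable adaptive solver
#' (`deSolve::lsoda`). Integration is restarted at every light-switch time
#' so that the discontinuous light indicator functions never fall inside a
#' solver step; within one segment the light intensities are constant.
#' Output is returned on a uniform grid (`dt`) merged with the exact switch
#' times.
#'
#' @param params a `pcs_params` object.
#' @param program a `light_program`.
#' @param t_end simulation horizon (h, > 0).
#' @param initial optional named initial state; default
#'   [pcs_initial_state()].
#' @param variant `"full"` model or `"no_binding"` ablation (no
#'   photoreceptor-COP1 binding, COP1-independent EL protein decay).
#' @param dt output grid spacing (h).
#' @param times optional explicit output times (overrides `dt`).
#' @param rtol,atol solver tolerances.
#' @param complex_decay_uses_complex see [clock_rhs()].
#' @return a `pcs_trace`: data frame with `time`, the 18 states, derived
#'   totals `TPhyA`, `TPhyB`, `TCry1`, light inputs `La`, `Lb` and the
#'   sampled intensities `I_red`, `I_blue`; metadata in attributes
#'   (`params_hash`, `variant`, `program`).
#' @export
#' @examples
#' \donttest{
#' tr <- pcs_simulate(pcs_params(), light_constant(0, 0), t_end = 300)
#' estimate_period(tr, "CL_m", transient_cutoff = 150)
#' }
pcs_simulate <- function(params, program, t_end,
                         initial = NULL,
                         variant = c("full", "no_binding"),
                         dt = 0.1, times = NULL,
                         rtol = 1e-6, atol = 1e-9,
                         complex_decay_uses_complex = TRUE) {
  variant <- match.arg(variant)
  params <- validate_params(params)
  stopifnot(inherits(program, "light_program"), t_end > 0)
  if (is.null(initial)) initial <- pcs_initial_state(params)
  y <- .check_state(initial)
  if (any(y < 0)) stop("initial state must be non-negative")

  grid <- if (is.null(times)) seq(0, t_end, by = dt) else sort(unique(times))
  if (max(grid) < t_end - 1e-9) grid <- c(grid, t_end)
  switches <- .switch_times(program, t_end)
  out_times <- sort(unique(c(grid, switches, 0, t_end)))

  # segment boundaries: 0, interior switches, t_end
  bounds <- c(0, switches, t_end)
  rows <- vector("list", length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    # sample just inside the segment so half-open boundaries are respected
    li <- light_sample(program, a)
    seg_times <- out_times[out_times >= a - 1e-12 & out_times <= b + 1e-12]
    if (length(seg_times) < 2 || seg_times[1] > a) seg_times <- c(a, seg_times)
    if (seg_times[length(seg_times)] < b) seg_times <- c(seg_times, b)
    seg_times <- sort(unique(seg_times))
    cp <- .c_parms(params, variant, li[["I_red"]], li[["I_blue"]],
                   complex_decay_uses_complex)
    sol <- deSolve::lsoda(
      y = y, times = seg_times, func = "pcs_derivs", parms = cp,
      dllname = "phytoclock", initfunc = "pcs_init",
      nout = 5, outnames = c("TPhyA", "TPhyB", "TCry1", "La", "Lb"),
      rtol = rtol, atol = atol, maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("solver failure in light segment [%g, %g] h", a, b))
    sol <- as.data.frame(sol)
    y <- as.numeric(sol[nrow(sol), 1 + seq_len(18)])
    names(y) <- .pcs_state_names
    # numerical floor: tiny negative excursions are solver error
    neg <- y < 0
    if (any(neg)) {
      if (any(y < -1e-6))
        warning(sprintf(
          "state(s) %s below -1e-6 at t = %g h; flooring at 0",
          paste(.pcs_state_names[y < -1e-6], collapse = ", "), b))
      y[neg] <- 0
    }
    sol$I_red <- li[["I_red"]]
    sol$I_blue <- li[["I_blue"]]
    rows[[i]] <- sol
  }
  tr <- do.call(rbind, rows)
  names(tr)[1 + seq_len(18)] <- .pcs_state_names
  # at duplicated switch instants keep the incoming segment's row, so the
  # stored light columns honour the half-open [t_start, t_end) convention
  tr <- tr[!duplicated(tr$time, fromLast = TRUE), ]
  rownames(tr) <- NULL
  if (anyNA(tr)) stop("NaN in simulation trace")
  structure(tr,
            class = c("pcs_trace", "data.frame"),
            params_hash = .params_hash(params),
            variant = variant,
            program = program$description,
            rtol = rtol, atol = atol)
}

#' Estimate the oscillation period of a simulated species
#'
#' Finds local maxima of the species after a transient cutoff (peaks must
#' have prominence at least `prominence_frac` of the post-transient signal
#' range) and averages successive peak spacings, MATLAB
#' `findpeaks`-style. Peak times are refined by local parabolic
#' interpolation. A trace is called rhythmic only if at least `min_peaks`
#' peaks are found and the post-transient relative oscillation amplitude
#' `(max - min)/mean` exceeds `amp_threshold`.
#'
#' @param trace a `pcs_trace` (or any data frame with a `time` column).
#' @param species column name to analyse (default `"CL_m"`, the canonical
#'   clock readout).
#' @param transient_cutoff discard times below this (h).
#' @param min_peaks minimum number of peaks for rhythmicity.
#' @param prominence_frac minimum peak prominence, as a fraction of the
#'   post-transient range.
#' @param amp_threshold relative-amplitude floor below which the signal is
#'   classified arrhythmic.
#' @return an object of class `period_estimate`: list with `period`
#'   (mean, h), `cycle_periods`, `peak_times`, `rhythmic`, `amplitude`,
#'   `species`.
#' @export
estimate_period <- function(trace, species = "CL_m", transient_cutoff = 200,
                            min_peaks = 3, prominence_frac = 0.01,
                            amp_threshold = 0.01) {
  if (!species %in% names(trace))
    stop("species not in trace: ", species)
  keep <- trace$time >= transient_cutoff
  t <- trace$time[keep]
  x <- trace[[species]][keep]
  if (length(t) < 5)
    stop("trace too short beyond transient_cutoff")
  rng <- diff(range(x))
  m <- mean(x)
  amplitude <- if (m > 0) rng / m else 0
  pk <- .find_peaks(t, x, min_prominence = prominence_frac * rng)
  rhythmic <- length(pk) >= min_peaks && amplitude >= amp_threshold
  cycles <- if (length(pk) >= 2) diff(pk) else numeric(0)
  structure(list(
    period = if (rhythmic) mean(cycles) else NA_real_,
    cycle_periods = cycles,
    peak_times = pk,
    rhythmic = rhythmic,
    amplitude = amplitude,
    species = species,
    transient_cutoff = transient_cutoff), class = "period_estimate")
}

#' Classify rhythmicity
#'
#' @param estimate a `period_estimate`.
#' @return `"rhythmic"` or `"arrhythmic"`.
#' @export
classify_rhythmicity <- function(estimate) {
  stopifnot(inherits(estimate, "period_estimate"))
  if (isTRUE(estimate$rhythmic)) "rhythmic" else "arrhythmic"
}

#' @export
print.period_estimate <- function(x, ...) {
  if (x$rhythmic)
    cat(sprintf("<period_estimate> %s: %.2f h over %d cycles (amplitude %.3g)\n",
                x$species, x$period, length(x$cycle_periods), x$amplitude))
  else
    cat(sprintf("<period_estimate> %s: arrhythmic (%d peaks, amplitude %.3g)\n",
                x$species, length(x$peak_times), x$amplitude))
  invisible(x)
}

# local maxima with a prominence filter and parabolic sub-grid refinement
.find_peaks <- function(t, x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (!length(cand)) return(numeric(0))
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    i <- cand[k]
    # walk left/right until a higher sample or the boundary; the prominence
    # base is the higher of the two interval minima
    j <- i; lmin <- x[i]
    while (j > 1 && x[j] <= x[i]) { j <- j - 1; lmin <- min(lmin, x[j]) }
    j <- i; rmin <- x[i]
    while (j < n && x[j] <= x[i]) { j <- j + 1; rmin <- min(rmin, x[j]) }
    keep[k] <- (x[i] - max(lmin, rmin)) >= min_prominence
  }
  cand <- cand[keep]
  vapply(cand, function(i) {
    if (i <= 1 || i >= n) return(t[i])
    dt1 <- t[i] - t[i - 1]; dt2 <- t[i + 1] - t[i]
    if (abs(dt1 - dt2) > 1e-9) return(t[i])  # uneven grid: no refinement
    denom <- x[i - 1] - 2 * x[i] + x[i + 1]
    if (denom >= 0) return(t[i])
    t[i] + 0.5 * dt1 * (x[i - 1] - x[i + 1]) / denom
  }, numeric(1))
}
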