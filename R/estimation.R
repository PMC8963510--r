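.ref_series <- c("CL_m", "CL_p", "P97_m", "P97_p", "P51_m", "P51_p",
                 "EL_m", "EL_p", "PIF_m", "PIF_p",
                 "TPhyA", "TPhyB", "TCry1")

#' Build reference expression profiles from a simulation
#'
#' Simulates the model and extracts the thirteen reference series used by
#' the estimation cost: mRNA and protein of the five clock/growth genes
#' plus the three total photoreceptor pools. Useful for self-consistency
#' checks and parameter-recovery experiments.
#'
#' @param params a `pcs_params` object.
#' @param program entrainment light program.
#' @param t_end horizon (h).
#' @param dt reference time step (h).
#' @param t_start drop times before this (h), e.g. to skip the transient.
#' @param ... passed to [pcs_simulate()].
#' @return data frame with a `time` column and the thirteen series.
#' @export
make_reference_profiles <- function(params, program, t_end = 120, dt = 0.5,
                                    t_start = 0, ...) {
  tr <- pcs_simulate(params, program, t_end,
                     times = seq(0, t_end, by = dt), ...)
  out <- tr[tr$time >= t_start, c("time", .ref_series)]
  rownames(out) <- NULL
  out
}

#' Weighted mean-squared-error cost against reference profiles
#'
#' Simulates the model under `program`, samples it on the reference time
#' grid, and sums the squared residual of every reference series scaled by
#' `N * max(reference series)` (N = number of time points). The mRNA and
#' protein series of each gene contribute separately normalised summands;
#' photoreceptor references are compared against the simulated total pools
#' (free + COP1-bound).
#'
#' @param params a `pcs_params` object.
#' @param refs reference data frame as from [make_reference_profiles()]
#'   (columns `time` and any subset of the thirteen series).
#' @param program light program the references were recorded under.
#' @param ... passed to [pcs_simulate()].
#' @return scalar cost `e >= 0` (0 only at an exact profile match).
#' @export
pcs_cost <- function(params, refs, program, ...) {
  stopifnot(is.data.frame(refs), "time" %in% names(refs))
  series <- intersect(.ref_series, names(refs))
  if (!length(series)) stop("no reference series found in refs")
  tgrid <- refs$time
  if (is.unsorted(tgrid, strictly = TRUE))
    stop("reference time grid must be strictly increasing")
  tr <- pcs_simulate(params, program, t_end = max(tgrid),
                     times = tgrid, ...)
  sim <- tr[match(round(tgrid, 9), round(tr$time, 9)), , drop = FALSE]
  if (anyNA(sim$time)) stop("simulation grid does not cover reference grid")
  N <- length(tgrid)
  e <- 0
  for (s in series) {
    m <- max(refs[[s]])
    if (!is.finite(m) || m <= 0)
      stop("reference series has non-positive maximum: ", s)
    e <- e + sum((refs[[s]] - sim[[s]])^2) / (N * m)
  }
  e
}

#' Fit parameters to reference profiles
#'
#' Derivative-free (Nelder-Mead) minimisation of [pcs_cost()] over the
#' non-frozen parameters, optimised on the log scale so all parameters
#' stay positive. The light-intensity normalisers and the total COP1 pool
#' are frozen by default (they are adopted constants, not estimated).
#'
#' @param initial starting `pcs_params`.
#' @param refs reference profiles (see [pcs_cost()]).
#' @param program entrainment program used for the references.
#' @param frozen parameter names to hold fixed.
#' @param maxit Nelder-Mead iteration budget.
#' @param restarts number of restarts of the simplex from the current best
#'   (restarting re-inflates the simplex and escapes premature collapse).
#' @param trace_cost if `TRUE`, record the best-so-far cost sequence.
#' @param method `"nelder_mead"` (the classical derivative-free simplex,
#'   the default), `"lm"` (Levenberg-Marquardt on the residual vector via
#'   the `minpack.lm` package — the cost is a smooth sum of squares, for
#'   which a least-squares solver converges far faster), or `"hybrid"`
#'   (a Nelder-Mead stage followed by an LM polish).
#' @param ... passed to [pcs_cost()].
#' @return list with `params` (fitted set), `e_final`, `e_initial`,
#'   `cost_trace` (monotone non-increasing best-so-far costs) and
#'   `evaluations`.
#' @export
pcs_fit <- function(initial, refs, program,
                    frozen = c("eta1", "eta2", "Ctot"),
                    maxit = 2000, restarts = 1, trace_cost = TRUE,
                    method = c("nelder_mead", "lm", "hybrid"), ...) {
  method <- match.arg(method)
  initial <- validate_params(initial)
  frozen <- union(frozen, character(0))
  bad <- setdiff(frozen, .pcs_par_names)
  if (length(bad)) stop("unknown frozen parameter(s): ", paste(bad, collapse = ", "))
  free <- setdiff(.pcs_par_names, frozen)
  if (!length(free)) {
    e0 <- pcs_cost(initial, refs, program, ...)
    return(list(params = initial, e_final = e0, e_initial = e0,
                cost_trace = e0, evaluations = 1L))
  }
  if (any(unclass(initial)[free] <= 0))
    stop("free parameters must be > 0 for log-scale optimisation")

  env <- new.env()
  env$best <- Inf
  env$trace <- numeric(0)
  env$n <- 0L
  objective <- function(x) {
    p <- initial
    p[free] <- exp(x)
    p <- try(validate_params(p), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    e <- try(pcs_cost(p, refs, program, ...), silent = TRUE)
    if (inherits(e, "try-error") || !is.finite(e)) return(1e10)
    env$n <- env$n + 1L
    if (e < env$best) env$best <- e
    if (trace_cost) env$trace <- c(env$trace, env$best)
    e
  }
  x <- log(unclass(initial)[free])
  e0 <- pcs_cost(initial, refs, program, ...)
  if (!is.finite(e0)) stop("non-finite cost at the initial parameter set")
  best_x <- x
  best_e <- e0
  if (method %in% c("nelder_mead", "hybrid")) {
    for (r in seq_len(max(1L, restarts))) {
      fit <- stats::optim(best_x, objective, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-12))
      if (fit$value < best_e) {
        best_e <- fit$value
        best_x <- fit$par
      }
    }
  }
  if (method %in% c("lm", "hybrid")) {
    lm_out <- .fit_lm(initial, free, best_x, refs, program, env, ...)
    if (lm_out$e < best_e) {
      best_e <- lm_out$e
      best_x <- lm_out$x
    }
  }
  p_out <- initial
  p_out[free] <- exp(best_x)
  p_out <- validate_params(p_out)
  # the optimizer never returns a point worse than its start
  if (best_e > e0) {
    p_out <- initial
    best_e <- e0
  }
  list(params = p_out, e_final = best_e, e_initial = e0,
       cost_trace = if (trace_cost) cummin(c(e0, env$trace)) else NULL,
       evaluations = env$n)
}

# Levenberg-Marquardt refinement on the residual vector; log-scale with box
# bounds around the starting point to keep trial steps in the integrable
# region. Residuals are scaled so their sum of squares equals pcs_cost().
.fit_lm <- function(initial, free, x0, refs, program, env, ...) {
  if (!requireNamespace("minpack.lm", quietly = TRUE))
    stop('method = "lm" requires the minpack.lm package')
  series <- intersect(.ref_series, names(refs))
  N <- nrow(refs)
  wts <- vapply(series, function(s) sqrt(N * max(refs[[s]])), numeric(1))
  resid_fn <- function(x) {
    p <- initial
    p[free] <- exp(x)
    p <- try(validate_params(p), silent = TRUE)
    if (inherits(p, "try-error")) return(rep(1e3, N * length(series)))
    tr <- try(suppressWarnings(
      pcs_simulate(p, program, t_end = max(refs$time), times = refs$time,
                   ...)), silent = TRUE)
    if (inherits(tr, "try-error")) return(rep(1e3, N * length(series)))
    sim <- tr[match(round(refs$time, 9), round(tr$time, 9)), , drop = FALSE]
    env$n <- env$n + 1L
    unlist(lapply(series, function(s) (refs[[s]] - sim[[s]]) / wts[[s]]))
  }
  fit <- minpack.lm::nls.lm(
    par = x0, fn = resid_fn,
    lower = x0 - 1.5, upper = x0 + 1.5,
    control = minpack.lm::nls.lm.control(maxiter = 150, ptol = 1e-14,
                                         ftol = 1e-14))
  list(x = fit$par, e = sum(resid_fn(fit$par)^2))
}
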