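.hyp_qualities <- c("blue", "red", "mixed")
.hyp_photoperiods <- c("6L18D", "4L20D", "2L22D")

#' Simulate photoperiodic hypocotyl growth
#'
#' Runs the model for `days` days under a short-day photoperiod with the
#' given light quality (blue = blue only, red = red only, mixed = both
#' channels at the same intensity) starting at lights-on, and reads the
#' hypocotyl length at the end of the run. Lengths are reported directly
#' in mm (the hypocotyl state starts at zero).
#'
#' @param params a `pcs_params` object.
#' @param quality `"blue"`, `"red"` or `"mixed"`.
#' @param photoperiod `"6L18D"`, `"4L20D"`, `"2L22D"` or any `nLmD` label.
#' @param days number of 24-h days to simulate.
#' @param intensity per-channel intensity (umol m-2 s-1); mixed light uses
#'   this intensity on both channels.
#' @param variant `"full"` or `"no_binding"` (see [pcs_simulate()]).
#' @param ... passed to [pcs_simulate()].
#' @return a one-row data frame (class `growth_result`): `quality`,
#'   `photoperiod`, `length` (mm).
#' @export
#' @examples
#' \donttest{
#' simulate_growth(pcs_params(), "red", "2L22D")
#' }
simulate_growth <- function(params, quality, photoperiod, days = 10,
                            intensity = 26.62,
                            variant = c("full", "no_binding"), ...) {
  quality <- match.arg(quality, .hyp_qualities)
  variant <- match.arg(variant)
  I_red <- if (quality %in% c("red", "mixed")) intensity else 0
  I_blue <- if (quality %in% c("blue", "mixed")) intensity else 0
  prog <- light_photoperiod(photoperiod, I_red, I_blue)
  tr <- pcs_simulate(params, prog, t_end = days * 24, variant = variant, ...)
  structure(data.frame(quality = quality, photoperiod = photoperiod,
                       length = tr$HYP[nrow(tr)], stringsAsFactors = FALSE),
            class = c("growth_result", "data.frame"))
}

#' Min-max normalisation against measured extremes
#'
#' Affine map sending the simulated extremes of a photoperiod onto the
#' measured extremes:
#' `x_scaled = (max_exp - min_exp) * (x - min_sim)/(max_sim - min_sim) + min_exp`.
#'
#' @param x simulated value(s).
#' @param sim_extremes `c(min_sim, max_sim)` of the simulated block.
#' @param exp_extremes `c(min_exp, max_exp)` of the measured block.
#' @return normalised value(s).
#' @export
#' @examples
#' minmax_normalize(8.50, c(8.21, 8.86), c(5.13, 7.01))
minmax_normalize <- function(x, sim_extremes, exp_extremes) {
  stopifnot(length(sim_extremes) == 2, length(exp_extremes) == 2)
  if (diff(sim_extremes) <= 0)
    stop("degenerate simulated extremes (max_sim must exceed min_sim)")
  (exp_extremes[2] - exp_extremes[1]) * (x - sim_extremes[1]) /
    (sim_extremes[2] - sim_extremes[1]) + exp_extremes[1]
}

#' Measured hypocotyl lengths
#'
#' The packaged table of published mean measured hypocotyl lengths (mm) of
#' wild-type Arabidopsis seedlings grown for 10 days under blue, red and
#' mixed light at the three short-day photoperiods. Used as the reference
#' extremes for min-max normalisation of simulated lengths.
#'
#' @return data frame with columns `quality`, `photoperiod`, `length`.
#' @export
measured_hypocotyl <- function() {
  path <- system.file("extdata", "hypocotyl_measured.csv",
                      package = "phytoclock", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Hypocotyl growth across light qualities and photoperiods
#'
#' Simulates the full quality-by-photoperiod design (blue, red, mixed at
#' 2L22D, 4L20D, 6L18D) and optionally min-max-normalises the simulated
#' lengths per photoperiod against the packaged measured extremes.
#'
#' @param params a `pcs_params` object.
#' @param variant `"full"` or `"no_binding"`.
#' @param normalize add a `normalized` column.
#' @param days,intensity see [simulate_growth()].
#' @param ... passed to [pcs_simulate()].
#' @return data frame with one row per quality x photoperiod: `quality`,
#'   `photoperiod`, `length` and (optionally) `normalized` and `measured`.
#' @export
quality_comparison <- function(params, variant = c("full", "no_binding"),
                               normalize = TRUE, days = 10,
                               intensity = 26.62, ...) {
  variant <- match.arg(variant)
  grid <- expand.grid(quality = .hyp_qualities,
                      photoperiod = .hyp_photoperiods,
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    simulate_growth(params, grid$quality[i], grid$photoperiod[i],
                    days = days, intensity = intensity,
                    variant = variant, ...)))
  if (normalize) {
    meas <- measured_hypocotyl()
    res$measured <- meas$length[match(paste(res$quality, res$photoperiod),
                                      paste(meas$quality, meas$photoperiod))]
    res$normalized <- NA_real_
    for (pp in unique(res$photoperiod)) {
      i <- res$photoperiod == pp
      res$normalized[i] <- minmax_normalize(
        res$length[i], range(res$length[i]), range(res$measured[i]))
    }
  }
  res
}
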