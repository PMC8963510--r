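#' Light indicator functions
#'
#' The photoreceptor activation indicators are piecewise-constant switches
#' of the instantaneous light intensities: phyA responds to any light,
#' phyB to red only, cry1 to blue only. Any strictly positive intensity
#' flips the corresponding flag, so `theta_phyA == max(theta_phyB,
#' theta_cry1)` always holds.
#'
#' @param I_red,I_blue red/blue intensities (umol m-2 s-1, >= 0).
#' @return named numeric vector `c(theta_phyA, theta_phyB, theta_cry1)`
#'   with values in `{0, 1}`.
#' @export
#' @examples
#' light_indicators(40, 0)      # red only: phyA + phyB
#' light_indicators(0, 0)       # dark
light_indicators <- function(I_red, I_blue) {
  stopifnot(length(I_red) == 1, length(I_blue) == 1)
  if (!is.finite(I_red) || !is.finite(I_blue) || I_red < 0 || I_blue < 0)
    stop("light intensities must be finite and >= 0")
  thB <- as.numeric(I_red > 0)
  thC <- as.numeric(I_blue > 0)
  c(theta_phyA = max(thB, thC), theta_phyB = thB, theta_cry1 = thC)
}

#' Piecewise-constant light programs
#'
#' A light program is an ordered set of contiguous, non-overlapping
#' half-open segments `[t_start, t_end)` each holding constant red and blue
#' intensities, optionally repeating with a fixed period (cyclic programs
#' must tile one period exactly). `light_constant()` builds a constant
#' condition, `light_photoperiod()` an `nLmD` day/night cycle with dawn
#' (lights-on) at `t = 0`.
#'
#' @param segments data frame with columns `t_start`, `t_end`, `I_red`,
#'   `I_blue` (hours; intensities umol m-2 s-1).
#' @param period repeat period in hours, or `NA` for a non-repeating
#'   program.
#' @param description short label stored with the program.
#' @return an object of class `light_program`.
#' @export
light_program <- function(segments, period = NA_real_, description = "") {
  stopifnot(is.data.frame(segments),
            all(c("t_start", "t_end", "I_red", "I_blue") %in% names(segments)))
  segments <- segments[order(segments$t_start),
                       c("t_start", "t_end", "I_red", "I_blue")]
  rownames(segments) <- NULL
  if (nrow(segments) == 0) stop("a light program needs at least one segment")
  with(segments, {
    if (any(!is.finite(t_start)) ||
        any(!is.finite(t_end) & !is.infinite(t_end)))
      stop("segment times must be finite (t_end may be Inf)")
    if (any(t_end <= t_start)) stop("each segment needs t_end > t_start")
    if (any(!is.finite(I_red) | !is.finite(I_blue) | I_red < 0 | I_blue < 0))
      stop("light intensities must be finite and >= 0")
  })
  if (nrow(segments) > 1 &&
      any(abs(segments$t_end[-nrow(segments)] - segments$t_start[-1]) > 1e-9))
    stop("segments must be contiguous and non-overlapping")
  if (!is.na(period)) {
    span <- segments$t_end[nrow(segments)] - segments$t_start[1]
    if (abs(span - period) > 1e-9)
      stop("cyclic program segments must tile exactly one period")
  }
  structure(list(segments = segments, period = period,
                 description = description),
            class = "light_program")
}

#' @rdname light_program
#' @param I_red,I_blue constant intensities.
#' @export
light_constant <- function(I_red = 0, I_blue = 0) {
  light_program(
    data.frame(t_start = 0, t_end = 24, I_red = I_red, I_blue = I_blue),
    period = 24,
    description = sprintf("constant red=%g blue=%g", I_red, I_blue))
}

#' @rdname light_program
#' @param photoperiod label like `"6L18D"` (hours light then hours dark;
#'   must sum to the cycle length).
#' @export
light_photoperiod <- function(photoperiod, I_red = 0, I_blue = 0) {
  ld <- parse_photoperiod(photoperiod)
  segs <- data.frame(
    t_start = c(0, ld[1]),
    t_end = c(ld[1], ld[1] + ld[2]),
    I_red = c(I_red, 0),
    I_blue = c(I_blue, 0))
  light_program(segs, period = sum(ld),
                description = sprintf("%s red=%g blue=%g",
                                      photoperiod, I_red, I_blue))
}

#' @rdname light_program
#' @export
parse_photoperiod <- function(photoperiod) {
  m <- regmatches(photoperiod,
                  regexec("^([0-9.]+)L([0-9.]+)D$", photoperiod))[[1]]
  if (length(m) != 3)
    stop("photoperiod label must look like '6L18D', got: ", photoperiod)
  c(light = as.numeric(m[2]), dark = as.numeric(m[3]))
}

#' Sample a light program
#'
#' Evaluates the program at time `t` with the half-open segment convention
#' (`t_start <= t < t_end`); cyclic programs wrap `t` modulo their period.
#'
#' @param program a `light_program`.
#' @param t time (h, >= 0); vectorised.
#' @return for scalar `t` a named vector `c(I_red, I_blue)`; for vector `t`
#'   a two-column matrix.
#' @export
light_sample <- function(program, t) {
  stopifnot(inherits(program, "light_program"), all(t >= 0))
  segs <- program$segments
  tt <- t
  if (!is.na(program$period)) {
    t0 <- segs$t_start[1]
    tt <- t0 + (t - t0) %% program$period
  } else if (any(t >= segs$t_end[nrow(segs)] + 1e-12)) {
    stop("t beyond the end of a non-cyclic light program")
  }
  idx <- findInterval(tt + 1e-12, segs$t_start)
  idx[idx < 1] <- 1
  out <- cbind(I_red = segs$I_red[idx], I_blue = segs$I_blue[idx])
  if (length(t) == 1) out[1, ] else out
}

#' @export
print.light_program <- function(x, ...) {
  cat("<light_program> ", x$description,
      if (!is.na(x$period)) sprintf(" (cyclic, period %g h)", x$period)
      else " (non-cyclic)", "\n", sep = "")
  print(x$segments, ...)
  invisible(x)
}

# ---- stimulus protocols (phase-response-curve tests) -----------------------

# the six published PRC light-stimulus tests: background colour/intensity,
# stimulus colour/intensity/duration, and whether the stimulus replaces the
# background or is added on top of it
.prc_tests <- list(
  I   = list(name = "red-pulse",  bg_red = 0,  bg_blue = 0,
             st_red = 40,  st_blue = 0,  duration = 1, mode = "replace"),
  II  = list(name = "add-red",    bg_red = 80, bg_blue = 0,
             st_red = 160, st_blue = 0,  duration = 2, mode = "replace"),
  III = list(name = "dark-pulse", bg_red = 80, bg_blue = 0,
             st_red = 0,   st_blue = 0,  duration = 2, mode = "replace"),
  IV  = list(name = "blue-pulse", bg_red = 0,  bg_blue = 0,
             st_red = 0,   st_blue = 25, duration = 1, mode = "replace"),
  V   = list(name = "turn-blue",  bg_red = 80, bg_blue = 0,
             st_red = 0,   st_blue = 80, duration = 2, mode = "replace"),
  VI  = list(name = "add-blue",   bg_red = 80, bg_blue = 0,
             st_red = 0,   st_blue = 80, duration = 2, mode = "add")
)

#' Build a phase-response stimulus protocol
#'
#' Returns one of the six standard light-stimulus tests: red pulse in
#' darkness (I), doubled red under constant red (II), dark pulse under
#' constant red (III), blue pulse in darkness (IV), red switched to blue
#' (V), and blue added on top of red (VI, `mode = "add"`).
#'
#' @param test_id one of `"I"`..`"VI"`.
#' @param onset stimulus onset time (h).
#' @return an object of class `stimulus_protocol` with elements
#'   `background` (a `light_program`), `stimulus` (duration, intensities,
#'   mode) and `onset`.
#' @export
build_protocol <- function(test_id, onset) {
  test_id <- as.character(test_id)
  if (!test_id %in% names(.prc_tests))
    stop("unknown PRC test id: ", test_id, " (expected I..VI)")
  stopifnot(is.numeric(onset), length(onset) == 1, onset >= 0)
  tst <- .prc_tests[[test_id]]
  structure(list(
    test_id = test_id,
    name = tst$name,
    background = light_constant(tst$bg_red, tst$bg_blue),
    stimulus = list(duration = tst$duration, I_red = tst$st_red,
                    I_blue = tst$st_blue, mode = tst$mode),
    onset = onset), class = "stimulus_protocol")
}

#' Flatten a stimulus protocol into a simulable light program
#'
#' Splices the stimulus window into the (flattened) background program,
#' producing a non-cyclic program over `[0, t_end)`. In `mode = "add"` the
#' stimulus intensities are summed onto the background; in
#' `mode = "replace"` they substitute it.
#'
#' @param protocol a `stimulus_protocol`.
#' @param t_end simulation horizon (h); must cover the stimulus window.
#' @return a non-cyclic `light_program`.
#' @export
compose_protocol <- function(protocol, t_end) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  st <- protocol$stimulus
  if (st$duration <= 0) stop("stimulus duration must be > 0")
  t0 <- protocol$onset
  t1 <- t0 + st$duration
  if (t1 > t_end)
    stop("stimulus window [", t0, ", ", t1, ") extends beyond t_end = ", t_end)
  flat <- flatten_program(protocol$background, t_end)
  segs <- flat$segments
  pieces <- list()
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    cuts <- sort(unique(c(s$t_start, s$t_end,
                          pmin(pmax(c(t0, t1), s$t_start), s$t_end))))
    for (j in seq_len(length(cuts) - 1)) {
      a <- cuts[j]; b <- cuts[j + 1]
      if (b <= a) next
      inside <- a >= t0 && a < t1
      red <- s$I_red; blue <- s$I_blue
      if (inside) {
        if (st$mode == "add") {
          red <- red + st$I_red; blue <- blue + st$I_blue
        } else {
          red <- st$I_red; blue <- st$I_blue
        }
      }
      pieces[[length(pieces) + 1]] <-
        data.frame(t_start = a, t_end = b, I_red = red, I_blue = blue)
    }
  }
  segs <- do.call(rbind, pieces)
  # merge adjacent segments with identical intensities
  keep <- c(TRUE, diff(segs$I_red) != 0 | diff(segs$I_blue) != 0)
  merged <- segs[keep, ]
  merged$t_end <- c(segs$t_start[which(keep)[-1]], segs$t_end[nrow(segs)])
  light_program(merged, period = NA_real_,
                description = sprintf("PRC test %s (%s), onset %g h",
                                      protocol$test_id, protocol$name,
                                      protocol$onset))
}

#' Flatten a (possibly cyclic) program onto a finite horizon
#'
#' @param program a `light_program`.
#' @param t_end horizon (h).
#' @return a non-cyclic `light_program` covering `[0, t_end)`.
#' @export
flatten_program <- function(program, t_end) {
  stopifnot(inherits(program, "light_program"), t_end > 0)
  segs <- program$segments
  if (is.na(program$period)) {
    if (segs$t_end[nrow(segs)] < t_end - 1e-9)
      stop("non-cyclic program ends before t_end")
    segs <- segs[segs$t_start < t_end, ]
    segs$t_end <- pmin(segs$t_end, t_end)
    return(light_program(segs, NA_real_, program$description))
  }
  per <- program$period
  n_rep <- ceiling(t_end / per)
  reps <- lapply(seq_len(n_rep) - 1, function(k) {
    s <- segs
    s$t_start <- s$t_start + k * per
    s$t_end <- s$t_end + k * per
    s
  })
  all <- do.call(rbind, reps)
  all <- all[all$t_start < t_end, ]
  all$t_end <- pmin(all$t_end, t_end)
  keep <- c(TRUE, diff(all$I_red) != 0 | diff(all$I_blue) != 0)
  merged <- all[keep, ]
  merged$t_end <- c(all$t_start[which(keep)[-1]], all$t_end[nrow(all)])
  light_program(merged, NA_real_, program$description)
}

# interior light-switch times of a program over [0, t_end]
.switch_times <- function(program, t_end) {
  flat <- flatten_program(program, t_end)
  tt <- unique(c(flat$segments$t_start, flat$segments$t_end))
  sort(tt[tt > 0 & tt < t_end])
}
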