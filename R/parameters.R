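#' @useDynLib phytoclock, .registration = TRUE
#' @keywords internal
"_PACKAGE"

# Canonical parameter order. This order is shared with the compiled
# right-hand side (src/pcs_rhs.c) and must not be changed independently.
.pcs_par_names <- c(
  # transcription rates of CL, P97, P51, EL, PIF
  "v1", "v2", "v3", "v4", "v5",
  # Hill/binding constants of the repression terms and the growth switch
  paste0("K", 1:12),
  # mRNA decay (CL decay switches between light k1L and dark k1D)
  "k1L", "k1D", "k2", "k3", "k4", "k5",
  # translation rates (CL gains p1L in light)
  "p1", "p1L", "p2", "p3", "p4", "p5",
  # protein decay; dXD dark / dXL light pairs
  "d1", "d2D", "d2L", "d3D", "d3L", "d4D", "d4L", "d5D", "d5L",
  # hypocotyl growth: basal rate and PIF-dependent gain
  "g1", "g2",
  # photoreceptor synthesis/turnover kinetics
  "Ap3", "Am7", "Ak7", "q2", "Bp4", "Bm8", "Bk8", "Cp5", "Cm9", "Ck9",
  # light-input coefficients for the two target genes (a: CL, b: P97)
  "q1a", "q3a", "q4a", "q1b", "q3b", "q4b",
  # light-intensity normalisers inside the logarithmic intensity response
  "eta1", "eta2",
  # photoreceptor-COP1 binding and dissociation
  "kmpac", "kmpbc", "kmpcc", "kd",
  # EL protein degradation: basal and COP1-species-specific activities
  "de1", "de2", "de3", "de4", "de5",
  # total COP1 pool and the overexpression constant
  "Ctot", "c_ox"
)

# parameters that must be strictly positive (denominators)
.pcs_positive_pars <- c(paste0("K", 1:12), "Ak7", "Bk8", "Ck9", "Ctot")

#' Model parameter set
#'
#' Construct the named parameter vector of the plant circadian system model.
#' The set holds the 69 named scalars of the clock/photoreceptor/COP1/growth
#' equations plus an `ox` attribute carrying per-gene additive
#' overexpression constants (all zero for wild type; see
#' [apply_genotype()]).
#'
#' With no arguments the packaged default parameter file is loaded. This
#' file is a synthetic calibration produced with the package itself (see the
#' methods vignette): the model was fitted so that its free-running and
#' mutant periods, photoperiodic hypocotyl lengths and phase-response
#' behaviour reproduce the published validation values.
#'
#' @param ... named scalar overrides, e.g. `pcs_params(v1 = 5)`.
#' @param file optional path to a two-column delimited parameter file
#'   (`name value` or `name,value`); missing names are filled from the
#'   packaged defaults with a warning.
#' @return a numeric vector of class `pcs_params`.
#' @export
#' @examples
#' p <- pcs_params()
#' p["Ctot"]
#' p2 <- pcs_params(v1 = 1.1 * p[["v1"]])
pcs_params <- function(..., file = NULL) {
  base <- if (is.null(file)) .default_params() else read_parameters(file)
  dots <- c(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named")
    unknown <- setdiff(names(dots), .pcs_par_names)
    if (length(unknown))
      stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
    base[names(dots)] <- dots
  }
  validate_params(base)
}

.default_params_cache <- new.env(parent = emptyenv())

.default_params <- function() {
  if (is.null(.default_params_cache$p)) {
    path <- system.file("extdata", "parameters_synthetic.tsv",
                        package = "phytoclock", mustWork = TRUE)
    .default_params_cache$p <- read_parameters(path)
  }
  .default_params_cache$p
}

#' Validate a parameter set
#'
#' Checks completeness, finiteness and sign constraints: every rate and
#' binding constant must be finite and non-negative, and all Hill constants,
#' the Michaelis constants `Ak7`, `Bk8`, `Ck9` and the COP1 pool `Ctot`
#' strictly positive.
#'
#' @param params named numeric vector.
#' @return the validated `pcs_params` object (invisibly usable in pipes).
#' @export
validate_params <- function(params) {
  vals <- unclass(params)
  ox <- attr(params, "ox")
  missing <- setdiff(.pcs_par_names, names(vals))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(vals), .pcs_par_names)
  if (length(extra))
    stop("unknown parameter name(s): ", paste(extra, collapse = ", "))
  vals <- vals[.pcs_par_names]
  if (any(!is.finite(vals)))
    stop("non-finite parameter(s): ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  if (any(vals < 0))
    stop("negative parameter(s): ",
         paste(names(vals)[vals < 0], collapse = ", "))
  pos <- vals[.pcs_positive_pars]
  if (any(pos <= 0))
    stop("parameter(s) must be > 0: ",
         paste(.pcs_positive_pars[pos <= 0], collapse = ", "))
  if (is.null(ox)) ox <- numeric(5)
  stopifnot(length(ox) == 5, all(is.finite(ox)), all(ox >= 0))
  structure(vals, ox = as.numeric(ox), class = "pcs_params")
}

#' Read a parameter file
#'
#' Parameter files are two-column delimited text (`name` and `value`,
#' whitespace-, tab- or comma-separated; `#` starts a comment). Unknown
#' names are an error; names absent from the file are filled from the
#' packaged defaults with a warning listing them.
#'
#' @param path file path.
#' @return a `pcs_params` object.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  parts <- strsplit(raw, "[,\t ]+")
  bad <- lengths(parts) != 2
  if (any(bad))
    stop("malformed parameter line(s): ", paste(raw[bad], collapse = "; "))
  nm <- vapply(parts, `[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(val))
    stop("non-numeric value for parameter(s): ",
         paste(nm[is.na(val)], collapse = ", "))
  if (anyDuplicated(nm))
    stop("duplicated parameter name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  unknown <- setdiff(nm, .pcs_par_names)
  if (length(unknown))
    stop("unknown parameter name(s): ", paste(unknown, collapse = ", "))
  vals <- stats::setNames(val, nm)
  missing <- setdiff(.pcs_par_names, nm)
  if (length(missing)) {
    warning("parameter(s) missing from file, filled from packaged defaults: ",
            paste(missing, collapse = ", "))
    def <- .default_params()
    vals <- c(vals, unclass(def)[missing])
  }
  validate_params(vals)
}

#' Write a parameter file
#'
#' Writes the tab-separated `name value` representation read back by
#' [read_parameters()]; the round trip preserves values exactly (full
#' double precision via `format(..., digits = 17)`).
#'
#' @param params a `pcs_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  params <- validate_params(params)
  lines <- paste(names(params),
                 vapply(unname(unclass(params)),
                        function(x) format(x, digits = 17), ""),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.pcs_params <- function(x, ...) {
  cat("<pcs_params> ", length(x), " parameters\n", sep = "")
  ox <- attr(x, "ox")
  if (any(ox > 0))
    cat("  overexpression offsets (CL,P97,P51,EL,PIF): ",
        paste(format(ox), collapse = " "), "\n", sep = "")
  print(unclass(x)[.pcs_par_names], ...)
  invisible(x)
}

# short fingerprint of a parameter set for trace metadata (polynomial rolling
# hash over the printed values; stable across sessions, no digest dependency)
.params_hash <- function(params) {
  s <- paste(names(params), format(unclass(params), digits = 17),
             collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
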