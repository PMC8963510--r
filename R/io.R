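#' Write a simulation trace to CSV
#'
#' Writes the trace with its metadata (parameter fingerprint, model
#' variant, light program, solver tolerances, package version) as `#`
#' comment lines above a standard CSV header, so the file stays
#' spreadsheet-readable and self-describing.
#'
#' @param trace a `pcs_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pcs_trace"))
  if (!nrow(trace)) stop("refusing to write an empty trace")
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(
    params_hash = attr(trace, "params_hash"),
    variant = attr(trace, "variant"),
    program = attr(trace, "program"),
    rtol = format(attr(trace, "rtol")),
    atol = format(attr(trace, "atol")),
    tool_version = as.character(utils::packageVersion("phytoclock")))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' Read a simulation trace written by [write_trace()]
#'
#' @param path CSV path.
#' @return a `pcs_trace` with the stored metadata attributes.
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 50)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- sub("^[^:]*: ?", "", kv)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty trace file: ", path)
  structure(df, class = c("pcs_trace", "data.frame"),
            params_hash = meta$params_hash, variant = meta$variant,
            program = meta$program,
            rtol = as.numeric(meta$rtol), atol = as.numeric(meta$atol))
}

#' @export
print.pcs_trace <- function(x, ...) {
  cat(sprintf("<pcs_trace> %d time points over [%g, %g] h (%s variant; %s)\n",
              nrow(x), min(x$time), max(x$time),
              attr(x, "variant") %||% "?", attr(x, "program") %||% ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a light program from a config list or YAML file
#'
#' Accepts either a path to a YAML file or a list with a `mode` field:
#' `constant` (`red`, `blue`), `photoperiod` (`photoperiod` label, `red`,
#' `blue`) or `protocol` (`test`, `onset`, `t_end`).
#'
#' @param config list or YAML file path.
#' @return a `light_program`.
#' @export
read_light_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML light configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$mode))
  switch(config$mode,
    constant = light_constant(config$red %||% 0, config$blue %||% 0),
    photoperiod = light_photoperiod(config$photoperiod,
                                    config$red %||% 0, config$blue %||% 0),
    protocol = compose_protocol(
      build_protocol(config$test, config$onset),
      t_end = config$t_end %||% (config$onset + 600)),
    stop("unknown light config mode: ", config$mode))
}
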