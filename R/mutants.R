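# gene -> transcription-rate parameter of the merged model component
.gene_to_rate <- c(CL = "v1", P97 = "v2", P51 = "v3", EL = "v4", PIF = "v5")
# gene -> index of the additive overexpression offset in the ox attribute
.gene_to_ox <- c(CL = 1L, P97 = 2L, P51 = 3L, EL = 4L, PIF = 5L)

#' In-silico genotypes
#'
#' A genotype targets one merged model component (`CL` = LHY/CCA1, `P97` =
#' PRR9/PRR7, `P51` = PRR5/TOC1, `EL` = ELF4/LUX, `PIF` = PIF4/PIF5).
#' Knockdown halves the component's transcription rate (`strength = 0.5`);
#' overexpression adds a constant (`c_ox` by default) to the component's
#' mRNA production term.
#'
#' @param target one of `"CL"`, `"P97"`, `"P51"`, `"EL"`, `"PIF"`.
#' @param kind `"knockdown"` or `"overexpression"`.
#' @param label optional display label (e.g. `"\u0394prr7"`).
#' @param strength knockdown multiplier on the transcription rate (default
#'   0.5) or overexpression constant (default the parameter `c_ox`).
#' @return an object of class `genotype`.
#' @export
#' @examples
#' genotype("P97", "knockdown", label = "prr7 knockdown")
genotype <- function(target, kind = c("knockdown", "overexpression"),
                     label = NULL, strength = NULL) {
  kind <- match.arg(kind)
  target <- match.arg(target, names(.gene_to_rate))
  if (is.null(label))
    label <- paste0(target, if (kind == "knockdown") "-kd" else "-OX")
  structure(list(target = target, kind = kind, label = label,
                 strength = strength), class = "genotype")
}

#' Apply a genotype to a parameter set
#'
#' Pure transform: the input parameter set is not modified. Knockdown
#' multiplies the target's transcription rate (`v1`..`v5`); overexpression
#' stores an additive constant in the parameter set's `ox` attribute, which
#' the right-hand side adds to the target's mRNA production term
#' (constitutive extra transcription, not subject to the promoter's
#' repression; for EL it shares the light gate of EL transcription).
#'
#' @param params a `pcs_params` object.
#' @param geno a [genotype()].
#' @return a new `pcs_params` object.
#' @export
#' @examples
#' p <- pcs_params()
#' p_kd <- apply_genotype(p, genotype("P97", "knockdown"))
#' p_kd[["v2"]] / p[["v2"]]   # 0.5
apply_genotype <- function(params, geno) {
  params <- validate_params(params)
  stopifnot(inherits(geno, "genotype"))
  if (geno$kind == "knockdown") {
    mult <- if (is.null(geno$strength)) 0.5 else geno$strength
    stopifnot(mult >= 0)
    rate <- .gene_to_rate[[geno$target]]
    params[rate] <- unclass(params)[[rate]] * mult
  } else {
    add <- if (is.null(geno$strength)) unclass(params)[["c_ox"]] else geno$strength
    stopifnot(add >= 0)
    ox <- attr(params, "ox")
    ox[.gene_to_ox[[geno$target]]] <- ox[.gene_to_ox[[geno$target]]] + add
    attr(params, "ox") <- ox
  }
  validate_params(params)
}

# the standard validation battery rows: label, target, kind, condition
.battery_rows <- list(
  list("WT",          NA,    NA,               "LL"),
  list("WT",          NA,    NA,               "DD"),
  list("\u0394lhy/cca1", "CL",  "knockdown",   "LL"),
  list("\u0394toc1",     "P51", "knockdown",   "LL"),
  list("\u0394prr7",     "P97", "knockdown",   "LL"),
  list("\u0394elf3",     "EL",  "knockdown",   "LL"),
  list("PRR5-OX",        "P51", "overexpression", "LL"),
  list("ELF3-OX",        "EL",  "overexpression", "LL"),
  list("\u0394prr7",     "P97", "knockdown",   "DD"),
  list("\u0394elf3",     "EL",  "knockdown",   "DD"),
  list("ELF3-OX",        "EL",  "overexpression", "DD"))

#' Free-running period battery across genotypes
#'
#' Simulates the wild type and the standard knockdown/overexpression
#' genotypes under constant light (red and blue both at `LL_intensity`) and
#' constant darkness, and reports the CL mRNA free-running period, or
#' `"arr"` for arrhythmic traces.
#'
#' @param params a `pcs_params` object.
#' @param t_end horizon per simulation (h).
#' @param LL_intensity red and blue intensity of the constant-light
#'   condition (umol m-2 s-1).
#' @param ... passed to [pcs_simulate()].
#' @return data frame with columns `genotype`, `condition`, `period`
#'   (`NA` when arrhythmic), `rhythmic`, `label` (formatted period or
#'   `"arr"`).
#' @export
run_validation_battery <- function(params, t_end = 600, LL_intensity = 40,
                                   ...) {
  params <- validate_params(params)
  progs <- list(LL = light_constant(LL_intensity, LL_intensity),
                DD = light_constant(0, 0))
  out <- lapply(.battery_rows, function(row) {
    p <- params
    if (!is.na(row[[2]]))
      p <- apply_genotype(p, genotype(row[[2]], row[[3]], label = row[[1]]))
    tr <- pcs_simulate(p, progs[[row[[4]]]], t_end, ...)
    est <- estimate_period(tr, "CL_m")
    data.frame(genotype = row[[1]], condition = row[[4]],
               period = est$period, rhythmic = est$rhythmic,
               label = if (est$rhythmic) sprintf("%.1f", est$period) else "arr",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
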