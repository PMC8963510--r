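# A fixed, fully specified parameter set for unit tests that must not depend
# on the packaged calibration. Values are arbitrary but dynamically sane
# (positive, oscillation not required).
test_params <- function() {
  nm <- phytoclock:::.pcs_par_names
  v <- setNames(seq(0.31, by = 0.017, length.out = length(nm)), nm)
  v[c("eta1", "eta2", "Ctot")] <- 1
  v[paste0("K", 1:12)] <- seq(0.5, 1.6, length.out = 12)
  v[c("Ak7", "Bk8", "Ck9")] <- c(0.9, 1.1, 1.3)
  validate_params(v)
}

# Independent re-derivation of the model right-hand side, written directly
# from the printed rate equations (kept deliberately separate from the
# compiled implementation it is used to check).
reference_rhs <- function(state, I_red, I_blue, params,
                          variant = "full",
                          complex_decay_uses_complex = TRUE,
                          ox = numeric(5)) {
  p <- as.list(unclass(params))
  if (variant == "no_binding") {
    p$kmpac <- p$kmpbc <- p$kmpcc <- 0
    p$de2 <- p$de3 <- p$de4 <- p$de5 <- 0
  }
  s <- as.list(state)
  thB <- as.numeric(I_red != 0)
  thC <- as.numeric(I_blue != 0)
  thA <- max(thB, thC)
  TA <- s$PhyA + s$COP1_PhyA
  TB <- s$PhyB + s$COP1_PhyB
  TC <- s$Cry1 + s$COP1_Cry1
  La <- p$q1a * TA * thA + p$q3a * TB * log(p$eta1 * I_red + 1) * thB +
        p$q4a * TC * log(p$eta2 * I_blue + 1) * thC
  Lb <- p$q1b * TA * thA + p$q3b * TB * log(p$eta1 * I_red + 1) * thB +
        p$q4b * TC * log(p$eta2 * I_blue + 1) * thC
  hill2 <- function(x, K) (x / K)^2
  d <- numeric(18)
  d[1] <- (p$v1 + La) / (1 + hill2(s$P97_p, p$K1) + hill2(s$P51_p, p$K2)) +
          ox[1] - (p$k1L * thA + p$k1D * (1 - thA)) * s$CL_m
  d[2] <- (p$p1 + p$p1L * thA) * s$CL_m - p$d1 * s$CL_p
  d[3] <- (p$v2 + Lb) / (1 + hill2(s$CL_p, p$K3) + hill2(s$P51_p, p$K4) +
          hill2(s$EL_p, p$K5)) + ox[2] - p$k2 * s$P97_m
  d[4] <- p$p2 * s$P97_m - (p$d2D * (1 - thA) + p$d2L * thA) * s$P97_p
  d[5] <- p$v3 / (1 + hill2(s$CL_p, p$K6) + hill2(s$P51_p, p$K7)) +
          ox[3] - p$k3 * s$P51_m
  d[6] <- p$p3 * s$P51_m - (p$d3D * (1 - thA) + p$d3L * thA) * s$P51_p
  d[7] <- thA * (p$v4 / (1 + hill2(s$CL_p, p$K8) + hill2(s$P51_p, p$K9) +
          hill2(s$EL_p, p$K10)) + ox[4]) - p$k4 * s$EL_m
  d[8] <- p$p4 * s$EL_m - p$de1 * s$EL_p -
          ((p$de2 * s$COP1 + p$de3 * s$COP1_PhyA) / p$Ctot) * s$EL_p -
          ((p$de4 * s$COP1_PhyB + p$de5 * s$COP1_Cry1) / p$Ctot) * s$EL_p
  d[9] <- p$v5 / (1 + hill2(s$EL_p, p$K11)) + ox[5] - p$k5 * s$PIF_m
  d[10] <- p$p5 * s$PIF_m - (p$d5D * (1 - thA) + p$d5L * thA) * s$PIF_p
  d[11] <- p$g1 + p$g2 * s$PIF_p^2 / (p$K12^2 + s$PIF_p^2)
  d[12] <- (1 - thA) * p$Ap3 - p$Am7 * s$PhyA / (p$Ak7 + s$PhyA) -
           p$q2 * thA * s$PhyA -
           p$kmpac * thA * s$PhyA * s$COP1 + p$kd * s$COP1_PhyA
  d[13] <- p$Bp4 - p$Bm8 * s$PhyB / (p$Bk8 + s$PhyB) -
           p$kmpbc * thB * s$PhyB * s$COP1 + p$kd * s$COP1_PhyB
  d[14] <- p$Cp5 - p$Cm9 * s$Cry1 / (p$Ck9 + s$Cry1) -
           p$kmpcc * thC * s$Cry1 * s$COP1 + p$kd * s$COP1_Cry1
  decB <- if (complex_decay_uses_complex) s$COP1_PhyB else s$PhyB
  decC <- if (complex_decay_uses_complex) s$COP1_Cry1 else s$Cry1
  d[15] <- -p$kmpac * thA * s$PhyA * s$COP1 + p$kd * s$COP1_PhyA +
           p$kd * s$COP1_PhyB - p$kmpbc * thB * s$PhyB * s$COP1 -
           p$kmpcc * thC * s$Cry1 * s$COP1 + p$kd * s$COP1_Cry1 +
           p$Am7 * s$COP1_PhyA / (p$Ak7 + s$COP1_PhyA) +
           p$q2 * thA * s$COP1_PhyA +
           p$Bm8 * s$COP1_PhyB / (p$Bk8 + s$COP1_PhyB) +
           p$Cm9 * s$COP1_Cry1 / (p$Ck9 + s$COP1_Cry1)
  d[16] <- p$kmpac * thA * s$PhyA * s$COP1 - p$kd * s$COP1_PhyA -
           p$Am7 * s$COP1_PhyA / (p$Ak7 + s$COP1_PhyA) -
           p$q2 * thA * s$COP1_PhyA
  d[17] <- p$kmpbc * thB * s$PhyB * s$COP1 - p$kd * s$COP1_PhyB -
           p$Bm8 * decB / (p$Bk8 + decB)
  d[18] <- p$kmpcc * thC * s$Cry1 * s$COP1 - p$kd * s$COP1_Cry1 -
           p$Cm9 * decC / (p$Ck9 + decC)
  setNames(d, phytoclock:::.pcs_state_names)
}

# random valid states for property tests
random_state <- function(rng_scale = 3) {
  s <- setNames(runif(18, 0, rng_scale), phytoclock:::.pcs_state_names)
  s
}
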