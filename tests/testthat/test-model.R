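test_that("total photoreceptor pools are free plus complexed", {
  y <- pcs_initial_state(test_params())
  # complexes start at zero: totals equal free concentrations
  tot <- total_photoreceptors(y)
  expect_equal(unname(tot), unname(y[c("PhyA", "PhyB", "Cry1")]))
  y["PhyA"] <- 0.3; y["COP1_PhyA"] <- 0.2
  expect_equal(total_photoreceptors(y)[["TPhyA"]], 0.5)
})

test_that("light input evaluates its closed form and gates on indicators", {
  p <- test_params()
  y <- pcs_initial_state(p)
  # dark: all indicator-gated terms vanish regardless of state
  expect_equal(light_input("a", y, 0, 0, p), 0)
  y2 <- random_state()
  expect_equal(light_input("b", y2, 0, 0, p), 0)
  # hand evaluation: all q = 1, eta = 1, totals = 1, I_red = e - 1, no blue
  v <- unclass(p)
  v[c("q1a", "q3a", "q4a")] <- 1
  v[c("eta1", "eta2")] <- 1
  p1 <- validate_params(v)
  y1 <- pcs_initial_state(p1)
  y1[c("PhyA", "PhyB", "Cry1")] <- 1
  y1[c("COP1_PhyA", "COP1_PhyB", "COP1_Cry1")] <- 0
  expect_equal(light_input("a", y1, exp(1) - 1, 0, p1), 2, tolerance = 1e-12)
  # blue term contributes nothing when only red is on
  yc <- y1; yc["Cry1"] <- 77
  expect_equal(light_input("a", yc, exp(1) - 1, 0, p1), 2, tolerance = 1e-12)
  expect_error(light_input("c", y1, 0, 0, p1))
})

test_that("compiled right-hand side matches an independent re-derivation", {
  p <- test_params()
  set.seed(42)
  lights <- list(c(0, 0), c(40, 0), c(0, 25), c(26.62, 26.62), c(80, 80))
  for (variant in c("full", "no_binding")) {
    for (cdc in c(TRUE, FALSE)) {
      for (li in lights) {
        for (rep in 1:5) {
          y <- random_state()
          got <- clock_rhs(y, li[1], li[2], p, variant = variant,
                           complex_decay_uses_complex = cdc)
          want <- reference_rhs(y, li[1], li[2], p, variant = variant,
                                complex_decay_uses_complex = cdc)
          expect_equal(got, want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("dark limits: growth floor, gated EL transcription", {
  p <- test_params()
  y <- pcs_initial_state(p)
  y["PIF_p"] <- 0
  d <- clock_rhs(y, 0, 0, p)
  # with no PIF protein the Hill term vanishes: basal elongation only
  expect_equal(d[["HYP"]], p[["g1"]])
  # EL transcription is light-gated: pure decay in darkness
  y2 <- random_state()
  d2 <- clock_rhs(y2, 0, 0, p)
  expect_equal(d2[["EL_m"]], -p[["k4"]] * y2[["EL_m"]], tolerance = 1e-12)
})

test_that("no-binding variant keeps complexes frozen at zero", {
  p <- test_params()
  y <- pcs_initial_state(p)  # complexes at 0
  for (li in list(c(40, 0), c(0, 25), c(50, 50))) {
    d <- clock_rhs(y, li[1], li[2], p, variant = "no_binding")
    expect_equal(unname(d[c("COP1_PhyA", "COP1_PhyB", "COP1_Cry1")]),
                 c(0, 0, 0))
  }
  # in the dark the full variant also has no binding flux into complexes
  d <- clock_rhs(y, 0, 0, p, variant = "full")
  expect_equal(unname(d[c("COP1_PhyA", "COP1_PhyB", "COP1_Cry1")]),
               c(0, 0, 0))
})

test_that("ablation reduces photoreceptor dynamics to the standalone forms", {
  # with binding off, the photoreceptor derivatives must equal the
  # pre-COP1 formulation: synthesis minus saturable decay (and the
  # light-gated extra decay for phyA), with zero exchange
  p <- test_params()
  set.seed(7)
  for (li in list(c(0, 0), c(40, 0), c(0, 25), c(30, 30))) {
    th <- light_indicators(li[1], li[2])
    for (rep in 1:5) {
      y <- random_state()
      # complexes are dynamically frozen at zero under the ablation
      y[c("COP1_PhyA", "COP1_PhyB", "COP1_Cry1")] <- 0
      d <- clock_rhs(y, li[1], li[2], p, variant = "no_binding")
      expect_equal(d[["PhyA"]],
        (1 - th[["theta_phyA"]]) * p[["Ap3"]] -
          p[["Am7"]] * y[["PhyA"]] / (p[["Ak7"]] + y[["PhyA"]]) -
          p[["q2"]] * th[["theta_phyA"]] * y[["PhyA"]],
        tolerance = 1e-12)
      expect_equal(d[["PhyB"]],
        p[["Bp4"]] - p[["Bm8"]] * y[["PhyB"]] / (p[["Bk8"]] + y[["PhyB"]]),
        tolerance = 1e-12)
      expect_equal(d[["Cry1"]],
        p[["Cp5"]] - p[["Cm9"]] * y[["Cry1"]] / (p[["Ck9"]] + y[["Cry1"]]),
        tolerance = 1e-12)
    }
  }
})

test_that("overexpression offsets enter the production terms additively", {
  p <- test_params()
  y <- random_state()
  d0 <- clock_rhs(y, 40, 40, p)
  for (gene in c("CL", "P97", "P51", "PIF")) {
    pox <- apply_genotype(p, genotype(gene, "overexpression", strength = 0.37))
    d1 <- clock_rhs(y, 40, 40, pox)
    target <- c(CL = "CL_m", P97 = "P97_m", P51 = "P51_m", PIF = "PIF_m")[gene]
    expect_equal(d1[[target]] - d0[[target]], 0.37, tolerance = 1e-12)
    others <- setdiff(names(d0), target)
    expect_equal(d1[others], d0[others])
  }
  # EL overexpression shares the light gate of EL transcription
  pox <- apply_genotype(p, genotype("EL", "overexpression", strength = 0.37))
  expect_equal(clock_rhs(y, 40, 0, pox)[["EL_m"]] -
               clock_rhs(y, 40, 0, p)[["EL_m"]], 0.37, tolerance = 1e-12)
  expect_equal(clock_rhs(y, 0, 0, pox)[["EL_m"]],
               clock_rhs(y, 0, 0, p)[["EL_m"]])
})
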