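test_that("light indicators follow the red/blue switch semantics", {
  expect_equal(unname(light_indicators(40, 0)), c(1, 1, 0))
  expect_equal(unname(light_indicators(0, 0)), c(0, 0, 0))
  expect_equal(unname(light_indicators(0, 25)), c(1, 0, 1))
  expect_equal(unname(light_indicators(26.62, 26.62)), c(1, 1, 1))
  # any strictly positive intensity flips the flag
  expect_equal(unname(light_indicators(1e-12, 0)), c(1, 1, 0))
  expect_error(light_indicators(-1, 0), "finite and >= 0")
  expect_error(light_indicators(0, NaN), "finite and >= 0")
})

test_that("indicator consistency: theta_phyA = max(theta_phyB, theta_cry1)", {
  set.seed(11)
  for (i in 1:50) {
    ir <- sample(c(0, runif(1, 0, 100)), 1)
    ib <- sample(c(0, runif(1, 0, 100)), 1)
    th <- light_indicators(ir, ib)
    expect_equal(th[["theta_phyA"]],
                 max(th[["theta_phyB"]], th[["theta_cry1"]]))
  }
})

test_that("light programs validate their segment structure", {
  expect_error(light_program(data.frame(t_start = 0, t_end = 0,
                                        I_red = 1, I_blue = 0)),
               "t_end > t_start")
  expect_error(light_program(data.frame(t_start = c(0, 5), t_end = c(4, 10),
                                        I_red = 0, I_blue = 0)),
               "contiguous")
  expect_error(light_program(data.frame(t_start = 0, t_end = 10,
                                        I_red = -3, I_blue = 0)),
               ">= 0")
  # cyclic programs must tile the period exactly
  expect_error(light_program(data.frame(t_start = 0, t_end = 20,
                                        I_red = 0, I_blue = 0), period = 24),
               "tile")
})

test_that("photoperiod sampling is half-open with cyclic wrap", {
  prog <- light_photoperiod("6L18D", I_red = 26.62, I_blue = 0)
  expect_equal(unname(light_sample(prog, 3)), c(26.62, 0))
  expect_equal(unname(light_sample(prog, 10)), c(0, 0))
  # boundary instant belongs to the following segment
  expect_equal(unname(light_sample(prog, 6)), c(0, 0))
  expect_equal(unname(light_sample(prog, 24)), c(26.62, 0))
  # wrap: t = 26 under 2L22D equals t = 2
  p2 <- light_photoperiod("2L22D", 10, 0)
  expect_equal(light_sample(p2, 26), light_sample(p2, 2))
  expect_equal(unname(light_sample(p2, 26)), c(0, 0))
  # constant dark
  expect_equal(unname(light_sample(light_constant(0, 0), 123.4)), c(0, 0))
  # beyond a non-cyclic program
  flat <- flatten_program(prog, 48)
  expect_error(light_sample(flat, 49), "beyond the end")
})

test_that("photoperiod labels parse and reject malformed input", {
  expect_equal(unname(parse_photoperiod("6L18D")), c(6, 18))
  expect_equal(unname(parse_photoperiod("2L22D")), c(2, 22))
  expect_error(parse_photoperiod("6L18"), "label")
  expect_error(light_photoperiod("18D6L", 1, 0), "label")
})

test_that("the six stimulus protocols carry the published light settings", {
  cases <- list(
    I   = list(bg = c(0, 0),  st = c(40, 0),   dur = 1),
    II  = list(bg = c(80, 0), st = c(160, 0),  dur = 2),
    III = list(bg = c(80, 0), st = c(0, 0),    dur = 2),
    IV  = list(bg = c(0, 0),  st = c(0, 25),   dur = 1),
    V   = list(bg = c(80, 0), st = c(0, 80),   dur = 2),
    VI  = list(bg = c(80, 0), st = c(80, 80),  dur = 2))
  for (id in names(cases)) {
    proto <- build_protocol(id, onset = 100)
    prog <- compose_protocol(proto, t_end = 200)
    expect_equal(unname(light_sample(prog, 99.9)), cases[[id]]$bg,
                 info = paste("background, test", id))
    expect_equal(unname(light_sample(prog, 101 - 1e-9)), cases[[id]]$st,
                 info = paste("stimulus, test", id))
    expect_equal(unname(light_sample(prog, 100 + cases[[id]]$dur + 1e-9)),
                 cases[[id]]$bg, info = paste("after stimulus, test", id))
  }
  expect_error(build_protocol("VII", 10), "unknown PRC test")
})

test_that("composing preserves the background outside the stimulus window", {
  proto <- build_protocol("II", onset = 57.3)
  prog <- compose_protocol(proto, t_end = 150)
  tt <- seq(0, 149.9, by = 0.7)
  outside <- tt < 57.3 | tt >= 59.3
  bg <- proto$background
  got <- light_sample(prog, tt)
  want <- light_sample(bg, tt)
  expect_equal(got[outside, ], want[outside, ])
  # inside the window the replace-mode stimulus substitutes the background
  expect_true(all(got[!outside, "I_red"] == 160))
  # splicing preserves total duration
  segs <- prog$segments
  expect_equal(segs$t_start[1], 0)
  expect_equal(segs$t_end[nrow(segs)], 150)
  # stimulus past the horizon is rejected
  expect_error(compose_protocol(build_protocol("I", onset = 199.5), 200),
               "beyond")
})

test_that("add-mode stimulus sums intensities onto the background", {
  proto <- build_protocol("VI", onset = 30)
  prog <- compose_protocol(proto, t_end = 60)
  expect_equal(unname(light_sample(prog, 31)), c(80, 80))
  # a null stimulus composes to a program pointwise equal to background
  null_proto <- build_protocol("II", onset = 30)
  null_proto$stimulus$I_red <- 80 # same as background
  prog0 <- compose_protocol(null_proto, t_end = 60)
  tt <- seq(0, 59.9, by = 0.3)
  expect_equal(light_sample(prog0, tt), light_sample(proto$background, tt))
})

test_that("cyclic programs integrate exactly by segment arithmetic", {
  prog <- light_photoperiod("6L18D", 26.62, 0)
  segs <- prog$segments
  seg_sum <- sum((segs$t_end - segs$t_start) * segs$I_red)
  # piecewise-constant integral over one period via dense sampling
  tt <- seq(0, 24 - 1e-6, by = 1e-3)
  approx_int <- mean(light_sample(prog, tt)[, "I_red"]) * 24
  expect_equal(seg_sum, 6 * 26.62)
  expect_equal(approx_int, seg_sum, tolerance = 1e-3)
})
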