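test_that("rectangular hyperbola evaluates to hand-checked values", {
  p <- rect_params(alpha = 0.05, pnmax = 30, rp = 5)
  expect_equal(pn_model(p, 0), -5)
  expect_equal(pn_model(p, 400), 600 / 50 - 5)   # = 7
  # saturation limit: Pnmax - Rp
  p0 <- rect_params(alpha = 0.05, pnmax = 30, rp = 0)
  expect_equal(pn_model(p0, 1e9), 30, tolerance = 1e-5)
  expect_error(pn_model(p, -1), "non-negative")
})

test_that("Michaelis-Menten evaluates to hand-checked values", {
  p <- mm_params(pnmax = 30, k = 600, rp = 5)
  expect_equal(pn_model(p, 600), 15 - 5)         # half-saturation
  expect_equal(pn_model(p, 0), -5)
})

test_that("Michaelis-Menten equals rectangular hyperbola under K = Pnmax/alpha", {
  alpha <- 0.05; pnmax <- 30; rp <- 5
  grid <- seq(0, 1200, by = 1)
  rh <- pn_model(rect_params(alpha, pnmax, rp), grid)
  mm <- pn_model(mm_params(pnmax, pnmax / alpha, rp), grid)
  expect_lt(max(abs(rh - mm)), 1e-12)
})

test_that("modified rectangular hyperbola evaluates to hand-checked values", {
  p <- modrect_params(a = 0.06, b = 3e-4, c = 1e-3, rp = 5)
  expect_equal(pn_model(p, 0), -5)
  expect_equal(pn_model(p, 500), 0.06 * 0.85 / 1.5 * 500 - 5)  # = 12
  # degenerate b = c = 0 collapses to a line; rp > 0 needed for b,c = 0 check
  lin <- modrect_params(a = 0.06, b = 0, c = 0, rp = 5)
  expect_equal(pn_model(lin, c(10, 100, 700)), 0.06 * c(10, 100, 700) - 5)
})

test_that("all empirical models return exactly -rp at zero CO2", {
  for (p in list(rect_truth(), mm_truth(), modrect_truth()))
    expect_identical(pn_model(p, 0), -p$rp)
})

test_that("biochemical model matches an independent sub-rate computation", {
  p <- fvcb_params(vcmax = 100, j = 150, tpu = 10, rd = 1,
                   kc = 270, ko = 165, o = 210, gamma_star = 37)
  # independent arithmetic: wc = 100*50/(50 + 270*(1 + 210/165)) = 7.5342...,
  # wj = 150*50/(200 + 296) = 15.1209..., wp = 30; min is wc
  wc <- 100 * 50 / (50 + 270 * (1 + 210 / 165))
  expect_equal(unname(fvcb_limits(p, 50)[1, "wc"]), wc)
  expect_equal(pn_model(p, 50), wc * (1 - 37 / 50) - 1)
  expect_equal(pn_model(p, 50), 0.9589041, tolerance = 1e-7)
  # gross term vanishes at ci = gamma_star
  expect_equal(pn_model(p, 37), -1)
  # TPU-limited asymptote: 3*TPU - rd
  expect_equal(pn_model(p, 1e7), 3 * 10 - 1, tolerance = 1e-4)
  expect_error(pn_model(p, 0), "positive")
})

test_that("biochemical model is non-decreasing while Rubisco/RuBP limited, and min never exceeds a branch", {
  p <- fvcb_truth()
  ci <- seq(40, 900, by = 5)
  pn <- pn_model(p, ci)
  w <- fvcb_limits(p, ci)
  gross <- pn + p$rd
  expect_true(all(gross / (1 - p$gamma_star / ci) <= w[, "wc"] + 1e-12))
  expect_true(all(gross / (1 - p$gamma_star / ci) <= w[, "wj"] + 1e-12))
  expect_true(all(gross / (1 - p$gamma_star / ci) <= w[, "wp"] + 1e-12))
  active <- pmin(w[, "wc"], w[, "wj"]) < w[, "wp"]
  expect_true(all(diff(pn[active]) > 0))  # monotone while wc or wj limits
})

test_that("derived quantities: intercept, compensation point, realized maximum", {
  dq <- derived_quantities(rect_params(0.05, 30, 5))
  expect_equal(dq$intercept_at_zero, -5)
  # analytic compensation point of the rectangular hyperbola:
  # alpha*pnmax*C/(alpha*C+pnmax) = rp  =>  C = rp*pnmax/(alpha*(pnmax-rp))
  expect_equal(dq$co2_compensation_point, 5 * 30 / (0.05 * 25),
               tolerance = 1e-8)

  expect_equal(derived_quantities(modrect_params(0.06, 3e-4, 1e-3,
                                                 rp = 0))$co2_compensation_point,
               0)

  # brute-force grid oracle for the realized maximum
  p <- modrect_params(0.06, 3e-4, 1e-3, 5)
  grid <- seq(0, 1200, by = 0.01)
  oracle <- max(pn_model(p, grid))
  expect_equal(derived_quantities(p)$pn_max_realized, oracle,
               tolerance = 1e-6)
})

test_that("parameter constructors enforce invariants", {
  expect_error(rect_params(-0.1, 30, 5), "positive")
  expect_error(mm_params(30, 0, 5), "positive")
  expect_error(modrect_params(0.06, -1e-4, 1e-3, 5), "non-negative")
  expect_error(fvcb_params(100, 150, 10, rd = 1, gamma_star = 300),
               "below 'kc'")
  expect_error(fvcb_params(100, 150, 10, rd = -1), "non-negative")
})
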