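test_that("noiseless curves return their generating parameters (all model families)", {
  cases <- list(
    rect    = list(truth = rect_truth(), x = "ca"),
    mm      = list(truth = mm_truth(), x = "ca"),
    modrect = list(truth = modrect_truth(), x = "ca"),
    fvcb    = list(truth = fvcb_truth(), x = "ci"))
  for (mod in names(cases)) {
    truth <- cases[[mod]]$truth
    conc <- if (cases[[mod]]$x == "ci") 0.75 * ca_grid else ca_grid
    d <- noiseless_curve(truth, conc, cases[[mod]]$x)
    fit <- fit_co2_response(d, model = mod, x = cases[[mod]]$x)
    tv <- unlist(truth[names(coef(fit))])
    expect_lt(max(abs(coef(fit) - tv) / abs(tv)), 1e-4)
    expect_gt(fit$r2, 0.999999)
    expect_true(fit$converged)
  }
})

test_that("too few points is an input error", {
  d <- data.frame(ca = c(0, 400, 1200), pn = c(-5, 10, 15))
  expect_error(fit_co2_response(d, "rect", "ca"), "at least 5")
  # fvcb also counts only usable (ci > epsilon) points
  d2 <- data.frame(ci = c(0, 0.5, 300, 600, 900), pn = c(-2, -2, 10, 14, 15))
  expect_error(fit_co2_response(d2, "fvcb", "ci"), "at least 5")
})

test_that("initial guesses are sane and degenerate curves fall back to defaults", {
  # intercept read-off
  d <- noiseless_curve(rect_truth())
  g <- initial_guess(d$ca, d$pn, "rect")
  expect_equal(unname(g["rp"]), 6.5)
  # within 50% of the true saturation rate
  expect_lt(abs(g["pnmax"] - 25) / 25, 0.5)
  # all-equal responses: fixed defaults, no error
  g2 <- initial_guess(ca_grid, rep(3, 12), "modrect")
  expect_true(all(is.finite(g2)) && all(g2 > 0))
  g3 <- initial_guess(ca_grid, rep(3, 12), "fvcb")
  expect_true(all(is.finite(g3)))
})

test_that("returned fit has the best SSR among multi-start candidates and refits its own predictions to r2 = 1", {
  d <- noiseless_curve(modrect_truth())
  d$pn <- d$pn + c(0.1, -0.2, 0.15, -0.05, 0.2, -0.1, 0, 0.1, -0.15, 0.05,
                   0.1, -0.1)
  fit <- fit_co2_response(d, "modrect", "ca", n_starts = 8)
  # single-start fits from perturbed starting points never beat it
  for (scale in c(0.5, 1.5, 3)) {
    g <- coef(fit) * scale
    alt <- fit_co2_response(d, "modrect", "ca", start = g, n_starts = 1)
    expect_gte(alt$ssr, fit$ssr - 1e-10)
  }
  refit <- fit_co2_response(data.frame(ca = d$ca, pn = fitted(fit)),
                            "modrect", "ca")
  expect_equal(refit$r2, 1, tolerance = 1e-9)
})

test_that("median fitted respiration under Gaussian noise stays within 5% of truth", {
  truth <- modrect_truth()
  pn0 <- pn_model(truth, ca_grid)
  rps <- vapply(seq_len(200), function(i) {
    set.seed(1000 + i)
    d <- data.frame(ca = ca_grid, pn = pn0 + rnorm(12, 0, 0.3))
    fit_co2_response(d, "modrect", "ca", n_starts = 3)$respiration_estimate
  }, 0)
  expect_lt(abs(stats::median(rps) - truth$rp) / truth$rp, 0.05)
})

test_that("respiration estimate equals minus the model value at zero CO2", {
  d <- noiseless_curve(rect_truth())
  d$pn <- d$pn + rep(c(0.12, -0.12), 6)
  for (mod in c("rect", "mm", "modrect")) {
    fit <- fit_co2_response(d, mod, "ca")
    expect_equal(fit$respiration_estimate, -pn_model(fit$params, 0))
    expect_lte(fit$r2, 1)
  }
})

test_that("fitted-vs-measured comparison reproduces the deviation arithmetic", {
  # wheat, modified model: A/Ci 5.599, A/Ca 2.716, measured 2.036
  dr <- deviation_reduction(5.599, 2.716, 2.036)
  expect_equal(dr$delta_ci, 3.563)
  expect_equal(dr$delta_ca, 0.680)
  expect_equal(dr$pct_reduction, 80.915, tolerance = 1e-4)
  # zero deviation: reduction undefined, reported absent
  expect_true(is.na(deviation_reduction(2.036, 2.5, 2.036)$pct_reduction))

  fits <- data.frame(species = rep(c("wheat", "bean"), each = 2),
                     model = "modrect",
                     x_axis = c("ci", "ca", "ci", "ca"),
                     estimate = c(5.599, 2.716, 4.612, 2.779))
  measured <- data.frame(species = c("wheat", "bean"),
                         measured = c(2.036, 1.893))
  rep_tab <- compare_fitted_measured(fits, measured)
  expect_equal(rep_tab$pct_reduction[rep_tab$species == "bean"], 67.414,
               tolerance = 1e-4)
  expect_true(all(rep_tab$bias_ci > 0))  # both axes overestimate here

  # a model lacking its counterpart axis is skipped with a warning
  partial <- fits[-2, ]   # wheat loses its A/Ca fit; bean stays complete
  expect_warning(rep2 <- compare_fitted_measured(partial, measured),
                 "missing")
  expect_equal(rep2$species, "bean")
})
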