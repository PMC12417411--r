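test_that("default truth profiles hit the configured magnitudes", {
  tp <- true_profiles(sim_config())
  w <- tp[tp$species == "wheat", ]
  expect_equal(w$rp[w$ca == 600], 12.307)
  expect_equal(w$rp[w$ca == 0], 4.923)
  expect_equal(w$rn[w$ca == 0], 3.862)
  expect_equal(w$rn[w$ca == 1200], 1.453)
  b <- tp[tp$species == "bean", ]
  expect_equal(b$rp[b$ca == 1000], 11.673)
  expect_equal(b$rp[b$ca == 0], 4.686)
  # vertex symmetry of the quadratic profile
  cfg <- sim_config(ca_levels = c(0, 400, 600, 800, 1200))
  tp2 <- true_profiles(cfg)
  w2 <- tp2[tp2$species == "wheat", ]
  expect_equal(w2$rp[w2$ca == 400], w2$rp[w2$ca == 800])
  # all profiles non-negative on the grid
  expect_true(all(tp$rp >= 0 & tp$rd >= 0 & tp$rn >= 0))
})

test_that("simulation is deterministic given a seed and leaves the RNG alone", {
  cfg <- sim_config(seed = 99)
  set.seed(1); before <- .Random.seed
  d1 <- simulate_gas_exchange(cfg)
  expect_identical(before, .Random.seed)
  d2 <- simulate_gas_exchange(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_gas_exchange(cfg, seed = 100)
  expect_false(identical(d1$pn, d3$pn))
})

test_that("noiseless generation closes the partitioning equations by construction", {
  cfg <- quiet_config()
  d <- simulate_gas_exchange(cfg)
  tp <- true_profiles(cfg)
  for (sp in c("wheat", "bean")) {
    tsp <- tp[tp$species == sp, ]
    l21 <- d[d$species == sp & d$par > 0 & d$o2 > 0.1, ]
    l2 <- d[d$species == sp & d$par > 0 & d$o2 < 0.1, ]
    l21 <- l21[order(l21$ca), ]; l2 <- l2[order(l2$ca), ]
    expect_equal(photorespiration_rate(l2$pn, l21$pn), tsp$rp,
                 tolerance = 1e-12)
    # at zero CO2 the 21% light flux is minus the combined respiration
    expect_equal(l21$pn[l21$ca == 0], -(tsp$rp[1] + tsp$rd[1]))
    # intercellular CO2 is the fixed fraction of ambient
    expect_equal(l21$ci, cfg$ci_ratio * l21$ca)
  }
})

test_that("full pipeline on noiseless defaults puts the photorespiration peaks at 600 and 1000", {
  series <- build_respiration_series(simulate_gas_exchange(quiet_config()))
  rp_w <- series_quantity(series, "wheat", "rp")
  rp_b <- series_quantity(series, "bean", "rp")
  expect_equal(peak_ca(rp_w$ca, rp_w$mean)$ca_peak, 600)
  expect_equal(peak_ca(rp_b$ca, rp_b$mean)$ca_peak, 1000)
})

test_that("replicate means stay within 3 SE of truth at >= 95% of grid points", {
  cfg0 <- sim_config()   # noise_sd = 0.3, n = 5
  tp <- true_profiles(cfg0)
  bound <- 3 * 0.3 / sqrt(5)
  hits <- 0L; total <- 0L
  for (s in 1:100) {
    series <- build_respiration_series(
      simulate_gas_exchange(cfg0, seed = 5000 + s))
    for (sp in c("wheat", "bean")) {
      got <- series_quantity(series, sp, "rp")$mean
      truth <- tp$rp[tp$species == sp]
      hits <- hits + sum(abs(got - truth) <= bound)
      total <- total + length(truth)
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(ci_ratio = 0), "ci_ratio")
  expect_error(sim_config(ca_levels = c(0, 100)), "ca_levels")
  expect_error(species_profile("x", rp_min = 5, rp_max = 4, rp_peak_ca = 600,
                               rn_at_zero = 3, rn_at_max_ca = 1,
                               gross_a = 0.1, gross_b = 3e-4, gross_c = 1e-3),
               "below")
  # a peak so early the quadratic dips below zero at high CO2
  bad <- species_profile("x", rp_min = 1, rp_max = 10, rp_peak_ca = 300,
                         rn_at_zero = 3, rn_at_max_ca = 1,
                         gross_a = 0.1, gross_b = 3e-4, gross_c = 1e-3)
  expect_error(sim_config(species = list(x = bad)), "below zero")
})
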