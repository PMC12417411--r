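test_that("differential-oxygen subtraction isolates photorespiration", {
  # wheat zero-CO2 fluxes: Pn(2%) = -Rd = -2.036, Pn(21%) = -RL = -6.548
  expect_equal(photorespiration_rate(-2.036, -6.548), 4.512)
  expect_equal(photorespiration_rate(3.3, 3.3), 0)
  # bean means subtract to 4.441 (direct arithmetic on the printed values)
  expect_equal(photorespiration_rate(-1.893, -6.334), 4.441)
  expect_error(photorespiration_rate(c(1, 2), 1), "equal length")
})

test_that("recovery/inhibition profile has the documented shape", {
  ca <- c(0, 200, 600, 1200)
  prof <- recovery_inhibition(ca, c(4.923, 9, 12.307, 5.2))
  expect_equal(attr(prof, "rp_max"), 12.307)
  expect_equal(attr(prof, "ca_at_peak"), 600)
  expect_equal(prof$ratio[1], (12.307 - 4.923) / 12.307)
  expect_equal(prof$ratio[prof$ca == 600], 0)
  expect_true(all(prof$ratio >= 0 & prof$ratio <= 1))
  # phases are a prefix (recovery) then a suffix (inhibition)
  expect_equal(prof$phase, c("recovery", "recovery", "recovery",
                             "inhibition"))

  # flat series: all ratios zero, peak tie broken to the lowest CO2
  flat <- recovery_inhibition(ca, rep(3, 4))
  expect_true(all(flat$ratio == 0))
  expect_equal(attr(flat, "ca_at_peak"), 0)
  # complete suppression gives ratio 1
  expect_equal(recovery_inhibition(ca, c(0, 9, 12, 5))$ratio[1], 1)

  expect_error(recovery_inhibition(c(0, 100), c(1, 2)), "at least 3")
  expect_error(recovery_inhibition(ca, rep(0, 4)), "undefined")
  expect_error(recovery_inhibition(ca, c(-1, 2, 3, 1)), "non-negative")
})

test_that("recovery ratio is anti-monotone in photorespiration", {
  set.seed(42)
  for (i in 1:20) {
    rp <- runif(8, 0.5, 12)
    prof <- recovery_inhibition(seq_along(rp) * 100, rp)
    ord <- order(prof$rp)
    expect_true(all(diff(prof$ratio[ord]) <= 1e-12))
  }
})

test_that("day respiration from the dark rate respects its bounds", {
  expect_equal(rd_in_light(3.862, 0), 3.862)
  expect_equal(rd_in_light(3.862, 1), 0)
  expect_equal(rd_in_light(3.862, 0.600), 1.5448)
  set.seed(7)
  rn <- runif(50, 0, 5); ratio <- runif(50)
  expect_true(all(rd_in_light(rn, ratio) <= rn))
  expect_error(rd_in_light(3, 1.2), "\\[0, 1\\]")
  expect_error(rd_in_light(-1, 0.5), "non-negative")
})

test_that("the partitioning pipeline recovers generator truth on noiseless data", {
  cfg <- quiet_config()
  series <- build_respiration_series(simulate_gas_exchange(cfg))
  tp <- true_profiles(cfg)
  for (sp in c("wheat", "bean")) {
    tsp <- tp[tp$species == sp, ]
    for (q in c("rp", "rd", "rn21", "rn2")) {
      got <- series_quantity(series, sp, q)$mean
      truth <- tsp[[if (q %in% c("rn21", "rn2")) "rn" else q]]
      expect_lt(max(abs(got - truth)), 1e-10)
    }
    # RL at Ca = 0 is read directly off the net-source 21% curve = Rp + Rd
    rl0 <- series_quantity(series, sp, "rl")$mean[1]
    expect_equal(rl0, tsp$rp[1] + tsp$rd[1], tolerance = 1e-10)
  }
  # single replicate: SDs absent, means intact
  expect_true(all(is.na(series$sd)))
  expect_true(all(series$n == 1L))
})

test_that("missing curve classes raise a structured error naming the class", {
  d <- simulate_gas_exchange(quiet_config())
  expect_error(build_respiration_series(d[d$par > 0, ]), "dark")
  expect_error(build_respiration_series(d[!(d$par > 0 & d$o2 < 0.1), ]),
               "light 2% O2")
  expect_error(build_respiration_series(d[, setdiff(names(d), "pn")]),
               "missing columns")
})

test_that("negative noisy photorespiration replicates are retained and flagged", {
  d <- simulate_gas_exchange(quiet_config())
  # force one replicate's low-CO2 pair to invert
  i21 <- which(d$species == "wheat" & d$par > 0 & d$o2 > 0.1 & d$ca == 0)
  i2 <- which(d$species == "wheat" & d$par > 0 & d$o2 < 0.1 & d$ca == 0)
  d$pn[i2] <- d$pn[i21] - 0.5
  series <- build_respiration_series(d)
  qc <- attr(series, "qc_negative_rp")
  expect_false(is.null(qc))
  expect_equal(qc$ca, 0)
  # the mean keeps the negative value (no clamping)
  expect_equal(series_quantity(series, "wheat", "rp")$mean[1], -0.5)
})
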