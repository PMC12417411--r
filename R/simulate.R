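# Synthetic gas-exchange generator.
#
# Emulates the study design the partitioning pipeline assumes: a 12-level
# ambient-CO2 staircase, light (saturating PAR) and dark curves at 21% and
# 2% O2, n replicates, homoscedastic Gaussian instrument noise.  The truth
# profiles are the conditions the analysis targets: a unimodal (quadratic)
# photorespiration profile anchored at its zero-CO2 value and its peak, a
# linearly declining dark respiration, and a day respiration derived from
# the dark rate through the same CO2 recovery/inhibition relation the
# pipeline inverts — so noiseless data close the partitioning equations
# exactly.

#' The study's ambient CO2 staircase
#' @export
ca_levels_default <- function() {
  c(0, 50, 80, 100, 150, 200, 380, 400, 600, 800, 1000, 1200)
}

#' Species truth profile for the synthetic generator
#'
#' @param name Species label.
#' @param rp_min Photorespiration at zero ambient CO2
#'   (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param rp_max Peak photorespiration.
#' @param rp_peak_ca Ambient CO2 of the photorespiration peak
#'   (\eqn{\mu}mol mol\eqn{^{-1}}).
#' @param rn_at_zero,rn_at_max_ca Dark respiration at the grid ends (linear
#'   in between).
#' @param gross_a,gross_b,gross_c Modified-rectangular-hyperbola parameters
#'   of the gross assimilation curve (no respiration term).
#' @return List of class `species_profile`.
#' @export
species_profile <- function(name, rp_min, rp_max, rp_peak_ca,
                            rn_at_zero, rn_at_max_ca,
                            gross_a, gross_b, gross_c) {
  check_positive(rp_min, "rp_min"); check_positive(rp_max, "rp_max")
  if (rp_min >= rp_max) stop_domain("'rp_min' must be below 'rp_max'")
  check_positive(rp_peak_ca, "rp_peak_ca")
  check_positive(rn_at_zero, "rn_at_zero")
  check_positive(rn_at_max_ca, "rn_at_max_ca")
  structure(list(name = name, rp_min = rp_min, rp_max = rp_max,
                 rp_peak_ca = rp_peak_ca, rn_at_zero = rn_at_zero,
                 rn_at_max_ca = rn_at_max_ca,
                 gross = modrect_params(gross_a, gross_b, gross_c, rp = 0)),
            class = "species_profile")
}

default_profiles <- function() {
  list(
    wheat = species_profile("wheat", rp_min = 4.923, rp_max = 12.307,
                            rp_peak_ca = 600, rn_at_zero = 3.862,
                            rn_at_max_ca = 1.453,
                            gross_a = 0.10, gross_b = 3e-4, gross_c = 1.2e-3),
    bean  = species_profile("bean", rp_min = 4.686, rp_max = 11.673,
                            rp_peak_ca = 1000, rn_at_zero = 4.040,
                            rn_at_max_ca = 1.210,
                            gross_a = 0.09, gross_b = 3e-4, gross_c = 1.5e-3))
}

#' Configuration of the synthetic gas-exchange generator
#'
#' Defaults reproduce the measurement design the analysis assumes: the
#' 12-level ambient CO2 staircase, two O2 levels (0.21 and 0.02), saturating
#' and zero PAR, five replicates, and wheat/bean truth profiles whose
#' magnitudes match the observed flux ranges (wheat photorespiration
#' 4.923 to 12.307 peaking at 600; bean 4.686 to 11.673 peaking at 1000;
#' dark respiration declining 3.862 to 1.453 and 4.040 to 1.210).
#'
#' @param species List of [species_profile()] objects.
#' @param ca_levels Ambient CO2 grid (\eqn{\mu}mol mol\eqn{^{-1}}).
#' @param n_replicates Replicates per curve.
#' @param noise_sd Homoscedastic Gaussian noise SD (flux units).
#' @param ci_ratio Fixed intercellular/ambient CO2 ratio in (0, 1].
#' @param par_light PAR of the light curves (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param seed Integer seed; simulation is bit-reproducible given it.
#' @return List of class `sim_config` (validated).
#' @export
sim_config <- function(species = default_profiles(),
                       ca_levels = ca_levels_default(),
                       n_replicates = 5, noise_sd = 0.3, ci_ratio = 0.75,
                       par_light = 2000, seed = 1L) {
  if (!length(species) || !all(vapply(species, inherits, TRUE,
                                      "species_profile")))
    stop_domain("'species' must be a list of species_profile objects")
  if (length(ca_levels) < 3L || any(ca_levels < 0) ||
      any(duplicated(ca_levels)))
    stop_domain("'ca_levels' must be >= 3 distinct non-negative values")
  ca_levels <- sort(ca_levels)
  if (n_replicates < 1L) stop_domain("'n_replicates' must be >= 1")
  if (noise_sd < 0) stop_domain("'noise_sd' must be >= 0")
  if (ci_ratio <= 0 || ci_ratio > 1) stop_domain("'ci_ratio' must be in (0, 1]")
  for (sp in species) {
    if (sp$rp_peak_ca <= min(ca_levels) || sp$rp_peak_ca > max(ca_levels))
      stop_domain(sprintf("species '%s': peak CO2 outside the grid", sp$name))
    if (1 - sp$gross$b * max(ca_levels) <= 0)
      stop_domain(sprintf("species '%s': gross curve turns invalid (1 - b*C <= 0) on the grid",
                          sp$name))
  }
  cfg <- structure(list(species = species, ca_levels = ca_levels,
                        n_replicates = as.integer(n_replicates),
                        noise_sd = noise_sd, ci_ratio = ci_ratio,
                        par_light = par_light, seed = as.integer(seed)),
                   class = "sim_config")
  tp <- true_profiles(cfg)   # validates non-negativity on the grid
  if (any(tp$rp < 0) || any(tp$rd < 0) || any(tp$rn < 0))
    stop_domain("a truth profile dips below zero on the CO2 grid")
  cfg
}

profile_rp <- function(sp, ca) {
  sp$rp_max - (sp$rp_max - sp$rp_min) * ((ca - sp$rp_peak_ca) / sp$rp_peak_ca)^2
}

profile_rn <- function(sp, ca, ca_max) {
  sp$rn_at_zero + (sp$rn_at_max_ca - sp$rn_at_zero) * ca / ca_max
}

#' Truth profiles of the synthetic generator
#'
#' Evaluates, on the configured CO2 grid, the generating profiles:
#' photorespiration \eqn{R_p(C_a)} (quadratic through its zero-CO2 value
#' with vertex at the peak), dark respiration \eqn{R_n(C_a)} (linear between
#' its endpoints), day respiration
#' \eqn{R_d(C_a) = R_n(C_a)\,R_p(C_a)/R_{p,max}} (the recycling relation the
#' partitioning scheme inverts), and the gross assimilation curve.
#'
#' @param config A [sim_config()].
#' @return Data frame: `species`, `ca`, `gross`, `rp`, `rd`, `rn`.
#' @export
true_profiles <- function(config) {
  ca <- config$ca_levels
  ca_max <- max(ca)
  do.call(rbind, lapply(config$species, function(sp) {
    rp <- profile_rp(sp, ca)
    rn <- profile_rn(sp, ca, ca_max)
    data.frame(species = sp$name, ca = ca,
               gross = pn_model(sp$gross, ca),
               rp = rp,
               rd = rn * rp / sp$rp_max,
               rn = rn,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Simulate a replicated gas-exchange dataset
#'
#' For every species, replicate and CO2 level, generates the four measured
#' curves: light at 21% O2 (\eqn{P_n = G - R_p - R_d}), light at 2% O2
#' (photorespiration suppressed: \eqn{P_n = G - R_d}), and dark at both O2
#' levels (\eqn{P_n = -R_n}; the dark rate does not depend on O2).
#' Intercellular CO2 is `ci_ratio * ca`.  Independent Gaussian noise of SD
#' `noise_sd` is added to every observation.  Output is bit-reproducible
#' for a given seed and leaves the caller's RNG state untouched.
#'
#' @param config A [sim_config()].
#' @param seed Overrides `config$seed` when given.
#' @return Long-format data frame of class `gas_exchange` with columns
#'   `species`, `replicate`, `o2`, `par`, `ca`, `ci`, `pn`.
#' @export
#' @examples
#' d <- simulate_gas_exchange(sim_config(noise_sd = 0, n_replicates = 1))
#' head(d)
simulate_gas_exchange <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) stop_domain("'config' must be a sim_config")
  tp <- true_profiles(config)
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        par = c(config$par_light, 0),
                        o2 = c(0.21, 0.02),
                        species = unname(vapply(config$species, `[[`, "",
                                                "name")),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(design)), function(i) {
    de <- as.list(design[i, ])
    pr <- tp[tp$species == de$species, ]
    signal <- if (de$par > 0) {
      if (de$o2 > 0.1) pr$gross - pr$rp - pr$rd else pr$gross - pr$rd
    } else {
      -pr$rn
    }
    data.frame(species = de$species, replicate = de$replicate,
               o2 = de$o2, par = de$par, ca = pr$ca,
               ci = config$ci_ratio * pr$ca, pn = signal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  with_preserved_rng({
    set.seed(seed)
    out$pn <- out$pn + stats::rnorm(nrow(out), 0, config$noise_sd)
  })
  structure(out, class = c("gas_exchange", "data.frame"))
}
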