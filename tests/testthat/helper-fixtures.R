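# Shared fixtures: the study's CO2 staircase and small generating models.

ca_grid <- ca_levels_default()

rect_truth <- function() rect_params(alpha = 0.08, pnmax = 25, rp = 6.5)
modrect_truth <- function() modrect_params(a = 0.07, b = 4e-4, c = 2e-3,
                                           rp = 6.3)
mm_truth <- function() mm_params(pnmax = 25, k = 25 / 0.08, rp = 6.5)
# chosen so all three limitation states are active on the 12-level Ci grid
fvcb_truth <- function() fvcb_params(vcmax = 100, j = 150, tpu = 11,
                                     rd = 1.5)

noiseless_curve <- function(params, conc = ca_grid, x = "ca") {
  keep <- if (inherits(params, "fvcb_params")) conc > 1 else rep(TRUE,
                                                                 length(conc))
  d <- data.frame(pn = pn_model(params, conc[keep]))
  d[[x]] <- conc[keep]
  d
}

quiet_config <- function(...) {
  sim_config(noise_sd = 0, n_replicates = 1, ...)
}
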