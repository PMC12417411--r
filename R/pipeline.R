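# End-to-end driver: simulate (or take) a dataset, fit every model on both
# CO2 axes per replicate, partition respiration, regress fluxes on ambient
# CO2, compare fitted respiration with the measured zero-CO2 values, and
# write all reports.

log_line <- function(con, level, ..., threshold = "info") {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[threshold]]) {
    msg <- sprintf("[%s] %s", toupper(level), paste0(...))
    writeLines(msg, con)
  }
}

#' Run the full respiratory-parameter pipeline
#'
#' Orchestrates the complete analysis: (1) obtain data — either the supplied
#' long-format dataset or a synthetic one generated from `config`; (2) fit
#' the requested CO2-response models per species, replicate, O2 level and
#' CO2 axis; (3) build the per-CO2 respiration series by the
#' differential-oxygen partitioning scheme; (4) fit CO2 trends (quadratic
#' for photorespiration and day respiration, linear for dark respiration);
#' (5) compare fitted respiration estimates against the measured zero-CO2
#' values on both axes.  All tables are written as CSV, a machine-readable
#' summary as JSON, and a run log records the seed and configuration so any
#' stochastic run can be repeated exactly.
#'
#' @param out_dir Output directory (created if absent).
#' @param data Optional `gas_exchange` data frame; when `NULL` a dataset is
#'   simulated from `config`.
#' @param config A [sim_config()] used when `data` is `NULL`.
#' @param seed Seed for the simulation (defaults to `config$seed`).
#' @param models Model identifiers to fit.
#' @param x_axes CO2 axes to fit on.
#' @param degree Polynomial degree for the unimodal flux trends.
#' @param rn_source Dark series feeding the day-respiration calculation.
#' @param n_starts Multi-start attempts per fit.
#' @param log_level `"debug"`, `"info"` or `"warn"`.
#' @return Invisibly, a list with `fits`, `series`, `profiles`, `trends`,
#'   `comparison` and the output `paths`.
#' @export
run_pipeline <- function(out_dir, data = NULL, config = sim_config(),
                         seed = NULL, models = c("modrect", "rect", "fvcb"),
                         x_axes = c("ca", "ci"), degree = 2,
                         rn_source = "21", n_starts = 8,
                         log_level = c("info", "debug", "warn")) {
  log_level <- match.arg(log_level)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  lg <- function(level, ...) log_line(con, level, ..., threshold = log_level)

  if (is.null(seed)) seed <- config$seed
  lg("info", "co2resp ", as.character(utils::packageVersion("co2resp")),
     " | R ", paste(R.version$major, R.version$minor, sep = "."))
  lg("info", "started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  lg("info", "seed: ", seed)

  if (is.null(data)) {
    lg("info", "simulating dataset: ",
       length(config$species), " species, ",
       length(config$ca_levels), " CO2 levels, n = ", config$n_replicates,
       ", noise_sd = ", config$noise_sd)
    data <- simulate_gas_exchange(config, seed = seed)
  } else {
    lg("info", "using supplied dataset: ", nrow(data), " rows")
  }
  lg("info", "config: ci_ratio=", config$ci_ratio,
     " par_light=", config$par_light,
     " ca_levels=", paste(config$ca_levels, collapse = ","))

  # --- stage: fit ------------------------------------------------------
  light <- data[is_light(data$par), , drop = FALSE]
  fit_rows <- list()
  for (sp in unique(light$species)) for (o2 in sort(unique(light$o2),
                                                    decreasing = TRUE))
    for (rep_id in unique(light$replicate[light$species == sp])) {
      curve <- light[light$species == sp & light$o2 == o2 &
                       light$replicate == rep_id, , drop = FALSE]
      if (!nrow(curve)) next
      for (mod in models) for (ax in x_axes) {
        fit <- tryCatch(
          fit_co2_response(curve, model = mod, x = ax, o2 = o2,
                           n_starts = n_starts),
          error = function(e) {
            lg("warn", "fit failed [", sp, "/", mod, "/", ax, "/rep ",
               rep_id, "]: ", conditionMessage(e))
            NULL
          })
        if (is.null(fit)) next
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          species = sp, replicate = rep_id, o2 = o2, model = mod,
          x_axis = ax, respiration_estimate = fit$respiration_estimate,
          r2 = fit$r2, ssr = fit$ssr, converged = fit$converged,
          n_points = fit$n_points_used,
          t(fit$coefficients), stringsAsFactors = FALSE)
      }
    }
  if (!length(fit_rows)) stop_domain("pipeline stage 'fit': no model converged")
  fits <- do.call(rbind, lapply(fit_rows, function(d) {
    all_cols <- unique(unlist(lapply(fit_rows, names)))
    d[setdiff(all_cols, names(d))] <- NA
    d[all_cols]
  }))
  lg("info", "fitted ", nrow(fits), " model-curve combinations")

  # --- stage: partition ------------------------------------------------
  series <- tryCatch(build_respiration_series(data, rn_source = rn_source),
                     error = function(e) stop_domain(
                       "pipeline stage 'partition': ", conditionMessage(e)))
  profiles <- attr(series, "profiles")
  lg("info", "partitioned ", length(profiles), " species")

  # --- stage: regress --------------------------------------------------
  trend_rows <- list()
  for (sp in unique(series$species)) {
    for (q in c("rp", "rd", "rn21", "rn2")) {
      sq <- series_quantity(series, sp, q)
      kind <- if (q %in% c("rp", "rd")) "polynomial" else "linear"
      tf <- tryCatch(fit_trend(sq$ca, sq$mean, kind,
                               if (kind == "linear") 1 else degree),
                     error = function(e) NULL)
      if (is.null(tf)) next
      pk <- peak_ca(sq$ca, sq$mean, degree = if (kind == "linear") NULL
                                            else degree)
      trend_rows[[length(trend_rows) + 1L]] <- data.frame(
        species = sp, quantity = q, kind = tf$kind, degree = tf$degree,
        r2 = tf$r2, x_at_extremum = tf$x_at_extremum,
        ca_peak = pk$ca_peak, monotone = pk$monotone,
        coefficients = paste(sprintf("%.10g", tf$coefficients),
                             collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  trends <- do.call(rbind, trend_rows)
  lg("info", "fitted ", nrow(trends), " CO2 trends")

  # --- stage: compare --------------------------------------------------
  # measured references at Ca = 0: R_L from the 21% curve, R_d from the 2%
  measured_rl <- do.call(rbind, lapply(unique(series$species), function(sp) {
    sq <- series_quantity(series, sp, "rl")
    data.frame(species = sp, measured = sq$mean[sq$ca == min(sq$ca)])
  }))
  measured_rd <- do.call(rbind, lapply(unique(series$species), function(sp) {
    sq <- series_quantity(series, sp, "rd")
    data.frame(species = sp, measured = sq$mean[sq$ca == min(sq$ca)])
  }))
  agg <- stats::aggregate(respiration_estimate ~ species + model + x_axis + o2,
                          data = fits, FUN = mean)
  names(agg)[names(agg) == "respiration_estimate"] <- "estimate"
  comparison <- NULL
  if (all(c("ca", "ci") %in% x_axes)) {
    cmp21 <- tryCatch(compare_fitted_measured(agg[agg$o2 > 0.1, ],
                                              measured_rl),
                      error = function(e) NULL)
    cmp2 <- tryCatch(compare_fitted_measured(agg[agg$o2 <= 0.1, ],
                                             measured_rd),
                     error = function(e) NULL)
    if (!is.null(cmp21)) cmp21 <- cbind(reference = "rl_21pct",
                                        as.data.frame(cmp21))
    if (!is.null(cmp2)) cmp2 <- cbind(reference = "rd_2pct",
                                      as.data.frame(cmp2))
    comparison <- rbind(cmp21, cmp2)
  }

  # --- write outputs ---------------------------------------------------
  paths <- list(
    fits = file.path(out_dir, "fits.csv"),
    series = file.path(out_dir, "series.csv"),
    profiles = file.path(out_dir, "profiles.csv"),
    trends = file.path(out_dir, "trends.csv"),
    comparison = file.path(out_dir, "comparison.csv"),
    summary = file.path(out_dir, "summary.json"),
    log = log_path)
  utils::write.csv(fits, paths$fits, row.names = FALSE)
  utils::write.csv(as.data.frame(series), paths$series, row.names = FALSE)
  prof_df <- do.call(rbind, lapply(profiles, as.data.frame))
  utils::write.csv(prof_df, paths$profiles, row.names = FALSE)
  utils::write.csv(trends, paths$trends, row.names = FALSE)
  if (!is.null(comparison))
    utils::write.csv(comparison, paths$comparison, row.names = FALSE)

  summary_obj <- list(
    seed = seed,
    n_fits = nrow(fits),
    species = unique(series$species),
    fit_means = agg,
    trends = trends,
    comparison = if (!is.null(comparison)) comparison else NULL,
    recovery = lapply(profiles, function(p)
      list(rp_max = attr(p, "rp_max"), ca_at_peak = attr(p, "ca_at_peak"),
           ratio = p$ratio, ca = p$ca)))
  jsonlite::write_json(summary_obj, paths$summary, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", na = "null")
  lg("info", "wrote outputs to ", out_dir)

  invisible(list(fits = fits, series = series, profiles = profiles,
                 trends = trends, comparison = comparison, paths = paths))
}
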