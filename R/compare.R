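# Fitted-vs-measured deviation comparison between the A/Ci and A/Ca axes.

#' Deviation of fitted respiration from the measured value, per axis
#'
#' For a respiration estimate obtained on the A/Ci axis and on the A/Ca axis
#' of the same curves, computes the absolute deviations from the measured
#' value, \eqn{\Delta = |fitted - measured|}, and the percent reduction in
#' deviation achieved by the A/Ca fit,
#' \eqn{(\Delta_{Ci} - \Delta_{Ca}) / \Delta_{Ci} \times 100}.
#'
#' @param fitted_ci,fitted_ca Fitted respiration estimates
#'   (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}) from the two axes.
#' @param measured Measured respiration value.
#' @return Data frame with `delta_ci`, `delta_ca`, `pct_reduction` (NA when
#'   \eqn{\Delta_{Ci} = 0}), and the signed biases `bias_ci`, `bias_ca`
#'   (positive = overestimate).  Vectorized over its arguments.
#' @export
#' @examples
#' deviation_reduction(fitted_ci = 5.599, fitted_ca = 2.716, measured = 2.036)
deviation_reduction <- function(fitted_ci, fitted_ca, measured) {
  n <- max(length(fitted_ci), length(fitted_ca), length(measured))
  fitted_ci <- rep_len(fitted_ci, n)
  fitted_ca <- rep_len(fitted_ca, n)
  measured <- rep_len(measured, n)
  delta_ci <- abs(fitted_ci - measured)
  delta_ca <- abs(fitted_ca - measured)
  pct <- ifelse(delta_ci > 0, (delta_ci - delta_ca) / delta_ci * 100,
                NA_real_)
  data.frame(delta_ci = delta_ci, delta_ca = delta_ca, pct_reduction = pct,
             bias_ci = fitted_ci - measured, bias_ca = fitted_ca - measured)
}

#' Compare fitted respiration estimates with measured values across axes
#'
#' Pairs, for every species and model, the respiration estimate fitted on
#' the A/Ci axis with its A/Ca counterpart and the measured value, and
#' reports the deviations and the percent deviation reduction of the A/Ca
#' fit (see [deviation_reduction()]).  Models lacking one of the two axes
#' are skipped with a warning.
#'
#' @param fits Data frame with columns `species`, `model`, `x_axis`
#'   (`"ca"`/`"ci"`) and `estimate` — e.g. replicate-averaged
#'   `respiration_estimate`s from [fit_co2_response()].
#' @param measured Data frame with columns `species` and `measured` (the
#'   measured respiration at zero CO2 for the matching O2 level).
#' @return Data frame of class `comparison_report`: one row per
#'   species-model pair with deviations, percent reduction and signed bias.
#' @export
#' @examples
#' fits <- data.frame(species = "wheat", model = "modrect",
#'                    x_axis = c("ci", "ca"), estimate = c(5.599, 2.716))
#' compare_fitted_measured(fits, data.frame(species = "wheat", measured = 2.036))
compare_fitted_measured <- function(fits, measured) {
  req <- c("species", "model", "x_axis", "estimate")
  if (!all(req %in% names(fits)))
    stop_domain("'fits' needs columns: ", paste(req, collapse = ", "))
  if (!all(c("species", "measured") %in% names(measured)))
    stop_domain("'measured' needs columns species, measured")

  rows <- list()
  for (sp in unique(fits$species)) {
    m_row <- measured$measured[measured$species == sp]
    if (!length(m_row)) {
      warning("no measured value for species '", sp, "'; skipped")
      next
    }
    fs <- fits[fits$species == sp, ]
    for (mod in unique(fs$model)) {
      e_ci <- fs$estimate[fs$model == mod & fs$x_axis == "ci"]
      e_ca <- fs$estimate[fs$model == mod & fs$x_axis == "ca"]
      if (!length(e_ci) || !length(e_ca)) {
        warning(sprintf(
          "species '%s', model '%s': missing %s-axis counterpart; skipped",
          sp, mod, if (length(e_ci)) "ca" else "ci"))
        next
      }
      dr <- deviation_reduction(mean(e_ci), mean(e_ca), m_row[1L])
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(species = sp, model = mod,
                         fitted_ci = mean(e_ci), fitted_ca = mean(e_ca),
                         measured = m_row[1L]), dr)
    }
  }
  if (!length(rows)) stop_domain("no comparable species-model pairs")
  structure(do.call(rbind, rows),
            class = c("comparison_report", "data.frame"))
}

#' @export
print.comparison_report <- function(x, digits = 3, ...) {
  cat("Fitted-vs-measured deviation report (A/Ci vs A/Ca)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
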