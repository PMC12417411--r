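# Differential-O2 partitioning of respiration in the light.
#
# Sign convention throughout: net photosynthetic rate Pn is signed (negative
# when the leaf is a net CO2 source); the respiratory fluxes R_L, R_p, R_d,
# R_n are positive magnitudes.

#' Photorespiration rate by the differential-oxygen method
#'
#' Low oxygen (2%) suppresses Rubisco oxygenation, so the difference of the
#' net rates measured at the two O2 levels under identical CO2 and light
#' isolates photorespiration: \eqn{R_p = P_{n,2%} - P_{n,21%}}.  At zero
#' ambient CO2 and saturating light this equals \eqn{R_L - R_d}.
#'
#' Under measurement noise the difference can come out negative; such values
#' are returned as-is (clamping would bias replicate averages) and can be
#' flagged downstream.
#'
#' @param pn_2pct Net rate at 2% O2 (signed, \eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param pn_21pct Net rate at 21% O2 at the same CO2 and light.
#' @return Photorespiration rate(s), \eqn{\mu}mol CO2 m\eqn{^{-2}} s\eqn{^{-1}}.
#' @export
#' @examples
#' photorespiration_rate(pn_2pct = -2.036, pn_21pct = -6.548)  # 4.512
photorespiration_rate <- function(pn_2pct, pn_21pct) {
  if (length(pn_2pct) != length(pn_21pct))
    stop_domain("'pn_2pct' and 'pn_21pct' must have equal length")
  pn_2pct - pn_21pct
}

#' CO2 recovery and inhibition profile of photorespiration
#'
#' For an ordered series of photorespiration rates over ambient CO2 levels,
#' computes the ratio \eqn{(R_{p,max} - R_{p,i}) / R_{p,max}} at every level.
#' Below the CO2 concentration of maximal photorespiration the ratio is read
#' as the recovery ratio (fraction of respired CO2 re-assimilated by the
#' chloroplast); above it, as the inhibition ratio (fractional suppression of
#' photorespiration by competitive carboxylation).  \eqn{R_{p,max}} is the
#' series maximum; ties break to the lowest CO2 level.
#'
#' @param ca Ambient CO2 levels (\eqn{\mu}mol mol\eqn{^{-1}}), at least 3.
#' @param rp Photorespiration rates at those levels, all \eqn{\ge 0}.
#' @param species Optional label carried into the result.
#' @return A data frame of class `recovery_profile` with columns `ca`, `rp`,
#'   `ratio`, `phase`, and attributes `rp_max` and `ca_at_peak`.
#' @export
#' @examples
#' prof <- recovery_inhibition(c(0, 200, 600, 1200), c(4.923, 9, 12.307, 5.2))
#' attr(prof, "ca_at_peak")
recovery_inhibition <- function(ca, rp, species = NULL) {
  if (length(ca) != length(rp))
    stop_domain("'ca' and 'rp' must have equal length")
  if (length(ca) < 3L)
    stop_domain("need at least 3 CO2 levels for a recovery profile")
  if (any(!is.finite(rp)) || any(rp < 0))
    stop_domain("'rp' must be finite and non-negative")
  ord <- order(ca)
  ca <- ca[ord]; rp <- rp[ord]
  rp_max <- max(rp)
  if (rp_max <= 0)
    stop_domain("all-zero photorespiration: recovery profile undefined")
  ca_peak <- ca[which(rp == rp_max)[1L]]  # ties -> lowest CO2
  ratio <- (rp_max - rp) / rp_max
  out <- data.frame(ca = ca, rp = rp, ratio = ratio,
                    phase = ifelse(ca <= ca_peak, "recovery", "inhibition"),
                    stringsAsFactors = FALSE)
  if (!is.null(species)) out <- cbind(species = species, out)
  structure(out, rp_max = rp_max, ca_at_peak = ca_peak,
            class = c("recovery_profile", "data.frame"))
}

#' Mitochondrial respiration in the light from the dark rate
#'
#' Mitochondrially respired CO2 is assumed to be recycled (at low CO2) and
#' inhibited (at high CO2) with the same efficiency as photorespiratory CO2,
#' so the day respiration at CO2 level *i* is
#' \eqn{R_{d,i} = R_{n,i}\,(1 - \rho_i)} with \eqn{\rho_i} the recovery or
#' inhibition ratio from [recovery_inhibition()].
#'
#' @param rn Dark respiration rate(s) \eqn{R_n \ge 0}.
#' @param ratio Recovery/inhibition ratio(s) in \eqn{[0, 1]}.
#' @return Day respiration rate(s); never exceeds `rn`.
#' @export
#' @examples
#' rd_in_light(3.862, 0.6)
rd_in_light <- function(rn, ratio) {
  if (any(!is.finite(rn)) || any(rn < 0))
    stop_domain("'rn' must be finite and non-negative")
  if (any(!is.finite(ratio)) || any(ratio < 0) || any(ratio > 1))
    stop_domain("'ratio' must lie in [0, 1]")
  rn * (1 - ratio)
}

# helpers ---------------------------------------------------------------

mean_sd <- function(v) {
  v <- v[is.finite(v)]
  c(mean = mean(v),
    sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
    n = length(v))
}

is_light <- function(par) is.finite(par) & par > 0

#' Build the per-CO2 respiration series from a replicated dataset
#'
#' Applies the full partitioning scheme to a long-format gas-exchange dataset
#' (see [read_gas_exchange_csv()] or [simulate_gas_exchange()]).  For every
#' species it requires four curve classes over a shared ambient-CO2 grid:
#' light (PAR > 0) at 21% and at 2% O2, and dark (PAR = 0) at both O2
#' levels.  Per replicate and CO2 level it computes
#' \itemize{
#'   \item \eqn{R_p = P_{n,2%} - P_{n,21%}} (differential-O2 method),
#'   \item \eqn{R_n} as the magnitude of the dark net rate, per O2 level,
#'   \item the recovery/inhibition ratio from the replicate-mean \eqn{R_p}
#'     series, and \eqn{R_d = R_n (1 - \rho)},
#'   \item \eqn{R_L} as \eqn{-P_{n,21%}} where the leaf is a net source,
#'     else \eqn{R_p + R_d}.
#' }
#' Replicate dispersion is reported as the sample SD of per-replicate values
#' (absent for a single replicate).
#'
#' @param data Long-format data frame with columns `species`, `replicate`,
#'   `o2`, `par`, `ca`, `pn` (`ci` optional).
#' @param rn_source Which dark series feeds the day-respiration calculation:
#'   `"21"` (default; O2 level has no significant effect on the dark rate) or
#'   `"2"`.
#' @return Long data frame of class `respiration_series` with columns
#'   `species`, `ca`, `quantity` (`rl`, `rp`, `rd`, `rn21`, `rn2`), `mean`,
#'   `sd`, `n`; negative-\eqn{R_p} replicate cells are listed in the
#'   `"qc_negative_rp"` attribute, and the per-species recovery profiles in
#'   the `"profiles"` attribute.
#' @export
build_respiration_series <- function(data, rn_source = c("21", "2")) {
  rn_source <- match.arg(rn_source)
  req <- c("species", "replicate", "o2", "par", "ca", "pn")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop_domain("missing columns: ", paste(miss, collapse = ", "))

  out <- list()
  qc <- list()
  profiles <- list()
  for (sp in unique(data$species)) {
    d <- data[data$species == sp, , drop = FALSE]
    classes <- list(
      "light 21% O2 (PAR > 0)" = d[is_light(d$par) & d$o2 > 0.1, ],
      "light 2% O2 (PAR > 0)"  = d[is_light(d$par) & d$o2 <= 0.1, ],
      "dark 21% O2 (PAR 0)"    = d[!is_light(d$par) & d$o2 > 0.1, ],
      "dark 2% O2 (PAR 0)"     = d[!is_light(d$par) & d$o2 <= 0.1, ])
    absent <- names(classes)[vapply(classes, nrow, 0L) == 0L]
    if (length(absent))
      stop_domain(sprintf("species '%s': missing curve class(es): %s",
                          sp, paste(absent, collapse = "; ")))

    l21 <- classes[[1L]]; l2 <- classes[[2L]]
    dk21 <- classes[[3L]]; dk2 <- classes[[4L]]

    pair <- merge(l2[, c("replicate", "ca", "pn")],
                  l21[, c("replicate", "ca", "pn")],
                  by = c("replicate", "ca"), suffixes = c("_2", "_21"))
    if (!nrow(pair))
      stop_domain(sprintf(
        "species '%s': light curves at the two O2 levels share no (replicate, ca)", sp))
    pair$rp <- photorespiration_rate(pair$pn_2, pair$pn_21)

    neg <- pair[pair$rp < 0, c("replicate", "ca", "rp")]
    if (nrow(neg)) qc[[sp]] <- cbind(species = sp, neg)

    ca_grid <- sort(unique(pair$ca))
    rp_stats <- t(vapply(ca_grid,
                         function(cc) mean_sd(pair$rp[pair$ca == cc]),
                         numeric(3)))

    prof <- recovery_inhibition(ca_grid, pmax(rp_stats[, "mean"], 0),
                                species = sp)
    profiles[[sp]] <- prof
    ratio_of <- stats::setNames(prof$ratio, prof$ca)

    rn_src <- if (rn_source == "21") dk21 else dk2
    rn_src <- rn_src[rn_src$ca %in% ca_grid, ]
    rn_src$rn <- -rn_src$pn
    rd_rep <- rn_src
    rd_rep$rd <- rd_in_light(pmax(rd_rep$rn, 0),
                             ratio_of[as.character(rd_rep$ca)])

    # R_L per replicate: direct read-off where the leaf is a net source,
    # otherwise reconstructed as R_p + R_d
    rl_rep <- merge(pair[, c("replicate", "ca", "rp", "pn_21")],
                    rd_rep[, c("replicate", "ca", "rd")],
                    by = c("replicate", "ca"))
    rl_rep$rl <- ifelse(rl_rep$pn_21 < 0, -rl_rep$pn_21,
                        rl_rep$rp + rl_rep$rd)

    stat_rows <- function(df, col, quantity) {
      m <- t(vapply(ca_grid, function(cc) mean_sd(df[[col]][df$ca == cc]),
                    numeric(3)))
      data.frame(species = sp, ca = ca_grid, quantity = quantity,
                 mean = m[, "mean"], sd = m[, "sd"], n = as.integer(m[, "n"]),
                 stringsAsFactors = FALSE)
    }
    dk21$rn <- -dk21$pn
    dk2$rn <- -dk2$pn
    out[[sp]] <- rbind(
      stat_rows(rl_rep, "rl", "rl"),
      data.frame(species = sp, ca = ca_grid, quantity = "rp",
                 mean = rp_stats[, "mean"], sd = rp_stats[, "sd"],
                 n = as.integer(rp_stats[, "n"]), stringsAsFactors = FALSE),
      stat_rows(rd_rep, "rd", "rd"),
      stat_rows(dk21[dk21$ca %in% ca_grid, ], "rn", "rn21"),
      stat_rows(dk2[dk2$ca %in% ca_grid, ], "rn", "rn2"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res,
            qc_negative_rp = if (length(qc)) do.call(rbind, qc) else NULL,
            profiles = profiles,
            class = c("respiration_series", "data.frame"))
}

#' Extract one flux from a respiration series
#'
#' @param series A [build_respiration_series()] result.
#' @param species Species label.
#' @param quantity One of `"rl"`, `"rp"`, `"rd"`, `"rn21"`, `"rn2"`.
#' @return Data frame `ca`, `mean`, `sd`, `n` ordered by `ca`.
#' @export
series_quantity <- function(series, species, quantity) {
  d <- as.data.frame(series)[series$species == species &
                               series$quantity == quantity,
                             c("ca", "mean", "sd", "n")]
  d <- d[order(d$ca), ]
  rownames(d) <- NULL
  d
}

#' @export
print.respiration_series <- function(x, ...) {
  cat("Respiration series:",
      paste(unique(x$species), collapse = ", "),
      sprintf("| %d CO2 levels | quantities: %s\n",
              length(unique(x$ca)),
              paste(unique(x$quantity), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 12))
  if (nrow(x) > 12) cat("...", nrow(x) - 12, "more rows\n")
  qc <- attr(x, "qc_negative_rp")
  if (!is.null(qc))
    cat("QC: ", nrow(qc), " negative per-replicate R_p value(s) retained\n")
  invisible(x)
}
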