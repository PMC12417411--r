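# Nonlinear least-squares fitting of CO2-response curves.
#
# Levenberg-Marquardt (minpack.lm::nls.lm) with box constraints keeping all
# rate parameters non-negative, wrapped in a deterministic multi-start so the
# non-smooth min{wc,wj,wp} of the biochemical model and the ill-conditioned
# modified hyperbola do not trap the fit in local minima.

MODEL_IDS <- c("modrect", "rect", "mm", "fvcb")

model_par_names <- function(model) {
  switch(model,
         rect    = c("alpha", "pnmax", "rp"),
         mm      = c("pnmax", "k", "rp"),
         modrect = c("a", "b", "c", "rp"),
         fvcb    = c("vcmax", "j", "tpu", "rd"))
}

params_from_vector <- function(model, p, constants = NULL) {
  p <- as.list(p)
  switch(model,
         rect    = rect_params(p$alpha, p$pnmax, p$rp),
         mm      = mm_params(p$pnmax, p$k, p$rp),
         modrect = modrect_params(p$a, p$b, p$c, p$rp),
         fvcb    = fvcb_params(p$vcmax, p$j, p$tpu, p$rd,
                               kc = constants$kc, ko = constants$ko,
                               o = constants$o,
                               gamma_star = constants$gamma_star))
}

# raw (unvalidated) model evaluation used inside the optimizer, where the
# trial vector may sit on a bound
eval_raw <- function(model, p, conc, constants) {
  switch(model,
    rect    = p["alpha"] * p["pnmax"] * conc /
                (p["alpha"] * conc + p["pnmax"]) - p["rp"],
    mm      = p["pnmax"] * conc / (conc + p["k"]) - p["rp"],
    modrect = p["a"] * (1 - p["b"] * conc) / (1 + p["c"] * conc) * conc -
                p["rp"],
    fvcb    = {
      kmc <- constants$kc * (1 + constants$o / constants$ko)
      wc <- p["vcmax"] * conc / (conc + kmc)
      wj <- p["j"] * conc / (4 * conc + 8 * constants$gamma_star)
      wp <- 3 * p["tpu"]
      pmin(wc, wj, wp) * (1 - constants$gamma_star / conc) - p["rd"]
    })
}

model_bounds <- function(model, cmax) {
  switch(model,
    rect    = list(lower = c(alpha = 1e-8, pnmax = 1e-6, rp = 0),
                   upper = c(alpha = Inf,  pnmax = Inf,  rp = Inf)),
    mm      = list(lower = c(pnmax = 1e-6, k = 1e-3, rp = 0),
                   upper = c(pnmax = Inf,  k = Inf,  rp = Inf)),
    modrect = list(lower = c(a = 1e-8, b = 0, c = 0, rp = 0),
                   upper = c(a = Inf, b = (1 - 1e-9) / max(cmax, 1),
                             c = Inf, rp = Inf)),
    fvcb    = list(lower = c(vcmax = 1e-6, j = 1e-6, tpu = 1e-6, rd = 0),
                   upper = c(vcmax = Inf, j = Inf, tpu = Inf, rd = Inf)))
}

# deterministic seed derived from the curve itself, so multi-start
# perturbations are reproducible without touching the caller's RNG stream
curve_seed <- function(x, y) {
  v <- c(x, y)
  v <- v[is.finite(v)]
  h <- sum(abs(v) * (seq_along(v) %% 97 + 1)) %% 2147483629
  as.integer(floor(h)) + 1L
}

with_preserved_rng <- function(code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  force(code)
}

#' Heuristic starting values for a CO2-response fit
#'
#' Reads the respiration intercept off the lowest-CO2 observation, the
#' initial slope off the two lowest-CO2 points (after adding the intercept
#' back), and the saturation rate off the curve maximum.  Degenerate (flat)
#' curves fall back to fixed defaults instead of failing.
#'
#' @param conc CO2 concentrations (\eqn{\mu}mol mol\eqn{^{-1}}).
#' @param pn Net rates (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param model One of `"modrect"`, `"rect"`, `"mm"`, `"fvcb"`.
#' @param constants Kinetic constants (biochemical model only); see
#'   [fvcb_constants()].
#' @return Named numeric vector of starting values.
#' @export
initial_guess <- function(conc, pn, model = MODEL_IDS,
                          constants = fvcb_constants()) {
  model <- match.arg(model)
  if (!length(conc) || length(conc) != length(pn))
    stop_domain("'conc' and 'pn' must be non-empty and of equal length")
  ord <- order(conc)
  conc <- conc[ord]; pn <- pn[ord]

  flat <- stats::sd(pn) < 1e-12 || length(unique(conc)) < 2L
  r0 <- max(0, -pn[1L])
  if (flat) {
    return(switch(model,
                  rect    = c(alpha = 0.05, pnmax = 20, rp = 1),
                  mm      = c(pnmax = 20, k = 400, rp = 1),
                  modrect = c(a = 0.05, b = 1e-4, c = 1e-3, rp = 1),
                  fvcb    = c(vcmax = 50, j = 90, tpu = 7, rd = 1)))
  }

  # slope of the two lowest-concentration points with distinct conc
  i2 <- which(conc > conc[1L])[1L]
  slope <- (pn[i2] - pn[1L]) / (conc[i2] - conc[1L])
  slope <- max(slope, 1e-4)
  pmax_guess <- max(max(pn) + r0, 1e-3)

  switch(model,
    rect    = c(alpha = slope, pnmax = pmax_guess, rp = r0),
    mm      = c(pnmax = pmax_guess, k = pmax_guess / slope, rp = r0),
    modrect = c(a = slope, b = 1e-4, c = 1e-3, rp = r0),
    fvcb    = {
      kmc <- constants$kc * (1 + constants$o / constants$ko)
      vc <- max(slope * kmc, 5)
      c(vcmax = vc, j = 1.8 * vc, tpu = pmax_guess / 3,
        rd = max(r0, 0.1))
    })
}

#' Fit a CO2-response model to a gas-exchange curve
#'
#' Estimates the parameters of one of four CO2-response models — modified
#' rectangular hyperbola (`"modrect"`), rectangular hyperbola (`"rect"`),
#' Michaelis-Menten (`"mm"`) or the Farquhar-type biochemical model
#' (`"fvcb"`) — from a single response curve of net photosynthetic rate
#' against ambient (`x = "ca"`) or intercellular (`x = "ci"`) CO2, by
#' bounded Levenberg-Marquardt least squares with deterministic multi-start.
#'
#' The fitted respiration term (`rp` for the empirical models, `rd` for the
#' biochemical model) equals minus the model value at zero CO2 and is
#' reported as `respiration_estimate`; on a 21% O2 curve it estimates the
#' total respiration in the light \eqn{R_L}, on a 2% O2 curve the
#' mitochondrial respiration \eqn{R_d}.
#'
#' @param data A data frame with columns `pn` and `ca` and/or `ci` (one
#'   replicate's curve), or `NULL` when `conc`/`pn` vectors are supplied.
#' @param model Model identifier.
#' @param x Which CO2 axis to fit against: `"ca"` or `"ci"`.
#' @param conc,pn Optional numeric vectors used instead of `data`.
#' @param start Optional named starting vector; default [initial_guess()].
#' @param n_starts Number of multi-start attempts (the heuristic start plus
#'   log-normal perturbations of it, seeded deterministically from the data).
#' @param ci_epsilon Biochemical model only: observations with CO2 at or
#'   below this value are excluded (the compensation factor divides by C).
#' @param o2 Oxygen fraction used to pick kinetic constants when `constants`
#'   is `NULL`; taken from an `o2` column of `data` when present.
#' @param constants Kinetic constants for the biochemical model.
#' @param control Passed to [minpack.lm::nls.lm()].
#' @return Object of class `co2fit`: fitted `params`, `coefficients`,
#'   `respiration_estimate`, `r2`, `ssr`, `residuals`, `fitted.values`,
#'   `converged`, `n_points_used`, and the data used.
#' @export
#' @examples
#' truth <- rect_params(alpha = 0.08, pnmax = 25, rp = 6.5)
#' ca <- c(0, 50, 80, 100, 150, 200, 380, 400, 600, 800, 1000, 1200)
#' fit <- fit_co2_response(data.frame(ca = ca, pn = pn_model(truth, ca)),
#'                         model = "rect", x = "ca")
#' coef(fit)
fit_co2_response <- function(data = NULL, model = MODEL_IDS,
                             x = c("ca", "ci"), conc = NULL, pn = NULL,
                             start = NULL, n_starts = 8, ci_epsilon = 1,
                             o2 = NULL, constants = NULL,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 400, ftol = 1e-14, ptol = 1e-14)) {
  model <- match.arg(model)
  x <- match.arg(x)
  cl <- match.call()

  if (is.null(conc) || is.null(pn)) {
    if (is.null(data)) stop_domain("supply 'data' or both 'conc' and 'pn'")
    if (!x %in% names(data))
      stop_domain(sprintf("column '%s' not found in 'data'", x))
    if (!"pn" %in% names(data)) stop_domain("column 'pn' not found in 'data'")
    conc <- data[[x]]
    pn <- data$pn
    if (is.null(o2) && "o2" %in% names(data)) o2 <- data$o2[1L]
  }
  keep <- is.finite(conc) & is.finite(pn)
  if (model == "fvcb") keep <- keep & conc > ci_epsilon
  conc <- conc[keep]; pn <- pn[keep]
  n <- length(conc)
  if (n < 5L)
    stop_domain(sprintf("need at least 5 usable points to fit (got %d)", n))

  if (is.null(constants)) constants <- fvcb_constants(if (is.null(o2)) 0.21 else o2)
  bounds <- model_bounds(model, max(conc))
  pnames <- model_par_names(model)

  guess <- if (is.null(start)) {
    initial_guess(conc, pn, model, constants)
  } else {
    if (!all(pnames %in% names(start)))
      stop_domain("'start' must name all of: ", paste(pnames, collapse = ", "))
    start[pnames]
  }
  guess <- pmin(pmax(guess, bounds$lower), ifelse(is.finite(bounds$upper),
                                                  bounds$upper, guess))

  resid_fn <- function(p) {
    names(p) <- pnames
    pn - eval_raw(model, p, conc, constants)
  }

  starts <- list(guess)
  if (n_starts > 1) {
    with_preserved_rng({
      set.seed(curve_seed(conc, pn))
      base <- pmax(abs(guess), 1e-2)
      for (k in seq_len(n_starts - 1)) {
        cand <- base * exp(stats::rnorm(length(guess), 0, 0.4))
        cand <- pmin(pmax(cand, bounds$lower),
                     ifelse(is.finite(bounds$upper), bounds$upper * 0.999,
                            cand))
        names(cand) <- pnames
        starts[[k + 1L]] <- cand
      }
    })
  }

  best <- NULL
  best_ssr <- Inf
  best_conv <- FALSE
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = bounds$lower, upper = bounds$upper,
                         control = control),
      error = function(e) NULL)
    if (is.null(res)) next
    ssr <- sum(res$fvec^2)
    if (ssr < best_ssr) {
      best <- res; best_ssr <- ssr; best_conv <- res$info %in% 1:4
    }
  }
  if (is.null(best))
    stop_domain("no start converged for model '", model, "'")

  est <- stats::setNames(as.numeric(best$par), pnames)
  params <- params_from_vector(model, est, constants)
  fitted_vals <- eval_raw(model, est, conc, constants)
  resids <- pn - fitted_vals
  sstot <- sum((pn - mean(pn))^2)
  r2 <- if (sstot > 0) 1 - best_ssr / sstot else NA_real_

  structure(list(
    model = model,
    x_axis = x,
    params = params,
    coefficients = est,
    respiration_estimate = unname(est[if (model == "fvcb") "rd" else "rp"]),
    r2 = r2,
    ssr = best_ssr,
    residuals = resids,
    fitted.values = fitted_vals,
    converged = best_conv,
    n_points_used = n,
    data = data.frame(conc = conc, pn = pn),
    constants = constants,
    call = cl), class = "co2fit")
}

# S3 methods ------------------------------------------------------------

#' @export
print.co2fit <- function(x, digits = 4, ...) {
  label <- c(modrect = "modified rectangular hyperbola",
             rect = "rectangular hyperbola",
             mm = "Michaelis-Menten",
             fvcb = "biochemical (Farquhar-type)")[x$model]
  cat("CO2-response fit:", label,
      sprintf("(A/%s)\n", if (x$x_axis == "ca") "Ca" else "Ci"))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Respiration estimate: %.*f umol m-2 s-1; R2 = %.*f; n = %d%s\n",
              digits, x$respiration_estimate, digits, x$r2, x$n_points_used,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
coef.co2fit <- function(object, ...) object$coefficients

#' @export
fitted.co2fit <- function(object, ...) object$fitted.values

#' @export
residuals.co2fit <- function(object, ...) object$residuals

#' @export
deviance.co2fit <- function(object, ...) object$ssr

#' @export
predict.co2fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  conc <- if (is.data.frame(newdata)) {
    col <- if (object$x_axis %in% names(newdata)) object$x_axis else "conc"
    newdata[[col]]
  } else {
    newdata
  }
  pn_model(object$params, conc)
}

#' @export
summary.co2fit <- function(object, ...) {
  dq <- derived_quantities(object,
                           c_max = max(object$data$conc, 1200))
  structure(list(fit = object,
                 sigma = sqrt(object$ssr /
                                max(object$n_points_used -
                                      length(object$coefficients), 1)),
                 derived = dq), class = "summary.co2fit")
}

#' @export
print.summary.co2fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("Residual SD: %.*f\n", digits, x$sigma))
  cat(sprintf("Intercept at zero CO2: %.*f (== -respiration estimate for empirical models)\n",
              digits, x$derived$intercept_at_zero))
  if (is.na(x$derived$co2_compensation_point)) {
    cat("CO2 compensation point: absent on the scanned interval\n")
  } else {
    cat(sprintf("CO2 compensation point: %.*f umol mol-1\n", digits,
                x$derived$co2_compensation_point))
  }
  cat(sprintf("Realized maximum: %.*f at C = %.*f\n", digits,
              x$derived$pn_max_realized, digits, x$derived$ca_at_max))
  invisible(x)
}

#' @export
plot.co2fit <- function(x, n_curve = 200, ...) {
  d <- x$data
  lo <- if (x$model == "fvcb") max(min(d$conc), 1e-6) else 0
  grid <- seq(lo, max(d$conc), length.out = n_curve)
  graphics::plot(d$conc, d$pn,
                 xlab = sprintf("C%s (umol mol-1)",
                                if (x$x_axis == "ca") "a" else "i"),
                 ylab = "Pn (umol CO2 m-2 s-1)", ...)
  graphics::lines(grid, pn_model(x$params, grid))
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
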