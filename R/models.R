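# Parameter constructors ------------------------------------------------

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_domain(sprintf("'%s' must be a single strictly positive number", name))
  x
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_domain(sprintf("'%s' must be a single non-negative number", name))
  x
}

check_conc <- function(conc) {
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0))
    stop_domain("CO2 concentration must be non-negative and finite")
  conc
}

#' Rectangular hyperbola model parameters
#'
#' Parameter set for the rectangular hyperbola CO2-response model
#' \deqn{P_n = \frac{\alpha P_{nmax} C}{\alpha C + P_{nmax}} - R_p,}
#' where the intercept term `rp` is the fitted respiration rate in the light
#' (interpreted as \eqn{R_L} on a 21% O2 curve, \eqn{R_d} on a 2% O2 curve).
#'
#' @param alpha Initial slope of the CO2-response curve
#'   (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}} per \eqn{\mu}mol mol\eqn{^{-1}}).
#' @param pnmax Maximum photosynthetic rate (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param rp Respiration intercept (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}), \eqn{\ge 0}.
#' @return An object of class `rect_params`.
#' @seealso [pn_model()], [fit_co2_response()]
#' @export
#' @examples
#' p <- rect_params(alpha = 0.05, pnmax = 30, rp = 5)
#' pn_model(p, c(0, 400))
rect_params <- function(alpha, pnmax, rp = 0) {
  structure(list(alpha = check_positive(alpha, "alpha"),
                 pnmax = check_positive(pnmax, "pnmax"),
                 rp    = check_nonneg(rp, "rp")),
            class = c("rect_params", "co2_params"))
}

#' Michaelis-Menten model parameters
#'
#' Parameter set for \eqn{P_n = P_{nmax} C / (C + K) - R_p}.  Algebraically
#' identical to the rectangular hyperbola under \eqn{K = P_{nmax}/\alpha}.
#'
#' @param pnmax Maximum photosynthetic rate (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param k Michaelis constant (\eqn{\mu}mol mol\eqn{^{-1}}).
#' @param rp Respiration intercept, \eqn{\ge 0}.
#' @return An object of class `mm_params`.
#' @export
mm_params <- function(pnmax, k, rp = 0) {
  structure(list(pnmax = check_positive(pnmax, "pnmax"),
                 k     = check_positive(k, "k"),
                 rp    = check_nonneg(rp, "rp")),
            class = c("mm_params", "co2_params"))
}

#' Modified rectangular hyperbola model parameters
#'
#' Parameter set for
#' \deqn{P_n = a\,\frac{1 - bC}{1 + cC}\,C - R_p.}
#' This non-rectangular form admits a CO2 optimum followed by decline and
#' is the model that tracks measured respiration intercepts most closely on
#' A/Ca curves.
#'
#' @param a Initial slope (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}} per
#'   \eqn{\mu}mol mol\eqn{^{-1}}).
#' @param b,c Shape coefficients (mol \eqn{\mu}mol\eqn{^{-1}}), \eqn{\ge 0}.
#' @param rp Respiration intercept, \eqn{\ge 0}.
#' @return An object of class `modrect_params`.
#' @export
modrect_params <- function(a, b, c, rp = 0) {
  structure(list(a  = check_positive(a, "a"),
                 b  = check_nonneg(b, "b"),
                 c  = check_nonneg(c, "c"),
                 rp = check_nonneg(rp, "rp")),
            class = c("modrect_params", "co2_params"))
}

#' Farquhar-type biochemical model parameters
#'
#' Parameters for the biochemical CO2-response model
#' \deqn{P_n = \min\{w_c, w_j, w_p\}\,(1 - \Gamma^*/C_i) - R_d,}
#' with the standard sub-rates
#' \eqn{w_c = V_{cmax} C_i / (C_i + K_c(1 + O/K_o))} (Rubisco-limited),
#' \eqn{w_j = J C_i / (4 C_i + 8\Gamma^*)} (RuBP-regeneration-limited) and
#' \eqn{w_p = 3\,TPU} (triose-phosphate-utilization-limited).
#'
#' Kinetic constants are held fixed rather than fitted so that only
#' `vcmax`, `j`, `tpu` and `rd` are free; on 12-point curves this keeps the
#' model identifiable.
#'
#' @param vcmax Maximum carboxylation rate (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param j Electron-transport rate (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param tpu Triose-phosphate utilization rate (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}).
#' @param rd Mitochondrial respiration in the light (\eqn{\mu}mol m\eqn{^{-2}} s\eqn{^{-1}}), \eqn{\ge 0}.
#' @param kc Rubisco Michaelis constant for CO2 (\eqn{\mu}mol mol\eqn{^{-1}}).
#' @param ko Rubisco Michaelis constant for O2 (mmol mol\eqn{^{-1}}).
#' @param o Oxygen concentration (mmol mol\eqn{^{-1}}); 210 at 21% O2, 20 at 2% O2.
#' @param gamma_star Photorespiratory CO2 compensation point
#'   \eqn{\Gamma^*} (\eqn{\mu}mol mol\eqn{^{-1}}); must be below `kc`.
#' @return An object of class `fvcb_params`.
#' @export
#' @examples
#' p <- fvcb_params(vcmax = 100, j = 150, tpu = 11, rd = 1.5)
#' pn_model(p, c(100, 400, 900))
fvcb_params <- function(vcmax, j, tpu, rd = 0,
                        kc = 270, ko = 165, o = 210, gamma_star = 37) {
  p <- list(vcmax = check_positive(vcmax, "vcmax"),
            j     = check_positive(j, "j"),
            tpu   = check_positive(tpu, "tpu"),
            rd    = check_nonneg(rd, "rd"),
            kc    = check_positive(kc, "kc"),
            ko    = check_positive(ko, "ko"),
            o     = check_positive(o, "o"),
            gamma_star = check_positive(gamma_star, "gamma_star"))
  if (p$gamma_star >= p$kc)
    stop_domain("'gamma_star' must be below 'kc'")
  structure(p, class = c("fvcb_params", "co2_params"))
}

#' Fixed kinetic constants for the biochemical model at a given O2 level
#'
#' @param o2 Oxygen mole fraction, 0.21 or 0.02.
#' @return Named list with `kc`, `ko`, `o`, `gamma_star`.
#' @export
fvcb_constants <- function(o2 = 0.21) {
  if (!is.numeric(o2) || length(o2) != 1L || o2 <= 0 || o2 > 1)
    stop_domain("'o2' must be an oxygen fraction in (0, 1]")
  list(kc = 270, ko = 165, o = 1000 * o2, gamma_star = 37)
}

# Forward evaluation ----------------------------------------------------

#' Evaluate a CO2-response model
#'
#' Forward evaluation of the net photosynthetic rate \eqn{P_n} predicted by a
#' parameter set at one or more CO2 concentrations.  Dispatches on the
#' parameter class created by [rect_params()], [mm_params()],
#' [modrect_params()] or [fvcb_params()].
#'
#' @param params A `co2_params` object.
#' @param conc CO2 concentration(s), \eqn{\mu}mol mol\eqn{^{-1}}; non-negative
#'   (strictly positive for the biochemical model, whose compensation factor
#'   divides by \eqn{C_i}).
#' @param ... Unused.
#' @return Numeric vector of net rates (\eqn{\mu}mol CO2 m\eqn{^{-2}} s\eqn{^{-1}}).
#' @export
pn_model <- function(params, conc, ...) UseMethod("pn_model")

#' @export
pn_model.rect_params <- function(params, conc, ...) {
  check_conc(conc)
  params$alpha * params$pnmax * conc / (params$alpha * conc + params$pnmax) -
    params$rp
}

#' @export
pn_model.mm_params <- function(params, conc, ...) {
  check_conc(conc)
  params$pnmax * conc / (conc + params$k) - params$rp
}

#' @export
pn_model.modrect_params <- function(params, conc, ...) {
  check_conc(conc)
  denom <- 1 + params$c * conc
  if (any(denom <= 0)) stop_domain("1 + c*C must stay positive")
  params$a * (1 - params$b * conc) / denom * conc - params$rp
}

#' @export
pn_model.fvcb_params <- function(params, conc, ...) {
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc <= 0))
    stop_domain("the biochemical model requires strictly positive CO2; exclude near-zero points upstream")
  w <- fvcb_limits(params, conc)
  unname(pmin(w[, "wc"], w[, "wj"], w[, "wp"]) *
           (1 - params$gamma_star / conc) - params$rd)
}

#' Limitation-state sub-rates of the biochemical model
#'
#' @param params An `fvcb_params` object.
#' @param ci Intercellular CO2 (\eqn{\mu}mol mol\eqn{^{-1}}), strictly positive.
#' @return Matrix with columns `wc`, `wj`, `wp` (one row per `ci`).
#' @export
fvcb_limits <- function(params, ci) {
  if (any(ci <= 0)) stop_domain("'ci' must be strictly positive")
  kmc <- params$kc * (1 + params$o / params$ko)
  cbind(wc = params$vcmax * ci / (ci + kmc),
        wj = params$j * ci / (4 * ci + 8 * params$gamma_star),
        wp = rep(3 * params$tpu, length(ci)))
}

# Derived quantities ----------------------------------------------------

#' Zero-CO2 intercept, compensation point and realized maximum of a model
#'
#' Numerically characterizes a fitted or constructed CO2-response model on
#' \eqn{[0, C_{max}]}: the model value at \eqn{C = 0} (for the empirical
#' models this is exactly \eqn{-R_p}, the respiration rate in the light read
#' off the curve), the CO2 compensation point (root of the model, absent when
#' the model does not change sign on the interval), and the realized maximum
#' net rate.  Extrema and roots are located by a dense grid scan with local
#' refinement rather than closed form.
#'
#' @param object A `co2_params` object or a [fit_co2_response()] fit.
#' @param c_max Upper end of the CO2 interval (\eqn{\mu}mol mol\eqn{^{-1}}).
#' @param grid_n Number of grid points for the coarse scan.
#' @return List with `intercept_at_zero`, `co2_compensation_point` (NA if no
#'   sign change) and `pn_max_realized` (with `ca_at_max`).
#' @export
#' @examples
#' derived_quantities(rect_params(0.05, 30, 5))
derived_quantities <- function(object, c_max = 1200, grid_n = 4001) {
  params <- if (inherits(object, "co2fit")) object$params else object
  if (!inherits(params, "co2_params"))
    stop_domain("'object' must be a co2_params object or a co2fit")
  lo <- if (inherits(params, "fvcb_params")) 1e-8 else 0
  f <- function(x) pn_model(params, pmax(x, lo))

  grid <- seq(lo, c_max, length.out = grid_n)
  y <- f(grid)

  # compensation point: first crossing from <= 0 to > 0
  comp <- NA_real_
  s <- sign(y)
  cross <- which(s[-1] * s[-length(s)] < 0)
  if (length(cross)) {
    i <- cross[1L]
    comp <- stats::uniroot(f, lower = grid[i], upper = grid[i + 1L],
                           tol = 1e-12)$root
  } else if (any(y == 0)) {
    comp <- grid[which(y == 0)[1L]]
  }

  # realized maximum: refine around the best grid point
  i <- which.max(y)
  lower <- grid[max(i - 1L, 1L)]
  upper <- grid[min(i + 1L, grid_n)]
  opt <- stats::optimize(f, lower = lower, upper = upper, maximum = TRUE,
                         tol = 1e-10)
  list(intercept_at_zero = f(lo),
       co2_compensation_point = comp,
       pn_max_realized = opt$objective,
       ca_at_max = opt$maximum)
}
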