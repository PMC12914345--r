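#' Variable-RBE model parameters
#'
#' Parameters of the phenomenological proton RBE model of McNamara,
#' Schuemann and Paganetti (2015, Phys. Med. Biol. 60, 8399), in which RBE
#' depends on dose per fraction, dose-averaged LET, and the tissue's
#' linear-quadratic parameter `(alpha/beta)_x`:
#' `RBEmax = p0 + p1 * LETd / (a/b)x` and
#' `RBEmin = q0 + q1 * sqrt((a/b)x) * LETd`. The published coefficient fit
#' is the default; coefficients are configuration data so alternative fits
#' can be supplied without code changes.
#'
#' @param alpha_beta_x tissue `(alpha/beta)_x` in Gy (2 for OARs, 10 for
#'   tumor by convention here).
#' @param n_fractions number of treatment fractions (default 30).
#' @param c scaling constant of the linear LET-weighted dose surrogate,
#'   um/keV (default 0.04).
#' @param rbe_max_intercept,rbe_max_slope,rbe_min_intercept,rbe_min_slope
#'   model coefficients (defaults: McNamara et al. 2015).
#' @return object of class `rbe_parameters`.
#' @export
rbe_parameters <- function(alpha_beta_x = 10, n_fractions = 30, c = 0.04,
                           rbe_max_intercept = 0.99064,
                           rbe_max_slope = 0.35605,
                           rbe_min_intercept = 1.1012,
                           rbe_min_slope = -0.0038703) {
  if (alpha_beta_x <= 0)
    stop_letplan("(alpha/beta)_x must be > 0",
                 class = "letplan_domain_error")
  if (n_fractions < 1)
    stop_letplan("n_fractions must be >= 1", class = "letplan_domain_error")
  if (c < 0)
    stop_letplan("c must be >= 0", class = "letplan_domain_error")
  structure(
    list(alpha_beta_x = alpha_beta_x, n_fractions = n_fractions, c = c,
         rbe_max_intercept = rbe_max_intercept,
         rbe_max_slope = rbe_max_slope,
         rbe_min_intercept = rbe_min_intercept,
         rbe_min_slope = rbe_min_slope),
    class = "rbe_parameters"
  )
}

#' Constant-RBE-weighted dose
#'
#' The clinical convention: protons are assumed 10\% more effective than
#' photons irrespective of LET, dose, or tissue.
#'
#' @param physical_dose nonnegative physical dose (Gy), any shape.
#' @param rbe the constant factor (default 1.1).
#' @return dose in Gy(RBE), same shape.
#' @export
constant_rbe_dose <- function(physical_dose, rbe = 1.1) {
  if (any(physical_dose < 0))
    stop_letplan("physical dose must be >= 0",
                 class = "letplan_domain_error")
  rbe * physical_dose
}

#' Variable-RBE-weighted dose (McNamara model)
#'
#' Computes per-voxel RBE from dose per fraction `d = total / n_fractions`,
#' dose-averaged LET, and `(alpha/beta)_x` via
#' `RBE = (sqrt((a/b)x^2 + 4 d (a/b)x RBEmax + 4 d^2 RBEmin^2) - (a/b)x) /
#' (2 d)`, then returns the total RBE-weighted dose
#' `n_fractions * RBE * d`. Voxels with zero dose return zero (the limit is
#' handled, not an error).
#'
#' @param physical_dose total physical dose per voxel (Gy).
#' @param letd dose-averaged LET per voxel (keV/um).
#' @param params an [rbe_parameters()].
#' @return total variable-RBE-weighted dose per voxel, Gy(RBE).
#' @export
variable_rbe_dose <- function(physical_dose, letd, params) {
  if (any(physical_dose < 0) || any(letd < 0))
    stop_letplan("dose and LETd must be >= 0",
                 class = "letplan_domain_error")
  n <- max(length(physical_dose), length(letd))
  physical_dose <- rep_len(physical_dose, n)
  letd <- rep_len(letd, n)
  ab <- params$alpha_beta_x
  d <- physical_dose / params$n_fractions
  rbe_max <- params$rbe_max_intercept + params$rbe_max_slope * letd / ab
  rbe_min <- params$rbe_min_intercept +
    params$rbe_min_slope * sqrt(ab) * letd
  out <- numeric(length(d))
  pos <- d > 0
  rbe <- (sqrt(ab^2 + 4 * d[pos] * ab * rbe_max[pos] +
                 4 * d[pos]^2 * rbe_min[pos]^2) - ab) / (2 * d[pos])
  out[pos] <- params$n_fractions * rbe * d[pos]
  out
}

#' Linear LET-weighted dose surrogate
#'
#' Approximates RBE-weighted dose as `D * (1 + c * LETd)`; the term
#' `c * LETd * D` is the LET-dependent biological dose component.
#'
#' @param physical_dose physical dose (Gy).
#' @param letd dose-averaged LET (keV/um).
#' @param c scaling constant, um/keV (default 0.04).
#' @return list with `component` (`c * LETd * D`, Gy) and `total`
#'   (`D + component`, Gy).
#' @examples
#' let_weighted_dose(50, 5)  # component 10, total 60
#' @export
let_weighted_dose <- function(physical_dose, letd, c = 0.04) {
  if (c < 0)
    stop_letplan("c must be >= 0", class = "letplan_domain_error")
  if (any(physical_dose < 0) || any(letd < 0))
    stop_letplan("dose and LETd must be >= 0",
                 class = "letplan_domain_error")
  component <- c * letd * physical_dose
  list(component = component, total = physical_dose + component)
}
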