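# Published characterization constants for the GMS BT-125-1 seed and the
# comparator seeds.  These are vendored reference numbers: they are used as
# ground truth for the synthetic measurement arm and as the comparison
# surface for newly simulated datasets; the package never fits to them.

#' Published dose rate constants of comparator seeds
#'
#' Reference dose rate constants used for comparison: PharmaSeed BT-125-1
#' (molybdenum rod), PharmaSeed BT-125-2 (silver rod) and the model 6711
#' seed, plus the published GMS BT-125-1 values (Monte Carlo, measured and
#' their consensus mean).
#'
#' @return List with `comparators` (data.frame) and the published GMS
#'   values `lambda_mc`, `lambda_exp`, `lambda_consensus`.
#' @export
published_lambdas <- function() {
  list(
    comparators = data.frame(
      seed = c("PharmaSeed BT-125-1", "PharmaSeed BT-125-2", "model 6711"),
      marker = c("molybdenum rod", "silver rod", "silver rod"),
      marker_length_cm = c(0.325, 0.325, 0.300),
      lambda = c(0.950, 0.967, 0.965)),
    lambda_mc = 0.975,
    lambda_exp = 0.943,
    lambda_consensus = 0.959)
}

#' Published quintic fit of the radial dose function
#'
#' Coefficients a0..a5 of the published fifth-order fit of g(r) for the
#' GMS BT-125-1 seed (r in cm, valid 0.5-10 cm).
#'
#' @return Named numeric vector a0..a5.
#' @export
published_g_fit <- function() {
  c(a0 = 1.185, a1 = -0.175, a2 = -1.702e-02, a3 = 6.741e-03,
    a4 = -6.827e-04, a5 = 2.437e-05)
}

#' Published Monte Carlo anisotropy function table
#'
#' F(r, theta) for the GMS BT-125-1 seed on the standard grid (radii
#' 0.5-7 cm, angles 0-90 degrees; the 0.5 cm column only carries the
#' 20-degree grid, and F(r, 90) = 1 by normalization).
#'
#' @return data.frame `r_cm`, `theta_deg`, `F` (NA where not tabulated).
#' @export
published_anisotropy_mc <- function() {
  radii <- c(0.5, 0.7, 1, 1.5, 2, 3, 4, 5, 6, 7)
  theta <- seq(0, 90, by = 10)
  vals <- rbind(
    c(NA,    0.303, 0.375, 0.419, 0.437, 0.539, 0.623, 0.607, 0.639, 0.710),
    c(0.387, 0.450, 0.512, 0.590, 0.574, 0.639, 0.729, 0.693, 0.666, 0.758),
    c(NA,    0.674, 0.710, 0.771, 0.666, 0.712, 0.843, 0.782, 0.721, 0.798),
    c(0.778, 0.809, 0.810, 0.809, 0.705, 0.807, 0.912, 0.850, 0.837, 0.873),
    c(NA,    0.891, 0.889, 0.942, 0.841, 0.875, 0.963, 0.915, 0.858, 0.920),
    c(0.906, 0.949, 0.966, 1.031, 0.931, 0.988, 1.029, 0.947, 0.917, 0.957),
    c(NA,    1.005, 0.981, 1.041, 0.951, 0.990, 1.049, 0.956, 0.953, 1.006),
    c(0.949, 0.991, 1.015, 1.053, 0.960, 1.028, 1.045, 0.985, 0.941, 1.013),
    c(NA,    0.994, 0.978, 1.061, 1.020, 1.044, 1.047, 1.010, 0.948, 0.996),
    c(1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000))
  data.frame(r_cm = rep(radii, each = length(theta)),
             theta_deg = rep(theta, times = length(radii)),
             F = as.vector(vals))
}

#' Published p0 coefficients of the anisotropy-function fits
#'
#' The leading coefficient (theta -> 0 intercept) of the published quintic
#' anisotropy fits at each radius.  The remaining published coefficients
#' are not sign-consistent with F(r, 90) = 1 under any obvious angular
#' unit, so only p0 is vendored for comparison.
#'
#' @return data.frame `r_cm`, `p0`.
#' @export
published_anisotropy_p0 <- function() {
  data.frame(r_cm = c(0.7, 1, 1.5, 2, 3, 4, 5, 6, 7),
             p0 = c(0.298, 0.370, 0.417, 0.439, 0.541, 0.622, 0.608,
                    0.639, 0.709))
}

#' Seed strengths of the measured batch
#'
#' Manufacturer-stated strengths of the six seeds used in the measurement
#' campaign, in mCi.
#'
#' @return Numeric vector of six strengths.
#' @export
published_seed_strengths <- function() {
  c(1.041, 1.016, 0.995, 0.991, 0.901, 0.860)
}

#' Reference TG-43 dataset used as synthetic-campaign ground truth
#'
#' Builds a complete `tg43_dataset` from the published characterization of
#' the GMS BT-125-1 seed: the published Monte Carlo dose rate constant,
#' g(r) evaluated from the published quintic fit, the published anisotropy
#' table, and a smooth SYNTHETIC PMMA-to-water conversion surface
#' \eqn{P(r) = \exp(c (r - 1))} (the published work prints no conversion
#' table; this stand-in only has to be smooth and shared between the
#' generator and the analysis chain).
#'
#' @param p_phant_slope Log-slope c of the synthetic conversion factor per
#'   cm; the default is a mild attenuation-difference estimate from the
#'   vendored cross sections.
#' @return A [tg43_dataset()].
#' @export
reference_dataset <- function(p_phant_slope = -0.008) {
  radii <- c(0.5, 0.7, seq(1, 10, by = 0.5))
  gfit <- published_g_fit()
  g <- eval_radial_poly(gfit, radii)
  g <- g / eval_radial_poly(gfit, 1)  # exact normalization at r0
  g_table <- data.frame(r_cm = radii, g = g)
  f_table <- published_anisotropy_mc()
  f_table <- f_table[is.finite(f_table$F), ]
  grid <- expand.grid(r_cm = radii, theta_deg = seq(0, 90, by = 10))
  p_phant <- data.frame(grid,
                        p_phant = exp(p_phant_slope * (grid$r_cm - 1)),
                        rel_err = 0)
  tg43_dataset(lambda = published_lambdas()$lambda_mc, L = 0.325,
               g_table = g_table, f_table = f_table,
               g_fit = gfit / eval_radial_poly(gfit, 1),
               p_phant = p_phant,
               provenance = list(source = "published characterization",
                                 p_phant = "synthetic stand-in"))
}
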