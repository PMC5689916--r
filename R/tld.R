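# Synthetic thermoluminescent-dosimetry arm: phantom layouts, the reading
# generator with the campaign noise model, and the analysis chain turning
# readings back into experimental TG-43 parameters.

TLD_ENERGY_RESPONSE_PHANTOM <- 1.14  # relative energy response at ~33 keV in PMMA
TLD_ENERGY_RESPONSE_CALIB <- 1.17    # at the 48 keV calibration quality

#' PMMA phantom hole layouts
#'
#' Phantom I (dose rate constant and radial dose function): the seed axis is
#' perpendicular to the slab plane, all holes lie on the transverse plane
#' (polar angle 90 degrees) at radii 0.5, 0.7 and 1-10 cm in 0.5 cm steps,
#' each successive hole rotated by 5 degrees in azimuth so that no dosimeter
#' shadows another.  Phantom II (anisotropy function): radii 0.5-7 cm with
#' measurement angles 0-350 degrees in 10 degree steps (20 degrees at
#' r = 0.5 cm) around the seed long axis.
#'
#' @param which `"I"` or `"II"`.
#' @return Object of class `phantom_layout` with a `holes` data.frame
#'   (`r_cm`, `angle_deg`, `theta_deg` used for dose evaluation), TLD rod
#'   dimensions and the machining tolerance.
#' @export
phantom_layout <- function(which = c("I", "II")) {
  which <- match.arg(which)
  if (which == "I") {
    radii <- c(0.5, 0.7, seq(1, 10, by = 0.5))
    holes <- data.frame(r_cm = radii,
                        angle_deg = 5 * (seq_along(radii) - 1),
                        theta_deg = 90)
  } else {
    radii <- c(0.5, 0.7, 1, 1.5, 2, 3, 4, 5, 6, 7)
    holes <- do.call(rbind, lapply(radii, function(r) {
      # the 20-degree grid at 0.5 cm runs through the odd multiples of ten
      # degrees so that the folded quadrant includes 90 degrees
      ang <- if (r == 0.5) seq(10, 350, by = 20) else seq(0, 350, by = 10)
      data.frame(r_cm = r, angle_deg = ang,
                 theta_deg = ifelse(ang <= 180, ang, 360 - ang))
    }))
  }
  structure(list(id = which, holes = holes, tld_length_cm = 0.6,
                 tld_diameter_cm = 0.1, machining_tolerance_cm = 0.005),
            class = "phantom_layout")
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("<phantom_layout> %s: %d holes, radii %g-%g cm\n", x$id,
              nrow(x$holes), min(x$holes$r_cm), max(x$holes$r_cm)))
  invisible(x)
}

#' Measurement noise model
#'
#' Component magnitudes of the measurement uncertainty budget, used by the
#' synthetic reading generator: repetitive-reading CV (Type A, per
#' reading), hole-positioning radial jitter (drawn once per hole per
#' campaign: machining errors are frozen into a phantom), and the
#' campaign-level systematics for TLD dose calibration, seed strength and
#' PMMA-to-water conversion.  `positioning_sigma_cm` defaults to
#' 0.035/2.1 cm so that the induced dose CV at 1 cm is about 3.5% (the
#' log-slope of the dose profile at 1 cm is about -2.1 per cm); the induced
#' CV then grows automatically toward the seed, where the dose gradient is
#' steepest.
#'
#' @param repetitive_cv,calibration_cv,strength_cv,conversion_cv Relative
#'   standard deviations (fractions, not percent).
#' @param positioning_sigma_cm Radial jitter standard deviation in cm.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(repetitive_cv = 0.045,
                        positioning_sigma_cm = 0.035 / 2.1,
                        calibration_cv = 0.026, strength_cv = 0.030,
                        conversion_cv = 0.030) {
  vals <- c(repetitive_cv, positioning_sigma_cm, calibration_cv,
            strength_cv, conversion_cv)
  if (any(vals < 0)) stop("noise components must be non-negative")
  structure(list(repetitive_cv = repetitive_cv,
                 positioning_sigma_cm = positioning_sigma_cm,
                 calibration_cv = calibration_cv,
                 strength_cv = strength_cv,
                 conversion_cv = conversion_cv),
            class = "noise_model")
}

#' Noise-free model (for round-trip checks)
#' @return A [noise_model()] with every component zero.
#' @export
noise_model_zero <- function() {
  noise_model(0, 0, 0, 0, 0)
}

#' TLD calibration curve
#'
#' Linear light-to-dose calibration, valid below the saturation bound.
#'
#' @param slope_cgy_per_unit Dose (cGy) per light unit.
#' @param linear_max_cgy Upper end of the linear range (default 10 Gy).
#' @return Object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope_cgy_per_unit = 0.01,
                              linear_max_cgy = 1000) {
  stopifnot(slope_cgy_per_unit > 0, linear_max_cgy > 0)
  structure(list(slope = slope_cgy_per_unit, linear_max = linear_max_cgy),
            class = "calibration_curve")
}

# mean-1 lognormal multiplicative error
lnorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

# decay-weighted effective exposure time in hours
effective_exposure_h <- function(exposure_h,
                                 half_life_h = I125_HALF_LIFE_DAYS * 24) {
  half_life_h / log(2) * (1 - 2^(-exposure_h / half_life_h))
}

# bilinear lookup of a conversion-factor table (columns r_cm, theta_deg,
# p_phant); shared by the generator and the analysis chain so that the
# noiseless round trip is exact.
interp_p_phant <- function(p_table, r, theta_deg) {
  th <- pmin(theta_deg, 180 - theta_deg)
  radii <- sort(unique(p_table$r_cm))
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    if (length(radii) == 1) {
      d <- p_table[abs(p_table$r_cm - radii) < 1e-9, ]
      if (nrow(d) == 1) { out[i] <- d$p_phant; next }
      d <- d[order(d$theta_deg), ]
      out[i] <- approx(d$theta_deg, d$p_phant,
                       xout = min(max(th[i], min(d$theta_deg)),
                                  max(d$theta_deg)), rule = 2)$y
      next
    }
    rq <- min(max(r[i], radii[1]), radii[length(radii)])
    j <- findInterval(rq, radii, all.inside = TRUE)
    r1 <- radii[j]; r2 <- radii[j + 1]
    w <- if (r2 > r1) (rq - r1) / (r2 - r1) else 0
    col <- function(rr) {
      d <- p_table[abs(p_table$r_cm - rr) < 1e-9, ]
      if (nrow(d) == 1) return(d$p_phant)
      d <- d[order(d$theta_deg), ]
      approx(d$theta_deg, d$p_phant,
             xout = min(max(th[i], min(d$theta_deg)), max(d$theta_deg)),
             rule = 2)$y
    }
    out[i] <- (1 - w) * col(r1) + w * col(r2)
  }
  out
}

# dose evaluation points representing a TLD rod: 5 samples along its axis
tld_sample_points <- function(r, theta_deg, layout_id, length_cm) {
  offs <- seq(-length_cm / 2, length_cm / 2, length.out = 5)
  th <- theta_deg * pi / 180
  if (layout_id == "I") {
    # rod axis parallel to the seed axis (z); hole on the transverse plane
    rp <- sqrt(r^2 + offs^2)
    thp <- acos(offs / rp) * 180 / pi
  } else {
    # rod axis perpendicular to the measurement plane
    rp <- sqrt(r^2 + offs^2)
    thp <- acos(r * cos(th) / rp) * 180 / pi
  }
  list(r = rp, theta = thp)
}

#' Generate a synthetic TLD reading campaign
#'
#' Emulates one measurement campaign: six seeds of the given strengths
#' exposed in a phantom, each hole read once.  The true PMMA dose rate at a
#' (jittered) hole position is the water dose rate reconstructed from the
#' ground-truth TG-43 dataset divided by the conversion factor; readings
#' include source decay over the exposure, the relative TLD energy
#' response, per-reading repetitive noise, and the campaign-level
#' systematic factors of the noise model.  The returned object carries what
#' a real analyst would have: the nominal calibration, the labelled
#' strengths and a conversion table bearing the campaign's conversion
#' systematic - not the true factors.
#'
#' @param truth A [tg43_dataset()] with a `p_phant` table.
#' @param layout A [phantom_layout()].
#' @param strengths_mci Labelled seed strengths (mCi).
#' @param noise A [noise_model()].
#' @param exposure_h Exposure duration in hours (> 0).
#' @param cal A [calibration_curve()] (nominal).
#' @param rng_seed Optional integer seed.
#' @param tld_volume_average Represent each rod by 5 axial sample points
#'   (default); `FALSE` treats dosimeters as points (used by the noiseless
#'   round-trip checks).
#' @return Object of class `tld_readings`: `readings` data.frame
#'   (`seed_id`, `r_cm`, `angle_deg`, `theta_deg`, `reading`,
#'   `exposure_h`), the nominal `cal`, `strengths_mci`, the analyst's
#'   `p_phant` table and layout metadata.
#' @export
generate_synthetic_readings <- function(truth, layout, strengths_mci,
                                        noise = noise_model(),
                                        exposure_h = 48,
                                        cal = calibration_curve(),
                                        rng_seed = NULL,
                                        tld_volume_average = TRUE) {
  stopifnot(inherits(truth, "tg43_dataset"), inherits(layout,
            "phantom_layout"), inherits(noise, "noise_model"))
  if (exposure_h <= 0) stop("exposure must be positive")
  if (is.null(truth$p_phant)) stop("truth dataset lacks a p_phant table")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  holes <- layout$holes
  nh <- nrow(holes)
  ns <- length(strengths_mci)

  # campaign-level draws
  f_cal <- lnorm_factor(1, noise$calibration_cv)        # true slope factor
  f_str <- lnorm_factor(1, noise$strength_cv)           # true strength factor
  f_conv <- lnorm_factor(1, noise$conversion_cv)        # analyst's P error
  dr_holes <- rnorm(nh, 0, noise$positioning_sigma_cm)  # frozen per phantom

  slope_true <- cal$slope * f_cal
  tau <- effective_exposure_h(exposure_h)
  resp <- TLD_ENERGY_RESPONSE_PHANTOM / TLD_ENERGY_RESPONSE_CALIB

  out <- NULL
  for (s in seq_len(ns)) {
    sk_true <- strengths_mci[s] * f_str * U_PER_MCI
    r_true <- pmax(holes$r_cm + dr_holes, 0.05)
    dw <- numeric(nh)
    for (i in seq_len(nh)) {
      if (tld_volume_average) {
        pts <- tld_sample_points(r_true[i], holes$theta_deg[i], layout$id,
                                 layout$tld_length_cm)
        dw[i] <- mean(reconstruct_dose_rate(truth, sk_true, pts$r,
                                            pts$theta,
                                            allow_extrapolation = TRUE))
        dpm <- dw[i] / interp_p_phant(truth$p_phant, r_true[i],
                                      holes$theta_deg[i])
      } else {
        dw[i] <- reconstruct_dose_rate(truth, sk_true, r_true[i],
                                       holes$theta_deg[i],
                                       allow_extrapolation = TRUE)
        dpm <- dw[i] / interp_p_phant(truth$p_phant, r_true[i],
                                      holes$theta_deg[i])
      }
      dose_cgy <- dpm * tau                       # integrated PMMA dose
      light <- dose_cgy * resp / slope_true
      out <- rbind(out, data.frame(
        seed_id = s, r_cm = holes$r_cm[i], angle_deg = holes$angle_deg[i],
        theta_deg = holes$theta_deg[i],
        reading = light * lnorm_factor(1, noise$repetitive_cv),
        exposure_h = exposure_h))
    }
  }
  p_analyst <- truth$p_phant
  p_analyst$p_phant <- p_analyst$p_phant * f_conv
  structure(list(readings = out, cal = cal, strengths_mci = strengths_mci,
                 p_phant = p_analyst, layout_id = layout$id,
                 exposure_h = exposure_h,
                 energy_response = resp),
            class = "tld_readings")
}

#' @export
print.tld_readings <- function(x, ...) {
  cat(sprintf("<tld_readings> phantom %s: %d seeds x %d holes\n",
              x$layout_id, length(x$strengths_mci),
              nrow(x$readings) / length(x$strengths_mci)))
  invisible(x)
}

#' Convert raw TLD readings to PMMA dose rates
#'
#' dose = reading x slope / energy-response; dose rate = dose / effective
#' (decay-corrected) exposure time.  Readings above the linear range of the
#' calibration curve are an error (saturation).
#'
#' @param rs A `tld_readings` object.
#' @param cal Calibration curve; defaults to the one carried by `rs`.
#' @return data.frame of per-hole PMMA dose rates (`dose_rate_cgy_h`),
#'   with seed and position columns.
#' @export
readings_to_dose_rates <- function(rs, cal = rs$cal) {
  d <- rs$readings
  dose <- d$reading * cal$slope
  if (any(dose > cal$linear_max))
    stop("reading beyond the linear calibration range (saturation)")
  dose <- dose / rs$energy_response
  tau <- effective_exposure_h(d$exposure_h)
  cbind(d[c("seed_id", "r_cm", "angle_deg", "theta_deg")],
        dose_rate_cgy_h = dose / tau)
}

#' Fold a full-circle angular table onto the 0-90 degree quadrant
#'
#' Measurement angles run 0-350 degrees; each angle and its supplementary
#' partners (\eqn{180-\theta}, \eqn{180+\theta}, \eqn{360-\theta}) probe
#' mirror-equivalent points of a symmetric seed and are averaged.  Missing
#' entries are skipped; the number averaged is recorded.
#'
#' @param tab data.frame with `angle_deg` (0-350) and `value`.
#' @return data.frame `theta_deg` (0-90), `value`, `n_averaged`.
#' @export
average_supplementary_angles <- function(tab) {
  a <- tab$angle_deg %% 360
  fold <- pmin(a %% 180, 180 - (a %% 180))
  keep <- is.finite(tab$value)
  agg <- split(tab$value[keep], fold[keep])
  data.frame(theta_deg = as.numeric(names(agg)),
             value = vapply(agg, mean, 0),
             n_averaged = vapply(agg, length, 0L),
             row.names = NULL)
}

#' Derive experimental TG-43 parameters from a reading campaign
#'
#' The measurement analysis chain: readings to PMMA dose rates, conversion
#' to water with the campaign's conversion table, per-seed normalization by
#' the labelled strength, averaging across seeds, then the TG-43 relations:
#' \eqn{\Lambda = D(r_0,\theta_0)/S_K} from the phantom-I reference hole,
#' g(r) from the phantom-I transverse profile, and F(r,theta) from the
#' folded phantom-II table.  The measurement uncertainty budget total is
#' attached to the dose rate constant.
#'
#' @param rates_I Output of [readings_to_dose_rates()] for phantom I.
#' @param rates_II Optional, for phantom II (anisotropy); `NULL` to skip.
#' @param p_phant Conversion table (use the one carried by the readings).
#' @param strengths_mci Labelled strengths, mCi.
#' @param L Active length, cm.
#' @return List with `lambda`, `lambda_pct_uncertainty`, `g_table`,
#'   `f_table` (NULL if no phantom II data).
#' @export
derive_experimental_parameters <- function(rates_I, rates_II = NULL,
                                           p_phant, strengths_mci,
                                           L = 0.325) {
  sk_u <- strengths_mci * U_PER_MCI
  di <- rates_I
  di$dw <- di$dose_rate_cgy_h *
    interp_p_phant(p_phant, di$r_cm, di$theta_deg)
  if (!any(abs(di$r_cm - 1) < 1e-9)) stop("no reference hole at r0 = 1 cm")

  # dose rate constant: reference hole, per seed, then averaged
  ref <- di[abs(di$r_cm - 1) < 1e-9, ]
  lam_i <- ref$dw / sk_u[ref$seed_id]
  lambda <- mean(lam_i)

  # radial dose function, per seed then averaged
  gtabs <- lapply(split(di, di$seed_id), function(d) {
    d0 <- d$dw[abs(d$r_cm - 1) < 1e-9]
    g <- (d$dw / d0) * (geometry_function(1, 90, L) /
                          geometry_function(d$r_cm, 90, L))
    data.frame(r_cm = d$r_cm, g = g)
  })
  r_all <- sort(unique(di$r_cm))
  g_mean <- vapply(r_all, function(r)
    mean(vapply(gtabs, function(t) t$g[abs(t$r_cm - r) < 1e-9][1], 0)), 0)
  g_table <- data.frame(r_cm = r_all, g = g_mean)

  f_table <- NULL
  if (!is.null(rates_II)) {
    dii <- rates_II
    dii$dw <- dii$dose_rate_cgy_h *
      interp_p_phant(p_phant, dii$r_cm, dii$theta_deg)
    per_seed <- lapply(split(dii, dii$seed_id), function(d) {
      do.call(rbind, lapply(split(d, d$r_cm), function(dr) {
        folded <- average_supplementary_angles(
          data.frame(angle_deg = dr$angle_deg, value = dr$dw))
        i90 <- which(abs(folded$theta_deg - 90) < 1e-6)
        if (length(i90) != 1) stop("no 90-degree hole at r = ", dr$r_cm[1])
        r <- dr$r_cm[1]
        Fv <- (folded$value / folded$value[i90]) *
          (geometry_function(r, 90, L) /
             geometry_function(r, folded$theta_deg, L))
        Fv[i90] <- 1
        data.frame(r_cm = r, theta_deg = folded$theta_deg, F = Fv)
      }))
    })
    key <- paste(per_seed[[1]]$r_cm, per_seed[[1]]$theta_deg)
    fmat <- vapply(per_seed, function(t) t$F, numeric(nrow(per_seed[[1]])))
    f_table <- data.frame(r_cm = per_seed[[1]]$r_cm,
                          theta_deg = per_seed[[1]]$theta_deg,
                          F = rowMeans(fmat))
    rownames(f_table) <- NULL
    stopifnot(length(unique(key)) == nrow(f_table))
  }

  list(lambda = lambda,
       lambda_pct_uncertainty = rss_total(measurement_budget()$value_pct),
       g_table = g_table, f_table = f_table)
}
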