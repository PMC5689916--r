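test_that("phantom layouts match the measurement geometry", {
  p1 <- phantom_layout("I")
  expect_equal(sort(unique(p1$holes$r_cm)), c(0.5, 0.7, seq(1, 10, 0.5)))
  expect_true(all(p1$holes$theta_deg == 90))
  expect_equal(nrow(p1$holes), 21)  # one hole per radius, 5 deg apart
  expect_equal(diff(p1$holes$angle_deg), rep(5, 20))

  p2 <- phantom_layout("II")
  expect_equal(sort(unique(p2$holes$r_cm)),
               c(0.5, 0.7, 1, 1.5, 2, 3, 4, 5, 6, 7))
  a05 <- p2$holes$angle_deg[p2$holes$r_cm == 0.5]
  expect_equal(diff(sort(a05))[1], 20)
  a1 <- p2$holes$angle_deg[p2$holes$r_cm == 1]
  expect_equal(sort(a1), seq(0, 350, 10))
  # every radius folds onto a quadrant that includes 90 degrees
  for (r in unique(p2$holes$r_cm)) {
    a <- p2$holes$angle_deg[p2$holes$r_cm == r] %% 180
    expect_true(any(pmin(a, 180 - a) == 90))
  }
  expect_equal(p2$tld_length_cm, 0.6)
  expect_equal(p2$tld_diameter_cm, 0.1)
})

test_that("the noiseless analysis chain inverts the generator exactly", {
  truth <- reference_dataset()
  s <- published_seed_strengths()
  rs1 <- generate_synthetic_readings(truth, phantom_layout("I"), s,
                                     noise = noise_model_zero(),
                                     rng_seed = 301,
                                     tld_volume_average = FALSE)
  rs2 <- generate_synthetic_readings(truth, phantom_layout("II"), s,
                                     noise = noise_model_zero(),
                                     rng_seed = 302,
                                     tld_volume_average = FALSE)
  res <- derive_experimental_parameters(readings_to_dose_rates(rs1),
                                        readings_to_dose_rates(rs2),
                                        rs1$p_phant, s)
  expect_equal(res$lambda, truth$lambda, tolerance = 1e-12)
  g_truth <- eval_radial_poly(truth$g_fit, res$g_table$r_cm)
  expect_equal(res$g_table$g, g_truth, tolerance = 1e-12)
  # anisotropy recovered at the folded grid
  m <- merge(res$f_table, truth$f_table, by = c("r_cm", "theta_deg"))
  expect_equal(m$F.x, m$F.y, tolerance = 1e-12)
})

test_that("readings scale linearly with exposure and signal", {
  truth <- reference_dataset()
  gen <- function(h) generate_synthetic_readings(
    truth, phantom_layout("I"), 1.0, noise = noise_model_zero(),
    exposure_h = h, rng_seed = 303, tld_volume_average = FALSE)
  r48 <- gen(48)
  r96 <- gen(96)
  # doubling a short exposure nearly doubles readings (decay slightly less)
  ratio <- r96$readings$reading / r48$readings$reading
  expect_true(all(abs(ratio - 2) < 0.05))
  expect_true(all(ratio < 2))
  expect_error(generate_synthetic_readings(truth, phantom_layout("I"), 1,
                                           exposure_h = -1), "positive")
})

test_that("dose conversion is linear, rejects saturation, and divides out response", {
  truth <- reference_dataset()
  rs <- generate_synthetic_readings(truth, phantom_layout("I"), 1.0,
                                    noise = noise_model_zero(),
                                    rng_seed = 304,
                                    tld_volume_average = FALSE)
  base <- readings_to_dose_rates(rs)
  rs2 <- rs
  rs2$readings$reading <- 2 * rs$readings$reading
  expect_equal(readings_to_dose_rates(rs2)$dose_rate_cgy_h,
               2 * base$dose_rate_cgy_h)
  rs3 <- rs
  rs3$readings$reading <- 0 * rs$readings$reading
  expect_true(all(readings_to_dose_rates(rs3)$dose_rate_cgy_h == 0))
  # two dosimeter batches differing only in energy response yield the same dose
  rs4 <- rs
  rs4$energy_response <- rs$energy_response * 1.14
  rs4$readings$reading <- rs$readings$reading * 1.14
  expect_equal(readings_to_dose_rates(rs4)$dose_rate_cgy_h,
               base$dose_rate_cgy_h)
  # saturation beyond the linear bound errors
  rs5 <- rs
  rs5$readings$reading <- rs$readings$reading + 2e5
  expect_error(readings_to_dose_rates(rs5), "saturation")
})

test_that("per-reading repetitive noise reproduces its nominal CV", {
  truth <- reference_dataset()
  nm <- noise_model(repetitive_cv = 0.045, positioning_sigma_cm = 0,
                    calibration_cv = 0, strength_cv = 0, conversion_cv = 0)
  set.seed(305)
  reads <- replicate(500, {
    rs <- generate_synthetic_readings(truth, phantom_layout("I"), 1.0,
                                      noise = nm, tld_volume_average = FALSE)
    rs$readings$reading[rs$readings$r_cm == 1]
  })
  cv <- sd(reads) / mean(reads)
  expect_lt(abs(cv - 0.045), 0.01)
})

test_that("supplementary-angle folding averages mirror partners", {
  # v at 10 deg and w at 190 deg fold to their mean at 10 deg
  tab <- data.frame(angle_deg = c(10, 190), value = c(2, 4))
  out <- average_supplementary_angles(tab)
  expect_equal(out$value[out$theta_deg == 10], 3)
  expect_equal(out$n_averaged[out$theta_deg == 10], 2L)
  # a perfectly symmetric full circle collapses to any quadrant
  ang <- seq(0, 350, by = 10)
  sym <- data.frame(angle_deg = ang,
                    value = cos(pmin(ang %% 180, 180 - ang %% 180) *
                                pi / 180) + 2)
  out2 <- average_supplementary_angles(sym)
  expect_equal(out2$value, cos(out2$theta_deg * pi / 180) + 2,
               tolerance = 1e-12)
  # idempotent on an already-folded table
  out3 <- average_supplementary_angles(
    data.frame(angle_deg = out2$theta_deg, value = out2$value))
  expect_equal(out3$value, out2$value, tolerance = 1e-12)
  # missing entries are skipped with the count recorded
  tab4 <- data.frame(angle_deg = c(20, 160, 200, 340),
                     value = c(1, 3, NA, 5))
  out4 <- average_supplementary_angles(tab4)
  expect_equal(out4$value, 3)
  expect_equal(out4$n_averaged, 3L)
})

test_that("finite TLD rods average the dose over their length", {
  truth <- reference_dataset()
  rs_pt <- generate_synthetic_readings(truth, phantom_layout("I"), 1.0,
                                       noise = noise_model_zero(),
                                       rng_seed = 306,
                                       tld_volume_average = FALSE)
  rs_vol <- generate_synthetic_readings(truth, phantom_layout("I"), 1.0,
                                        noise = noise_model_zero(),
                                        rng_seed = 306)
  r1 <- rs_pt$readings$reading[rs_pt$readings$r_cm == 1]
  r2 <- rs_vol$readings$reading[rs_vol$readings$r_cm == 1]
  # the 6 mm rod sees a lower average dose than its centre point
  expect_lt(r2, r1)
  expect_gt(r2 / r1, 0.9)
})
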