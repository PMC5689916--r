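test_that("line-source geometry function matches limits and the integral oracle", {
  # point-source limit
  expect_equal(geometry_function(2, 90, 0), 0.25, tolerance = 1e-14)
  # transverse value for the default active length (beta = 2 atan(L/2r))
  expect_equal(geometry_function(1, 90, 0.325), 0.9913348, tolerance = 1e-7)
  expect_equal(geometry_function(1, 90, 0.325),
               oracle_geometry(1, 90, 0.325), tolerance = 1e-10)
  # long-axis limit 1/(r^2 - L^2/4)
  expect_equal(geometry_function(1, 0, 0.325), 1 / (1 - 0.325^2 / 4),
               tolerance = 1e-12)
  expect_equal(geometry_function(1, 180, 0.325), 1 / (1 - 0.325^2 / 4),
               tolerance = 1e-12)
  # random points against the numeric double-integration oracle
  set.seed(201)
  for (i in 1:100) {
    r <- runif(1, 0.3, 10)
    th <- runif(1, 1, 179)
    expect_equal(geometry_function(r, th, 0.325),
                 oracle_geometry(r, th, 0.325), tolerance = 1e-6)
  }
  # G r^2 -> 1 uniformly as L/r -> 0
  th <- seq(0, 180, by = 5)
  g <- geometry_function(1, th, 1e-4)
  expect_true(all(abs(g - 1) < 1e-8))
  # on-axis points inside the source extent are invalid
  expect_error(geometry_function(0.1, 0, 0.325), "inside the source")
})

test_that("dose rate constant is a unit-consistent ratio", {
  expect_equal(dose_rate_constant(1, 1), 1)
  expect_error(dose_rate_constant(1, 0), "positive")
  expect_error(dose_rate_constant(1, -2), "positive")
  # per-history normalization cancels
  expect_equal(dose_rate_constant(2 * 0.123, 2 * 0.456),
               dose_rate_constant(0.123, 0.456))
})

test_that("consensus constant is the arithmetic mean", {
  expect_equal(average_dose_rate_constant(0.975, 0.943), 0.959)
  expect_equal(average_dose_rate_constant(0.7, 0.7), 0.7)
  expect_equal(average_dose_rate_constant(1.0, 0.9), 0.95)
})

test_that("radial dose function normalizes and removes pure geometry", {
  radii <- c(0.5, 1, 2, 5)
  # dose proportional to the geometry function -> g identically 1
  fake <- data.frame(r_cm = radii, theta_deg = 90,
                     dose_per_history = geometry_function(radii, 90, 0.325),
                     rel_err = 0.01, medium = "water", histories = 1,
                     rng_seed = 1)
  g <- radial_dose_function(fake, 0.325)
  expect_equal(g$g, rep(1, 4), tolerance = 1e-12)
  expect_identical(g$g[g$r_cm == 1], 1)
  expect_error(radial_dose_function(fake[fake$r_cm != 1, ], 0.325), "r0")
})

test_that("quintic g(r) fit round-trips the published coefficients", {
  cf <- published_g_fit()
  radii <- c(0.5, 0.7, seq(1, 10, by = 0.5))
  g <- data.frame(r_cm = radii, g = eval_radial_poly(cf, radii))
  fit <- fit_radial_poly(g)
  expect_equal(unname(fit$coefficients), unname(cf), tolerance = 1e-9)
  expect_lt(fit$max_residual, 1e-9)
  # evaluating the published coefficients at the reference radius
  expect_equal(eval_radial_poly(cf, 1), 0.999, tolerance = 1e-3)
  # constant data give a0 = 1, everything else zero
  fit1 <- fit_radial_poly(data.frame(r_cm = radii, g = 1))
  expect_equal(unname(fit1$coefficients), c(1, 0, 0, 0, 0, 0),
               tolerance = 1e-9)
  expect_error(fit_radial_poly(g[1:5, ]), "7 radii")
  expect_error(fit_radial_poly(data.frame(r_cm = rep(1, 8),
                                          g = rep(1, 8))), "rank")
})

test_that("anisotropy function normalizes at 90 degrees and folds mirrors", {
  radii <- rep(c(1, 2), each = 19)
  th <- rep(seq(0, 180, by = 10), 2)
  # isotropic point source: dose = 1/r^2 -> F = 1 everywhere (L = 0)
  fake <- data.frame(r_cm = radii, theta_deg = th,
                     dose_per_history = 1 / radii^2, rel_err = 0.01,
                     medium = "water", histories = 1, rng_seed = 1)
  f <- anisotropy_function(fake, 0)
  expect_true(all(abs(f$F - 1) < 1e-12))
  expect_true(all(f$theta_deg >= 0 & f$theta_deg <= 90))
  expect_true(all(f$F[abs(f$theta_deg - 90) < 1e-6] == 1))
  expect_error(anisotropy_function(fake[th != 90, ], 0, radii = 1),
               "90-degree")
})

test_that("quintic anisotropy fits recover known columns", {
  # constant column
  th <- seq(0, 90, by = 10)
  p <- fit_anisotropy_poly(th, rep(1, length(th)))
  expect_equal(unname(p), c(1, 0, 0, 0, 0, 0), tolerance = 1e-9)
  # round-trip of a known quintic in radians
  coefs <- c(0.3, 0.9, 0.4, -0.8, 0.3, -0.04)
  Fv <- drop(outer(th * pi / 180, 0:5, `^`) %*% coefs)
  expect_equal(unname(fit_anisotropy_poly(th, Fv)), coefs, tolerance = 1e-9)
  # the published 0.7 cm column: p0 approximates F(0.7, 0) = 0.303
  pub <- published_anisotropy_mc()
  d <- pub[pub$r_cm == 0.7 & is.finite(pub$F), ]
  p0 <- fit_anisotropy_poly(d$theta_deg, d$F)[["p0"]]
  expect_lt(abs(p0 - 0.303), 0.02)
  expect_error(fit_anisotropy_poly(th[1:4], Fv[1:4]), "7 angles")
})

test_that("phantom conversion factors are ratios with propagated errors", {
  tw <- data.frame(r_cm = c(1, 2), theta_deg = 90,
                   dose_per_history = c(2, 1), rel_err = c(0.01, 0.02))
  # identical media give exactly one
  expect_equal(pmma_to_water_factor(tw, tw)$p_phant, c(1, 1))
  tp <- tw
  tp$dose_per_history <- c(4, 1)
  tp$rel_err <- c(0.03, 0.01)
  pf <- pmma_to_water_factor(tw, tp)
  expect_equal(pf$p_phant, c(0.5, 1))
  expect_equal(pf$rel_err, sqrt(tw$rel_err^2 + tp$rel_err^2))
  expect_error(pmma_to_water_factor(tw, tp[2:1, ]), "do not match")
})

test_that("dose reconstruction recombines the factors consistently", {
  ds <- reference_dataset()
  # the reference point returns Sk * Lambda
  expect_equal(reconstruct_dose_rate(ds, 2, 1, 90), 2 * ds$lambda,
               tolerance = 1e-12)
  # reconstruction at transverse table nodes equals Lambda g G/G0 (1%)
  r <- c(0.5, 2, 5, 7)
  got <- reconstruct_dose_rate(ds, 1, r, 90)
  want <- ds$lambda * eval_radial_poly(ds$g_fit, r) *
    geometry_function(r, 90, ds$L) / geometry_function(1, 90, ds$L)
  expect_equal(got, want, tolerance = 0.01)
  # monotone decrease along the transverse axis
  prof <- reconstruct_dose_rate(ds, 1, seq(1, 7, by = 0.5), 90)
  expect_true(all(diff(prof) < 0))
  expect_error(reconstruct_dose_rate(ds, 1, 12, 90), "outside")
  expect_silent(reconstruct_dose_rate(ds, 1, 12, 90,
                                      allow_extrapolation = TRUE))
})

test_that("TG-43 datasets serialize and validate on read", {
  ds <- reference_dataset()
  dir <- tempfile("tg43")
  write_tg43_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir, c("lambda.csv", "g.csv",
                                               "F.csv", "metadata.json")))))
  back <- read_tg43_dataset(dir)
  expect_equal(back$lambda, ds$lambda)
  expect_equal(back$g_table$g, ds$g_table$g)
  expect_equal(back$f_table$F, ds$f_table$F)
  # invariants enforced by the constructor
  bad_g <- ds$g_table
  bad_g$g[bad_g$r_cm == 1] <- 1.05
  expect_error(tg43_dataset(ds$lambda, ds$L, bad_g, ds$f_table),
               "normalized")
  bad_f <- ds$f_table
  bad_f$F[1] <- -0.1
  expect_error(tg43_dataset(ds$lambda, ds$L, ds$g_table, bad_f), "positive")
})
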