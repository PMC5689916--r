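test_that("regions partition space and match the engineering drawing", {
  expect_equal(region_at(seed_fix, c(0, 0, 0)), "marker")
  # between the capsule inner radius (0.034) and outer radius (0.040)
  expect_equal(region_at(seed_fix, c(0, 0.039, 0)), "capsule_wall")
  expect_equal(region_at(seed_fix, c(0, 0.036, 0)), "capsule_wall")
  expect_equal(region_at(seed_fix, c(0, 0.030, 0)), "capsule_gap")
  expect_equal(region_at(seed_fix, c(0, 0.05, 0)), "exterior")
  expect_equal(region_at(seed_fix, c(0, 0, 0.2249)), "capsule_wall")
  expect_equal(region_at(seed_fix, c(0, 0, 0.2251)), "exterior")
})

test_that("region classification agrees with a signed-distance oracle", {
  set.seed(101)
  n <- 5000
  pts <- cbind(runif(n, -0.06, 0.06), runif(n, -0.06, 0.06),
               runif(n, -0.26, 0.26))
  got <- region_at(seed_fix, pts)
  want <- apply(pts, 1, function(p) oracle_region(seed_fix, p))
  expect_identical(got, unname(want))
})

test_that("region classification is axisymmetric", {
  set.seed(102)
  n <- 500
  pts <- cbind(runif(n, -0.06, 0.06), runif(n, -0.06, 0.06),
               runif(n, -0.26, 0.26))
  phi <- runif(n, 0, 2 * pi)
  rot <- cbind(pts[, 1] * cos(phi) - pts[, 2] * sin(phi),
               pts[, 1] * sin(phi) + pts[, 2] * cos(phi), pts[, 3])
  expect_identical(region_at(seed_fix, pts), region_at(seed_fix, rot))
})

test_that("boundary distances match the drawing and a ray-marching oracle", {
  d <- distance_to_boundary(seed_fix, c(0, 0, 0), c(0, 0, 1))
  expect_equal(d$distance, 0.1625, tolerance = 1e-12)
  expect_equal(d$next_region, "coating")
  d <- distance_to_boundary(seed_fix, c(0, 0, 0), c(0, 1, 0))
  expect_equal(d$distance, 0.025, tolerance = 1e-12)

  expect_error(distance_to_boundary(seed_fix, c(0, 0, 0), c(0, 0, 0)),
               "zero-length")

  # marching oracle at 1 um steps
  set.seed(103)
  step <- 1e-4
  for (i in 1:200) {
    p <- c(runif(1, -0.05, 0.05), runif(1, -0.05, 0.05),
           runif(1, -0.25, 0.25))
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    res <- distance_to_boundary(seed_fix, p, u)
    if (!is.finite(res$distance) || res$distance > 0.6) next
    r0 <- region_at(seed_fix, p)
    k <- 1
    repeat {
      q <- p + k * step * u
      if (region_at(seed_fix, q) != r0 || k * step > 0.7) break
      k <- k + 1
    }
    expect_lt(abs(res$distance - k * step), 1.5 * step)
    # marching just past the returned boundary changes region
    expect_equal(region_at(seed_fix, p + (res$distance + 1e-7) * u),
                 res$next_region)
  }
})

test_that("exterior rays that miss the capsule report no boundary", {
  res <- distance_to_boundary(seed_fix, c(1, 0, 0), c(1, 0, 0) / 1)
  expect_identical(res$distance, Inf)
})

test_that("default model volumes agree with closed-form solids", {
  expect_equal(seed_region_volume(seed_fix, "marker"),
               pi * 0.025^2 * 0.325, tolerance = 1e-12)
  # independent numeric integration of the wall solid of revolution
  wall_profile <- function(z) {
    vapply(z, function(zz) {
      az <- abs(zz)
      ro <- if (az <= 0.175) 0.04 else sqrt(max(0, 0.05^2 - (az - 0.175)^2))
      ri <- if (az <= 0.175) 0.034 else sqrt(max(0, 0.044^2 - (az - 0.175)^2))
      pi * (min(ro, 0.04)^2 - min(ri, 0.034)^2)
    }, 0)
  }
  vn <- integrate(wall_profile, -0.225, 0.225, subdivisions = 2000,
                  rel.tol = 1e-12)$value
  expect_equal(seed_region_volume(seed_fix, "capsule_wall"), vn,
               tolerance = 1e-9)
})

test_that("invalid seed dimensions are rejected", {
  expect_error(seed_model("gms-bt-125-1", marker_length = 0.5),
               "does not fit")
  expect_error(seed_model("gms-bt-125-1", marker_length = -1), "positive")
  expect_error(seed_model("gms-bt-125-1", coating_thickness = 0.02),
               "coating")
  expect_error(seed_model("no-such-seed"), "unknown seed model")
})
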