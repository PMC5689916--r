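# Shared fixtures: the cross-section library, the default seed model, and
# memoised Monte Carlo runs reused by several test files so the expensive
# transport work is done once per session.

xs_fix <- xs_library()
seed_fix <- seed_model()

.mc_cache <- new.env(parent = emptyenv())

mc_cached <- function(name, expr) {
  if (!exists(name, envir = .mc_cache)) assign(name, expr, envir = .mc_cache)
  get(name, envir = .mc_cache)
}

# vacuum air-kerma-strength run at the default history budget
ak_full <- function() {
  mc_cached("ak", air_kerma_strength(seed_fix, xs_fix, histories = 2e6,
                                     rng_seed = 20170914))
}

# water dose table on the full published grid
water_full <- function() {
  mc_cached("water", dose_rate_table(seed_fix, xs_fix, "water",
                                     histories = 2e6, rng_seed = 20170915))
}

# independent signed-distance region classifier (pure R, no ray tracing)
oracle_region <- function(seed, p) {
  rmark <- seed$marker_diameter / 2
  zmark <- seed$marker_length / 2
  rcoat <- rmark + seed$coating_thickness
  zcoat <- zmark + seed$coating_thickness
  rout <- seed$capsule_outer_diameter / 2
  rin <- rout - seed$capsule_wall
  Rout <- seed$end_cap_radius
  Rin <- Rout - seed$capsule_wall
  zc <- seed$capsule_length / 2 - Rout
  s <- sqrt(p[1]^2 + p[2]^2)
  az <- abs(p[3])
  inside_solid <- function(rc, R) {
    s <= rc && (az <= zc || s^2 + (az - zc)^2 <= R^2)
  }
  if (s <= rmark && az <= zmark) return("marker")
  if (s <= rcoat && az <= zcoat) return("coating")
  if (inside_solid(rin, Rin)) return("capsule_gap")
  if (inside_solid(rout, Rout)) return("capsule_wall")
  "exterior"
}

# numeric double-integration oracle for the line-source geometry function
oracle_geometry <- function(r, theta_deg, L) {
  th <- theta_deg * pi / 180
  y <- r * sin(th)
  z <- r * cos(th)
  integrate(function(t) 1 / (y^2 + (z - t)^2), -L / 2, L / 2,
            rel.tol = 1e-12)$value / L
}
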