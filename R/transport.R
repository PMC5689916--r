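# Analog photon transport around the encapsulated seed.  The C++ engine in
# src/transport.cpp does the per-photon work; these wrappers fix the
# material bookkeeping, seeding and unit chain.

MC_MATERIALS <- c("silver", "titanium", "water", "air", "pmma")
MC_CUTOFF_KEV <- 5
DEFAULT_RNG_SEED <- 20170914

mat_index <- function(name) {
  if (identical(name, "vacuum")) return(-1L)
  i <- match(name, MC_MATERIALS)
  if (is.na(i)) stop("unknown transport material: ", name)
  i - 1L
}

region_material_indices <- function(seed, exterior) {
  rm <- seed$region_materials
  vapply(c(rm$marker, rm$coating, rm$capsule_wall, rm$capsule_gap, exterior),
         mat_index, integer(1))
}

run_engine <- function(seed, xs, spectrum, histories, tally, phantom_radius,
                       exterior, score_material, rng_seed,
                       source_mode = 0L, cutoff_kev = MC_CUTOFF_KEV) {
  stopifnot(histories >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  geom <- if (is.null(seed)) numeric(0) else seed_geom_vector(seed)
  region_mat <- if (is.null(seed))
    c(-1L, -1L, -1L, -1L, mat_index(exterior))
  else region_material_indices(seed, exterior)
  cpp_run_mc(geom, xs_for_cpp(xs, MC_MATERIALS), region_mat,
             unclass(spectrum), as.integer(histories),
             if (inherits(tally, "ring_tally")) tally$cpp else
               empty_tally_cpp(),
             phantom_radius, mat_index(score_material), cutoff_kev,
             fluo_pars(), as.integer(source_mode))
}

#' Sample seed emissions
#'
#' Draws photon starting states: position uniform over the coating surface
#' (lateral surface plus end faces), isotropic direction, energy from the
#' line spectrum.
#'
#' @param seed A [seed_model()], or `NULL` for a point source at the origin.
#' @param spectrum A [photon_spectrum()].
#' @param n Number of samples.
#' @param rng_seed Optional integer seed.
#' @return data.frame with columns x, y, z, ux, uy, uz, energy_kev.
#' @export
sample_emission <- function(seed, spectrum, n, rng_seed = NULL) {
  stopifnot(inherits(spectrum, "photon_spectrum"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  geom <- if (is.null(seed)) numeric(0) else seed_geom_vector(seed)
  m <- cpp_sample_emission(geom, unclass(spectrum), as.integer(n))
  out <- as.data.frame(m)
  names(out) <- c("x", "y", "z", "ux", "uy", "uz", "energy_kev")
  out
}

#' Transport a single photon
#'
#' Analog transport of one photon through the seed and phantom: exponential
#' free paths, photoelectric absorption (with silver K fluorescence above
#' the K edge), free-electron Klein-Nishina incoherent scattering, coherent
#' scattering with a screened form-factor angular model, and a 5 keV cutoff.
#'
#' @param state List with `position` (cm), `direction`, `energy_kev`.
#' @param seed A [seed_model()] or `NULL`.
#' @param xs An [xs_library()].
#' @param phantom_medium `"water"`, `"pmma"`, `"air"` or `"vacuum"`.
#' @param phantom_radius Phantom sphere radius, cm.
#' @param rng_seed Optional integer seed.
#' @return List with `segments` (matrix of straight track segments with
#'   energy and region), `fate` (`"absorbed"`, `"escaped"` or `"cutoff"`)
#'   and `final_energy`.
#' @export
transport_photon <- function(state, seed, xs, phantom_medium = "water",
                             phantom_radius = 15, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- sqrt(sum(state$direction^2))
  if (!is.finite(n) || n < 1e-12) stop("zero-length direction")
  geom <- if (is.null(seed)) numeric(0) else seed_geom_vector(seed)
  region_mat <- if (is.null(seed))
    c(-1L, -1L, -1L, -1L, mat_index(phantom_medium))
  else region_material_indices(seed, phantom_medium)
  res <- cpp_track_photon(geom, xs_for_cpp(xs, MC_MATERIALS), region_mat,
                          state$position, state$direction, state$energy_kev,
                          phantom_radius, MC_CUTOFF_KEV, fluo_pars())
  res$fate <- c("absorbed", "escaped", "cutoff")[res$fate + 1L]
  res
}

#' Track-length kerma estimator (reference R implementation)
#'
#' Scores straight track segments onto a ring tally: each sub-segment inside
#' a cell contributes length x energy x (mu_en/rho) / volume, i.e. collision
#' kerma per unit mass.  This is the plain-R counterpart of the estimator
#' fused into the transport engine, kept as an auditable reference.
#'
#' @param segments Matrix with columns x0,y0,z0,x1,y1,z1,energy_kev (as
#'   produced by [transport_photon()]).
#' @param tally A [ring_tally()].
#' @param xs An [xs_library()].
#' @param medium Scoring medium for mu_en/rho.
#' @return Numeric vector of kerma contributions (keV/g) per cell.
#' @export
score_kerma <- function(segments, tally, xs, medium = "water") {
  stopifnot(inherits(tally, "ring_tally"))
  cells <- tally$cells
  if (any(cells$volume_cm3 <= 0)) stop("zero-volume cell")
  out <- numeric(nrow(cells))
  if (is.null(segments) || nrow(segments) == 0) return(out)
  for (k in seq_len(nrow(segments))) {
    p <- as.numeric(segments[k, 1:3])
    q <- as.numeric(segments[k, 4:6])
    e <- as.numeric(segments[k, 7])
    len <- sqrt(sum((q - p)^2))
    if (len <= 0) next
    d <- (q - p) / len
    w <- e * interaction_coefficients(xs, medium, e)[["mu_en"]]
    # breakpoints: crossings of every cell sphere and cone
    ts <- c(0, len)
    for (R in unique(c(cells$r_lo, cells$r_hi))) {
      b <- sum(p * d); cc <- sum(p^2) - R^2
      disc <- b^2 - cc
      if (disc > 0) ts <- c(ts, -b + sqrt(disc), -b - sqrt(disc))
    }
    for (th in unique(c(cells$theta_lo, cells$theta_hi))) {
      if (th <= 0 || th >= 180) next
      cth <- cos(th * pi / 180)
      a <- d[3]^2 - cth^2
      b <- p[3] * d[3] - cth^2 * sum(p * d)
      cc <- p[3]^2 - cth^2 * sum(p^2)
      if (abs(a) < 1e-14) {
        if (abs(b) > 1e-14) ts <- c(ts, -cc / (2 * b))
      } else if (b^2 - a * cc > 0) {
        sq <- sqrt(b^2 - a * cc)
        ts <- c(ts, (-b - sq) / a, (-b + sq) / a)
      }
    }
    ts <- sort(unique(pmin(pmax(ts, 0), len)))
    mids <- (ts[-1] + ts[-length(ts)]) / 2
    dls <- diff(ts)
    for (j in seq_along(mids)) {
      if (dls[j] <= 1e-13) next
      pm <- p + mids[j] * d
      r <- sqrt(sum(pm^2))
      th <- acos(pm[3] / r) * 180 / pi
      hit <- which(r >= cells$r_lo & r <= cells$r_hi &
                   th >= cells$theta_lo & th <= cells$theta_hi)
      if (length(hit) == 1)
        out[hit] <- out[hit] + dls[j] * w / cells$volume_cm3[hit]
    }
  }
  out
}

#' Air-kerma strength
#'
#' Places the seed at the centre of a vacuum sphere (default 15 cm radius)
#' and scores air kerma with the track-length estimator in a thin transverse
#' ring cell at `distance` (ring-tally equivalent of a small voxel at
#' 10 cm), with the 5 keV cutoff suppressing titanium fluorescence.
#' Returns the air-kerma rate times distance squared, per emitted photon:
#' numerically, keV cm^2/g per history.
#'
#' @param seed A [seed_model()], or `NULL` for a bare point source.
#' @param xs An [xs_library()].
#' @param spectrum A [photon_spectrum()]; defaults to the I-125 five lines.
#' @param histories Number of primary photons (>= 1e4).
#' @param rng_seed Integer seed for reproducibility.
#' @param distance Scoring distance on the transverse axis, cm.
#' @param vacuum_radius Radius of the vacuum sphere, cm.
#' @return List with `sk_per_history`, `rel_err`, `histories`, `distance`.
#' @export
air_kerma_strength <- function(seed, xs, spectrum = i125_spectrum(),
                               histories = 2e6,
                               rng_seed = DEFAULT_RNG_SEED,
                               distance = 10, vacuum_radius = 15) {
  if (histories < 1e4) stop("histories must be at least 1e4")
  tly <- ring_tally(distance, angles = 90, dr_half = 0.05,
                    dtheta_half = 0.5)
  raw <- run_engine(seed, xs, spectrum, histories, tly, vacuum_radius,
                    exterior = "vacuum", score_material = "air",
                    rng_seed = rng_seed,
                    source_mode = if (is.null(seed)) 1L else 0L)
  tg <- tally_result(tly, raw, "vacuum", histories, rng_seed)
  list(sk_per_history = tg$dose_per_history[1] * distance^2,
       rel_err = tg$rel_err[1], histories = histories, distance = distance,
       energy_balance = attr(tg, "energy_balance"))
}

#' Scoring grid used for the published tables
#'
#' Radii 0.5, 0.7 and 1 to 10 cm in 0.5 cm steps.  Radii up to 7 cm carry
#' the full polar grid (10 degree steps, 20 degrees at r = 0.5 cm, over
#' 0-180); larger radii only the transverse cell.
#'
#' @return List of `radii` and per-radius `angles` for [dose_rate_table()].
#' @export
default_scoring_grid <- function() {
  radii <- c(0.5, 0.7, seq(1, 10, by = 0.5))
  f_radii <- c(0.5, 0.7, 1, 1.5, 2, 3, 4, 5, 6, 7)
  angles <- lapply(radii, function(r) {
    if (r == 0.5) seq(10, 170, by = 20)
    else if (r %in% f_radii) seq(0, 180, by = 10)
    else 90
  })
  list(radii = radii, angles = angles)
}

#' Monte Carlo dose-rate table in a phantom
#'
#' Transports seed photons through a spherical phantom (default 15 cm
#' radius, i.e. 30 cm diameter) of water or PMMA and scores collision kerma
#' (= dose at these energies) on ring cells at the requested (r, theta)
#' grid.
#'
#' @param seed A [seed_model()] (or `NULL` for a point source).
#' @param xs An [xs_library()].
#' @param medium Phantom material, `"water"` or `"pmma"`.
#' @param radii,angles Scoring grid; defaults to [default_scoring_grid()].
#' @param spectrum A [photon_spectrum()].
#' @param histories Primary photon count.
#' @param rng_seed Integer seed.
#' @param phantom_radius Phantom sphere radius, cm; all scoring radii must
#'   fit inside.
#' @param score_medium Medium whose mass energy-absorption coefficient
#'   weights the kerma estimator.  The default scores dose to a
#'   water-equivalent detector whatever the phantom material, which is what
#'   the TG-43 chain and the phantom conversion factor
#'   [pmma_to_water_factor()] require; detector energy response is handled
#'   separately in the measurement arm.
#' @return A `tally_grid` data.frame: `r_cm`, `theta_deg`,
#'   `dose_per_history` (keV/g), `rel_err`, `medium`, `histories`.
#' @export
dose_rate_table <- function(seed, xs, medium = c("water", "pmma"),
                            radii = NULL, angles = NULL,
                            spectrum = i125_spectrum(), histories = 5e6,
                            rng_seed = DEFAULT_RNG_SEED,
                            phantom_radius = 15, score_medium = "water") {
  medium <- match.arg(medium)
  if (is.null(radii)) {
    g <- default_scoring_grid()
    radii <- g$radii
    angles <- g$angles
  }
  if (is.null(angles)) angles <- 90
  if (max(radii) >= phantom_radius)
    stop("scoring radius beyond the phantom boundary")
  tly <- ring_tally(radii, angles)
  raw <- run_engine(seed, xs, spectrum, histories, tly, phantom_radius,
                    exterior = medium, score_material = score_medium,
                    rng_seed = rng_seed,
                    source_mode = if (is.null(seed)) 1L else 0L)
  tally_result(tly, raw, medium, histories, rng_seed)
}
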