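#' Parametric seed model
#'
#' Builds the solid model of an encapsulated low-energy seed: a cylindrical
#' radio-opaque marker rod carrying a thin radioactive coating (lateral
#' surface and end faces), inside a welded capsule whose ends are
#' hemispherical shells truncated by the capsule body cylinder.  The seed
#' long axis is z, the origin is the seed centre, and the polar angle
#' \eqn{\theta} is measured from +z, so \eqn{\theta_0 = 90}\eqn{^\circ} is
#' the transverse plane.
#'
#' Named configurations are read from the bundled `seed_models.yaml`:
#' `"gms-bt-125-1"` (default; 0.325 cm silver rod, 0.5 um iodine coating,
#' 0.45 cm titanium capsule, 0.006 cm wall) and `"model-6711"` (0.300 cm
#' rod, 0.005 cm wall) for benchmarking.
#'
#' @param name Named configuration, or `NULL` when building from parts.
#' @param ... Individual dimensions overriding the named configuration
#'   (`marker_length`, `marker_diameter`, `coating_thickness`,
#'   `capsule_length`, `capsule_outer_diameter`, `capsule_wall`,
#'   `end_cap_radius`, all cm) plus `region_materials`/`region_densities`.
#' @param config_file YAML file with seed definitions; defaults to the
#'   bundled file.
#' @return Object of class `seed_model`.
#' @export
seed_model <- function(name = "gms-bt-125-1", ...,
                       config_file = system.file("extdata",
                                                 "seed_models.yaml",
                                                 package = "brachychar")) {
  defs <- yaml::read_yaml(config_file)
  if (!is.null(name)) {
    if (is.null(defs[[name]])) stop("unknown seed model: ", name)
    pars <- defs[[name]]
  } else {
    pars <- list()
  }
  dots <- list(...)
  pars[names(dots)] <- dots
  req <- c("marker_length", "marker_diameter", "coating_thickness",
           "capsule_length", "capsule_outer_diameter", "capsule_wall",
           "end_cap_radius")
  missing <- setdiff(req, names(pars))
  if (length(missing)) stop("missing fields: ", paste(missing, collapse = ", "))
  for (f in req) {
    if (!is.numeric(pars[[f]]) || pars[[f]] <= 0)
      stop("field ", f, " must be a positive length (cm)")
  }
  if (pars$coating_thickness >= pars$marker_diameter / 10)
    stop("coating_thickness must be small compared to the marker diameter")
  if (pars$marker_length + 2 * pars$end_cap_radius >
      pars$capsule_length + 1e-9)
    stop("marker does not fit inside the capsule interior")
  if (pars$capsule_wall >= pars$capsule_outer_diameter / 2)
    stop("capsule wall thicker than its radius")
  pars$name <- if (is.null(name)) "custom" else name
  structure(pars, class = "seed_model")
}

#' @export
print.seed_model <- function(x, ...) {
  cat(sprintf("<seed_model> %s\n", x$name))
  cat(sprintf("  marker: %.3f cm x %.3f cm diameter (%s)\n",
              x$marker_length, x$marker_diameter,
              x$region_materials$marker))
  cat(sprintf("  coating: %.1f um\n", x$coating_thickness * 1e4))
  cat(sprintf("  capsule: %.3f cm x %.3f cm od, wall %.3f cm (%s)\n",
              x$capsule_length, x$capsule_outer_diameter, x$capsule_wall,
              x$region_materials$capsule_wall))
  invisible(x)
}

# numeric parameter vector handed to the C++ geometry
seed_geom_vector <- function(seed) {
  stopifnot(inherits(seed, "seed_model"))
  c(seed$marker_length, seed$marker_diameter, seed$coating_thickness,
    seed$capsule_length, seed$capsule_outer_diameter, seed$capsule_wall,
    seed$end_cap_radius)
}

#' Classify points by seed region
#'
#' The five regions (`marker`, `coating`, `capsule_wall`, `capsule_gap`,
#' `exterior`) partition space: every point belongs to exactly one.
#'
#' @param seed A [seed_model()].
#' @param points Numeric vector of length 3 or an n x 3 matrix (cm).
#' @return Character vector of region names.
#' @export
region_at <- function(seed, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  idx <- cpp_region_at(seed_geom_vector(seed), points)
  REGION_NAMES[idx + 1L]
}

#' Ray distance to the next region boundary
#'
#' Marches a ray from `origin` along `direction` and returns the distance to
#' the first surface where the region changes, together with the region
#' entered.  Rays that leave every modelled surface (or start outside and
#' miss the capsule, with no phantom) report an infinite distance.
#'
#' @param seed A [seed_model()].
#' @param origin Length-3 numeric, cm.
#' @param direction Length-3 numeric; normalized internally, zero length is
#'   an error.
#' @param phantom_radius Radius of the surrounding phantom sphere, or `Inf`
#'   for none.
#' @return List with `distance` (cm), `region` (at the origin) and
#'   `next_region` (entered at the boundary; `"escaped"` past the phantom).
#' @export
distance_to_boundary <- function(seed, origin, direction,
                                 phantom_radius = Inf) {
  n <- sqrt(sum(direction^2))
  if (!is.finite(n) || n < 1e-12) stop("zero-length direction")
  res <- cpp_distance_to_boundary(seed_geom_vector(seed), origin,
                                  direction / n,
                                  if (is.finite(phantom_radius))
                                    phantom_radius else -1)
  list(distance = if (res$distance >= 1e29) Inf else res$distance,
       region = REGION_NAMES[res$region + 1L],
       next_region = if (res$next_region < 0) "escaped"
                     else REGION_NAMES[res$next_region + 1L])
}

#' Analytic region volumes of the default solid model
#'
#' Closed-form volumes (cylinder plus truncated spherical caps) used to
#' validate the ray-traced geometry.
#'
#' @param seed A [seed_model()].
#' @param region One of `"marker"`, `"capsule_wall"`, `"capsule_interior"`.
#' @return Volume in cm^3.
#' @export
seed_region_volume <- function(seed, region = c("marker", "capsule_wall",
                                                "capsule_interior")) {
  region <- match.arg(region)
  rmark <- seed$marker_diameter / 2
  rout <- seed$capsule_outer_diameter / 2
  rin <- rout - seed$capsule_wall
  Rout <- seed$end_cap_radius
  Rin <- Rout - seed$capsule_wall
  zc <- seed$capsule_length / 2 - Rout
  # solid of revolution: cylinder radius rc for |z| <= zc, closed by a
  # sphere of radius R centred at z = +-zc, truncated by the cylinder
  solid <- function(rc, R) {
    u0 <- sqrt(max(0, R^2 - rc^2))   # cap reaches the cylinder here
    cap <- pi * rc^2 * u0 + pi * (R^2 * (R - u0) - (R^3 - u0^3) / 3)
    pi * rc^2 * (2 * zc) + 2 * cap
  }
  switch(region,
    marker = pi * rmark^2 * seed$marker_length,
    capsule_interior = solid(rin, Rin),
    capsule_wall = solid(rout, Rout) - solid(rin, Rin))
}
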