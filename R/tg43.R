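# TG-43 quantities: geometry function, dose rate constant, radial dose
# function g(r), 2-D anisotropy function F(r,theta), phantom conversion
# factors, and dose reconstruction from a finished dataset.

#' Line-source geometry function
#'
#' \eqn{G(r,\theta) = \beta / (L r \sin\theta)} with \eqn{\beta} the angle
#' subtended by the active length L at the field point.  On the long axis
#' (\eqn{\theta} = 0 or 180) the standard line-source limit
#' \eqn{1/(r^2 - L^2/4)} is used; with L = 0 the point-source inverse
#' square \eqn{1/r^2} is returned.
#'
#' @param r Radial distance, cm (> 0).
#' @param theta_deg Polar angle from the seed long axis, degrees (0-180).
#' @param L Active length, cm.
#' @return Geometry function value(s), cm^-2.
#' @export
geometry_function <- function(r, theta_deg, L) {
  stopifnot(L >= 0)
  n <- max(length(r), length(theta_deg))
  r <- rep_len(r, n)
  theta_deg <- rep_len(theta_deg, n)
  if (any(r <= 0)) stop("r must be positive")
  if (any(theta_deg < 0 | theta_deg > 180)) stop("theta must be in [0, 180]")
  if (L == 0) return(1 / r^2)
  th <- theta_deg * pi / 180
  on_axis <- sin(th) < 1e-9
  if (any(on_axis & r <= L / 2))
    stop("field point on the long axis inside the source extent")
  z <- r * cos(th)
  s <- r * sin(th)
  # angle at the field point subtended by the segment z in [-L/2, L/2]
  beta <- atan2(s, z - L / 2) - atan2(s, z + L / 2)
  g <- ifelse(on_axis, 1 / (r^2 - L^2 / 4), beta / (L * r * sin(th)))
  g
}

#' Dose rate constant
#'
#' \eqn{\Lambda = \dot D(r_0,\theta_0) / S_K} with the reference point at
#' 1 cm on the transverse axis.  Both inputs are per emitted photon from
#' consistent runs, so the emission normalization cancels.  With the dose
#' rate in keV/g per history and the air-kerma strength in keV cm^2/g per
#' history the ratio is numerically in cGy h^-1 U^-1
#' (U = uGy m^2 h^-1 = 1e-2 Gy cm^2 h^-1 and 1 cGy = 1e-2 Gy, so the energy
#' and time units cancel).
#'
#' @param dose_rate_at_ref Dose rate at (1 cm, 90 deg) per history.
#' @param sk Air-kerma strength per history (same emission normalization).
#' @return Dose rate constant in cGy h^-1 U^-1.
#' @export
dose_rate_constant <- function(dose_rate_at_ref, sk) {
  if (!is.numeric(sk) || sk <= 0) stop("air-kerma strength must be positive")
  dose_rate_at_ref / sk
}

#' Consensus dose rate constant
#'
#' The recommended dose rate constant is the arithmetic mean of the Monte
#' Carlo and the experimental determinations.
#'
#' @param lambda_mc,lambda_exp Positive dose rate constants.
#' @return Their arithmetic mean.
#' @export
average_dose_rate_constant <- function(lambda_mc, lambda_exp) {
  stopifnot(lambda_mc > 0, lambda_exp > 0)
  (lambda_mc + lambda_exp) / 2
}

#' Radial dose function from a tally grid
#'
#' \eqn{g(r) = [D(r,\theta_0)/D(r_0,\theta_0)]\,
#' [G(r_0,\theta_0)/G(r,\theta_0)]} on the transverse axis, normalized to
#' exactly 1 at \eqn{r_0} = 1 cm.
#'
#' @param tally A `tally_grid` from [dose_rate_table()] containing
#'   transverse (theta = 90) cells including r = 1 cm.
#' @param L Active length for the geometry function, cm.
#' @param r0 Reference radius, cm.
#' @return data.frame `r_cm`, `g`, `rel_err` (MC error of the ratio), with
#'   attribute `L`.
#' @export
radial_dose_function <- function(tally, L, r0 = 1) {
  tr <- tally[abs(tally$theta_deg - 90) < 1e-6, ]
  i0 <- which(abs(tr$r_cm - r0) < 1e-9)
  if (length(i0) != 1) stop("tally has no transverse cell at r0 = ", r0)
  d0 <- tr$dose_per_history[i0]
  g <- (tr$dose_per_history / d0) *
    (geometry_function(r0, 90, L) / geometry_function(tr$r_cm, 90, L))
  rel <- sqrt(tr$rel_err^2 + tr$rel_err[i0]^2)
  rel[i0] <- 0
  g[i0] <- 1
  out <- data.frame(r_cm = tr$r_cm, g = g, rel_err = rel)
  attr(out, "L") <- L
  out[order(out$r_cm), ]
}

#' Fifth-order polynomial fit of g(r)
#'
#' Unweighted least squares of \eqn{g(r) = a_0 + a_1 r + \dots + a_5 r^5}.
#'
#' @param g_table data.frame with `r_cm` and `g` (>= 7 radii).
#' @return List with `coefficients` (a0..a5), `residuals`, `max_residual`.
#' @export
fit_radial_poly <- function(g_table) {
  r <- g_table$r_cm
  g <- g_table$g
  if (length(r) < 7) stop("need at least 7 radii for a quintic fit")
  X <- outer(r, 0:5, `^`)
  fit <- lm.fit(X, g)
  if (fit$rank < 6) stop("rank-deficient design: radii are degenerate")
  cf <- setNames(fit$coefficients, paste0("a", 0:5))
  list(coefficients = cf, residuals = fit$residuals,
       max_residual = max(abs(fit$residuals)))
}

#' Evaluate radial-dose-function polynomial coefficients
#'
#' @param coefficients Numeric a0..a5.
#' @param r Radii, cm.
#' @return Polynomial values.
#' @export
eval_radial_poly <- function(coefficients, r) {
  drop(outer(r, 0:5, `^`) %*% as.numeric(coefficients))
}

#' 2-D anisotropy function from a tally grid
#'
#' \eqn{F(r,\theta) = [D(r,\theta)/D(r,\theta_0)]\,
#' [G(r,\theta_0)/G(r,\theta)]}, normalized to exactly 1 at 90 degrees at
#' every radius.  Because the seed is mirror-symmetric, values at
#' \eqn{\theta} and \eqn{180-\theta} are averaged onto the 0-90 degree
#' quadrant.
#'
#' @param tally A `tally_grid` with a 90-degree cell at every radius to use.
#' @param L Active length, cm.
#' @param radii Radii to extract; defaults to all radii having more than
#'   one angle.
#' @return data.frame `r_cm`, `theta_deg` (0-90), `F`, `rel_err`.
#' @export
anisotropy_function <- function(tally, L, radii = NULL) {
  if (is.null(radii)) {
    tab <- table(tally$r_cm)
    radii <- as.numeric(names(tab))[tab > 1]
  }
  out <- NULL
  for (r in radii) {
    d <- tally[abs(tally$r_cm - r) < 1e-9, ]
    i90 <- which(abs(d$theta_deg - 90) < 1e-6)
    if (length(i90) != 1) stop("no 90-degree cell at r = ", r)
    Fv <- (d$dose_per_history / d$dose_per_history[i90]) *
      (geometry_function(r, 90, L) / geometry_function(r, d$theta_deg, L))
    rel <- sqrt(d$rel_err^2 + d$rel_err[i90]^2)
    th_f <- pmin(d$theta_deg, 180 - d$theta_deg)
    agg <- lapply(split(seq_along(Fv), th_f), function(ix)
      c(mean(Fv[ix]), sqrt(sum(rel[ix]^2)) / length(ix)))
    th_u <- as.numeric(names(agg))
    vals <- t(vapply(agg, identity, numeric(2)))
    Fq <- vals[, 1]
    rq <- vals[, 2]
    Fq[abs(th_u - 90) < 1e-6] <- 1
    rq[abs(th_u - 90) < 1e-6] <- 0
    out <- rbind(out, data.frame(r_cm = r, theta_deg = th_u, F = Fq,
                                 rel_err = rq))
  }
  rownames(out) <- NULL
  attr(out, "L") <- L
  out
}

#' Quintic fit of an anisotropy-function column
#'
#' Least-squares fit of \eqn{F(\theta) = p_0 + p_1\theta + \dots +
#' p_5\theta^5} with \eqn{\theta} in radians, so that \eqn{p_0}
#' approximates F(r, 0).  Missing angles are skipped.
#'
#' @param theta_deg Angles in degrees (>= 7 after removing NA).
#' @param F Anisotropy values.
#' @return Named coefficients p0..p5.
#' @export
fit_anisotropy_poly <- function(theta_deg, F) {
  keep <- is.finite(theta_deg) & is.finite(F)
  th <- theta_deg[keep] * pi / 180
  Fv <- F[keep]
  if (length(th) < 7) stop("need at least 7 angles for a quintic fit")
  X <- outer(th, 0:5, `^`)
  fit <- lm.fit(X, Fv)
  if (fit$rank < 6) stop("rank-deficient design: angles are degenerate")
  setNames(fit$coefficients, paste0("p", 0:5))
}

#' PMMA-to-water phantom conversion factors
#'
#' Element-wise ratio \eqn{P_{phant}(r,\theta) = D^{water}(r,\theta) /
#' D^{PMMA}(r,\theta)} of two tally grids on matched (r, theta) grids, with
#' the relative MC errors combined in quadrature.
#'
#' @param tally_water,tally_pmma Matched `tally_grid` objects.
#' @return data.frame `r_cm`, `theta_deg`, `p_phant`, `rel_err`.
#' @export
pmma_to_water_factor <- function(tally_water, tally_pmma) {
  kw <- paste(tally_water$r_cm, tally_water$theta_deg)
  kp <- paste(tally_pmma$r_cm, tally_pmma$theta_deg)
  if (nrow(tally_water) != nrow(tally_pmma) || !all(kw == kp))
    stop("tally grids do not match")
  data.frame(r_cm = tally_water$r_cm, theta_deg = tally_water$theta_deg,
             p_phant = tally_water$dose_per_history /
               tally_pmma$dose_per_history,
             rel_err = sqrt(tally_water$rel_err^2 + tally_pmma$rel_err^2))
}

#' Assemble a TG-43 dataset
#'
#' Bundles the derived quantities with their normalization invariants
#' enforced: \eqn{g(r_0) = 1}, \eqn{F(r, 90) = 1}, all values positive.
#'
#' @param lambda Dose rate constant, cGy h^-1 U^-1.
#' @param L Active length, cm.
#' @param g_table data.frame `r_cm`, `g` (from [radial_dose_function()]).
#' @param g_fit Optional coefficients a0..a5.
#' @param f_table data.frame `r_cm`, `theta_deg`, `F`.
#' @param f_fits Optional data.frame of per-radius coefficients p0..p5.
#' @param p_phant Optional conversion-factor table.
#' @param provenance Optional list (histories, seeds, medium, ...).
#' @return Object of class `tg43_dataset`.
#' @export
tg43_dataset <- function(lambda, L, g_table, f_table, g_fit = NULL,
                         f_fits = NULL, p_phant = NULL, provenance = list()) {
  stopifnot(lambda > 0, L > 0)
  i0 <- which(abs(g_table$r_cm - 1) < 1e-9)
  if (length(i0) != 1 || abs(g_table$g[i0] - 1) > 1e-9)
    stop("g table must be normalized to 1 at r0 = 1 cm")
  f90 <- f_table$F[abs(f_table$theta_deg - 90) < 1e-6]
  if (any(abs(f90 - 1) > 1e-9)) stop("F must be 1 at 90 degrees")
  if (any(f_table$F <= 0, na.rm = TRUE)) stop("F values must be positive")
  structure(list(lambda = lambda, L = L, r0 = 1, theta0 = 90,
                 g_table = g_table, g_fit = g_fit, f_table = f_table,
                 f_fits = f_fits, p_phant = p_phant,
                 provenance = provenance),
            class = "tg43_dataset")
}

#' @export
print.tg43_dataset <- function(x, ...) {
  cat("<tg43_dataset>\n")
  cat(sprintf("  dose rate constant: %.4f cGy/h/U (L = %.3f cm)\n",
              x$lambda, x$L))
  cat(sprintf("  g(r): %d radii [%g, %g] cm%s\n", nrow(x$g_table),
              min(x$g_table$r_cm), max(x$g_table$r_cm),
              if (!is.null(x$g_fit)) ", quintic fit attached" else ""))
  cat(sprintf("  F(r,theta): %d radii\n", length(unique(x$f_table$r_cm))))
  invisible(x)
}

#' @export
summary.tg43_dataset <- function(object, ...) {
  print(object)
  if (!is.null(object$g_fit)) {
    cat("  g fit coefficients:\n")
    print(round(object$g_fit, 6))
  }
  invisible(object)
}

#' Reconstruct the dose rate from a TG-43 dataset
#'
#' \eqn{\dot D(r,\theta) = S_K \Lambda [G(r,\theta)/G(r_0,\theta_0)]
#' g(r) F(r,\theta)}.  g(r) uses the quintic fit when present, otherwise
#' log-linear interpolation of the table; F uses bilinear interpolation in
#' (r, theta) on the folded 0-90 degree quadrant.
#'
#' @param ds A [tg43_dataset()].
#' @param sk Air-kerma strength in U.
#' @param r Radial distance, cm.
#' @param theta_deg Polar angle, degrees.
#' @param allow_extrapolation Clamp to the table range instead of erroring.
#' @return Dose rate in cGy/h.
#' @export
reconstruct_dose_rate <- function(ds, sk, r, theta_deg,
                                  allow_extrapolation = FALSE) {
  stopifnot(inherits(ds, "tg43_dataset"))
  n <- max(length(r), length(theta_deg))
  r <- rep_len(r, n)
  theta_deg <- rep_len(theta_deg, n)
  rr <- range(ds$g_table$r_cm)
  if (!allow_extrapolation && (any(r < rr[1] - 1e-9) || any(r > rr[2] + 1e-9)))
    stop("r outside the tabulated range [", rr[1], ", ", rr[2], "] cm")
  rc <- pmin(pmax(r, rr[1]), rr[2])
  gv <- if (!is.null(ds$g_fit)) eval_radial_poly(ds$g_fit, rc)
        else exp(approx(ds$g_table$r_cm, log(ds$g_table$g), xout = rc,
                        rule = 2)$y)
  Fv <- interp_f_table(ds$f_table, rc, theta_deg)
  G <- geometry_function(r, theta_deg, ds$L)
  G0 <- geometry_function(ds$r0, ds$theta0, ds$L)
  sk * ds$lambda * (G / G0) * gv * Fv
}

# bilinear interpolation of the folded anisotropy table; clamped at edges
interp_f_table <- function(f_table, r, theta_deg) {
  th <- pmin(theta_deg, 180 - theta_deg)
  radii <- sort(unique(f_table$r_cm))
  out <- numeric(length(r))
  for (i in seq_along(r)) {
    if (length(radii) == 1) {
      out[i] <- interp_f_column(f_table, radii, th[i])
      next
    }
    rq <- min(max(r[i], radii[1]), radii[length(radii)])
    j <- findInterval(rq, radii, all.inside = TRUE)
    r1 <- radii[j]; r2 <- radii[j + 1]
    w <- if (r2 > r1) (rq - r1) / (r2 - r1) else 0
    f1 <- interp_f_column(f_table, r1, th[i])
    f2 <- interp_f_column(f_table, r2, th[i])
    out[i] <- (1 - w) * f1 + w * f2
  }
  out
}

interp_f_column <- function(f_table, r, th) {
  d <- f_table[abs(f_table$r_cm - r) < 1e-9 & is.finite(f_table$F), ]
  if (nrow(d) == 1) return(d$F)
  d <- d[order(d$theta_deg), ]
  approx(d$theta_deg, d$F, xout = min(max(th, min(d$theta_deg)),
                                      max(d$theta_deg)), rule = 2)$y
}

#' Write / read a TG-43 dataset as a directory of CSV files
#'
#' Serializes `lambda.csv`, `g.csv`, `g_fit.csv`, `F.csv`, `F_fit.csv`,
#' `pphant.csv` (when present) plus `metadata.json`; the reader validates
#' the normalization invariants.
#'
#' @param ds A [tg43_dataset()].
#' @param dir Output directory (created if needed).
#' @return `write_tg43_dataset` the directory, invisibly;
#'   `read_tg43_dataset` the dataset.
#' @export
write_tg43_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(lambda = ds$lambda, L = ds$L),
            file.path(dir, "lambda.csv"), row.names = FALSE)
  write.csv(ds$g_table, file.path(dir, "g.csv"), row.names = FALSE)
  if (!is.null(ds$g_fit))
    write.csv(as.data.frame(t(ds$g_fit)), file.path(dir, "g_fit.csv"),
              row.names = FALSE)
  write.csv(ds$f_table, file.path(dir, "F.csv"), row.names = FALSE)
  if (!is.null(ds$f_fits))
    write.csv(ds$f_fits, file.path(dir, "F_fit.csv"), row.names = FALSE)
  if (!is.null(ds$p_phant))
    write.csv(ds$p_phant, file.path(dir, "pphant.csv"), row.names = FALSE)
  jsonlite::write_json(ds$provenance, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_tg43_dataset
#' @export
read_tg43_dataset <- function(dir) {
  lam <- read.csv(file.path(dir, "lambda.csv"))
  g <- read.csv(file.path(dir, "g.csv"))
  f <- read.csv(file.path(dir, "F.csv"))
  gf <- if (file.exists(file.path(dir, "g_fit.csv")))
    unlist(read.csv(file.path(dir, "g_fit.csv"))[1, ]) else NULL
  ff <- if (file.exists(file.path(dir, "F_fit.csv")))
    read.csv(file.path(dir, "F_fit.csv")) else NULL
  pp <- if (file.exists(file.path(dir, "pphant.csv")))
    read.csv(file.path(dir, "pphant.csv")) else NULL
  prov <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  tg43_dataset(lam$lambda, lam$L, g, f, g_fit = gf, f_fits = ff,
               p_phant = pp, provenance = as.list(prov))
}
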