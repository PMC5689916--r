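# Type A/B uncertainty bookkeeping: named component budgets combined in
# quadrature (no covariance), as is standard for seed dosimetry reports.

#' Uncertainty budget
#'
#' @param component Component names.
#' @param type `"A"` (statistical) or `"B"` (systematic), per component.
#' @param value_pct Relative standard uncertainty in percent (>= 0).
#' @return Object of class `uncertainty_budget` (data.frame) with the
#'   root-sum-square total as attribute `total_pct`.
#' @export
uncertainty_budget <- function(component, type, value_pct) {
  stopifnot(length(component) == length(type),
            length(component) == length(value_pct))
  if (any(value_pct < 0)) stop("uncertainty components must be >= 0")
  if (!all(type %in% c("A", "B"))) stop("type must be 'A' or 'B'")
  out <- data.frame(component = component, type = type,
                    value_pct = value_pct)
  attr(out, "total_pct") <- rss_total(value_pct)
  class(out) <- c("uncertainty_budget", class(out))
  out
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  cat("<uncertainty_budget>\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-32s %s %5.1f %%\n", x$component[i], x$type[i],
                x$value_pct[i]))
  cat(sprintf("  %-32s   %5.1f %%\n", "total (RSS)",
              round_half_up(attr(x, "total_pct"), 1)))
  invisible(x)
}

# half-up decimal rounding (the convention of the printed budget tables)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Root-sum-square total of uncertainty components
#'
#' \eqn{\sqrt{\sum u_i^2}}.  Full precision is returned; use `digits` to
#' reproduce the one-decimal presentation of budget tables (half-up).
#'
#' @param components_pct Component values in percent (>= 0).
#' @param digits Optional decimal rounding (half-up).
#' @return Total in percent.
#' @export
rss_total <- function(components_pct, digits = NULL) {
  if (any(components_pct < 0)) stop("negative uncertainty component")
  tot <- sqrt(sum(components_pct^2))
  if (!is.null(digits)) tot <- round_half_up(tot, digits)
  tot
}

#' Combined uncertainty of the dose rate constant
#'
#' \eqn{\%u_\Lambda = \sqrt{\%u_{D(r_0,\theta_0)}^2 + \%u_{S_K}^2}}.
#'
#' @param u_dose_pct,u_sk_pct Relative uncertainties in percent (>= 0).
#' @return Combined relative uncertainty in percent.
#' @export
lambda_uncertainty <- function(u_dose_pct, u_sk_pct) {
  if (u_dose_pct < 0 || u_sk_pct < 0) stop("negative uncertainty component")
  sqrt(u_dose_pct^2 + u_sk_pct^2)
}

#' Per-cell Monte Carlo statistical errors
#'
#' Relative standard errors of a tally grid, in percent.  Along the
#' transverse axis these grow with distance for a fixed history budget.
#'
#' @param tally A `tally_grid`.
#' @return data.frame `r_cm`, `theta_deg`, `rel_err_pct`.
#' @export
mc_statistical_errors <- function(tally) {
  if (is.null(tally$histories) || tally$histories[1] <= 0)
    stop("tally has no histories")
  data.frame(r_cm = tally$r_cm, theta_deg = tally$theta_deg,
             rel_err_pct = 100 * tally$rel_err)
}

#' Published measurement uncertainty budget
#'
#' Components associated with the TLD-measured dose rate constant: seed
#' strength 3.0, TLD source position 3.5, TLD dose calibration 2.6,
#' PMMA-to-water conversion 3.0 (all Type B) and repetitive measurements
#' 4.5 (Type A); RSS total 7.6%.
#'
#' @return An [uncertainty_budget()].
#' @export
measurement_budget <- function() {
  uncertainty_budget(
    c("Seed strength", "TLD source position", "TLD dose calibration",
      "PMMA-to-water conversion", "Repetitive measurements"),
    c("B", "B", "B", "B", "A"),
    c(3.0, 3.5, 2.6, 3.0, 4.5))
}

#' Published Monte Carlo uncertainty budget
#'
#' Components associated with the simulated dose rate constant: MC
#' statistics 3.2 and dose deposition 0.5 (Type A); seed/TLD positioning
#' 3.5, cross-sections 1.5, seed geometry 2.0 and source spectrum 0.2
#' (Type B); RSS total 5.4%.
#'
#' @return An [uncertainty_budget()].
#' @export
mc_budget <- function() {
  uncertainty_budget(
    c("MC statistics", "Seed/TLD positioning", "Cross-sections",
      "Seed geometry", "Source spectrum", "Dose deposition"),
    c("A", "B", "B", "B", "B", "A"),
    c(3.2, 3.5, 1.5, 2.0, 0.2, 0.5))
}

#' Read or write a budget as CSV
#'
#' CSV mirrors the printed table layout: columns `component`, `type`,
#' `value_pct`.
#'
#' @param budget An [uncertainty_budget()].
#' @param file CSV path.
#' @return The budget (reader) or the path, invisibly (writer).
#' @export
write_budget_csv <- function(budget, file) {
  write.csv(as.data.frame(budget), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_budget_csv
#' @export
read_budget_csv <- function(file) {
  d <- read.csv(file, stringsAsFactors = FALSE)
  uncertainty_budget(d$component, d$type, d$value_pct)
}
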