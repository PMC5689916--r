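# End-to-end characterization: Monte Carlo arm -> TG-43 extraction ->
# synthetic measurement arm -> budgets -> comparison with published seeds.

#' Characterization run configuration
#'
#' Defaults reproduce the study conditions: the GMS BT-125-1 model, a 30 cm
#' diameter spherical phantom, the published scoring grids, 2e6 histories
#' for the air-kerma run and 5e6 for each dose table, the six published
#' seed strengths and the standard noise magnitudes.
#'
#' @param seed_model_name Named seed configuration.
#' @param histories_sk,histories_table History budgets.
#' @param rng_seed Master RNG seed (sub-seeds are derived from it).
#' @param media Phantom media to simulate (first one is the reference
#'   medium for the dose rate constant).
#' @param radii,angles Scoring grid; defaults to [default_scoring_grid()].
#' @param noise A [noise_model()].
#' @param exposure_h Synthetic campaign exposure, hours.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return List of class `run_config`.
#' @export
characterization_config <- function(seed_model_name = "gms-bt-125-1",
                                    histories_sk = 2e6,
                                    histories_table = 5e6,
                                    rng_seed = DEFAULT_RNG_SEED,
                                    media = c("water", "pmma"),
                                    radii = NULL, angles = NULL,
                                    noise = noise_model(),
                                    exposure_h = 48, out_dir = NULL) {
  if (is.null(radii)) {
    g <- default_scoring_grid()
    radii <- g$radii
    angles <- g$angles
  }
  stopifnot(histories_sk >= 1e4, histories_table >= 1e4,
            all(media %in% c("water", "pmma")))
  structure(list(seed_model_name = seed_model_name,
                 histories_sk = histories_sk,
                 histories_table = histories_table, rng_seed = rng_seed,
                 media = media, radii = radii, angles = angles,
                 noise = noise, exposure_h = exposure_h,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full characterization pipeline
#'
#' Chains: (1) vacuum air-kerma-strength run; (2) dose tables in each
#' phantom medium; (3) TG-43 extraction (dose rate constant, g(r) with
#' quintic fit, F(r, theta) with per-radius fits, PMMA-to-water factors
#' when both media are simulated); (4) one synthetic TLD campaign analysed
#' back to an experimental dose rate constant; (5) the consensus (mean)
#' dose rate constant and uncertainty budgets; (6) comparison against the
#' published comparator seeds.  With `out_dir` set, the dataset and report
#' tables are written as CSV plus a JSON summary.
#'
#' @param config A [characterization_config()].
#' @param xs An [xs_library()] (loaded from the bundled tables if omitted).
#' @return List of class `seed_characterization`.
#' @export
run_characterization <- function(config = characterization_config(),
                                 xs = xs_library()) {
  stopifnot(inherits(config, "run_config"))
  seed <- seed_model(config$seed_model_name)
  L <- seed$marker_length
  set.seed(config$rng_seed)
  sub_seeds <- sample.int(2^31 - 2, 4 + length(config$media))

  sk <- air_kerma_strength(seed, xs, histories = config$histories_sk,
                           rng_seed = sub_seeds[1])

  tallies <- list()
  for (i in seq_along(config$media)) {
    m <- config$media[i]
    tallies[[m]] <- dose_rate_table(seed, xs, medium = m,
                                    radii = config$radii,
                                    angles = config$angles,
                                    histories = config$histories_table,
                                    rng_seed = sub_seeds[1 + i])
  }
  ref_medium <- config$media[1]
  tw <- tallies[[ref_medium]]
  d_ref <- tw$dose_per_history[abs(tw$r_cm - 1) < 1e-9 &
                                 abs(tw$theta_deg - 90) < 1e-6]
  lambda_mc <- dose_rate_constant(d_ref, sk$sk_per_history)

  g_table <- radial_dose_function(tw, L)
  g_fit <- if (nrow(g_table) >= 7) fit_radial_poly(g_table) else NULL
  f_table <- anisotropy_function(tw, L)
  f_fits <- do.call(rbind, lapply(split(f_table, f_table$r_cm), function(d) {
    if (sum(is.finite(d$F)) < 7) return(NULL)
    data.frame(r_cm = d$r_cm[1],
               as.list(fit_anisotropy_poly(d$theta_deg, d$F)))
  }))
  p_phant <- if (all(c("water", "pmma") %in% names(tallies)))
    pmma_to_water_factor(tallies$water, tallies$pmma) else NULL

  ds <- tg43_dataset(lambda_mc, L, g_table, f_table,
                     g_fit = if (!is.null(g_fit)) g_fit$coefficients,
                     f_fits = f_fits, p_phant = p_phant,
                     provenance = list(
                       seed_model = config$seed_model_name,
                       histories_sk = config$histories_sk,
                       histories_table = config$histories_table,
                       rng_seed = config$rng_seed,
                       media = config$media))

  # synthetic measurement arm (skipped if no conversion surface available)
  experiment <- NULL
  lambda_exp <- NA_real_
  p_for_campaign <- if (!is.null(p_phant)) p_phant else
    reference_dataset()$p_phant
  truth <- ds
  truth$p_phant <- p_for_campaign
  strengths <- published_seed_strengths()
  rs1 <- generate_synthetic_readings(truth, phantom_layout("I"), strengths,
                                     noise = config$noise,
                                     exposure_h = config$exposure_h,
                                     rng_seed = sub_seeds[2 +
                                       length(config$media)])
  rates1 <- readings_to_dose_rates(rs1)
  rs2 <- generate_synthetic_readings(truth, phantom_layout("II"), strengths,
                                     noise = config$noise,
                                     exposure_h = config$exposure_h,
                                     rng_seed = sub_seeds[3 +
                                       length(config$media)])
  rates2 <- readings_to_dose_rates(rs2)
  experiment <- derive_experimental_parameters(rates1, rates2, rs1$p_phant,
                                               strengths, L = L)
  lambda_exp <- experiment$lambda

  lambda_consensus <- average_dose_rate_constant(lambda_mc, lambda_exp)
  comparison <- compare_to_reference(lambda_consensus)

  res <- structure(list(
    dataset = ds, sk = sk, tallies = tallies,
    lambda_mc = lambda_mc, lambda_exp = lambda_exp,
    lambda_consensus = lambda_consensus,
    experiment = experiment, comparison = comparison,
    budgets = list(measurement = measurement_budget(), mc = mc_budget()),
    config = config), class = "seed_characterization")

  if (!is.null(config$out_dir)) write_characterization(res, config$out_dir)
  res
}

#' @export
print.seed_characterization <- function(x, ...) {
  cat("<seed_characterization>", x$config$seed_model_name, "\n")
  cat(sprintf("  Lambda (MC)        : %.4f cGy/h/U (budget %.1f%%)\n",
              x$lambda_mc, round_half_up(rss_total(x$budgets$mc$value_pct))))
  cat(sprintf("  Lambda (synthetic) : %.4f cGy/h/U (budget %.1f%%)\n",
              x$lambda_exp,
              round_half_up(rss_total(x$budgets$measurement$value_pct))))
  cat(sprintf("  Lambda (consensus) : %.4f cGy/h/U\n", x$lambda_consensus))
  cat("  comparison with published seeds (% difference):\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Percent differences against the published comparator seeds
#'
#' \eqn{100 |\Lambda - \Lambda_{ref}| / \Lambda} for each reference seed,
#' with this dataset's value as denominator.
#'
#' @param lambda Dose rate constant of this dataset.
#' @param reference data.frame with `seed` and `lambda` columns; defaults
#'   to the vendored comparators.
#' @return The reference table with a `pct_difference` column.
#' @export
compare_to_reference <- function(lambda,
                                 reference = published_lambdas()$comparators) {
  reference$pct_difference <- 100 * abs(lambda - reference$lambda) / lambda
  reference
}

write_characterization <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tg43_dataset(res$dataset, file.path(dir, "dataset"))
  for (m in names(res$tallies))
    write.csv(as.data.frame(res$tallies[[m]]),
              file.path(dir, paste0("tally_", m, ".csv")), row.names = FALSE)
  write_budget_csv(res$budgets$measurement,
                   file.path(dir, "budget_measurement.csv"))
  write_budget_csv(res$budgets$mc, file.path(dir, "budget_mc.csv"))
  write.csv(res$comparison, file.path(dir, "comparison.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(
    lambda_mc = res$lambda_mc, lambda_exp = res$lambda_exp,
    lambda_consensus = res$lambda_consensus,
    sk_per_history = res$sk$sk_per_history,
    rng_seed = res$config$rng_seed,
    histories_sk = res$config$histories_sk,
    histories_table = res$config$histories_table),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
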