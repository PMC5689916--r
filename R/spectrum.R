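#' Photon emission spectrum
#'
#' A discrete line spectrum given as energies (keV) and emission
#' probabilities.  Probabilities must sum to one (within 1e-9); they are not
#' renormalized silently.
#'
#' @param energy_kev Line energies in keV.
#' @param probability Emission probabilities, same length.
#' @return Object of class `photon_spectrum` (two-column matrix).
#' @export
photon_spectrum <- function(energy_kev, probability) {
  if (length(energy_kev) == 0) stop("empty spectrum")
  if (length(energy_kev) != length(probability))
    stop("energy and probability lengths differ")
  if (any(probability < 0)) stop("negative emission probability")
  if (abs(sum(probability) - 1) > 1e-9)
    stop("emission probabilities must sum to 1")
  m <- cbind(energy_kev = energy_kev, probability = probability)
  structure(m, class = c("photon_spectrum", class(m)))
}

#' The five-line I-125 spectrum
#'
#' The standard consensus I-125 emission spectrum: 27.2 keV (27.5%),
#' 27.5 keV (51.3%), 31.0 keV (13.7%), 31.7 keV (3.0%) and 35.5 keV (4.5%).
#'
#' @return A [photon_spectrum()].
#' @export
i125_spectrum <- function() {
  photon_spectrum(c(27.2, 27.5, 31.0, 31.7, 35.5),
                  c(0.275, 0.513, 0.137, 0.030, 0.045))
}

#' @export
print.photon_spectrum <- function(x, ...) {
  cat("<photon_spectrum>", nrow(x), "line(s), mean",
      sprintf("%.3f keV\n", sum(x[, 1] * x[, 2]) / sum(x[, 2])))
  invisible(x)
}
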