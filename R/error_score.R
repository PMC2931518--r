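#' Simulated-experiment error model
#'
#' The per-point standard deviation assigned to a reference intensity curve:
#' \deqn{\sigma_q = I_q (q + \alpha)^\beta}
#' with defaults alpha = 0.15 and beta = 0.3. The (q + alpha) scaling makes
#' the model stricter in the mid q-range than the plain I_q^beta rule.
#'
#' @param alpha Nonnegative offset (dimensionless), default 0.15.
#' @param beta Nonnegative exponent (dimensionless), default 0.3.
#' @return An object of class `error_model`.
#' @export
error_model <- function(alpha = 0.15, beta = 0.3) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0)
  structure(list(alpha = alpha, beta = beta), class = "error_model")
}

sigma_values <- function(q, I, model, floor_eps = 1e-12 * max(I, 1e-300)) {
  pmax(I * (q + model$alpha)^model$beta, floor_eps)
}

#' Attach model errors to a curve
#'
#' Fills the sigma column of a curve from the error model,
#' `sigma_q = I_q (q + alpha)^beta`, floored at `1e-12 * max(I)` so that
#' zero intensities never produce a zero standard deviation.
#'
#' @param curve A `saxs_curve` with nonnegative intensities.
#' @param model An [error_model()].
#' @return The curve with its `sigma` column (re)filled.
#' @export
sigma_curve <- function(curve, model = error_model()) {
  stopifnot(inherits(curve, "saxs_curve"), inherits(model, "error_model"))
  if (any(curve$I < 0)) stop("negative intensities; error model requires I >= 0")
  scattering_curve(curve$q, curve$I, sigma_values(curve$q, curve$I, model))
}

check_same_grid <- function(reference, computed) {
  if (!grids_match(reference$q, computed$q))
    stop("curves are on different q grids")
}

#' Error-scaled chi-square curve discrepancy
#'
#' \deqn{S = \frac{1}{Q - 1} \sum_q \left(\frac{I_q - I'_q}{\sigma_q}\right)^2}
#' where I is the reference curve, I' the computed curve, Q the number of
#' q-bins and sigma_q the reference's model error. S = 0 iff the curves are
#' identical; S near 1 means the curves differ by about one model standard
#' deviation per point.
#'
#' @param reference Reference `saxs_curve`; its intensities define sigma.
#' @param computed Computed `saxs_curve` on the same grid.
#' @param model An [error_model()].
#' @return Scalar S.
#' @export
chi2_S <- function(reference, computed, model = error_model()) {
  check_same_grid(reference, computed)
  sig <- sigma_values(reference$q, reference$I, model)
  sum(((reference$I - computed$I) / sig)^2) / (length(reference$q) - 1L)
}

#' Gaussian log-likelihood of a reference curve given a computed curve
#'
#' Each reference intensity is treated as a draw from a Gaussian centered
#' at the computed intensity with the model error of the reference:
#' \deqn{\log P(I | I') = \sum_q \log N(I_q \mid I'_q, \sigma_q)}
#' with the full normalization constant included.
#'
#' @inheritParams chi2_S
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(reference, computed, model = error_model()) {
  check_same_grid(reference, computed)
  sig <- sigma_values(reference$q, reference$I, model)
  sum(stats::dnorm(reference$I, mean = computed$I, sd = sig, log = TRUE))
}

#' Decoy-recognition Z-score
#'
#' Z = (E_native - mean(E)) / sd(E), where the mean and the sample standard
#' deviation run over all conformations of the set (native included) and E
#' is an energy (negative log-posterior). Negative Z means the native
#' structure is favored over the decoys.
#'
#' @param native_energy Scalar energy of the native structure.
#' @param decoy_energies Energies of at least two decoys.
#' @param target Optional identifier stored in the report.
#' @return An object of class `zscore_report`: list with `target`,
#'   `native_energy`, `decoy_energies` and `z`.
#' @export
zscore <- function(native_energy, decoy_energies, target = NA_character_) {
  stopifnot(is.numeric(native_energy), length(native_energy) == 1L,
            is.finite(native_energy))
  if (length(decoy_energies) < 2L) stop("at least two decoy energies required")
  if (any(!is.finite(decoy_energies))) stop("non-finite decoy energies")
  all_e <- c(native_energy, decoy_energies)
  s <- stats::sd(all_e)
  if (s == 0) stop("zero energy spread; Z-score undefined")
  structure(list(target = target, native_energy = native_energy,
                 decoy_energies = as.numeric(decoy_energies),
                 z = (native_energy - mean(all_e)) / s),
            class = "zscore_report")
}

#' @export
print.zscore_report <- function(x, ...) {
  cat(sprintf("Z-score report%s: native E = %.6g, %d decoys, Z = %.4f\n",
              if (is.na(x$target)) "" else paste0(" [", x$target, "]"),
              x$native_energy, length(x$decoy_energies), x$z))
  invisible(x)
}

#' Write a Z-score report as JSON
#'
#' @param report A `zscore_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_zscore_report <- function(report, path) {
  stopifnot(inherits(report, "zscore_report"))
  jsonlite::write_json(
    list(target = report$target, native_energy = report$native_energy,
         decoy_energies = report$decoy_energies, z = report$z),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
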