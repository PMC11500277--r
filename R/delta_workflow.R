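# End-to-end delta-ML experiment on the synthetic surrogate pair: sample
# geometries from the high-level surface, fit a small PIP correction to
# the HL - LL residuals, and measure how much the composed surface
# improves held-out energies and harmonic frequencies.

#' Run the synthetic delta-ML experiment
#'
#' The protocol mirrors the correction-fitting study: `n_data` geometries
#' are sampled from the high-level (HL) surface up to `e_max` above its
#' minimum, split `n_train` / rest with `seed`; a PIP correction of order
#' `delta_order` (208 functions for ethanol at order 2) is fitted to the
#' HL - LL energy residuals on the training half; the corrected surface
#' LL + correction is then scored on the held-out half against HL, next
#' to the uncorrected LL surface.  Harmonic frequencies are compared by
#' optimizing each surface from the HL minimum and taking the MAE over
#' the 3N-6 physical modes.
#'
#' @param spec a [surrogate_spec()].
#' @param n_data total sampled geometries (default 2319).
#' @param n_train training-set size (default 2069, leaving 250 held out).
#' @param delta_order polynomial order of the correction basis.
#' @param seed seed for the split (sampling is seeded by `spec`).
#' @param compare_frequencies also compute the frequency MAEs (adds a few
#'   seconds of Hessian work).
#' @return list with the fitted correction (`fit`), the composed surface
#'   (`composed`), held-out RMSEs `rmse_ll_test` and `rmse_composed_test`
#'   (cm^-1), their ratio `rmse_improvement`, frequency MAEs
#'   `freq_mae_ll` / `freq_mae_composed` (cm^-1, NA unless requested),
#'   and the surrogate `pair`.
#' @export
delta_ml_experiment <- function(spec = surrogate_spec(), n_data = 2319,
                                n_train = 2069, delta_order = 2,
                                seed = spec$seed,
                                compare_frequencies = TRUE) {
  pair <- make_surrogate_pair(spec)
  geoms <- sample_geometries(pair$hl, n = n_data, e_max = spec$e_max,
                             seed = spec$seed + 10L,
                             temperature = spec$temperature)
  hl_data <- build_dataset(pair$hl, geoms, energy_unit = "cm-1",
                           provenance = sprintf("surrogate HL, seed %d",
                                                spec$seed))
  halves <- split_dataset(hl_data, n_train = n_train, seed = seed)
  basis <- build_pip_basis(ethanol_symmetry(), delta_order)
  fit <- fit_delta(pair$ll, basis, halves$train, test = halves$test)
  composed <- compose_delta(pair$ll, fit$model)
  rmse_ll <- rmse_report(pair$ll, halves$test)$rmse_energy
  rmse_comp <- rmse_report(composed, halves$test)$rmse_energy

  fmae_ll <- fmae_comp <- NA_real_
  if (compare_frequencies) {
    start <- optimize_geometry(pair$hl, ethanol_geometry())$geometry
    freqs <- function(surface) {
      sp <- optimize_geometry(surface, start)
      physical_frequencies(normal_modes(
        hessian(surface, sp$geometry),
        atomic_masses(sp$geometry$elements)))
    }
    f_hl <- freqs(pair$hl)
    fmae_ll <- frequency_mae(f_hl, freqs(pair$ll))
    fmae_comp <- frequency_mae(f_hl, freqs(composed))
  }
  list(pair = pair, fit = fit, composed = composed,
       rmse_ll_test = rmse_ll, rmse_composed_test = rmse_comp,
       rmse_improvement = rmse_ll / rmse_comp,
       freq_mae_ll = fmae_ll, freq_mae_composed = fmae_comp,
       n_train = n_train, n_test = n_data - n_train)
}
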