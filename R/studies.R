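#' Power-law parameter recovery study
#'
#' Simulates `n` single-cycle traces from the pure power-law strip
#' ([power_law_tissue()]), runs each through the full analysis pipeline
#' (segmentation, curve building, log-log fit of the lengthening curve) and
#' returns the fitted parameters next to the generating truth. Because the
#' generating model is exactly the fitted model class, `k_hat` and `A_hat`
#' estimate known ground truth; `A` is recovered less accurately than `k`
#' because the intercept of the log-log regression extrapolates to the
#' reference length (and absorbs the hold-averaged step-transient bias),
#' whereas the slope does not.
#'
#' @param n Number of simulated strips.
#' @param amplitude,exponent Generating power-law parameters.
#' @param noise_sd Transducer noise (mN).
#' @param protocol Strain protocol (single cycle by default).
#' @param geometry Strip geometry.
#' @param seed Integer seed; strip `i` uses `seed + i`.
#' @return A tibble with one row per strip: `strip`, `A_true`, `k_true`,
#'   `A_hat`, `k_hat`, `r_squared`, `n_points`, `valid`, and relative errors
#'   `A_rel_err`, `k_rel_err`.
#' @export
recovery_study <- function(n = 100, amplitude = 0.12, exponent = 6,
                           noise_sd = 0.2,
                           protocol = strain_protocol(n_cycles = 1),
                           geometry = strip_geometry(), seed = 1) {
  params <- power_law_tissue(amplitude = amplitude, exponent = exponent,
                             geometry = geometry)
  purrr::map_dfr(seq_len(n), function(i) {
    tr <- simulate_trace(protocol, params, noise_sd = noise_sd,
                         seed = seed + i)
    fit <- tr |>
      segment_steps() |>
      build_cycle_curves() |>
      cycle_curve(1, "lengthen") |>
      fit_power_law()
    tibble::tibble(
      strip = i, A_true = amplitude, k_true = exponent,
      A_hat = fit$A, k_hat = fit$k, r_squared = fit$r_squared,
      n_points = fit$n_points, valid = fit$valid,
      A_rel_err = abs(fit$A - amplitude) / amplitude,
      k_rel_err = abs(fit$k - exponent) / exponent
    )
  })
}

#' Simulate a two-arm stiffness study
#'
#' Emulates the vehicle-versus-cytokine-cocktail design: `n_per_arm` strips
#' per arm, each a pure power-law strip whose stiffening exponent is drawn
#' from a normal distribution around the arm mean (between-strip biological
#' variability), simulated through the stepwise protocol and fitted. The
#' cocktail arm's larger exponent encodes the stiffer, less distensible
#' matrix.
#'
#' @param n_per_arm Strips per arm.
#' @param k_vehicle,k_cocktail Arm-mean stiffening exponents.
#' @param k_sd Between-strip standard deviation of the exponent.
#' @param amplitude Generating amplitude (shared).
#' @param noise_sd Transducer noise (mN).
#' @param protocol Strain protocol (single cycle by default).
#' @param seed Integer seed.
#' @return A tibble of per-strip fits with columns `arm`, `strip`, `k_true`,
#'   `A_hat`, `k_hat`, `r_squared`, `valid`. Feed into [compare_k()].
#' @examples
#' \donttest{
#' fits <- stiffness_study(n_per_arm = 4, seed = 1)
#' compare_k(fits, k_hat, arm)
#' }
#' @export
stiffness_study <- function(n_per_arm = 8, k_vehicle = 6, k_cocktail = 9,
                            k_sd = 1, amplitude = 0.12, noise_sd = 0.2,
                            protocol = strain_protocol(n_cycles = 1),
                            seed = 1) {
  arms <- tibble::tibble(
    arm = rep(c("vehicle", "cocktail"), each = n_per_arm),
    k_mean = rep(c(k_vehicle, k_cocktail), each = n_per_arm)
  )
  draws <- withr::with_seed(seed, list(
    k_true = pmax(1.5, rnorm(nrow(arms), mean = arms$k_mean, sd = k_sd)),
    sub_seed = sample.int(.Machine$integer.max, nrow(arms))
  ))
  k_true <- draws$k_true
  purrr::map_dfr(seq_len(nrow(arms)), function(i) {
    params <- power_law_tissue(amplitude = amplitude, exponent = k_true[i])
    tr <- simulate_trace(protocol, params, noise_sd = noise_sd,
                         seed = draws$sub_seed[i])
    fit <- tr |>
      segment_steps() |>
      build_cycle_curves() |>
      cycle_curve(1, "lengthen") |>
      fit_power_law()
    tibble::tibble(arm = arms$arm[i], strip = i, k_true = k_true[i],
                   A_hat = fit$A, k_hat = fit$k, r_squared = fit$r_squared,
                   valid = fit$valid)
  })
}
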