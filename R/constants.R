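#' Physical constants of the amide 15N spin system
#'
#' Bundles the constants entering the dipolar and chemical-shift-anisotropy
#' (CSA) relaxation mechanisms of a backbone amide 15N nucleus, together
#' with the derived interaction constants used by [forward_rates()].
#'
#' The dipolar constant is \eqn{d = (\mu_0/4\pi)\,\hbar\,\gamma_H\gamma_N /
#' r_{NH}^3} and the CSA constant \eqn{c^2 = (\omega_N\,\Delta\sigma)^2/3}.
#' Defaults are the values conventional for backbone amide model-free
#' analysis: \eqn{r_{NH} = 1.02} Angstrom and \eqn{\Delta\sigma = -160} ppm.
#'
#' @param proton_freq 1H Larmor frequency in MHz.
#' @param rNH N-H bond length in Angstrom (must lie in `[0.9, 1.1]`).
#' @param csa 15N chemical-shift anisotropy in ppm.
#' @param gamma_h,gamma_n gyromagnetic ratios of 1H and 15N in rad s-1 T-1;
#'   `gamma_n` is negative.
#'
#' @return An object of class `"spin_constants"`: a list with the inputs
#'   plus `gamma_ratio` (\eqn{\gamma_H/\gamma_N}, negative), the angular
#'   frequencies `omega_h` and `omega_n` (rad/s, magnitudes), and the
#'   interaction constants `d2` and `c2` (rad2 s-2).
#' @examples
#' sc <- spin_constants(600.13)
#' sc$omega_n / (2 * pi * 1e6)  # 15N frequency, MHz (~60.8 at 600 MHz 1H)
#' @export
spin_constants <- function(proton_freq = 600.13, rNH = 1.02, csa = -160,
                           gamma_h = 2.6752218744e8,
                           gamma_n = -2.7126180436e7) {
  if (!is.numeric(proton_freq) || proton_freq <= 0)
    stop_invalid("'proton_freq' must be a positive frequency in MHz")
  if (rNH < 0.9 || rNH > 1.1)
    stop_invalid("'rNH' must lie in [0.9, 1.1] Angstrom")
  omega_h <- 2 * pi * proton_freq * 1e6
  omega_n <- omega_h * abs(gamma_n / gamma_h)
  hbar <- 1.054571817e-34
  d <- 1e-7 * hbar * gamma_h * abs(gamma_n) / (rNH * 1e-10)^3
  out <- list(proton_freq = proton_freq, rNH = rNH, csa = csa,
              gamma_h = gamma_h, gamma_n = gamma_n,
              gamma_ratio = gamma_h / gamma_n,
              omega_h = omega_h, omega_n = omega_n,
              d2 = d * d, c2 = (omega_n * csa * 1e-6)^2 / 3)
  stopifnot(out$d2 > 0, out$c2 > 0)
  class(out) <- "spin_constants"
  out
}

#' @export
print.spin_constants <- function(x, ...) {
  cat("Amide 15N spin-system constants\n")
  cat(sprintf("  1H  frequency : %.2f MHz\n", x$proton_freq))
  cat(sprintf("  15N frequency : %.2f MHz\n", x$omega_n / (2 * pi * 1e6)))
  cat(sprintf("  rNH %.3f A, CSA %.1f ppm, gammaH/gammaN %.4f\n",
              x$rNH, x$csa, x$gamma_ratio))
  invisible(x)
}
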