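#' Acquisition scheme for synthetic relaxation experiments
#'
#' Describes the measurement conditions under which synthetic decay series
#' and NOE pairs are generated. Defaults reproduce a typical study of a
#' small protein at 600 MHz: an on-resonance 1560 Hz spin lock, R1
#' relaxation delays of 10*, 150, 300, 450, 600*, 700, 900 and 1200 ms and
#' R1rho delays of 10*, 50, 80, 100*, 120, 150, 170 and 190 ms (starred
#' delays acquired in duplicate), 1% Gaussian intensity noise, 303 K.
#'
#' Duplicate delays are emitted as separate noisy observations, not
#' averaged, so downstream fitting sees the full degrees of freedom.
#'
#' @param proton_freq 1H Larmor frequency, MHz.
#' @param nitrogen_freq 15N Larmor frequency, MHz; defaults to the value
#'   implied by the gyromagnetic ratio and must agree with it to 0.5%.
#' @param spinlock_b1 spin-lock field strength, Hz.
#' @param offset resonance offset from the spin-lock carrier, Hz (scalar
#'   applied to all residues or one value per residue; 0 = on resonance).
#' @param r1_delays,r1rho_delays unique relaxation delays in ms.
#' @param duplicate_delays list with elements `r1` and `r1rho` giving the
#'   delays (ms) acquired a second time.
#' @param noise_sigma Gaussian noise sd as a fraction of initial intensity.
#' @param temperature sample temperature, K.
#' @return An object of class `"acquisition_scheme"`.
#' @export
acquisition_scheme <- function(proton_freq = 600.13,
                               nitrogen_freq = NULL,
                               spinlock_b1 = 1560,
                               offset = 0,
                               r1_delays = c(10, 150, 300, 450, 600, 700,
                                             900, 1200),
                               r1rho_delays = c(10, 50, 80, 100, 120, 150,
                                                170, 190),
                               duplicate_delays = list(r1 = c(10, 600),
                                                       r1rho = c(10, 100)),
                               noise_sigma = 0.01,
                               temperature = 303) {
  if (any(r1_delays <= 0) || any(r1rho_delays <= 0))
    stop_invalid("all relaxation delays must be > 0")
  if (noise_sigma < 0) stop_invalid("'noise_sigma' must be >= 0")
  implied <- spin_constants(proton_freq)$omega_n / (2 * pi * 1e6)
  if (is.null(nitrogen_freq)) nitrogen_freq <- implied
  if (abs(nitrogen_freq - implied) / implied > 0.005)
    stop_invalid(sprintf(
      "'nitrogen_freq' (%.2f MHz) inconsistent with 'proton_freq' (implies %.2f MHz)",
      nitrogen_freq, implied))
  out <- list(proton_freq = proton_freq, nitrogen_freq = nitrogen_freq,
              spinlock_b1 = spinlock_b1, offset = offset,
              r1_delays = r1_delays, r1rho_delays = r1rho_delays,
              duplicate_delays = duplicate_delays,
              noise_sigma = noise_sigma, temperature = temperature)
  class(out) <- "acquisition_scheme"
  out
}

# Full delay vector (ms) including duplicate acquisitions.
scheme_delays <- function(scheme, experiment = c("r1", "r1rho")) {
  experiment <- match.arg(experiment)
  base <- if (experiment == "r1") scheme$r1_delays else scheme$r1rho_delays
  dup <- scheme$duplicate_delays[[experiment]] %||% numeric(0)
  sort(c(base, dup))
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat("Acquisition scheme\n")
  cat(sprintf("  1H %.2f MHz / 15N %.2f MHz, %g K\n",
              x$proton_freq, x$nitrogen_freq, x$temperature))
  cat(sprintf("  spin lock %g Hz, offset %s Hz\n", x$spinlock_b1,
              paste(unique(x$offset), collapse = "/")))
  cat("  R1 delays (ms):   ", paste(scheme_delays(x, "r1"), collapse = ", "), "\n")
  cat("  R1rho delays (ms):", paste(scheme_delays(x, "r1rho"), collapse = ", "), "\n")
  cat(sprintf("  intensity noise %.3g x I0\n", x$noise_sigma))
  invisible(x)
}
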