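#' Spin-lock geometry
#'
#' Tilt angle of the effective field in an off-resonance spin-lock
#' experiment: `theta = arctan(omega1 / delta_omega)`, computed from the
#' magnitudes of the spin-lock field strength and the resonance offset and
#' mapped to `(0, pi/2]`; a zero offset (on resonance) gives
#' `theta = pi/2`.
#'
#' @param omega1 spin-lock field strength in Hz (> 0).
#' @param delta_omega resonance offset from the carrier in Hz (vectorized).
#' @return An object of class `"spinlock_geometry"`: list with `omega1`,
#'   `delta_omega` and the tilt angle(s) `theta` in radians.
#' @export
spinlock_geometry <- function(omega1, delta_omega = 0) {
  if (any(omega1 <= 0)) stop_invalid("'omega1' must be > 0 (Hz)")
  theta <- ifelse(delta_omega == 0, pi / 2,
                  atan(abs(omega1) / abs(delta_omega)))
  structure(list(omega1 = omega1, delta_omega = delta_omega, theta = theta),
            class = "spinlock_geometry")
}

#' Transverse relaxation rate from a rotating-frame rate
#'
#' Solves the tilted-frame relation
#' `R1rho = R1 cos^2(theta) + R2eff sin^2(theta)` for the effective
#' transverse rate, i.e. `R2eff = (R1rho - R1 cos^2 theta) / sin^2 theta`.
#' Any conformational-exchange contribution remains folded into `R2eff`;
#' its separation from the exchange-free transverse rate happens in the
#' model-free analysis.
#'
#' @param r1rho rotating-frame relaxation rate, s-1.
#' @param r1 longitudinal relaxation rate, s-1.
#' @param geom a [spinlock_geometry()] object.
#' @return effective transverse rate R2eff in s-1 (vectorized).
#' @examples
#' r2_from_r1rho(9, 1.2, spinlock_geometry(1560, 0))     # 9 on resonance
#' r2_from_r1rho(6, 2, spinlock_geometry(1560, 1560))    # 10 at 45 degrees
#' @export
r2_from_r1rho <- function(r1rho, r1, geom = spinlock_geometry(1560, 0)) {
  th <- geom$theta
  if (any(sin(th) == 0)) stop_invalid("tilt angle must have sin(theta) != 0")
  bad <- r1rho < r1 * cos(th)^2
  if (any(bad))
    stop_invalid("r1rho < r1*cos^2(theta): inconsistent rates ",
                 "(noise or mis-assignment)")
  (r1rho - r1 * cos(th)^2) / sin(th)^2
}

#' Heteronuclear NOE from a saturation intensity pair
#'
#' Steady-state 15N-\{1H\} NOE as the cross-peak intensity ratio of spectra
#' recorded with and without proton saturation, with first-order error
#' propagation of the two intensity noise estimates.
#'
#' @param saturated,unsaturated cross-peak intensities.
#' @param sigmas length-2 numeric: noise sd of the saturated and
#'   unsaturated intensities.
#' @return list with elements `noe` and `noe_error`.
#' @examples
#' hetero_noe(80, 100, c(2, 2))
#' @export
hetero_noe <- function(saturated, unsaturated, sigmas = c(0, 0)) {
  if (any(unsaturated <= 0))
    stop_invalid("'unsaturated' intensity must be > 0")
  noe <- saturated / unsaturated
  err <- sqrt((sigmas[1] / unsaturated)^2 +
                (saturated * sigmas[2] / unsaturated^2)^2)
  list(noe = noe, noe_error = err)
}
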