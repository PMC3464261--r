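#' Construct a decay series
#'
#' The unit of rate fitting: one residue's peak volumes against relaxation
#' delay, with a single noise-level estimate.
#'
#' @param residue_index 1-based residue number.
#' @param delays relaxation delays in seconds (>= 3 values, all > 0).
#' @param volumes peak volumes (arbitrary units), same length as `delays`.
#' @param sigma noise sd of a single volume (same units); `NA` if unknown.
#' @return An object of class `"decay_series"`.
#' @export
decay_series <- function(residue_index, delays, volumes, sigma = NA_real_) {
  if (length(delays) != length(volumes) || length(delays) < 3)
    stop_invalid("'delays' and 'volumes' must have equal length >= 3")
  if (any(delays <= 0)) stop_invalid("all delays must be > 0 (seconds)")
  if (!is.na(sigma) && sigma < 0) stop_invalid("'sigma' must be >= 0")
  structure(list(residue_index = as.integer(residue_index),
                 delays = as.numeric(delays),
                 volumes = as.numeric(volumes),
                 sigma = as.numeric(sigma)),
            class = "decay_series")
}

#' Generate a complete synthetic relaxation dataset
#'
#' Forward-models R1 and R1rho intensity decays and saturated/unsaturated
#' NOE intensity pairs for every residue of a ground-truth profile, then
#' adds Gaussian noise of sd `noise_sigma * I0` to every observation
#' (duplicate delays receive independent draws).
#'
#' The R1rho decay rate for a residue at tilt angle theta is
#' `R1 cos^2(theta) + R2 sin^2(theta)` with R2 from [forward_rates()]
#' (exchange included), so the on-resonance default makes the R1rho decay
#' rate equal to R2.
#'
#' @param truth a `"truth_profile"` from [generate_profile()] (or any data
#'   frame with columns `residue_index`, `s2`, `tau_e`, `rex`).
#' @param tau_m overall rotational correlation time in ns.
#' @param scheme an [acquisition_scheme()].
#' @param seed integer seed.
#' @param i0 noiseless initial intensity of every decay.
#' @param consts a [spin_constants()] object; its field must match the
#'   scheme's `proton_freq`.
#' @return An object of class `"relax_dataset"`: a list with `truth`,
#'   `tau_m`, `scheme`, `decays_r1`, `decays_r1rho` (lists of
#'   [decay_series()] keyed by residue), `noe_pairs` (data frame with
#'   `residue_index`, `saturated`, `unsaturated`, `sigma`), and `seed`.
#' @examples
#' ds <- generate_dataset(generate_profile(10, seed = 1), tau_m = 7.9,
#'                        seed = 2)
#' length(ds$decays_r1)
#' @export
generate_dataset <- function(truth, tau_m = 7.9,
                             scheme = acquisition_scheme(),
                             seed = 1, i0 = 100,
                             consts = spin_constants(scheme$proton_freq)) {
  if (is.null(truth) || nrow(truth) == 0)
    stop_invalid("'truth' must contain at least one residue")
  if (tau_m <= 0) stop_invalid("'tau_m' must be > 0 (ns)")
  rates <- forward_rates(truth$s2, truth$tau_e, truth$rex, tau_m, consts)
  geom <- spinlock_geometry(scheme$spinlock_b1,
                            rep_len(scheme$offset, nrow(truth)))
  r1rho_rate <- rates$r1 * cos(geom$theta)^2 + rates$r2 * sin(geom$theta)^2
  t_r1 <- scheme_delays(scheme, "r1") / 1000
  t_r1rho <- scheme_delays(scheme, "r1rho") / 1000
  sd_abs <- scheme$noise_sigma * i0
  with_seed(seed, {
    mk <- function(res, rate, delays) {
      vols <- i0 * exp(-rate * delays) +
        stats::rnorm(length(delays), sd = sd_abs)
      decay_series(res, delays, vols, sigma = sd_abs)
    }
    decays_r1 <- lapply(seq_len(nrow(truth)), function(i)
      mk(truth$residue_index[i], rates$r1[i], t_r1))
    decays_r1rho <- lapply(seq_len(nrow(truth)), function(i)
      mk(truth$residue_index[i], r1rho_rate[i], t_r1rho))
    names(decays_r1) <- names(decays_r1rho) <- truth$residue_index
    noe_pairs <- data.frame(
      residue_index = truth$residue_index,
      saturated = rates$noe * i0 + stats::rnorm(nrow(truth), sd = sd_abs),
      unsaturated = i0 + stats::rnorm(nrow(truth), sd = sd_abs),
      sigma = sd_abs)
    structure(list(truth = truth, tau_m = tau_m, scheme = scheme,
                   decays_r1 = decays_r1, decays_r1rho = decays_r1rho,
                   noe_pairs = noe_pairs, seed = seed, i0 = i0,
                   consts = consts),
              class = "relax_dataset")
  })
}

#' @export
print.relax_dataset <- function(x, ...) {
  cat(sprintf("Synthetic relaxation dataset: %d residues, tau_m %.2f ns, noise %.3g x I0, seed %d\n",
              nrow(x$truth), x$tau_m, x$scheme$noise_sigma, x$seed))
  invisible(x)
}
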