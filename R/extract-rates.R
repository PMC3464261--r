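#' Extract per-residue relaxation rates from a dataset
#'
#' Runs the rate-extraction stage over a [generate_dataset()] object (or
#' equivalent lists of decay series and NOE pairs): fits every R1 and
#' R1rho decay by [fit_exponential()], converts R1rho to the effective
#' transverse rate with [r2_from_r1rho()] using the scheme's spin-lock
#' geometry, and forms the heteronuclear NOE with propagated errors.
#'
#' @param dataset a `"relax_dataset"`, or a list with elements
#'   `decays_r1`, `decays_r1rho`, `noe_pairs` and `scheme`.
#' @param n_mc Monte-Carlo replicates per decay fit.
#' @param seed integer seed (each residue derives its own sub-seed).
#' @return A data frame of class `"rates_table"` with columns
#'   `residue_index`, `r1`, `r1_err`, `r2`, `r2_err`, `noe`, `noe_err`.
#' @examples
#' ds <- generate_dataset(generate_profile(8, seed = 1), seed = 2)
#' extract_rates(ds, n_mc = 50, seed = 3)
#' @export
extract_rates <- function(dataset, n_mc = 500, seed = 1) {
  residues <- as.integer(names(dataset$decays_r1))
  scheme <- dataset$scheme
  geom <- spinlock_geometry(scheme$spinlock_b1,
                            rep_len(scheme$offset, length(residues)))
  rows <- lapply(seq_along(residues), function(i) {
    f1 <- fit_exponential(dataset$decays_r1[[i]], n_mc = n_mc,
                          seed = seed + 7L * i)
    frho <- fit_exponential(dataset$decays_r1rho[[i]], n_mc = n_mc,
                            seed = seed + 7L * i + 3L)
    gi <- spinlock_geometry(geom$omega1, geom$delta_omega[[i]])
    r2 <- r2_from_r1rho(frho$rate, f1$rate, gi)
    # first-order propagation through the tilt relation
    r2_err <- sqrt((frho$rate_error / sin(gi$theta)^2)^2 +
                     (f1$rate_error * cos(gi$theta)^2 / sin(gi$theta)^2)^2)
    np <- dataset$noe_pairs[dataset$noe_pairs$residue_index == residues[i], ]
    noe <- hetero_noe(np$saturated, np$unsaturated,
                      c(np$sigma, np$sigma))
    data.frame(residue_index = residues[i],
               r1 = f1$rate, r1_err = f1$rate_error,
               r2 = r2, r2_err = r2_err,
               noe = noe$noe, noe_err = noe$noe_error)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("rates_table", "data.frame")
  out
}
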