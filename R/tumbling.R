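#' Select the residue subset for tumbling-time averaging
#'
#' Residues with slow internal motions or conformational exchange bias the
#' apparent tumbling time obtained from the R2/R1 ratio. This selector
#' excludes (i) residues whose heteronuclear NOE falls below `noe_min`
#' (fast internal motions) and (ii) residues whose T1/T2 ratio (equal to
#' R2/R1) deviates from the median of the current subset by more than
#' `n_sd` standard deviations (exchange, overlap). The sd trimming is
#' iterated until the subset is stable, so a tight cluster of
#' rigid-residue ratios is isolated even when the deviants dominate the
#' initial spread.
#'
#' @param rates a `"rates_table"` (see [extract_rates()]) or data frame
#'   with columns `residue_index`, `r1`, `r2`, `noe`.
#' @param tau_estimates per-residue apparent tau_m in ns, as returned by
#'   [estimate_tau_m()] (computed from `rates` when omitted).
#' @param noe_min NOE exclusion threshold (default 0.65).
#' @param n_sd trimming width in standard deviations (default 1.5).
#' @param max_iter maximum trimming rounds.
#' @param consts a [spin_constants()] object.
#' @return An object of class `"tumbling_estimate"`: list with
#'   `per_residue_tau_m` (named, ns), `included` (residue indices used),
#'   `average_tau_m` (ns, mean over included residues), and `excluded`
#'   (data frame of dropped residues with the reason).
#' @export
select_tumbling_subset <- function(rates, tau_estimates = NULL,
                                   noe_min = 0.65, n_sd = 1.5,
                                   max_iter = 10,
                                   consts = spin_constants()) {
  if (is.null(tau_estimates))
    tau_estimates <- estimate_tau_m(rates$r1, rates$r2, consts)
  res <- rates$residue_index
  reason <- rep(NA_character_, length(res))
  keep <- !is.na(tau_estimates)
  reason[!keep] <- "no rigid-rotor solution"
  low_noe <- keep & rates$noe < noe_min
  reason[low_noe] <- "NOE below threshold"
  keep <- keep & !low_noe
  if (sum(keep) < 5)
    stop_invalid("fewer than 5 residues survive selection")
  ratio <- rates$r2 / rates$r1
  for (it in seq_len(max_iter)) {
    med <- stats::median(ratio[keep])
    s <- stats::sd(ratio[keep])
    # stop once the surviving cluster is tight (relative floor guards
    # against whittling an exact cluster on rounding noise)
    if (!is.finite(s) || s <= 1e-8 * abs(med)) break
    drop <- keep & abs(ratio - med) > n_sd * s
    if (!any(drop) || sum(keep & !drop) < 5) break
    reason[drop] <- "T1/T2 outlier"
    keep <- keep & !drop
  }
  per <- tau_estimates[keep]
  names(per) <- res[keep]
  out <- list(per_residue_tau_m = per,
              included = res[keep],
              average_tau_m = mean(per),
              excluded = data.frame(residue_index = res[!keep],
                                    reason = reason[!keep]))
  class(out) <- "tumbling_estimate"
  out
}

#' @export
print.tumbling_estimate <- function(x, ...) {
  cat(sprintf("Tumbling-time estimate: %.3f ns (mean over %d residues, %d excluded)\n",
              x$average_tau_m, length(x$included), nrow(x$excluded)))
  invisible(x)
}
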