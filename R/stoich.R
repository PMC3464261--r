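#' Protein:metal stoichiometry from concentrations
#'
#' Computes the molar protein-to-metal ratio and expresses it as the
#' smallest convincing integer pair `p:q`. The integer form is the
#' smallest denominator `q <= max_q` whose best integer numerator
#' reproduces the ratio within `rel_tol` (default 1%); when no small
#' pair is that close, the overall error-minimizing pair is used. This
#' rounds a ratio of 28.0/21.0 to `4:3` and 116/1.78 to `65:1`.
#'
#' @param protein_conc protein concentration (any unit, e.g. uM).
#' @param metal_conc metal concentration (same unit).
#' @param max_q largest denominator considered (default 10).
#' @param rel_tol relative error accepted for a small-denominator pair.
#' @return list with `ratio` (numeric, protein/metal) and `label`
#'   (string `"p:q"`).
#' @examples
#' stoichiometry_ratio(28.0, 21.0)   # 4:3
#' stoichiometry_ratio(116, 1.78)    # 65:1
#' @export
stoichiometry_ratio <- function(protein_conc, metal_conc, max_q = 10,
                                rel_tol = 0.01) {
  if (protein_conc <= 0 || metal_conc <= 0)
    stop_invalid("concentrations must be > 0")
  ratio <- protein_conc / metal_conc
  best <- NULL
  for (q in seq_len(max_q)) {
    p <- max(1L, round(ratio * q))
    err <- abs(p / q - ratio) / ratio
    if (is.null(best) || err < best$err) best <- list(p = p, q = q,
                                                      err = err)
    if (err <= rel_tol) { best <- list(p = p, q = q, err = err); break }
  }
  g <- gcd_int(best$p, best$q)
  list(ratio = ratio, label = sprintf("%d:%d", best$p / g, best$q / g))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
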