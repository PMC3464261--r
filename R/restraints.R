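#' Classify NOE distance restraints by sequence separation
#'
#' Partitions residue-pair restraints into the four conventional classes:
#' intraresidual (i = j), sequential (|i - j| = 1), short range
#' (1 < |i - j| <= 4) and long range (|i - j| > 4). The classes are
#' disjoint and exhaustive, so the counts always sum to the number of
#' restraints.
#'
#' @param restraints data frame with columns `residue_i`, `residue_j`
#'   (1-based indices); zero rows allowed.
#' @return named integer vector with elements `intra`, `sequential`,
#'   `short`, `long` and attribute `total`.
#' @examples
#' classify_restraints(data.frame(residue_i = c(5, 5, 5, 5),
#'                                residue_j = c(5, 6, 8, 20)))
#' @export
classify_restraints <- function(restraints) {
  if (nrow(restraints) == 0)
    return(structure(c(intra = 0L, sequential = 0L, short = 0L, long = 0L),
                     total = 0L))
  if (any(restraints$residue_i < 1) || any(restraints$residue_j < 1))
    stop_invalid("residue indices must be >= 1")
  sep <- abs(restraints$residue_i - restraints$residue_j)
  out <- c(intra = sum(sep == 0),
           sequential = sum(sep == 1),
           short = sum(sep > 1 & sep <= 4),
           long = sum(sep > 4))
  structure(as.integer(out), names = names(out),
            total = nrow(restraints))
}

#' Generate a random restraint list with given class counts
#'
#' Fixture generator: emits residue-pair records whose sequence-separation
#' classes match the requested counts, in random order.
#'
#' @param counts named vector with `intra`, `sequential`, `short`, `long`.
#' @param n_residues chain length to draw residue indices from.
#' @param seed integer seed.
#' @return data frame with `residue_i`, `residue_j`.
#' @export
generate_restraints <- function(counts = c(intra = 606, sequential = 329,
                                           short = 92, long = 11),
                                n_residues = 114, seed = 1) {
  with_seed(seed, {
    draw <- function(k, sep_min, sep_max) {
      if (k == 0) return(NULL)
      sep <- if (sep_min == sep_max) rep(sep_min, k)
             else sample(sep_min:sep_max, k, replace = TRUE)
      i <- vapply(sep, function(s) sample(seq_len(n_residues - s), 1L),
                  integer(1))
      data.frame(residue_i = i, residue_j = i + sep)
    }
    out <- rbind(draw(counts[["intra"]], 0, 0),
                 draw(counts[["sequential"]], 1, 1),
                 draw(counts[["short"]], 2, 4),
                 draw(counts[["long"]], 5, min(20, n_residues - 1)))
    out <- out[sample(nrow(out)), ]
    rownames(out) <- NULL
    out
  })
}
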