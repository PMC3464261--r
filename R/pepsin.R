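# Pepsin cleavage-site prediction after the ExPASy PeptideCutter
# specificity model for pepsin. The enzyme prefers bulky hydrophobic
# residues (F/L at pH 1.3; additionally W/Y above pH 2) at P1 or P1', and
# cleavage is blocked by proline at P2 or P2' and by H/K/R at P3. The
# positional rule matrix below is vendored data transcribed from the
# documented PeptideCutter model.

PEPSIN_RULES <- list(
  "pepsin_pH1.3" = list(p1_hydrophobic = c("F", "L")),
  "pepsin_pH>2"  = list(p1_hydrophobic = c("F", "L", "W", "Y"))
)

#' Map theoretical pepsin cleavage sites on a sequence
#'
#' Predicts pepsin cleavage positions (cleavage after position `p`, i.e.
#' between `p` and `p + 1`) using the PeptideCutter specificity model.
#' A site requires either the P1 or the P1' residue to be hydrophobic
#' (F/L at pH 1.3, F/L/W/Y above pH 2), with the documented blocking
#' rules: no cleavage with proline at P2 or P2', H/K/R at P3, or arginine
#' at P1 (for the P1'-driven variant). Sites need a full P3-P2' window,
#' so only positions `3 <= p <= n - 2` are eligible.
#'
#' @param sequence one-letter amino-acid string.
#' @param rule_set `"pepsin_pH1.3"` (default) or `"pepsin_pH>2"`.
#' @return An object of class `"cleavage_map"`: list with `sequence`,
#'   `sites` (integer cleavage positions) and `rule_set`.
#' @examples
#' pepsin_sites("MKVFLAWPYHRLLFAEG")$sites
#' @export
pepsin_sites <- function(sequence, rule_set = c("pepsin_pH1.3",
                                                "pepsin_pH>2")) {
  rule_set <- match.arg(rule_set)
  s <- check_sequence(sequence)
  n <- length(s)
  hydro <- PEPSIN_RULES[[rule_set]]$p1_hydrophobic
  sites <- integer(0)
  if (n >= 5) {
    for (p in 3:(n - 2)) {
      common <- s[p - 1] != "P" && !(s[p - 2] %in% c("H", "K", "R")) &&
        s[p + 2] != "P"
      if (!common) next
      by_p1prime <- s[p + 1] %in% hydro && s[p] != "R"
      by_p1 <- s[p] %in% hydro
      if (by_p1prime || by_p1) sites <- c(sites, p)
    }
  }
  structure(list(sequence = sequence, sites = sites, rule_set = rule_set),
            class = "cleavage_map")
}

#' @export
print.cleavage_map <- function(x, ...) {
  cat(sprintf("Pepsin cleavage map (%s): %d site(s) in %d residues\n",
              x$rule_set, length(x$sites), nchar(x$sequence)))
  if (length(x$sites)) cat("  after positions:",
                           paste(x$sites, collapse = ", "), "\n")
  invisible(x)
}

#' Solvent-exposed cleavage sites
#'
#' Filters a cleavage map to the sites whose P1 residue is accessible to
#' solvent, judged by the summed accessible surface area of its backbone
#' amide atoms (N, plus H when hydrogens are included in the SASA run).
#' Sites buried in the protein interior are the ones a compact fold
#' protects from proteolysis.
#'
#' @param structure a [protein_structure()] whose sequence matches the
#'   cleavage map.
#' @param cleavage_map a [pepsin_sites()] result.
#' @param sasa_threshold exposure threshold in Angstrom^2 (a site is
#'   exposed when its P1 amide area reaches this; 0 keeps every site,
#'   `Inf` keeps none).
#' @param sasa optional precomputed [shrake_rupley_sasa()] result.
#' @param ... passed to [shrake_rupley_sasa()].
#' @return integer vector: the exposed subset of `cleavage_map$sites`,
#'   with the per-site areas as the `area` attribute.
#' @export
exposed_cleavage_sites <- function(structure, cleavage_map,
                                   sasa_threshold, sasa = NULL, ...) {
  if (structure_sequence(structure) != cleavage_map$sequence)
    stop_invalid("structure sequence does not match cleavage map")
  if (is.null(sasa))
    sasa <- shrake_rupley_sasa(structure, include_h = TRUE, ...)
  areas <- vapply(cleavage_map$sites, function(p) {
    sel <- sasa$resno == p & sasa$elety %in% c("N", "H", "HN")
    sum(sasa$area[sel])
  }, numeric(1))
  keep <- areas >= sasa_threshold
  structure(cleavage_map$sites[keep], area = areas[keep])
}
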