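# Shrake-Rupley solvent-accessible surface area.
#
# Each atom's accessible sphere (van der Waals radius + probe) is sampled
# with a deterministic Fibonacci point set; a point is accessible when it
# lies outside every neighbouring atom's probe-expanded sphere.

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, CU = 1.40, ZN = 1.39, FE = 1.40)

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom solvent-accessible surface area by deterministic sphere-point
#' sampling. By default only heavy atoms are considered (hydrogens are
#' ignored entirely), mirroring the behaviour of classic SASA programs.
#' An isolated atom's area equals \eqn{4\pi(r + p)^2} up to quadrature
#' error of order `1/n_points`.
#'
#' @param structure a [protein_structure()] (first model used).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points sphere sample points per atom (default 960).
#' @param include_h include hydrogen atoms as spheres.
#' @param radii named van der Waals radius set (Angstrom) by element;
#'   unknown elements fall back to `default_radius` with a warning.
#' @param default_radius fallback radius, Angstrom.
#' @return data frame of class `"sasa_result"`: per-atom rows with
#'   `resno`, `elety`, `elem`, `area` (Angstrom^2), plus attributes
#'   `probe` and `n_points`.
#' @examples
#' helix <- generate_toy_structure(strrep("A", 8), "helix")
#' sr <- shrake_rupley_sasa(helix, n_points = 240)
#' sum(sr$area)
#' @export
shrake_rupley_sasa <- function(structure, probe = 1.4, n_points = 960,
                               include_h = FALSE, radii = VDW_RADII,
                               default_radius = 1.70) {
  m <- structure_model(structure)
  if (!include_h) m <- m[toupper(m$elem) != "H", , drop = FALSE]
  if (!nrow(m)) stop_invalid("no atoms to analyse")
  elem <- toupper(m$elem)
  r <- unname(radii[elem])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(elem[is.na(r)]),
                                         collapse = ", "),
            ": using default radius ", default_radius, " A")
    r[is.na(r)] <- default_radius
  }
  xyz <- as.matrix(m[, c("x", "y", "z")])
  n <- nrow(xyz)
  pts <- fibonacci_sphere(n_points)
  rr <- r + probe
  area <- numeric(n)
  # neighbour lists via a single distance matrix (fixtures are small)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    sph <- pts * rr[i] + matrix(xyz[i, ], n_points, 3, byrow = TRUE)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- (sph[, 1] - xyz[j, 1])^2 + (sph[, 2] - xyz[j, 2])^2 +
        (sph[, 3] - xyz[j, 3])^2
      acc <- acc & dj >= rr[j]^2
    }
    area[i] <- 4 * pi * rr[i]^2 * mean(acc)
  }
  out <- data.frame(resno = m$resno, elety = m$elety, elem = m$elem,
                    area = area)
  attr(out, "probe") <- probe
  attr(out, "n_points") <- n_points
  class(out) <- c("sasa_result", "data.frame")
  out
}
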