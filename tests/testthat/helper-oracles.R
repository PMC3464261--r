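# Independent oracles used across the test files. These are deliberate
# re-derivations (literal formula transcriptions, brute-force searches,
# closed forms) kept separate from the package implementation.

# Literal transcription of the dipolar + CSA relaxation expressions with
# its own constant evaluation; only shares the published physical
# constants with the package.
oracle_rates <- function(s2, te_ps, rex, tm_ns, freq_mhz = 600.13) {
  hbar <- 1.054571817e-34
  gh <- 2.6752218744e8
  gn <- -2.7126180436e7
  rnh <- 1.02e-10
  csa <- -160e-6
  wh <- 2 * pi * freq_mhz * 1e6
  wn <- wh * abs(gn) / gh
  d <- 1e-7 * hbar * gh * abs(gn) / rnh^3
  d2 <- d^2
  c2 <- (wn * csa)^2 / 3
  tm <- tm_ns * 1e-9
  te <- te_ps * 1e-12
  J <- function(w) {
    out <- 0.4 * s2 * tm / (1 + (w * tm)^2)
    if (te > 0) {
      tp <- 1 / (1 / tm + 1 / te)
      out <- out + 0.4 * (1 - s2) * tp / (1 + (w * tp)^2)
    }
    out
  }
  r1 <- d2 / 4 * (J(wh - wn) + 3 * J(wn) + 6 * J(wh + wn)) + c2 * J(wn)
  r2 <- d2 / 8 * (4 * J(0) + J(wh - wn) + 3 * J(wn) + 6 * J(wh) +
                    6 * J(wh + wn)) + c2 / 6 * (4 * J(0) + 3 * J(wn)) + rex
  noe <- 1 + d2 / 4 * (gh / gn) * (6 * J(wh + wn) - J(wh - wn)) / r1
  c(r1 = r1, r2 = r2, noe = noe)
}

# Brute-force scan oracle for the apparent tumbling time: finest grid
# argmin of |rigid ratio - target|.
oracle_tau_m <- function(r1, r2, grid = seq(0.5, 50, by = 0.001)) {
  ratios <- vapply(grid, function(tm) {
    o <- oracle_rates(1, 0, 0, tm)
    o["r2"] / o["r1"]
  }, numeric(1))
  grid[which.min(abs(ratios - r2 / r1))]
}

# Brute-force 2-D grid oracle for the S2 + Rex model.
oracle_fit_s2rex <- function(obs, tau_m,
                             s2_grid = seq(0.5, 1, by = 0.002),
                             rex_grid = seq(0, 8, by = 0.02)) {
  best <- c(Inf, NA, NA)
  for (s2 in s2_grid) {
    base <- oracle_rates(s2, 0, 0, tau_m)
    chi <- ((base["r1"] - obs$r1) / obs$r1_err)^2 +
      ((base["r2"] + rex_grid - obs$r2) / obs$r2_err)^2 +
      ((base["noe"] - obs$noe) / obs$noe_err)^2
    k <- which.min(chi)
    if (chi[k] < best[1]) best <- c(chi[k], s2, rex_grid[k])
  }
  list(chi2 = best[1], s2 = best[2], rex = best[3])
}

# 1 Angstrom grid-search oracle for metal-center feasibility: smallest
# flat-bottom penalty over a bounding box around the restrained atoms.
oracle_center_search <- function(coords, lower, upper, spacing = 1) {
  lo <- apply(coords, 2, min) - upper
  hi <- apply(coords, 2, max) + upper
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  best <- Inf
  for (z in gz) {
    grid <- as.matrix(expand.grid(x = gx, y = gy, z = z))
    pen <- rep(0, nrow(grid))
    for (k in seq_len(nrow(coords))) {
      d <- sqrt((grid[, 1] - coords[k, 1])^2 +
                  (grid[, 2] - coords[k, 2])^2 +
                  (grid[, 3] - coords[k, 3])^2)
      pen <- pen + pmax(0, d - upper)^2 + pmax(0, lower - d)^2
    }
    best <- min(best, min(pen))
  }
  best
}

# Analytic accessible area of one of two identical spheres of radius R
# whose centers are d apart (spherical-cap geometry).
oracle_two_sphere_area <- function(R, d) {
  if (d >= 2 * R) return(4 * pi * R^2)
  h <- R - d / 2            # cap height buried in the neighbour
  4 * pi * R^2 - 2 * pi * R * h
}

# Fixture: standard acquisition delay vectors (seconds).
r1_delays_s <- function() sort(c(10, 150, 300, 450, 600, 700, 900, 1200,
                                 10, 600)) / 1000
r1rho_delays_s <- function() sort(c(10, 50, 80, 100, 120, 150, 170, 190,
                                    10, 100)) / 1000
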