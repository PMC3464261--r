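# Toy backbone builder with ideal covalent geometry. Atoms are placed by
# internal coordinates (NeRF chaining): each new atom is defined by a bond
# length, bond angle and torsion relative to the three preceding ones.

# Place atom D given positions A, B, C, bond |CD|, angle B-C-D (deg) and
# torsion A-B-C-D (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                n_h = 1.01,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.5, omega = 180)

#' Generate a toy backbone structure with ideal geometry
#'
#' Builds backbone N, CA, C, O and amide H atoms for a sequence in either
#' ideal alpha-helical (phi = -57, psi = -47 degrees) or fully extended
#' (phi = psi = 180) conformation. Residues are numbered from 1. The
#' result is a fixture-grade structure for geometric algorithms (solvent
#' accessibility, metal-site localization, hydrodynamics), not a physical
#' model: no side chains beyond the amide are placed.
#'
#' @param sequence one-letter amino-acid string (length >= 4).
#' @param geometry `"helix"` or `"extended"`.
#' @param phi,psi optional explicit backbone torsions (degrees),
#'   overriding `geometry`.
#' @return a [protein_structure()].
#' @examples
#' helix <- generate_toy_structure(strrep("A", 10), "helix")
#' @export
generate_toy_structure <- function(sequence,
                                   geometry = c("helix", "extended"),
                                   phi = NULL, psi = NULL) {
  letters1 <- check_sequence(sequence)
  if (length(letters1) < 4) stop_invalid("sequence length must be >= 4")
  geometry <- match.arg(geometry)
  if (is.null(phi)) phi <- if (geometry == "helix") -57 else 180
  if (is.null(psi)) psi <- if (geometry == "helix") -47 else 180
  g <- BB_GEOM
  n_res <- length(letters1)
  # seed the first residue's N, CA, C in a canonical frame
  N <- matrix(NA_real_, n_res, 3); CA <- N; C <- N; O <- N; H <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    if (i < n_res) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                               g$c_n, g$ang_ca_c_n, psi)
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ],
                                g$n_ca, g$ang_c_n_ca, g$omega)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ],
                               g$ca_c, g$ang_n_ca_c, phi)
    }
    # carbonyl O opposite the next N (psi + 180 about the same axis)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$c_o, g$ang_ca_c_o, psi + 180)
    # amide H in the peptide plane, roughly anti to the bisector
    hdir <- if (i == 1) {
      v <- N[i, ] - CA[i, ]; v / sqrt(sum(v^2))
    } else {
      v1 <- C[i - 1, ] - N[i, ]; v1 <- v1 / sqrt(sum(v1^2))
      v2 <- CA[i, ] - N[i, ]; v2 <- v2 / sqrt(sum(v2^2))
      v <- -(v1 + v2); v / sqrt(sum(v^2))
    }
    H[i, ] <- N[i, ] + g$n_h * hdir
  }
  resid3 <- aa_three(letters1)
  per_res <- function(mat, name, elem) {
    data.frame(model = 1L, chain = "A", resno = seq_len(n_res),
               resid = resid3, elety = name, elem = elem,
               x = mat[, 1], y = mat[, 2], z = mat[, 3],
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(per_res(N, "N", "N"), per_res(CA, "CA", "C"),
                 per_res(C, "C", "C"), per_res(O, "O", "O"),
                 per_res(H, "H", "H"))
  atoms <- atoms[order(atoms$resno, match(atoms$elety,
                                          c("N", "H", "CA", "C", "O"))), ]
  rownames(atoms) <- NULL
  protein_structure(atoms)
}

# Heavy side-chain atom counts per residue (beyond the backbone).
SIDECHAIN_HEAVY <- c(A = 1, R = 7, N = 4, D = 4, C = 2, Q = 5, E = 5,
                     G = 0, H = 6, I = 4, L = 4, K = 5, M = 4, F = 7,
                     P = 3, S = 2, T = 3, V = 3, W = 10, Y = 8)

# Rigid transform helpers for assembling multi-segment fixtures.
transform_structure <- function(structure, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(rotation)
  structure$x <- xyz[, 1] + translation[1]
  structure$y <- xyz[, 2] + translation[2]
  structure$z <- xyz[, 3] + translation[3]
  structure
}

rotation_between <- function(a, b) {
  # rotation matrix taking unit vector a onto unit vector b
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) return(diag(c(1, -1, -1)))
  vx <- skew3(v)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Synthetic compact four-helix-bundle structure
#'
#' Assembles an entirely synthetic, compact 114-residue fold from four
#' ideal helices packed as an antiparallel bundle with connecting loops,
#' plus pseudo side-chain heavy atoms (one bead per heavy side-chain atom,
#' stacked outward from each CA) so that the heavy-atom count per residue
#' matches the sequence composition. It is a stand-in used where a
#' deposited experimental structure is unavailable: realistic in size and
#' atom density for hydrodynamic and surface-area calculations, but not a
#' real protein fold.
#'
#' @param sequence one-letter sequence (default: the package's synthetic
#'   2S-albumin-like 114-residue sequence, [synthetic_2s_sequence()]).
#' @param seed integer seed for the deterministic side-chain jitter.
#' @return a [protein_structure()].
#' @export
synthetic_bundle_structure <- function(sequence = synthetic_2s_sequence(),
                                       seed = 1) {
  letters1 <- check_sequence(sequence)
  n <- length(letters1)
  if (n < 40) stop_invalid("bundle fixture needs >= 40 residues")
  # split the chain into 4 helices separated by 3 loops; helix length is
  # kept short (as in compact disulfide-knotted folds) with the remainder
  # of the chain in the loops
  n_helix <- max(10L, round(n / 7))
  n_loop <- (n - 4L * n_helix) %/% 3L
  rem <- n - 4L * n_helix - 3L * n_loop
  lens <- c(n_helix + rem, rep(c(n_loop, n_helix), 3L))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  seg_type <- rep(c("helix", "loop"), length.out = 7L)
  # bundle geometry: helix axes along +/- z on a square of side ~10.5 A
  xy <- list(c(0, 0), c(10.5, 0), c(10.5, 10.5), c(0, 10.5))
  updown <- c(1, -1, 1, -1)
  blocks <- list()
  h_idx <- 0L
  for (s in seq_along(lens)) {
    idx <- starts[s]:ends[s]
    sub <- paste(letters1[idx], collapse = "")
    if (seg_type[s] == "helix") {
      h_idx <- h_idx + 1L
      seg <- generate_toy_structure(sub, "helix")
      ca <- seg[seg$elety == "CA", c("x", "y", "z")]
      axis <- stats::prcomp(ca)$rotation[, 1]
      Rz <- rotation_between(axis, c(0, 0, updown[h_idx]))
      seg <- transform_structure(seg, Rz)
      ca2 <- seg[seg$elety == "CA", c("x", "y", "z")]
      ctr <- colMeans(ca2)
      z0 <- min(ca2$z)
      seg <- transform_structure(
        seg, diag(3),
        c(xy[[h_idx]][1] - ctr[1], xy[[h_idx]][2] - ctr[2], -z0))
    } else {
      # loop residues: straight run of backbone atoms bridging helix ends
      seg <- generate_toy_structure(paste0(sub, "AAAA"), "extended")
      seg <- seg[seg$resno <= length(idx), , drop = FALSE]
      from <- xy[[h_idx]]; to <- xy[[h_idx + 1L]]
      zlev <- if (updown[h_idx] > 0) n_helix * 1.5 + 2 else -2
      tfrac <- (seg$resno - 0.5) / length(idx)
      base <- as.matrix(seg[, c("x", "y", "z")])
      base <- base - matrix(colMeans(base), nrow(base), 3, byrow = TRUE)
      seg$x <- from[1] + tfrac * (to[1] - from[1]) + 0.45 * base[, 2]
      seg$y <- from[2] + tfrac * (to[2] - from[2]) + 0.3 * base[, 1]
      seg$z <- zlev + 1.5 * sin(pi * tfrac) + 0.35 * base[, 2]
    }
    seg$resno <- seg$resno + starts[s] - 1L
    blocks[[s]] <- as.data.frame(seg)
  }
  atoms <- do.call(rbind, blocks)
  # pseudo side-chain heavy atoms stacked outward from each CA
  core_xy <- c(5.25, 5.25)
  sc <- with_seed(seed, {
    rows <- list()
    for (i in seq_len(n)) {
      k <- SIDECHAIN_HEAVY[[letters1[i]]]
      if (k == 0) next
      ca <- atoms[atoms$resno == i & atoms$elety == "CA", ]
      dir <- c(ca$x - core_xy[1], ca$y - core_xy[2], 0)
      nrm <- sqrt(sum(dir^2))
      dir <- if (nrm < 1e-6) c(1, 0, 0) else dir / nrm
      # pack side-chain beads in shells of three around the CA-outward
      # direction so even long side chains stay within ~5 A of the CA
      jit <- matrix(stats::runif(3 * k, -0.8, 0.8), k, 3)
      shell <- 1.3 * (1 + (seq_len(k) - 1) %/% 3)
      rows[[length(rows) + 1L]] <- data.frame(
        model = 1L, chain = "A", resno = i, resid = aa_three(letters1[i]),
        elety = paste0("S", seq_len(k)), elem = "C",
        x = ca$x + dir[1] * shell + jit[, 1],
        y = ca$y + dir[2] * shell + jit[, 2],
        z = ca$z + jit[, 3], stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  atoms <- rbind(atoms, sc)
  atoms <- atoms[order(atoms$resno), ]
  rownames(atoms) <- NULL
  protein_structure(atoms)
}

#' Synthetic 2S-albumin-like sequence
#'
#' An invented 114-residue sequence with the residue composition typical
#' of methionine-rich seed-storage 2S albumins (cysteine-rich core,
#' glutamine/arginine-rich loops). Purely synthetic: used as a
#' reproducible default input for fixtures and simulations.
#'
#' @return a single string of 114 one-letter codes.
#' @export
synthetic_2s_sequence <- function() {
  s <- paste0("MAKLTILVALALFLLAAHASARQQWELQGDRRCQSQLERANLRPCEQHLMQKIQRDEDSY",
              "ERDPYSPSQDPYSPSQDPDRRDPYSPSPYDRRGAGSSQHQERCCNELNEFENNQRCMC")
  substr(s, 1, 114)
}
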