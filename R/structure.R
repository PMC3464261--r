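#' Protein structure container
#'
#' A light atom-record table used across the package: one row per atom
#' with columns `model`, `chain`, `resno`, `resid` (3-letter residue
#' name), `elety` (atom name), `elem` (element), `x`, `y`, `z`
#' (Angstrom). Multi-model NMR ensembles carry one `model` id per member.
#'
#' @param atoms data frame with the columns above.
#' @return the data frame with class `"protein_structure"` prepended.
#' @export
protein_structure <- function(atoms) {
  need <- c("model", "chain", "resno", "resid", "elety", "elem",
            "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop_invalid("'atoms' must have columns ", paste(need, collapse = ", "))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop_invalid("coordinates must be finite")
  key <- paste(atoms$model, atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key))
    stop_invalid("duplicate (model, chain, residue, atom) records")
  class(atoms) <- unique(c("protein_structure", class(atoms)))
  atoms
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("Protein structure: %d atoms, %d residue(s), %d model(s)\n",
              nrow(x), length(unique(x$resno)), length(unique(x$model))))
  invisible(x)
}

#' Extract one model from a structure ensemble
#'
#' @param structure a `"protein_structure"`.
#' @param model model id (default: first).
#' @return a single-model `"protein_structure"`.
#' @export
structure_model <- function(structure, model = NULL) {
  if (is.null(model)) model <- min(structure$model)
  out <- structure[structure$model == model, , drop = FALSE]
  if (!nrow(out)) stop_invalid("model ", model, " not present")
  out
}

#' One-letter sequence of a structure
#'
#' @param structure a `"protein_structure"` (first model used).
#' @return single string of one-letter codes, in residue-number order.
#' @export
structure_sequence <- function(structure) {
  m <- structure_model(structure)
  m <- m[order(m$resno), ]
  res <- m[!duplicated(m$resno), c("resno", "resid")]
  rev3 <- stats::setNames(names(AA1), AA1)
  letters1 <- rev3[res$resid]
  if (anyNA(letters1))
    stop_invalid("non-standard residue name(s): ",
                 paste(unique(res$resid[is.na(letters1)]), collapse = ", "))
  paste(letters1, collapse = "")
}

#' Read a (possibly multi-model) PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] returning the package's
#' [protein_structure()] atom table; every model of an NMR ensemble
#' becomes a block of rows with its own `model` id.
#'
#' @param file path to a PDB file.
#' @return a `"protein_structure"`.
#' @export
read_structure_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  elem <- at$elesy
  if (is.null(elem) || all(!nzchar(elem)))
    elem <- substr(trimws(at$elety), 1, 1)
  one <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                    elety = at$elety, elem = trimws(elem),
                    stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(n_models), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    cbind(data.frame(model = m), one,
          data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  })
  protein_structure(do.call(rbind, blocks))
}

#' Write a structure (with optional metal site) to PDB
#'
#' Writes the first model of a structure via [bio3d::write.pdb()]; when a
#' fitted `"center_model"` (see [locate_center()]) is supplied, a copper
#' HETATM record is appended at the fitted position.
#'
#' @param structure a `"protein_structure"`.
#' @param file output path.
#' @param center optional `"center_model"` or length-3 coordinate vector.
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(structure, file, center = NULL) {
  m <- structure_model(structure)
  xyz <- as.vector(t(as.matrix(m[, c("x", "y", "z")])))
  n <- nrow(m)
  type <- rep("ATOM", n); resid <- m$resid; resno <- m$resno
  elety <- m$elety; chain <- m$chain; elesy <- m$elem
  if (!is.null(center)) {
    pos <- if (inherits(center, "center_model")) center$position else center
    xyz <- c(xyz, pos)
    type <- c(type, "HETATM"); resid <- c(resid, "CU")
    resno <- c(resno, max(m$resno) + 1L); elety <- c(elety, "CU")
    chain <- c(chain, chain[1]); elesy <- c(elesy, "CU")
  }
  bio3d::write.pdb(file = file, type = type, xyz = xyz, resno = resno,
                   resid = resid, elety = elety, chain = chain,
                   elesy = elesy)
  invisible(file)
}

# Amide atoms (backbone N and its H if present) of one structure model.
amide_atoms <- function(m, include_sidechain = FALSE) {
  sel <- m$elety %in% c("N", "H", "HN")
  if (include_sidechain)
    sel <- sel | grepl("^(NE2|ND2|HE2|HD2)", m$elety)
  m[sel, , drop = FALSE]
}
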