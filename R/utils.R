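# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so library calls never disturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 3x3 skew-symmetric (cross-product) matrix of a length-3 vector.
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

aa_three <- function(letters1) {
  out <- AA1[letters1]
  if (anyNA(out))
    stop_invalid("unknown amino-acid letter(s): ",
                 paste(unique(letters1[is.na(out)]), collapse = ", "))
  unname(out)
}

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop_invalid("'sequence' must be a single non-empty string")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(letters1), names(AA1))
  if (length(bad))
    stop_invalid("unknown amino-acid letter(s): ", paste(bad, collapse = ", "))
  letters1
}
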