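# Scoring and physicochemical constants shared across modules.

#' Standard amino-acid alphabet
#'
#' The twenty proteinogenic residues in the conventional BLOSUM row order,
#' without ambiguity codes. `X` is tolerated by the aligner (scores zero
#' against everything) but is not part of this vector.
#'
#' @return Character vector of 20 one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' BLOSUM62 substitution matrix
#'
#' The canonical BLOSUM62 half-bit scoring matrix over the 20 standard
#' residues, extended with an `X` row/column that scores 0 against every
#' residue (unknowns neither reward nor penalize an alignment column).
#'
#' @return Integer matrix with dimnames over the 21-letter alphabet.
#' @export
blosum62 <- function() {
  aa <- aa_alphabet()
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)
  m <- matrix(as.integer(v), 20, 20, byrow = TRUE, dimnames = list(aa, aa))
  m <- rbind(cbind(m, X = 0L), X = 0L)
  colnames(m)[21] <- "X"
  m
}

# Average (isotope-weighted) residue masses in daltons, i.e. the mass of the
# amino acid minus one water; a peptide mass is the residue sum plus water.
.residue_mass <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)

.water_mass <- 18.01528

# pKa sets for the Henderson-Hasselbalch charge model. "positive" groups are
# protonated below their pKa; "negative" groups deprotonated above it.
.pka_tables <- list(
  EMBOSS = list(
    nterm = 8.6, cterm = 3.6,
    positive = c(K = 10.8, R = 12.5, H = 6.5),
    negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1)),
  # Simplified Bjellqvist-style set (position-specific corrections dropped).
  Bjellqvist = list(
    nterm = 7.5, cterm = 3.55,
    positive = c(K = 10.0, R = 12.0, H = 5.98),
    negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)))

#' Background amino-acid frequencies
#'
#' Robinson & Robinson residue frequencies, used as the substitution and
#' random-protein model by the synthetic-data generators.
#'
#' @return Named numeric vector over the 20 standard residues, summing to 1.
#' @export
aa_background <- function() {
  f <- c(A = 0.0780, R = 0.0512, N = 0.0448, D = 0.0536, C = 0.0192,
         Q = 0.0426, E = 0.0629, G = 0.0738, H = 0.0219, I = 0.0514,
         L = 0.0901, K = 0.0574, M = 0.0224, F = 0.0385, P = 0.0520,
         S = 0.0712, T = 0.0584, W = 0.0132, Y = 0.0321, V = 0.0644)
  f / sum(f)
}

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulations never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Validate a protein string over the 20-letter alphabet (+ optional X).
check_protein <- function(seq, allow_x = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq))
    stop(sprintf("%s must be a non-empty string", what))
  ok <- aa_alphabet()
  if (allow_x) ok <- c(ok, "X")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(ch), ok)
  if (length(bad))
    stop(sprintf("%s contains invalid residue(s): %s", what,
                 paste(bad, collapse = ", ")))
  invisible(ch)
}
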