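#' Monoisotopic mass constants
#'
#' Residue masses for the 20 standard amino acids (monoisotopic, Da),
#' plus the masses of water and a proton, and the modification deltas used
#' throughout: fixed carbamidomethylation of cysteine (+57.02146 Da) and
#' variable oxidation of methionine (+15.99491 Da).
#'
#' @format Named numeric vector of residue masses (Da).
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

#' @rdname mass-constants
#' @export
MASS_WATER <- 18.010565

#' @rdname mass-constants
#' @export
MASS_PROTON <- 1.0072765

#' @rdname mass-constants
#' @export
MOD_CARBAMIDOMETHYL <- 57.02146

#' @rdname mass-constants
#' @export
MOD_OXIDATION <- 15.99491

#' Kyte-Doolittle hydropathy indices for the 20 standard amino acids.
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AA20 <- names(RESIDUE_MASSES)

# BLOSUM62 substitution scores (standard 20x20 half-bit table, public
# domain; Henikoff & Henikoff ordering ARNDCQEGHILKMFPSTWYV).
.blosum62_rows <- c(
  "A  4 -1 -2 -2  0 -1 -1  0 -2 -1 -1 -1 -1 -2 -1  1  0 -3 -2  0",
  "R -1  5  0 -2 -3  1  0 -2  0 -3 -2  2 -1 -3 -2 -1 -1 -3 -2 -3",
  "N -2  0  6  1 -3  0  0  0  1 -3 -3  0 -2 -3 -2  1  0 -4 -2 -3",
  "D -2 -2  1  6 -3  0  2 -1 -1 -3 -4 -1 -3 -3 -1  0 -1 -4 -3 -3",
  "C  0 -3 -3 -3  9 -3 -4 -3 -3 -1 -1 -3 -1 -2 -3 -1 -1 -2 -2 -1",
  "Q -1  1  0  0 -3  5  2 -2  0 -3 -2  1  0 -3 -1  0 -1 -2 -1 -2",
  "E -1  0  0  2 -4  2  5 -2  0 -3 -3  1 -2 -3 -1  0 -1 -3 -2 -2",
  "G  0 -2  0 -1 -3 -2 -2  6 -2 -4 -4 -2 -3 -3 -2  0 -2 -2 -3 -3",
  "H -2  0  1 -1 -3  0  0 -2  8 -3 -3 -1 -2 -1 -2 -1 -2 -2  2 -3",
  "I -1 -3 -3 -3 -1 -3 -3 -4 -3  4  2 -3  1  0 -3 -2 -1 -3 -1  3",
  "L -1 -2 -3 -4 -1 -2 -3 -4 -3  2  4 -2  2  0 -3 -2 -1 -2 -1  1",
  "K -1  2  0 -1 -3  1  1 -2 -1 -3 -2  5 -1 -3 -1  0 -1 -3 -2 -2",
  "M -1 -1 -2 -3 -1  0 -2 -3 -2  1  2 -1  5  0 -2 -1 -1 -1 -1  1",
  "F -2 -3 -3 -3 -2 -3 -3 -3 -1  0  0 -3  0  6 -4 -2 -2  1  3 -1",
  "P -1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4  7 -1 -1 -4 -3 -2",
  "S  1 -1  1  0 -1  0  0  0 -1 -2 -2  0 -1 -2 -1  4  1 -3 -2 -2",
  "T  0 -1  0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1  1  5 -2 -2  0",
  "W -3 -3 -4 -4 -2 -2 -3 -2 -2 -3 -2 -3 -1  1 -4 -3 -2 11  2 -3",
  "Y -2 -2 -2 -3 -2 -1 -2 -3  2 -1 -1 -2 -1  3 -3 -2 -2  2  7 -1",
  "V  0 -3 -3 -3 -1 -2 -2 -3 -3  3  1 -2  1 -1 -2 -2  0 -3 -1  4"
)

.parse_blosum62 <- function() {
  parts <- strsplit(trimws(.blosum62_rows), "\\s+")
  aa <- vapply(parts, `[`, character(1), 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(20)))
  dimnames(m) <- list(aa, aa)
  m
}

#' BLOSUM62 substitution matrix (20 standard amino acids).
#' @export
BLOSUM62_MATRIX <- .parse_blosum62()

.check_protein <- function(protein, allow_empty = FALSE) {
  stopifnot(is.character(protein), length(protein) == 1L, !is.na(protein))
  if (!allow_empty && nchar(protein) == 0L)
    stop("empty protein/peptide sequence", call. = FALSE)
  bad <- setdiff(strsplit(protein, "")[[1]], AA20)
  if (length(bad))
    stop("unknown residue character(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  invisible(protein)
}
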