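#' Modified peptides
#'
#' A peptide sequence together with a list of mass modifications. The fixed
#' carbamidomethylation of cysteine is applied automatically unless
#' \code{fixed_cys = FALSE}; variable methionine oxidation is added via
#' \code{oxidized_met} positions.
#'
#' @param sequence amino acid string (standard 20 residues).
#' @param mods optional data.frame with columns \code{position} (1-based)
#'   and \code{delta} (Da) for additional variable modifications.
#' @param oxidized_met integer positions of oxidized methionines.
#' @param fixed_cys apply carbamidomethyl to every cysteine (default TRUE).
#' @return an object of class \code{ModifiedPeptide}.
#' @export
modified_peptide <- function(sequence, mods = NULL, oxidized_met = integer(),
                             fixed_cys = TRUE) {
  .check_protein(sequence)
  n <- nchar(sequence)
  res <- strsplit(sequence, "")[[1]]
  pos <- integer(0); delta <- numeric(0)
  if (fixed_cys) {
    cpos <- which(res == "C")
    pos <- c(pos, cpos); delta <- c(delta, rep(MOD_CARBAMIDOMETHYL, length(cpos)))
  }
  if (length(oxidized_met)) {
    oxidized_met <- as.integer(oxidized_met)
    if (any(oxidized_met < 1L | oxidized_met > n))
      stop("oxidized_met position outside sequence", call. = FALSE)
    if (any(res[oxidized_met] != "M"))
      stop("oxidized_met position is not a methionine", call. = FALSE)
    pos <- c(pos, oxidized_met)
    delta <- c(delta, rep(MOD_OXIDATION, length(oxidized_met)))
  }
  if (!is.null(mods) && nrow(mods)) {
    if (any(mods$position < 1L | mods$position > n))
      stop("modification position outside sequence", call. = FALSE)
    pos <- c(pos, as.integer(mods$position)); delta <- c(delta, mods$delta)
  }
  structure(list(sequence = sequence,
                 mods = data.frame(position = pos, delta = delta)),
            class = "ModifiedPeptide")
}

#' @export
print.ModifiedPeptide <- function(x, ...) {
  cat("ModifiedPeptide:", x$sequence)
  if (nrow(x$mods))
    cat(sprintf(" [%s]", paste(sprintf("%d:%+.5f", x$mods$position,
                                       x$mods$delta), collapse = ", ")))
  cat("\n")
  invisible(x)
}

.as_modpep <- function(p) {
  if (inherits(p, "ModifiedPeptide")) p else modified_peptide(p)
}

# per-residue mass vector including modification deltas
.residue_mass_vector <- function(p) {
  p <- .as_modpep(p)
  m <- unname(RESIDUE_MASSES[strsplit(p$sequence, "")[[1]]])
  if (nrow(p$mods))
    for (k in seq_len(nrow(p$mods)))
      m[p$mods$position[k]] <- m[p$mods$position[k]] + p$mods$delta[k]
  m
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus modification deltas plus one water.
#'
#' @param p a \code{ModifiedPeptide} or a plain sequence string (fixed Cys
#'   modification is then applied).
#' @return neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("PEPTIDE")  # 799.35996
#' @export
peptide_mass <- function(p) {
  sum(.residue_mass_vector(p)) + MASS_WATER
}

#' Theoretical m/z of a peptide at a given charge
#' @param p peptide (see \code{\link{peptide_mass}}).
#' @param charge precursor charge (>= 1).
#' @export
peptide_mz <- function(p, charge) {
  charge <- as.integer(charge)
  if (charge < 1L) stop("charge must be >= 1", call. = FALSE)
  (peptide_mass(p) + charge * MASS_PROTON) / charge
}

#' Theoretical singly charged b/y fragment ions
#'
#' For a peptide of length n, computes the 2(n-1) singly protonated b and y
#' ions: b_i is the sum of the first i residue masses (with modifications)
#' plus a proton; y_i is the sum of the last i residue masses plus water
#' plus a proton. Complementarity b_i + y_(n-i) = M + 2 protons holds
#' exactly.
#'
#' @inheritParams peptide_mass
#' @param max_index report ions up to this index (default n-1).
#' @return data.frame with columns series ("b"/"y"), index, theoretical_mz.
#' @export
theoretical_ions <- function(p, max_index = NULL) {
  p <- .as_modpep(p)
  n <- nchar(p$sequence)
  if (n < 2L) stop("peptide must have length >= 2 for fragment ions",
                   call. = FALSE)
  if (is.null(max_index)) max_index <- n - 1L
  max_index <- min(as.integer(max_index), n - 1L)
  rm <- .residue_mass_vector(p)
  idx <- seq_len(max_index)
  b <- cumsum(rm)[idx] + MASS_PROTON
  y <- cumsum(rev(rm))[idx] + MASS_WATER + MASS_PROTON
  data.frame(series = rep(c("b", "y"), each = max_index),
             index = c(idx, idx),
             theoretical_mz = c(b, y),
             stringsAsFactors = FALSE)
}

#' Spectrum constructor
#'
#' @param spectrum_id identifier string.
#' @param precursor_mz observed precursor m/z (Da).
#' @param precursor_charge integer charge >= 1.
#' @param mz,intensity fragment peak arrays; peaks are sorted by m/z.
#' @export
spectrum <- function(spectrum_id, precursor_mz, precursor_charge, mz,
                     intensity = rep(1, length(mz))) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = as.integer(precursor_charge),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o])),
            class = "Spectrum")
}

#' Mass tolerances used by search and curation
#'
#' Defaults: 10 ppm precursor tolerance, 0.02 Da fragment tolerance, and a
#' 2 ppm absolute precursor-error curation cutoff.
#' @param precursor_ppm,fragment_da,curation_ppm positive numerics.
#' @export
tolerances <- function(precursor_ppm = 10, fragment_da = 0.02,
                       curation_ppm = 2.0) {
  stopifnot(precursor_ppm > 0, fragment_da > 0, curation_ppm > 0)
  list(precursor_ppm = precursor_ppm, fragment_da = fragment_da,
       curation_ppm = curation_ppm)
}

#' Match theoretical b/y ions to spectrum peaks
#'
#' Each theoretical ion is matched to the nearest peak within the fragment
#' tolerance; ties on distance go to the higher-intensity peak. A peak is
#' used at most once per (series, index) annotation.
#'
#' @param p peptide.
#' @param s \code{Spectrum}.
#' @param tol tolerances list (\code{\link{tolerances}}).
#' @return data.frame: series, index, theoretical_mz, observed_mz, delta_da,
#'   with NA observed_mz for unmatched ions.
#' @export
match_spectrum <- function(p, s, tol = tolerances()) {
  theo <- theoretical_ions(p)
  nx <- nrow(theo)
  theo$observed_mz <- rep(NA_real_, nx)
  theo$delta_da <- rep(NA_real_, nx)
  if (!length(s$mz)) return(theo)
  for (i in seq_len(nx)) {
    d <- abs(s$mz - theo$theoretical_mz[i])
    within <- which(d <= tol$fragment_da)
    if (!length(within)) next
    dmin <- min(d[within])
    best <- within[d[within] <= dmin + 1e-12]
    if (length(best) > 1L) best <- best[which.max(s$intensity[best])]
    theo$observed_mz[i] <- s$mz[best]
    theo$delta_da[i] <- s$mz[best] - theo$theoretical_mz[i]
  }
  theo
}

#' Signed precursor mass error in ppm
#'
#' ppm = (observed_neutral - theoretical_neutral) / theoretical_neutral * 1e6
#' where observed_neutral = precursor_mz * z - z * proton.
#'
#' @param p peptide.
#' @param s \code{Spectrum} (uses precursor_mz and precursor_charge).
#' @export
precursor_ppm_error <- function(p, s) {
  z <- s$precursor_charge
  if (is.na(z) || z < 1L) stop("precursor charge must be >= 1", call. = FALSE)
  theo <- peptide_mass(p)
  obs <- s$precursor_mz * z - z * MASS_PROTON
  (obs - theo) / theo * 1e6
}

#' Longest run of consecutive matched fragment indices
#'
#' Counts, within the b series and the y series separately, the longest run
#' of consecutive ion indices with an observed match, and returns the
#' maximum of the two. With \code{combined = TRUE} the two series are merged
#' into one index set before run counting (a looser reading, off by
#' default).
#'
#' @param annotations data.frame from \code{\link{match_spectrum}} (or any
#'   frame with series, index, observed_mz columns).
#' @param combined merge b and y indices before counting (default FALSE).
#' @return integer run length (0 if no matches).
#' @export
longest_consecutive_run <- function(annotations, combined = FALSE) {
  matched <- annotations[!is.na(annotations$observed_mz), , drop = FALSE]
  if (!nrow(matched)) return(0L)
  run_of <- function(idx) {
    idx <- sort(unique(as.integer(idx)))
    if (!length(idx)) return(0L)
    breaks <- c(0L, which(diff(idx) != 1L), length(idx))
    max(diff(breaks))
  }
  if (combined) return(run_of(matched$index))
  max(run_of(matched$index[matched$series == "b"]),
      run_of(matched$index[matched$series == "y"]))
}
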