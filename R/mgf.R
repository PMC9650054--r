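#' Write centroided spectra as MGF
#'
#' One BEGIN/END IONS block per spectrum with TITLE, PEPMASS and CHARGE
#' headers; fixed numeric formatting so identical inputs yield identical
#' bytes.
#'
#' @param spectra list of \code{\link{spectrum}} objects.
#' @param path output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 sprintf("PEPMASS=%.6f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$precursor_charge),
                 sprintf("%.6f %.1f", s$mz, s$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Read an MGF file
#' @param path MGF path.
#' @return list of \code{\link{spectrum}} objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "BEGIN IONS") {
      title <- NA_character_; pepmass <- NA_real_; charge <- 1L
      mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && lines[i] != "END IONS") {
        ln <- lines[i]
        if (startsWith(ln, "TITLE=")) {
          title <- substring(ln, 7L)
        } else if (startsWith(ln, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(substring(ln, 9L), "\\s+")[[1]][1])
        } else if (startsWith(ln, "CHARGE=")) {
          charge <- as.integer(gsub("[^0-9]", "", substring(ln, 8L)))
        } else if (grepl("^[0-9]", ln)) {
          v <- as.numeric(strsplit(ln, "\\s+")[[1]])
          mz <- c(mz, v[1]); int <- c(int, if (length(v) > 1) v[2] else 1)
        }
        i <- i + 1L
      }
      out[[length(out) + 1L]] <- spectrum(title, pepmass, charge, mz, int)
    }
    i <- i + 1L
  }
  names(out) <- vapply(out, `[[`, character(1), "spectrum_id")
  out
}
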