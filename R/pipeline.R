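#' Annotate a PSM table against spectra
#'
#' For each PSM, re-annotates the referenced spectrum at the fragment
#' tolerance to obtain the longest consecutive b/y run, and computes the
#' signed precursor ppm error from the table's precursor m/z and charge.
#'
#' @param psms data.frame with spectrum_id, peptide, charge, precursor_mz.
#' @param spectra named list of \code{\link{spectrum}} objects (names =
#'   spectrum ids).
#' @param tol \code{\link{tolerances}}.
#' @return the input with added run_length and ppm columns.
#' @export
annotate_psms <- function(psms, spectra, tol = tolerances()) {
  need <- c("spectrum_id", "peptide", "charge", "precursor_mz")
  miss <- setdiff(need, names(psms))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  psms$run_length <- NA_integer_
  psms$ppm <- NA_real_
  for (i in seq_len(nrow(psms))) {
    pep <- modified_peptide(psms$peptide[i])
    s <- spectra[[psms$spectrum_id[i]]]
    if (is.null(s)) stop("spectrum not found: ", psms$spectrum_id[i],
                         call. = FALSE)
    ann <- match_spectrum(pep, s, tol)
    psms$run_length[i] <- longest_consecutive_run(ann)
    # ppm from the table's precursor m/z (the search engine's record)
    obs <- psms$precursor_mz[i] * psms$charge[i] -
      psms$charge[i] * MASS_PROTON
    theo <- peptide_mass(pep)
    psms$ppm[i] <- (obs - theo) / theo * 1e6
  }
  psms
}

#' Run the full discovery pipeline on synthetic data
#'
#' simulate -> build database -> digest/map -> annotate -> curate ->
#' quantify, writing all intermediate files under \code{outdir}. This is
#' the end-to-end surface exercised by the test suite: the final SEPome
#' is compared against the planted ground truth.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param outdir working directory (created).
#' @param thresholds \code{\link{curation_thresholds}}.
#' @param rules protease names used for the uniqueness mapping.
#' @return list: sim (ground truth etc.), db, mapping, report
#'   (CurationReport), quant (differential test results).
#' @export
run_pipeline <- function(cfg = sim_config(), outdir = tempfile("seppipe"),
                         thresholds = curation_thresholds(),
                         rules = protease_names()) {
  sim <- full_simulation(cfg, outdir)
  transcripts <- sim$transcripts
  db <- build_database(transcripts, orf_config())
  psms <- sim$psms
  psms <- annotate_psms(psms, sim$spectra)
  mapping <- map_peptides_to_seps(unique(psms$peptide), db, rules,
                                  max_missed = 2L)
  report <- assemble_sepome(psms, db, sim$proteome, thresholds,
                            mapping = mapping)
  groups <- sim$groups
  quant <- differential_test(sim$intensities, groups)
  write_sep_fasta(db, file.path(outdir, "seps.fasta"),
                  file.path(outdir, "sep_provenance.tsv"))
  write_curation_report(report, outdir)
  write_quant_results(quant, sim$intensities, outdir)
  list(sim = sim, db = db, mapping = mapping, psms = psms,
       report = report, quant = quant)
}
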