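#' Synthetic-data configuration
#'
#' One object holds every knob of the synthetic world: stranded
#' transcripts carrying planted sORFs with an AUG/GUG/UUG start-codon
#' mixture, spectra with partial b/y coverage and controlled precursor
#' ppm error, a PSM table with planted curation violations, an annotated
#' proteome in which a fraction of planted SEPs is embedded (so the
#' novelty screen has both classes), and 3-vs-3 log-normal intensity
#' matrices with planted fold changes. Defaults reflect the emulated
#' study design: start-codon mixture 44/22/34 (ATG/GTG/TTG, the observed
#' AUG and GUG shares with the remainder on UUG), sORFs of 8-100 aa,
#' three replicates per group, and a 4-fold planted effect at 10% CV.
#'
#' @param seed integer RNG seed; fixed seed implies byte-identical output
#'   files.
#' @param n_transcripts,transcript_length transcript count and length (nt).
#' @param n_planted_sorfs number of planted sORFs (one per transcript;
#'   must not exceed n_transcripts).
#' @param start_codon_weights named probabilities over ATG/GTG/TTG
#'   (must sum to 1).
#' @param sorf_length_range inclusive amino acid length bounds, within
#'   [8, 100].
#' @param fragment_coverage per-ion emission probability in spectra.
#' @param fragment_jitter_da SD of fragment m/z jitter (clamped to 0.015
#'   Da so every emitted ion stays inside the 0.02 Da match tolerance).
#' @param precursor_ppm_sigma SD of the signed precursor ppm error
#'   (clamped to 1.8 ppm for non-violation spectra).
#' @param noise_peaks noise peaks per spectrum (placed > 0.05 Da from any
#'   theoretical ion so ground truth stays exact).
#' @param n_replicates samples per group (>= 2).
#' @param planted_fc fold change multiplier for planted DE SEPs (> 0).
#' @param cv coefficient of variation of intensities on the natural scale.
#' @param dropout per-cell missingness probability in the intensity
#'   matrix.
#' @param frac_de fraction of SEPs planted as differentially abundant.
#' @param frac_known fraction of planted SEPs embedded in the annotated
#'   proteome (hence not novel).
#' @param n_proteome,proteome_length annotated proteome size.
#' @param frac_low_score,frac_high_ppm,frac_low_run,frac_short_peptide
#'   fractions of PSMs planted to violate each curation rule.
#' @export
sim_config <- function(seed = 1L, n_transcripts = 60L,
                       transcript_length = 600L, n_planted_sorfs = 30L,
                       start_codon_weights = c(ATG = 0.44, GTG = 0.22,
                                               TTG = 0.34),
                       sorf_length_range = c(8L, 100L),
                       fragment_coverage = 0.9,
                       fragment_jitter_da = 0.003,
                       precursor_ppm_sigma = 0.5, noise_peaks = 5L,
                       n_replicates = 3L, planted_fc = 4, cv = 0.1,
                       dropout = 0, frac_de = 0.2, frac_known = 0.2,
                       n_proteome = 15L, proteome_length = 200L,
                       frac_low_score = 0.1, frac_high_ppm = 0.1,
                       frac_low_run = 0.1, frac_short_peptide = 0.05) {
  stopifnot(abs(sum(start_codon_weights) - 1) < 1e-9,
            all(names(start_codon_weights) %in% c("ATG", "GTG", "TTG")),
            sorf_length_range[1] >= 8L, sorf_length_range[2] <= 100L,
            sorf_length_range[1] <= sorf_length_range[2],
            fragment_coverage >= 0, fragment_coverage <= 1,
            dropout >= 0, dropout < 1, frac_de >= 0, frac_de <= 1,
            frac_known >= 0, frac_known <= 1,
            n_replicates >= 2L)
  if (planted_fc <= 0) stop("planted_fc must be > 0", call. = FALSE)
  if (n_planted_sorfs > n_transcripts)
    stop("n_planted_sorfs may not exceed n_transcripts", call. = FALSE)
  as.list(environment())
}

.aa_codons <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      gc <- Biostrings::getGeneticCode("11")
      gc <- gc[gc != "*"]
      tab <<- split(names(gc), unname(gc))
    }
    tab
  }
})

.encode_protein_tail <- function(protein) {
  # codons for residues 2..n (the initiator codon is chosen separately)
  tab <- .aa_codons()
  res <- strsplit(protein, "")[[1]][-1]
  vapply(res, function(a) sample(tab[[a]], 1L), character(1))
}

#' Simulate transcripts with planted sORFs
#'
#' Background sequence is uniform over ACGT (no codon-usage model). Each
#' planted sORF gets a start codon drawn from the configured mixture, a
#' random protein of in-range length, an in-frame stop immediately after,
#' and a guard stop codon immediately upstream of the start so the
#' planted start is guaranteed to be the first start of its inter-stop
#' segment (making every planted protein recoverable by default ORF
#' calling). Background may still contain additional ORFs; the returned
#' ground truth is authoritative for what was planted.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{transcripts} (named character vector) and
#'   \code{truth} (data.frame transcript_id, frame, start, end,
#'   start_codon, protein).
#' @export
simulate_transcripts <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  len <- cfg$transcript_length
  ids <- sprintf("tx%04d", seq_len(n))
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
  names(seqs) <- ids
  truth <- NULL
  rows <- list()
  for (i in seq_len(cfg$n_planted_sorfs)) {
    L <- sample(cfg$sorf_length_range[1]:cfg$sorf_length_range[2], 1L)
    window <- 3L + 3L * L + 3L  # guard stop + ORF + stop
    if (window > len)
      stop(sprintf("transcript %s too short (%d nt) to host a %d aa sORF",
                   ids[i], len, L), call. = FALSE)
    start_codon <- sample(names(cfg$start_codon_weights), 1L,
                          prob = cfg$start_codon_weights)
    protein <- paste(c("M", sample(AA20, L - 1L, replace = TRUE)),
                     collapse = "")
    insert <- paste(c(sample(STOP_CODONS, 1L), start_codon,
                      .encode_protein_tail(protein),
                      sample(STOP_CODONS, 1L)), collapse = "")
    # any offset is valid: the reading frame is simply g mod 3
    g <- sample(0:(len - window), 1L)
    s <- g + 3L
    substr(seqs[i], g + 1L, g + window) <- insert
    rows[[i]] <- data.frame(transcript_id = ids[i], frame = s %% 3L,
                            start = s, end = s + 3L * L,
                            start_codon = start_codon, protein = protein,
                            stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), frame = integer(0),
               start = integer(0), end = integer(0),
               start_codon = character(0), protein = character(0))
  list(transcripts = seqs, truth = truth)
}

#' Simulate an annotated proteome embedding a subset of planted SEPs
#'
#' Random proteins of roughly \code{proteome_length} residues; a fraction
#' \code{frac_known} of the planted SEPs is embedded verbatim inside host
#' proteins so the novelty screen sees true known proteins.
#'
#' @param planted data.frame from \code{\link{simulate_transcripts}}
#'   truth (uses the protein column).
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{proteome} (named character vector),
#'   \code{known_idx} (indices into \code{planted} of embedded SEPs).
#' @export
simulate_proteome <- function(planted, cfg = sim_config()) {
  set.seed(cfg$seed + 101L)
  n <- cfg$n_proteome
  prots <- vapply(seq_len(n), function(i)
    paste(sample(AA20, cfg$proteome_length, replace = TRUE), collapse = ""),
    character(1))
  names(prots) <- sprintf("annot%04d", seq_len(n))
  n_known <- floor(cfg$frac_known * nrow(planted))
  known_idx <- if (n_known > 0)
    sort(sample(seq_len(nrow(planted)), n_known)) else integer(0)
  for (j in seq_along(known_idx)) {
    host <- 1L + (j - 1L) %% n
    sep <- planted$protein[known_idx[j]]
    at <- sample(seq_len(nchar(prots[host]) - 1L), 1L)
    prots[host] <- paste0(substr(prots[host], 1L, at), sep,
                          substr(prots[host], at + 1L, nchar(prots[host])))
  }
  list(proteome = prots, known_idx = known_idx)
}

.longest_run_from_mask <- function(series, index, included) {
  run_of <- function(idx) {
    idx <- sort(idx)
    if (!length(idx)) return(0L)
    breaks <- c(0L, which(diff(idx) != 1L), length(idx))
    max(diff(breaks))
  }
  max(run_of(index[included & series == "b"]),
      run_of(index[included & series == "y"]))
}

#' Simulate annotated MS/MS spectra for a peptide table
#'
#' Each peptide yields one spectrum: theoretical singly charged b/y ions
#' are emitted independently with probability \code{fragment_coverage},
#' jittered by clamped Gaussian noise inside the 0.02 Da fragment
#' tolerance, and mixed with noise peaks placed at least 0.05 Da from
#' every theoretical ion. Ions whose theoretical m/z lies within 0.05 Da
#' of another theoretical ion are never emitted, so the emitted ladder is
#' unambiguous and the stored ground-truth run length is exactly
#' recoverable by re-annotation. Rows flagged \code{low_run} get an
#' alternating-index ladder (run length 1). The precursor m/z encodes a
#' signed ppm error: clamped N(0, precursor_ppm_sigma) normally, or a
#' planted 3-8 ppm violation for rows flagged \code{high_ppm}.
#'
#' @param peptable data.frame with columns peptide, sep_id, charge and
#'   logical columns low_run, high_ppm (missing flags default to FALSE).
#' @param cfg a \code{\link{sim_config}}.
#' @return list: \code{spectra} (list of \code{\link{spectrum}}),
#'   \code{truth} (spectrum_id, peptide, sep_id, charge, true_run,
#'   true_ppm).
#' @export
simulate_spectra <- function(peptable, cfg = sim_config()) {
  if (!nrow(peptable)) stop("peptide table is empty", call. = FALSE)
  if (any(!nzchar(peptable$peptide)))
    stop("empty peptide sequence", call. = FALSE)
  if (is.null(peptable$low_run)) peptable$low_run <- FALSE
  if (is.null(peptable$high_ppm)) peptable$high_ppm <- FALSE
  if (is.null(peptable$charge)) peptable$charge <- 2L
  if (any(peptable$charge < 1L)) stop("charges must be >= 1", call. = FALSE)
  set.seed(cfg$seed + 202L)
  spectra <- vector("list", nrow(peptable))
  truth <- vector("list", nrow(peptable))
  for (i in seq_len(nrow(peptable))) {
    pep <- modified_peptide(peptable$peptide[i])
    z <- as.integer(peptable$charge[i])
    theo <- theoretical_ions(pep)
    nt <- nrow(theo)
    # ambiguous ions (too close to another theoretical ion) are never emitted
    d <- abs(outer(theo$theoretical_mz, theo$theoretical_mz, "-"))
    diag(d) <- Inf
    ambiguous <- apply(d, 1L, min) < 0.05
    if (peptable$low_run[i]) {
      included <- theo$index %% 2L == 1L
    } else {
      included <- stats::runif(nt) < cfg$fragment_coverage
    }
    included <- included & !ambiguous
    jitter <- pmin(pmax(stats::rnorm(nt, 0, cfg$fragment_jitter_da),
                        -0.015), 0.015)
    mz <- theo$theoretical_mz[included] + jitter[included]
    intensity <- stats::runif(sum(included), 0.2, 1) * 1e5
    # noise peaks, rejected near any theoretical ion
    if (cfg$noise_peaks > 0) {
      lo <- 100; hi <- max(theo$theoretical_mz) * 1.05 + 50
      noise <- numeric(0)
      while (length(noise) < cfg$noise_peaks) {
        cand <- stats::runif(cfg$noise_peaks, lo, hi)
        ok <- vapply(cand, function(x)
          min(abs(x - theo$theoretical_mz)) > 0.05, logical(1))
        noise <- c(noise, cand[ok])
      }
      noise <- noise[seq_len(cfg$noise_peaks)]
      mz <- c(mz, noise)
      intensity <- c(intensity, stats::runif(cfg$noise_peaks, 0.01, 0.1) * 1e5)
    }
    ppm <- if (peptable$high_ppm[i]) {
      sample(c(-1, 1), 1L) * stats::runif(1L, 3, 8)
    } else {
      pmin(pmax(stats::rnorm(1L, 0, cfg$precursor_ppm_sigma), -1.8), 1.8)
    }
    mass <- peptide_mass(pep) * (1 + ppm * 1e-6)
    pre_mz <- (mass + z * MASS_PROTON) / z
    sid <- sprintf("scan%05d", i)
    spectra[[i]] <- spectrum(sid, pre_mz, z, mz, intensity)
    truth[[i]] <- data.frame(
      spectrum_id = sid, peptide = peptable$peptide[i],
      sep_id = peptable$sep_id[i], charge = z,
      true_run = .longest_run_from_mask(theo$series, theo$index, included),
      true_ppm = ppm, stringsAsFactors = FALSE)
  }
  names(spectra) <- vapply(spectra, `[[`, character(1), "spectrum_id")
  list(spectra = spectra, truth = do.call(rbind, truth))
}

#' Simulate a search-engine PSM table with planted violations
#'
#' Scores for ordinary rows are drawn uniform on [30, 60] (all passing the
#' score > 20 rule); rows flagged \code{low_score} get uniform [5, 15].
#' The returned truth records, per PSM, whether each curation rule is
#' satisfied given the realized peptide length, run length, ppm error and
#' score.
#'
#' @param spectrum_truth truth data.frame from
#'   \code{\link{simulate_spectra}}.
#' @param cfg a \code{\link{sim_config}}.
#' @param low_score logical vector (length nrow) flagging planted
#'   sub-threshold scores; when NULL, drawn with cfg$frac_low_score.
#' @param thresholds \code{\link{curation_thresholds}} used to record the
#'   expected pass flags.
#' @return list: \code{psms} (spectrum_id, peptide, charge, modifications,
#'   score, precursor_mz, sep_id), \code{truth} (per-PSM rule flags and
#'   expected pass).
#' @export
simulate_psm_table <- function(spectrum_truth, cfg = sim_config(),
                               low_score = NULL,
                               thresholds = curation_thresholds()) {
  set.seed(cfg$seed + 303L)
  n <- nrow(spectrum_truth)
  if (is.null(low_score))
    low_score <- stats::runif(n) < cfg$frac_low_score
  score <- ifelse(low_score, stats::runif(n, 5, 15), stats::runif(n, 30, 60))
  pre_mz <- vapply(seq_len(n), function(i) {
    mass <- peptide_mass(spectrum_truth$peptide[i]) *
      (1 + spectrum_truth$true_ppm[i] * 1e-6)
    (mass + spectrum_truth$charge[i] * MASS_PROTON) / spectrum_truth$charge[i]
  }, numeric(1))
  psms <- data.frame(
    spectrum_id = spectrum_truth$spectrum_id,
    peptide = spectrum_truth$peptide,
    charge = spectrum_truth$charge,
    modifications = ifelse(grepl("C", spectrum_truth$peptide),
                           "carbamidomethyl-C", ""),
    score = round(score, 2), precursor_mz = pre_mz,
    sep_id = spectrum_truth$sep_id, stringsAsFactors = FALSE)
  tr <- data.frame(
    spectrum_id = spectrum_truth$spectrum_id,
    sep_id = spectrum_truth$sep_id,
    len_ok = nchar(spectrum_truth$peptide) >= thresholds$min_peptide_len,
    run_ok = spectrum_truth$true_run >= thresholds$min_consecutive_ions,
    ppm_ok = abs(spectrum_truth$true_ppm) < thresholds$max_abs_ppm,
    score_ok = psms$score > thresholds$min_score,
    stringsAsFactors = FALSE)
  tr$pass <- tr$len_ok & tr$run_ok & tr$ppm_ok & tr$score_ok
  list(psms = psms, truth = tr)
}

#' Simulate a log-normal SEP intensity matrix with planted fold changes
#'
#' Intensities are log-normal around per-SEP baselines (log2 means uniform
#' on [18, 26]) with the log-scale SD implied by the configured natural-
#' scale CV. Planted differentially abundant SEPs have their treatment
#' mean multiplied by \code{planted_fc}; null SEPs share group means.
#' Optional per-cell dropout sets values to NA.
#'
#' @param n_seps number of SEP rows.
#' @param cfg a \code{\link{sim_config}}.
#' @param sep_ids optional row names (default SEP000001...).
#' @param de_idx optional integer indices of planted DE rows; drawn with
#'   cfg$frac_de when NULL.
#' @return list: \code{matrix} (n_seps x 2*n_replicates, treatment columns
#'   first), \code{groups}, \code{truth} (sep_id, true_fc).
#' @export
simulate_abundance <- function(n_seps, cfg = sim_config(), sep_ids = NULL,
                               de_idx = NULL) {
  if (cfg$planted_fc <= 0) stop("planted_fc must be > 0", call. = FALSE)
  if (cfg$n_replicates < 2L) stop("need >= 2 replicates", call. = FALSE)
  set.seed(cfg$seed + 404L)
  if (is.null(sep_ids)) sep_ids <- sprintf("SEP%06d", seq_len(n_seps))
  if (is.null(de_idx)) {
    n_de <- round(cfg$frac_de * n_seps)
    de_idx <- if (n_de > 0) sort(sample(seq_len(n_seps), n_de)) else integer(0)
  }
  sigma_log2 <- sqrt(log(1 + cfg$cv^2)) / log(2)
  mu <- stats::runif(n_seps, 18, 26)
  r <- cfg$n_replicates
  fc <- rep(1, n_seps)
  fc[de_idx] <- cfg$planted_fc
  treat <- matrix(2^(stats::rnorm(n_seps * r, mean = rep(mu + log2(fc), r),
                                  sd = sigma_log2)), nrow = n_seps)
  ctrl <- matrix(2^(stats::rnorm(n_seps * r, mean = rep(mu, r),
                                 sd = sigma_log2)), nrow = n_seps)
  m <- cbind(treat, ctrl)
  dimnames(m) <- list(sep_ids,
                      c(sprintf("treatment_%d", seq_len(r)),
                        sprintf("control_%d", seq_len(r))))
  if (cfg$dropout > 0)
    m[matrix(stats::runif(length(m)) < cfg$dropout, nrow = n_seps)] <- NA
  list(matrix = m,
       groups = rep(c("treatment", "control"), each = r),
       truth = data.frame(sep_id = sep_ids, true_fc = fc,
                          stringsAsFactors = FALSE))
}

#' Select evidence peptides and violation flags for the planted SEPs
#'
#' Tryptic digestion (0 missed cleavages) of each planted protein; up to
#' \code{per_sep} products of 7-30 aa become PSM rows. Additional short
#' (5-6 aa) peptides and low-run flags are planted per the configured
#' violation fractions; each row carries at most one planted violation.
#'
#' @param planted truth data.frame from \code{\link{simulate_transcripts}}.
#' @param cfg a \code{\link{sim_config}}.
#' @param per_sep evidence peptides per SEP (default 2).
#' @return data.frame: peptide, sep_id, charge, low_run, high_ppm,
#'   short_peptide.
#' @export
select_evidence_peptides <- function(planted, cfg = sim_config(),
                                     per_sep = 2L) {
  set.seed(cfg$seed + 505L)
  rows <- list()
  for (i in seq_len(nrow(planted))) {
    prod <- digest(planted$protein[i], "trypsin", max_missed = 0L)
    ok <- prod$peptide[nchar(prod$peptide) >= 7L & nchar(prod$peptide) <= 30L]
    ok <- unique(ok)
    if (!length(ok)) next
    take <- ok[seq_len(min(per_sep, length(ok)))]
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = take, sep_id = planted$sep_id[i] %||% planted$protein[i],
      stringsAsFactors = FALSE)
  }
  pt <- do.call(rbind, rows)
  n <- nrow(pt)
  pt$charge <- 2L
  # at most one planted violation per row
  u <- stats::runif(n)
  pt$low_run <- u < cfg$frac_low_run
  pt$high_ppm <- u >= cfg$frac_low_run &
    u < cfg$frac_low_run + cfg$frac_high_ppm
  pt$short_peptide <- FALSE
  n_short <- round(cfg$frac_short_peptide * n)
  if (n_short > 0) {
    src <- sample(seq_len(n), n_short)
    short <- data.frame(
      peptide = vapply(pt$peptide[src], function(p)
        substr(p, 1L, sample(5:6, 1L)), character(1)),
      sep_id = pt$sep_id[src], charge = 2L, low_run = FALSE,
      high_ppm = FALSE, short_peptide = TRUE, stringsAsFactors = FALSE)
    pt <- rbind(pt, short)
  }
  rownames(pt) <- NULL
  pt
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-data generator and write all pipeline inputs
#'
#' Writes transcripts.fasta, proteome.fasta, spectra.mgf, psms.tsv,
#' intensities.tsv and truth.json under \code{outdir}. With a fixed seed
#' the outputs are byte-identical across runs.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param outdir output directory (created).
#' @return (invisibly) a list with all in-memory objects and the ground
#'   truth.
#' @export
full_simulation <- function(cfg = sim_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tx <- simulate_transcripts(cfg)
  planted <- tx$truth
  planted$sep_id <- sprintf("sorf%03d", seq_len(nrow(planted)))
  prot <- simulate_proteome(planted, cfg)
  peptable <- select_evidence_peptides(planted, cfg)
  spec <- simulate_spectra(peptable, cfg)
  psm <- simulate_psm_table(spec$truth, cfg)
  n_seps <- nrow(planted)
  abun <- simulate_abundance(n_seps, cfg, sep_ids = planted$sep_id)

  write_fasta(tx$transcripts, file.path(outdir, "transcripts.fasta"))
  write_fasta(prot$proteome, file.path(outdir, "proteome.fasta"))
  write_mgf(spec$spectra, file.path(outdir, "spectra.mgf"))
  utils::write.table(psm$psms, file.path(outdir, "psms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  im <- cbind(sep_id = rownames(abun$matrix), as.data.frame(abun$matrix))
  utils::write.table(im, file.path(outdir, "intensities.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    config = cfg[setdiff(names(cfg), "start_codon_weights")],
    start_codon_weights = as.list(cfg$start_codon_weights),
    planted_sorfs = planted,
    known_sep_ids = planted$sep_id[prot$known_idx],
    spectrum_truth = spec$truth,
    psm_truth = psm$truth,
    abundance_truth = abun$truth,
    groups = abun$groups)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(truth, list(transcripts = tx$transcripts,
                          proteome = prot$proteome,
                          spectra = spec$spectra, psms = psm$psms,
                          intensities = abun$matrix)))
}
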