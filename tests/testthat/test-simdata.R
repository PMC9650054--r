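test_that("sim_config validates its invariants", {
  expect_error(sim_config(start_codon_weights = c(ATG = 0.5, GTG = 0.2,
                                                  TTG = 0.2)))
  expect_error(sim_config(sorf_length_range = c(5, 50)))
  expect_error(sim_config(planted_fc = 0), "planted_fc")
  expect_error(sim_config(n_planted_sorfs = 10, n_transcripts = 5),
               "exceed")
})

test_that("planted sORFs obey the configured lengths and start codons", {
  cfg <- sim_config(seed = 1, n_transcripts = 10, n_planted_sorfs = 10,
                    sorf_length_range = c(8, 30))
  sim <- simulate_transcripts(cfg)
  expect_equal(nrow(sim$truth), 10L)
  expect_true(all(nchar(sim$truth$protein) >= 8 &
                    nchar(sim$truth$protein) <= 30))
  # degenerate mixture: all ATG
  cfg2 <- sim_config(seed = 2, n_transcripts = 10, n_planted_sorfs = 10,
                     start_codon_weights = c(ATG = 1, GTG = 0, TTG = 0))
  sim2 <- simulate_transcripts(cfg2)
  expect_true(all(sim2$truth$start_codon == "ATG"))
  # coordinates point at real start codons in the emitted sequence
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$transcripts[[sim$truth$transcript_id[i]]]
    s <- sim$truth$start[i]
    expect_equal(substr(tr, s + 1, s + 3), sim$truth$start_codon[i])
    expect_equal(sim$truth$frame[i], s %% 3)
  }
  # sizing error names the transcript
  expect_error(simulate_transcripts(
    sim_config(seed = 3, transcript_length = 100,
               sorf_length_range = c(50, 100))), "tx0001")
})

test_that("fixed seed gives byte-identical output files", {
  cfg <- sim_config(seed = 7, n_transcripts = 8, n_planted_sorfs = 8,
                    n_proteome = 3)
  d1 <- tempfile(); d2 <- tempfile()
  full_simulation(cfg, d1)
  full_simulation(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("spectrum coverage extremes give the stated truths", {
  peptable <- data.frame(peptide = c("SAMPLEK", "ELTMATER"),
                         sep_id = c("a", "b"), charge = 2L,
                         stringsAsFactors = FALSE)
  full <- simulate_spectra(peptable,
                           sim_config(fragment_coverage = 1, noise_peaks = 0))
  # full coverage: truth run = len - 1 and every theoretical ion present
  expect_equal(full$truth$true_run, nchar(peptable$peptide) - 1L)
  for (i in 1:2) {
    ann <- match_spectrum(modified_peptide(peptable$peptide[i]),
                          full$spectra[[i]])
    expect_true(all(!is.na(ann$observed_mz)))
  }
  none <- simulate_spectra(peptable,
                           sim_config(fragment_coverage = 0, noise_peaks = 3))
  expect_equal(none$truth$true_run, c(0L, 0L))
  expect_equal(lengths(lapply(none$spectra, `[[`, "mz")),
               c(scan00001 = 3L, scan00002 = 3L))
  expect_error(simulate_spectra(peptable[0, ]), "empty")
})

test_that("realized run lengths equal an independent recount from peaks", {
  set.seed(61)
  peptable <- data.frame(
    peptide = vapply(sample(7:20, 40, TRUE), random_protein, character(1)),
    sep_id = "x", charge = 2L, stringsAsFactors = FALSE)
  out <- simulate_spectra(peptable, sim_config(seed = 8,
                                               fragment_coverage = 0.6))
  for (i in seq_len(nrow(peptable))) {
    theo <- theoretical_ions(peptable$peptide[i])
    near <- vapply(theo$theoretical_mz, function(t)
      any(abs(out$spectra[[i]]$mz - t) <= 0.02), logical(1))
    recount <- oracle_run(theo$index[near & theo$series == "b"],
                          theo$index[near & theo$series == "y"])
    expect_equal(out$truth$true_run[i], recount, label = peptable$peptide[i])
  }
})

test_that("planted precursor ppm errors are recoverable exactly", {
  peptable <- data.frame(peptide = rep("SAMPLEKWR", 6), sep_id = "x",
                         charge = 2L, low_run = FALSE,
                         high_ppm = c(rep(FALSE, 3), rep(TRUE, 3)),
                         stringsAsFactors = FALSE)
  out <- simulate_spectra(peptable, sim_config(seed = 12))
  for (i in 1:6) {
    ppm <- precursor_ppm_error(modified_peptide("SAMPLEKWR"),
                               out$spectra[[i]])
    expect_equal(ppm, out$truth$true_ppm[i], tolerance = 1e-6)
  }
  expect_true(all(abs(out$truth$true_ppm[1:3]) < 2))
  expect_true(all(abs(out$truth$true_ppm[4:6]) > 2))
})

test_that("psm table plants score violations and records rule flags", {
  peptable <- data.frame(peptide = rep("SAMPLEKWR", 20), sep_id = "x",
                         charge = 2L, stringsAsFactors = FALSE)
  spec <- simulate_spectra(peptable, sim_config(seed = 13))
  low <- rep(c(TRUE, FALSE), 10)
  psm <- simulate_psm_table(spec$truth, sim_config(seed = 13),
                            low_score = low)
  expect_identical(psm$truth$score_ok, !low)
  expect_true(all(psm$psms$score[low] < 20))
  expect_true(all(psm$psms$score[!low] > 20))
  # all-benign table passes curation entirely
  spec2 <- simulate_spectra(
    data.frame(peptide = rep("SAMPLEKWR", 5), sep_id = "x", charge = 2L),
    sim_config(seed = 14, fragment_coverage = 1, noise_peaks = 0))
  psm2 <- simulate_psm_table(spec2$truth, sim_config(seed = 14),
                             low_score = rep(FALSE, 5))
  expect_true(all(psm2$truth$pass))
})

test_that("abundance matrices have the stated shape and effects", {
  cfg <- sim_config(seed = 15, n_replicates = 3, planted_fc = 4, cv = 0.1)
  ab <- simulate_abundance(50, cfg)
  expect_equal(dim(ab$matrix), c(50L, 6L))
  expect_equal(ab$groups, rep(c("treatment", "control"), each = 3))
  de <- ab$truth$true_fc > 1
  # planted empirical FC within [3, 5] at cv = 0.1, n = 3
  fc <- rowMeans(ab$matrix[de, 1:3]) / rowMeans(ab$matrix[de, 4:6])
  expect_true(all(fc > 3 & fc < 5))
  # dropout produces missing cells
  ab2 <- simulate_abundance(50, sim_config(seed = 16, dropout = 0.2))
  expect_gt(sum(is.na(ab2$matrix)), 0)
})

test_that("full_simulation writes every pipeline input plus truth", {
  d <- tempfile()
  cfg <- sim_config(seed = 17, n_transcripts = 8, n_planted_sorfs = 8,
                    n_proteome = 3)
  sim <- full_simulation(cfg, d)
  expect_setequal(list.files(d),
                  c("transcripts.fasta", "proteome.fasta", "spectra.mgf",
                    "psms.tsv", "intensities.tsv", "truth.json"))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth$planted_sorfs), 8L)
  # every planted item refers to an emitted record
  tx <- read_fasta(file.path(d, "transcripts.fasta"))
  expect_true(all(truth$planted_sorfs$transcript_id %in% names(tx)))
  psms <- read.delim(file.path(d, "psms.tsv"))
  expect_true(all(truth$psm_truth$spectrum_id %in% psms$spectrum_id))
  expect_true(all(truth$spectrum_truth$sep_id %in%
                    truth$planted_sorfs$sep_id))
})
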