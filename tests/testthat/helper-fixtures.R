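# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

# default-configuration end-to-end pipeline run (seed 1)
pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipeline)) {
    .fixture_env$pipeline <- run_pipeline(sim_config(seed = 1L),
                                          outdir = tempfile("pipefix"))
  }
  .fixture_env$pipeline
}

# the planted SEPs expected to survive curation: novel per ground truth,
# with >= 1 PSM passing every rule whose peptide maps uniquely to the
# SEP's database entry (mapping comes from the digest module, which is
# validated against its own brute-force oracle elsewhere)
expected_final_sepome <- function(res) {
  truth <- res$sim
  planted <- truth$planted_sorfs
  novel <- setdiff(planted$sep_id, truth$known_sep_ids)
  dbid <- res$db$entries$sep_id[match(planted$protein,
                                      res$db$entries$protein)]
  names(dbid) <- planted$sep_id
  psms <- merge(truth$psms,
                truth$psm_truth[, c("spectrum_id", "pass")],
                by = "spectrum_id")
  umap <- res$mapping[res$mapping$unique, ]
  out <- character(0)
  for (sid in novel) {
    peps <- psms$peptide[psms$sep_id == sid & psms$pass]
    if (any(peps %in% umap$peptide[umap$sep_id == dbid[[sid]]]))
      out <- c(out, dbid[[sid]])
  }
  sort(out)
}
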