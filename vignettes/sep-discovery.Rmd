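---
title: "Discovering sORF-encoded peptides: models, filters and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sORF-encoded peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepomics)
```

## The problem

Small open reading frames (sORFs, conventionally under 100 codons) are
systematically missed by genome annotation length cutoffs, yet many are
translated into functional peptides (SEPs). Proteogenomic discovery
couples a transcriptome-derived custom database to peptidomic mass
spectrometry: candidate SEPs are predicted from transcripts, spectra are
searched against the candidate database, and the resulting
peptide-spectrum matches (PSMs) are curated to remove weak matches and
fragments of already-annotated proteins. `sepomics` implements this
prediction / discovery-support / curation workflow plus label-free
differential abundance, and pairs it with a synthetic-data generator that
carries machine-readable ground truth, so every stage can be tested
end-to-end against planted answers.

## Prediction: ORF calling and the candidate database

Transcripts are scanned in the three forward frames (assembled
transcripts are stranded; a `six_frame` flag exists for genome input but
is off by default). Within a frame, the sequence is partitioned by
in-frame stop codons (TAA/TAG/TGA; bacterial code, table 11). In each
inter-stop segment the *first* configured start codon opens the reported
ORF; downstream in-segment starts are reported only with
`emit_nested_starts = TRUE`, because the one-ORF-per-segment (longest)
convention is what `getorf`-style callers produce by default. ORFs
truncated by the transcript end (no downstream stop) are dropped: a
candidate requires both a start and a stop.

Bacterial sORFs initiate frequently at GUG and UUG, so the default start
set is {ATG, GTG, TTG}. The initiator is rendered as methionine
regardless of codon (initiator-tRNA convention) unless
`translate_start_as_met = FALSE`; the choice is a flag because literal
translation is also defensible. Codons containing N never act as starts
or stops and translate to X.

`build_database()` keeps ORFs of 8–100 amino acids (inclusive on both
ends), merges exact duplicate proteins into one entry with merged
provenance, and assigns `SEP000001`-style identifiers in lexicographic
protein order so that reruns are diffable. Identical proteins arising
from different transcripts are one entry with multi-record provenance;
`start_codon_summary()` attributes one start codon per SEP, that of its
first provenance record (ordered by transcript id, then offset).

## Digestion

Six proteases are modelled, with standard specificities: trypsin
(C-terminal to K/R, not before P), ArgC (C-terminal to R, not before P),
LysC (C-terminal to K), LysN (N-terminal to K), chymotrypsin (C-terminal
to F/W/Y/L, not before P), and *mirror-trypsin*, modelled as the
N-terminal mirror of trypsin (cleaves before K/R). Mirror-trypsin is
nonstandard nomenclature; the rule is a named, swappable entry in
`protease_rule()` should the reagent turn out to differ. Digestion
enumerates every peptide bounded by termini or cleavage sites spanning at
most `max_missed` internal sites (default 2). At zero missed cleavages
the products tile the protein exactly — a property the tests assert.
N-terminal Met clipping and semi-specific cleavage are not modelled.

A peptide is *unique* if it arises as a valid digest product of exactly
one database entry (`map_peptides_to_seps()`); uniqueness is what lets a
peptide count as evidence for a specific SEP.

## Fragment ions and mass arithmetic

Neutral peptide mass is the sum of monoisotopic residue masses plus
modification deltas plus one water. The fixed modification is
carbamidomethyl-C (+57.02146 Da, applied automatically whenever C
occurs); the variable modification is Met oxidation (+15.99491 Da).
Singly protonated b and y ions are

$$b_i = \sum_{k \le i} m_k + m_{H^+},\qquad
  y_i = \sum_{k > n-i} m_k + m_{H_2O} + m_{H^+},$$

which satisfy the complementarity identity
$b_i + y_{n-i} = M + 2\,m_{H^+}$ exactly; the tests assert it to
$10^{-9}$ Da on random modified peptides. Only 1+ fragments are generated
by default (the curation rule references b/y ions without charge
qualification); no neutral losses, a/c/x/z ions or isotope peaks.

Matching assigns each theoretical ion the nearest peak within the
fragment tolerance (default 0.02 Da), breaking distance ties toward the
higher-intensity peak, deterministically. The precursor error is the
signed relative deviation
$\mathrm{ppm} = (M_\mathrm{obs} - M_\mathrm{theo})/M_\mathrm{theo}\times 10^6$
with $M_\mathrm{obs} = z\,(m/z) - z\,m_{H^+}$.

`longest_consecutive_run()` counts the longest run of consecutive
matched indices *within* the b series and within the y series, and takes
the maximum — the stricter of the two readings of "consecutive b/y
ions"; `combined = TRUE` merges the ladders first, for the looser
reading.

## Curation

The PSM funnel applies four rules as a conjunction (so the pass set is
order-invariant; the *first* failing rule in the fixed order
length → run → ppm → score is recorded for accounting):

| rule | default | boundary |
|---|---|---|
| peptide length | ≥ 7 aa | inclusive |
| consecutive b/y run | ≥ 4 | inclusive |
| abs. precursor error | < 2 ppm | strict |
| search score | > 20 | strict |

The length and run bounds are inclusive and the ppm/score bounds strict
because that is the only reading consistent with both phrasings of the
criteria the thresholds come from. The search score is consumed as given
(a −10lgP-style engine score); it is never recomputed, and the upstream
1% FDR is treated as a documented property of the input table.

Novelty screening replaces an irreproducible, version-dependent BLAST-
against-nr step with a local alignment against a user-supplied annotated
proteome. A SEP `matches_annotated` if any supporting peptide (or the SEP
itself) is an exact substring of an annotated protein, or if
Smith–Waterman alignment (BLOSUM62, affine gaps costing
$11 + L$ for a gap of length $L$, deterministic traceback preferring
diagonal, then up, then left) reaches ≥ 90% identity over an aligned
query span covering ≥ 80% of the SEP. The 90/80 thresholds are not from
the source workflow (which used nr BLAST); they are configuration values
surfaced in the report. A shared-4-mer prefilter skips hopeless
alignments; at the default thresholds it is provably exact, because any
alignment with ≥ 90% identity over ≥ 7 aligned columns must contain a run
of ≥ 4 consecutive identical residues (for spans below 10 columns the
integer-ceiling on matches forces perfect identity). Lowering the
thresholds substantially can break that guarantee, so `k = NULL`
disables the prefilter.

`assemble_sepome()` fixes the stage order: database hit → known-protein
removal → PSM filters → uniqueness → final. Candidacy is derived from the
digest-module mapping (which entries could have produced each observed
peptide), not from identifiers carried in the PSM table; that keeps
candidacy and uniqueness mutually consistent. A SEP survives iff it is
novel and has at least one passing PSM whose peptide maps uniquely to it.
Funnel counts are monotone non-increasing by construction and the tests
assert it.

## Quantification

Differential abundance uses Student's two-sample t-test with pooled
variance on log2 intensities (log transformation for variance
stabilization — the upstream description names the test but not the
scale; Welch's form is a flag), Benjamini–Hochberg adjustment over the
tested set, and classification: *up* iff fold change > 2 and adjusted
p < 0.05, *down* iff fold change < 0.5 and adjusted p < 0.05. Fold
change is the ratio of raw group means reported as log2 (mean-of-raw
versus median, and raw versus log means, were open choices; this one is
documented here and tested). Missing values are not imputed: a SEP with
fewer than two non-missing values in either group is reported untested
rather than guessed at. `row_zscore()` provides the raw z-scores used
for heatmaps ((x − mean)/SD per row, sample SD; constant rows return
zeros and a flag), `ddct()` implements 2^−ΔΔCt relative qPCR
quantification against a reference gene, and `gravy()` the Kyte–Doolittle
grand average of hydropathy (hydrophobic iff > 0).

## The synthetic world

`sim_config()` states the world once; generators derive fixed seeds from
it (`seed`, `seed+101`, `+202`, `+303`, `+404`, `+505` for transcripts,
proteome, spectra, PSM table, abundance, peptide selection), so a fixed
seed yields byte-identical output files.

*Transcripts.* Background is uniform ACGT (no codon-usage model — it is
not needed to test the pipeline). Each planted sORF draws its start codon
from the configured mixture (default ATG .44 / GTG .22 / TTG .34 — the
observed AUG/GUG shares with the remainder on UUG, renormalised over the
three modelled codons), a length uniform on 8–100 aa, and a uniform
placement; an in-frame *guard stop* is written immediately upstream of
the start so the planted start is guaranteed first in its segment, hence
recoverable by default ORF calling. Background ORFs arise freely; ground
truth records what was planted and is authoritative.

*Spectra.* Theoretical b/y ions are emitted independently with
probability `fragment_coverage` (default 0.9), with three guarantees
that make the stored truth *exactly* recoverable by re-annotation:
fragment jitter is clamped to ±0.015 Da (inside the 0.02 Da tolerance);
noise peaks are rejection-sampled more than 0.05 Da from every
theoretical ion; and theoretical ions closer than 0.05 Da to one another
are never emitted (otherwise one peak could legally match two ladder
positions and an honest recount could differ from the truth). Rows
planted as run-violations get an alternating-index ladder (run length 1).
Precursor ppm errors are clamped N(0, 0.5 ppm) normally and a planted
±(3–8) ppm for violation rows. One spectrum per peptide, 1+ fragments,
2+ precursors — the minimal faithful surface; no retention time, isotope
envelopes or decoys.

*PSM table.* Scores are uniform on [30, 60] (passing) or [5, 15]
(planted violations). Each PSM carries at most one planted violation so
per-rule attribution is testable. The truth records, per PSM, whether
each rule is satisfied given the realized length/run/ppm/score.

*Proteome.* Random proteins of ~200 aa; a fraction (default 20%) of
planted SEPs is embedded verbatim in host proteins so the novelty screen
sees both classes.

*Abundance.* Log-normal intensities: baselines log2-uniform on [18, 26]
(a typical label-free intensity range), log-scale SD implied by the
natural-scale CV via $\sigma_{\log_2} = \sqrt{\log(1+cv^2)}/\log 2$.
Planted DE SEPs have the treatment mean multiplied by `planted_fc`
(default 4 at CV 0.1 with 3 replicates per group — the stated power-check
world); null SEPs share group means. Dropout is a per-cell probability
(default 0) so the missing-data policy is testable. The log-normal/CV
form is an assumption recorded in configuration, not a claim about any
real dataset.

What a green end-to-end test establishes: that the pipeline recovers
exactly the planted novel, evidence-sufficient SEPs under the stated
world. What it does not establish: robustness to chimeric spectra,
co-eluting peptides, real noise structure, retention-time effects,
search-engine scoring behaviour, or non-uniform codon usage — none of
which are modelled.

## Numerical choices and degenerate inputs

- Masses are monoisotopic to 5–6 decimals; complementarity is exact
  because both ladders are cumulative sums of the same residue vector.
- Peak-match ties (equal distance) go to the higher-intensity peak; ties
  in Smith–Waterman traceback prefer diagonal, then up, then left.
- Zero surviving database entries is a warning and an empty database,
  not an error; an empty PSM table yields an all-zero funnel; a constant
  intensity row z-scores to zeros with a flag; a group entirely missing
  is a matrix-level error.
- BH adjustment passes NA p-values through (untested SEPs) and adjusts
  over the tested set only, matching how untested rows are reported.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(sim_config(seed = 1), outdir = tempdir())
res$report$funnel
#>            db_hit     after_novelty after_psm_filters  after_uniqueness
#>                29                24                23                23
#>             final
#>                23
head(res$quant[res$quant$class == "up", c("sep_id", "log2fc", "adj_p")])
```

With seed 1, 30 sORFs are planted; 29 reach the database-hit stage (one
has no tryptic peptide of 7–30 aa and so never acquires spectra), 5 are
embedded in the annotated proteome and removed as known, one loses all
its PSMs to planted violations, and 23 novel SEPs with passing unique
evidence survive — exactly the planted expectation computed from ground
truth.

## Known limitations

- Forward-strand, single-transcript ORF calling; no splice awareness.
- The novelty screen depends on the supplied proteome; it cannot flag
  homology to proteins absent from it (the nr-scale search it replaces
  is out of scope by design; a FASTA export hook exists for external
  BLAST, but pipeline status never depends on it).
- Scores are consumed, never modelled: FDR estimation, rescoring and
  spectral prediction are out of scope.
- The abundance model is i.i.d. log-normal per cell; no sample-level
  batch effects or normalization are simulated (median-centering is
  available but off by default, as no normalization beyond the search
  engine's own is described upstream).
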