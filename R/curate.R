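#' Curation thresholds for the PSM quality funnel
#'
#' Defaults encode the four-rule curation: peptide length >= 7 amino
#' acids, longest consecutive b/y ion run >= 4, absolute precursor error
#' < 2 ppm, search score > 20 (the -10lgP score of the upstream engine is
#' consumed as-is, never recomputed). Length and run are inclusive bounds;
#' ppm and score strict. The upstream 1% FDR is a documented property of
#' the consumed PSM table, not recomputed here.
#'
#' @param min_peptide_len,min_consecutive_ions inclusive minima.
#' @param max_abs_ppm,min_score strict bounds.
#' @param upstream_fdr recorded in reports only.
#' @export
curation_thresholds <- function(min_peptide_len = 7L,
                                min_consecutive_ions = 4L,
                                max_abs_ppm = 2.0, min_score = 20.0,
                                upstream_fdr = 0.01) {
  stopifnot(min_peptide_len > 0, min_consecutive_ions > 0, max_abs_ppm > 0,
            min_score > 0)
  list(min_peptide_len = as.integer(min_peptide_len),
       min_consecutive_ions = as.integer(min_consecutive_ions),
       max_abs_ppm = max_abs_ppm, min_score = min_score,
       upstream_fdr = upstream_fdr)
}

.rule_order <- c("min_peptide_len", "min_consecutive_ions", "max_abs_ppm",
                 "min_score")

#' Apply the PSM-level curation filters
#'
#' A PSM passes iff peptide length >= min_peptide_len AND run_length >=
#' min_consecutive_ions AND |ppm| < max_abs_ppm AND score > min_score.
#' The first violated rule (in the fixed order length, run, ppm, score)
#' is recorded; the pass set itself is order-invariant since the filters
#' are a conjunction.
#'
#' @param psms data.frame with columns peptide, run_length, ppm, score
#'   (and any carry-through columns, e.g. spectrum_id, sep_id).
#' @param thresholds a \code{\link{curation_thresholds}} list.
#' @return the input with added logical column \code{pass} and character
#'   column \code{fail_rule} (NA when passing).
#' @export
filter_psms <- function(psms, thresholds = curation_thresholds()) {
  required <- c("peptide", "run_length", "ppm", "score")
  missing_cols <- setdiff(required, names(psms))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  t <- thresholds
  if (!nrow(psms)) {
    psms$pass <- logical(0)
    psms$fail_rule <- character(0)
    return(psms)
  }
  viol <- cbind(
    min_peptide_len = nchar(psms$peptide) < t$min_peptide_len,
    min_consecutive_ions = psms$run_length < t$min_consecutive_ions,
    max_abs_ppm = abs(psms$ppm) >= t$max_abs_ppm,
    min_score = psms$score <= t$min_score
  )
  first_fail <- apply(viol, 1L, function(v)
    if (any(v)) .rule_order[which(v)[1]] else NA_character_)
  psms$pass <- !apply(viol, 1L, any)
  psms$fail_rule <- first_fail
  psms
}

#' Smith-Waterman local alignment
#'
#' Affine-gap local alignment (BLOSUM62, gap open 11, gap extend 1 by
#' default; a gap of length L costs open + L*extend). Stands in for the
#' BLAST novelty screen against an annotated proteome. Traceback ties
#' prefer diagonal, then up, then left, so results are deterministic.
#'
#' @param query,subject amino acid strings.
#' @param matrix substitution matrix (default \code{BLOSUM62_MATRIX}).
#' @param gap_open,gap_extend affine gap parameters.
#' @return list: score, identity (percent over aligned columns), matches,
#'   aligned_cols, query/subject start/end (1-based, NA when score 0),
#'   query_span, subject_span.
#' @export
local_align <- function(query, subject, matrix = BLOSUM62_MATRIX,
                        gap_open = 11, gap_extend = 1) {
  .check_protein(query)
  .check_protein(subject)
  .sw_align_cpp(query, subject, matrix, rownames(matrix), gap_open,
                gap_extend)
}

.kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1L), k:n))
}

#' Novelty screen against an annotated proteome
#'
#' A SEP candidate is \code{matches_annotated} if (a) any of its
#' supporting peptides is an exact substring of an annotated protein, or
#' (b) the SEP aligns to an annotated protein with percent identity >=
#' \code{identity_threshold} over an aligned query span covering >=
#' \code{coverage_threshold} of the SEP length. Otherwise \code{novel}.
#' A shared-k-mer prefilter (default k = 4) skips alignments that cannot
#' reach the default thresholds; it is exact for the defaults because any
#' qualifying alignment must contain a run of >= 4 identical residues.
#'
#' @param seps named character vector of candidate SEP proteins
#'   (names = sep ids).
#' @param proteome named character vector of annotated proteins.
#' @param supporting_peptides optional data.frame (sep_id, peptide) used
#'   for the exact-substring rule.
#' @param identity_threshold percent identity (default 90).
#' @param coverage_threshold fraction of SEP length (default 0.8).
#' @param k prefilter k-mer size; \code{NULL} disables the prefilter.
#' @return data.frame: sep_id, status, best_identity, best_coverage,
#'   best_subject.
#' @export
novelty_screen <- function(seps, proteome, supporting_peptides = NULL,
                           identity_threshold = 90,
                           coverage_threshold = 0.8, k = 4L) {
  if (!length(proteome)) stop("proteome must be non-empty", call. = FALSE)
  stopifnot(!is.null(names(seps)), !is.null(names(proteome)))
  prot_kmers <- if (!is.null(k))
    lapply(proteome, .kmers, k = as.integer(k)) else NULL
  out <- data.frame(sep_id = names(seps), status = "novel",
                    best_identity = 0, best_coverage = 0,
                    best_subject = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(seps)) {
    sid <- names(seps)[i]; sp <- seps[[i]]
    # (a) exact substring of an annotated protein: SEP itself or peptides
    peps <- sp
    if (!is.null(supporting_peptides)) {
      extra <- supporting_peptides$peptide[supporting_peptides$sep_id == sid]
      peps <- c(peps, extra)
    }
    hit <- FALSE
    for (pep in peps) {
      if (any(vapply(proteome, function(pr) grepl(pep, pr, fixed = TRUE),
                     logical(1)))) { hit <- TRUE; break }
    }
    if (hit) {
      out$status[i] <- "matches_annotated"
      out$best_identity[i] <- 100
      out$best_coverage[i] <- 1
      next
    }
    # (b) alignment screen
    subjects <- names(proteome)
    if (!is.null(prot_kmers)) {
      qk <- .kmers(sp, as.integer(k))
      keep <- vapply(prot_kmers, function(pk) any(qk %in% pk), logical(1))
      subjects <- names(proteome)[keep]
    }
    for (sub in subjects) {
      al <- local_align(sp, proteome[[sub]])
      cov <- al$query_span / nchar(sp)
      if (al$identity > out$best_identity[i] ||
          (al$identity == out$best_identity[i] && cov > out$best_coverage[i])) {
        out$best_identity[i] <- al$identity
        out$best_coverage[i] <- cov
        out$best_subject[i] <- sub
      }
      if (al$identity >= identity_threshold && cov >= coverage_threshold) {
        out$status[i] <- "matches_annotated"
        break
      }
    }
  }
  out
}

#' Assemble the final SEPome through the curation funnel
#'
#' Stage order: database hit (entries supported by any PSM peptide) ->
#' known-protein removal (novelty screen) -> PSM quality filters ->
#' peptide uniqueness -> final SEPome. A SEP survives iff it is novel and
#' has at least one passing PSM whose peptide maps uniquely to it.
#' Candidacy is derived from the peptide-to-database mapping, never from
#' identifiers carried in the PSM table.
#'
#' @param psms data.frame with columns spectrum_id, peptide, run_length,
#'   ppm, score.
#' @param db a \code{SepDatabase}.
#' @param proteome named character vector of annotated proteins.
#' @param thresholds \code{\link{curation_thresholds}}.
#' @param mapping optional precomputed \code{\link{map_peptides_to_seps}}
#'   result; computed from the db when NULL.
#' @param rules protease names for the uniqueness mapping.
#' @param max_missed missed cleavages for the uniqueness mapping.
#' @return a \code{CurationReport}: list with \code{psms} (flagged),
#'   \code{novelty}, \code{funnel} (named counts), \code{sepome}
#'   (data.frame sep_id, protein, n_supporting), \code{evidence} (passing
#'   PSMs joined to their uniquely mapped SEP), \code{parameters}.
#' @export
assemble_sepome <- function(psms, db, proteome,
                            thresholds = curation_thresholds(),
                            mapping = NULL, rules = protease_names(),
                            max_missed = 2L) {
  if (is.null(mapping))
    mapping <- map_peptides_to_seps(unique(psms$peptide), db, rules,
                                    max_missed)
  # stage 1: candidates = entries hit by >= 1 PSM peptide
  candidates <- sort(unique(mapping$sep_id[mapping$peptide %in%
                                             psms$peptide]))
  # stage 2: novelty
  seps <- db$entries$protein[match(candidates, db$entries$sep_id)]
  names(seps) <- candidates
  nov <- if (length(candidates))
    novelty_screen(seps, proteome) else
    data.frame(sep_id = character(0), status = character(0))
  novel_ids <- nov$sep_id[nov$status == "novel"]
  # stage 3: PSM filters
  flagged <- filter_psms(psms, thresholds)
  pass_pep <- unique(flagged$peptide[flagged$pass])
  after_filter <- intersect(novel_ids,
                            unique(mapping$sep_id[mapping$peptide %in%
                                                    pass_pep]))
  # stage 4: uniqueness -- join passing PSMs to their unique mapping
  umap <- mapping[mapping$unique, c("peptide", "sep_id")]
  umap <- umap[!duplicated(umap$peptide), , drop = FALSE]
  evidence <- flagged[flagged$pass & flagged$peptide %in% umap$peptide, ,
                      drop = FALSE]
  evidence$sep_id <- umap$sep_id[match(evidence$peptide, umap$peptide)]
  evidence <- evidence[evidence$sep_id %in% after_filter, , drop = FALSE]
  final_ids <- intersect(after_filter, unique(evidence$sep_id))
  sepome <- data.frame(
    sep_id = final_ids,
    protein = db$entries$protein[match(final_ids, db$entries$sep_id)],
    n_supporting = as.integer(table(evidence$sep_id)[final_ids]),
    stringsAsFactors = FALSE)
  funnel <- c(db_hit = length(candidates),
              after_novelty = length(novel_ids),
              after_psm_filters = length(after_filter),
              after_uniqueness = length(final_ids),
              final = length(final_ids))
  rep <- list(psms = flagged, novelty = nov, funnel = funnel,
              sepome = sepome, evidence = evidence,
              parameters = thresholds)
  class(rep) <- "CurationReport"
  rep
}

#' @export
print.CurationReport <- function(x, ...) {
  cat("CurationReport funnel:\n")
  print(x$funnel)
  cat(sprintf("final SEPome: %d entries\n", nrow(x$sepome)))
  invisible(x)
}

#' Write a curation report to disk
#'
#' Emits curation_report.json (funnel + parameters), sepome.fasta and
#' evidence.tsv under \code{dir}.
#' @param report a \code{CurationReport}.
#' @param dir output directory (created if absent).
#' @export
write_curation_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(funnel = as.list(report$funnel), parameters = report$parameters),
    file.path(dir, "curation_report.json"), auto_unbox = TRUE, digits = NA)
  if (nrow(report$sepome)) {
    seps <- report$sepome$protein
    names(seps) <- report$sepome$sep_id
    write_fasta(seps, file.path(dir, "sepome.fasta"))
  } else writeLines(character(0), file.path(dir, "sepome.fasta"))
  utils::write.table(report$evidence, file.path(dir, "evidence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
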