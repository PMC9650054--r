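#' ORF-calling configuration
#'
#' Controls the prediction step that turns transcripts into candidate
#' sORF-encoded peptides (SEPs). Bacterial sORFs frequently initiate at
#' GTG/TTG in addition to ATG, so all three are enabled by default; the
#' initiator is rendered as methionine (initiator-tRNA convention) unless
#' \code{translate_start_as_met = FALSE}.
#'
#' @param start_codons character vector of allowed start codons
#'   (DNA alphabet; default ATG, GTG, TTG).
#' @param min_len,max_len inclusive protein length bounds in amino acids
#'   applied by \code{\link{build_database}} (defaults 8 and 100).
#' @param translate_start_as_met render the initiator codon as M.
#' @param emit_nested_starts also report ORFs opened by starts downstream
#'   of the first start in an inter-stop segment (default FALSE: one ORF,
#'   the longest, per segment).
#' @param six_frame additionally scan the reverse complement (default
#'   FALSE: assembled transcripts are stranded).
#' @export
orf_config <- function(start_codons = c("ATG", "GTG", "TTG"),
                       min_len = 8L, max_len = 100L,
                       translate_start_as_met = TRUE,
                       emit_nested_starts = FALSE,
                       six_frame = FALSE) {
  start_codons <- toupper(start_codons)
  stopifnot(all(nchar(start_codons) == 3L), min_len >= 1L, max_len >= min_len)
  list(start_codons = start_codons, min_len = as.integer(min_len),
       max_len = as.integer(max_len),
       translate_start_as_met = isTRUE(translate_start_as_met),
       emit_nested_starts = isTRUE(emit_nested_starts),
       six_frame = isTRUE(six_frame))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::getGeneticCode("11")
    tab
  }
})

#' Translate an in-frame DNA sequence
#'
#' Bacterial code (table 11). Codons containing N translate to X; stop
#' codons translate to * (callers normally exclude the stop).
#'
#' @param dna in-frame nucleotide string, length divisible by 3.
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  if (n == 0L) return("")
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  tab <- .codon_table()
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X",
               unname(tab[codons]))
  paste(aa, collapse = "")
}

.check_transcript <- function(sequence, id = "transcript") {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop(sprintf("invalid nucleotide '%s' at offset %d in %s",
                 chars[bad[1]], bad[1] - 1L, id), call. = FALSE)
  if (!length(chars)) stop("empty transcript: ", id, call. = FALSE)
  invisible(TRUE)
}

.empty_orfs <- function() {
  data.frame(transcript_id = character(0), frame = integer(0),
             start = integer(0), end = integer(0),
             start_codon = character(0), strand = character(0),
             protein = character(0), stringsAsFactors = FALSE)
}

.find_orfs_one_strand <- function(id, sequence, cfg, strand) {
  n <- nchar(sequence)
  starts <- integer(0); stops <- integer(0); frames <- integer(0)
  for (frame in 0:2) {
    if (n - frame < 3L) next
    pos <- seq.int(frame, n - 3L, by = 3L)                 # 0-based
    codons <- substring(sequence, pos + 1L, pos + 3L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% cfg$start_codons
    if (!any(is_stop) || !any(is_start)) next
    seg <- c(0L, cumsum(is_stop))[seq_along(codons)]       # stops before i
    stop_i <- which(is_stop)
    start_i <- which(is_start & !is_stop)
    if (!length(start_i)) next
    start_seg <- split(start_i, seg[start_i])
    for (j in stop_i) {
      sl <- start_seg[[as.character(seg[j])]]
      if (is.null(sl)) next
      if (!cfg$emit_nested_starts) sl <- sl[1]
      starts <- c(starts, pos[sl])
      stops <- c(stops, rep.int(pos[j], length(sl)))
      frames <- c(frames, rep.int(frame, length(sl)))
    }
  }
  if (!length(starts)) return(.empty_orfs())
  prot <- vapply(seq_along(starts), function(k)
    translate_dna(substr(sequence, starts[k] + 1L, stops[k])), character(1))
  if (cfg$translate_start_as_met)
    prot <- paste0("M", substring(prot, 2L))
  data.frame(transcript_id = id, frame = frames, start = starts,
             end = stops,
             start_codon = substring(sequence, starts + 1L, starts + 3L),
             strand = strand, protein = prot, stringsAsFactors = FALSE)
}

#' Call open reading frames on a transcript
#'
#' Scans the three forward frames (six with \code{cfg$six_frame}). Within
#' each frame the transcript is partitioned by in-frame stop codons; the
#' first configured start codon in each inter-stop segment opens the
#' reported ORF (every subsequent start too if
#' \code{cfg$emit_nested_starts}). ORFs lacking a downstream in-frame stop
#' are not reported. Coordinates are 0-based; \code{end} is the offset of
#' the stop codon's first base, so protein length = (end - start)/3.
#'
#' @param id transcript identifier.
#' @param sequence nucleotide string (ACGTN).
#' @param cfg an \code{\link{orf_config}}.
#' @return data.frame of ORF records: transcript_id, frame, start, end,
#'   start_codon, strand, protein.
#' @export
find_orfs <- function(id, sequence, cfg = orf_config()) {
  sequence <- toupper(sequence)
  .check_transcript(sequence, id)
  res <- .find_orfs_one_strand(id, sequence, cfg, "+")
  if (cfg$six_frame) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
    res <- rbind(res, .find_orfs_one_strand(id, rc, cfg, "-"))
  }
  res
}

#' Build a deduplicated SEP candidate database
#'
#' Runs \code{\link{find_orfs}} over every transcript, keeps ORFs whose
#' protein length lies in [min_len, max_len], merges exact duplicate
#' protein sequences into single entries with merged provenance, and
#' assigns zero-padded sequential identifiers in lexicographic protein
#' order (so reruns are diffable).
#'
#' @param transcripts named character vector (names are transcript ids) or
#'   a \code{Biostrings::DNAStringSet}.
#' @param cfg an \code{\link{orf_config}}.
#' @return a \code{SepDatabase}: list with \code{entries} (sep_id, protein,
#'   length) and \code{provenance} (sep_id + ORF record columns).
#' @export
build_database <- function(transcripts, cfg = orf_config()) {
  if (inherits(transcripts, "DNAStringSet")) {
    seqs <- as.character(transcripts)
  } else {
    seqs <- as.character(transcripts)
    names(seqs) <- names(transcripts)
  }
  if (!length(seqs)) stop("at least one transcript required", call. = FALSE)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("transcripts must be named", call. = FALSE)
  orfs <- do.call(rbind, lapply(names(seqs), function(id)
    find_orfs(id, seqs[[id]], cfg)))
  orfs <- orfs[nchar(orfs$protein) >= cfg$min_len &
               nchar(orfs$protein) <= cfg$max_len, , drop = FALSE]
  if (!nrow(orfs)) {
    warning("no ORFs survive the length filter; empty database")
    db <- list(entries = data.frame(sep_id = character(0),
                                    protein = character(0),
                                    length = integer(0),
                                    stringsAsFactors = FALSE),
               provenance = cbind(data.frame(sep_id = character(0)), orfs),
               config = cfg)
    class(db) <- "SepDatabase"
    return(db)
  }
  prots <- sort(unique(orfs$protein))
  sep_id <- sprintf("SEP%06d", seq_along(prots))
  names(sep_id) <- prots
  orfs <- orfs[order(match(orfs$protein, prots), orfs$transcript_id,
                     orfs$start), , drop = FALSE]
  prov <- cbind(data.frame(sep_id = unname(sep_id[orfs$protein]),
                           stringsAsFactors = FALSE), orfs)
  rownames(prov) <- NULL
  db <- list(entries = data.frame(sep_id = unname(sep_id), protein = prots,
                                  length = nchar(prots),
                                  stringsAsFactors = FALSE),
             provenance = prov, config = cfg)
  class(db) <- "SepDatabase"
  db
}

#' @export
print.SepDatabase <- function(x, ...) {
  cat(sprintf("SepDatabase: %d entries (lengths %s aa), %d provenance records\n",
              nrow(x$entries),
              if (nrow(x$entries)) paste(range(x$entries$length), collapse = "-")
              else "-", nrow(x$provenance)))
  invisible(x)
}

#' Start-codon usage of a SEP database
#'
#' One start codon per SEP: that of its first provenance record (records
#' are ordered by transcript id, then start offset, at build time).
#'
#' @param db a \code{SepDatabase}.
#' @return data.frame with codon, count, fraction (fractions sum to 1).
#' @export
start_codon_summary <- function(db) {
  if (!nrow(db$entries))
    return(data.frame(codon = character(0), count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  first <- db$provenance[!duplicated(db$provenance$sep_id), , drop = FALSE]
  tab <- table(first$start_codon)
  data.frame(codon = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
}

#' Length distribution of a SEP database
#' @param db a \code{SepDatabase}.
#' @return named numeric: n, min, q1, median, q3, max (empty db -> all NA,
#'   n = 0).
#' @export
length_summary <- function(db) {
  len <- db$entries$length
  if (!length(len))
    return(c(n = 0, min = NA, q1 = NA, median = NA, q3 = NA, max = NA))
  q <- stats::quantile(len, c(0.25, 0.5, 0.75), names = FALSE)
  c(n = length(len), min = min(len), q1 = q[1], median = q[2], q3 = q[3],
    max = max(len))
}

#' Write a SEP database as FASTA (plus optional provenance TSV)
#'
#' Headers carry the first provenance record:
#' \code{>SEP000001 tr=<id> frame=<f> start=<s> codon=<c>}.
#'
#' @param db a \code{SepDatabase}.
#' @param path output FASTA path.
#' @param provenance_path optional TSV path for the full provenance table.
#' @export
write_sep_fasta <- function(db, path, provenance_path = NULL) {
  first <- db$provenance[!duplicated(db$provenance$sep_id), , drop = FALSE]
  first <- first[match(db$entries$sep_id, first$sep_id), , drop = FALSE]
  lines <- character(0)
  if (nrow(db$entries)) {
    hdr <- sprintf(">%s tr=%s frame=%d start=%d codon=%s",
                   db$entries$sep_id, first$transcript_id, first$frame,
                   first$start, first$start_codon)
    lines <- as.vector(rbind(hdr, db$entries$protein))
  }
  writeLines(lines, path)
  if (!is.null(provenance_path))
    utils::write.table(db$provenance, provenance_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  invisible(path)
}
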