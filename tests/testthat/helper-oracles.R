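# Independent brute-force oracles. These deliberately re-derive results
# from first principles (or from an unrelated mature implementation) and
# must stay independent of the code paths they check.

# --- ORF calling ------------------------------------------------------------

# Enumerate every (frame, start-codon position), scan forward for the first
# in-frame stop; keep nested starts or only the first start per inter-stop
# segment. Translation via Biostrings, independent of translate_dna().
oracle_find_orfs <- function(sequence, starts = c("ATG", "GTG", "TTG"),
                             nested = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(sequence)
  out <- list()
  for (frame in 0:2) {
    if (n - frame < 3) next
    pos <- seq.int(frame, n - 3, by = 3)
    codons <- substring(sequence, pos + 1, pos + 3)
    for (k in seq_along(pos)) {
      if (!codons[k] %in% starts) next
      stop_k <- which(codons %in% stops & seq_along(pos) > k)
      if (!length(stop_k)) next
      stop_k <- stop_k[1]
      # first-start rule: no other start since the previous in-frame stop
      if (!nested) {
        prev_stops <- which(codons %in% stops & seq_along(pos) < k)
        seg_begin <- if (length(prev_stops)) max(prev_stops) + 1L else 1L
        earlier <- which(codons %in% starts &
                           seq_along(pos) >= seg_begin & seq_along(pos) < k)
        if (length(earlier)) next
      }
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(sequence, pos[k] + 1, pos[stop_k])),
        genetic.code = Biostrings::getGeneticCode("11")))
      aa <- paste0("M", substring(aa, 2))
      out[[length(out) + 1L]] <- data.frame(
        frame = frame, start = pos[k], end = pos[stop_k],
        start_codon = codons[k], protein = aa, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), start = integer(0),
                      end = integer(0), start_codon = character(0),
                      protein = character(0)))
  do.call(rbind, out)
}

random_transcript <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(names(sepomics::RESIDUE_MASSES), len, replace = TRUE),
        collapse = "")
}

# encode a protein as an ORF-bearing transcript: guard stop, ATG, codons,
# stop (deterministic codon choice so no RNG needed)
encode_protein <- function(protein, start_codon = "ATG") {
  gc11 <- Biostrings::getGeneticCode("11")
  gc11 <- gc11[gc11 != "*"]
  first_codon <- vapply(strsplit(protein, "")[[1]][-1],
                        function(a) names(gc11)[gc11 == a][1], character(1))
  paste(c("TAA", start_codon, first_codon, "TAA"), collapse = "")
}

# --- digestion --------------------------------------------------------------

# independent site derivation straight from the enzyme definitions
oracle_sites <- function(protein, enzyme) {
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  keep <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    keep[i] <- switch(enzyme,
      trypsin = res[i] %in% c("K", "R") && res[i + 1] != "P",
      argc = res[i] == "R" && res[i + 1] != "P",
      chymotrypsin = res[i] %in% c("F", "W", "Y", "L") && res[i + 1] != "P",
      lysc = res[i] == "K",
      lysn = res[i + 1] == "K",
      mirror_trypsin = res[i + 1] %in% c("K", "R"))
  }
  which(keep)
}

# exhaustive substring filter: a substring [s, e) is a product iff both
# boundaries are termini or sites and it spans <= max_missed internal sites
oracle_digest <- function(protein, enzyme, max_missed) {
  n <- nchar(protein)
  sites <- oracle_sites(protein, enzyme)
  bounds <- c(0L, sites, n)
  out <- character(0)
  for (s in 0:(n - 1)) for (e in (s + 1):n) {
    if (!(s %in% bounds) || !(e %in% bounds)) next
    internal <- sum(sites > s & sites < e)
    if (internal <= max_missed)
      out <- c(out, substr(protein, s + 1, e))
  }
  sort(out)
}

# --- ions -------------------------------------------------------------------

# brute-force window scan for the longest consecutive matched index run
oracle_run <- function(b_idx, y_idx) {
  best <- 0L
  for (idx in list(b_idx, y_idx)) {
    idx <- unique(idx)
    if (!length(idx)) next
    for (i in idx) {
      L <- 0L
      while ((i + L) %in% idx) L <- L + 1L
      best <- max(best, L)
    }
  }
  best
}

# --- alignment --------------------------------------------------------------

# exhaustive local alignment score for tiny sequences: maximise over all
# substring pairs and all gapped alignments (plain recursion, affine gaps
# costing open + L*ext)
oracle_sw_exhaustive <- function(a, b, mat = sepomics::BLOSUM62_MATRIX,
                                 open = 11, ext = 1) {
  glob <- function(x, y) {
    rec <- function(i, j, last) {
      if (i > nchar(x) && j > nchar(y)) return(0)
      best <- -Inf
      if (i <= nchar(x) && j <= nchar(y))
        best <- max(best, mat[substr(x, i, i), substr(y, j, j)] +
                      rec(i + 1, j + 1, "d"))
      if (i <= nchar(x))
        best <- max(best, rec(i + 1, j, "u") -
                      (if (last == "u") ext else open + ext))
      if (j <= nchar(y))
        best <- max(best, rec(i, j + 1, "l") -
                      (if (last == "l") ext else open + ext))
      best
    }
    rec(1, 1, "d")
  }
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (s1 in 1:na) for (e1 in s1:na)
    for (s2 in 1:nb) for (e2 in s2:nb)
      best <- max(best, glob(substr(a, s1, e1), substr(b, s2, e2)))
  best
}

# mature-library oracle (optimal over all alignments by construction)
oracle_sw_biostrings <- function(a, b) {
  B62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
  max(0, Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = B62,
    gapOpening = 11, gapExtension = 1)))
}

# --- statistics -------------------------------------------------------------

# literal step-up definition with explicit loops
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}
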