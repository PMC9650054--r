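#' Protease cleavage rules
#'
#' The six proteases used for multi-enzyme SEP digestion. Specificities
#' follow standard usage: trypsin cleaves C-terminal to K/R except before
#' P; ArgC C-terminal to R except before P; LysC C-terminal to K; LysN
#' N-terminal to K; chymotrypsin C-terminal to F/W/Y/L except before P.
#' "mirror_trypsin" is modelled as the N-terminal mirror of trypsin
#' (cleaves before K/R); the rule is a named, swappable entry should the
#' reagent differ.
#'
#' @param name one of trypsin, argc, chymotrypsin, lysc, lysn,
#'   mirror_trypsin.
#' @return a ProteaseRule list: name, cleave_residues, side
#'   ("C"/"N"), no_before_proline flag.
#' @export
protease_rule <- function(name) {
  name <- tolower(name)
  rules <- list(
    trypsin        = list(cleave_residues = c("K", "R"), side = "C",
                          no_before_proline = TRUE),
    argc           = list(cleave_residues = "R", side = "C",
                          no_before_proline = TRUE),
    chymotrypsin   = list(cleave_residues = c("F", "W", "Y", "L"), side = "C",
                          no_before_proline = TRUE),
    lysc           = list(cleave_residues = "K", side = "C",
                          no_before_proline = FALSE),
    lysn           = list(cleave_residues = "K", side = "N",
                          no_before_proline = FALSE),
    mirror_trypsin = list(cleave_residues = c("K", "R"), side = "N",
                          no_before_proline = FALSE)
  )
  if (!name %in% names(rules))
    stop("unknown protease: ", name, " (known: ",
         paste(names(rules), collapse = ", "), ")", call. = FALSE)
  c(list(name = name), rules[[name]])
}

#' All supported protease names
#' @export
protease_names <- function() {
  c("trypsin", "argc", "chymotrypsin", "lysc", "lysn", "mirror_trypsin")
}

#' Cleavage sites of a protease on a protein
#'
#' Sites are inter-residue indices: site i means cleavage between residues
#' i and i+1 (1-based residues), i.e. after the i-th residue. Termini are
#' not reported as sites.
#'
#' @param protein amino acid string.
#' @param rule a ProteaseRule (see \code{\link{protease_rule}}) or name.
#' @return increasing integer vector of sites in 1..(n-1).
#' @export
cleavage_sites <- function(protein, rule) {
  if (is.character(rule)) rule <- protease_rule(rule)
  .check_protein(protein)
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  if (n < 2L) return(integer(0))
  if (rule$side == "C") {
    pos <- which(res %in% rule$cleave_residues)
    pos <- pos[pos < n]
    if (rule$no_before_proline) pos <- pos[res[pos + 1L] != "P"]
  } else {
    pos <- which(res %in% rule$cleave_residues) - 1L
    pos <- pos[pos >= 1L]
  }
  sort(unique(as.integer(pos)))
}

#' In-silico digestion with missed cleavages
#'
#' Enumerates every peptide bounded by termini or cleavage sites that
#' spans at most \code{max_missed} internal sites.
#'
#' @param protein amino acid string.
#' @param rule protease rule or name.
#' @param max_missed maximum internal (missed) cleavage sites (default 2).
#' @param parent_id identifier recorded in the output.
#' @return data.frame: parent_id, peptide, start, end (0-based half-open),
#'   missed_cleavages.
#' @export
digest <- function(protein, rule, max_missed = 2L, parent_id = "protein") {
  if (is.character(rule)) rule <- protease_rule(rule)
  stopifnot(max_missed >= 0L)
  .check_protein(protein)
  n <- nchar(protein)
  bounds <- c(0L, cleavage_sites(protein, rule), n)
  k <- length(bounds)
  out <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):min(k, i + 1L + max_missed)) {
      s <- bounds[i]; e <- bounds[j]
      out[[length(out) + 1L]] <- data.frame(
        parent_id = parent_id,
        peptide = substr(protein, s + 1L, e),
        start = s, end = e, missed_cleavages = j - i - 1L,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Map peptides onto a SEP database with uniqueness flags
#'
#' A peptide is flagged unique iff it arises as a valid digest product
#' (under any of the given protease rules, within \code{max_missed}) of
#' exactly one database entry. Peptides hitting no entry land in the
#' unmapped bucket (attribute \code{unmapped}).
#'
#' @param peptides character vector of peptide sequences.
#' @param db a \code{SepDatabase}.
#' @param rules character vector of protease names (default all six).
#' @param max_missed maximum missed cleavages (default 2).
#' @return data.frame: peptide, sep_id, start, end, unique;
#'   attr "unmapped" holds peptides not found.
#' @export
map_peptides_to_seps <- function(peptides, db, rules = protease_names(),
                                 max_missed = 2L) {
  peptides <- unique(peptides)
  # digest every entry once, index products
  prods <- list()
  for (i in seq_len(nrow(db$entries))) {
    for (r in rules) {
      d <- digest(db$entries$protein[i], r, max_missed,
                  parent_id = db$entries$sep_id[i])
      prods[[length(prods) + 1L]] <- d
    }
  }
  prods <- if (length(prods)) do.call(rbind, prods) else
    data.frame(parent_id = character(0), peptide = character(0),
               start = integer(0), end = integer(0))
  prods <- prods[prods$peptide %in% peptides, , drop = FALSE]
  prods <- unique(prods[, c("parent_id", "peptide", "start", "end")])
  if (nrow(prods)) {
    nsep <- tapply(prods$parent_id, prods$peptide,
                   function(x) length(unique(x)))
    res <- data.frame(peptide = prods$peptide, sep_id = prods$parent_id,
                      start = prods$start, end = prods$end,
                      unique = unname(nsep[prods$peptide] == 1L),
                      stringsAsFactors = FALSE)
    res <- res[order(res$peptide, res$sep_id, res$start), , drop = FALSE]
    rownames(res) <- NULL
  } else {
    res <- data.frame(peptide = character(0), sep_id = character(0),
                      start = integer(0), end = integer(0),
                      unique = logical(0), stringsAsFactors = FALSE)
  }
  attr(res, "unmapped") <- setdiff(peptides, res$peptide)
  res
}

#' Write digestion products as TSV
#' @param products data.frame from \code{\link{digest}}.
#' @param path output path.
#' @export
write_digest_tsv <- function(products, path) {
  utils::write.table(products, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
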