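make_psms <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(spectrum_id = r[[1]], peptide = r[[2]],
               run_length = as.integer(r[[3]]), ppm = as.numeric(r[[4]]),
               score = as.numeric(r[[5]]), stringsAsFactors = FALSE)))
}

test_that("filter_psms boundary semantics: len/run inclusive, ppm/score strict", {
  p <- make_psms(
    list("s1", "AAAAAAA", 4, 1.9, 20.01),   # exactly at every boundary: pass
    list("s2", "AAAAAA", 4, 1.9, 20.01),    # 6 aa: fail length
    list("s3", "AAAAAAA", 3, 1.9, 20.01),   # run 3: fail run
    list("s4", "AAAAAAA", 4, 2.0, 20.01),   # ppm == 2: fail (strict)
    list("s5", "AAAAAAA", 4, 1.9, 20.0),    # score == 20: fail (strict)
    list("s6", "AAAAAAA", 4, -1.9, 20.01))  # filter uses |ppm|
  out <- filter_psms(p)
  expect_identical(out$pass, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(out$fail_rule,
                   c(NA, "min_peptide_len", "min_consecutive_ions",
                     "max_abs_ppm", "min_score", NA))
})

test_that("filter_psms records the FIRST failing rule in fixed order", {
  p <- make_psms(list("s1", "AAA", 0, 9, 1))  # violates everything
  expect_equal(filter_psms(p)$fail_rule, "min_peptide_len")
  p2 <- make_psms(list("s1", "AAAAAAA", 0, 9, 1))
  expect_equal(filter_psms(p2)$fail_rule, "min_consecutive_ions")
})

test_that("filter conjunction is order-invariant under row permutation", {
  set.seed(41)
  p <- data.frame(spectrum_id = sprintf("s%02d", 1:40),
                  peptide = vapply(sample(5:10, 40, TRUE), random_protein,
                                   character(1)),
                  run_length = sample(0:8, 40, TRUE),
                  ppm = runif(40, -4, 4), score = runif(40, 10, 40),
                  stringsAsFactors = FALSE)
  out1 <- filter_psms(p)
  perm <- sample(nrow(p))
  out2 <- filter_psms(p[perm, ])
  expect_identical(out2$pass[order(perm)], out1$pass)
})

test_that("filter_psms names missing columns", {
  expect_error(filter_psms(data.frame(peptide = "AAAA")),
               "run_length.*ppm.*score")
})

test_that("local_align handles identity and all-negative cases", {
  a <- local_align("MKLVNPQRST", "MKLVNPQRST")
  expect_equal(a$identity, 100)
  expect_equal(a$aligned_cols, 10)
  expect_equal(a$query_span, 10)
  # Smith-Waterman floors at zero when nothing scores positive
  z <- local_align("WWWW", "PPPP")
  expect_equal(z$score, 0)
  expect_equal(z$aligned_cols, 0)
})

test_that("local_align score is symmetric for the symmetric matrix", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_protein(sample(4:12, 1)); b <- random_protein(sample(4:12, 1))
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
})

test_that("local_align equals exhaustive enumeration on tiny pairs", {
  set.seed(43)
  for (i in 1:12) {
    a <- random_protein(sample(2:4, 1)); b <- random_protein(sample(2:4, 1))
    expect_equal(local_align(a, b)$score, oracle_sw_exhaustive(a, b),
                 label = paste(a, b))
  }
})

test_that("local_align equals the Biostrings optimum on random pairs", {
  set.seed(44)
  for (i in 1:60) {
    a <- random_protein(sample(2:8, 1)); b <- random_protein(sample(2:8, 1))
    expect_equal(local_align(a, b)$score, oracle_sw_biostrings(a, b),
                 label = paste(a, b))
  }
})

test_that("BLOSUM62 constant matches the Biostrings copy", {
  B62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()))
  aa <- rownames(BLOSUM62_MATRIX)
  expect_equal(unname(BLOSUM62_MATRIX),
               unname(B62[aa, aa]), ignore_attr = TRUE)
})

test_that("novelty_screen: substring, novel, and alignment-based calls", {
  proteome <- c(host = paste0("MSTART", "MKLVNPQRSTWK", "ENDSEQ"),
                other = "MAAAAAAAAAAAAAAAAAAAAAAA")
  # exact substring of annotated protein
  r1 <- novelty_screen(c(sep1 = "MKLVNPQRSTWK"), proteome)
  expect_equal(r1$status, "matches_annotated")
  # random sequence vs unrelated proteome
  set.seed(45)
  r2 <- novelty_screen(c(sep2 = "WDYHECFNIQGV"), proteome)
  expect_equal(r2$status, "novel")
  # near-identical (1 substitution in 12 aa = 91.7% identity, full coverage)
  r3 <- novelty_screen(c(sep3 = "MKLVNPARSTWK"), proteome)
  expect_equal(r3$status, "matches_annotated")
  # supporting peptide substring triggers the call even for a novel SEP
  r4 <- novelty_screen(c(sep4 = "WDYHECFNIQGV"), proteome,
                       supporting_peptides = data.frame(
                         sep_id = "sep4", peptide = "MKLVNPQ"))
  expect_equal(r4$status, "matches_annotated")
})

test_that("k-mer prefilter never changes novelty statuses", {
  set.seed(46)
  proteome <- vapply(1:8, function(i) random_protein(120), character(1))
  names(proteome) <- paste0("p", 1:8)
  seps <- vapply(1:60, function(i) random_protein(sample(8:40, 1)),
                 character(1))
  # plant some true positives: substrings and near-copies
  seps[1] <- substr(proteome[1], 10, 30)
  sub <- substr(proteome[2], 5, 44)
  substr(sub, 20, 20) <- if (substr(sub, 20, 20) == "A") "G" else "A"
  seps[2] <- sub
  names(seps) <- paste0("sep", seq_along(seps))
  with_pf <- novelty_screen(seps, proteome, k = 4)
  without_pf <- novelty_screen(seps, proteome, k = NULL)
  expect_identical(with_pf$status, without_pf$status)
  expect_equal(with_pf$status[1], "matches_annotated")
  expect_equal(with_pf$status[2], "matches_annotated")
})

test_that("assemble_sepome builds a monotone funnel on a constructed case", {
  # five candidates: one killed by novelty, one by PSM filter, one lacking
  # a unique peptide, two surviving
  prots <- c(A = "MWDDDATKAGGSELK", B = "MHHHHHHKCCCCCCK",
             C = "MNNNNNNKDDDDDDK", D = "MQQQQQQKEEEEEEK",
             E = "MQQQQQQKFFFFFFK")
  tx <- vapply(prots, encode_protein, character(1))
  db <- build_database(tx)
  id_of <- function(p) db$entries$sep_id[db$entries$protein == p]
  proteome <- c(known = paste0("MXXX", prots[["A"]], "YYY"))
  psms <- make_psms(
    list("s1", "MWDDDATK", 6, 0.5, 45),   # A: passes but known
    list("s2", "MHHHHHHK", 6, 0.5, 45),   # B: passes, novel, unique
    list("s3", "MNNNNNNK", 2, 0.5, 45),   # C: fails run filter
    list("s4", "MQQQQQQK", 6, 0.5, 45),   # D+E: shared peptide, not unique
    list("s5", "EEEEEEK", 6, 0.5, 45))    # D: unique rescue
  rep <- assemble_sepome(psms, db, proteome, rules = "trypsin",
                         max_missed = 0)
  expect_equal(unname(rep$funnel["db_hit"]), 5L)
  expect_true(all(diff(rep$funnel) <= 0))
  expect_setequal(rep$sepome$sep_id,
                  c(id_of(prots[["B"]]), id_of(prots[["D"]])))
  # every final SEP has at least one passing unique supporting PSM
  expect_true(all(rep$sepome$n_supporting >= 1))
})

test_that("assemble_sepome on empty PSM input yields an all-zero funnel", {
  tx <- c(a = encode_protein("MWDDDATKAGGSE"))
  db <- build_database(tx)
  psms <- data.frame(spectrum_id = character(0), peptide = character(0),
                     run_length = integer(0), ppm = numeric(0),
                     score = numeric(0))
  rep <- assemble_sepome(psms, db, c(p = "MAAAAAAAAAA"))
  expect_true(all(rep$funnel == 0))
  expect_equal(nrow(rep$sepome), 0L)
})

test_that("curation report files are written", {
  fix <- pipeline_fixture()
  d <- tempfile("rep")
  write_curation_report(fix$report, d)
  expect_true(file.exists(file.path(d, "curation_report.json")))
  j <- jsonlite::read_json(file.path(d, "curation_report.json"))
  expect_equal(j$funnel$final, nrow(fix$report$sepome))
  seps <- read_fasta(file.path(d, "sepome.fasta"))
  expect_setequal(unname(seps), fix$report$sepome$protein)
})
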