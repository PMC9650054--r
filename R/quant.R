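#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: adj p for the i-th smallest p is
#' min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' original order.
#'
#' @param p numeric vector of p values in [0, 1] (NA passed through).
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(pv[o] * m / (m:1)))[ro]
    out[ok] <- adj
  }
  out
}

#' Differential SEP abundance between treatment and control
#'
#' Student's two-sample t-test (pooled variance by default) on log2
#' intensities, Benjamini-Hochberg adjustment across the tested set, and
#' classification against fold-change and adjusted-p cutoffs: up iff
#' FC > fc_threshold and adj p < alpha, down iff FC < 1/fc_threshold and
#' adj p < alpha, otherwise unchanged. Fold change is the ratio of raw
#' group means (treatment/control), reported as log2. SEPs with fewer
#' than two non-missing values in either group are reported untested
#' (class NA).
#'
#' @param m numeric matrix, rows = SEPs (rownames = ids), columns =
#'   samples; zero or NA intensities are treated as missing.
#' @param groups character/factor of length ncol(m) with two levels.
#' @param treatment,control level names (default "treatment"/"control").
#' @param fc_threshold fold-change cutoff (default 2).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param welch use Welch's unequal-variance test instead of pooled.
#' @return data.frame: sep_id, log2fc, t, df, p, adj_p, class, tested.
#' @export
differential_test <- function(m, groups, treatment = "treatment",
                              control = "control", fc_threshold = 2,
                              alpha = 0.05, welch = FALSE) {
  stopifnot(is.matrix(m), length(groups) == ncol(m))
  groups <- as.character(groups)
  it <- which(groups == treatment)
  ic <- which(groups == control)
  if (length(it) < 2L || length(ic) < 2L)
    stop("need >= 2 samples per group", call. = FALSE)
  m[!is.na(m) & m <= 0] <- NA
  if (all(is.na(m[, it])) || all(is.na(m[, ic])))
    stop("a group is entirely missing", call. = FALSE)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("row%04d", seq_len(nrow(m)))
  res <- data.frame(sep_id = ids, log2fc = NA_real_, t = NA_real_,
                    df = NA_real_, p = NA_real_, adj_p = NA_real_,
                    class = NA_character_, tested = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    xt <- m[i, it]; xc <- m[i, ic]
    xt <- xt[!is.na(xt)]; xc <- xc[!is.na(xc)]
    if (length(xt) < 2L || length(xc) < 2L) next
    res$log2fc[i] <- log2(mean(xt) / mean(xc))
    tt <- stats::t.test(log2(xt), log2(xc), var.equal = !welch)
    res$t[i] <- unname(tt$statistic)
    res$df[i] <- unname(tt$parameter)
    res$p[i] <- tt$p.value
    res$tested[i] <- TRUE
  }
  res$adj_p <- bh_adjust(res$p)
  fc <- 2^res$log2fc
  res$class <- ifelse(!res$tested, NA_character_,
                ifelse(fc > fc_threshold & res$adj_p < alpha, "up",
                ifelse(fc < 1 / fc_threshold & res$adj_p < alpha, "down",
                       "unchanged")))
  res
}

#' Row-wise z-scores of an intensity matrix
#'
#' (x - row mean) / row SD with the sample (n-1) SD. Rows with zero SD
#' are returned as zeros and flagged in the \code{constant} attribute.
#'
#' @param m numeric matrix.
#' @export
row_zscore <- function(m) {
  stopifnot(is.matrix(m))
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1L, stats::sd, na.rm = TRUE)
  constant <- !is.na(sdv) & sdv == 0
  sdv[constant] <- 1
  z <- sweep(sweep(m, 1L, mu, "-"), 1L, sdv, "/")
  z[constant, ] <- 0
  attr(z, "constant") <- constant
  z
}

#' Relative expression by the 2^-ddCt method
#'
#' dCt = Ct_target - Ct_reference per condition (replicate-wise);
#' ddCt = mean dCt(treated) - mean dCt(control); fold = 2^-ddCt.
#' The SD is propagated from per-replicate 2^-dCt values of the treated
#' condition normalised to the control mean.
#'
#' @param ct_target_treated,ct_ref_treated numeric Ct replicates (treated).
#' @param ct_target_control,ct_ref_control numeric Ct replicates (control).
#' @return list: fold, ddct, fold_sd.
#' @export
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  for (x in list(ct_target_treated, ct_ref_treated, ct_target_control,
                 ct_ref_control)) {
    if (!length(x) || any(!is.finite(x)) || any(x <= 0))
      stop("Ct values must be finite and positive", call. = FALSE)
  }
  stopifnot(length(ct_target_treated) == length(ct_ref_treated),
            length(ct_target_control) == length(ct_ref_control))
  dct_t <- ct_target_treated - ct_ref_treated
  dct_c <- ct_target_control - ct_ref_control
  ddct_val <- mean(dct_t) - mean(dct_c)
  folds <- 2^(-(dct_t - mean(dct_c)))
  list(fold = 2^(-ddct_val), ddct = ddct_val,
       fold_sd = if (length(folds) > 1L) stats::sd(folds) else NA_real_)
}

#' GRAVY hydropathy score
#'
#' Mean Kyte-Doolittle index over the residues of a protein; positive
#' scores indicate hydrophobic peptides.
#'
#' @param protein amino acid string (standard residues).
#' @param hydrophobic_cutoff classification boundary (default 0).
#' @return list: score, hydrophobic.
#' @export
gravy <- function(protein, hydrophobic_cutoff = 0) {
  .check_protein(protein)
  sc <- mean(KYTE_DOOLITTLE[strsplit(protein, "")[[1]]])
  list(score = unname(sc), hydrophobic = unname(sc > hydrophobic_cutoff))
}

#' Write quantification results and a z-score matrix
#' @param results data.frame from \code{\link{differential_test}}.
#' @param m the intensity matrix used.
#' @param dir output directory.
#' @export
write_quant_results <- function(results, m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(results, file.path(dir, "quant_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  z <- row_zscore(m)
  utils::write.table(cbind(sep_id = rownames(m), as.data.frame(z)),
                     file.path(dir, "zscore.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
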