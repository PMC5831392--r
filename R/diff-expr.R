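## TPM normalization and the Audic-Claverie conditional Poisson exact test.

#' miRNA count matrix
#'
#' @param counts Non-negative numeric matrix, miRNAs in rows, libraries in
#'   columns (fractional counts arise under the fractional multi-assignment
#'   policy).
#' @param library_totals Named numeric vector of total clean reads per
#'   library (the normalisation denominators), aligned with the columns.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, library_totals) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), length(library_totals) == ncol(counts),
            all(library_totals > 0))
  if (is.null(names(library_totals))) names(library_totals) <- colnames(counts)
  if (is.null(colnames(counts))) colnames(counts) <- names(library_totals)
  if (any(colSums(counts) > library_totals + 1e-8)) {
    warning("column sums exceed library totals")
  }
  structure(list(counts = counts, library_totals = library_totals),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("Count matrix:", nrow(x$counts), "miRNAs x", ncol(x$counts),
      "libraries\n")
  cat("Library totals:", paste(names(x$library_totals),
                               format(x$library_totals, trim = TRUE),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Normalize counts to transcripts per million (TPM)
#'
#' `tpm[i, j] = counts[i, j] / library_totals[j] * 1e6`, with the total clean
#' reads of each library as the denominator.
#'
#' @param counts A [count_matrix()].
#' @return Numeric TPM matrix with the same dimnames.
#' @export
tpm_normalize <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  if (any(counts$library_totals <= 0)) stop("library totals must be positive")
  sweep(counts$counts, 2L, counts$library_totals, "/") * 1e6
}

#' Log2 fold-change between two expression values
#'
#' @param tpm_a,tpm_b Non-negative expression values (treatment, control).
#' @param pseudocount Added to both values before the ratio; default 0.01 TPM
#'   to handle zeros.
#' @return `log2((tpm_a + pseudocount) / (tpm_b + pseudocount))`.
#' @export
log2_fold_change <- function(tpm_a, tpm_b, pseudocount = 0.01) {
  stopifnot(all(tpm_a >= 0), all(tpm_b >= 0))
  log2((tpm_a + pseudocount) / (tpm_b + pseudocount))
}

#' Audic-Claverie conditional probability
#'
#' Probability of observing `y` reads in a library of `n2` total reads given
#' `x` reads observed in a library of `n1` total reads, under independent
#' Poisson sampling of the same transcript:
#' `p(y|x) = (n2/n1)^y * (x+y)! / (x! y!) * (1 + n2/n1)^-(x+y+1)`.
#' Computed in log space with `lgamma` (direct factorials would overflow).
#' For fixed `x`, `p(y|x)` sums to 1 over `y >= 0`.
#'
#' @param y Count in the second library (vectorised).
#' @param x Count in the first library.
#' @param n1,n2 Total clean reads of the first and second library.
#' @return Probability vector aligned with `y`.
#' @export
ac_probability <- function(y, x, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), n1 > 0, n2 > 0)
  logr <- log(n2) - log(n1)
  log1pr <- log1p(n2 / n1)
  exp(y * logr + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1pr)
}

# Upper tail D = sum_{y' >= y} p(y'|x), summed directly until the remainder
# is negligible.
.ac_upper_tail <- function(x, y, n1, n2) {
  r <- n2 / n1
  mean_nb <- (x + 1) * r
  hi <- max(y + 64, ceiling(mean_nb + 20 * sqrt(mean_nb * (1 + r)) + 64))
  repeat {
    term_hi <- ac_probability(hi, x, n1, n2)
    if (term_hi < 1e-18 || hi > y + 1e7) break
    hi <- hi * 2L
  }
  sum(ac_probability(y:hi, x, n1, n2))
}

.ac_lower_tail <- function(x, y, n1, n2) {
  sum(ac_probability(0:y, x, n1, n2))
}

#' Audic-Claverie exact test for two library counts
#'
#' Computes the lower tail `C = sum_{y' <= y} p(y'|x)` and the upper tail
#' `D = sum_{y' >= y} p(y'|x)` (the observed count is included in both
#' tails). The default two-sided p-value doubles the smaller tail and caps at
#' 1; one-sided modes return the corresponding tail.
#'
#' @param x,y Observed counts in the two libraries (non-negative integers;
#'   fractional counts are rounded).
#' @param n1,n2 Total clean reads of the two libraries.
#' @param alternative `"two.sided"` (default), `"less"` (lower tail `C`) or
#'   `"greater"` (upper tail `D`).
#' @return The p-value.
#' @export
ac_test <- function(x, y, n1, n2,
                    alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- round(x)
  y <- round(y)
  stopifnot(x >= 0, y >= 0, n1 > 0, n2 > 0)
  C <- .ac_lower_tail(x, y, n1, n2)
  D <- .ac_upper_tail(x, y, n1, n2)
  switch(alternative,
         two.sided = min(1, 2 * min(C, D)),
         less = min(1, C),
         greater = min(1, D))
}

#' Call differentially expressed miRNAs between two libraries
#'
#' TPM-normalises the pair, computes log2 fold-changes and Audic-Claverie
#' p-values, applies a Bonferroni correction over the miRNAs tested in this
#' pair, and calls significance at `|log2fc| >= log2(min_fold)` and corrected
#' p below `alpha`.
#'
#' @param counts A [count_matrix()].
#' @param pair Character vector of two library names `c(a, b)`; fold-changes
#'   are `a` over `b`.
#' @param min_fold Fold-change threshold (default 2).
#' @param alpha Corrected p-value threshold (default 0.01).
#' @param pseudocount Passed to [log2_fold_change()].
#' @param alternative Passed to [ac_test()].
#' @return A `differential_result` data.frame: `mirna_id`, `tpm_a`, `tpm_b`,
#'   `log2fc`, `p_raw`, `p_bonferroni`, `significant`, `direction`
#'   (`up_in_a` / `up_in_b`), with the tested count `m` as an attribute.
#'   miRNAs with zero counts in both libraries of the pair are not tested.
#' @export
call_differential <- function(counts, pair, min_fold = 2, alpha = 0.01,
                              pseudocount = 0.01,
                              alternative = "two.sided") {
  stopifnot(inherits(counts, "count_matrix"), length(pair) == 2,
            all(pair %in% colnames(counts$counts)))
  a <- pair[1]
  b <- pair[2]
  tpm <- tpm_normalize(counts)
  tested <- which(counts$counts[, a] > 0 | counts$counts[, b] > 0)
  m <- length(tested)
  rows <- lapply(tested, function(i) {
    x <- counts$counts[i, a]
    y <- counts$counts[i, b]
    p <- ac_test(x, y, counts$library_totals[[a]],
                 counts$library_totals[[b]], alternative = alternative)
    data.frame(
      mirna_id = rownames(counts$counts)[i],
      tpm_a = tpm[i, a], tpm_b = tpm[i, b],
      log2fc = log2_fold_change(tpm[i, a], tpm[i, b], pseudocount),
      p_raw = p, stringsAsFactors = FALSE
    )
  })
  res <- if (m) do.call(rbind, rows) else
    data.frame(mirna_id = character(), tpm_a = numeric(), tpm_b = numeric(),
               log2fc = numeric(), p_raw = numeric())
  res$p_bonferroni <- pmin(1, res$p_raw * m)
  res$significant <- abs(res$log2fc) >= log2(min_fold) &
    res$p_bonferroni < alpha
  res$direction <- ifelse(res$log2fc >= 0, "up_in_a", "up_in_b")
  rownames(res) <- NULL
  structure(res, pair = pair, m = m, alpha = alpha, min_fold = min_fold,
            class = c("differential_result", "data.frame"))
}

#' @export
summary.differential_result <- function(object, ...) {
  pair <- attr(object, "pair")
  sig <- object[object$significant, , drop = FALSE]
  list(
    pair = pair,
    tested = attr(object, "m"),
    significant = nrow(sig),
    up_in_a = sum(sig$direction == "up_in_a"),
    up_in_b = sum(sig$direction == "up_in_b")
  )
}

#' @export
print.differential_result <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "Differential expression %s vs %s: %d tested, %d significant (%d up in %s, %d up in %s)\n",
    s$pair[1], s$pair[2], s$tested, s$significant,
    s$up_in_a, s$pair[1], s$up_in_b, s$pair[2]))
  invisible(x)
}

#' Relative expression by the 2^-ddCt method
#'
#' @param ct_target,ct_ref Threshold cycles of the target and reference gene
#'   in the sample of interest.
#' @param ct_target_cal,ct_ref_cal The same in the calibrator sample.
#' @return Fold expression `2^-((ct_target - ct_ref) - (ct_target_cal -
#'   ct_ref_cal))`.
#' @export
relative_expression_ddct <- function(ct_target, ct_ref, ct_target_cal,
                                     ct_ref_cal) {
  stopifnot(all(c(ct_target, ct_ref, ct_target_cal, ct_ref_cal) > 0))
  2^-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal))
}
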