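## Hypergeometric over-representation analysis with FDR control.

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without replacement
#' from a background of `N` genes of which `K` carry the annotation. Exact
#' log-space evaluation via `lchoose`.
#'
#' @param k Observed annotated genes among the candidates.
#' @param K Annotated genes in the background.
#' @param n Number of candidate genes.
#' @param N Background size.
#' @return `P(X >= k)`.
#' @export
hypergeom_upper <- function(k, K, n, N) {
  stopifnot(k >= 0, k <= min(K, n), K <= N, n <= N)
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

#' Term over-representation among candidate target genes
#'
#' One hypergeometric test per annotation term with at least one candidate
#' and at least `min_term_size` background genes; adjusted within each
#' namespace (Benjamini-Hochberg by default, Bonferroni switchable).
#' Candidates outside the background are dropped with a warning.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param table Annotation data.frame with columns `term_id`, `gene_id`,
#'   `namespace`, and optionally `term_name`.
#' @param background Character vector of background gene ids (e.g. the
#'   expressed genes, FPKM > 1).
#' @param fdr_cutoff Significance cutoff on the adjusted p-value (default 0.1).
#' @param method Multiple-testing method: `"BH"` (default) or `"bonferroni"`.
#' @param min_term_size Smallest testable term (default 2; singleton terms
#'   give degenerate tests).
#' @return data.frame of `EnrichmentResult` rows: `term_id`, `term_name`,
#'   `namespace`, `k`, `K`, `n`, `N`, `p_raw`, `fdr`, `significant`, sorted
#'   by `fdr` then `p_raw`.
#' @export
enrich <- function(candidates, table, background, fdr_cutoff = 0.1,
                   method = c("BH", "bonferroni"), min_term_size = 2L) {
  method <- match.arg(method)
  background <- unique(background)
  candidates <- unique(candidates)
  outside <- setdiff(candidates, background)
  if (length(outside)) {
    warning(length(outside), " candidate gene(s) outside the background; dropped")
    candidates <- intersect(candidates, background)
  }
  empty <- data.frame(
    term_id = character(), term_name = character(), namespace = character(),
    k = integer(), K = integer(), n = integer(), N = integer(),
    p_raw = numeric(), fdr = numeric(), significant = logical()
  )
  if (!length(candidates)) return(empty)
  if (is.null(table$term_name)) table$term_name <- table$term_id
  table <- table[table$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(candidates)

  terms <- unique(table[, c("term_id", "term_name", "namespace")])
  rows <- list()
  for (i in seq_len(nrow(terms))) {
    t_genes <- unique(table$gene_id[table$term_id == terms$term_id[i]])
    K <- length(t_genes)
    if (K < min_term_size) next
    k <- length(intersect(t_genes, candidates))
    if (k < 1L) next
    rows[[length(rows) + 1L]] <- data.frame(
      term_id = terms$term_id[i], term_name = terms$term_name[i],
      namespace = terms$namespace[i], k = k, K = K, n = n, N = N,
      p_raw = hypergeom_upper(k, K, n, N), stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res$fdr <- NA_real_
  for (ns in unique(res$namespace)) {
    sel <- res$namespace == ns
    res$fdr[sel] <- stats::p.adjust(res$p_raw[sel], method = method)
  }
  res$significant <- res$fdr < fdr_cutoff
  res <- res[order(res$fdr, res$p_raw, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
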