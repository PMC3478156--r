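#' One-sided Fisher exact p for term over-representation
#'
#' Exact hypergeometric tail probability that the test set contains at least
#' the observed number of term-annotated genes, given the 2x2 margins.
#'
#' @param in_annot test-set genes with the term.
#' @param in_other test-set genes without the term.
#' @param out_annot reference genes (outside the test set) with the term.
#' @param out_other reference genes without the term.
#' @param alternative `"over"` (default) or `"under"` representation.
#' @return One-sided exact p-value.
#' @export
fisher_term <- function(in_annot, in_other, out_annot, out_other,
                        alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  counts <- c(in_annot, in_other, out_annot, out_other)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  k_annot <- in_annot + out_annot     # annotated genes in the universe
  k_other <- in_other + out_other
  n_test <- in_annot + in_other
  if (alternative == "over") {
    stats::phyper(in_annot - 1, k_annot, k_other, n_test, lower.tail = FALSE)
  } else {
    stats::phyper(in_annot, k_annot, k_other, n_test, lower.tail = TRUE)
  }
}

#' GO-term over-representation analysis
#'
#' One Fisher exact test per term occurring in the universe, comparing the
#' test set against the whole universe (genes without any annotation stay in
#' the denominators). Benjamini-Hochberg q-values are computed over all
#' tested terms; terms with q below the FDR cutoff are flagged.
#'
#' @param test_set character vector of gene ids, subset of `universe`.
#' @param universe character vector of gene ids (the reference set).
#' @param annotations data.frame with `gene_id`, `term`.
#' @param fdr_cutoff flagging threshold on the BH q-value (default 0.005).
#' @param alternative `"over"` (default) or `"under"`.
#' @return data.frame sorted by q then p: term, the 2x2 counts, relative
#'   term frequencies in the test and reference sets, `p`, `q`, `flagged`.
#' @export
enrich <- function(test_set, universe, annotations, fdr_cutoff = 0.005,
                   alternative = c("over", "under")) {
  alternative <- match.arg(alternative)
  test_set <- unique(test_set)
  universe <- unique(universe)
  if (!all(test_set %in% universe)) {
    stop("test_set must be a subset of the universe")
  }
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term")])
  terms <- sort(unique(ann$term))
  n_univ <- length(universe)
  n_test <- length(test_set)
  if (length(terms) == 0) {
    return(data.frame(term = character(0), in_annot = integer(0),
                      in_other = integer(0), out_annot = integer(0),
                      out_other = integer(0), freq_test = numeric(0),
                      freq_ref = numeric(0), p = numeric(0), q = numeric(0),
                      flagged = logical(0), stringsAsFactors = FALSE))
  }
  in_test <- ann$gene_id %in% test_set
  annot_total <- table(factor(ann$term, levels = terms))
  annot_in <- table(factor(ann$term[in_test], levels = terms))
  in_annot <- as.integer(annot_in)
  out_annot <- as.integer(annot_total) - in_annot
  in_other <- n_test - in_annot
  out_other <- (n_univ - n_test) - out_annot
  p <- vapply(seq_along(terms), function(i) {
    fisher_term(in_annot[i], in_other[i], out_annot[i], out_other[i],
                alternative = alternative)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(term = terms,
                    in_annot = in_annot, in_other = in_other,
                    out_annot = out_annot, out_other = out_other,
                    freq_test = if (n_test > 0) in_annot / n_test else NA_real_,
                    freq_ref = as.integer(annot_total) / n_univ,
                    p = p, q = q, flagged = q < fdr_cutoff,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
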