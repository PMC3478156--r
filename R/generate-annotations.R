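#' Generate a synthetic gene -> GO-term annotation table
#'
#' Every term annotates genes independently with a background rate; one
#' optional planted term is over-represented in a designated gene subset by
#' a multiplicative enrichment factor (annotation probability
#' `min(1, factor * background_rate)` inside the subset).
#'
#' @param genes character vector of gene ids (the annotation universe).
#' @param n_terms number of terms (`term001`, ...). `0` gives an empty table.
#' @param planted optional list with `term` (id, must be one of the
#'   generated terms or a new id), `genes` (subset of `genes`) and `factor`
#'   (>= 1).
#' @param background_rate per-term annotation probability outside planted
#'   subsets (default 0.05).
#' @param seed random seed.
#' @return data.frame with columns `gene_id`, `term`.
#' @export
generate_annotations <- function(genes, n_terms, planted = NULL,
                                 background_rate = 0.05, seed = 1L) {
  if (n_terms < 0) stop("configuration error: n_terms must be >= 0")
  terms <- if (n_terms > 0) sprintf("term%03d", seq_len(n_terms)) else character(0)
  if (!is.null(planted)) {
    if (is.null(planted$term) || is.null(planted$genes) ||
        is.null(planted$factor)) {
      stop("configuration error: planted needs term, genes and factor")
    }
    if (planted$factor < 1) {
      stop("configuration error: enrichment factor must be >= 1")
    }
    if (!all(planted$genes %in% genes)) {
      stop("configuration error: planted subset must be within genes")
    }
    terms <- union(terms, planted$term)
  }
  if (length(terms) == 0) {
    return(data.frame(gene_id = character(0), term = character(0),
                      stringsAsFactors = FALSE))
  }
  set.seed(substream_seed(seed, 21L))
  out <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    p <- rep(background_rate, length(genes))
    if (!is.null(planted) && terms[i] == planted$term) {
      p[genes %in% planted$genes] <- pmin(1, planted$factor * background_rate)
    }
    hit <- stats::runif(length(genes)) < p
    out[[i]] <- data.frame(gene_id = genes[hit],
                           term = rep(terms[i], sum(hit)),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write an annotation table to TSV
#'
#' @param annotations data.frame with `gene_id`, `term`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an annotation table from TSV
#'
#' @param path two-column TSV (`gene_id`, `term`).
#' @return data.frame with `gene_id`, `term`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term") %in% names(df))) {
    stop("annotation table needs columns gene_id and term")
  }
  df[, c("gene_id", "term")]
}
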