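#' Time-course design of the synchrony experiment
#'
#' Hours after silicate replenishment at which arrays were hybridized. The
#' 0 h sample is the silicon-starved, arrested culture and serves as the
#' baseline for all fold changes.
#'
#' @return Integer vector of hours, baseline first.
#' @export
design_hours <- function() c(0L, 2L, 4L, 7L, 8L, 9L)

#' Probe-level expression matrix
#'
#' Builds the central data object of the workflow: linear-scale probe
#' intensities indexed by gene, timepoint and probe. All selection
#' statistics, fold-change profiles and clustering read from this object.
#'
#' @param data data.frame with columns `gene_id`, `probe_id`, `timepoint_h`,
#'   `intensity` (linear fluorescence units, strictly positive).
#' @param hours timepoint design; defaults to [design_hours()].
#'
#' @return An object of class `expr_matrix`: the long table plus sorted gene
#'   ids and the hour design.
#' @export
expression_matrix <- function(data, hours = design_hours()) {
  req <- c("gene_id", "probe_id", "timepoint_h", "intensity")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    stop("expression data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  data$gene_id <- as.character(data$gene_id)
  data$probe_id <- as.character(data$probe_id)
  data$timepoint_h <- as.numeric(data$timepoint_h)
  data$intensity <- as.numeric(data$intensity)
  if (anyNA(data$intensity) || any(data$intensity <= 0)) {
    bad <- which(is.na(data$intensity) | data$intensity <= 0)
    stop("non-positive or missing intensity at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  if (!all(data$timepoint_h %in% hours)) {
    stop("timepoint(s) outside the design: ",
         paste(setdiff(unique(data$timepoint_h), hours), collapse = ", "))
  }
  key <- paste(data$gene_id, data$probe_id, data$timepoint_h, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- which(duplicated(key))
    stop("duplicate (gene, probe, timepoint) at data row(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  genes <- sort(unique(data$gene_id))
  # every gene needs >= 2 probes at every timepoint for variance estimates
  cnt <- table(data$gene_id, data$timepoint_h)
  if (ncol(cnt) < length(hours) || any(cnt < 2L)) {
    offenders <- rownames(cnt)[apply(cnt, 1L, function(r) any(r < 2L))]
    if (ncol(cnt) < length(hours)) {
      stop("missing timepoint(s): design has ", length(hours),
           " hours but data covers ", ncol(cnt))
    }
    stop("gene(s) with fewer than 2 probes at some timepoint: ",
         paste(utils::head(offenders, 10L), collapse = ", "))
  }
  structure(
    list(data = data[order(data$gene_id, data$timepoint_h, data$probe_id), ,
                     drop = FALSE],
         genes = genes, hours = sort(as.numeric(hours))),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d timepoints (%s h), %d probe measurements\n",
              length(x$genes), length(x$hours),
              paste(x$hours, collapse = ", "), nrow(x$data)))
  invisible(x)
}

#' Read a probe-level expression matrix from TSV
#'
#' The dialect is the one the generator writes: a header line and the four
#' columns `gene_id`, `probe_id`, `timepoint_h`, `intensity`. Malformed rows
#' are reported with their 1-based file line numbers (header is line 1).
#'
#' @param path path to a tab-separated file.
#' @param hours timepoint design.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, hours = design_hours()) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- which(is.na(df$intensity) | df$intensity <= 0)
  if (length(bad) > 0) {
    stop("non-positive intensity in ", path, " at line(s): ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "))
  }
  key <- paste(df$gene_id, df$probe_id, df$timepoint_h, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (gene, probe, timepoint) in ", path, " at line(s): ",
         paste(utils::head(dup + 1L, 10L), collapse = ", "))
  }
  expression_matrix(df, hours = hours)
}

#' Write a probe-level expression matrix to TSV
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  utils::write.table(x$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Import a GEO series-matrix-style expression table
#'
#' Parses the `!series_matrix_table_begin` ... `!series_matrix_table_end`
#' block of a series-matrix file: rows are probes, columns are samples.
#' Sample columns are mapped to hours of the synchrony via `sample_hours`,
#' and probe ids to genes via `probe_genes`.
#'
#' @param path series-matrix file.
#' @param sample_hours named numeric vector: sample id -> hour.
#' @param probe_genes named character vector: probe id -> gene id.
#' @return An `expr_matrix`.
#' @export
read_series_matrix <- function(path, sample_hours, probe_genes) {
  if (!file.exists(path)) stop("series matrix file not found: ", path)
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L) {
    stop("no series matrix table block found in ", path)
  }
  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  samples <- names(tab)[-1L]
  unknown <- setdiff(samples, names(sample_hours))
  if (length(unknown) > 0) {
    stop("sample(s) without an hour mapping: ", paste(unknown, collapse = ", "))
  }
  probes <- as.character(tab[[1L]])
  if (!all(probes %in% names(probe_genes))) {
    stop("probe(s) without a gene mapping: ",
         paste(utils::head(setdiff(probes, names(probe_genes)), 5L), collapse = ", "))
  }
  long <- data.frame(
    gene_id = rep(unname(probe_genes[probes]), times = length(samples)),
    probe_id = rep(probes, times = length(samples)),
    timepoint_h = rep(unname(sample_hours[samples]), each = length(probes)),
    intensity = as.numeric(unlist(tab[-1L], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  expression_matrix(long)
}

#' Summarize probe intensities to a gene-level value
#'
#' @param x an `expr_matrix`.
#' @param gene gene id.
#' @param hour timepoint (hours).
#' @param method `"median"` (default, robust to probe-affinity outliers) or
#'   `"mean"`.
#' @return Scalar summary intensity (linear scale).
#' @export
summarize_gene <- function(x, gene, hour, method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_matrix"))
  if (!gene %in% x$genes) stop("unknown gene: ", gene)
  if (!hour %in% x$hours) stop("unknown timepoint: ", hour)
  v <- x$data$intensity[x$data$gene_id == gene & x$data$timepoint_h == hour]
  if (method == "median") stats::median(v) else mean(v)
}

# gene x hour matrix of probe summaries, rows ordered as x$genes
gene_summaries <- function(x, method = c("median", "mean")) {
  method <- match.arg(method)
  fun <- if (method == "median") stats::median else mean
  g <- factor(x$data$gene_id, levels = x$genes)
  h <- factor(x$data$timepoint_h, levels = x$hours)
  out <- tapply(x$data$intensity, list(g, h), fun)
  m <- matrix(out, nrow = length(x$genes), ncol = length(x$hours),
              dimnames = list(x$genes, as.character(x$hours)))
  m
}

#' Log2 fold-change profile of a gene
#'
#' Vector of log2(summary_t / summary_0) for the post-replenishment
#' timepoints, the substrate for the co-expression heatmap and clustering.
#'
#' @param x an `expr_matrix`.
#' @param gene gene id.
#' @param method probe summarization method.
#' @return Named numeric vector over the non-baseline hours.
#' @export
log2_profile <- function(x, gene, method = c("median", "mean")) {
  method <- match.arg(method)
  base <- summarize_gene(x, gene, x$hours[1L], method = method)
  later <- x$hours[-1L]
  v <- vapply(later, function(h) {
    log2(summarize_gene(x, gene, h, method = method) / base)
  }, numeric(1))
  names(v) <- as.character(later)
  v
}

#' Log2 fold-change profiles for all genes
#'
#' @param x an `expr_matrix`.
#' @param method probe summarization method.
#' @return Matrix (genes x non-baseline hours) of log2 ratios relative to
#'   the 0 h baseline.
#' @export
log2_profiles <- function(x, method = c("median", "mean")) {
  method <- match.arg(method)
  s <- gene_summaries(x, method = method)
  prof <- log2(s[, -1L, drop = FALSE] / s[, 1L])
  prof
}

#' Profile flatness
#'
#' Maximum absolute log2 ratio across timepoints. A gene whose expression
#' "does not substantially vary" over the synchrony scores below the
#' threshold and is excluded from cluster analysis.
#'
#' @param profile numeric log2-ratio vector (or matrix, one row per gene).
#' @return Numeric flatness score(s).
#' @export
flatness <- function(profile) {
  if (is.matrix(profile)) {
    apply(abs(profile), 1L, max)
  } else {
    max(abs(profile))
  }
}

#' Flat-gene classification
#'
#' @param profile log2-ratio vector or matrix.
#' @param threshold flatness threshold in log2 units (default 0.5, i.e. a
#'   maximal 1.4-fold change).
#' @return Logical: `TRUE` for flat profiles.
#' @export
is_flat <- function(profile, threshold = 0.5) {
  flatness(profile) < threshold
}
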