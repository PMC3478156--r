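# Group summary statistics over pooled probe-level log2 intensities.
# Returns per-gene n, mean, var (rows ordered as x$genes).
group_stats <- function(x, hours) {
  sel <- x$data$timepoint_h %in% hours
  g <- factor(x$data$gene_id[sel], levels = x$genes)
  y <- log2(x$data$intensity[sel])
  n <- as.vector(rowsum(rep(1, length(y)), g))
  s1 <- as.vector(rowsum(y, g))
  s2 <- as.vector(rowsum(y * y, g))
  m <- s1 / n
  v <- (s2 - n * m^2) / (n - 1)
  v <- pmax(v, 0) # guard tiny negative values from cancellation
  list(n = n, mean = m, var = v)
}

# Dataset-wide variance floor: half the smallest nonzero within-group
# (gene x timepoint) variance of log2 intensities. Applied only to
# zero-variance groups so degenerate (noise-free) inputs keep a defined
# statistic without perturbing regular ones.
variance_floor <- function(x) {
  vs <- unlist(lapply(x$hours, function(h) group_stats(x, h)$var))
  nz <- vs[vs > 0]
  if (length(nz) == 0) return(0)
  min(nz) / 2
}

# Vectorised two-sample t on group summary stats. Welch by default;
# Student's pooled-variance variant selectable. Zero variances are lifted
# to `var_floor` before use.
welch_t <- function(sa, sb, method = c("welch", "student"), var_floor = 0) {
  method <- match.arg(method)
  va <- ifelse(sa$var <= 0, var_floor, sa$var)
  vb <- ifelse(sb$var <= 0, var_floor, sb$var)
  d <- sa$mean - sb$mean
  if (method == "welch") {
    sea2 <- va / sa$n
    seb2 <- vb / sb$n
    se <- sqrt(sea2 + seb2)
    df <- (sea2 + seb2)^2 / (sea2^2 / (sa$n - 1) + seb2^2 / (sb$n - 1))
  } else {
    sp2 <- ((sa$n - 1) * va + (sb$n - 1) * vb) / (sa$n + sb$n - 2)
    se <- sqrt(sp2 * (1 / sa$n + 1 / sb$n))
    df <- sa$n + sb$n - 2
  }
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, sign(d) * Inf))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df), ifelse(d == 0, 1, 0))
  list(statistic = t, df = df, p.value = p, mean_a = sa$mean, mean_b = sb$mean)
}

#' Two-sample t-test between pooled timepoints of one gene
#'
#' Compares log2 probe intensities pooled across the hours of group A with
#' those pooled across group B. Probes are the replicates (the design has
#' one array per timepoint). Welch's unequal-variance test is the default;
#' Student's pooled-variance test is available.
#'
#' @param x an `expr_matrix`.
#' @param gene gene id.
#' @param hours_a,hours_b disjoint sets of hours to pool.
#' @param method `"welch"` (default) or `"student"`.
#' @param direction `"two_sided"` (default), `"a_greater"` or `"b_greater"`
#'   for one-sided alternatives.
#' @param var_floor variance substituted for zero within-group variances;
#'   default is [variance_floor] of the two groups at hand.
#' @return List with `statistic`, `df`, `p.value`, and the group means
#'   (`mean_a`, `mean_b`, log2 scale).
#' @export
timepoint_ttest <- function(x, gene, hours_a, hours_b,
                            method = c("welch", "student"),
                            direction = c("two_sided", "a_greater", "b_greater"),
                            var_floor = NULL) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  stopifnot(inherits(x, "expr_matrix"))
  if (!gene %in% x$genes) stop("unknown gene: ", gene)
  if (length(intersect(hours_a, hours_b)) > 0) stop("groups must be disjoint")
  grab <- function(hours) {
    log2(x$data$intensity[x$data$gene_id == gene & x$data$timepoint_h %in% hours])
  }
  ya <- grab(hours_a)
  yb <- grab(hours_b)
  if (length(ya) < 2 || length(yb) < 2) {
    stop("statistic undefined: each group needs >= 2 probe-level values")
  }
  if (is.null(var_floor)) {
    vs <- c(stats::var(ya), stats::var(yb))
    nz <- vs[vs > 0]
    var_floor <- if (length(nz) > 0) min(nz) / 2 else 0
  }
  sa <- list(n = length(ya), mean = mean(ya), var = stats::var(ya))
  sb <- list(n = length(yb), mean = mean(yb), var = stats::var(yb))
  res <- welch_t(sa, sb, method = method, var_floor = var_floor)
  if (direction == "a_greater") {
    res$p.value <- if (is.infinite(res$statistic)) {
      as.numeric(res$statistic < 0)
    } else stats::pt(res$statistic, res$df, lower.tail = FALSE)
  } else if (direction == "b_greater") {
    res$p.value <- if (is.infinite(res$statistic)) {
      as.numeric(res$statistic > 0)
    } else stats::pt(res$statistic, res$df)
  }
  res
}
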