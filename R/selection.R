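#' Specification of a timepoint contrast
#'
#' A named contrast between two disjoint groups of hours, tested on pooled
#' probe-level log2 intensities.
#'
#' @param name label.
#' @param group_a,group_b disjoint, non-empty sets of hours.
#' @param direction `"a_greater"`, `"b_greater"` or `"two_sided"`.
#' @param alpha significance level in (0, 1).
#' @param combine how a rule combines several elementary contrasts
#'   (`"any"` or `"all"`).
#' @return A `contrast_spec` list.
#' @export
contrast_spec <- function(name, group_a, group_b,
                          direction = c("two_sided", "a_greater", "b_greater"),
                          alpha = 0.05, combine = c("any", "all")) {
  direction <- match.arg(direction)
  combine <- match.arg(combine)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("contrast groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0) {
    stop("contrast groups must be disjoint")
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 direction = direction, alpha = alpha, combine = combine),
            class = "contrast_spec")
}

# Vectorised elementary contrast over all genes: two-sided p on pooled log2
# probe intensities plus the sign of the mean difference.
run_contrast <- function(x, hours_a, hours_b,
                         method = c("welch", "student"), var_floor = NULL) {
  method <- match.arg(method)
  if (is.null(var_floor)) var_floor <- variance_floor(x)
  sa <- group_stats(x, hours_a)
  sb <- group_stats(x, hours_b)
  res <- welch_t(sa, sb, method = method, var_floor = var_floor)
  data.frame(gene_id = x$genes,
             statistic = res$statistic,
             p = res$p.value,
             mean_a = res$mean_a,
             mean_b = res$mean_b,
             up = res$mean_a > res$mean_b,
             stringsAsFactors = FALSE)
}

#' Differentially expressed gene universe
#'
#' A gene enters the universe when its expression at at least one
#' post-replenishment timepoint differs significantly (two-sided t-test on
#' probe-level log2 intensities) from the 0 h baseline.
#'
#' @param x an `expr_matrix`.
#' @param alpha per-contrast significance level.
#' @param method t-test variant.
#' @param adjust `"none"` (raw p, the screening default) or
#'   `"BH"` for Benjamini-Hochberg within each contrast.
#' @return data.frame with one row per gene: per-contrast p-values
#'   (`p_<hour>`) and the `selected` flag.
#' @export
select_universe <- function(x, alpha = 0.05, method = c("welch", "student"),
                            adjust = c("none", "BH")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  vf <- variance_floor(x)
  base <- x$hours[1L]
  later <- x$hours[-1L]
  out <- data.frame(gene_id = x$genes, stringsAsFactors = FALSE)
  sel <- rep(FALSE, length(x$genes))
  for (h in later) {
    r <- run_contrast(x, h, base, method = method, var_floor = vf)
    p <- if (adjust == "BH") stats::p.adjust(r$p, "BH") else r$p
    out[[paste0("p_", h)]] <- p
    sel <- sel | (p < alpha)
  }
  out$selected <- sel
  out
}

#' Silaffin-like response genes (SLRG)
#'
#' Genes with the expression profile of the valve-formation marker Tpsil3:
#' significantly up-regulated at 7 h or at 8 h relative to the 0 h and 4 h
#' reference. The 2 h and 9 h timepoints never enter the contrast (girdle
#' band synthesis and post-division signals would confound it).
#'
#' @param x an `expr_matrix`.
#' @param alpha significance level.
#' @param mode `"pooled"` (default): reference is the pooled {0, 4} h group;
#'   `"per_timepoint"`: the test hour must beat 0 h and 4 h separately.
#' @param method t-test variant.
#' @param adjust p-value adjustment, as in [select_universe()].
#' @return data.frame: per-contrast p-values, direction flags, `selected`.
#' @export
select_slrg <- function(x, alpha = 0.05, mode = c("pooled", "per_timepoint"),
                        method = c("welch", "student"),
                        adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  vf <- variance_floor(x)
  adj <- function(p) if (adjust == "BH") stats::p.adjust(p, "BH") else p
  if (mode == "pooled") {
    r7 <- run_contrast(x, 7, c(0, 4), method = method, var_floor = vf)
    r8 <- run_contrast(x, 8, c(0, 4), method = method, var_floor = vf)
    p7 <- adj(r7$p); p8 <- adj(r8$p)
    out <- data.frame(gene_id = x$genes,
                      p_7 = p7, up_7 = r7$up,
                      p_8 = p8, up_8 = r8$up,
                      stringsAsFactors = FALSE)
    out$selected <- (p7 < alpha & r7$up) | (p8 < alpha & r8$up)
  } else {
    hit <- function(h) {
      r0 <- run_contrast(x, h, 0, method = method, var_floor = vf)
      r4 <- run_contrast(x, h, 4, method = method, var_floor = vf)
      list(p0 = adj(r0$p), p4 = adj(r4$p),
           ok = adj(r0$p) < alpha & r0$up & adj(r4$p) < alpha & r4$up)
    }
    h7 <- hit(7); h8 <- hit(8)
    out <- data.frame(gene_id = x$genes,
                      p_7_vs_0 = h7$p0, p_7_vs_4 = h7$p4,
                      p_8_vs_0 = h8$p0, p_8_vs_4 = h8$p4,
                      stringsAsFactors = FALSE)
    out$selected <- h7$ok | h8$ok
  }
  out
}

#' Silicon starvation response genes (SSRG)
#'
#' Genes significantly up-regulated in the starved, arrested culture (0 h)
#' relative to the post-replenishment timepoints.
#'
#' @param x an `expr_matrix`.
#' @param alpha significance level.
#' @param combine `"all"` (default): 0 h must beat every one of
#'   {2, 4, 7, 8, 9} h; `"any"`: any one suffices; `"pooled"`: 0 h against
#'   the pooled post-replenishment group.
#' @param method t-test variant.
#' @param adjust p-value adjustment, as in [select_universe()].
#' @return data.frame: per-contrast p-values, direction flags, `selected`.
#' @export
select_ssrg <- function(x, alpha = 0.05, combine = c("all", "any", "pooled"),
                        method = c("welch", "student"),
                        adjust = c("none", "BH")) {
  combine <- match.arg(combine)
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  vf <- variance_floor(x)
  adj <- function(p) if (adjust == "BH") stats::p.adjust(p, "BH") else p
  base <- x$hours[1L]
  later <- x$hours[-1L]
  out <- data.frame(gene_id = x$genes, stringsAsFactors = FALSE)
  if (combine == "pooled") {
    r <- run_contrast(x, base, later, method = method, var_floor = vf)
    p <- adj(r$p)
    out$p_pooled <- p
    out$selected <- p < alpha & r$up
    return(out)
  }
  hits <- matrix(FALSE, nrow = length(x$genes), ncol = length(later))
  for (i in seq_along(later)) {
    r <- run_contrast(x, base, later[i], method = method, var_floor = vf)
    p <- adj(r$p)
    out[[paste0("p_", later[i])]] <- p
    hits[, i] <- p < alpha & r$up
  }
  out$selected <- if (combine == "all") rowSums(hits) == ncol(hits)
                  else rowSums(hits) > 0
  out
}

#' Apply a generic timepoint contrast to every gene
#'
#' @param x an `expr_matrix`.
#' @param spec a [contrast_spec()].
#' @param method t-test variant.
#' @return data.frame: gene, statistic, p (respecting the spec's direction),
#'   direction sign and `selected` at the spec's alpha.
#' @export
apply_contrast <- function(x, spec, method = c("welch", "student")) {
  stopifnot(inherits(spec, "contrast_spec"))
  method <- match.arg(method)
  r <- run_contrast(x, spec$group_a, spec$group_b, method = method)
  p <- r$p
  ok <- rep(TRUE, nrow(r))
  if (spec$direction == "a_greater") ok <- r$up
  if (spec$direction == "b_greater") ok <- !r$up & r$mean_a != r$mean_b
  data.frame(gene_id = r$gene_id, statistic = r$statistic, p = p,
             sign = sign(r$mean_a - r$mean_b),
             selected = p < spec$alpha & ok,
             stringsAsFactors = FALSE)
}

#' Write a selection result table to TSV
#'
#' @param result data.frame from one of the `select_*` functions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
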