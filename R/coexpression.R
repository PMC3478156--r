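#' Distance between fold-change profiles
#'
#' @param profiles matrix (genes x timepoints) of log2 ratios, rownames =
#'   gene ids.
#' @param metric `"one_minus_pearson"` (default; in [0, 2], invariant to
#'   positive affine transforms of a profile) or `"euclidean"`.
#' @return A `dist` object. Under the correlation metric, constant profiles
#'   (zero variance, correlation undefined) are dropped with a warning.
#' @export
profile_dist <- function(profiles, metric = c("one_minus_pearson", "euclidean")) {
  metric <- match.arg(metric)
  if (is.null(rownames(profiles))) stop("profiles must have gene rownames")
  if (metric == "one_minus_pearson") {
    sds <- apply(profiles, 1L, stats::sd)
    if (any(sds == 0)) {
      warning("excluding ", sum(sds == 0),
              " constant profile(s) (correlation undefined): ",
              paste(utils::head(rownames(profiles)[sds == 0], 5L),
                    collapse = ", "))
      profiles <- profiles[sds > 0, , drop = FALSE]
    }
    if (nrow(profiles) < 2) stop("need >= 2 non-constant profiles")
    stats::as.dist(1 - stats::cor(t(profiles)))
  } else {
    if (nrow(profiles) < 2) stop("need >= 2 profiles")
    stats::dist(profiles)
  }
}

#' Hierarchical clustering of fold-change profiles
#'
#' Agglomerative clustering of per-gene log2-ratio profiles, the operation
#' behind the expression heatmap. Input rows are sorted by gene id before
#' agglomeration so the tree is independent of input order (distance ties
#' are then resolved by the sorted order, i.e. lexicographically by gene
#' id).
#'
#' @param profiles matrix of log2 ratios with gene rownames.
#' @param metric see [profile_dist()].
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return An `hclust` object.
#' @export
cluster_profiles <- function(profiles,
                             metric = c("one_minus_pearson", "euclidean"),
                             linkage = c("average", "complete", "single")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  d <- profile_dist(profiles, metric = metric)
  stats::hclust(d, method = linkage)
}

# leaf labels under each merge-tree node of an hclust object
node_members <- function(hc) {
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    mem <- integer(0)
    for (k in kids) {
      mem <- c(mem, if (k < 0) -k else members[[k]])
    }
    members[[i]] <- mem
  }
  lapply(members, function(ix) hc$labels[ix])
}

#' Marker-anchored co-expression cluster
#'
#' The largest dendrogram subtree containing the marker gene in which every
#' member's Pearson correlation with the marker profile reaches `r_min`.
#' This reproduces "the heatmap cluster containing the marker" without
#' committing to a fixed cut height.
#'
#' @param hc `hclust` tree from [cluster_profiles()].
#' @param profiles the profile matrix the tree was built from.
#' @param marker marker gene id (must be a leaf).
#' @param r_min correlation floor (default 0.9).
#' @return List of class `marker_cluster`: `marker`, `members`, `min_cor`,
#'   `r_min`.
#' @export
marker_cluster <- function(hc, profiles, marker, r_min = 0.9) {
  if (!marker %in% hc$labels) {
    if (marker %in% rownames(profiles)) {
      stop("marker '", marker,
           "' was excluded from clustering (constant profile)")
    }
    stop("marker '", marker, "' is not among the clustered genes")
  }
  mp <- profiles[marker, ]
  cors <- apply(profiles[hc$labels, , drop = FALSE], 1L,
                function(v) suppressWarnings(stats::cor(v, mp)))
  members <- node_members(hc)
  best <- marker
  for (i in seq_along(members)) {
    if (!marker %in% members[[i]]) next
    cs <- cors[members[[i]]]
    if (any(is.na(cs)) || any(cs < r_min)) next
    if (length(members[[i]]) > length(best)) best <- members[[i]]
  }
  structure(list(marker = marker,
                 members = sort(best),
                 min_cor = min(cors[best]),
                 r_min = r_min),
            class = "marker_cluster")
}

#' @export
print.marker_cluster <- function(x, ...) {
  cat(sprintf("marker_cluster: %d genes around '%s' (min cor %.3f, r_min %.2f)\n",
              length(x$members), x$marker, x$min_cor, x$r_min))
  invisible(x)
}

#' Silicon-transporter co-regulation clusters
#'
#' For each marker (the SIT1/SIT2/SIT3 paralogs), either a "flat" verdict —
#' the marker's expression does not substantially vary over the synchrony,
#' so cluster analysis is not performed — or the marker-anchored cluster
#' extracted from the non-flat gene universe.
#'
#' @param profiles matrix of log2 ratios with gene rownames (all candidate
#'   genes; flat ones are removed internally).
#' @param markers named character vector of marker gene ids.
#' @param r_min correlation floor for cluster membership.
#' @param flat_threshold flatness threshold (max |log2 ratio|).
#' @param metric,linkage clustering parameters.
#' @return Named list, one entry per marker: either the string `"flat"` or a
#'   `marker_cluster`.
#' @export
sit_coregulation <- function(profiles, markers, r_min = 0.9,
                             flat_threshold = 0.5,
                             metric = c("one_minus_pearson", "euclidean"),
                             linkage = c("average", "complete", "single")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  missing_m <- setdiff(markers, rownames(profiles))
  if (length(missing_m) > 0) {
    stop("unknown marker gene(s): ", paste(missing_m, collapse = ", "))
  }
  keep <- !is_flat(profiles, threshold = flat_threshold)
  nonflat <- profiles[keep, , drop = FALSE]
  hc <- NULL
  out <- vector("list", length(markers))
  names(out) <- names(markers)
  for (i in seq_along(markers)) {
    m <- markers[i]
    if (is_flat(profiles[m, ], threshold = flat_threshold)) {
      out[[i]] <- "flat"
      next
    }
    if (is.null(hc)) {
      hc <- cluster_profiles(nonflat, metric = metric, linkage = linkage)
    }
    out[[i]] <- marker_cluster(hc, nonflat, m, r_min = r_min)
  }
  out
}

#' Export a dendrogram in Newick format
#'
#' @param hc an `hclust` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write cluster membership to TSV
#'
#' @param cluster a `marker_cluster` (or list of them / "flat" verdicts).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster <- function(cluster, path) {
  rows <- function(cl, name) {
    if (identical(cl, "flat")) {
      data.frame(cluster = name, gene_id = NA_character_, verdict = "flat",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = name, gene_id = cl$members, verdict = "member",
                 stringsAsFactors = FALSE)
    }
  }
  df <- if (inherits(cluster, "marker_cluster")) {
    rows(cluster, cluster$marker)
  } else {
    do.call(rbind, lapply(names(cluster), function(nm) rows(cluster[[nm]], nm)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
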