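# Independent brute-force oracles used to verify the package implementations.

# Textbook two-sample t (closed form), Welch or pooled-variance Student.
oracle_ttest <- function(a, b, welch = TRUE) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  d <- mean(a) - mean(b)
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  t <- d / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Hypergeometric upper-tail by direct summation over the support with
# choose(); independent of phyper.
oracle_hyper_tail <- function(in_annot, in_other, out_annot, out_other) {
  k_annot <- in_annot + out_annot
  k_other <- in_other + out_other
  n_test <- in_annot + in_other
  hi <- min(k_annot, n_test)
  if (in_annot > hi) return(0)
  ks <- in_annot:hi
  sum(choose(k_annot, ks) * choose(k_other, n_test - ks)) /
    choose(k_annot + k_other, n_test)
}

# Benjamini-Hochberg by explicit sort and cumulative minimum.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- (m / seq_len(m)) * p[o]
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# O(n^3) agglomerative clustering returning merge heights, for checking
# hclust-based trees. dist_m: full symmetric distance matrix.
oracle_agglomerate <- function(dist_m, linkage = "average") {
  n <- nrow(dist_m)
  clusters <- as.list(seq_len(n))
  d <- dist_m
  active <- seq_len(n)
  heights <- numeric(n - 1)
  members <- list()
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i >= j) next
        dij <- d[active[i], active[j]]
        if (dij < bestd) {
          bestd <- dij
          best <- c(active[i], active[j])
        }
      }
    }
    a <- best[1]; b <- best[2]
    heights[step] <- bestd
    merged <- c(clusters[[a]], clusters[[b]])
    members[[step]] <- sort(merged)
    # update distances to the new cluster, stored at slot a
    for (k in active) {
      if (k == a || k == b) next
      dd <- switch(linkage,
        average = (length(clusters[[a]]) * d[a, k] +
                   length(clusters[[b]]) * d[b, k]) /
                  (length(clusters[[a]]) + length(clusters[[b]])),
        complete = max(d[a, k], d[b, k]),
        single = min(d[a, k], d[b, k]))
      d[a, k] <- dd
      d[k, a] <- dd
    }
    clusters[[a]] <- merged
    active <- setdiff(active, b)
  }
  list(heights = heights, members = members)
}

# Brute-force motif matcher: position-by-position comparison.
oracle_motif <- function(seq, pattern) {
  s <- strsplit(toupper(seq), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  hits <- integer(0)
  if (length(p) > length(s)) return(hits)
  for (i in seq_len(length(s) - length(p) + 1)) {
    ok <- TRUE
    for (j in seq_along(p)) {
      if (p[j] != "X" && s[i + j - 1] != p[j]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

# Brute-force Kyte-Doolittle window scan (no cumsum tricks).
oracle_tm_windows <- function(seq, window = 19, threshold = 1.6) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2, X = 0)
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (n < window) return(integer(0))
  which(vapply(seq_len(n - window + 1), function(i) {
    sum(round(kd[s[i:(i + window - 1)]] * 10)) >=
      threshold * window * 10 - 1e-6
  }, logical(1)))
}

# Small expression matrix from explicit probe values:
# values = list(gene_id = list(`0` = c(...), `2` = c(...), ...))
toy_matrix <- function(values, hours = design_hours()) {
  rows <- list()
  for (g in names(values)) {
    for (h in names(values[[g]])) {
      v <- values[[g]][[h]]
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = g,
        probe_id = paste0(g, "_p", seq_along(v)),
        timepoint_h = as.numeric(h),
        intensity = v,
        stringsAsFactors = FALSE)
    }
  }
  expression_matrix(do.call(rbind, rows), hours = hours)
}

# Gene with the same probe vector at every timepoint, scaled per hour.
toy_gene <- function(base = c(90, 100, 110, 100), scale_by_hour = rep(1, 6),
                     hours = design_hours()) {
  v <- lapply(seq_along(hours), function(i) base * scale_by_hour[i])
  names(v) <- as.character(hours)
  v
}
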