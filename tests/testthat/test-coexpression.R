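make_profiles <- function(n, seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n * 5, sd = sd), nrow = n,
              dimnames = list(sprintf("g%03d", seq_len(n)),
                              c("2", "4", "7", "8", "9")))
  m
}

test_that("identical profiles merge first; anti-correlated last", {
  prof <- rbind(a = c(1, 0, 3, 3, 0.5),
                b = c(1, 0, 3, 3, 0.5) * 2 + 1,   # cor = 1 with a
                c = -c(1, 0, 3, 3, 0.5))
  hc <- cluster_profiles(prof)
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("a", "b"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
})

test_that("merge heights match the brute-force agglomeration oracle", {
  for (linkage in c("average", "complete", "single")) {
    prof <- make_profiles(10, seed = 21)
    hc <- cluster_profiles(prof, linkage = linkage)
    d <- as.matrix(1 - cor(t(prof)))
    orc <- oracle_agglomerate(d, linkage = linkage)
    expect_equal(hc$height, orc$heights, tolerance = 1e-12,
                 info = linkage)
    # memberships at every merge agree
    mine <- lapply(seq_len(nrow(hc$merge)), function(i) NULL)
    members <- list()
    for (i in seq_len(nrow(hc$merge))) {
      kids <- hc$merge[i, ]
      mem <- integer(0)
      for (k in kids) mem <- c(mem, if (k < 0) -k else members[[k]])
      members[[i]] <- mem
      mine[[i]] <- sort(hc$labels[mem])
    }
    theirs <- lapply(orc$members, function(ix) sort(rownames(prof)[ix]))
    expect_equal(mine, theirs, info = linkage)
  }
})

test_that("clustering is invariant to input row order", {
  prof <- make_profiles(15, seed = 22)
  hc1 <- cluster_profiles(prof)
  perm <- sample(nrow(prof))
  hc2 <- cluster_profiles(prof[perm, ])
  expect_identical(hc1$labels, hc2$labels)
  expect_equal(hc1$height, hc2$height)
  for (k in 2:6) {
    c1 <- cutree(hc1, k)
    c2 <- cutree(hc2, k)
    # same partition up to cluster relabelling
    expect_equal(length(unique(paste(c1, c2))), k)
  }
})

test_that("constant profiles are excluded with a warning under correlation", {
  prof <- rbind(make_profiles(4, seed = 23), konst = rep(2, 5))
  expect_warning(d <- profile_dist(prof), "constant")
  expect_equal(attr(d, "Size"), 4)
  hc <- suppressWarnings(cluster_profiles(prof))
  expect_false("konst" %in% hc$labels)
  expect_error(marker_cluster(hc, prof, "konst"), "constant")
  expect_error(marker_cluster(hc, prof, "missing"), "not among")
})

test_that("marker_cluster respects the correlation floor", {
  prof <- make_profiles(12, seed = 24)
  hc <- cluster_profiles(prof)
  # r_min = 1 with no duplicates: the marker alone
  mc1 <- marker_cluster(hc, prof, "g001", r_min = 1)
  expect_equal(mc1$members, "g001")
  # r_min = -1: the whole tree
  mcall <- marker_cluster(hc, prof, "g001", r_min = -1)
  expect_setequal(mcall$members, rownames(prof))
  # monotone in r_min: raising the floor never adds members
  rs <- c(-1, 0, 0.5, 0.9, 1)
  sizes <- vapply(rs, function(r) {
    length(marker_cluster(hc, prof, "g001", r_min = r)$members)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # every member satisfies the floor
  mc <- marker_cluster(hc, prof, "g001", r_min = 0.5)
  cors <- apply(prof[mc$members, , drop = FALSE], 1,
                function(v) cor(v, prof["g001", ]))
  expect_true(all(cors >= 0.5))
  expect_equal(mc$min_cor, min(cors))
})

test_that("correlation-based clusters are invariant to affine profile maps", {
  prof <- make_profiles(10, seed = 25)
  prof2 <- prof
  prof2["g003", ] <- 2.5 * prof["g003", ] + 7   # positive scale + shift
  hc1 <- cluster_profiles(prof)
  hc2 <- cluster_profiles(prof2)
  expect_equal(hc1$height, hc2$height, tolerance = 1e-12)
  mc1 <- marker_cluster(hc1, prof, "g003", r_min = 0)
  mc2 <- marker_cluster(hc2, prof2, "g003", r_min = 0)
  expect_identical(mc1$members, mc2$members)
})

test_that("planted marker groups are recovered from noisy data", {
  cfg <- generator_config(
    n_genes = 300,
    # shaped archetypes over a flat background: a constant-shape archetype
    # (uniform fold change at all timepoints) has no defined correlation
    # geometry and is not a meaningful part of a shape-recovery experiment
    archetype_mixture = c(silaffin = 23 / 300, sit1 = 10 / 300,
                          sit2 = 15 / 300,
                          flat = 1 - 23 / 300 - 10 / 300 - 15 / 300),
    noise_sd = 0.15, seed = 26)
  g <- generate_expression(cfg)
  tr <- g$truth$genes
  prof <- log2_profiles(g$matrix)
  planted <- tr$gene_id[tr$archetype == "silaffin"]
  marker <- planted[1]
  nonflat <- prof[!is_flat(prof), , drop = FALSE]
  hc <- suppressWarnings(cluster_profiles(nonflat))
  mc <- marker_cluster(hc, nonflat, marker)
  expect_gte(length(intersect(mc$members, planted)), 0.9 * length(planted))
  expect_lte(length(setdiff(mc$members, planted)), 1)
})

test_that("SIT markers get clusters or a flat verdict", {
  cfg <- generator_config(
    n_genes = 300,
    # shaped archetypes over a flat background: a constant-shape archetype
    # (uniform fold change at all timepoints) has no defined correlation
    # geometry and is not a meaningful part of a shape-recovery experiment
    archetype_mixture = c(silaffin = 23 / 300, sit1 = 10 / 300,
                          sit2 = 15 / 300,
                          flat = 1 - 23 / 300 - 10 / 300 - 15 / 300),
    noise_sd = 0.15, seed = 27)
  g <- generate_expression(cfg)
  tr <- g$truth$genes
  prof <- log2_profiles(g$matrix)
  sit1_genes <- tr$gene_id[tr$archetype == "sit1"]
  sit2_genes <- tr$gene_id[tr$archetype == "sit2"]
  markers <- c(sit1 = sit1_genes[1], sit2 = sit2_genes[1],
               sit3 = tr$gene_id[tr$archetype == "flat"][1])
  res <- suppressWarnings(sit_coregulation(prof, markers))
  expect_identical(res$sit3, "flat")
  # each recovered cluster within 1 member of its planted set
  for (pair in list(list(res$sit1, sit1_genes), list(res$sit2, sit2_genes))) {
    got <- pair[[1]]$members
    want <- pair[[2]]
    expect_lte(length(setdiff(got, want)) + length(setdiff(want, got)), 1)
  }
  # SIT1/SIT2 archetype correlation is below the floor: disjoint clusters
  expect_length(intersect(res$sit1$members, res$sit2$members), 0)
  expect_error(sit_coregulation(prof, c(sit1 = "nope")), "unknown marker")
})

test_that("dendrograms export to Newick with all genes as tips", {
  prof <- make_profiles(8, seed = 28)
  hc <- cluster_profiles(prof)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(prof))
})
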