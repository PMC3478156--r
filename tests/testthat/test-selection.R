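test_that("t statistics match the closed-form oracle", {
  # equal-variance groups: Welch reduces to Student, t = 8.573 at df = 4
  a <- c(8, 9, 10); b <- c(1, 2, 3)
  x <- toy_matrix(list(g1 = list(`0` = 2^b, `2` = 2^a, `4` = 2^b,
                                 `7` = 2^a, `8` = 2^a, `9` = 2^b)))
  res <- timepoint_ttest(x, "g1", hours_a = 2, hours_b = 0)
  orc <- oracle_ttest(a, b)
  expect_equal(res$statistic, orc$t, tolerance = 1e-10)
  expect_equal(res$statistic, 7 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(round(res$statistic, 3), 8.573)
  expect_equal(res$df, 4, tolerance = 1e-10)
  expect_equal(res$p.value, orc$p, tolerance = 1e-10)
  expect_lt(res$p.value, 2e-3)

  # unequal-variance groups against stats::t.test as independent check
  set.seed(42)
  for (r in 1:20) {
    ya <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 3))
    yb <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    xm <- toy_matrix(list(g = list(`0` = 2^yb, `2` = 2^ya, `4` = 2^yb,
                                   `7` = 2^ya, `8` = 2^ya, `9` = 2^yb)))
    mine <- timepoint_ttest(xm, "g", 2, 0)
    ref <- t.test(ya, yb)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
    mine_s <- timepoint_ttest(xm, "g", 2, 0, method = "student")
    ref_s <- t.test(ya, yb, var.equal = TRUE)
    expect_equal(mine_s$statistic, unname(ref_s$statistic), tolerance = 1e-10)
    expect_equal(mine_s$p.value, ref_s$p.value, tolerance = 1e-10)
  }
})

test_that("identical groups give t = 0, p = 1", {
  x <- toy_matrix(list(g1 = toy_gene(base = c(10, 20, 30))))
  res <- timepoint_ttest(x, "g1", 7, 0)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
})

test_that("pooled groups and degenerate variances are handled", {
  x <- toy_matrix(list(g1 = list(`0` = c(100, 100), `2` = c(100, 100),
                                 `4` = c(100, 100), `7` = c(800, 800),
                                 `8` = c(800, 800), `9` = c(100, 100))))
  # zero variance but a real difference: selected with p -> 0
  res <- timepoint_ttest(x, "g1", 7, 0)
  expect_lt(res$p.value, 1e-6)
  u <- select_universe(x)
  expect_true(u$selected[u$gene_id == "g1"])
  # zero variance, zero difference
  res0 <- timepoint_ttest(x, "g1", 4, 0)
  expect_equal(res0$p.value, 1)
  expect_error(timepoint_ttest(x, "g1", 7, 7), "disjoint")
  expect_error(
    timepoint_ttest(toy_matrix(list(g1 = toy_gene(base = c(1, 2)))),
                    "zz", 7, 0), "unknown gene")
})

test_that("SLRG rule requires up-regulation at 7 or 8 h vs the 0/4 h pool", {
  up <- toy_gene(base = c(100, 104, 96, 101), scale_by_hour = c(1, 1, 1, 8, 8, 1))
  down <- toy_gene(base = c(100, 104, 96, 101), scale_by_hour = c(8, 1, 8, 1, 1, 1))
  flat <- toy_gene(base = c(100, 104, 96, 101))
  x <- toy_matrix(list(up = up, down = down, flat = flat))
  sl <- select_slrg(x)
  expect_true(sl$selected[sl$gene_id == "up"])
  # higher 0 h than 7/8 h: never selected regardless of p
  expect_false(sl$selected[sl$gene_id == "down"])
  expect_false(sl$selected[sl$gene_id == "flat"])
  # all-equal matrix -> empty selection
  xeq <- toy_matrix(list(a = flat, b = flat))
  expect_false(any(select_slrg(xeq)$selected))
  # the 2 h and 9 h signals never enter: a gene up only at 2 and 9 h
  only29 <- toy_gene(base = c(100, 104, 96, 101),
                     scale_by_hour = c(1, 8, 1, 1, 1, 8))
  x29 <- toy_matrix(list(g = only29))
  expect_false(any(select_slrg(x29)$selected))
  # per-timepoint mode agrees on this clean case
  slp <- select_slrg(x, mode = "per_timepoint")
  expect_true(slp$selected[slp$gene_id == "up"])
  expect_false(slp$selected[slp$gene_id == "down"])
})

test_that("SSRG rule requires 0 h above every later timepoint", {
  starved <- toy_gene(base = c(100, 104, 96, 101),
                      scale_by_hour = c(8, 1, 1, 1, 1, 1))
  # elevated at 0 h AND equally at 7 h: not selected under combine = all
  twopeak <- toy_gene(base = c(100, 104, 96, 101),
                      scale_by_hour = c(8, 1, 1, 8, 1, 1))
  x <- toy_matrix(list(starved = starved, twopeak = twopeak))
  ss <- select_ssrg(x)
  expect_true(ss$selected[ss$gene_id == "starved"])
  expect_false(ss$selected[ss$gene_id == "twopeak"])
  # combine = any accepts the two-peak gene
  ssany <- select_ssrg(x, combine = "any")
  expect_true(ssany$selected[ssany$gene_id == "twopeak"])
  # pooled mode selects the starved gene
  sspool <- select_ssrg(x, combine = "pooled")
  expect_true(sspool$selected[sspool$gene_id == "starved"])
})

test_that("selection is invariant to per-gene intensity scaling", {
  cfg <- generator_config(n_genes = 50, seed = 13)
  g <- generate_expression(cfg)
  x <- g$matrix
  scaled <- x$data
  scaled$intensity <- scaled$intensity * 1000
  x2 <- expression_matrix(scaled)
  expect_equal(select_slrg(x)$selected, select_slrg(x2)$selected)
  expect_equal(select_ssrg(x)$selected, select_ssrg(x2)$selected)
  expect_equal(select_universe(x)$selected, select_universe(x2)$selected)
})

test_that("SLRG and SSRG are disjoint on zero-noise data", {
  cfg <- generator_config(
    n_genes = 60,
    archetype_mixture = c(silaffin = 0.3, starvation = 0.3, flat = 0.4),
    probe_affinity_sd = 0, noise_sd = 0, seed = 14)
  g <- generate_expression(cfg)
  # zero-noise probes are identical within groups; variance floor keeps the
  # statistic defined
  sl <- select_slrg(g$matrix)
  ss <- select_ssrg(g$matrix)
  expect_length(intersect(sl$gene_id[sl$selected], ss$gene_id[ss$selected]), 0)
  tr <- g$truth$genes
  expect_setequal(sl$gene_id[sl$selected], tr$gene_id[tr$archetype == "silaffin"])
  expect_setequal(ss$gene_id[ss$selected], tr$gene_id[tr$archetype == "starvation"])
})

test_that("generic contrasts respect direction and validate groups", {
  expect_error(contrast_spec("x", c(7, 8), c(8, 0)), "disjoint")
  expect_error(contrast_spec("x", numeric(0), 0), "non-empty")
  expect_error(contrast_spec("x", 7, 0, alpha = 1.5), "alpha")
  up <- toy_gene(base = c(100, 104, 96, 101), scale_by_hour = c(1, 1, 1, 8, 8, 1))
  x <- toy_matrix(list(g = up))
  spec_up <- contrast_spec("valve", c(7, 8), c(0, 4), direction = "a_greater")
  spec_down <- contrast_spec("valve", c(7, 8), c(0, 4), direction = "b_greater")
  expect_true(apply_contrast(x, spec_up)$selected)
  expect_false(apply_contrast(x, spec_down)$selected)
})

test_that("BH adjustment is available behind a flag and is more stringent", {
  cfg <- generator_config(n_genes = 200, seed = 15)
  g <- generate_expression(cfg)
  raw <- select_slrg(g$matrix)
  adj <- select_slrg(g$matrix, adjust = "BH")
  expect_true(all(adj$p_7 >= raw$p_7 - 1e-12))
  expect_true(all(raw$selected | !adj$selected))
})
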