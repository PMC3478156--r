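test_that("composition is exact integer arithmetic scaled to percent", {
  comp <- composition("SSSSSKKKKK")
  expect_equal(comp[["S"]], 50)
  expect_equal(comp[["K"]], 50)
  expect_equal(sum(comp), 100)
  comp2 <- composition("ACDEFGHIKL")
  for (aa in strsplit("ACDEFGHIKL", "")[[1]]) {
    expect_equal(comp2[[aa]], 10)
  }
  # sub-range, 1-based inclusive
  expect_equal(composition("AAAASSSS", range = c(5, 8))[["S"]], 100)
  expect_equal(composition("AAAASSSS", range = c(1, 8)),
               composition("AAAASSSS"))
  expect_error(composition("AAAA", range = c(3, 2)), "invalid range")
  expect_error(composition("AAAA", range = c(0, 2)), "invalid range")
  expect_error(composition("AB1"), "non-standard")
  # case-insensitive
  expect_equal(composition("ssssskkkkk"), composition("SSSSSKKKKK"))
})

test_that("the Ser/Lys screen is boundary-inclusive and needs a signal peptide", {
  # mature sequence at exactly 18% Ser / 10% Lys (50 residues: 9 S, 5 K)
  mature <- paste(c(rep("S", 9), rep("K", 5), rep("D", 36)), collapse = "")
  sp_prefix <- "MKLLVLLFLLAQA"   # cleavage after position 13
  seq <- paste0(sp_prefix, mature)
  call <- targeting_call(seq)
  expect_true(call$sp_present)
  expect_equal(call$cleavage, 13)
  expect_true(scheffel_screen(seq, call))
  # same composition, no signal peptide
  no_sp <- paste0("M", mature, "M")
  call2 <- list(sp_present = FALSE, cleavage = NA_integer_)
  expect_false(scheffel_screen(no_sp, call2))
  # one serine short of the threshold fails
  mature_low <- paste(c(rep("S", 8), rep("K", 5), rep("D", 37)), collapse = "")
  seq_low <- paste0(sp_prefix, mature_low)
  expect_false(scheffel_screen(seq_low, targeting_call(seq_low)))
})

test_that("motif scan finds overlapping hits and matches the brute matcher", {
  expect_equal(motif_scan("AKSSKA", "KSSK"), 2L)
  expect_equal(motif_scan("KSSKSSK", "KXXK"), c(1L, 4L))
  expect_equal(motif_scan("MSMSMSM", "MSMSM"), c(1L, 3L))
  expect_length(motif_scan("AAAA", "KSSK"), 0)
  expect_error(motif_scan("AAAA", ""), "empty")
  expect_error(motif_scan("AAAA", "K1K"), "standard residues")
  set.seed(12)
  for (r in 1:30) {
    seq <- paste(sample(c("K", "S", "M", "A"), 200, replace = TRUE),
                 collapse = "")
    for (pat in c("KXXK", "KSSK", "MSMSM", "XKX")) {
      expect_identical(motif_scan(seq, pat), oracle_motif(seq, pat),
                       info = pat)
    }
  }
})

test_that("perfect tandem repeats are reported exactly", {
  expect_rep <- function(seq, p_range, period, copies) {
    rep <- repeat_detect(seq, p_range = p_range)
    expect_equal(nrow(rep), 1)
    expect_equal(rep$period, period)
    expect_equal(rep$copies, copies)
    expect_equal(rep$identity, 1.0)
  }
  expect_rep("ACDEACDEACDE", c(2, 5), 4, 3)
  # p = 8 also matches over 4 positions but span < 2p: not reported
  rep8 <- repeat_detect("ACDEACDEACDE", p_range = c(8, 8))
  expect_equal(nrow(rep8), 0)
  # property: random units, all periods and copy numbers
  set.seed(13)
  for (r in 1:25) {
    p <- sample(3:20, 1)
    k <- sample(2:5, 1)
    unit <- sample(c("A","R","N","D","C","Q","E","G","H","I",
                          "L","K","M","F","P","S","T","W","Y","V"),
                   p, replace = TRUE)
    # skip degenerate units with internal period
    if (any(vapply(seq_len(p - 1), function(q) {
      all(unit[seq_len(p - q)] == unit[(q + 1):p])
    }, logical(1)))) next
    seq <- paste(rep(unit, k), collapse = "")
    reps <- repeat_detect(seq, p_range = c(2, p), identity_min = 0.9)
    expect_equal(nrow(reps), 1, info = paste(p, k))
    expect_equal(reps$period, p)
    expect_equal(reps$copies, k)
    expect_equal(reps$identity, 1.0)
  }
})

test_that("a noisy 53-residue x3 repeat is detected at period 53", {
  set.seed(14)
  pr <- generate_proteome(proteome_config(
    6, frac_repeat = 1, frac_motif = 0, frac_signal = 0, frac_tm = 0,
    frac_serlys = 0, length_range = c(322, 322), seed = 15))
  for (i in seq_along(pr$proteins)) {
    reps <- repeat_detect(pr$proteins[[i]], p_range = c(2, 60),
                          identity_min = 0.5)
    hit <- reps[reps$period == 53, ]
    expect_equal(nrow(hit), 1)
    expect_gte(hit$copies, 3)
  }
  expect_error(repeat_detect("AAAA", p_range = c(1, 2)), "period range")
})

test_that("the signal-peptide heuristic follows the (-3,-1) rule", {
  seq <- paste0("MKLLLLLLLLAGASALA",
                paste(rep("DNEQ", 50), collapse = ""))
  call <- signal_peptide(seq)
  expect_true(call$sp_present)
  # cleavage after c - 1 with small residues at c-3 and c-1
  ch <- strsplit(seq, "")[[1]]
  cc <- call$cleavage + 1
  expect_true(ch[cc - 3] %in% c("A", "G", "S", "C", "T"))
  expect_true(ch[cc - 1] %in% c("A", "G", "S", "C", "T"))
  # poly-Ser has no hydrophobic window
  expect_false(signal_peptide(strrep("S", 200))$sp_present)
  # no call on short sequences, not an error
  expect_true(is.na(signal_peptide("MKLLLLLLLLAGA")$sp_present))
  # case-insensitive and deterministic
  expect_identical(signal_peptide(tolower(seq)), signal_peptide(seq))
})

test_that("TM segments follow Kyte-Doolittle windows and merge overlaps", {
  expect_equal(nrow(tm_segments(strrep("L", 30))), 1)
  expect_equal(tm_segments(strrep("L", 30))$start, 1)
  expect_equal(tm_segments(strrep("L", 30))$end, 30)
  expect_equal(nrow(tm_segments(strrep("D", 30))), 0)
  expect_equal(nrow(tm_segments(strrep("L", 10))), 0)
  # half-Leu / half-Asp: segment confined to the Leu half (+ window edge)
  seq <- paste0(strrep("L", 30), strrep("D", 30))
  seg <- tm_segments(seq)
  win <- oracle_tm_windows(seq)
  expect_equal(seg$start, min(win))
  expect_equal(seg$end, max(win) + 18)
  expect_lte(seg$end, 30 + 18)
  # fuzz: merged segments cover exactly the oracle's above-threshold windows
  set.seed(16)
  for (r in 1:10) {
    s <- paste(sample(c("L", "I", "V", "D", "K", "S"), 150, replace = TRUE,
                      prob = c(2, 2, 2, 1, 1, 1)), collapse = "")
    seg <- tm_segments(s)
    win <- oracle_tm_windows(s)
    covered <- unlist(apply(seg, 1, function(x) x[1]:x[2], simplify = FALSE))
    expect_setequal(unique(unlist(lapply(win, function(i) i:(i + 18)))),
                    covered)
  }
  expect_identical(tm_segments(tolower(strrep("L", 30))),
                   tm_segments(strrep("L", 30)))
})

test_that("triage partitions by targeting class and flags annotation", {
  empty <- triage(character(0), list())
  expect_equal(nrow(empty$table), 0)
  calls <- list(
    mem = list(sp_present = TRUE, cleavage = 13,
               tm = data.frame(start = 40, end = 60)),
    sol = list(sp_present = TRUE, cleavage = 13,
               tm = data.frame(start = integer(0), end = integer(0))),
    cyt = list(sp_present = FALSE, cleavage = NA,
               tm = data.frame(start = integer(0), end = integer(0))),
    unk = list(sp_present = NA, cleavage = NA,
               tm = data.frame(start = integer(0), end = integer(0))))
  res <- triage(c("mem", "sol", "cyt", "unk", "missing"), calls,
                annotated = c(mem = TRUE, sol = FALSE))
  expect_equal(res$table$class,
               c("membrane", "intralumenal", "other", "no_call", "no_call"))
  expect_equal(res$table$annotated, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # a protein queried in two selected sets appears once per query
  res2 <- triage(c("mem", "mem"), calls)
  expect_equal(nrow(res2$table), 2)
})

test_that("external targeting predictions are importable and override", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tsp_present\tcleavage\ttm_intervals",
               "p1\tTRUE\t20\t30-52;80-101",
               "p2\tFALSE\t\t",
               "p3\tTRUE\t18\t"), path)
  calls <- import_targeting(path)
  expect_true(calls$p1$sp_present)
  expect_equal(calls$p1$tm$start, c(30, 80))
  expect_equal(calls$p1$class, "membrane")
  expect_false(calls$p2$sp_present)
  expect_equal(calls$p2$class, "cytosolic")
  expect_equal(calls$p3$class, "soluble_secreted")
})
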