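AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kyte-Doolittle hydropathy; X (unknown) scores 0.
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2,
                   X = 0)

HYDROPHOBIC <- c("A", "I", "L", "F", "V", "M", "W", "C")
SMALL_RES <- c("A", "G", "S", "C", "T")

check_protein <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 1) stop("protein sequence must have length >= 1")
  ch <- strsplit(seq, "")[[1]]
  bad <- setdiff(unique(ch), c(AA_STANDARD, "X"))
  if (length(bad) > 0) {
    stop("non-standard residue(s): ", paste(bad, collapse = ", "))
  }
  seq
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_proteins <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(toupper(as.character(aa)), names(aa))
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Amino-acid composition (residues per 100 amino acids)
#'
#' @param seq protein sequence (one-letter, case-insensitive).
#' @param range optional 1-based inclusive `c(start, end)` sub-range.
#' @return Named numeric vector of percentages over the 20 standard residues
#'   plus X; sums to 100.
#' @export
composition <- function(seq, range = NULL) {
  seq <- check_protein(seq)
  if (!is.null(range)) {
    if (length(range) != 2 || range[1] < 1 || range[2] > nchar(seq) ||
        range[1] > range[2]) {
      stop("invalid range: must be 1-based inclusive within the sequence")
    }
    seq <- substr(seq, range[1], range[2])
  }
  ch <- strsplit(seq, "")[[1]]
  counts <- table(factor(ch, levels = c(AA_STANDARD, "X")))
  100 * as.vector(counts) / length(ch) -> pct
  stats::setNames(pct, c(AA_STANDARD, "X"))
}

#' Ser/Lys composition screen for frustule-protein candidates
#'
#' The composition filter for silicification candidates: at least 18% serine
#' and at least 10% lysine per 100 amino acids (boundaries inclusive) plus an
#' ER signal peptide. By default the composition is computed on the mature
#' sequence (after signal-peptide cleavage), modelling the secreted protein.
#'
#' @param seq protein sequence.
#' @param targeting a targeting call as returned by [targeting_call()] (or
#'   assembled from imported predictions): list with `sp_present` and
#'   `cleavage`.
#' @param min_ser,min_lys thresholds in residues per 100 amino acids.
#' @param use_mature compute composition after cleavage (default) or on the
#'   full sequence.
#' @return Logical: passes the screen.
#' @export
scheffel_screen <- function(seq, targeting, min_ser = 18, min_lys = 10,
                            use_mature = TRUE) {
  seq <- check_protein(seq)
  if (!isTRUE(targeting$sp_present)) return(FALSE)
  if (use_mature && !is.null(targeting$cleavage) &&
      !is.na(targeting$cleavage) && targeting$cleavage < nchar(seq)) {
    seq <- substr(seq, targeting$cleavage + 1, nchar(seq))
  }
  comp <- composition(seq)
  comp[["S"]] >= min_ser && comp[["K"]] >= min_lys
}

#' Scan for a peptide motif (X = any residue), overlaps allowed
#'
#' @param seq protein sequence.
#' @param pattern motif over the 20 standard residues and `X`, e.g. `"KXXK"`,
#'   `"KSSK"`, `"MSMSM"`.
#' @return Integer vector of 1-based match start positions (possibly empty).
#' @export
motif_scan <- function(seq, pattern) {
  seq <- check_protein(seq)
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0) stop("empty motif pattern")
  pch <- strsplit(pattern, "")[[1]]
  if (!all(pch %in% c(AA_STANDARD, "X"))) {
    stop("motif pattern must use standard residues and X")
  }
  rx <- paste0("(?=", gsub("X", ".", pattern, fixed = TRUE), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Detect internal tandem repeats by period scan
#'
#' Self-comparison repeat detector: for each candidate period p the
#' per-position indicator `m(i) = [seq(i) == seq(i+p)]` is smoothed with a
#' window of length p; maximal runs of windows whose mean identity reaches
#' `identity_min` define candidate repeat regions. A region must span at
#' least `min_copies * p` residues. Overlapping reports at different periods
#' are resolved by the highest identity x span, ties to the smallest period.
#'
#' @param seq protein sequence.
#' @param p_range `c(p_min, p_max)` period range; `p_min >= 2`,
#'   `p_max < length/2`.
#' @param identity_min minimal mean per-position identity between positions
#'   one period apart.
#' @param min_copies minimal number of repeat copies (span / period).
#' @return data.frame with columns `period`, `start`, `end`, `span`,
#'   `copies`, `identity` (zero rows when nothing is found).
#' @export
repeat_detect <- function(seq, p_range = c(2, 60), identity_min = 0.5,
                          min_copies = 2) {
  seq <- check_protein(seq)
  L <- nchar(seq)
  p_min <- as.integer(p_range[1])
  p_max <- as.integer(min(p_range[2], floor(L / 2)))  # span 2p must fit
  if (p_min < 2) stop("invalid period range: p_min must be >= 2")
  empty <- data.frame(period = integer(0), start = integer(0),
                      end = integer(0), span = integer(0),
                      copies = integer(0), identity = numeric(0))
  if (p_max < p_min) return(empty)
  ch <- strsplit(seq, "")[[1]]
  reports <- list()
  for (p in p_min:p_max) {
    m <- as.numeric(ch[seq_len(L - p)] == ch[(p + 1):L])
    nm <- length(m)
    if (nm < p) next
    # windowed mean of m, window length p
    cs <- cumsum(c(0, m))
    wmean <- (cs[(p + 1):(nm + 1)] - cs[seq_len(nm - p + 1)]) / p
    above <- wmean >= identity_min
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      a <- starts[k]            # first window start (index into m)
      e <- ends[k] + p - 1      # last m-position covered by the run
      # trim so the whole region satisfies the identity threshold
      while (e > a && mean(m[a:e]) < identity_min) {
        if (m[a] <= m[e]) a <- a + 1 else e <- e - 1
      }
      span <- (e - a + 1) + p   # residues covered in the sequence
      if (span < min_copies * p) next
      if (mean(m[a:e]) < identity_min) next
      reports[[length(reports) + 1]] <- data.frame(
        period = p, start = a, end = a + span - 1, span = span,
        copies = span %/% p, identity = mean(m[a:e]))
    }
  }
  if (length(reports) == 0) return(empty)
  rep_df <- do.call(rbind, reports)
  # resolve overlaps: highest identity x span wins, ties to smallest period
  ord <- order(-rep_df$identity * rep_df$span, rep_df$period, rep_df$start)
  rep_df <- rep_df[ord, , drop = FALSE]
  keep <- logical(nrow(rep_df))
  for (i in seq_len(nrow(rep_df))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (rep_df$start[i] <= rep_df$end[j] && rep_df$end[i] >= rep_df$start[j]) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  out <- rep_df[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Heuristic ER signal-peptide call
#'
#' A rule-based stand-in for a trained predictor, designed for self-contained
#' testing: within residues 1-40 the call requires a hydrophobic h-region
#' (8 consecutive residues with >= 6 of A,I,L,F,V,M,W,C) starting at
#' position 2-20, at least one K/R before it (n-region charge), and a
#' cleavage-site position c located 3-12 residues after the h-region with
#' small residues (A,G,S,C,T) at c-3 and c-1 (the von Heijne (-3,-1) rule);
#' cleavage occurs after c-1. The earliest admissible cleavage site is
#' reported. External predictions can override this heuristic via
#' [import_targeting()].
#'
#' @param seq protein sequence.
#' @return List with `sp_present` (logical, `NA` = no call on sequences
#'   shorter than 25 residues) and `cleavage` (last residue of the signal
#'   peptide; the mature protein starts at `cleavage + 1`).
#' @export
signal_peptide <- function(seq) {
  seq <- check_protein(seq)
  L <- nchar(seq)
  if (L < 25) return(list(sp_present = NA, cleavage = NA_integer_))
  ch <- strsplit(seq, "")[[1]]
  hyd <- ch %in% HYDROPHOBIC
  small <- ch %in% SMALL_RES
  charged <- ch %in% c("K", "R")
  best_c <- NA_integer_
  for (h in 2:min(20L, L - 7L)) {
    if (sum(hyd[h:(h + 7)]) < 6) next
    if (h >= 2 && !any(charged[1:(h - 1)])) next
    c_lo <- h + 10L           # 3 residues after the h-region end (h+7)
    c_hi <- min(h + 19L, 40L, L)
    if (c_lo > c_hi) next
    for (cc in c_lo:c_hi) {
      if (small[cc - 3] && small[cc - 1]) {
        if (is.na(best_c) || cc < best_c) best_c <- cc
        break
      }
    }
  }
  if (is.na(best_c)) {
    list(sp_present = FALSE, cleavage = NA_integer_)
  } else {
    list(sp_present = TRUE, cleavage = best_c - 1L)
  }
}

#' Transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Sliding window of length 19; windows with mean hydropathy >= 1.6 are
#' called transmembrane and overlapping windows are merged into maximal
#' segments.
#'
#' @param seq protein sequence.
#' @param window window length (default 19).
#' @param threshold mean-hydropathy threshold (default 1.6).
#' @return data.frame with columns `start`, `end` (1-based inclusive,
#'   non-overlapping); zero rows when none found or sequence shorter than
#'   the window.
#' @export
tm_segments <- function(seq, window = 19, threshold = 1.6) {
  seq <- check_protein(seq)
  L <- nchar(seq)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (L < window) return(empty)
  ch <- strsplit(seq, "")[[1]]
  # hydropathies are exact tenths: integer arithmetic avoids boundary
  # artefacts for windows sitting exactly on the threshold
  hyd10 <- as.integer(round(unname(KD_HYDROPATHY[ch]) * 10))
  cs <- cumsum(c(0L, hyd10))
  wsum10 <- cs[(window + 1):(L + 1)] - cs[seq_len(L - window + 1)]
  hits <- which(wsum10 >= threshold * window * 10 - 1e-6)
  if (length(hits) == 0) return(empty)
  # merge overlapping windows [i, i + window - 1]
  starts <- integer(0); ends <- integer(0)
  cur_s <- hits[1]; cur_e <- hits[1] + window - 1
  for (i in hits[-1]) {
    if (i <= cur_e) {
      cur_e <- i + window - 1
    } else {
      starts <- c(starts, cur_s); ends <- c(ends, cur_e)
      cur_s <- i; cur_e <- i + window - 1
    }
  }
  starts <- c(starts, cur_s); ends <- c(ends, cur_e)
  data.frame(start = starts, end = ends)
}

#' Combined targeting call for one protein
#'
#' Runs the signal-peptide heuristic, then the transmembrane scan on the
#' mature sequence (the signal peptide's own hydrophobic core must not count
#' as a membrane anchor). Reported TM intervals use full-sequence
#' coordinates.
#'
#' @param seq protein sequence.
#' @return List: `sp_present`, `cleavage`, `tm` (data.frame of segments) and
#'   `class` in `{soluble_secreted, membrane, cytosolic, no_call}`.
#' @export
targeting_call <- function(seq) {
  seq <- check_protein(seq)
  sp <- signal_peptide(seq)
  offset <- 0L
  scan_seq <- seq
  if (isTRUE(sp$sp_present)) {
    offset <- sp$cleavage
    scan_seq <- substr(seq, sp$cleavage + 1, nchar(seq))
  }
  tm <- tm_segments(scan_seq)
  if (nrow(tm) > 0) tm <- data.frame(start = tm$start + offset,
                                     end = tm$end + offset)
  cls <- if (is.na(sp$sp_present)) {
    "no_call"
  } else if (isTRUE(sp$sp_present)) {
    if (nrow(tm) > 0) "membrane" else "soluble_secreted"
  } else "cytosolic"
  list(sp_present = sp$sp_present, cleavage = sp$cleavage, tm = tm,
       class = cls)
}

#' Import external targeting predictions
#'
#' Reads a TSV with columns `protein_id`, `sp_present` (TRUE/FALSE),
#' `cleavage` (last signal-peptide residue, empty/NA when absent) and
#' `tm_intervals` (semicolon-separated `start-end` pairs, empty when none).
#' Predictions from any external tool override the built-in heuristics.
#'
#' @param path TSV path.
#' @return Named list of targeting calls (as in [targeting_call()]).
#' @export
import_targeting <- function(path) {
  if (!file.exists(path)) stop("targeting file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(tm_intervals = "character"))
  calls <- lapply(seq_len(nrow(df)), function(i) {
    iv <- df$tm_intervals[i]
    tm <- if (is.na(iv) || !nzchar(iv)) {
      data.frame(start = integer(0), end = integer(0))
    } else {
      parts <- strsplit(strsplit(iv, ";")[[1]], "-")
      data.frame(start = as.integer(vapply(parts, `[`, "", 1)),
                 end = as.integer(vapply(parts, `[`, "", 2)))
    }
    sp <- as.logical(df$sp_present[i])
    cls <- if (is.na(sp)) "no_call"
           else if (sp && nrow(tm) > 0) "membrane"
           else if (sp) "soluble_secreted"
           else "cytosolic"
    list(sp_present = sp,
         cleavage = suppressWarnings(as.integer(df$cleavage[i])),
         tm = tm, class = cls)
  })
  stats::setNames(calls, df$protein_id)
}

#' Triage of candidate genes by targeting class
#'
#' Partitions a selected gene set into SDV-candidate classes: signal peptide
#' plus transmembrane segment(s) -> membrane candidate; signal peptide
#' without transmembrane segment -> intralumenal (soluble secreted)
#' candidate; no signal peptide -> other; missing call -> no_call. The
#' caller supplies an annotated/unknown flag per protein for the cross
#' tabulation.
#'
#' @param genes character vector of selected gene/protein ids.
#' @param calls named list of targeting calls.
#' @param annotated named logical vector (TRUE = has functional annotation);
#'   ids absent from it are treated as unknown.
#' @return List with `table` (per-gene class and annotation flag) and
#'   `counts` (class x annotated cross-tabulation as a data.frame).
#' @export
triage <- function(genes, calls, annotated = NULL) {
  cls <- vapply(genes, function(g) {
    call <- calls[[g]]
    if (is.null(call) || is.na(call$sp_present)) return("no_call")
    if (isTRUE(call$sp_present)) {
      if (nrow(call$tm) > 0) "membrane" else "intralumenal"
    } else "other"
  }, character(1))
  ann <- if (is.null(annotated)) rep(FALSE, length(genes)) else {
    out <- annotated[genes]
    out[is.na(out)] <- FALSE
    unname(out)
  }
  tab <- data.frame(gene_id = genes, class = unname(cls), annotated = ann,
                    stringsAsFactors = FALSE)
  lvl <- c("membrane", "intralumenal", "other", "no_call")
  counts <- as.data.frame(table(class = factor(tab$class, levels = lvl),
                                annotated = tab$annotated))
  list(table = tab, counts = counts)
}
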