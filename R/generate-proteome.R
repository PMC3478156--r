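#' Configuration for the synthetic proteome generator
#'
#' Each protein independently receives planted features with the stated
#' fractions. Planted features are constructed to satisfy the corresponding
#' detector definitions (planted-truth closure): signal peptides satisfy the
#' h-region/(-3,-1) rule, repeats keep per-position identity above the
#' detection threshold, Ser/Lys-biased sequences meet the composition screen
#' thresholds exactly by count, and proteins without a planted signal
#' peptide or transmembrane segment are resampled until the detectors stay
#' silent on them.
#'
#' @param n_proteins number of proteins.
#' @param length_range min/max mature-sequence length (residues).
#' @param frac_repeat,frac_motif,frac_signal,frac_tm,frac_serlys feature
#'   fractions in [0, 1].
#' @param repeat_unit_len,repeat_copies,repeat_sub_rate geometry of planted
#'   tandem repeats (default: a 53-residue unit, 3 copies, 10% point
#'   substitutions).
#' @param min_ser,min_lys composition targets for Ser/Lys-biased proteins
#'   (percent; defaults match the screen thresholds with margin).
#' @param seed master seed.
#' @return A validated `proteome_config` list.
#' @export
proteome_config <- function(n_proteins,
                            length_range = c(200, 400),
                            frac_repeat = 0.1,
                            frac_motif = 0.2,
                            frac_signal = 0.3,
                            frac_tm = 0.15,
                            frac_serlys = 0.1,
                            repeat_unit_len = 53,
                            repeat_copies = 3,
                            repeat_sub_rate = 0.1,
                            min_ser = 22,
                            min_lys = 14,
                            seed = 1L) {
  fr <- c(frac_repeat, frac_motif, frac_signal, frac_tm, frac_serlys)
  if (any(fr < 0 | fr > 1)) {
    stop("configuration error: feature fractions must be in [0, 1]")
  }
  if (min_ser + min_lys > 100) {
    stop("configuration error: Ser and Lys targets exceed 100%")
  }
  if (repeat_unit_len < 2 || repeat_copies < 2) {
    stop("configuration error: repeat unit >= 2 residues, >= 2 copies")
  }
  if (repeat_sub_rate < 0 || repeat_sub_rate > 0.2) {
    stop("configuration error: substitution rate must be in [0, 0.2]")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 frac_repeat = frac_repeat, frac_motif = frac_motif,
                 frac_signal = frac_signal, frac_tm = frac_tm,
                 frac_serlys = frac_serlys,
                 repeat_unit_len = as.integer(repeat_unit_len),
                 repeat_copies = as.integer(repeat_copies),
                 repeat_sub_rate = repeat_sub_rate,
                 min_ser = min_ser, min_lys = min_lys,
                 seed = as.integer(seed)),
            class = "proteome_config")
}

# Rule-satisfying signal-peptide prefix: M, a charged n-region residue, an
# 8-residue hydrophobic h-region, then A-x-A so cleavage falls after
# position 13.
make_sp_prefix <- function() {
  paste0("MK", paste(sample(HYDROPHOBIC, 8, replace = TRUE), collapse = ""),
         "A", sample(c("Q", "N", "E"), 1), "A")
}

# Tandem repeat block with bounded substitutions: at most floor(rate * u)
# point substitutions per copy, so per-position identity between adjacent
# copies stays >= 1 - 2 * rate.
make_repeat_block <- function(unit_len, copies, sub_rate) {
  unit <- sample(AA_STANDARD, unit_len, replace = TRUE)
  block <- character(0)
  nsub <- floor(sub_rate * unit_len)
  for (k in seq_len(copies)) {
    cp <- unit
    if (nsub > 0) {
      pos <- sample(unit_len, nsub)
      cp[pos] <- sample(AA_STANDARD, nsub, replace = TRUE)
    }
    block <- c(block, cp)
  }
  block
}

#' Generate a synthetic proteome with planted sequence features
#'
#' @param config a [proteome_config()].
#' @return List with `proteins` (named character vector, FASTA-writable) and
#'   `truth`: a data.frame (one row per protein) with the planted feature
#'   flags and geometry (`repeat_period`, `repeat_copies`, `repeat_start`,
#'   `sp_cleavage`, `ser_pct`, `lys_pct`) plus list-columns `motif_pos`
#'   (planted KSSK starts) and `tm_intervals`.
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "proteome_config"))
  n <- config$n_proteins
  if (n == 0) {
    return(list(proteins = stats::setNames(character(0), character(0)),
                truth = data.frame(protein_id = character(0))))
  }
  set.seed(substream_seed(config$seed, 11L))
  ids <- sprintf("prot%04d", seq_len(n))
  has <- function(frac) stats::runif(n) < frac
  f_rep <- has(config$frac_repeat)
  f_mot <- has(config$frac_motif)
  f_sp <- has(config$frac_signal)
  f_tm <- has(config$frac_tm)
  # a repeat block would overwrite a composition-biased body, so the two
  # planted features are kept mutually exclusive
  f_sl <- has(config$frac_serlys) & !f_rep
  lens <- sample(config$length_range[1]:config$length_range[2], n,
                 replace = TRUE)

  proteins <- character(n)
  truth <- data.frame(protein_id = ids,
                      has_repeat = f_rep, repeat_period = NA_integer_,
                      repeat_copies = NA_integer_, repeat_start = NA_integer_,
                      has_motif = f_mot,
                      has_sp = f_sp, sp_cleavage = NA_integer_,
                      has_tm = f_tm,
                      serlys_biased = f_sl,
                      ser_pct = NA_real_, lys_pct = NA_real_,
                      stringsAsFactors = FALSE)
  truth$motif_pos <- vector("list", n)
  truth$tm_intervals <- vector("list", n)

  for (i in seq_len(n)) {
    for (attempt in 1:100) {
      L <- lens[i]
      if (f_sl[i]) {
        # exact counts guarantee the composition thresholds
        n_ser <- ceiling(config$min_ser / 100 * L)
        n_lys <- ceiling(config$min_lys / 100 * L)
        rest <- sample(setdiff(AA_STANDARD, c("S", "K")), L - n_ser - n_lys,
                       replace = TRUE)
        body <- sample(c(rep("S", n_ser), rep("K", n_lys), rest))
      } else {
        body <- sample(AA_STANDARD, L, replace = TRUE)
      }
      rep_start_mature <- NA_integer_
      if (f_rep[i]) {
        block <- make_repeat_block(config$repeat_unit_len,
                                   config$repeat_copies,
                                   config$repeat_sub_rate)
        rep_start_mature <- 30L
        if (length(block) + rep_start_mature > length(body)) {
          body <- c(body, sample(AA_STANDARD,
                                 length(block) + rep_start_mature +
                                   30L - length(body),
                                 replace = TRUE))
        }
        body[rep_start_mature:(rep_start_mature + length(block) - 1)] <- block
      }
      tm_iv <- NULL
      if (f_tm[i]) {
        anchor <- sample(c("I", "L", "V", "F"), 21, replace = TRUE)
        pos <- length(body) - 40L
        body[pos:(pos + 20L)] <- anchor
        tm_iv <- c(pos, pos + 20L)
      }
      motif_pos_mature <- integer(0)
      if (f_mot[i]) {
        # plant KSSK twice and MSMSM once, outside repeat/TM regions
        forbidden <- integer(0)
        if (f_rep[i]) {
          forbidden <- c(forbidden, rep_start_mature:(rep_start_mature +
            config$repeat_unit_len * config$repeat_copies - 1))
        }
        if (f_tm[i]) forbidden <- c(forbidden, tm_iv[1]:tm_iv[2])
        cand <- seq(7, length(body) - 5, by = 7)
        cand <- cand[vapply(cand, function(s) {
          !any(s:(s + 4) %in% forbidden)
        }, logical(1))]
        if (length(cand) < 3) next
        spots <- sort(sample(cand, 3))
        body[spots[1]:(spots[1] + 3)] <- c("K", "S", "S", "K")
        body[spots[2]:(spots[2] + 3)] <- c("K", "S", "S", "K")
        body[spots[3]:(spots[3] + 4)] <- c("M", "S", "M", "S", "M")
        motif_pos_mature <- spots[1:2]
      }
      prefix <- if (f_sp[i]) strsplit(make_sp_prefix(), "")[[1]] else "M"
      seqv <- c(prefix, body)
      seq <- paste(seqv, collapse = "")
      offset <- length(prefix)

      # planted-truth closure: detectors must agree with the planted labels
      sp_call <- signal_peptide(seq)
      if (!identical(isTRUE(sp_call$sp_present), f_sp[i])) next
      mature <- if (f_sp[i]) substr(seq, sp_call$cleavage + 1, nchar(seq))
                else seq
      tm_call <- tm_segments(mature)
      if ((nrow(tm_call) > 0) != f_tm[i]) next

      proteins[i] <- seq
      if (f_sp[i]) truth$sp_cleavage[i] <- sp_call$cleavage
      if (f_rep[i]) {
        truth$repeat_period[i] <- config$repeat_unit_len
        truth$repeat_copies[i] <- config$repeat_copies
        truth$repeat_start[i] <- rep_start_mature + offset
      }
      if (f_mot[i]) truth$motif_pos[[i]] <- motif_pos_mature + offset
      if (f_tm[i]) {
        truth$tm_intervals[[i]] <- list(c(tm_iv[1] + offset,
                                          tm_iv[2] + offset))
      }
      comp_src <- if (f_sp[i]) mature else seq
      cp <- composition(comp_src)
      truth$ser_pct[i] <- cp[["S"]]
      truth$lys_pct[i] <- cp[["K"]]
      break
    }
    if (proteins[i] == "") {
      stop("could not realise planted features for protein ", ids[i])
    }
  }
  names(proteins) <- ids
  list(proteins = proteins, truth = truth)
}
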