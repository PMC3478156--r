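#' Pipeline run configuration
#'
#' @param expression path to the probe-level expression TSV.
#' @param proteins optional FASTA of protein sequences for the candidate
#'   screen.
#' @param annotations optional gene->term TSV for the enrichment stage.
#' @param targeting optional TSV of external signal-peptide/TM predictions
#'   (see [import_targeting()]); overrides the built-in heuristics.
#' @param markers named character vector of marker gene ids; recognised
#'   names: `tpsil3`, `sit1`, `sit2`, `sit3`.
#' @param alpha significance level for the selection rules.
#' @param fdr_cutoff BH q cutoff for enrichment flagging.
#' @param r_min marker-cluster correlation floor.
#' @param flat_threshold flatness threshold (max |log2 ratio|).
#' @param metric,linkage clustering parameters.
#' @param min_ser,min_lys composition-screen thresholds (percent).
#' @param repeat_p_range,repeat_identity_min,repeat_min_copies repeat
#'   detector parameters.
#' @param motifs motif patterns scanned on every protein.
#' @param seed recorded in the manifest (all pipeline stages are
#'   deterministic given their inputs; the seed matters only when the
#'   caller generated the inputs).
#' @param out_dir output directory (created if needed).
#' @return A `run_config` list.
#' @export
run_config <- function(expression,
                       proteins = NULL,
                       annotations = NULL,
                       targeting = NULL,
                       markers = character(0),
                       alpha = 0.05,
                       fdr_cutoff = 0.005,
                       r_min = 0.9,
                       flat_threshold = 0.5,
                       metric = "one_minus_pearson",
                       linkage = "average",
                       min_ser = 18,
                       min_lys = 10,
                       repeat_p_range = c(2, 60),
                       repeat_identity_min = 0.5,
                       repeat_min_copies = 2,
                       motifs = c("KXXK", "KSSK", "MSMSM"),
                       seed = 1L,
                       out_dir = "results/run") {
  structure(list(expression = expression, proteins = proteins,
                 annotations = annotations, targeting = targeting,
                 markers = markers, alpha = alpha, fdr_cutoff = fdr_cutoff,
                 r_min = r_min, flat_threshold = flat_threshold,
                 metric = metric, linkage = linkage,
                 min_ser = min_ser, min_lys = min_lys,
                 repeat_p_range = repeat_p_range,
                 repeat_identity_min = repeat_identity_min,
                 repeat_min_copies = repeat_min_copies,
                 motifs = motifs, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full silicon-response analysis
#'
#' Orchestrates universe/SLRG/SSRG selection, fold-change profiling,
#' marker-anchored clustering (with flat-gene exclusion), GO
#' over-representation of the SLRG and SSRG sets against the universe, the
#' protein sequence screen, set overlaps, and a machine-readable manifest
#' with a content hash for every output file. A rerun with the same config
#' and inputs is bit-identical (verified by the manifest hashes).
#'
#' @param config a [run_config()].
#' @return List: the output `manifest` (also written as `manifest.json`),
#'   plus the in-memory stage results (`universe`, `slrg`, `ssrg`,
#'   `clusters`, `enrichment`, `screen`, `overlaps`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c("expression", "proteins", "annotations", "targeting")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]])) {
      stop("pipeline input missing: ", p, " file not found: ", config[[p]])
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  x <- stage("read_expression", read_expression(config$expression))

  universe <- stage("select_universe", select_universe(x, alpha = config$alpha))
  slrg <- stage("select_slrg", select_slrg(x, alpha = config$alpha))
  ssrg <- stage("select_ssrg", select_ssrg(x, alpha = config$alpha))
  files <- c(files,
             write_tsv(universe, out("universe.tsv")),
             write_tsv(slrg, out("slrg.tsv")),
             write_tsv(ssrg, out("ssrg.tsv")))
  universe_genes <- universe$gene_id[universe$selected]
  slrg_genes <- slrg$gene_id[slrg$selected]
  ssrg_genes <- ssrg$gene_id[ssrg$selected]

  profiles <- stage("log2_profiles", log2_profiles(x))
  files <- c(files, write_tsv(
    data.frame(gene_id = rownames(profiles), profiles, check.names = FALSE),
    out("log2_profiles.tsv")))

  clusters <- list()
  if ("tpsil3" %in% names(config$markers)) {
    tps <- stage("tpsil3_cluster", {
      marker <- config$markers[["tpsil3"]]
      pool <- union(slrg_genes, marker)
      sub <- profiles[rownames(profiles) %in% pool, , drop = FALSE]
      sub <- sub[!is_flat(sub, config$flat_threshold), , drop = FALSE]
      hc <- cluster_profiles(sub, metric = config$metric,
                             linkage = config$linkage)
      list(hc = hc, cluster = marker_cluster(hc, sub, marker,
                                             r_min = config$r_min))
    })
    clusters$tpsil3 <- tps$cluster
    files <- c(files,
               write_dendrogram_newick(tps$hc, out("slrg_dendrogram.nwk")),
               write_cluster(clusters$tpsil3, out("tpsil3_cluster.tsv")))
  }
  sit_names <- intersect(c("sit1", "sit2", "sit3"), names(config$markers))
  if (length(sit_names) > 0) {
    clusters$sit <- stage("sit_coregulation", {
      sit_coregulation(profiles, config$markers[sit_names],
                       r_min = config$r_min,
                       flat_threshold = config$flat_threshold,
                       metric = config$metric, linkage = config$linkage)
    })
    files <- c(files, write_cluster(clusters$sit, out("sit_clusters.tsv")))
  }

  # reference set for over-representation is the total data set (all genes
  # on the array), not the differentially expressed universe
  enrichment <- list()
  if (!is.null(config$annotations)) {
    ann <- stage("read_annotations", read_annotations(config$annotations))
    enrichment$slrg <- stage("enrich_slrg",
      enrich(slrg_genes, x$genes, ann, fdr_cutoff = config$fdr_cutoff))
    enrichment$ssrg <- stage("enrich_ssrg",
      enrich(ssrg_genes, x$genes, ann, fdr_cutoff = config$fdr_cutoff))
    files <- c(files,
               write_tsv(enrichment$slrg, out("enrichment_slrg.tsv")),
               write_tsv(enrichment$ssrg, out("enrichment_ssrg.tsv")))
  }

  screen <- NULL
  if (!is.null(config$proteins)) {
    screen <- stage("sequence_screen", {
      prot <- read_proteins(config$proteins)
      calls <- if (!is.null(config$targeting)) {
        import_targeting(config$targeting)
      } else {
        lapply(prot, targeting_call)
      }
      screen_proteome(prot, calls, config)
    })
    files <- c(files,
               write_tsv(screen$features, out("sequence_screen.tsv")),
               write_tsv(screen$repeats, out("repeats.tsv")))
    tri <- stage("triage", triage(names(screen$calls), screen$calls))
    files <- c(files, write_tsv(tri$table, out("triage.tsv")))
    screen$triage <- tri
  }

  sets <- list(universe = universe_genes, SLRG = slrg_genes,
               SSRG = ssrg_genes)
  if (!is.null(screen)) {
    sets$scheffel <- screen$features$protein_id[screen$features$scheffel_pass]
  }
  overlaps <- stage("overlap", overlap(sets[c("SLRG", "SSRG")]))
  files <- c(files, write_tsv(overlaps$pairwise, out("overlaps.tsv")))

  counts <- data.frame(
    set = c("universe", "SLRG", "SSRG"),
    n = c(length(universe_genes), length(slrg_genes), length(ssrg_genes)))
  files <- c(files, write_tsv(counts, out("set_sizes.tsv")))

  cfg_json <- out("config.json")
  jsonlite::write_json(
    config[setdiff(names(config), character(0))], cfg_json,
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  files <- c(files, cfg_json)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_json)),
    seed = config$seed,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  list(manifest = manifest, universe = universe, slrg = slrg, ssrg = ssrg,
       profiles = profiles, clusters = clusters, enrichment = enrichment,
       screen = screen, overlaps = overlaps, counts = counts)
}

#' Sequence-feature screen over a whole proteome
#'
#' @param proteins named character vector of sequences.
#' @param calls named list of targeting calls (heuristic or imported).
#' @param config a [run_config()] carrying the screen thresholds.
#' @return List: `features` (one row per protein: Ser/Lys percentages,
#'   screen verdict, motif counts, repeat/TM/SP summary), `repeats` (all
#'   repeat reports), `calls`.
#' @export
screen_proteome <- function(proteins, calls, config = run_config("unused")) {
  ids <- names(proteins)
  rep_all <- list()
  rows <- lapply(ids, function(id) {
    seq <- proteins[[id]]
    call <- calls[[id]]
    comp <- composition(seq)
    reps <- repeat_detect(seq, p_range = config$repeat_p_range,
                          identity_min = config$repeat_identity_min,
                          min_copies = config$repeat_min_copies)
    if (nrow(reps) > 0) {
      rep_all[[id]] <<- cbind(protein_id = id, reps)
    }
    motif_counts <- vapply(config$motifs,
                           function(m) length(motif_scan(seq, m)), numeric(1))
    row <- data.frame(protein_id = id,
                      length = nchar(seq),
                      ser_pct = comp[["S"]],
                      lys_pct = comp[["K"]],
                      sp_present = isTRUE(call$sp_present),
                      cleavage = if (is.null(call$cleavage)) NA_integer_
                                 else call$cleavage,
                      n_tm = nrow(call$tm),
                      n_repeats = nrow(reps),
                      scheffel_pass = scheffel_screen(
                        seq, call, min_ser = config$min_ser,
                        min_lys = config$min_lys),
                      stringsAsFactors = FALSE)
    for (i in seq_along(config$motifs)) {
      row[[paste0("n_", config$motifs[i])]] <- motif_counts[i]
    }
    row
  })
  features <- do.call(rbind, rows)
  repeats <- if (length(rep_all) > 0) do.call(rbind, c(rep_all,
                                                       make.row.names = FALSE))
             else data.frame(protein_id = character(0), period = integer(0),
                             start = integer(0), end = integer(0),
                             span = integer(0), copies = integer(0),
                             identity = numeric(0))
  list(features = features, repeats = repeats, calls = calls)
}

#' Overlap report between named gene sets
#'
#' Exact pairwise intersection and set-difference counts, member lists, and
#' (for up to three sets) the Venn-region breakdown.
#'
#' @param sets named list of character vectors.
#' @return List of class `overlap_report`: `pairwise` (data.frame),
#'   `members` (list of pairwise intersections), `venn` (data.frame or
#'   `NULL` for > 3 sets).
#' @export
overlap <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  nm <- names(sets)
  pairs <- if (length(nm) >= 2) utils::combn(nm, 2, simplify = FALSE) else list()
  pw <- do.call(rbind, lapply(pairs, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    data.frame(set_a = p[1], set_b = p[2],
               n_a = length(a), n_b = length(b),
               intersection = length(intersect(a, b)),
               only_a = length(setdiff(a, b)),
               only_b = length(setdiff(b, a)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(pw)) {
    pw <- data.frame(set_a = character(0), set_b = character(0),
                     n_a = integer(0), n_b = integer(0),
                     intersection = integer(0), only_a = integer(0),
                     only_b = integer(0), stringsAsFactors = FALSE)
  }
  members <- lapply(pairs, function(p) {
    sort(intersect(sets[[p[1]]], sets[[p[2]]]))
  })
  names(members) <- vapply(pairs, paste, "", collapse = " & ")
  venn <- NULL
  if (length(nm) <= 3 && length(nm) >= 1) {
    all_genes <- unique(unlist(sets))
    pattern <- sapply(sets, function(s) all_genes %in% s)
    pattern <- matrix(pattern, ncol = length(nm),
                      dimnames = list(NULL, nm))
    key <- apply(pattern, 1L, function(r) paste(nm[r], collapse = " & "))
    venn <- as.data.frame(table(region = key), stringsAsFactors = FALSE)
  }
  structure(list(pairwise = pw, members = members, venn = venn),
            class = "overlap_report")
}
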