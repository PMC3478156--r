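#!/usr/bin/env Rscript
# Protein sequence screen for silicification candidates: Ser/Lys
# composition with the signal-peptide requirement, KXXK/KSSK/MSMSM motifs,
# internal tandem repeats, and signal-peptide/transmembrane triage, scored
# against the planted proteome truth.

suppressPackageStartupMessages(library(silresponse))

out <- "results/screen"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
prot <- read_proteins("results/data/proteins.fasta")
truth <- utils::read.delim("results/data/truth_proteins.tsv")

calls <- lapply(prot, targeting_call)
cfg <- run_config("unused")   # default screen thresholds
scr <- screen_proteome(prot, calls, cfg)
utils::write.table(scr$features, file.path(out, "sequence_screen.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(scr$repeats, file.path(out, "repeats.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tri <- triage(names(prot), calls)
utils::write.table(tri$table, file.path(out, "triage.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# recovery against planted truth
sp_hat <- scr$features$sp_present
tm_hat <- scr$features$n_tm > 0
stopifnot(identical(scr$features$protein_id, truth$protein_id))
message(sprintf("signal peptides: %d called / %d planted (accuracy %.3f)",
                sum(sp_hat), sum(truth$has_sp), mean(sp_hat == truth$has_sp)))
message(sprintf("TM proteins: %d called / %d planted (accuracy %.3f)",
                sum(tm_hat), sum(truth$has_tm), mean(tm_hat == truth$has_tm)))
rep_truth <- truth$protein_id[truth$has_repeat]
rep_found <- vapply(rep_truth, function(id) {
  53 %in% scr$repeats$period[scr$repeats$protein_id == id]
}, logical(1))
message(sprintf("planted 53-aa repeats recovered: %d / %d",
                sum(rep_found), length(rep_truth)))
scheffel_truth <- truth$protein_id[truth$serlys_biased & truth$has_sp]
message(sprintf("composition screen: %d pass (planted Ser/Lys+SP: %d, recovered %d)",
                sum(scr$features$scheffel_pass), length(scheffel_truth),
                sum(scheffel_truth %in%
                      scr$features$protein_id[scr$features$scheffel_pass])))
cls <- table(tri$table$class)
message("triage: ", paste(names(cls), cls, sep = "=", collapse = ", "))
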