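#!/usr/bin/env Rscript
# Gene-set selection on the simulated time course: the differentially
# expressed universe (any timepoint vs 0 h), the silaffin-like response
# genes (up at 7 or 8 h vs the 0/4 h reference) and the silicon starvation
# response genes (up at 0 h vs every later timepoint), each scored against
# the planted truth.

suppressPackageStartupMessages(library(silresponse))

out <- "results/selection"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
x <- read_expression("results/data/expression.tsv")
truth <- utils::read.delim("results/data/truth_genes.tsv")

u <- select_universe(x, alpha = 0.05)
sl <- select_slrg(x, alpha = 0.05)
ss <- select_ssrg(x, alpha = 0.05)
write_selection(u, file.path(out, "universe.tsv"))
write_selection(sl, file.path(out, "slrg.tsv"))
write_selection(ss, file.path(out, "ssrg.tsv"))

score <- function(selected_ids, truth_ids, n_flat, fp_flat) {
  c(n_selected = length(selected_ids),
    n_planted = length(truth_ids),
    sensitivity = mean(truth_ids %in% selected_ids),
    flat_fp_rate = fp_flat)
}
flat_ids <- truth$gene_id[truth$archetype == "flat"]
sl_ids <- sl$gene_id[sl$selected]
ss_ids <- ss$gene_id[ss$selected]
u_ids <- u$gene_id[u$selected]

metrics <- rbind(
  universe = score(u_ids, truth$gene_id[!truth$flat], length(flat_ids),
                   mean(flat_ids %in% u_ids)),
  SLRG = score(sl_ids, truth$gene_id[truth$archetype == "silaffin"],
               length(flat_ids), mean(flat_ids %in% sl_ids)),
  SSRG = score(ss_ids, truth$gene_id[truth$archetype == "starvation"],
               length(flat_ids), mean(flat_ids %in% ss_ids)))
metrics_df <- data.frame(set = rownames(metrics), metrics, row.names = NULL)
utils::write.table(metrics_df, file.path(out, "recovery_metrics.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("universe: %d genes selected (sensitivity %.3f on planted non-flat)",
                length(u_ids), metrics["universe", "sensitivity"]))
message(sprintf("SLRG: %d genes (sensitivity %.3f, flat FP rate %.4f)",
                length(sl_ids), metrics["SLRG", "sensitivity"],
                metrics["SLRG", "flat_fp_rate"]))
message(sprintf("SSRG: %d genes (sensitivity %.3f, flat FP rate %.4f)",
                length(ss_ids), metrics["SSRG", "sensitivity"],
                metrics["SSRG", "flat_fp_rate"]))
message("SLRG/SSRG overlap: ", length(intersect(sl_ids, ss_ids)), " genes")
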