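#!/usr/bin/env Rscript
# GO over-representation of the SLRG and SSRG sets against the total data
# set: one-sided Fisher exact test per term, Benjamini-Hochberg FDR,
# flagged at q < 0.005.

suppressPackageStartupMessages(library(silresponse))

out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ann <- read_annotations("results/data/annotations.tsv")
truth <- utils::read.delim("results/data/truth_genes.tsv")
sl <- utils::read.delim("results/selection/slrg.tsv")
ss <- utils::read.delim("results/selection/ssrg.tsv")
universe <- truth$gene_id   # the total data set is the reference

for (set in list(list(name = "slrg", genes = sl$gene_id[sl$selected]),
                 list(name = "ssrg", genes = ss$gene_id[ss$selected]))) {
  res <- enrich(set$genes, universe, ann, fdr_cutoff = 0.005)
  utils::write.table(res, file.path(out, paste0(set$name, "_enrichment.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  flagged <- res[res$flagged, ]
  message(sprintf("%s: %d/%d terms flagged at q < 0.005", toupper(set$name),
                  nrow(flagged), nrow(res)))
  if (nrow(flagged) > 0) {
    message("  top term: ", flagged$term[1],
            sprintf(" (%.1f%% of test set vs %.1f%% of reference, q = %.2e)",
                    100 * flagged$freq_test[1], 100 * flagged$freq_ref[1],
                    flagged$q[1]))
  }
}
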