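#!/usr/bin/env Rscript
# Simulate the workflow's inputs: a synchronized silicon-starvation/replenishment
# time course (10,000 genes x 6 timepoints x 16 probes), a proteome with
# planted sequence features, and a GO annotation table with one term
# over-represented among the valve-formation genes. Writes the inputs that
# the downstream analysis scripts read, plus the planted truth tables.

suppressPackageStartupMessages(library(silresponse))

seed <- 20120920L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("simulating expression time course (10,000 genes, 16 probes/gene)")
cfg <- generator_config(n_genes = 10000, seed = seed)
g <- generate_expression(cfg)
write_expression(g$matrix, file.path(out, "expression.tsv"))
utils::write.table(g$truth$genes, file.path(out, "truth_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(gene_id = rownames(g$truth$profiles), g$truth$profiles,
             check.names = FALSE),
  file.path(out, "truth_profiles.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

tr <- g$truth$genes
message("archetype mixture realised: ",
        paste(names(table(tr$archetype)), table(tr$archetype),
              sep = "=", collapse = ", "))

message("simulating proteome (300 proteins with planted features)")
pr <- generate_proteome(proteome_config(300, seed = seed + 1L))
write_proteins(pr$proteins, file.path(out, "proteins.fasta"))
truth_flat <- pr$truth[, setdiff(names(pr$truth),
                                 c("motif_pos", "tm_intervals"))]
utils::write.table(truth_flat, file.path(out, "truth_proteins.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("simulating GO annotations (50 terms; one planted in the ",
        "valve-formation genes)")
ann <- generate_annotations(
  tr$gene_id, 50,
  planted = list(term = "GO_valve_formation",
                 genes = tr$gene_id[tr$archetype == "silaffin"],
                 factor = 12),
  seed = seed + 2L)
write_annotations(ann, file.path(out, "annotations.tsv"))

# marker genes for the downstream cluster analyses
markers <- data.frame(
  role = c("tpsil3", "sit1", "sit2", "sit3"),
  gene_id = c(tr$gene_id[tr$archetype == "silaffin"][1],
              tr$gene_id[tr$archetype == "sit1"][1],
              tr$gene_id[tr$archetype == "sit2"][1],
              tr$gene_id[tr$archetype == "flat"][1]))
utils::write.table(markers, file.path(out, "markers.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("inputs written under ", out)
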