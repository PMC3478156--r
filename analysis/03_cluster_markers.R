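#!/usr/bin/env Rscript
# Marker-anchored co-expression clusters on log2 fold-change profiles:
# the Tpsil3 (valve formation) cluster extracted from the SLRG set, and the
# silicon-transporter clusters over the non-flat universe with the flatness
# verdict for SIT3.

suppressPackageStartupMessages(library(silresponse))

out <- "results/clusters"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
x <- read_expression("results/data/expression.tsv")
truth <- utils::read.delim("results/data/truth_genes.tsv")
markers <- utils::read.delim("results/data/markers.tsv")
marker_of <- function(role) markers$gene_id[markers$role == role]
sl <- utils::read.delim("results/selection/slrg.tsv")

prof <- log2_profiles(x)
utils::write.table(
  data.frame(gene_id = rownames(prof), prof, check.names = FALSE),
  file.path(out, "log2_profiles.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

# Tpsil3 cluster: hierarchical clustering (1 - Pearson, average linkage)
# of the SLRG profiles, flat genes excluded, then the largest subtree
# around the marker with member correlation >= 0.9
pool_ids <- union(sl$gene_id[sl$selected], marker_of("tpsil3"))
pool <- prof[rownames(prof) %in% pool_ids, , drop = FALSE]
pool <- pool[!is_flat(pool), , drop = FALSE]
hc <- suppressWarnings(cluster_profiles(pool))
write_dendrogram_newick(hc, file.path(out, "slrg_dendrogram.nwk"))
mc <- marker_cluster(hc, pool, marker_of("tpsil3"), r_min = 0.9)
write_cluster(mc, file.path(out, "tpsil3_cluster.tsv"))

planted <- truth$gene_id[truth$archetype == "silaffin"]
message(sprintf(
  "Tpsil3 cluster: %d genes (planted %d, recall %.3f, %d intruders, min cor %.3f)",
  length(mc$members), length(planted),
  length(intersect(mc$members, planted)) / length(planted),
  length(setdiff(mc$members, planted)), mc$min_cor))

# SIT co-regulation over the non-flat universe; SIT3 is expected flat
sitm <- c(sit1 = marker_of("sit1"), sit2 = marker_of("sit2"),
          sit3 = marker_of("sit3"))
sits <- suppressWarnings(sit_coregulation(prof, sitm))
write_cluster(sits, file.path(out, "sit_clusters.tsv"))
for (nm in names(sits)) {
  if (identical(sits[[nm]], "flat")) {
    message(nm, ": flat verdict (no cluster analysis performed)")
  } else {
    want <- truth$gene_id[truth$archetype == nm]
    message(sprintf("%s cluster: %d genes (planted %d, %d recovered)",
                    nm, length(sits[[nm]]$members), length(want),
                    length(intersect(sits[[nm]]$members, want))))
  }
}
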