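# Synthetic input bundle on disk plus a matching pipeline config.
make_run_inputs <- function(dir, n_genes = 200, seed = 33) {
  cfg <- generator_config(
    n_genes = n_genes,
    archetype_mixture = c(silaffin = 0.06, starvation = 0.06, sit1 = 0.03,
                          sit2 = 0.04, flat = 0.66, random = 0.15),
    seed = seed)
  g <- generate_expression(cfg)
  tr <- g$truth$genes
  expr_path <- file.path(dir, "expression.tsv")
  write_expression(g$matrix, expr_path)

  pr <- generate_proteome(proteome_config(30, seed = seed))
  fasta_path <- file.path(dir, "proteins.fasta")
  write_proteins(pr$proteins, fasta_path)

  slrg_truth <- tr$gene_id[tr$archetype == "silaffin"]
  ann <- generate_annotations(tr$gene_id, 40,
                              planted = list(term = "valve_formation",
                                             genes = slrg_truth, factor = 15),
                              seed = seed)
  ann_path <- file.path(dir, "annotations.tsv")
  write_annotations(ann, ann_path)

  markers <- c(tpsil3 = slrg_truth[1],
               sit1 = tr$gene_id[tr$archetype == "sit1"][1],
               sit2 = tr$gene_id[tr$archetype == "sit2"][1],
               sit3 = tr$gene_id[tr$archetype == "flat"][1])
  list(truth = g$truth, proteome_truth = pr$truth,
       config = run_config(expression = expr_path, proteins = fasta_path,
                           annotations = ann_path, markers = markers,
                           seed = seed,
                           out_dir = file.path(dir, "run")))
}
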