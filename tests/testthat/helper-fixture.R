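# Builds a complete, small synthetic input bundle on disk and returns the
# pipeline configuration pointing at it. Everything is generated in code;
# nothing is stored in the repository.
build_pipeline_fixture <- function(dir, seed = 101, n_samples = 60,
                                   n_genes = 300) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- synthetic_annotation(n_genes, paste0("chr", 1:16),
                            n_region_genes = c(chr8 = 60))
  co <- simulate_cohort(n_samples, g$annotation,
                        prevalence = c(chr8 = 0.5, chr1q = 0.15,
                                       chr12 = 0.1, chr16q = 0.1),
                        direction = c(chr8 = "gain", chr1q = "gain",
                                      chr12 = "gain", chr16q = "loss"),
                        centromeres = g$centromeres, seed = seed)
  write_expression_tsv(co$expression, file.path(dir, "expression.tsv"))
  gainscan:::write_tsv_plain(g$annotation, file.path(dir, "annotation.tsv"))
  gainscan:::write_tsv_plain(g$centromeres, file.path(dir, "centromeres.tsv"))
  write_clinical_tsv(co$clinical, file.path(dir, "clinical.tsv"))
  write_cnv_tsv(co$cnv_truth, file.path(dir, "cnv.tsv"))

  set.seed(seed + 1)
  sets <- build_chromosome_genesets(g$annotation, g$centromeres)["chr8"]
  for (i in 1:5) {
    sets[[sprintf("RANDOM_SET_%d", i)]] <- sort(sample(g$annotation$gene_id, 15))
  }
  sets[["PROLIF_LIKE"]] <- g$annotation$gene_id[
    g$annotation$chromosome == "chr8"][1:10]
  write_gmt(sets, file.path(dir, "sets.gmt"))

  om <- simulate_knockdown_omics(150, 10, n_blocks = 2, n_reps = 3,
                                 protein_effect = -1, missing_rate = 0.1,
                                 seed = seed + 2)
  write_omics_dir(om, file.path(dir, "omics"))

  drugs <- sprintf("drug%d", 1:3)
  dr <- do.call(rbind, lapply(seq_along(drugs), function(i) {
    rbind(
      simulate_dose_response(ic50 = 1, hill = 2.5,
                             doses = 10^seq(-2, 2, length.out = 9),
                             noise_sd = 0.03, n_reps = 2, drug = drugs[i],
                             condition = "control", seed = seed + 10 + i),
      simulate_dose_response(ic50 = ifelse(i == 2, 0.1, 1), hill = 2.5,
                             doses = 10^seq(-2, 2, length.out = 9),
                             noise_sd = 0.03, n_reps = 2, drug = drugs[i],
                             condition = "knockdown", seed = seed + 20 + i)
    )
  }))
  write_dose_response_tsv(dr, file.path(dir, "drugs.tsv"))

  list(
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    centromeres = file.path(dir, "centromeres.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    cnv = file.path(dir, "cnv.tsv"),
    gene_sets = file.path(dir, "sets.gmt"),
    omics_dir = file.path(dir, "omics"),
    drug_response = file.path(dir, "drugs.tsv"),
    focus_region = "chr8",
    confounder_regions = c("chr1q", "chr12", "chr16q"),
    association_set = "PROLIF_LIKE",
    n_perm = 200,
    out_dir = file.path(dir, "out"),
    seed = seed
  )
}
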