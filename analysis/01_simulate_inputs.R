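#!/usr/bin/env Rscript
# Builds the synthetic study inputs used by all downstream analysis scripts:
# a 196-sample discovery cohort (the size of the microarray cohort the
# design emulates) with ~50% chr8-gain prevalence and recurrent confounder
# CNVs, a paired knockdown proteome/transcriptome experiment with 50
# planted translational targets, and a two-condition drug panel with one
# 10-fold-sensitized compound. Everything is written as plain TSV/GMT under
# results/synthetic/ together with a truth JSON.

library(gainscan)

seed <- 20260920
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- synthetic_annotation(2000, paste0("chr", 1:20),
                               n_region_genes = c(chr8 = 300))
cohort <- simulate_cohort(
  196, genome$annotation,
  prevalence = c(chr8 = 0.5, chr1q = 0.15, chr12 = 0.12, chr16q = 0.12),
  direction = c(chr8 = "gain", chr1q = "gain", chr12 = "gain",
                chr16q = "loss"),
  centromeres = genome$centromeres, seed = seed
)
write_expression_tsv(cohort$expression, file.path(out, "expression.tsv"))
write_clinical_tsv(cohort$clinical, file.path(out, "clinical.tsv"))
write_cnv_tsv(cohort$cnv_truth, file.path(out, "cnv.tsv"))
gainscan:::write_tsv_plain(genome$annotation, file.path(out, "annotation.tsv"))
gainscan:::write_tsv_plain(genome$centromeres, file.path(out, "centromeres.tsv"))

# proteins share the cohort's gene-id space so the cascade can cross-link
# protein candidates to the transcript survival screen; the planted
# translational targets include the driver itself (its protein synthesis
# responds to the knockdown) plus chr8 and genome-wide genes
chr8_genes <- genome$annotation$gene_id[genome$annotation$chromosome == "chr8"]
other_genes <- setdiff(genome$annotation$gene_id, chr8_genes)
set.seed(seed + 1)
targets <- c(cohort$driver_gene_id,
             sample(setdiff(chr8_genes, cohort$driver_gene_id), 30),
             sample(other_genes, 19))
omics <- simulate_knockdown_omics(2000, 50, n_blocks = 3, n_reps = 4,
                                  protein_effect = -1, mrna_effect = 0,
                                  missing_rate = 0.1, noise_sd = 0.3,
                                  feature_ids = genome$annotation$gene_id,
                                  target_ids = targets, seed = seed + 2)
write_omics_dir(omics, file.path(out, "omics"))

# gene sets: the chr8 signature set, null sets, three dosage-responsive
# modules (mostly chr8-encoded, hence co-regulated with the driver through
# the gain), and a literature-style association set holding the driver and
# a subset of the planted targets
sets <- build_chromosome_genesets(genome$annotation, genome$centromeres)["chr8"]
for (i in 1:20) {
  sets[[sprintf("RANDOM_SET_%02d", i)]] <-
    sort(sample(genome$annotation$gene_id, sample(10:40, 1)))
}
for (i in 1:3) {
  sets[[sprintf("DOSAGE_RESPONSIVE_%d", i)]] <-
    sort(c(sample(chr8_genes, 30), sample(other_genes, 10)))
}
sets[["CDK46_ASSOCIATION"]] <- sort(c(cohort$driver_gene_id,
                                      sample(setdiff(targets,
                                                     cohort$driver_gene_id), 19),
                                      sample(other_genes, 20)))
write_gmt(sets, file.path(out, "sets.gmt"))

drugs <- sprintf("drug%02d", 1:20)
dr <- do.call(rbind, lapply(seq_along(drugs), function(i) {
  base <- c(0.2, 0.5, 1, 2, 5)[1 + (i %% 5)]
  rbind(
    simulate_dose_response(ic50 = base, hill = 2.5,
                           doses = base * 10^seq(-3, 2, length.out = 9),
                           noise_sd = 0.03, n_reps = 3, drug = drugs[i],
                           condition = "high_expression", seed = seed + 100 + i),
    simulate_dose_response(ic50 = if (i == 13) base * 10 else base, hill = 2.5,
                           doses = base * 10^seq(-3, 2, length.out = 9),
                           noise_sd = 0.03, n_reps = 3, drug = drugs[i],
                           condition = "low_expression", seed = seed + 200 + i)
  )
}))
write_dose_response_tsv(dr, file.path(out, "drugs.tsv"))

jsonlite::write_json(
  list(seed = seed, driver_gene = cohort$driver_gene_id,
       translational_targets = omics$truth, sensitized_drug = "drug13",
       params = cohort$params),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA
)

cat("Synthetic inputs written to", out, "\n")
cat("Planted driver gene:", cohort$driver_gene_id, "\n")
cat("chr8 gain prevalence (realized):",
    mean(cohort$cnv_truth$status[cohort$cnv_truth$region == "chr8"] == "gain"),
    "\n")
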