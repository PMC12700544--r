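#!/usr/bin/env Rscript
# Proteome/transcriptome integration: moderated differential abundance per
# cell-line block after the one-value-per-replicate-group detection filter,
# pooling across blocks, the translational-regulation filter (protein
# change without mRNA change in any block), and the candidate
# prioritization cascade (top-decile downregulated -> association set ->
# adverse survival association in the cohort screen).

library(gainscan)

inp <- "results/synthetic"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

omics <- read_omics_dir(file.path(inp, "omics"))
sets <- read_gmt(file.path(inp, "sets.gmt"))
truth <- jsonlite::read_json(file.path(inp, "truth.json"))
screen <- list(results = utils::read.table(
  file.path(out, "survival_screen.tsv"), header = TRUE, sep = "\t"))

n_quant <- nrow(omics$protein[[1]])
detected <- Reduce(intersect, lapply(names(omics$protein), function(b) {
  filter_detected(omics$protein[[b]], omics$design[[b]])
}))
cat(sprintf("%d proteins quantified; %d pass the >=1-value-per-replicate-group filter in every block\n",
            n_quant, length(detected)))

stats <- omics_pair_stats(omics, d0 = 4)
gainscan:::write_tsv_plain(stats$pooled, file.path(out, "protein_pooled_stats.tsv"))

tt <- translational_targets(stats, protein_fdr = 0.05, mrna_floor = 0.05)
gainscan:::write_tsv_plain(data.frame(feature_id = tt$candidates),
                           file.path(out, "translational_candidates.tsv"))
planted <- unlist(truth$translational_targets)
cat(sprintf("%d translational candidates (protein BH < 0.05, mRNA quiet in all blocks); recall %.2f, precision %.2f vs planted truth\n",
            length(tt$candidates),
            mean(planted %in% tt$candidates),
            mean(tt$candidates %in% planted)))

cascade <- prioritize_candidates(stats, sets[["CDK46_ASSOCIATION"]], screen,
                                 decile = 0.10, survival_alpha = 0.05)
jsonlite::write_json(list(counts = as.list(cascade$counts),
                          stages = cascade$stages),
                     file.path(out, "cascade.json"),
                     auto_unbox = TRUE, digits = NA)
cat("Cascade counts:",
    paste(sprintf("%s=%d", names(cascade$counts), cascade$counts),
          collapse = ", "), "\n")
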