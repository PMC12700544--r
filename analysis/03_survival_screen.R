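#!/usr/bin/env Rscript
# Survival analyses: Kaplan-Meier + Mantel-Haenszel comparison of the
# inferred chr8-signature groups (whole cohort and the exclusive-chr8-gain
# subset without confounder CNVs), the genome-wide survival batch screen
# with Bonferroni/BH control (whole genome and chr8-restricted), quartile
# stratification by the top chr8 hit, and its effect size against the
# signature groups.

library(gainscan)

inp <- "results/synthetic"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression_tsv(file.path(inp, "expression.tsv"))
clinical <- read_clinical_tsv(file.path(inp, "clinical.tsv"))
cnv <- read_cnv_tsv(file.path(inp, "cnv.tsv"))
annotation <- read_annotation_tsv(file.path(inp, "annotation.tsv"))
groups <- utils::read.table(file.path(out, "chr8_signature_groups.tsv"),
                            header = TRUE, sep = "\t")
truth <- jsonlite::read_json(file.path(inp, "truth.json"))

lab <- factor(groups$label, levels = c("low", "high"))
names(lab) <- groups$sample_id
cl <- clinical[match(groups$sample_id, clinical$sample_id), ]

lr <- logrank_test(cl$time, cl$event, lab)
cat(sprintf("OS, high vs low chr8 signature (n = %d): log-rank chi2 = %.2f, p = %.4f\n",
            nrow(cl), lr$chisq, lr$p))

km <- do.call(rbind, lapply(levels(lab), function(lv) {
  fit <- km_estimate(cl$time[lab == lv], cl$event[lab == lv])
  cbind(group = lv, as.data.frame(fit))
}))
gainscan:::write_tsv_plain(km, file.path(out, "km_signature_groups.tsv"))

# exclusive chr8-gain subset: drop samples with confounder CNVs
sub <- exclusive_cnv_subset(cnv, "chr8", c("chr1q", "chr12", "chr16q"))
idx <- match(sub$sample_id, cl$sample_id)
lr_ex <- logrank_test(cl$time[idx], cl$event[idx],
                      ifelse(sub$focus_gain, "gain", "no_gain"))
cat(sprintf("OS, exclusive chr8 gain vs none (n = %d): log-rank p = %.4f\n",
            nrow(sub), lr_ex$p))

# genome-wide batch screen, median split
screen <- survival_batch_screen(expr, clinical, mode = "median")
gainscan:::write_tsv_plain(screen$results, file.path(out, "survival_screen.tsv"))
top <- screen$results[1, ]
driver <- truth$driver_gene
drow <- screen$results[screen$results$gene_id == driver, ]
cat(sprintf("Screen (m = %d genes): top hit %s (p = %.3g); planted driver %s rank %d (Bonferroni p = %.3g)\n",
            screen$m, top$gene_id, top$p, driver, drow$rank, drow$bonferroni_p))

# chr8-restricted screen, mirroring a chromosome-focused multiplicity scope
chr8_genes <- annotation$gene_id[annotation$chromosome == "chr8"]
screen8 <- survival_batch_screen(expr, clinical, gene_subset = chr8_genes)
d8 <- screen8$results[screen8$results$gene_id == driver, ]
cat(sprintf("chr8-restricted screen (m = %d): driver Bonferroni p = %.3g\n",
            screen8$m, d8$bonferroni_p))

# quartile stratification by the driver transcript
common <- intersect(colnames(expr), clinical$sample_id)
q <- expression_stratify(expr[driver, common], mode = "quartile")
lrq <- logrank_test(clinical$time[match(common, clinical$sample_id)],
                    clinical$event[match(common, clinical$sample_id)], q)
cat(sprintf("OS by %s quartile: chi2 = %.2f (df = %d), p = %.4g\n",
            driver, lrq$chisq, lrq$df, lrq$p))

# driver expression vs signature score association
sc <- utils::read.table(file.path(out, "chr8_signature_groups.tsv"),
                        header = TRUE, sep = "\t")
r <- stats::cor(expr[driver, sc$sample_id], sc$score)
d <- cohens_d(expr[driver, sc$sample_id[sc$label == "high"]],
              expr[driver, sc$sample_id[sc$label == "low"]])
cat(sprintf("%s expression vs chr8 score: Pearson r = %.2f; high-vs-low Cohen's d = %.2f\n",
            driver, r, d))
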