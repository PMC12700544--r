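# gainscan

Chromosome-8 gain is a recurrent aneuploidy in Ewing sarcoma and several
other cancers, present in roughly half of tumors. When a whole chromosome
is gained, the genes it carries are expressed at a dosage-shifted level,
so the gain leaves a detectable footprint in bulk expression data even
when no DNA-level copy-number assay is available. `gainscan` implements,
as a tested and reusable R package plus a scripted analysis workflow, the
computational chain that exploits this:

1. **Gain inference from expression** — single-sample gene-set enrichment
   scores (ssGSEA) for the chr8 gene set, two-group hierarchical
   clustering (`hclust`, complete linkage) of the scores, and validation
   by concordance with external CNV calls and by chromosomal position
   enrichment of the differentially expressed genes.
2. **Survival analysis** — Kaplan–Meier estimation and the
   Mantel–Haenszel (log-rank) test, a confounder-free "exclusive gain"
   sub-cohort rule, and a genome-wide survival batch screen (median or
   quartile expression splits, Bonferroni/BH control over the tested
   scope) that ranks every gene by its association with overall survival.
3. **Preranked GSEA** — correlation- and fold-change-based rankings, a
   seeded gene-permutation null (ES, NES, permutation p, BH), and the
   three-way Venn intersection of significant sets.
4. **Proteome–transcriptome integration** — detection filtering
   (≥1 value per replicate group), a Welch-type moderated t with a fixed
   shrinkage prior per cell-line block, Stouffer pooling across blocks,
   the translational-regulation filter (protein change with no mRNA
   change in any block), and the candidate prioritization cascade
   (top-decile downregulated → association set → adverse survival).
5. **Drug response** — four-parameter logistic (4PL) IC50 fitting by
   bounded Levenberg–Marquardt, differential-sensitivity ranking by
   Δlog10 IC50, and exact/approximate Mann–Whitney responder tests.

Because the original patient cohorts and proteomics deposits are not
bundled, the package ships seeded synthetic-data generators
(`simulate_cohort`, `simulate_knockdown_omics`, `simulate_dose_response`)
that reproduce the statistical structure each stage assumes — ~50%
gain prevalence, a multiplicative log2(3/2) dosage effect, an exponential
proportional-hazards survival model tied to one planted driver gene,
planted translational targets with group-structured missingness, and 4PL
curves with known IC50 — so every claim is validated against planted
ground truth.

## Worked example

The numbered scripts under `analysis/` run the full study on a synthetic
cohort (196 samples, 2,000 genes, 300 on chr8, planted driver
`chr8_g0001`) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_inputs.R
Rscript analysis/02_infer_chr8_gain.R
Rscript analysis/03_survival_screen.R
Rscript analysis/04_enrichment_triad.R
Rscript analysis/05_translational_filter.R
Rscript analysis/06_drug_response.R
```

Output of the run (abridged):

```
chr8-signature clustering vs CNV truth: accuracy 1.000 (n = 196), Fisher p = 1.77e-58
215 DEGs between inferred groups; 215 (100%) map to chr8
OS, high vs low chr8 signature (n = 196): log-rank chi2 = 4.81, p = 0.0283
OS, exclusive chr8 gain vs none (n = 135): log-rank p = 0.0060
Screen (m = 2000 genes): top hit chr8_g0001 (p = 2.86e-11); planted driver chr8_g0001 rank 1 (Bonferroni p = 5.72e-08)
chr8_g0001 expression vs chr8 score: Pearson r = 0.32; high-vs-low Cohen's d = 0.70
Triple-overlap sets: DOSAGE_RESPONSIVE_1, DOSAGE_RESPONSIVE_2, DOSAGE_RESPONSIVE_3
49 translational candidates (protein BH < 0.05, mRNA quiet in all blocks); recall 0.98, precision 1.00 vs planted truth
Cascade counts: downregulated=1024, top_decile=102, association=20, survival=2
Top differential-sensitivity hit: drug13 (delta log10 IC50 = 0.97; planted: drug13)
Driver expression, responders vs non-responders (n = 14): one-tailed Mann-Whitney p = 0.0265 (exact)
```

Reading this: the expression signature recovers the planted gain status
perfectly and the DEG positions confirm the signature is chromosome-8
specific; carriers of the inferred gain survive shorter (log-rank
p = 0.028, sharpened to 0.006 after excluding confounder CNVs); the
genome-wide screen ranks the planted driver first; the enrichment triad's
triple overlap contains exactly the three planted dosage-responsive
modules; the translational filter recovers 49/50 planted targets with no
false positives; the cascade funnels 1,024 downregulated proteins to 2
survival-relevant candidates; and the drug ranked first for differential
sensitivity is the one simulated with a 10-fold IC50 shift.

The same chain is available as a single configuration-driven call,
`run_full_pipeline(config)`, which writes a checksummed manifest and is
byte-identical across reruns with the same seed (see
`?run_full_pipeline` and `?validate_config`).

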