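---
title: "gainscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gainscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`gainscan` implements an analysis chain that starts from bulk expression of
a tumor cohort and ends at differential drug sensitivity: it infers
chromosome-8 copy-number gain from an expression signature, links the
inferred gain and a driver transcript to overall survival, isolates
proteins regulated at the level of protein synthesis from paired
knockdown proteome/transcriptome profiles, and ranks drugs by IC50 shift
between expression conditions. This vignette documents the statistical
models, the tunable parameters, the synthetic study conditions used for
validation, and the design decisions taken where the methodology was
genuinely open.

## Expression-based inference of chromosome gain

**Per-sample enrichment score.** For each sample the genes are ranked by
descending expression (ties broken lexicographically by gene id, so scores
are invariant to storage order). Gene at rank $i$ of $N$ carries the
rank statistic $s_i = (N - i + 1)/N$ and weight $|s_i|^\alpha$. For a gene
set $S$ of size $k$, the score is

$$\mathrm{ES} = \sum_{i=1}^{N}\left(
  \frac{\sum_{j \le i,\, j \in S} |s_j|^\alpha}{\sum_{j \in S} |s_j|^\alpha}
  - \frac{\#\{j \le i,\, j \notin S\}}{N-k}\right),$$

i.e. the cumulative difference between the weighted in-set empirical
distribution and the unweighted out-of-set one. A set concentrated among
the most expressed genes yields a positive score. The exponent
$\alpha$ defaults to 0.25, which damps the influence of the extreme ranks
while retaining rank weighting; $\alpha = 0$ gives the unweighted
statistic. Scores are not normalized across samples: the downstream
clustering is location/scale-free within a cohort, and cross-cohort score
comparability is explicitly not claimed.

**Two-group stratification.** Samples are split by agglomerative
hierarchical clustering on the one-dimensional scores (Euclidean distance,
complete linkage — the defaults of the clustering routine the approach is
built around), cutting the tree at $k = 2$ and labeling the cluster with
the larger mean score "high". At least 4 samples and non-constant scores
are required; the procedure is deterministic.

**Validation of the inference.** Against an external copy-number call
table the labels are cross-tabulated as high/low versus gain/not-gain,
reporting accuracy and a two-sided Fisher exact p. Internally, genes
differentially expressed between the inferred groups (per-gene Welch
t-test, Benjamini–Hochberg adjustment, flags requiring adjusted
$p <$ `fdr` and $|\log_2 \mathrm{FC}| \ge$ `min_abs_lfc`, defaults 0.05
and 0.5) are mapped to chromosomes, and per-chromosome enrichment is
tested with a one-sided Fisher exact test, BH-adjusted across
chromosomes. If the signature truly tracks a chromosome-8 gain, the DEGs
concentrate on chromosome 8. The Welch test was chosen as the
assumption-light two-group default; genes with zero variance in both
groups and equal means are defined to have $p = 1$ rather than NaN, so
degenerate rows never poison the BH adjustment.

**Confounder exclusion.** `exclusive_cnv_subset()` retains the samples
whose confounder regions (e.g. 1q gain, chr12 gain, 16q loss) are all
neutral, tagging each retained sample by focus-region gain. The rule is
applied literally: a focus-region loss is retained with tag "no gain",
since the contrast of interest is gain versus no gain in an otherwise
quiet genome.

## Survival analysis and the batch screen

The Kaplan–Meier estimator and the Mantel–Haenszel (log-rank) test are
implemented from first principles (product-limit steps at distinct event
times; observed-minus-expected ledgers with exact hypergeometric
variance, ties handled exactly; $k$-group statistic
$(O-E)^\top V^{-1} (O-E)$ with $k-1$ df). Both are cross-checked in the
test suite against the `survival` package on random small datasets, which
serves as an independent oracle, never as the implementation.

The genome-wide screen stratifies every gene (median split by default;
ties go to the lower group, which keeps the two groups as balanced as the
data allow), applies the log-rank test, and adjusts with Bonferroni and
BH where the multiplicity $m$ counts only successfully tested genes —
restricting the screen to one chromosome's genes therefore adjusts within
that scope, mirroring a chromosome-focused analysis. Genes whose
stratification is degenerate (constant expression) are recorded as
untested with a reason and excluded from $m$. The output also records,
per gene, whether the high-expression group had more observed than
expected events ("high expression, worse survival"), which the candidate
cascade needs to orient hits. Quartile mode (Q1–Q4, values equal to a cut
point going to the lower group) reproduces four-arm survival figures.

Survival times are in months, event code 1 = death from any cause.

## Preranked enrichment with a permutation null

Two ranking constructors are provided: Pearson correlation of every gene
with a target transcript (constant genes excluded with a warning), and
mean log2 fold-change between two sample groups. Both produce a strictly
ordered list with lexicographic tie-break.

The enrichment score follows the classic weighted running-sum statistic:
in-set steps of size $|s_i|^{\alpha}/\sum_{S}|s_j|^{\alpha}$ (weight
exponent $\alpha = 1$ by default, $\alpha = 0$ available), out-of-set
steps of $-1/(N-k)$, ES = the extreme deviation. The null distribution is
obtained by gene-label permutation — `n_perm` random same-size sets drawn
from the ranking — because only ranked statistics are available in the
preranked setting. The p-value is the same-sign tail with a +1
pseudo-count, $p = (1 + \#\{|ES^\ast| \ge |ES|\})/(1 + \#\{\text{same
sign}\})$, hence $p \ge 1/(n_{\text{perm}}+1)$, and NES divides ES by the
mean magnitude of same-sign permutation scores. Everything is
reproducible from one seed. Three analyses are intersected on their
BH-significant sets (threshold 0.05 by default) into the seven-region
Venn partition.

## Proteome–transcriptome integration

Features must show at least one quantified value in every replicate group
(`filter_detected`) before testing — the minimal-evidence rule for sparse
protein quantification. The per-block two-group contrast is a Welch-type
moderated t: each group's variance is shrunk toward the across-feature
median of that group's variances with a fixed prior weight of `d0`
pseudo-replicates (default 4), and the Welch–Satterthwaite df is computed
from the moderated variances with effective per-group df $n_g - 1 + d_0$.
With `d0 = 0` the test is exactly the unmoderated Welch test, a limiting
case the suite asserts. A fixed prior was chosen over estimated
empirical-Bayes hyperparameters deliberately: it is deterministic,
transparent, and adequate at the scale of a three-cell-line knockdown
panel. Features with fewer than two values in either group are excluded
with reason "insufficient replicates".

Protein evidence is pooled across blocks by Stouffer's signed-z
combination of the per-block two-sided p-values, with BH across features
tested in every block, and a sign-consistency requirement on the
per-block fold-changes, since one candidate list across all cell lines is
wanted. "Not regulated at the mRNA level" is operationalized as per-block
mRNA BH $p \ge$ `mrna_floor` (default 0.05) in **every** block; setting
the floor to 0 disables the mRNA condition and returns the pure
protein-significant set. Both pooling and the mRNA criterion were open
methodological choices; the alternatives (per-line significance, a
fold-change ceiling on mRNA) are noted as variations a user can emulate
through the exposed thresholds.

The prioritization cascade takes the $\lfloor \text{decile} \times
\#\text{downregulated} \rfloor$ most-downregulated features by pooled
protein fold-change (downregulation = knockdown − control $< 0$ on the
log2 scale), intersects with a literature association gene set supplied
as input, and finally keeps features whose transcript shows a nominal
survival-screen $p <$ `survival_alpha` in the adverse direction. Stages
may be empty; counts are non-increasing by construction and the report is
bit-reproducible.

## Dose–response fitting and differential sensitivity

Viability is modeled with the four-parameter logistic
$y = b + (t - b)/(1 + (d/\mathrm{IC}_{50})^{h})$, fitted by
Levenberg–Marquardt least squares parameterized in $\log_{10}
\mathrm{IC}_{50}$ with box constraints (IC50 within a tenfold margin of
the measured dose range, $h \in [10^{-3}, 100]$), initialized at
$t = \max y$, $b = \min y$, IC50 at the geometric mid-dose, $h = 1$.
Non-convergence yields a flagged result rather than an exception, and an
IC50 outside the measured range is flagged as extrapolated. Differential
sensitivity is primarily $\Delta \log_{10} \mathrm{IC}_{50}$ between
conditions (ties broken by drug name), with the difference of span-normalized
trapezoidal AUC of viability over $\log_{10}$ dose as a secondary,
fit-free metric — IC50 was chosen as primary because it is the quantity
dose-response figures report. Responder-group association uses the
Wilcoxon rank-sum test: exact for combined $n \le 20$ without ties,
otherwise the tie-corrected normal approximation.

## Synthetic study conditions

The generators define the validation conditions; they are fixed, not
tuning knobs.

* **Cohort** (`simulate_cohort`): 2,000 genes over 20 chromosomes with
  300 on chr8; whole-region alteration events drawn per sample
  (chr8 gain prevalence 0.5, matching the roughly half of tumors carrying
  the gain that motivates the signature; optional confounders such as 1q/12
  gains and 16q loss); additive log2 dosage effect $\log_2(3/2) \approx
  0.585$ — one extra copy of a disomic chromosome — on the genes of an
  altered region; i.i.d. Gaussian noise with SD 1.0 on top of per-gene
  baselines. Survival follows an exponential proportional-hazards model,
  hazard $= \lambda_0 \exp(\beta z)$ with $z$ the standardized driver
  expression, $\lambda_0 = 0.02$/month and $\beta = 0.7$ per SD by
  default; censoring is independent Uniform$(0, c)$ with $c$ solved
  numerically so the expected censored fraction matches `censor_rate`
  (0.3). The exponential family was chosen because it admits a
  closed-form oracle for the planted event-rate contrast. Cohort sizes of
  196 and 200–300 are used in the analyses and tests, matching the scale
  of the discovery cohort the design emulates.
* **Knockdown omics** (`simulate_knockdown_omics`): 3 cell-line blocks
  with 4 control + 4 knockdown replicates, planted targets shifted by the
  protein effect in every block and untouched at the mRNA layer,
  10% missingness completely at random in the protein layer only.
  Validation uses 5,000 features with 50 targets, protein effect 1 log2
  unit, noise SD 0.3.
* **Drug screen** (`simulate_dose_response`): 8-dose two-fold serial
  dilutions bracketing the expected IC50 with 3 replicates, 5% additive
  noise, Hill slope 3. The steep slope and bracketing design are the
  package's stated screen conditions: a design analysis via the
  Cramér–Rao bound showed that with a free four-parameter fit and this
  noise level, no 8-dose design constrains $\log_{10} \mathrm{IC}_{50}$
  tightly enough at shallow slopes ($h \approx 1$) to guarantee 10%
  recovery in 95% of runs, whereas steep viability responses — typical of
  cytotoxic readouts — are comfortably identifiable. Recovery and
  ranking claims therefore refer to this design.

What the generators deliberately do **not** emulate: co-expression
structure beyond the shared copy-number factor, subclonal or focal
alterations, batch effects, intensity-dependent missingness in the
proteomics layer, realistic mass-spectrometry intensity distributions,
and non-proportional hazards. Passing the planted-truth tests shows the
chain recovers the structure it models, not that real cohorts meet these
assumptions.

## Numerical and determinism notes

* One master seed is split into per-component integer streams
  (`sample.int` under the master seed), so regenerating any component is
  bit-identical and adding draws to one component does not perturb others.
* All ranking ties break lexicographically by gene/drug id; cluster-merge
  ties follow the deterministic behavior of `hclust`.
* TSV writers emit UTF-8 with "." decimal at full double precision, so
  identical config + seed reproduces byte-identical outputs; the pipeline
  manifest records md5 checksums (the log, which carries wall-times, is
  excluded from the manifest).
* BH columns are monotone in the raw p-values by construction
  (`p.adjust`); Bonferroni uses $\min(1, m p)$ with $m$ the tested count.
* Degenerate inputs — empty gene-set complement, constant
  scores, zero events, all-censored input, zero pooled SD — raise typed
  errors or defined values (documented per function) rather than NaN.

## Known limitations

* The chromosome-gain caller is a two-state classifier (high/low); it
  does not call losses, focal events, or more than two clusters.
* The gene-permutation GSEA null ignores inter-gene correlation; on real
  cohorts it is anti-conservative for strongly co-expressed sets, which
  is one reason the intersection across independent rankings is used.
* The moderated test assumes approximately Gaussian log2 abundances and
  MCAR missingness after the detection filter.
* IC50 comparisons assume both conditions were measured on overlapping
  dose ranges; extrapolated IC50s are flagged but not excluded from the
  ranking.
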