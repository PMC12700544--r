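#' Detection filter for replicate-grouped matrices
#'
#' Retains features with at least one non-missing value in every replicate
#' group — the minimal-evidence rule applied before differential analysis
#' of sparse protein quantifications.
#'
#' @param mat Features x samples matrix (may contain NA).
#' @param replicate_groups Named character/factor assigning each column to
#'   exactly one replicate group.
#' @return Character vector of retained feature ids.
#' @export
filter_detected <- function(mat, replicate_groups) {
  if (is.null(names(replicate_groups))) {
    if (length(replicate_groups) != ncol(mat)) stop("group per column required")
    names(replicate_groups) <- colnames(mat)
  }
  unassigned <- setdiff(colnames(mat), names(replicate_groups))
  if (length(unassigned)) stop("sample(s) not assigned to a replicate group: ",
                               paste(unassigned, collapse = ", "))
  groups <- replicate_groups[colnames(mat)]
  ok <- rep(TRUE, nrow(mat))
  for (g in unique(groups)) {
    ok <- ok & rowSums(!is.na(mat[, groups == g, drop = FALSE])) >= 1L
  }
  rownames(mat)[ok]
}

#' Moderated two-group differential abundance per block
#'
#' Per feature and block: Welch-type contrast (knockdown minus control) on
#' log2 values with variance moderation — each group's variance is shrunk
#' toward the across-feature median of that group's variances with prior
#' weight `d0` pseudo-replicates, and the Welch-Satterthwaite df is
#' computed from the moderated variances with effective per-group df
#' (n_g - 1 + d0). With `d0 = 0` this is exactly the unmoderated Welch
#' test. Features with fewer than 2 non-missing values in either group are
#' excluded with reason "insufficient replicates". BH adjustment spans all
#' tested features within the block.
#'
#' @param mat Features x samples matrix (log2, may contain NA).
#' @param design Named vector assigning columns to "control"/"knockdown".
#' @param d0 Prior degrees of freedom of the moderation (default 4).
#' @return list: `stats` (data.frame feature_id, log2fc, t, df, p, adj_p)
#'   and `excluded` (data.frame feature_id, reason).
#' @export
differential_abundance <- function(mat, design, d0 = 4) {
  if (is.null(names(design))) {
    stopifnot(length(design) == ncol(mat))
    names(design) <- colnames(mat)
  }
  stopifnot(all(design %in% c("control", "knockdown")))
  kd <- mat[, names(design)[design == "knockdown"], drop = FALSE]
  ct <- mat[, names(design)[design == "control"], drop = FALSE]
  n1 <- rowSums(!is.na(kd)); n2 <- rowSums(!is.na(ct))
  testable <- n1 >= 2L & n2 >= 2L
  excluded <- data.frame(feature_id = rownames(mat)[!testable],
                         reason = rep("insufficient replicates", sum(!testable)),
                         stringsAsFactors = FALSE)
  kd <- kd[testable, , drop = FALSE]; ct <- ct[testable, , drop = FALSE]
  n1 <- n1[testable]; n2 <- n2[testable]
  m1 <- rowMeans(kd, na.rm = TRUE); m2 <- rowMeans(ct, na.rm = TRUE)
  v1 <- rowVars_na(kd, m1, n1); v2 <- rowVars_na(ct, m2, n2)
  v1_prior <- stats::median(v1); v2_prior <- stats::median(v2)
  v1m <- (d0 * v1_prior + (n1 - 1) * v1) / (d0 + n1 - 1)
  v2m <- (d0 * v2_prior + (n2 - 1) * v2) / (d0 + n2 - 1)
  se2 <- v1m / n1 + v2m / n2
  diff <- m1 - m2
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1m / n1)^2 / (n1 - 1 + d0) + (v2m / n2)^2 / (n2 - 1 + d0))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  p[zero & diff == 0] <- 1
  p[zero & diff != 0] <- 0
  stats_df <- data.frame(feature_id = rownames(kd), log2fc = diff, t = t,
                         df = df, p = p,
                         adj_p = stats::p.adjust(p, method = "BH"),
                         stringsAsFactors = FALSE, row.names = NULL)
  list(stats = stats_df, excluded = excluded, d0 = d0)
}

#' Per-block differential statistics for a paired omics experiment
#'
#' Runs the detection filter plus [differential_abundance()] on each
#' protein block, the (complete) mRNA blocks, and pools protein evidence
#' across blocks by Stouffer's signed-z combination of the per-block
#' two-sided p-values, with a pooled BH adjustment across features tested
#' in every block.
#'
#' @param omics `synthetic_omics_pair`-like list with `protein`, `mrna`
#'   (lists of matrices per block) and `design` (per-block group vectors).
#' @param d0 Moderation prior df passed through.
#' @return list of class `omics_pair_stats`: `protein` / `mrna` per-block
#'   stats, `pooled` (feature_id, mean_log2fc, sign_consistent, z, p,
#'   adj_p), `excluded` per block.
#' @export
omics_pair_stats <- function(omics, d0 = 4) {
  blocks <- names(omics$protein)
  prot <- lapply(blocks, function(b) {
    m <- omics$protein[[b]]
    keep <- filter_detected(m, omics$design[[b]])
    differential_abundance(m[keep, , drop = FALSE], omics$design[[b]], d0 = d0)
  })
  mrna <- lapply(blocks, function(b) {
    differential_abundance(omics$mrna[[b]], omics$design[[b]], d0 = d0)
  })
  names(prot) <- names(mrna) <- blocks

  common <- Reduce(intersect, lapply(prot, function(x) x$stats$feature_id))
  zmat <- vapply(prot, function(x) {
    s <- x$stats[match(common, x$stats$feature_id), ]
    sign(s$log2fc) * stats::qnorm(pmax(s$p, 1e-300) / 2, lower.tail = FALSE)
  }, numeric(length(common)))
  lfc <- vapply(prot, function(x) {
    x$stats$log2fc[match(common, x$stats$feature_id)]
  }, numeric(length(common)))
  if (length(common) == 1L) {
    zmat <- matrix(zmat, 1L); lfc <- matrix(lfc, 1L)
  }
  z <- rowSums(zmat) / sqrt(ncol(zmat))
  p <- 2 * stats::pnorm(-abs(z))
  pooled <- data.frame(
    feature_id = common,
    mean_log2fc = rowMeans(lfc),
    sign_consistent = apply(lfc, 1L, function(x) all(x > 0) || all(x < 0)),
    z = z, p = p, adj_p = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(protein = prot, mrna = mrna, pooled = pooled,
                 blocks = blocks, d0 = d0),
            class = "omics_pair_stats")
}

#' Translationally regulated candidate features
#'
#' A feature is a candidate iff its pooled protein evidence is significant
#' (pooled BH p < `protein_fdr`) with a consistent fold-change sign across
#' blocks, AND its mRNA layer shows no regulation in any block (per-block
#' mRNA BH p >= `mrna_floor`). Features absent from the mRNA layer are
#' excluded with a reason.
#'
#' @param stats `omics_pair_stats` object.
#' @param protein_fdr Pooled protein BH threshold (default 0.05).
#' @param mrna_floor Minimum per-block mRNA BH p (default 0.05; 0 disables
#'   the mRNA condition, reducing to the protein-significant set).
#' @return list: `candidates` (feature ids), `table` (per-feature decision
#'   columns), `excluded` (feature_id, reason).
#' @export
translational_targets <- function(stats, protein_fdr = 0.05,
                                  mrna_floor = 0.05) {
  pooled <- stats$pooled
  mrna_p <- vapply(stats$mrna, function(x) {
    x$stats$adj_p[match(pooled$feature_id, x$stats$feature_id)]
  }, numeric(nrow(pooled)))
  if (nrow(pooled) == 1L) mrna_p <- matrix(mrna_p, 1L)
  in_mrna <- stats::complete.cases(mrna_p)
  excluded <- data.frame(feature_id = pooled$feature_id[!in_mrna],
                         reason = rep("absent from mRNA layer", sum(!in_mrna)),
                         stringsAsFactors = FALSE)
  prot_sig <- pooled$adj_p < protein_fdr & pooled$sign_consistent
  mrna_quiet <- in_mrna & rowSums(mrna_p < mrna_floor, na.rm = TRUE) == 0L
  cand <- pooled$feature_id[prot_sig & mrna_quiet & in_mrna]
  tab <- data.frame(feature_id = pooled$feature_id,
                    protein_significant = prot_sig,
                    mrna_quiet = mrna_quiet,
                    candidate = pooled$feature_id %in% cand,
                    stringsAsFactors = FALSE)
  list(candidates = sort(cand), table = tab, excluded = excluded,
       protein_fdr = protein_fdr, mrna_floor = mrna_floor)
}

#' Candidate prioritization cascade
#'
#' Stage 1 takes the floor(`decile` x number of downregulated features)
#' most-downregulated features by pooled protein log2 fold-change
#' (knockdown minus control < 0); stage 2 intersects with a literature
#' association gene set; stage 3 keeps features whose transcript shows a
#' nominal survival-screen p below `survival_alpha` with the adverse
#' direction (high expression, worse survival).
#'
#' @param stats `omics_pair_stats` object (or any data.frame with
#'   feature_id and mean_log2fc in `$pooled`).
#' @param association_set Character vector of gene/feature ids.
#' @param screen_result Result of [survival_batch_screen()].
#' @param decile Fraction of downregulated features kept (default 0.10).
#' @param survival_alpha Nominal screen p threshold (default 0.05).
#' @param feature_subset Optional ids restricting the input pool (e.g. the
#'   translational candidates).
#' @return list of class `cascade_report`: `stages` (named list of id
#'   vectors), `counts`.
#' @export
prioritize_candidates <- function(stats, association_set, screen_result,
                                  decile = 0.10, survival_alpha = 0.05,
                                  feature_subset = NULL) {
  if (decile <= 0 || decile > 1) stop("decile must be in (0,1]")
  pooled <- stats$pooled
  if (!is.null(feature_subset)) {
    pooled <- pooled[pooled$feature_id %in% feature_subset, , drop = FALSE]
  }
  down <- pooled[pooled$mean_log2fc < 0, , drop = FALSE]
  down <- down[order(down$mean_log2fc, down$feature_id), , drop = FALSE]
  n1 <- floor(decile * nrow(down))
  stage1 <- down$feature_id[seq_len(n1)]
  stage2 <- intersect(stage1, association_set)
  sr <- screen_result$results
  adverse <- sr$gene_id[sr$p < survival_alpha & sr$high_expr_worse]
  stage3 <- intersect(stage2, adverse)
  stages <- list(downregulated = down$feature_id,
                 top_decile = stage1,
                 association = stage2,
                 survival = stage3)
  structure(list(stages = stages,
                 counts = vapply(stages, length, 1L),
                 decile = decile, survival_alpha = survival_alpha),
            class = "cascade_report")
}
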