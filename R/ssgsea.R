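#' Single-sample gene-set enrichment scores
#'
#' For each sample, genes are ranked by descending expression (ties broken
#' by gene id for determinism). Each gene carries the rank statistic
#' (N - rank + 1) / N, and the score is the sum over all rank positions of
#' the difference between the weighted in-set cumulative fraction (weights
#' |statistic|^alpha) and the unweighted out-of-set cumulative fraction.
#' Scores are not normalized across samples; downstream two-group
#' clustering is location/scale invariant within a cohort.
#'
#' @param expr Expression matrix (genes x samples).
#' @param gene_set Character vector of member gene ids; must intersect the
#'   expressed universe and must not cover it entirely.
#' @param alpha Weighting exponent (default 0.25).
#' @return Named numeric vector of per-sample scores with attributes
#'   `gene_set_size` (members used) and `alpha`.
#' @export
ssgsea_scores <- function(expr, gene_set, alpha = 0.25) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  genes <- rownames(expr)
  members <- intersect(genes, gene_set)
  if (length(members) == 0L) stop("gene set has empty intersection with expression universe")
  if (length(members) == length(genes)) {
    stop("gene set covers the full expression universe (empty complement)")
  }
  n <- length(genes)
  k <- length(members)
  in_set <- genes %in% members
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(-expr[, j], genes)
    inord <- in_set[ord]
    stat <- (n - seq_len(n) + 1) / n
    w <- abs(stat)^alpha * inord
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inord) / (n - k)
    sum(p_in - p_out)
  }, 0)
  names(scores) <- colnames(expr)
  attr(scores, "gene_set_size") <- k
  attr(scores, "alpha") <- alpha
  scores
}

#' Two-group stratification of per-sample scores
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance on the 1-D scores), tree cut at k = 2; the cluster with the
#' larger mean score is labeled "high".
#'
#' @param scores Named numeric vector (>= 4 samples, not all identical).
#' @return list of class `stratification`: `labels` (named factor
#'   high/low), `cluster_means`, `linkage`.
#' @export
stratify_two_groups <- function(scores) {
  if (length(scores) < 4L) stop("need >= 4 samples to stratify")
  if (diff(range(scores)) == 0) stop("degenerate scores: all identical")
  hc <- stats::hclust(stats::dist(scores), method = "complete")
  cl <- stats::cutree(hc, k = 2L)
  m <- tapply(scores, cl, mean)
  high_cl <- as.integer(names(m)[which.max(m)])
  labels <- factor(ifelse(cl == high_cl, "high", "low"),
                   levels = c("low", "high"))
  names(labels) <- names(scores)
  list(labels = labels,
       cluster_means = c(low = unname(min(m)), high = unname(max(m))),
       linkage = "complete/euclidean")
}

#' Concordance between inferred stratification and CNV calls
#'
#' Cross-tabulates high/low labels against gain vs not-gain status for one
#' region and reports accuracy (high <-> gain) plus a two-sided Fisher
#' exact p-value.
#'
#' @param stratification Result of [stratify_two_groups()].
#' @param cnv Long CNV table (`sample_id`, `region`, `status`).
#' @param region Region to compare against (default "chr8").
#' @return list: `confusion` (2x2 table), `accuracy`, `fisher_p`, `n`.
#' @export
cnv_concordance <- function(stratification, cnv, region = "chr8") {
  region <- normalize_chromosome(region)
  sub <- cnv[cnv$region == region, ]
  common <- intersect(names(stratification$labels), sub$sample_id)
  if (length(common) == 0L) stop("no sample overlap between labels and CNV table")
  lab <- stratification$labels[common]
  truth <- factor(ifelse(sub$status[match(common, sub$sample_id)] == "gain",
                         "gain", "not_gain"), levels = c("gain", "not_gain"))
  if (any(table(truth) < 2L)) stop("need >= 2 samples per truth class")
  conf <- table(label = factor(lab, levels = c("high", "low")), truth)
  acc <- (conf["high", "gain"] + conf["low", "not_gain"]) / sum(conf)
  p <- stats::fisher.test(conf)$p.value
  list(confusion = conf, accuracy = as.numeric(acc), fisher_p = p,
       n = length(common))
}

#' Differential expression between two labeled groups
#'
#' Per-gene Welch two-sample t-test on log2 values with Benjamini-Hochberg
#' adjustment over all tested genes. Genes with zero variance in both
#' groups and equal means get p = 1 (defined, not an error); zero variance
#' with unequal means gets p = 0.
#'
#' @param expr Expression matrix (genes x samples).
#' @param labels Factor/character per sample with exactly two levels.
#' @param fdr BH-adjusted p threshold for the DEG flag (default 0.05).
#' @param min_abs_lfc Minimum |log2FC| for the DEG flag (default 0.5).
#' @return data.frame: gene_id, log2fc (first-level minus second, see
#'   Details), t, p, adj_p, deg.
#' @details `log2fc` is mean(group "high") - mean(group "low") when levels
#'   are high/low; otherwise second level minus first level of
#'   `factor(labels)`.
#' @export
differential_expression <- function(expr, labels, fdr = 0.05,
                                    min_abs_lfc = 0.5) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (all(c("low", "high") %in% levels(labels))) {
    labels <- factor(as.character(labels), levels = c("low", "high"))
  }
  g1 <- labels == levels(labels)[2L]  # "high" / second level
  g2 <- labels == levels(labels)[1L]
  if (sum(g1) < 2L || sum(g2) < 2L) stop("need >= 2 samples per group")
  welch <- welch_rows(expr[, g1, drop = FALSE], expr[, g2, drop = FALSE])
  adj <- stats::p.adjust(welch$p, method = "BH")
  data.frame(gene_id = rownames(expr), log2fc = welch$diff, t = welch$t,
             p = welch$p, adj_p = adj,
             deg = adj < fdr & abs(welch$diff) >= min_abs_lfc,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized Welch t across rows of two matrices (NAs removed per row).
welch_rows <- function(a, b) {
  n1 <- rowSums(!is.na(a)); n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE); m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- rowVars_na(a, m1, n1); v2 <- rowVars_na(b, m2, n2)
  diff <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # degenerate rows: no variance anywhere
  zero <- se2 == 0
  p[zero & diff == 0] <- 1
  t[zero & diff == 0] <- 0
  p[zero & diff != 0] <- 0
  t[zero & diff != 0] <- Inf * sign(diff[zero & diff != 0])
  list(diff = diff, t = t, p = p, df = df, n1 = n1, n2 = n2, v1 = v1, v2 = v2)
}

rowVars_na <- function(m, means, n) {
  rowSums((m - means)^2, na.rm = TRUE) / (n - 1)
}

#' Chromosomal position enrichment of differentially expressed genes
#'
#' One-sided (enrichment) Fisher exact test per chromosome of DEG status
#' against chromosome membership, BH-adjusted across chromosomes.
#'
#' @param deg_table Output of [differential_expression()].
#' @param annotation Gene annotation covering every tested gene.
#' @return data.frame: chromosome, n_deg, n_non_deg, odds_ratio, p, adj_p,
#'   sorted by p.
#' @export
position_enrichment <- function(deg_table, annotation) {
  annotation <- validate_annotation(annotation)
  idx <- match(deg_table$gene_id, annotation$gene_id)
  if (anyNA(idx)) {
    stop("unannotated gene id(s): ",
         paste(utils::head(deg_table$gene_id[is.na(idx)], 5L), collapse = ", "))
  }
  chrom <- annotation$chromosome[idx]
  deg <- deg_table$deg
  res <- do.call(rbind, lapply(sort(unique(chrom)), function(ch) {
    on_ch <- chrom == ch
    tab <- matrix(c(sum(deg & on_ch), sum(deg & !on_ch),
                    sum(!deg & on_ch), sum(!deg & !on_ch)), 2L, 2L,
                  byrow = TRUE)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(chromosome = ch, n_deg = tab[1L, 1L], n_non_deg = tab[2L, 1L],
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  }))
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p, res$chromosome), , drop = FALSE]
}

#' Samples with an exclusive focus-region gain (or no alteration at all)
#'
#' Retains samples whose confounder regions are all neutral; each retained
#' sample is tagged by whether the focus region is gained. Samples carrying
#' any confounder alteration (gain or loss) are excluded, mirroring the
#' exclusion of co-occurring recurrent CNVs when isolating the effect of a
#' single chromosomal gain.
#'
#' @param cnv Long CNV table.
#' @param focus_region Region of interest (default "chr8").
#' @param confounder_regions Regions that must be neutral (e.g.
#'   `c("chr1q", "chr12", "chr16q")`).
#' @return data.frame: `sample_id`, `focus_gain` (logical).
#' @export
exclusive_cnv_subset <- function(cnv, focus_region = "chr8",
                                 confounder_regions) {
  focus_region <- normalize_chromosome(focus_region)
  confounder_regions <- normalize_chromosome(confounder_regions)
  regions <- unique(cnv$region)
  miss <- setdiff(c(focus_region, confounder_regions), regions)
  if (length(miss)) stop("region(s) absent from CNV table: ",
                         paste(miss, collapse = ", "))
  wide <- split(cnv, cnv$sample_id)
  rows <- lapply(wide, function(d) {
    st <- stats::setNames(d$status, d$region)
    if (any(st[confounder_regions] != "neutral")) return(NULL)
    data.frame(sample_id = d$sample_id[1L],
               focus_gain = unname(st[focus_region] == "gain"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), focus_gain = logical())
  }
  rownames(out) <- NULL
  out[order(out$sample_id), , drop = FALSE]
}
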