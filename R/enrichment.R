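#' Rank genes by Pearson correlation with a target gene
#'
#' Pearson r between each other gene's expression and the target gene's
#' expression across samples. Constant genes are excluded with a warning;
#' ties are broken by gene id for a strict, deterministic ordering.
#'
#' @param expr Expression matrix (genes x samples, >= 3 samples).
#' @param target_gene Gene id present in `expr`.
#' @return data.frame of class `ranked_list`: `gene_id`, `stat`, sorted
#'   descending; attribute `provenance` = "correlation".
#' @export
rank_by_correlation <- function(expr, target_gene) {
  stopifnot(ncol(expr) >= 3L)
  if (!target_gene %in% rownames(expr)) stop("target gene absent: ", target_gene)
  y <- expr[target_gene, ]
  if (stats::sd(y) == 0) stop("target gene has constant expression")
  others <- setdiff(rownames(expr), target_gene)
  sds <- apply(expr[others, , drop = FALSE], 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from the ranking")
    others <- others[sds > 0]
  }
  r <- as.numeric(stats::cor(t(expr[others, , drop = FALSE]), y))
  ranked_list(others, r, "correlation")
}

#' Rank genes by log2 fold-change between two labeled groups
#'
#' Statistic = mean log2 difference, first group minus second
#' (e.g. gain minus no-gain).
#'
#' @param expr Expression matrix.
#' @param labels Two-level factor/character per sample; the statistic is
#'   `levels[2] - levels[1]` for `factor(labels)` unless levels are
#'   gain/neutral-style, see Details.
#' @param positive_level Level whose mean enters positively (default the
#'   second factor level).
#' @return `ranked_list` data.frame; attribute `provenance` = "foldchange".
#' @export
rank_by_foldchange <- function(expr, labels, positive_level = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (any(table(labels) == 0L)) stop("empty group")
  if (is.null(positive_level)) positive_level <- levels(labels)[2L]
  pos <- labels == positive_level
  stat <- rowMeans(expr[, pos, drop = FALSE]) -
    rowMeans(expr[, !pos, drop = FALSE])
  ranked_list(rownames(expr), as.numeric(stat), "foldchange")
}

ranked_list <- function(gene_id, stat, provenance) {
  if (anyNA(stat)) stop("NaN/NA ranking statistic")
  ord <- order(-stat, gene_id)
  out <- data.frame(gene_id = gene_id[ord], stat = stat[ord],
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("ranked_list", "data.frame")
  out
}

# Enrichment score of one set against a ranked list: running sum with
# in-set increments |stat|^alpha (normalized to total in-set weight) and
# out-of-set decrements 1/(N - k); ES is the extreme deviation. Computed
# from in-set positions only, O(k log k).
es_from_positions <- function(pos, stats_abs_alpha, n) {
  k <- length(pos)
  o <- order(pos)
  p <- pos[o]
  w <- stats_abs_alpha[o]
  W <- sum(w)
  if (W == 0) w <- rep(1, k) else w <- w / W
  cw <- cumsum(w)
  dec <- (p - seq_len(k)) / (n - k)
  after <- cw - dec           # running sum just after each in-set hit
  before <- c(0, cw[-k]) - dec  # just before each in-set hit
  hi <- max(after)
  lo <- min(before)
  if (hi >= abs(lo)) hi else lo
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' Classic weighted Kolmogorov-Smirnov-like running statistic on a ranked
#' gene list (weight exponent `alpha`, default 1). The null distribution
#' per set is obtained by drawing `n_perm` random gene sets of the same
#' size from the ranking; the p-value is the same-sign permutation tail
#' with a +1 pseudo-count, and NES is the enrichment score divided by the
#' mean magnitude of same-sign permutation scores. BH adjustment across
#' tested sets.
#'
#' @param ranked `ranked_list` (or data.frame gene_id/stat sorted desc).
#' @param sets Named list of gene sets; sets with < 2 members in the
#'   ranking are recorded untested.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Seed controlling all permutations.
#' @param alpha Weight exponent: 1 (classic) or 0 (unweighted).
#' @return list: `results` (data.frame set, size, es, nes, p, adj_p),
#'   `untested` (character), `n_perm`, `seed`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed, alpha = 1) {
  stopifnot(n_perm >= 100)
  if (missing(seed)) stop("seed is mandatory")
  validate_genesets(sets)
  n <- nrow(ranked)
  sa <- abs(ranked$stat)^alpha
  idx_of <- stats::setNames(seq_len(n), ranked$gene_id)

  with_seed(seed, {
    rows <- vector("list", length(sets))
    untested <- character()
    for (i in seq_along(sets)) {
      nm <- names(sets)[i]
      pos <- unname(idx_of[intersect(sets[[i]], ranked$gene_id)])
      k <- length(pos)
      if (k < 2L || k >= n) {
        untested <- c(untested, nm)
        next
      }
      es <- es_from_positions(pos, sa[pos], n)
      perm <- vapply(seq_len(n_perm), function(b) {
        pp <- sample.int(n, k)
        es_from_positions(pp, sa[pp], n)
      }, 0)
      same <- perm[sign(perm) == sign(es)]
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      rows[[i]] <- data.frame(set = nm, size = k, es = es, nes = nes, p = p,
                              stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows)
    if (!is.null(res)) {
      res$adj_p <- stats::p.adjust(res$p, method = "BH")
      rownames(res) <- NULL
    }
    list(results = res, untested = untested, n_perm = n_perm, seed = seed,
         alpha = alpha)
  })
}

#' Venn partition of significant sets across three enrichment analyses
#'
#' Assigns every gene set significant (BH-adjusted p below threshold) in at
#' least one of three analyses to exactly one of the 7 Venn regions.
#'
#' @param results_a,results_b,results_c Results from [gsea_preranked()]
#'   (the `$results` data.frame or the full list).
#' @param adj_p_threshold Significance threshold in (0,1), default 0.05.
#' @return list: `regions` (named list A, B, C, AB, AC, BC, ABC of set
#'   names) and `counts`.
#' @export
intersect_significant <- function(results_a, results_b, results_c,
                                  adj_p_threshold = 0.05) {
  if (adj_p_threshold <= 0 || adj_p_threshold >= 1) {
    stop("adj_p_threshold must be in (0,1)")
  }
  sig <- function(r) {
    if (is.list(r) && !is.data.frame(r)) r <- r$results
    r$set[r$adj_p < adj_p_threshold]
  }
  A <- sig(results_a); B <- sig(results_b); C <- sig(results_c)
  regions <- list(
    A = setdiff(A, union(B, C)),
    B = setdiff(B, union(A, C)),
    C = setdiff(C, union(A, B)),
    AB = setdiff(intersect(A, B), C),
    AC = setdiff(intersect(A, C), B),
    BC = setdiff(intersect(B, C), A),
    ABC = intersect(intersect(A, B), C)
  )
  regions <- lapply(regions, sort)
  list(regions = regions, counts = vapply(regions, length, 1L))
}
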