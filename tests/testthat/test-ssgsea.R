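test_that("per-sample enrichment scores match the brute-force running sum", {
  expr <- toy_expr(10, 3, seed = 2)
  sets <- list(top = rownames(expr)[order(-expr[, 1])][1:2],
               mixed = rownames(expr)[c(1, 5, 9)],
               single = rownames(expr)[4])
  for (alpha in c(0, 0.25, 1)) {
    for (s in sets) {
      got <- ssgsea_scores(expr, s, alpha = alpha)
      want <- vapply(seq_len(ncol(expr)), function(j) {
        brute_ssgsea(expr[, j], s, alpha)
      }, 0)
      expect_equal(unname(unclass(got))[seq_len(ncol(expr))], want,
                   tolerance = 1e-12)
    }
  }
})

test_that("scores are sign-monotone in set placement and order-invariant", {
  expr <- toy_expr(8, 5, seed = 4)
  for (j in seq_len(ncol(expr))) {
    ord <- rownames(expr)[order(-expr[, j])]
    expect_gt(ssgsea_scores(expr, ord[1:2], alpha = 0.25)[j], 0)
    expect_lt(ssgsea_scores(expr, ord[7:8], alpha = 0.25)[j], 0)
  }
  perm <- sample(nrow(expr))
  s <- rownames(expr)[c(2, 6)]
  expect_equal(ssgsea_scores(expr[perm, ], s), ssgsea_scores(expr, s),
               tolerance = 1e-12)
})

test_that("score computation rejects degenerate gene sets", {
  expr <- toy_expr(6, 2)
  expect_error(ssgsea_scores(expr, c("zz1", "zz2")), "empty intersection")
  expect_error(ssgsea_scores(expr, rownames(expr)), "complement")
})

test_that("two-group stratification separates and is translation invariant", {
  sc <- c(a = 0.0, b = 0.1, c = 5.0, d = 5.2)
  st <- stratify_two_groups(sc)
  expect_identical(as.character(st$labels), c("low", "low", "high", "high"))
  st2 <- stratify_two_groups(sc + 100)
  expect_identical(st$labels, st2$labels)
  expect_error(stratify_two_groups(rep(1, 5)), "degenerate")
  expect_error(stratify_two_groups(c(a = 1, b = 2, c = 3)), ">= 4")
})

test_that("stratification accuracy is monotone in the planted dosage effect", {
  g <- synthetic_annotation(600, n_region_genes = c(chr8 = 120))
  chr8 <- g$annotation$gene_id[g$annotation$chromosome == "chr8"]
  acc <- vapply(c(0, 0.29, 0.585), function(de) {
    co <- simulate_cohort(100, g$annotation, dosage_effect = de, seed = 77)
    st <- stratify_two_groups(ssgsea_scores(co$expression, chr8))
    cnv_concordance(st, co$cnv_truth, "chr8")$accuracy
  }, 0)
  expect_true(all(diff(acc) >= 0))
  expect_lt(acc[1], 0.75)   # chance level without signal
  expect_gt(acc[3], 0.95)   # one extra copy, unit noise
})

test_that("CNV concordance reports accuracy and the exact Fisher tail", {
  sc <- c(s1 = 1, s2 = 1.2, s3 = 8, s4 = 8.4)
  st <- stratify_two_groups(sc)
  truth <- data.frame(sample_id = paste0("s", 1:4), region = "chr8",
                      status = c("neutral", "neutral", "gain", "gain"))
  conc <- cnv_concordance(st, truth, "chr8")
  expect_equal(conc$accuracy, 1.0)
  inv <- truth; inv$status <- rev(inv$status)
  expect_equal(cnv_concordance(st, inv, "chr8")$accuracy, 0.0)

  # 10/0;0/10 confusion: two-sided Fisher p equals the hypergeometric tail
  st2 <- list(labels = factor(rep(c("high", "low"), each = 10),
                              levels = c("low", "high")))
  names(st2$labels) <- sprintf("t%02d", 1:20)
  truth2 <- data.frame(sample_id = sprintf("t%02d", 1:20), region = "chr8",
                       status = rep(c("gain", "neutral"), each = 10))
  p <- cnv_concordance(st2, truth2, "chr8")$fisher_p
  expect_equal(p, 2 / choose(20, 10), tolerance = 1e-12)
})

test_that("differential expression flags planted shifts and not identical groups", {
  set.seed(8)
  expr <- matrix(rnorm(100 * 40, sd = 0.5), 100, 40,
                 dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:40)))
  labels <- rep(c("low", "high"), each = 20)
  expr["g001", labels == "high"] <- expr["g001", labels == "high"] + 3
  deg <- differential_expression(expr, labels)
  expect_true(deg$deg[deg$gene_id == "g001"])
  expect_gt(deg$log2fc[deg$gene_id == "g001"], 2)
  expect_lt(sum(deg$deg), 5)

  dup <- cbind(expr[, 1:3], expr[, 1:3])
  colnames(dup) <- sprintf("d%d", 1:6)
  same <- differential_expression(dup, rep(c("a", "b"), each = 3),
                                  min_abs_lfc = 0)
  expect_true(all(same$p == 1))
  expect_false(any(same$deg))
})

test_that("differential expression controls the false-discovery proportion under the null", {
  set.seed(42)
  expr <- matrix(rnorm(100 * 20), 100, 20,
                 dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:20)))
  fdp <- vapply(1:200, function(i) {
    lab <- sample(rep(c("a", "b"), each = 10))
    d <- differential_expression(expr, lab, fdr = 0.05, min_abs_lfc = 0)
    sum(d$deg) / max(1L, sum(d$deg))  # all discoveries are false under the null
  }, 0)
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 / 200))
})

test_that("BH adjustment is monotone and bounded below by raw p", {
  set.seed(3)
  expr <- toy_expr(50, 12, seed = 3)
  deg <- differential_expression(expr, rep(c("a", "b"), 6))
  expect_true(all(deg$adj_p >= deg$p - 1e-15))
  o <- order(deg$p)
  expect_true(all(diff(deg$adj_p[o]) >= -1e-15))
})

test_that("position enrichment matches exhaustive hypergeometric tails", {
  # extreme construction: all 20 DEGs on chr8, 200 genes on 10 chromosomes
  ann <- data.frame(gene_id = sprintf("g%03d", 1:200),
                    chromosome = rep(paste0("chr", 1:10), each = 20),
                    start = 1, end = 2)
  deg <- data.frame(gene_id = ann$gene_id,
                    deg = ann$chromosome == "chr8" &
                      seq_len(200) %in% which(ann$chromosome == "chr8"))
  res <- position_enrichment(deg, ann)
  expect_identical(res$chromosome[1], "chr8")
  expect_equal(res$p[1], min(res$p))

  # 2x2 toy (8 DEG-on-chr8, 2 elsewhere, 12 nonDEG-on-chr8, 178 elsewhere)
  ann2 <- data.frame(gene_id = sprintf("h%03d", 1:200),
                     chromosome = c(rep("chr8", 20), rep("chr1", 180)),
                     start = 1, end = 2)
  deg2 <- data.frame(gene_id = ann2$gene_id,
                     deg = c(rep(TRUE, 8), rep(FALSE, 12), rep(TRUE, 2),
                             rep(FALSE, 178)))
  res2 <- position_enrichment(deg2, ann2)
  tail_p <- sum(stats::dhyper(8:10, 20, 180, 10))
  expect_equal(res2$p[res2$chromosome == "chr8"], tail_p, tolerance = 1e-12)

  # zero DEGs -> all p = 1
  deg3 <- deg2; deg3$deg <- FALSE
  expect_true(all(position_enrichment(deg3, ann2)$p == 1))
  # unannotated gene -> error listing the id
  expect_error(position_enrichment(rbind(deg2, data.frame(gene_id = "zz", deg = TRUE)),
                                   ann2), "zz")
})

test_that("exclusive-gain subsetting matches hand enumeration", {
  cnv <- expand.grid(sample_id = sprintf("s%d", 1:6),
                     region = c("chr8", "chr1q", "chr12"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cnv$status <- "neutral"
  set_status <- function(s, r, st) {
    cnv$status[cnv$sample_id == s & cnv$region == r] <<- st
  }
  set_status("s1", "chr8", "gain")                          # exclusive gain
  set_status("s2", "chr8", "gain"); set_status("s2", "chr1q", "gain")  # confounded
  set_status("s3", "chr1q", "loss")                         # confounder only
  set_status("s4", "chr12", "gain")                         # confounder only
  # s5 all neutral; s6 chr8 loss, confounders neutral
  set_status("s6", "chr8", "loss")
  res <- exclusive_cnv_subset(cnv, "chr8", c("chr1q", "chr12"))
  expect_identical(res$sample_id, c("s1", "s5", "s6"))
  expect_identical(res$focus_gain, c(TRUE, FALSE, FALSE))
  expect_error(exclusive_cnv_subset(cnv, "chr8", "chr16q"), "chr16q")
})
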