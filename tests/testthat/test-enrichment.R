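test_that("correlation ranking matches the closed-form Pearson r", {
  expr <- toy_expr(6, 4, seed = 6)
  expr["g02", ] <- expr["g01", ]          # identical to target
  expr["g03", ] <- -expr["g01", ]         # anti-correlated
  rk <- rank_by_correlation(expr, "g01")
  expect_identical(rk$gene_id[1], "g02")
  expect_equal(rk$stat[1], 1)
  expect_identical(rk$gene_id[nrow(rk)], "g03")
  expect_equal(rk$stat[nrow(rk)], -1)
  # 4-sample closed form: r = cov / (sd_x sd_y)
  x <- expr["g01", ]; y <- expr["g04", ]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rk$stat[rk$gene_id == "g04"], r_hand, tolerance = 1e-12)
  expect_false("g01" %in% rk$gene_id)

  expr["g05", ] <- 3
  expect_warning(rk2 <- rank_by_correlation(expr, "g01"), "constant")
  expect_false("g05" %in% rk2$gene_id)
  expr["g01", ] <- 1
  expect_error(rank_by_correlation(expr, "g01"), "constant")
})

test_that("fold-change ranking is a mean log2 difference, order invariant", {
  expr <- toy_expr(20, 10, seed = 7)
  lab <- rep(c("no_gain", "gain"), each = 5)
  expr[1, lab == "gain"] <- expr[1, lab == "gain"] + 1
  rk <- rank_by_foldchange(expr, lab, positive_level = "gain")
  g1 <- rownames(expr)[1]
  hand <- mean(expr[1, lab == "gain"]) - mean(expr[1, lab == "no_gain"])
  expect_equal(rk$stat[rk$gene_id == g1], hand, tolerance = 1e-12)
  # equal group means -> statistic 0
  eq <- matrix(c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1), nrow = 1,
               dimnames = list("g", sprintf("s%d", 1:10)))
  expect_error(rank_by_foldchange(eq, rep("a", 10)), "two levels")
  eq2 <- rbind(eq, eq + 1)
  rownames(eq2) <- c("g", "h")
  rk0 <- rank_by_foldchange(eq2, rep(c("a", "b"), each = 5))
  expect_equal(rk0$stat, c(0, 0))
  # sample order invariance
  perm <- sample(ncol(expr))
  rk2 <- rank_by_foldchange(expr[, perm], lab[perm], positive_level = "gain")
  expect_equal(rk, rk2, tolerance = 1e-12)
})

test_that("enrichment score equals exhaustive prefix enumeration", {
  set.seed(12)
  for (i in 1:20) {
    n <- 6
    stat <- sort(round(rnorm(n, 0, 2), 2), decreasing = TRUE)
    rk <- data.frame(gene_id = sprintf("g%d", 1:n), stat = stat)
    set <- sample(rk$gene_id, 2)
    got <- gsea_preranked(rk, list(S = set), n_perm = 100, seed = i)
    expect_equal(got$results$es, brute_es(rk, set, alpha = 1),
                 tolerance = 1e-12)
    got0 <- gsea_preranked(rk, list(S = set), n_perm = 100, seed = i,
                           alpha = 0)
    expect_equal(got0$results$es, brute_es(rk, set, alpha = 0),
                 tolerance = 1e-12)
  }
})

test_that("enrichment score agrees with fgsea's statistic", {
  set.seed(13)
  stat <- sort(rnorm(50), decreasing = TRUE)
  rk <- data.frame(gene_id = sprintf("g%02d", 1:50), stat = stat)
  for (i in 1:5) {
    set <- sample(rk$gene_id, 6)
    got <- gsea_preranked(rk, list(S = set), n_perm = 100, seed = i)
    ref <- fgsea::calcGseaStat(stats::setNames(rk$stat, rk$gene_id),
                               selectedStats = match(set, rk$gene_id),
                               gseaParam = 1)
    expect_equal(got$results$es, ref, tolerance = 1e-10)
  }
})

test_that("alpha = 0 scores are invariant to monotone rescaling of the statistic", {
  set.seed(14)
  stat <- sort(rnorm(30), decreasing = TRUE)
  rk <- data.frame(gene_id = sprintf("g%02d", 1:30), stat = stat)
  rk2 <- rk; rk2$stat <- rank(rk$stat) / 30  # monotone transform, same order
  set <- sample(rk$gene_id, 5)
  a <- gsea_preranked(rk, list(S = set), n_perm = 100, seed = 3, alpha = 0)
  b <- gsea_preranked(rk2, list(S = set), n_perm = 100, seed = 3, alpha = 0)
  expect_equal(a$results$es, b$results$es, tolerance = 1e-12)
})

test_that("seeded enrichment runs are reproducible and top sets significant", {
  set.seed(15)
  stat <- sort(rnorm(20, 0, 2), decreasing = TRUE)
  rk <- data.frame(gene_id = sprintf("g%02d", 1:20), stat = stat)
  sets <- list(top = rk$gene_id[1:3], spread = rk$gene_id[c(2, 10, 19)])
  a <- gsea_preranked(rk, sets, n_perm = 1000, seed = 99)
  b <- gsea_preranked(rk, sets, n_perm = 1000, seed = 99)
  expect_identical(a$results, b$results)
  expect_gt(a$results$es[a$results$set == "top"], 0)
  expect_lte(a$results$p[a$results$set == "top"], 0.05)
  expect_gte(min(a$results$p), 1 / (a$n_perm + 1))
  # disjoint set recorded untested
  u <- gsea_preranked(rk, list(gone = c("zz1", "zz2")), n_perm = 100, seed = 1)
  expect_identical(u$untested, "gone")
  expect_null(u$results)
})

test_that("three-way significance intersection partitions correctly", {
  mk <- function(sig, all = c("s1", "s2", "s3", "s4", "s5")) {
    data.frame(set = all, adj_p = ifelse(all %in% sig, 0.01, 0.5))
  }
  # identical significant sets -> all in the triple overlap
  r <- intersect_significant(mk(c("s1", "s2")), mk(c("s1", "s2")),
                             mk(c("s1", "s2")))
  expect_identical(r$regions$ABC, c("s1", "s2"))
  expect_equal(sum(r$counts), 2)
  # pairwise-disjoint significance -> empty triple overlap
  r2 <- intersect_significant(mk("s1"), mk("s2"), mk("s3"))
  expect_equal(unname(r2$counts[c("A", "B", "C")]), c(1L, 1L, 1L))
  expect_equal(unname(r2$counts["ABC"]), 0L)
  # hand-assigned partition
  r3 <- intersect_significant(mk(c("s1", "s2", "s4")), mk(c("s2", "s3", "s4")),
                              mk(c("s3", "s4", "s5")))
  expect_identical(r3$regions$A, "s1")
  expect_identical(r3$regions$AB, "s2")
  expect_identical(r3$regions$BC, "s3")
  expect_identical(r3$regions$ABC, "s4")
  expect_identical(r3$regions$C, "s5")
  expect_equal(sum(r3$counts), 5)
  expect_error(intersect_significant(mk("s1"), mk("s1"), mk("s1"),
                                     adj_p_threshold = 1.2), "0,1")
})
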