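make_mat <- function(values, features, samples) {
  matrix(values, length(features), length(samples), byrow = TRUE,
         dimnames = list(features, samples))
}

test_that("detection filter requires one value per replicate group", {
  samples <- c("c1", "c2", "k1", "k2")
  groups <- stats::setNames(c("ctr", "ctr", "kd", "kd"), samples)
  m <- make_mat(c(
    1, 2, 3, 4,      # f1 complete -> keep
    NA, 2, 3, NA,    # f2 one per group -> keep (boundary)
    NA, NA, 3, 4,    # f3 missing entire ctr group -> drop
    1, 2, NA, NA,    # f4 missing entire kd group -> drop
    NA, NA, NA, NA,  # f5 all missing -> drop
    1, NA, NA, 4     # f6 one per group -> keep
  ), sprintf("f%d", 1:6), samples)
  expect_identical(filter_detected(m, groups), c("f1", "f2", "f6"))
  expect_error(filter_detected(m[, 1:3], groups[1:2]), "not assigned")
})

test_that("detection filter is monotone in data completeness", {
  set.seed(30)
  om <- simulate_knockdown_omics(300, 10, n_blocks = 1, missing_rate = 0.2,
                                 seed = 31)
  m <- om$protein[[1]]
  kept <- filter_detected(m, om$design[[1]])
  m2 <- m
  m2[sample(length(m2), 200)] <- NA  # strictly more missingness
  kept2 <- filter_detected(m2, om$design[[1]])
  expect_true(all(kept2 %in% kept))
})

test_that("moderated test reduces to Welch at d0 = 0 on complete data", {
  set.seed(32)
  m <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%d", 1:8)))
  design <- stats::setNames(rep(c("control", "knockdown"), each = 4),
                            colnames(m))
  res <- differential_abundance(m, design, d0 = 0)$stats
  for (i in c(1, 17, 50)) {
    tt <- stats::t.test(m[i, 5:8], m[i, 1:4], var.equal = FALSE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(res$df[i], unname(tt$parameter), tolerance = 1e-10)
  }
})

test_that("features failing the two-value rule are excluded with a reason", {
  m <- make_mat(c(1, 2, 3, 4, NA, 2, 3, 4), c("f1", "f2"),
                c("c1", "c2", "k1", "k2"))
  design <- stats::setNames(c("control", "control", "knockdown", "knockdown"),
                            colnames(m))
  res <- differential_abundance(m, design)
  expect_identical(res$excluded$feature_id, "f2")
  expect_identical(res$excluded$reason, "insufficient replicates")
  expect_identical(res$stats$feature_id, "f1")
})

test_that("moderated test has power on planted effects and controls null FDR", {
  # power: planted -1 log2FC, sd 0.3, 4v4
  set.seed(33)
  hits <- vapply(1:50, function(i) {
    om <- simulate_knockdown_omics(200, 20, n_blocks = 1, n_reps = 4,
                                   protein_effect = -1, missing_rate = 0,
                                   noise_sd = 0.3, seed = 1000 + i)
    res <- differential_abundance(om$protein[[1]], om$design[[1]])
    mean(res$stats$adj_p[res$stats$feature_id %in% om$truth] < 0.05)
  }, 0)
  expect_gte(mean(hits), 0.9)

  # null: no effects -> mean false-discovery proportion bounded by the BH level
  fdp <- vapply(1:100, function(i) {
    om <- simulate_knockdown_omics(200, 0, n_blocks = 1, n_reps = 4,
                                   missing_rate = 0, noise_sd = 0.3,
                                   seed = 2000 + i)
    res <- differential_abundance(om$protein[[1]], om$design[[1]])
    sum(res$stats$adj_p < 0.05) / max(1L, sum(res$stats$adj_p < 0.05))
  }, 0)
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 / 100))
})

test_that("translational filter applies both the protein and mRNA conditions", {
  om <- simulate_knockdown_omics(800, 30, n_blocks = 3, n_reps = 4,
                                 protein_effect = 1, mrna_effect = 0,
                                 missing_rate = 0.1, noise_sd = 0.3,
                                 seed = 40)
  st <- omics_pair_stats(om)
  tt <- translational_targets(st)
  recall <- mean(om$truth %in% tt$candidates)
  precision <- mean(tt$candidates %in% om$truth)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.8)

  # a protein-significant feature that is also mRNA-significant is excluded
  om2 <- simulate_knockdown_omics(400, 15, n_blocks = 2, n_reps = 4,
                                  protein_effect = 1, mrna_effect = 1,
                                  missing_rate = 0, noise_sd = 0.2, seed = 41)
  st2 <- omics_pair_stats(om2)
  tt2 <- translational_targets(st2)
  expect_lte(sum(om2$truth %in% tt2$candidates), 1L)

  # mrna_floor = 0 disables the mRNA condition
  tt0 <- translational_targets(st2, mrna_floor = 0)
  pooled_sig <- st2$pooled$feature_id[st2$pooled$adj_p < 0.05 &
                                        st2$pooled$sign_consistent]
  expect_setequal(tt0$candidates, pooled_sig)

  # null experiment: candidate count within the FDR-consistent bound
  om0 <- simulate_knockdown_omics(800, 0, n_blocks = 3, n_reps = 4,
                                  missing_rate = 0.1, seed = 42)
  tt_null <- translational_targets(omics_pair_stats(om0))
  expect_lte(length(tt_null$candidates), ceiling(0.05 * 800))
})

test_that("prioritization cascade follows the floor-decile and stage rules", {
  # hand-built pooled stats: 20 downregulated features f01..f20 with
  # log2fc -2.0, -1.9, ..., plus upregulated ones that must be ignored
  pooled <- data.frame(
    feature_id = sprintf("f%02d", 1:25),
    mean_log2fc = c(seq(-2, -0.1, by = 0.1), seq(0.5, 0.9, by = 0.1)),
    sign_consistent = TRUE, z = 0, p = 0.5, adj_p = 0.5
  )
  st <- list(pooled = pooled)
  screen <- list(results = data.frame(
    gene_id = sprintf("f%02d", 1:25),
    p = c(0.01, 0.2, 0.01, rep(0.5, 22)),
    high_expr_worse = c(TRUE, TRUE, FALSE, rep(TRUE, 22))
  ))
  assoc <- c("f01", "f02", "f03", "f21")
  rep1 <- prioritize_candidates(st, assoc, screen, decile = 0.10,
                                survival_alpha = 0.05)
  # floor(0.10 * 20) = 2 most-downregulated
  expect_identical(rep1$stages$top_decile, c("f01", "f02"))
  expect_identical(rep1$stages$association, c("f01", "f02"))
  # f02 fails the survival condition (p = 0.2); f01 passes
  expect_identical(rep1$stages$survival, "f01")
  expect_true(all(diff(rep1$counts) <= 0))

  # empty association set -> stages 2 and 3 empty, not an error
  rep2 <- prioritize_candidates(st, character(), screen)
  expect_equal(unname(rep2$counts[c("association", "survival")]), c(0L, 0L))
})

test_that("cascade counts are non-increasing on random inputs", {
  set.seed(50)
  for (i in 1:10) {
    n <- 50
    pooled <- data.frame(feature_id = sprintf("r%02d", 1:n),
                         mean_log2fc = rnorm(n), sign_consistent = TRUE,
                         z = 0, p = 0.5, adj_p = 0.5)
    screen <- list(results = data.frame(gene_id = sprintf("r%02d", 1:n),
                                        p = runif(n),
                                        high_expr_worse = sample(c(TRUE, FALSE),
                                                                 n, TRUE)))
    assoc <- sample(pooled$feature_id, 10)
    rep <- prioritize_candidates(list(pooled = pooled), assoc, screen,
                                 decile = 0.2)
    expect_true(all(diff(rep$counts) <= 0))
    rep_b <- prioritize_candidates(list(pooled = pooled), assoc, screen,
                                   decile = 0.2)
    expect_identical(rep, rep_b)  # bit-identical from fixed inputs
  }
})
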