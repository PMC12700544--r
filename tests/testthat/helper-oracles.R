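# Independent brute-force oracles, kept deliberately naive (explicit loops)
# and separate from the package's vectorized implementations.

# Per-sample enrichment score by stepping through the ranked list one gene
# at a time.
brute_ssgsea <- function(x, gene_set, alpha) {
  genes <- names(x)
  ord <- order(-x, genes)
  n <- length(x)
  members <- intersect(genes, gene_set)
  k <- length(members)
  w_total <- 0
  for (i in seq_len(n)) {
    g <- genes[ord[i]]
    if (g %in% members) w_total <- w_total + ((n - i + 1) / n)^alpha
  }
  score <- 0; p_in <- 0; p_out <- 0
  for (i in seq_len(n)) {
    g <- genes[ord[i]]
    if (g %in% members) {
      p_in <- p_in + ((n - i + 1) / n)^alpha / w_total
    } else {
      p_out <- p_out + 1 / (n - k)
    }
    score <- score + (p_in - p_out)
  }
  score
}

# Enrichment score by exhaustive prefix enumeration of the running sum.
brute_es <- function(ranked, set, alpha = 1) {
  genes <- ranked$gene_id
  stat <- ranked$stat
  inset <- genes %in% set
  n <- length(genes)
  k <- sum(inset)
  w <- abs(stat)^alpha
  W <- sum(w[inset])
  run <- 0
  extremes <- numeric(n)
  for (i in seq_len(n)) {
    run <- run + if (inset[i]) w[i] / W else -1 / (n - k)
    extremes[i] <- run
  }
  hi <- max(c(0, extremes)); lo <- min(c(0, extremes))
  if (hi >= abs(lo)) hi else lo
}

# Log-rank chi-square for two groups via an explicit observed-minus-expected
# ledger over event times.
brute_logrank_2g <- function(times, events, groups) {
  lv <- sort(unique(groups))
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at <- times >= t
    n <- sum(at)
    n1 <- sum(at & groups == lv[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == lv[1])
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  (o - e)^2 / v
}

# Kaplan-Meier by stepwise product over event times.
brute_km <- function(times, events, at_time) {
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    if (t > at_time) break
    n <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n)
  }
  s
}

# One-sided Mann-Whitney p by enumerating every label arrangement.
brute_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  stats <- apply(combs, 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mean(stats >= obs)
}

toy_expr <- function(n_genes = 10, n_samples = 4, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, 8, 2), n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

toy_annotation_3chr <- function() {
  data.frame(
    gene_id = c("a1", "a2", "a3", "b1", "b2", "c1", "c2", "c3"),
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr8", "chr8", "chr8"),
    start = c(100, 5000, 9000, 100, 8000, 1000, 4400, 7000) * 1e3,
    end = c(200, 5100, 9100, 200, 8100, 2000, 5600, 7100) * 1e3,
    stringsAsFactors = FALSE
  )
}

toy_centromeres_3chr <- function() {
  data.frame(chromosome = c("chr1", "chr2", "chr8"),
             position = c(6e6, 5e6, 5e6), stringsAsFactors = FALSE)
}
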