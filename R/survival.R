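#' Kaplan-Meier product-limit estimate
#'
#' Right-continuous step estimator of the survival function under right
#' censoring. Censored-only input yields the constant function 1.
#'
#' @param times Positive follow-up times (months).
#' @param events 0 = censored, 1 = event.
#' @return data.frame of class `km_fit`: `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv` (S(t) just after `time`).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L)
  if (any(times <= 0) || any(!is.finite(times))) stop("times must be positive and finite")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  et <- sort(unique(times[events == 1]))
  if (length(et) == 0L) {
    out <- data.frame(time = numeric(), n_risk = numeric(),
                      n_event = numeric(), surv = numeric())
    class(out) <- c("km_fit", "data.frame")
    return(out)
  }
  n_risk <- vapply(et, function(t) sum(times >= t), 0)
  n_event <- vapply(et, function(t) sum(times == t & events == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = et, n_risk = n_risk, n_event = n_event, surv = surv)
  class(out) <- c("km_fit", "data.frame")
  out
}

#' Mantel-Haenszel (log-rank) test for k groups
#'
#' Sums observed-minus-expected events over distinct event times with the
#' hypergeometric variance-covariance (ties handled exactly); the statistic
#' is (O - E)' V^{-1} (O - E) over the first k - 1 groups, chi-square with
#' k - 1 df under the null.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group label per subject (>= 2 nonempty groups).
#' @return list: `chisq`, `df`, `p`, `observed`, `expected` (per group).
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need >= 2 nonempty groups")
  if (any(times <= 0)) stop("times must be positive")
  if (sum(events) == 0) {
    warning("zero events: log-rank p set to 1")
    O <- stats::setNames(rep(0, k), levels(groups))
    return(list(chisq = 0, df = k - 1L, p = 1, observed = O, expected = O))
  }
  et <- sort(unique(times[events == 1]))
  O <- rep(0, k); E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in et) {
    at_risk <- times >= t
    n <- sum(at_risk)
    nj <- tabulate(groups[at_risk], nbins = k)
    dead <- times == t & events == 1
    d <- sum(dead)
    dj <- tabulate(groups[dead], nbins = k)
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      frac <- nj / n
      vt <- d * (n - d) / (n - 1) * (diag(frac, k) - outer(frac, frac))
      V <- V + vt
    }
  }
  u <- (O - E)[-k]
  Vm <- V[-k, -k, drop = FALSE]
  chisq <- tryCatch(as.numeric(t(u) %*% solve(Vm, u)),
                    error = function(e) {
                      as.numeric(t(u) %*% MASS_ginv(Vm) %*% u)
                    })
  df <- k - 1L
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE),
       observed = stats::setNames(O, levels(groups)),
       expected = stats::setNames(E, levels(groups)))
}

# Moore-Penrose pseudo-inverse via SVD (fallback for singular V).
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > max(tol * s$d[1L], 0)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Stratify samples by expression of a single gene
#'
#' `median` mode yields two groups with ties going to the lower group;
#' `quartile` mode yields four groups Q1 (lowest) .. Q4 (highest) by
#' empirical quartiles, values equal to a cut point going to the lower
#' group.
#'
#' @param values Numeric vector (named by sample).
#' @param mode "median" or "quartile".
#' @return Factor of group labels ("low"/"high" or "Q1".."Q4").
#' @export
expression_stratify <- function(values, mode = c("median", "quartile")) {
  mode <- match.arg(mode)
  if (diff(range(values)) == 0) stop("all values identical; cannot stratify")
  if (mode == "median") {
    lab <- ifelse(values <= stats::median(values), "low", "high")
    out <- factor(lab, levels = c("low", "high"))
  } else {
    if (length(values) < 4L) stop("quartile mode needs >= 4 values")
    qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    lab <- cut(values, breaks = c(-Inf, qs, Inf),
               labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
    out <- factor(as.character(lab), levels = c("Q1", "Q2", "Q3", "Q4"))
    if (any(table(out) == 0L)) stop("degenerate quartile stratification (ties)")
  }
  names(out) <- names(values)
  out
}

#' Genome-wide survival batch screen
#'
#' For every gene: stratify samples by its expression, run the log-rank
#' test, and adjust nominal p-values by Bonferroni and Benjamini-Hochberg
#' over the set of successfully tested genes. The multiplicity m counts
#' only tested genes, so restricting `gene_subset` (e.g. to one
#' chromosome's genes) adjusts within that scope. Output is ranked by
#' ascending nominal p with deterministic tie-break by gene id.
#'
#' @param expr Expression matrix (genes x samples).
#' @param clinical Clinical table (`sample_id`, `time`, `event`).
#' @param mode Stratification mode, see [expression_stratify()].
#' @param gene_subset Optional gene ids restricting the screen.
#' @return list: `results` (data.frame gene_id, n_low/n_high or group
#'   sizes, chisq, p, bonferroni_p, bh_p, high_expr_worse, rank) and
#'   `untested` (data.frame gene_id, reason).
#' @export
survival_batch_screen <- function(expr, clinical, mode = "median",
                                  gene_subset = NULL) {
  common <- intersect(colnames(expr), clinical$sample_id)
  if (length(common) < 20L) stop("need >= 20 samples with clinical data")
  expr <- expr[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), ]
  genes <- rownames(expr)
  if (!is.null(gene_subset)) genes <- intersect(genes, gene_subset)
  if (length(genes) == 0L) stop("empty gene subset")

  rows <- vector("list", length(genes))
  untested <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    grp <- tryCatch(expression_stratify(expr[g, ], mode = mode),
                    error = function(e) conditionMessage(e))
    if (is.character(grp)) {
      untested[[g]] <- grp
      next
    }
    lr <- logrank_test(cl$time, cl$event, grp)
    top <- levels(grp)[nlevels(grp)]  # "high" or "Q4"
    rows[[i]] <- data.frame(
      gene_id = g, chisq = lr$chisq, p = lr$p,
      high_expr_worse = unname(lr$observed[top] > lr$expected[top]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable genes")
  m <- nrow(res)
  res$bonferroni_p <- pmin(1, m * res$p)
  res$bh_p <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$gene_id), ]
  res$rank <- seq_len(m)
  rownames(res) <- NULL
  untested_df <- data.frame(gene_id = names(untested),
                            reason = unlist(untested, use.names = FALSE),
                            stringsAsFactors = FALSE)
  list(results = res, untested = untested_df, m = m, mode = mode,
       n_samples = length(common))
}

#' Cohen's d effect size
#'
#' Difference of means over the pooled standard deviation (n - 1 weights).
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return Numeric scalar.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled SD")
  (mean(a) - mean(b)) / sqrt(sp2)
}
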