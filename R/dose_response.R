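#' Predicted viability of a four-parameter logistic curve
#' @param dose Concentration(s).
#' @param top,bottom,ic50,hill 4PL parameters.
#' @return Numeric vector.
#' @export
predict_4pl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of
#' `viability = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`
#' parameterized in log10(ic50), by Levenberg-Marquardt with box
#' constraints. Initialization: top = max(viability), bottom =
#' min(viability), ic50 = geometric mid-dose, hill = 1. ic50 is constrained
#' to [min dose / 10, max dose x 10]; a fitted ic50 outside the measured
#' dose range is flagged as extrapolated. Non-convergence yields a flagged
#' result, not an exception.
#'
#' @param curve data.frame with `dose` and `viability` columns (replicates
#'   as repeated doses); >= 4 distinct doses required.
#' @return list of class `fit_4pl`: `top`, `bottom`, `ic50`, `hill`,
#'   `rss`, `converged`, `ic50_in_range`, `n`.
#' @export
fit_4pl <- function(curve) {
  stopifnot(all(c("dose", "viability") %in% names(curve)))
  d <- curve$dose; y <- curve$viability
  if (any(d <= 0)) stop("doses must be strictly positive")
  if (any(!is.finite(y))) stop("viability must be finite")
  if (length(unique(d)) < 4L) stop("need >= 4 distinct doses")
  ld <- log10(d)
  start <- c(top = max(y), bottom = min(y),
             l10ic50 = mean(range(ld)), hill = 1)
  lower <- c(top = -Inf, bottom = -Inf, l10ic50 = min(ld) - 1, hill = 1e-3)
  upper <- c(top = Inf, bottom = Inf, l10ic50 = max(ld) + 1, hill = 100)
  residfun <- function(par) {
    par[["bottom"]] + (par[["top"]] - par[["bottom"]]) /
      (1 + 10^((ld - par[["l10ic50"]]) * par[["hill"]])) - y
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = residfun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && fit$info %in% 1:4
  if (!converged) {
    return(structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                          hill = NA_real_, rss = NA_real_, converged = FALSE,
                          ic50_in_range = FALSE, n = length(y)),
                     class = "fit_4pl"))
  }
  cf <- fit$par
  ic50 <- 10^cf[["l10ic50"]]
  structure(list(
    top = cf[["top"]], bottom = cf[["bottom"]], ic50 = ic50,
    hill = cf[["hill"]],
    rss = sum(fit$fvec^2),
    converged = TRUE,
    ic50_in_range = ic50 >= min(d) && ic50 <= max(d),
    n = length(y)
  ), class = "fit_4pl")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank drugs by IC50 shift between two conditions
#'
#' Fits every drug in both conditions, then ranks by
#' `delta_log10_ic50 = log10(IC50_a) - log10(IC50_b)` descending (large
#' positive = condition b more sensitive), ties broken by drug name.
#' Secondary metric: difference of the trapezoidal AUC of mean viability
#' over log10 dose, normalized by the log10 dose span.
#'
#' @param curves_a,curves_b Long dose-response tables (`drug`, `dose`,
#'   `viability`, optional `replicate`) per condition.
#' @return list: `ranking` (data.frame drug, ic50_a, ic50_b,
#'   delta_log10_ic50, auc_a, auc_b, delta_auc, rank), `excluded`
#'   (drug, reason).
#' @export
ic50_shift_ranking <- function(curves_a, curves_b) {
  drugs <- union(unique(curves_a$drug), unique(curves_b$drug))
  rows <- list(); excl <- list()
  for (dg in drugs) {
    ca <- curves_a[curves_a$drug == dg, , drop = FALSE]
    cb <- curves_b[curves_b$drug == dg, , drop = FALSE]
    if (nrow(ca) == 0L || nrow(cb) == 0L) {
      excl[[dg]] <- "missing in one condition"
      next
    }
    fa <- fit_4pl(ca); fb <- fit_4pl(cb)
    if (!fa$converged || !fb$converged) {
      excl[[dg]] <- "non-converged fit"
      next
    }
    rows[[dg]] <- data.frame(
      drug = dg, ic50_a = fa$ic50, ic50_b = fb$ic50,
      delta_log10_ic50 = log10(fa$ic50) - log10(fb$ic50),
      auc_a = auc_norm(ca), auc_b = auc_norm(cb),
      stringsAsFactors = FALSE
    )
  }
  ranking <- do.call(rbind, rows)
  if (!is.null(ranking)) {
    ranking$delta_auc <- ranking$auc_a - ranking$auc_b
    ranking <- ranking[order(-ranking$delta_log10_ic50, ranking$drug), ]
    ranking$rank <- seq_len(nrow(ranking))
    rownames(ranking) <- NULL
  }
  excluded <- data.frame(drug = names(excl),
                         reason = unlist(excl, use.names = FALSE),
                         stringsAsFactors = FALSE)
  list(ranking = ranking, excluded = excluded)
}

# Trapezoidal AUC of mean viability over log10 dose, normalized to span.
auc_norm <- function(curve) {
  mu <- tapply(curve$viability, curve$dose, mean)
  d <- log10(as.numeric(names(mu)))
  o <- order(d)
  d <- d[o]; mu <- as.numeric(mu)[o]
  sum(diff(d) * (utils::head(mu, -1) + mu[-1]) / 2) / (max(d) - min(d))
}

#' Mann-Whitney association between expression and responder status
#'
#' Wilcoxon rank-sum test of expression values between responder groups:
#' exact p for combined n <= 20 without ties, otherwise the normal
#' approximation with tie correction. `alternative = "greater"` tests
#' whether the *first* factor level of `labels` tends to larger values.
#'
#' @param values Numeric expression values.
#' @param labels Two-level responder labels, one per value.
#' @param alternative "two.sided", "greater" or "less".
#' @return list: `U` (statistic for the first level), `p`, `method`.
#' @export
responder_association <- function(values, labels,
                                  alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  if (any(table(labels) < 2L)) stop("each group needs n >= 2")
  x <- values[labels == levels(labels)[1L]]
  y <- values[labels == levels(labels)[2L]]
  n <- length(x) + length(y)
  ties <- anyDuplicated(values) > 0L
  exact <- n <= 20L && !ties
  wt <- stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                           correct = !exact)
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}
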