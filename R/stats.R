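## Cohort statistics: pooled two-sample t from summary data, exact
## Mann-Whitney U, two-sided Fisher exact 2x2, R^2, univariate screening at
## p < 0.1 and stepwise multivariate linear regression. All tests two-sided.

stat_result <- function(test, statistic, p_value, summaries = NULL,
                        reason = NULL) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(list(test = test, statistic = statistic,
                 p_value = min(p_value, 1), summaries = summaries,
                 reason = reason),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, ": statistic =", signif(x$statistic, 4),
      ", p =", signif(x$p_value, 3), "\n")
  if (!is.null(x$reason)) cat("  (", x$reason, ")\n")
  invisible(x)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Computes the classical pooled-variance two-sample t-test directly from
#' group means, SDs and sizes, as needed to check comparisons reported only
#' as mean +/- SD tables. Degenerate input (both SDs zero, equal means)
#' yields p = 1 by convention.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return a `stat_result` with the t statistic and two-sided p-value on
#'   `n1 + n2 - 2` degrees of freedom.
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    p <- if (mean1 == mean2) 1 else 0
    return(stat_result("pooled_t", if (mean1 == mean2) 0 else Inf, p,
                       reason = "degenerate: zero pooled variance"))
  }
  t <- (mean1 - mean2) / se
  p <- 2 * stats::pt(-abs(t), n1 + n2 - 2)
  stat_result("pooled_t", t, p,
              summaries = data.frame(mean = c(mean1, mean2),
                                     sd = c(sd1, sd2), n = c(n1, n2)))
}

## U statistic (number of (x, y) pairs with x > y, ties counting 1/2)
u_statistic <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

#' Mann-Whitney U test (exact by enumeration for small samples)
#'
#' Two-sided p-value by full enumeration of the permutation distribution of
#' U when `n1 + n2 <= 20` and there are no ties; otherwise the tie-corrected
#' normal approximation with continuity correction. The path used is
#' reported.
#'
#' @param x,y numeric samples (non-empty).
#' @return a `stat_result` (statistic = U of `x`).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  u_obs <- u_statistic(x, y)
  mu <- n1 * n2 / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (n1 + n2 <= 20 && !ties) {
    ## enumerate all assignments of the pooled ranks to group 1
    pooled <- rank(c(x, y))
    combos <- utils::combn(n1 + n2, n1)
    r1 <- matrix(pooled[combos], nrow = n1)
    u_all <- colSums(r1) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(stat_result("mann_whitney_exact", u_obs, p,
                       reason = "exact enumeration"))
  }
  ## tie-corrected normal approximation with continuity correction
  r <- rank(c(x, y))
  nt <- table(r)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * (n + 1 - sum(nt^3 - nt) / (n * (n - 1)))
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- 2 * stats::pnorm(-z)
  stat_result("mann_whitney_normal", u_obs, min(p, 1),
              reason = if (ties) "normal approximation (ties)"
                       else "normal approximation (large n)")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided convention: the sum of hypergeometric probabilities of all
#' tables with the same margins whose probability does not exceed that of
#' the observed table.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return a `stat_result` (statistic = odds-ratio sample estimate).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  a <- table[1, 1]
  m <- sum(table[1, ]); n <- sum(table[2, ]); k <- sum(table[, 1])
  if (m == 0 || n == 0 || k == 0 || k == m + n) {
    return(stat_result("fisher_exact", NA_real_, 1,
                       reason = "degenerate margin"))
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  or <- (table[1, 1] * table[2, 2]) / max(table[1, 2] * table[2, 1], 1e-12)
  stat_result("fisher_exact", or, min(p, 1))
}

#' Coefficient of determination (squared Pearson correlation)
#'
#' @param observed,predicted paired numeric vectors, n >= 3, both with
#'   positive variance.
#' @return R^2 in [0, 1].
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("inputs must be paired")
  if (length(observed) < 3) stop("need n >= 3")
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("zero variance in one of the inputs")
  stats::cor(observed, predicted)^2
}

#' Univariate screening of candidate predictors
#'
#' Fits a simple linear regression of the outcome on each candidate and
#' retains those whose slope p-value is strictly below `alpha_in` —
#' the entry gate to the stepwise multivariate model.
#'
#' @param table data.frame of the cohort.
#' @param outcome name of the numeric outcome column.
#' @param candidates character vector of candidate column names.
#' @param alpha_in screening threshold (default 0.1, strict).
#' @return data.frame: `candidate`, `p_value`, `retained`, `reason`.
#' @export
univariate_screen <- function(table, outcome, candidates, alpha_in = 0.1) {
  if (!is.numeric(table[[outcome]])) stop("outcome must be numeric")
  rows <- lapply(candidates, function(v) {
    x <- table[[v]]
    if (is.character(x) || is.logical(x)) x <- as.numeric(as.factor(x))
    if (stats::sd(x, na.rm = TRUE) == 0) {
      return(data.frame(candidate = v, p_value = NA_real_, retained = FALSE,
                        reason = "constant candidate",
                        stringsAsFactors = FALSE))
    }
    fit <- stats::lm(table[[outcome]] ~ x)
    cf <- summary(fit)$coefficients
    p <- if (nrow(cf) >= 2) cf[2, 4] else NA_real_
    if (!is.finite(p)) {
      return(data.frame(candidate = v, p_value = NA_real_, retained = FALSE,
                        reason = "slope p-value not defined",
                        stringsAsFactors = FALSE))
    }
    data.frame(candidate = v, p_value = p, retained = p < alpha_in,
               reason = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stepwise multivariate linear regression (forward entry / backward removal)
#'
#' Forward selection with entry threshold `alpha_enter` (candidate with the
#' smallest p-value in the expanded model enters if p < alpha_enter; ties
#' broken by column order), followed by backward removal of terms whose
#' p-value exceeds `alpha_remove`, iterated to a fixed point. Candidates are
#' standardised internally for the selection (t-based p-values are scale
#' invariant, so the selected set is unaffected); reported coefficients are
#' on the original scale. A candidate collinear with the current model is
#' dropped with a warning.
#'
#' @param table cohort data.frame.
#' @param outcome outcome column name.
#' @param candidates candidate column names (typically the retained set from
#'   [univariate_screen()]).
#' @param alpha_enter,alpha_remove entry / stay thresholds.
#' @return list of class `stepwise_fit`: `terms`, `coefficients`,
#'   `p_values`, `model` (the final `lm`), `dropped` (collinear).
#' @export
stepwise_lm <- function(table, outcome, candidates,
                        alpha_enter = 0.05, alpha_remove = 0.10) {
  if (length(candidates) < 1) stop("need at least one candidate")
  y <- table[[outcome]]
  X <- lapply(candidates, function(v) {
    x <- table[[v]]
    if (is.character(x) || is.logical(x)) x <- as.numeric(as.factor(x))
    x
  })
  names(X) <- candidates
  dropped <- character(0)
  Xs <- lapply(X, function(x) if (stats::sd(x) > 0) scale(x)[, 1] else x)
  dat <- as.data.frame(Xs)
  dat$.y <- y
  selected <- character(0)
  term_p <- function(sel) {
    ## per-term p-values of the model .y ~ sel
    f <- stats::as.formula(paste(".y ~",
                                 paste(sprintf("`%s`", sel), collapse = "+")))
    fit <- stats::lm(f, data = dat)
    cf <- summary(fit)$coefficients
    p <- cf[-1, 4]
    names(p) <- sel[seq_along(p)]
    list(fit = fit, p = p)
  }
  repeat {
    changed <- FALSE
    ## forward step
    remaining <- setdiff(candidates, c(selected, dropped))
    if (length(remaining) > 0) {
      pvals <- rep(NA_real_, length(remaining))
      for (i in seq_along(remaining)) {
        v <- remaining[i]
        trial <- c(selected, v)
        f <- stats::as.formula(paste(".y ~",
                                     paste(sprintf("`%s`", trial),
                                           collapse = "+")))
        fit <- stats::lm(f, data = dat)
        if (any(is.na(stats::coef(fit)))) {
          warning("dropping collinear candidate: ", v)
          dropped <- c(dropped, v)
          next
        }
        cf <- summary(fit)$coefficients
        pvals[i] <- cf[nrow(cf), 4]
      }
      ok <- which(!is.na(pvals))
      if (length(ok) > 0) {
        best <- ok[which.min(pvals[ok])]        # ties: first in column order
        if (pvals[best] < alpha_enter) {
          selected <- c(selected, remaining[best])
          changed <- TRUE
        }
      }
    }
    ## backward step
    if (length(selected) > 0) {
      tp <- term_p(selected)
      worst <- which.max(tp$p)
      if (tp$p[worst] > alpha_remove) {
        selected <- setdiff(selected, names(tp$p)[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(selected) == 0) {
    fit <- stats::lm(y ~ 1)
    return(structure(list(terms = character(0),
                          coefficients = stats::coef(fit),
                          p_values = numeric(0), model = fit,
                          dropped = dropped), class = "stepwise_fit"))
  }
  ## final fit on the original scale
  raw <- as.data.frame(X[selected])
  raw$.y <- y
  f <- stats::as.formula(paste(".y ~",
                               paste(sprintf("`%s`", selected),
                                     collapse = "+")))
  fit <- stats::lm(f, data = raw)
  cf <- summary(fit)$coefficients
  structure(list(terms = selected, coefficients = stats::coef(fit),
                 p_values = stats::setNames(cf[-1, 4], selected),
                 model = fit, dropped = dropped),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  if (length(x$terms) == 0) {
    cat("stepwise_fit: intercept-only model\n")
  } else {
    cat("stepwise_fit:", paste(x$terms, collapse = " + "), "\n")
    print(data.frame(term = x$terms,
                     coefficient = x$coefficients[-1],
                     p_value = signif(x$p_values, 3), row.names = NULL))
  }
  invisible(x)
}

#' Grouped summary table with per-row BAV vs TAV tests
#'
#' Produces the published table shape: one column per morphology group
#' (BAV0, BAV1, pooled BAV, TAV) and a p-value comparing BAV against TAV.
#' Continuous rows show mean +/- SD and use the pooled t-test when both
#' groups pass Shapiro-Wilk normality at alpha = 0.05, otherwise the
#' Mann-Whitney U test (flagged in `test`). Binary rows show n (%) and use
#' the Fisher exact test.
#'
#' @param table cohort data.frame with a `morphology` column (values `TAV`,
#'   `BAV0`, `BAV1`).
#' @param continuous character vector of numeric column names.
#' @param binary character vector of logical/0-1 column names.
#' @return data.frame: `variable`, formatted group columns, `p_value`,
#'   `test`.
#' @export
group_summary <- function(table, continuous, binary = character(0)) {
  is_bav <- table$morphology != "TAV"
  groups <- list(BAV0 = table$morphology == "BAV0",
                 BAV1 = table$morphology == "BAV1",
                 BAV = is_bav, TAV = !is_bav)
  fmt_cont <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  fmt_bin <- function(x) sprintf("%d (%.1f)", sum(x), 100 * mean(x))
  rows <- list()
  for (v in continuous) {
    x_bav <- table[[v]][is_bav]
    x_tav <- table[[v]][!is_bav]
    if (length(x_bav) < 2 || length(x_tav) < 2) {
      cells <- vapply(groups, function(g)
        if (sum(g) >= 2) fmt_cont(table[[v]][g]) else "n/a", character(1))
      rows[[v]] <- data.frame(variable = v, t(cells), p_value = NA_real_,
                              test = "not computable",
                              stringsAsFactors = FALSE)
      next
    }
    normal <- function(x) {
      if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value >= 0.05
    }
    if (normal(x_bav) && normal(x_tav)) {
      res <- pooled_t_from_summary(mean(x_bav), stats::sd(x_bav),
                                   length(x_bav), mean(x_tav),
                                   stats::sd(x_tav), length(x_tav))
      test_used <- "pooled_t"
    } else {
      res <- mann_whitney(x_bav, x_tav)
      test_used <- "mann_whitney"
    }
    cells <- vapply(groups, function(g)
      if (sum(g) >= 2) fmt_cont(table[[v]][g]) else "n/a", character(1))
    rows[[v]] <- data.frame(variable = v, t(cells), p_value = res$p_value,
                            test = test_used, stringsAsFactors = FALSE)
  }
  for (v in binary) {
    x <- as.logical(table[[v]])
    tab <- matrix(c(sum(x[is_bav]), sum(!x[is_bav]),
                    sum(x[!is_bav]), sum(!x[!is_bav])), 2, byrow = TRUE)
    res <- fisher_exact_2x2(tab)
    cells <- vapply(groups, function(g) fmt_bin(x[g]), character(1))
    rows[[v]] <- data.frame(variable = v, t(cells), p_value = res$p_value,
                            test = "fisher_exact", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
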