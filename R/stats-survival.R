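## Group-comparison statistics with a Shapiro-Wilk normality gate, and
## Kaplan-Meier / log-rank recurrence-free-survival analysis.

#' Two-group comparison with a normality gate
#'
#' Runs a Shapiro-Wilk normality test on each sample at alpha = 0.05; if both
#' pass, an unpaired t-test (equal variances) is used, otherwise the
#' Mann-Whitney (Wilcoxon rank-sum) test. The result records which branch ran.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param alphaNormality significance level of the normality gate.
#' @return a list of class `TestResult`: `testName`, `statistic`, `pValue`,
#'   `nPerGroup`, `normalityP`, `corrected`.
#' @export
twoGroupTest <- function(x, y, alphaNormality = 0.05) {
  if (length(x) < 3L || length(y) < 3L)
    stopf("each sample needs n >= 3 for the normality gate")
  swx <- stats::shapiro.test(x)$p.value
  swy <- stats::shapiro.test(y)$p.value
  if (swx > alphaNormality && swy > alphaNormality) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res <- list(testName = "t-test", statistic = unname(tt$statistic),
                pValue = tt$p.value)
  } else {
    wt <- stats::wilcox.test(x, y, exact = FALSE)
    res <- list(testName = "mann-whitney", statistic = unname(wt$statistic),
                pValue = wt$p.value)
  }
  structure(c(res, list(nPerGroup = c(length(x), length(y)),
                        normalityP = c(swx, swy), corrected = FALSE)),
            class = "TestResult")
}

#' Multi-group comparison with a normality gate
#'
#' Applies the Shapiro-Wilk gate to all groups; if every group passes, a
#' one-way ANOVA is used, otherwise Kruskal-Wallis. With `correct = TRUE`,
#' post-hoc pairwise p-values (t or Mann-Whitney per the same gate) are
#' Bonferroni-multiplied by the number of comparisons and capped at 1.
#'
#' @param groups list of >= 3 numeric samples (each n >= 3).
#' @param correct logical, apply Bonferroni-corrected post-hoc pairwise tests.
#' @param alphaNormality significance level of the normality gate.
#' @return a `TestResult` list; with `correct = TRUE` it also carries
#'   `pairwise`, a data frame of corrected pairwise p-values.
#' @export
multiGroupTest <- function(groups, correct = FALSE, alphaNormality = 0.05) {
  if (!is.list(groups) || length(groups) < 3L)
    stopf("need >= 3 groups (use twoGroupTest for two)")
  if (any(lengths(groups) < 3L)) stopf("each group needs n >= 3")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  sw <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, numeric(1))
  values <- unlist(groups)
  fac <- factor(rep(names(groups), lengths(groups)))
  if (all(sw > alphaNormality)) {
    fit <- stats::aov(values ~ fac)
    an <- summary(fit)[[1]]
    res <- list(testName = "anova", statistic = an[["F value"]][1],
                pValue = an[["Pr(>F)"]][1])
  } else {
    kw <- stats::kruskal.test(values, fac)
    res <- list(testName = "kruskal-wallis", statistic = unname(kw$statistic),
                pValue = kw$p.value)
  }
  out <- c(res, list(nPerGroup = lengths(groups), normalityP = sw,
                     corrected = correct))
  if (correct) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
    m <- length(pairs)
    pw <- do.call(rbind, lapply(pairs, function(p) {
      r <- twoGroupTest(groups[[p[1]]], groups[[p[2]]], alphaNormality)
      data.frame(group1 = p[1], group2 = p[2], test = r$testName,
                 pRaw = r$pValue, pCorrected = min(1, r$pValue * m),
                 stringsAsFactors = FALSE)
    }))
    out$pairwise <- pw
  }
  structure(out, class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$testName, x$statistic,
              x$pValue, if (isTRUE(x$corrected)) " (Bonferroni post-hoc attached)" else ""))
  invisible(x)
}

#' Kaplan-Meier recurrence-free-survival estimate
#'
#' Product-limit estimator with right censoring for one group.
#'
#' @param time event/censoring times, months (>= 0).
#' @param event logical or 0/1, TRUE when a recurrence occurred.
#' @return a list of class `KMEstimate`: `fit` (a `survfit` object), `time`,
#'   `surv` (step-function values) and `survivalAt(t)` accessor.
#' @examples
#' km <- kmEstimate(c(12, 20, 20, 20), c(TRUE, FALSE, FALSE, FALSE))
#' survivalAt(km, 11); survivalAt(km, 12)
#' @export
kmEstimate <- function(time, event) {
  if (any(time < 0)) stopf("negative survival times")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1)
  structure(list(fit = fit, time = fit$time, surv = fit$surv),
            class = "KMEstimate")
}

#' Survival probability at a queried time
#'
#' @param km a `KMEstimate`.
#' @param t query time (same units as the input times).
#' @return the product-limit estimate S(t); 1 before the first event.
#' @export
survivalAt <- function(km, t) {
  stopifnot(inherits(km, "KMEstimate"))
  idx <- which(km$time <= t)
  if (!length(idx)) return(1)
  km$surv[max(idx)]
}

#' @export
print.KMEstimate <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Log-rank comparison of survival curves
#'
#' @param time event/censoring times.
#' @param event event indicators.
#' @param group group labels (>= 2 nonempty groups; a joint test for >= 3).
#' @return a `TestResult` with the log-rank chi-square statistic and p-value.
#' @export
logrankCompare <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stopf("need at least two nonempty groups")
  if (any(table(group) == 0)) stopf("a group has zero subjects")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- length(sd$n) - 1
  structure(list(testName = "log-rank", statistic = sd$chisq,
                 pValue = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 nPerGroup = as.vector(sd$n), corrected = FALSE),
            class = "TestResult")
}
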