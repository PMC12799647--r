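# Cohort-level statistics for paired approach comparison: McNemar, ARR/NNT,
# Fisher/Woolf odds ratios, logistic regression, ROC/Youden with percentile
# bootstrap, Cohen's kappa, two-way mixed ICC, and rank tests.

#' Paired binary outcome table
#'
#' Cross-classification of one binary outcome under two paired conditions:
#' `a` = event under both, `b` = condition-1 only, `c` = condition-2 only,
#' `d` = neither. `b` and `c` are the discordant counts driving the McNemar
#' test.
#'
#' @param a,b,c,d non-negative counts.
#' @return object of class `paired_binary_table`.
#' @export
paired_binary_table <- function(a, b, c, d) {
  cnt <- c(a = a, b = b, c = c, d = d)
  if (any(cnt < 0)) stop("counts must be non-negative")
  n <- sum(cnt)
  if (n < 1) stop("empty table")
  structure(as.list(cnt), n = NULL,
            class = "paired_binary_table") -> out
  out$n <- n
  out
}

#' Build a paired table from two logical outcome vectors
#' @param cond1,cond2 logical vectors (same length, same shoulders).
#' @return a [paired_binary_table()].
#' @export
paired_table_from_outcomes <- function(cond1, cond2) {
  stopifnot(length(cond1) == length(cond2))
  paired_binary_table(sum(cond1 & cond2), sum(cond1 & !cond2),
                      sum(!cond1 & cond2), sum(!cond1 & !cond2))
}

#' Paired McNemar test on the discordant counts
#'
#' With continuity correction (the default),
#' \eqn{\chi^2 = (\max(|b-c|-1, 0))^2 / (b+c)}; without,
#' \eqn{\chi^2 = (b-c)^2/(b+c)}. p is the upper tail of the chi-square
#' distribution with 1 df.
#'
#' @param table a `paired_binary_table`.
#' @param continuity apply the continuity correction (default TRUE).
#' @return list with `chi2`, `p`, `b`, `c`, `continuity`.
#' @export
mcnemar <- function(table, continuity = TRUE) {
  b <- table$b; c <- table$c
  if (b + c == 0)
    stop("undefined test: no discordant pairs (b + c = 0)")
  chi2 <- if (continuity) max(abs(b - c) - 1, 0)^2 / (b + c)
          else (b - c)^2 / (b + c)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       b = b, c = c, continuity = continuity)
}

#' Absolute risk reduction and number needed to treat
#'
#' @param k_ref,k_alt event counts under the reference and alternative
#'   condition.
#' @param n number of paired subjects.
#' @return list with `rate_ref`, `rate_alt` (proportions), `arr`
#'   (rate_ref - rate_alt) and `nnt` (1/arr; `Inf` when arr = 0).
#' @export
arr_nnt <- function(k_ref, k_alt, n) {
  if (n < 1) stop("n must be >= 1")
  if (k_ref < 0 || k_ref > n || k_alt < 0 || k_alt > n)
    stop("counts must lie in [0, n]")
  rate_ref <- k_ref / n
  rate_alt <- k_alt / n
  arr <- rate_ref - rate_alt
  list(rate_ref = rate_ref, rate_alt = rate_alt, arr = arr,
       nnt = if (arr == 0) Inf else 1 / arr)
}

#' Odds ratio of a 2x2 table with Woolf CI and Fisher exact p
#'
#' OR is the sample cross-product ratio; the confidence interval is the
#' Woolf log-normal interval
#' \eqn{\exp(\log OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}. Structural zeros
#' get the Haldane-Anscombe 0.5 correction (flagged). The two-sided Fisher
#' p uses the point-probability summation rule.
#'
#' @param counts length-4 vector (r1c1, r1c2, r2c1, r2c2): rows are groups,
#'   columns are event / no-event.
#' @param ci_level confidence level (default 0.95).
#' @return list with `or`, `ci_low`, `ci_high`, `fisher_p`, `corrected`.
#' @export
odds_ratio_2x2 <- function(counts, ci_level = 0.95) {
  if (length(counts) != 4L || any(counts < 0))
    stop("counts must be 4 non-negative values")
  tab <- matrix(counts, 2L, 2L, byrow = TRUE)
  corrected <- any(counts == 0)
  w <- if (corrected) counts + 0.5 else counts
  if (corrected)
    warning("zero cell: Haldane-Anscombe 0.5 correction applied to OR/CI")
  or <- (w[1] * w[4]) / (w[2] * w[3])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       fisher_p = stats::fisher.test(tab)$p.value,
       corrected = corrected)
}

#' Binary logistic regression with Wald inference and AI-scaled odds ratios
#'
#' Maximum-likelihood fit (iteratively reweighted least squares via
#' [stats::glm()]); Wald standard errors from the observed information.
#' For predictors named in `per01_terms` (by default `AI`), the odds ratio
#' per +0.10 units, \eqn{\exp(0.1\beta)}, is reported alongside the
#' per-unit odds ratio. Perfect or quasi-perfect separation is detected and
#' flagged rather than silently diverging.
#'
#' @param y binary outcome (logical or 0/1).
#' @param X data frame of covariates.
#' @param terms RHS formula or character, e.g. `~ AI + age + sex` or
#'   `"AI * sex"`; default uses all columns of `X` additively.
#' @param ci_level confidence level for Wald CIs.
#' @param per01_terms names of predictors whose OR is also reported per
#'   +0.10 units.
#' @return object of class `logistic_fit`: `coefficients`,
#'   `standard_errors`, `wald_z`, `wald_p`, `or` table (per-unit and
#'   per-0.1 with CIs), `converged`, `separation`, and the underlying `glm`
#'   fit.
#' @export
logistic_fit <- function(y, X, terms = NULL, ci_level = 0.95,
                         per01_terms = "AI") {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; logistic fit undefined")
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("y and X must have matching rows")
  if (is.null(terms)) terms <- paste(names(X), collapse = " + ")
  rhs <- if (inherits(terms, "formula"))
    paste(deparse(terms[[length(terms)]]), collapse = "") else terms
  fml <- stats::as.formula(paste("..y ~", rhs))
  dat <- cbind(..y = y, X)
  if (length(stats::terms(fml, data = dat)) > 0 &&
      length(attr(stats::terms(fml, data = dat), "term.labels")) >= length(y))
    stop("more model terms than observations")
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  if (any(abs(co[-1]) > 15, na.rm = TRUE)) sep <- TRUE
  if (sep) warning("possible separation: coefficient estimates unreliable")
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  or <- data.frame(term = rownames(sm),
                   or_per_unit = exp(sm[, 1]),
                   ci_low = exp(sm[, 1] - z * sm[, 2]),
                   ci_high = exp(sm[, 1] + z * sm[, 2]),
                   row.names = NULL, stringsAsFactors = FALSE)
  s01 <- intersect(per01_terms, rownames(sm))
  or$or_per_0_1 <- NA_real_
  or$or_per_0_1_ci_low <- NA_real_
  or$or_per_0_1_ci_high <- NA_real_
  for (t in s01) {
    i <- match(t, or$term)
    or$or_per_0_1[i] <- exp(0.1 * sm[t, 1])
    or$or_per_0_1_ci_low[i] <- exp(0.1 * (sm[t, 1] - z * sm[t, 2]))
    or$or_per_0_1_ci_high[i] <- exp(0.1 * (sm[t, 1] + z * sm[t, 2]))
  }
  structure(list(coefficients = co,
                 standard_errors = sm[, 2],
                 wald_z = sm[, 3], wald_p = sm[, 4],
                 or = or, converged = fit$converged,
                 separation = sep, ci_level = ci_level, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic fit (binomial, IRLS)\n")
  tab <- data.frame(beta = round(x$coefficients, 4),
                    se = round(x$standard_errors, 4),
                    p = signif(x$wald_p, 3))
  print(tab)
  ai <- x$or[!is.na(x$or$or_per_0_1), , drop = FALSE]
  for (i in seq_len(nrow(ai)))
    cat(sprintf("OR per +0.10 %s: %.2f (%.0f%% CI %.2f-%.2f)\n",
                ai$term[i], ai$or_per_0_1[i], 100 * x$ci_level,
                ai$or_per_0_1_ci_low[i], ai$or_per_0_1_ci_high[i]))
  if (x$separation) cat("WARNING: possible separation\n")
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
summary.logistic_fit <- function(object, ...) {
  cbind(estimate = object$coefficients, se = object$standard_errors,
        z = object$wald_z, p = object$wald_p)
}

#' Empirical ROC analysis with Youden-optimal threshold
#'
#' AUC by the trapezoid rule (identical to the normalized Mann-Whitney U
#' statistic with half-counted ties). Candidate thresholds are midpoints
#' between consecutive distinct scores ("score >= threshold" predicts
#' positive); the threshold maximizing Youden's J = sensitivity +
#' specificity - 1 is chosen, ties broken toward the higher (more specific)
#' threshold.
#'
#' @param scores numeric predictor (higher = more positive).
#' @param labels binary outcome.
#' @return object of class `roc_result`: `auc`, `threshold`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `youden_j`, plus the full `curve`.
#' @export
roc_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present")
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  s <- sort(unique(scores))
  thr <- if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2 else s
  ev <- vapply(thr, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels) / n1
    spec <- sum(!pred & !labels) / n0
    c(sens, spec)
  }, numeric(2))
  j <- ev[1, ] + ev[2, ] - 1
  best <- max(which(j == max(j)))   # tie toward higher threshold
  t0 <- thr[best]
  pred <- scores >= t0
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  sens <- tp / n1; spec <- tn / n0
  structure(list(auc = auc, threshold = t0,
                 sensitivity = sens, specificity = spec,
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 youden_j = sens + spec - 1,
                 curve = data.frame(threshold = thr,
                                    sensitivity = ev[1, ],
                                    specificity = ev[2, ])),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f; Youden threshold %.3f (sens %.0f%%, spec %.0f%%, PPV %.0f%%, NPV %.0f%%)\n",
              x$auc, x$threshold, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$ppv, 100 * x$npv))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  o <- order(1 - x$curve$specificity, x$curve$sensitivity)
  plot(c(0, 1 - x$curve$specificity[o], 1), c(0, x$curve$sensitivity[o], 1),
       type = "l", xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Non-parametric percentile bootstrap at the subject level
#'
#' Resamples whole rows (shoulders) with replacement, applies `statistic`
#' (a function returning a named numeric vector) to each resample, and
#' reports the bootstrap median and percentile confidence interval per
#' quantity. Degenerate resamples (errors, e.g. one-class outcomes) are
#' skipped and counted.
#'
#' @param data data frame of per-shoulder rows.
#' @param statistic function(data) -> named numeric vector.
#' @param B resamples (default 1000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return data frame (one row per quantity): `median`, `ci_low`, `ci_high`;
#'   attribute `n_degenerate`.
#' @export
bootstrap_validate <- function(data, statistic, B = 1000L, seed = 1L,
                               conf = 0.95) {
  if (nrow(data) < 10L) stop("need >= 10 rows for bootstrap validation")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- nrow(data)
  draws <- list(); bad <- 0L
  for (i in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(statistic(data[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(v) || anyNA(v)) bad <- bad + 1L else draws[[length(draws) + 1L]] <- v
  }
  if (!length(draws)) stop("all bootstrap resamples were degenerate")
  M <- do.call(rbind, draws)
  a <- (1 - conf) / 2
  out <- data.frame(
    quantity = colnames(M),
    median = apply(M, 2L, stats::median),
    ci_low = apply(M, 2L, stats::quantile, probs = a, names = FALSE),
    ci_high = apply(M, 2L, stats::quantile, probs = 1 - a, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_degenerate") <- bad
  if (bad > 0.1 * B)
    warning(sprintf("%d of %d bootstrap resamples were degenerate", bad, B))
  out
}

#' Cohen's kappa for two raters
#'
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with expected agreement from the
#' marginal products. When both raters are constant and identical
#' (\eqn{p_e = 1}), kappa is defined as 1 by convention and flagged.
#'
#' @param r1,r2 outcome vectors of equal length (>= 2).
#' @return kappa (numeric scalar) with attributes `p_o` and `p_e`.
#' @export
cohens_kappa <- function(r1, r2) {
  if (length(r1) != length(r2) || length(r1) < 2L)
    stop("raters must have equal length >= 2")
  lev <- sort(unique(c(r1, r2)))
  t1 <- table(factor(r1, lev)) / length(r1)
  t2 <- table(factor(r2, lev)) / length(r2)
  p_o <- mean(r1 == r2)
  p_e <- sum(t1 * t2)
  k <- if (1 - p_e < 1e-12) {
    warning("both raters constant and identical: kappa = 1 by convention")
    1.0
  } else (p_o - p_e) / (1 - p_e)
  structure(k, p_o = p_o, p_e = p_e)
}

#' Two-way mixed intraclass correlation coefficient (single measures)
#'
#' ICC from the two-way ANOVA mean squares of a subjects x raters matrix:
#' consistency ICC(3,1) = (MSR - MSE) / (MSR + (k-1) MSE), or absolute
#' agreement ICC(2,1) including the rater variance. F-based confidence
#' interval (exact for consistency; Satterthwaite approximation for
#' agreement).
#'
#' @param M numeric matrix, subjects in rows, raters in columns, no missing
#'   cells.
#' @param form "consistency" (default, ICC(3,1)) or "agreement" (ICC(2,1)).
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `form`, mean squares.
#' @export
icc_two_way <- function(M, form = c("consistency", "agreement"),
                        conf = 0.95) {
  form <- match.arg(form)
  M <- as.matrix(M)
  n <- nrow(M); k <- ncol(M)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters")
  if (anyNA(M)) stop("missing cells are not supported")
  long <- data.frame(y = as.vector(M),
                     subj = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  # only the mean squares are used; anova's F-test warning on zero-residual
  # fits does not apply
  ms <- suppressWarnings(
    stats::anova(stats::aov(y ~ subj + rater, data = long))[, "Mean Sq"])
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  if (stats::var(rowMeans(M)) < 1e-12) {
    warning("zero between-subject variance: ICC defined as 0")
    return(list(icc = 0, ci_low = NA_real_, ci_high = NA_real_,
                form = form, MSR = MSR, MSC = MSC, MSE = MSE))
  }
  a <- (1 - conf) / 2
  if (form == "consistency") {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fo <- MSR / MSE
    FL <- Fo / stats::qf(1 - a, n - 1, (n - 1) * (k - 1))
    FU <- Fo * stats::qf(1 - a, (n - 1) * (k - 1), n - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  } else {
    icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    aa <- k * icc / (n * (1 - icc))
    bb <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (aa * MSC + bb * MSE)^2 /
      ((aa * MSC)^2 / (k - 1) + (bb * MSE)^2 / ((n - 1) * (k - 1)))
    FU <- stats::qf(1 - a, n - 1, v)
    FL <- stats::qf(1 - a, v, n - 1)
    lo <- n * (MSR - FU * MSE) /
      (FU * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FL * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FL * MSR)
  }
  list(icc = unname(icc), ci_low = unname(lo), ci_high = unname(hi),
       form = form, MSR = unname(MSR), MSC = unname(MSC), MSE = unname(MSE))
}

#' Spearman correlation and Mann-Whitney U test
#'
#' Convenience wrapper for the two rank procedures of the cohort analysis:
#' Spearman's rho between `x` and `y` (t-approximation p), and the
#' Mann-Whitney U comparison of `x` across two `groups` (normal
#' approximation with tie correction).
#'
#' @param x numeric vector.
#' @param y optional numeric vector for the correlation.
#' @param groups optional two-level factor for the group comparison.
#' @return list with elements `spearman` (`rho`, `p`) and/or `mannwhitney`
#'   (`U`, `p`).
#' @export
rank_tests <- function(x, y = NULL, groups = NULL) {
  out <- list()
  if (!is.null(y)) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("constant input: Spearman correlation undefined")
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    out$spearman <- list(rho = unname(ct$estimate), p = ct$p.value)
  }
  if (!is.null(groups)) {
    g <- factor(groups)
    if (nlevels(g) != 2L) stop("groups must have exactly two levels")
    wt <- suppressWarnings(
      stats::wilcox.test(x[g == levels(g)[1]], x[g == levels(g)[2]],
                         exact = FALSE, correct = TRUE))
    out$mannwhitney <- list(U = unname(wt$statistic), p = wt$p.value)
  }
  out
}

#' A-priori sample size for the paired McNemar test (Connor's method)
#'
#' Utility for planning: number of pairs needed to detect a difference in
#' discordant probabilities `p10` vs `p01` with the unconditional normal
#' approximation. The result depends entirely on the assumed discordance
#' structure, which should be stated alongside any use.
#'
#' @param p10,p01 assumed discordant-pair probabilities.
#' @param alpha two-sided type-I error (default 0.05).
#' @param power target power (default 0.80).
#' @return required number of pairs (integer, rounded up).
#' @export
mcnemar_sample_size <- function(p10, p01, alpha = 0.05, power = 0.80) {
  if (p10 == p01) stop("p10 and p01 must differ")
  pd <- p10 + p01
  delta <- p10 - p01
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  ceiling((za * sqrt(pd) + zb * sqrt(pd - delta^2))^2 / delta^2)
}
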