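#' Bland-Altman agreement between two paired measurement series
#'
#' Differences are `d = a - b` (first series minus second; the sign
#' convention is carried in the output). Limits of agreement are
#' `mean(d) +/- k * sd(d)`. Confidence intervals use t quantiles with
#' `n - 1` degrees of freedom: standard error `sd/sqrt(n)` for the mean
#' difference and the classical approximation `sd * sqrt(3/n)` for each
#' limit of agreement.
#'
#' @param a,b numeric vectors of equal length `>= 3` (micrometres in the
#'   intended use), aligned by case.
#' @param k limit multiplier (1.96 for 95% limits).
#' @param conf confidence level of the intervals.
#' @param labels length-2 character: names of the two series.
#' @return An object of class `bland_altman`: list with `n`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `ci_mean`, `ci_loa_low`,
#'   `ci_loa_high`, `k`, `labels`, and the per-case `means`/`diffs`.
#' @export
bland_altman <- function(a, b, k = 1.96, conf = 0.95,
                         labels = c("a", "b")) {
  if (length(a) != length(b)) stop("series lengths differ")
  keep <- complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L) stop("need at least 3 complete pairs")
  d <- a - b
  m <- mean(d); s <- sd(d)
  if (s == 0) warning("zero variance of differences; intervals are degenerate")
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  se_mean <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  structure(list(n = n, mean_diff = m, sd_diff = s,
                 loa_low = m - k * s, loa_high = m + k * s,
                 ci_mean = c(m - tq * se_mean, m + tq * se_mean),
                 ci_loa_low = c(m - k * s - tq * se_loa, m - k * s + tq * se_loa),
                 ci_loa_high = c(m + k * s - tq * se_loa, m + k * s + tq * se_loa),
                 k = k, conf = conf, labels = labels,
                 means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement, d = %s - %s (n = %d)\n",
              x$labels[1], x$labels[2], x$n))
  cat(sprintf("  mean difference %8.2f  (%.0f%% CI %7.2f, %7.2f)\n",
              x$mean_diff, 100 * x$conf, x$ci_mean[1], x$ci_mean[2]))
  cat(sprintf("  limits of agreement %.2f (%.2f, %.2f) to %.2f (%.2f, %.2f)\n",
              x$loa_low, x$ci_loa_low[1], x$ci_loa_low[2],
              x$loa_high, x$ci_loa_high[1], x$ci_loa_high[2]))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "mean of methods",
                              ylab = "difference", main = NULL, ...) {
  plot(x$means, x$diffs, xlab = xlab, ylab = ylab,
       main = main %||% sprintf("Bland-Altman: %s - %s",
                                x$labels[1], x$labels[2]),
       ylim = range(c(x$diffs, x$ci_loa_low, x$ci_loa_high)), ...)
  usr <- par("usr")
  polygon(c(usr[1], usr[2], usr[2], usr[1]),
          rep(x$ci_mean, each = 2)[c(1, 1, 2, 2)],
          col = gray(0.85), border = NA)
  points(x$means, x$diffs)
  abline(h = x$mean_diff, lwd = 2)
  abline(h = c(x$loa_low, x$loa_high), lty = 2)
  abline(h = c(x$ci_loa_low, x$ci_loa_high), lty = 3, col = gray(0.4))
  invisible(x)
}

#' Spearman rank correlation between two continuous series
#'
#' Mid-rank handling of ties, two-sided p value (asymptotic t
#' approximation, appropriate in the presence of ties).
#'
#' @param x,y numeric vectors of equal length `>= 4`.
#' @return list with `rho` and `p`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("constant series: rank correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Shapiro-Wilk normality test
#'
#' @param x numeric vector, `3 <= n <= 5000`, non-constant.
#' @return list with `W` and `p`.
#' @export
normality_test <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(x) == 0) stop("constant series: normality test undefined")
  st <- shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Quadratic-versus-linear model comparison
#'
#' Least-squares fits of `y ~ x` and `y ~ x + x^2`; the p value of the
#' quadratic improvement comes from the nested-model F test (equivalent
#' to the t test on the squared term).
#'
#' @param x,y numeric vectors of equal length `>= 4`.
#' @return list with `linear` and `quadratic` (`lm` fits),
#'   `p_quadratic_term`, and the two residual sums of squares.
#' @export
quad_vs_linear <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  if (length(unique(x)) < 3L)
    stop("degenerate design: need at least 3 distinct x values")
  fit1 <- lm(y ~ x)
  fit2 <- lm(y ~ x + I(x^2))
  a <- anova(fit1, fit2)
  list(linear = fit1, quadratic = fit2,
       p_quadratic_term = a$`Pr(>F)`[2],
       rss_linear = sum(residuals(fit1)^2),
       rss_quadratic = sum(residuals(fit2)^2))
}

#' Size-class cross-tabulation and marginal homogeneity
#'
#' Cross-tabulates two IVTS classifications of the same eyes, counts the
#' reclassified cases (off-diagonal) and tests marginal homogeneity with
#' the Stuart-Maxwell test (chi-squared with `K - 1` degrees of freedom;
#' identical classifications give p = 1 by convention).
#'
#' @param class_a,class_b vectors of classes (character or factor),
#'   aligned by case; coerced to the ordered levels small/medium/large
#'   when they only contain those values.
#' @return list with `table` (KxK), `n_reclassified`, `statistic`, `df`,
#'   `p`, and `test = "stuart-maxwell"`.
#' @export
size_crosstab <- function(class_a, class_b) {
  if (length(class_a) != length(class_b)) stop("series lengths differ")
  ivts <- c("small", "medium", "large")
  lv <- if (all(c(class_a, class_b) %in% ivts)) ivts
        else sort(unique(c(as.character(class_a), as.character(class_b))))
  fa <- factor(class_a, levels = lv)
  fb <- factor(class_b, levels = lv)
  tab <- table(fa, fb, dnn = c("a", "b"))
  n_re <- sum(tab) - sum(diag(tab))
  sm <- stuart_maxwell(unclass(tab))
  list(table = tab, n_reclassified = as.integer(n_re),
       statistic = sm$statistic, df = sm$df, p = sm$p,
       test = "stuart-maxwell")
}

# Stuart-Maxwell marginal homogeneity statistic for a KxK table
stuart_maxwell <- function(N) {
  K <- nrow(N)
  d <- rowSums(N) - colSums(N)
  if (all(d == 0) && all(N[upper.tri(N)] == 0) && all(N[lower.tri(N)] == 0))
    return(list(statistic = 0, df = K - 1L, p = 1))
  S <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    S[i, j] <- if (i == j) sum(N[i, ]) + sum(N[, i]) - 2 * N[i, i]
               else -(N[i, j] + N[j, i])
  }
  # drop one category (covariance of d is singular: sum(d) = 0)
  keep <- seq_len(K - 1L)
  Ssub <- S[keep, keep, drop = FALSE]
  dsub <- d[keep]
  qrS <- qr(Ssub)
  if (qrS$rank < K - 1L) {
    # degenerate sub-covariance: use the Moore-Penrose inverse of S
    e <- eigen(S, symmetric = TRUE)
    pos <- e$values > 1e-10 * max(e$values)
    Sinv <- e$vectors[, pos, drop = FALSE] %*%
      diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
    stat <- as.numeric(t(d) %*% Sinv %*% d)
    df <- sum(pos)
  } else {
    stat <- as.numeric(t(dsub) %*% solve(Ssub, dsub))
    df <- K - 1L
  }
  list(statistic = stat, df = as.integer(df),
       p = pchisq(stat, df = df, lower.tail = FALSE))
}
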