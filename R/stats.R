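## Normality battery and normality-gated group comparison.
##
## The four normality tests mirror the battery of the commercial software the
## workflow was built around: D'Agostino-Pearson K2, Anderson-Darling,
## Shapiro-Wilk, and Kolmogorov-Smirnov. The K-S member is the Lilliefors
## variant (null parameters estimated from the sample) — a plain K-S against
## a fully specified normal is invalid when mean and sd are estimated, so the
## corrected test stands in deliberately.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed-skewness and transformed-kurtosis statistics
#' (D'Agostino 1970; Anscombe-Glynn 1983) into K2 = Zs^2 + Zk^2, referred to
#' a chi-squared distribution with 2 degrees of freedom.
#'
#' @param x numeric sample, n >= 8.
#' @return list with `statistic` (K2) and `p.value`.
#' @export
dagostino_pearson_test <- function(x) {
  n <- length(x)
  if (n < 8) stop("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 == 0) stop("zero variance sample")
  b1 <- m3 / m2^1.5
  # skewness transform
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- delta * asinh(y / alpha)
  # kurtosis transform
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zs^2 + Zk^2
  list(statistic = K2, p.value = pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Anderson-Darling normality test
#'
#' A2 statistic with estimated mean/sd and the Stephens small-sample
#' correction; p-values from the standard case-3 approximation.
#'
#' @param x numeric sample, n >= 8.
#' @return list with `statistic` (A2, uncorrected) and `p.value`.
#' @export
anderson_darling_test <- function(x) {
  n <- length(x)
  if (n < 8) stop("Anderson-Darling test requires n >= 8")
  s <- sd(x)
  if (s == 0) stop("zero variance sample")
  z <- pnorm((sort(x) - mean(x)) / s)
  # clamp to keep logs finite for extreme observations
  z <- pmin(pmax(z, .Machine$double.xmin), 1 - .Machine$double.eps)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(z) + log(1 - rev(z))))
  AA <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (AA < 0.2) {
    1 - exp(-13.436 + 101.14 * AA - 223.73 * AA^2)
  } else if (AA < 0.34) {
    1 - exp(-8.318 + 42.796 * AA - 59.938 * AA^2)
  } else if (AA < 0.6) {
    exp(0.9177 - 4.279 * AA - 1.38 * AA^2)
  } else if (AA < 10) {
    exp(1.2937 - 5.709 * AA + 0.0186 * AA^2)
  } else 3.7e-24
  list(statistic = A2, p.value = min(max(p, 0), 1))
}

#' Lilliefors (Kolmogorov-Smirnov) normality test
#'
#' K-S distance between the empirical distribution and a normal with mean
#' and sd estimated from the sample; p-value by the Dallal-Wilkinson (1986)
#' approximation, switching to the Stephens polynomial in the upper tail as
#' in the standard implementations.
#'
#' @param x numeric sample, n >= 4.
#' @return list with `statistic` (D) and `p.value`.
#' @export
lilliefors_test <- function(x) {
  n <- length(x)
  if (n < 4) stop("Lilliefors test requires n >= 4")
  s <- sd(x)
  if (s == 0) stop("zero variance sample")
  z <- pnorm((sort(x) - mean(x)) / s)
  i <- seq_len(n)
  D <- max(pmax(i / n - z, z - (i - 1) / n))
  if (n > 100) { Kd <- D * (n / 100)^0.49; nd <- 100 } else { Kd <- D; nd <- n }
  p <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
             2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
             0.974598 / sqrt(nd) + 1.67997 / nd)
  if (p > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    p <- if (KK <= 0.302) 1
    else if (KK <= 0.5) 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
      138.55152 * KK^3 + 81.218052 * KK^4
    else if (KK <= 0.9) -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
      94.029866 * KK^3 - 32.355711 * KK^4
    else if (KK <= 1.31) 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
      12.234627 * KK^3 + 2.423045 * KK^4
    else 0
  }
  list(statistic = D, p.value = min(max(p, 0), 1))
}

# Shapiro-Wilk; stats::shapiro.test caps n at 5000, so larger samples are
# thinned deterministically (every k-th value in original order), which
# preserves the distribution and keeps the verdict reproducible.
shapiro_wilk_test <- function(x) {
  n <- length(x)
  if (n < 8) stop("Shapiro-Wilk test requires n >= 8")
  if (sd(x) == 0) stop("zero variance sample")
  if (n > 5000) x <- x[seq(1L, n, length.out = 5000L)]
  r <- shapiro.test(x)
  list(statistic = unname(r$statistic), p.value = r$p.value)
}

#' Four-test normality battery
#'
#' Runs D'Agostino-Pearson, Anderson-Darling, Shapiro-Wilk and Lilliefors
#' Kolmogorov-Smirnov on one sample and combines the verdicts. Under the
#' default `"all"` rule the sample counts as Gaussian only when every test
#' has p > alpha — conservative in the direction of non-parametric tests.
#'
#' @param x numeric sample.
#' @param alpha significance level of the battery (default 0.05).
#' @param rule combination rule: `"all"` (default), `"majority"`, or `"any"`
#'   of the four tests must retain normality.
#' @return object of class `normality_verdict`: list with `per_test_p`
#'   (named: `dagostino_pearson`, `anderson_darling`, `shapiro_wilk`,
#'   `kolmogorov_smirnov`), `gaussian`, `n`, `alpha`, `rule`.
#' @export
assess_normality <- function(x, alpha = 0.05,
                             rule = c("all", "majority", "any")) {
  rule <- match.arg(rule)
  n <- length(x)
  if (n < 4) stop("sample-size error: normality assessment requires n >= 4")
  p <- c(dagostino_pearson = NA_real_, anderson_darling = NA_real_,
         shapiro_wilk = NA_real_, kolmogorov_smirnov = NA_real_)
  if (sd(x) == 0) {
    warning("degenerate sample with zero variance; verdict: not Gaussian")
    gaussian <- FALSE
  } else if (n < 8) {
    warning("n < 8: the full battery is undefined; verdict: not Gaussian")
    p["kolmogorov_smirnov"] <- lilliefors_test(x)$p.value
    gaussian <- FALSE
  } else {
    p["dagostino_pearson"] <- dagostino_pearson_test(x)$p.value
    p["anderson_darling"] <- anderson_darling_test(x)$p.value
    p["shapiro_wilk"] <- shapiro_wilk_test(x)$p.value
    p["kolmogorov_smirnov"] <- lilliefors_test(x)$p.value
    retained <- p > alpha
    gaussian <- switch(rule,
                       all = all(retained),
                       majority = sum(retained) >= 3L,
                       any = any(retained))
  }
  structure(list(per_test_p = p, gaussian = gaussian, n = n, alpha = alpha,
                 rule = rule),
            class = "normality_verdict")
}

#' Star grade of a p-value
#'
#' `*`: p <= 0.05, `**`: p <= 0.01, `***`: p <= 0.001, `****`: p <= 0.0001,
#' `ns` otherwise (thresholds inclusive).
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return character vector of grades.
#' @export
grade_stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("domain error: p-values must lie in [0, 1]")
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] <= 1e-4, "****",
             ifelse(p[ok] <= 1e-3, "***",
             ifelse(p[ok] <= 1e-2, "**",
             ifelse(p[ok] <= 0.05, "*", "ns"))))
  out
}

#' Holm-Sidak step-down adjustment
#'
#' Adjusted p-values `1 - (1 - p_(i))^(m - i + 1)` over the ascending raw
#' p-values, made monotone by a running maximum; never smaller than raw.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
holm_sidak_adjust <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pairwise t comparisons after one-way ANOVA, using the pooled within-group
# variance (ANOVA mean-square error) with N - k degrees of freedom, then
# Holm-Sidak adjusted — the multiple-comparison style paired with ordinary
# one-way ANOVA in the source workflow's software.
anova_holm_sidak <- function(values, groups, pairs, alternative) {
  k <- length(unique(groups))
  N <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  sse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  mse <- sse / (N - k)
  res <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2] # alternative: mean(a) > mean(b) when "greater"
    se <- sqrt(mse * (1 / gn[[a]] + 1 / gn[[b]]))
    tstat <- (gm[[a]] - gm[[b]]) / se
    p <- switch(alternative,
                greater = stats::pt(tstat, df = N - k, lower.tail = FALSE),
                two.sided = 2 * stats::pt(abs(tstat), df = N - k,
                                          lower.tail = FALSE))
    data.frame(group1 = a, group2 = b, statistic = tstat, p_raw = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Dunn's rank-based pairwise comparisons after Kruskal-Wallis, with tie
# correction; provided as an extension (the source workflow names no
# follow-up for the non-parametric branch).
dunn_pairwise <- function(values, groups, pairs, alternative) {
  N <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, groups, mean)
  gn <- tapply(values, groups, length)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  res <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / gn[[a]] + 1 / gn[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    p <- switch(alternative,
                greater = pnorm(z, lower.tail = FALSE),
                two.sided = 2 * pnorm(abs(z), lower.tail = FALSE))
    data.frame(group1 = a, group2 = b, statistic = z, p_raw = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Normality-gated group comparison
#'
#' Implements the test-selection rule of the workflow: every group is run
#' through the four-test normality battery; with two groups, Gaussian data
#' get a one-tailed Student's t-test (no correction) and non-Gaussian data a
#' one-tailed Mann-Whitney U test; with three or more groups, Gaussian data
#' get ordinary one-way ANOVA with Holm-Sidak pairwise comparisons and
#' non-Gaussian data a Kruskal-Wallis test (with Dunn pairwise follow-up as
#' a labeled extension). One group failing the battery sends the whole
#' comparison to the non-parametric branch.
#'
#' When a control group is named, each comparison tests the one-directional
#' hypothesis treated > control; without a control the tests are two-sided
#' (with a warning), since no direction is defined.
#'
#' @param groups named list of numeric vectors, one per condition.
#' @param control name of the control group, or `NULL`.
#' @param alpha significance level (default 0.05, also used by the
#'   normality battery).
#' @param rule normality combination rule, see [assess_normality].
#' @return object of class `group_comparison`: list with `chosen_test` (one
#'   of `"t_one_tailed"`, `"mann_whitney_one_tailed"`, `"anova_holm_sidak"`,
#'   `"kruskal_wallis"`), `normality` (list of `normality_verdict`s),
#'   `overall_p` (ANOVA/Kruskal-Wallis omnibus p, `NA` for two groups),
#'   `comparisons` (data.frame: `group1`, `group2`, `n1`, `n2`, `p_raw`,
#'   `p_adj`, `stars`), `alpha`, `tail`.
#' @export
select_and_run <- function(groups, control = NULL, alpha = 0.05,
                           rule = c("all", "majority", "any")) {
  rule <- match.arg(rule)
  if (!is.list(groups) || length(groups) < 2L)
    stop("comparison error: at least two groups are required")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named by condition")
  if (any(vapply(groups, length, 1L) == 0L))
    stop("comparison error: empty group")
  if (!is.null(control) && !(control %in% names(groups)))
    stop("control group '", control, "' not among the groups")
  # canonical group order: control first, others alphabetically — makes the
  # outcome invariant under permutations of the input list
  nms <- sort(names(groups))
  if (!is.null(control)) nms <- c(control, setdiff(nms, control))
  groups <- groups[nms]

  normality <- lapply(groups, assess_normality, alpha = alpha, rule = rule)
  gaussian <- all(vapply(normality, function(v) v$gaussian, TRUE))
  two <- length(groups) == 2L

  if (is.null(control)) {
    warning("no control group designated; two-sided tests applied")
    alternative <- "two.sided"
    tail <- "two_sided"
  } else {
    alternative <- "greater" # treated > control
    tail <- "greater_than_control"
  }

  # comparisons: each non-control group vs the control (or, without a
  # control, all pairs)
  others <- if (is.null(control)) nms else setdiff(nms, control)
  pairs <- if (is.null(control)) {
    cmb <- utils::combn(nms, 2L)
    lapply(seq_len(ncol(cmb)), function(i) c(cmb[2L, i], cmb[1L, i]))
  } else {
    lapply(others, function(g) c(g, control))
  }

  overall_p <- NA_real_
  if (two) {
    a <- pairs[[1L]][1L]; b <- pairs[[1L]][2L]
    if (gaussian) {
      chosen <- "t_one_tailed"
      r <- t.test(groups[[a]], groups[[b]], alternative = alternative,
                  var.equal = TRUE)
    } else {
      chosen <- "mann_whitney_one_tailed"
      if (length(unique(c(groups[[a]], groups[[b]]))) == 1L)
        warning("rank-test warning: fully tied degenerate samples")
      r <- suppressWarnings(
        wilcox.test(groups[[a]], groups[[b]], alternative = alternative,
                    exact = FALSE))
    }
    cmp <- data.frame(group1 = a, group2 = b, p_raw = r$p.value,
                      p_adj = r$p.value, stringsAsFactors = FALSE)
  } else {
    values <- unlist(groups, use.names = FALSE)
    glab <- factor(rep(names(groups), lengths(groups)), levels = nms)
    if (gaussian) {
      chosen <- "anova_holm_sidak"
      fit <- aov(values ~ glab)
      overall_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
      cmp <- anova_holm_sidak(values, glab, pairs, alternative)
      cmp$p_adj <- holm_sidak_adjust(cmp$p_raw)
    } else {
      chosen <- "kruskal_wallis"
      overall_p <- kruskal.test(values, glab)$p.value
      cmp <- dunn_pairwise(values, glab, pairs, alternative)
      cmp$p_adj <- holm_sidak_adjust(cmp$p_raw)
    }
    cmp <- cmp[, c("group1", "group2", "p_raw", "p_adj")]
  }
  cmp$n1 <- lengths(groups)[cmp$group1]
  cmp$n2 <- lengths(groups)[cmp$group2]
  cmp$stars <- grade_stars(cmp$p_adj)
  cmp <- cmp[, c("group1", "group2", "n1", "n2", "p_raw", "p_adj", "stars")]
  rownames(cmp) <- NULL
  structure(list(chosen_test = chosen, normality = normality,
                 overall_p = overall_p, comparisons = cmp, alpha = alpha,
                 tail = tail),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: %s (tail: %s)>\n", x$chosen_test, x$tail))
  if (!is.na(x$overall_p))
    cat(sprintf("  omnibus p = %.4g\n", x$overall_p))
  print(x$comparisons)
  invisible(x)
}
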