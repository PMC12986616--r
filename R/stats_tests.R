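#' Two-way ANOVA with classical eta-squared
#'
#' Factorial analysis of a binned endpoint (e.g. genotype x diet, or diet x
#' PTD bin). Type III sums of squares are used so unbalanced designs (an
#' unavoidable consequence of mortality) are handled; effect size is
#' classical eta-squared, SS_effect / SS_total.
#'
#' @param data Data frame.
#' @param value,factor_a,factor_b Column names (strings).
#' @return Data frame with one row per effect (A, B, A:B, residual): `ss`,
#'   `df`, `F`, `p`, `eta_sq`.
#' @export
two_way_anova <- function(data, value = "value", factor_a = "factor_a",
                          factor_b = "factor_b") {
  stopifnot(all(c(value, factor_a, factor_b) %in% names(data)))
  d <- data.frame(
    y = data[[value]],
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2) {
    stop_domain("two_way_anova: each factor needs at least 2 levels")
  }
  fit <- lm(y ~ A * B, data = d,
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  rows <- c("A", "B", "A:B", "Residuals")
  a3 <- a3[rows, ]
  ss_total <- sum((d$y - mean(d$y))^2)
  out <- data.frame(
    effect = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "residual"),
    ss = a3[["Sum Sq"]],
    df = a3[["Df"]],
    F = a3[["F value"]],
    p = a3[["Pr(>F)"]],
    eta_sq = a3[["Sum Sq"]] / ss_total
  )
  rownames(out) <- NULL
  out
}

#' Sidak multiple-comparison adjustment
#'
#' Adjusted p = 1 - (1 - p)^m for m comparisons in the family, clipped to
#' \[0, 1\]; monotone in both arguments.
#'
#' @param p Unadjusted p-value(s).
#' @param m Number of comparisons in the family.
#' @return Adjusted p-value(s).
#' @examples
#' sidak_adjust(0.01, 3) # 0.029701
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' Welch's unpaired two-tailed t test
#'
#' @param x,y Numeric samples (>= 2 values each).
#' @return List: `t`, `df` (Welch-Satterthwaite), `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop_domain("welch_t: each sample needs >= 2 values")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop_domain("welch_t: zero variance in both samples with unequal means")
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' No continuity correction (matching the susceptibility analysis).
#'
#' @param table Integer matrix, 2 rows.
#' @return List: `chisq`, `df`, `p`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2) stop_domain("chi_square: expected a 2 x k table")
  if (any(table < 0) || any(table != floor(table))) {
    stop_domain("chi_square: counts must be nonnegative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_domain("chi_square: zero marginal")
  }
  ht <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chisq = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H, then Dunn's pairwise z statistics from the
#' pooled ranks with the same tie correction; pairwise p-values are
#' multiplicity-adjusted (Sidak by default, over all k(k-1)/2 pairs).
#'
#' @param groups Named list of numeric vectors.
#' @param adjust `"sidak"` or `"bonferroni"`.
#' @return List: `H`, `df`, `p`, and `pairs` data frame (`group1`, `group2`,
#'   `z`, `p_unadj`, `p_adj`).
#' @export
kruskal_dunn <- function(groups, adjust = c("sidak", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 2) stop_domain("kruskal_dunn: need >= 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(names(groups), 2)
  m <- ncol(combs)
  pairs <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                      z = NA_real_, p_unadj = NA_real_, p_adj = NA_real_)
  for (i in seq_len(m)) {
    g1 <- combs[1, i]; g2 <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[g1]] + 1 / n[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    p_un <- 2 * pnorm(-abs(z))
    pairs$z[i] <- z
    pairs$p_unadj[i] <- p_un
    pairs$p_adj[i] <- if (adjust == "sidak") sidak_adjust(p_un, m) else min(1, p_un * m)
  }
  list(H = unname(kw$statistic), df = unname(kw$parameter), p = kw$p.value,
       pairs = pairs)
}

#' Normality-gated group comparison
#'
#' Screens each group with Shapiro-Wilk; when every group is consistent with
#' normality (all p > alpha) the parametric route is used (Welch t for two
#' groups), otherwise the rank-based battery (Kruskal-Wallis with Dunn's post
#' hoc).
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Screening level (default 0.05).
#' @return List with `route` ("parametric" or "nonparametric") and `result`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  stopifnot(length(groups) >= 2)
  normal <- all(vapply(groups, function(g) {
    if (length(g) < 3 || var(g) == 0) return(FALSE)
    shapiro.test(g)$p.value > alpha
  }, logical(1)))
  if (normal && length(groups) == 2) {
    list(route = "parametric", result = welch_t(groups[[1]], groups[[2]]))
  } else {
    list(route = "nonparametric", result = kruskal_dunn(groups))
  }
}
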