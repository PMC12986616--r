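test_that("two-way ANOVA reproduces the hand SS decomposition when balanced", {
  set.seed(2)
  d <- expand.grid(factor_a = c("WT", "KO"), factor_b = c("SD", "KD"),
                   rep = 1:6)
  d$value <- rnorm(nrow(d)) +
    2 * (d$factor_a == "KO") + 1.5 * (d$factor_b == "KD") +
    1 * (d$factor_a == "KO" & d$factor_b == "KD")
  res <- two_way_anova(d)
  o <- oracle_anova_ss(d$value, d$factor_a, d$factor_b)
  expect_equal(res$ss[1], o$A, tolerance = 1e-9)
  expect_equal(res$ss[2], o$B, tolerance = 1e-9)
  expect_equal(res$ss[3], o$AB, tolerance = 1e-9)
  expect_equal(res$ss[4], o$resid, tolerance = 1e-9)
  # SS partition and eta-squared accounting
  expect_equal(sum(res$ss), o$total, tolerance = 1e-9)
  expect_equal(sum(res$eta_sq), 1, tolerance = 1e-9)
  expect_true(all(res$eta_sq >= 0 & res$eta_sq <= 1))
})

test_that("null and degenerate ANOVA designs behave correctly", {
  set.seed(5)
  d <- expand.grid(factor_a = c("a", "b"), factor_b = c("x", "y"), rep = 1:10)
  d$value <- rnorm(nrow(d)) # no effects
  res <- two_way_anova(d)
  expect_true(all(res$eta_sq[1:3] < 0.15))
  one_level <- d[d$factor_a == "a", ]
  expect_error(two_way_anova(one_level), "2 levels")
  # unbalanced designs are accepted (Type III)
  unb <- d[-(1:7), ]
  expect_silent(two_way_anova(unb))
})

test_that("Sidak adjustment follows 1 - (1 - p)^m", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3) # 0.029701
  expect_equal(sidak_adjust(1, 7), 1)
  expect_equal(sidak_adjust(0, 5), 0)
  # monotone in p and in m
  p <- seq(0, 1, by = 0.1)
  expect_true(all(diff(sidak_adjust(p, 4)) >= 0))
  expect_true(all(sidak_adjust(0.2, 1:6) == cummax(sidak_adjust(0.2, 1:6))))
})

test_that("Welch's t matches the hand formula", {
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7, 23.2, 17.5, 20.6, 18.0, 23.9, 21.6, 24.3, 20.4, 24.0, 13.2)
  res <- welch_t(x, y)
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                     (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-9)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  # antisymmetry and identical-sample null
  expect_equal(welch_t(y, x)$t, -res$t, tolerance = 1e-12)
  same <- welch_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(1, c(2, 3)), ">= 2 values")
})

test_that("chi-square on contingency tables matches hand computation", {
  prop <- matrix(c(10, 20, 5, 10), nrow = 2) # proportional rows
  expect_equal(chi_square(prop)$chisq, 0, tolerance = 1e-12)
  diag2 <- matrix(c(10, 0, 0, 10), nrow = 2)
  res <- chi_square(diag2)
  expect_equal(res$chisq, 20, tolerance = 1e-12)
  expect_identical(res$df, 1L)
  # invariant to row swap
  expect_equal(chi_square(diag2[2:1, ])$chisq, res$chisq, tolerance = 1e-12)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), nrow = 2)), "marginal")
  expect_error(chi_square(matrix(1:6, nrow = 3)), "2 x k")
})

test_that("Kruskal-Wallis with Dunn post hoc matches hand ranks", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  res <- kruskal_dunn(g)
  # H with no ties: 12/(N(N+1)) * sum n_i rbar_i^2 - 3(N+1)
  rbar <- c(2, 5, 8)
  H_hand <- 12 / (9 * 10) * sum(3 * rbar^2) - 3 * 10
  expect_equal(res$H, H_hand, tolerance = 1e-9)
  expect_identical(nrow(res$pairs), 3L)
  # hand Dunn z for pair (a, b)
  z_hand <- (2 - 5) / sqrt((9 * 10 / 12) * (1/3 + 1/3))
  expect_equal(res$pairs$z[1], z_hand, tolerance = 1e-9)
  expect_equal(res$pairs$p_adj[1], sidak_adjust(2 * pnorm(-abs(z_hand)), 3),
               tolerance = 1e-12)
  # identical groups: H ~ 0
  same <- kruskal_dunn(list(x = c(1, 2, 3), y = c(1, 2, 3)))
  expect_lt(same$H, 1e-9)
  # invariant under strictly monotone transforms
  res2 <- kruskal_dunn(lapply(g, exp))
  expect_equal(res2$H, res$H, tolerance = 1e-12)
  # tie correction agrees with kruskal.test
  tied <- list(a = c(1, 1, 2), b = c(2, 3, 3), c = c(1, 3, 4))
  expect_equal(kruskal_dunn(tied)$H,
               unname(kruskal.test(tied)$statistic), tolerance = 1e-12)
})

test_that("the normality gate routes to the rank battery when violated", {
  set.seed(9)
  gauss <- list(a = rnorm(30), b = rnorm(30))
  expect_identical(compare_groups(gauss)$route, "parametric")
  skewed <- list(a = rexp(30)^3, b = rexp(30)^3)
  expect_identical(compare_groups(skewed)$route, "nonparametric")
})
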