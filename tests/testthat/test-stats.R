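test_that("welch_t matches the closed-form Welch statistic", {
  x <- c(1, 2, 3)
  y <- c(2, 4, 6)
  got <- welch_t(x, y)
  vx <- var(x) / 3
  vy <- var(y) / 3
  t_hand <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_hand <- (vx + vy)^2 / (vx^2 / 2 + vy^2 / 2)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, df_hand, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical samples
  same <- welch_t(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # equal n and equal variance reduces to Student's t
  set.seed(2)
  a <- rnorm(8)
  b <- a + 0.5  # same variance exactly
  expect_equal(welch_t(a, b)$t,
               unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-10)
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("gg_epsilon is exact in the analytic cases and bounded in general", {
  expect_equal(gg_epsilon(matrix(c(2, 0.4, 0.4, 1), 2)), 1)
  # compound symmetry at any k
  cs <- matrix(0.6, 5, 5)
  diag(cs) <- 1.6
  expect_equal(gg_epsilon(cs), 1, tolerance = 1e-10)
  # fixed 3x3 case against a direct textbook computation
  S <- matrix(0.5, 3, 3)
  diag(S) <- c(1, 2, 3)
  k <- 3
  sbar <- mean(diag(S))
  rowm <- rowMeans(S)
  gm <- mean(S)
  eps_direct <- (k * (sbar - gm))^2 /
    ((k - 1) * (sum(S^2) - 2 * k * sum(rowm^2) + k^2 * gm^2))
  expect_equal(gg_epsilon(S), eps_direct, tolerance = 1e-10)
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2)), "symmetric")
  # bounds on random PSD matrices
  set.seed(9)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    A <- matrix(rnorm(k * k), k)
    S <- crossprod(A) + diag(k) * 1e-6
    e <- gg_epsilon(S)
    expect_gte(e, 1 / (k - 1))
    expect_lte(e, 1)
  }
})

test_that("mixed RM ANOVA matches the aov error-stratum decomposition", {
  check_against_aov <- function(values, group) {
    fit <- rm_mixed_anova(values, group)
    n <- nrow(values)
    k <- ncol(values)
    long <- data.frame(y = as.vector(values),
                       subj = factor(rep(seq_len(n), k)),
                       sess = factor(rep(seq_len(k), each = n)),
                       grp = factor(rep(group, k)))
    a <- summary(aov(y ~ grp * sess + Error(subj / sess), data = long))
    s1 <- a[["Error: subj"]][[1]]
    s2 <- a[["Error: subj:sess"]][[1]]
    expect_equal(fit$table$F[1], s1["grp", "F value"], tolerance = 1e-8)
    expect_equal(fit$table$F[2], s2["sess", "F value"], tolerance = 1e-8)
    expect_equal(fit$table$F[3], s2["grp:sess", "F value"], tolerance = 1e-8)
    expect_equal(unname(fit$ss["subj"]), s1["Residuals", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(unname(fit$ss["error"]), s2["Residuals", "Sum Sq"],
                 tolerance = 1e-8)
  }
  # balanced 4 subjects x 3 sessions toy data
  set.seed(31)
  v <- matrix(rnorm(12, 10), 4, 3) + outer(c(0, 0, 2, 2), c(0, 1, 2))
  check_against_aov(v, c("a", "a", "b", "b"))
  # unbalanced groups (3 + 2), 6 sessions
  v2 <- matrix(rnorm(30, 5), 5, 6)
  check_against_aov(v2, c("a", "a", "a", "b", "b"))
  # identical groups give F = 0 for the group effect
  v3 <- rbind(v2[1:2, ], v2[1:2, ])
  f3 <- rm_mixed_anova(v3, c("a", "a", "b", "b"))
  expect_equal(f3$table$F[1], 0, tolerance = 1e-12)
})

test_that("GG-corrected dfs follow the fractional pattern", {
  set.seed(41)
  v <- matrix(rnorm(21 * 6, 10), 21, 6)
  v[, 3] <- v[, 3] * 3  # break sphericity
  grp <- rep(c("a", "b"), c(11, 10))
  fit <- rm_mixed_anova(v, grp)
  eps <- fit$epsilon
  expect_lt(eps, 1)
  expect_equal(fit$table$df1[2], 5 * eps)
  expect_equal(fit$table$df2[2], 95 * eps)
  expect_equal(fit$table$df1[1], 1)
  expect_equal(fit$table$df2[1], 19)
  expect_error(rm_mixed_anova(v[, 1:3] * NA, grp), "unbalanced")
  expect_error(rm_mixed_anova(v[1:3, ], c("a", "a", "b")), ">= 2")
})

test_that("post-hoc procedures match their closed forms", {
  cm <- c(g1 = 10, g2 = 10, g3 = 10)
  expect_true(all(tukey_hsd(cm, 2, 12, 5)$p > 0.999))
  expect_true(all(fisher_lsd(cm, 2, 12, 5)$p > 0.999))
  # two cells: Tukey equals the unadjusted pooled t-test
  cm2 <- c(a = 3, b = 5)
  tk <- tukey_hsd(cm2, 1.5, 10, c(6, 5))
  ls <- fisher_lsd(cm2, 1.5, 10, c(6, 5))
  expect_equal(tk$p, ls$p, tolerance = 1e-6)
  t_hand <- (3 - 5) / sqrt(1.5 * (1 / 6 + 1 / 5))
  expect_equal(ls$p, 2 * pt(abs(t_hand), 10, lower.tail = FALSE),
               tolerance = 1e-12)
  # three-cell studentized range computed independently
  cm3 <- c(a = 1, b = 2.5, c = 4)
  tk3 <- tukey_hsd(cm3, 2, 27, 10)
  q_ac <- abs(1 - 4) / sqrt(2 * (1 / 10 + 1 / 10) / 2)
  expect_equal(tk3$p[tk3$comparison == "a - c"],
               ptukey(q_ac, 3, 27, lower.tail = FALSE), tolerance = 1e-10)
  expect_error(tukey_hsd(cm3, -1, 27, 10), "error term")
})

test_that("linear_fit matches the normal equations and conventions", {
  x <- c(0, 1, 2, 3, 4)
  y <- c(1, 1, 3, 2, 5)
  fit <- linear_fit(x, y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(fit$slope, slope, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(fit$r_squared, cor(x, y)^2, tolerance = 1e-12)
  expect_equal(fit$F, fit$r_squared * 3 / (1 - fit$r_squared),
               tolerance = 1e-10)
  # exact line
  expect_equal(suppressWarnings(linear_fit(x, 2 * x))$r_squared, 1)
  # constant outcome convention
  f0 <- linear_fit(x, rep(2, 5))
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 0)
  expect_equal(f0$p, 1)
  expect_error(linear_fit(rep(1, 5), y), "constant predictor")
})

test_that("simple effects reproduce hand-computed LSD comparisons for k = 2", {
  set.seed(8)
  v <- cbind(rnorm(10, 5), rnorm(10, 6))
  grp <- rep(c("a", "b"), each = 5)
  fit <- rm_mixed_anova(v, grp, within_name = "phase")
  se <- simple_effects(fit, "fisher_lsd", c("early", "late"))
  ms_b <- (fit$ms_subj + fit$ms_err) / 2
  cm <- fit$cell_means
  d <- cm["a", 1] - cm["b", 1]
  t_hand <- d / sqrt(ms_b * (1 / 5 + 1 / 5))
  got <- se[se$scope == "between_at_level" & se$level == "early", ]
  expect_equal(got$difference, unname(d), tolerance = 1e-12)
  df_b <- (fit$ms_subj + fit$ms_err)^2 /
    (fit$ms_subj^2 / fit$df_subj + fit$ms_err^2 / fit$df_err)
  expect_equal(got$p, unname(2 * pt(abs(t_hand), df_b, lower.tail = FALSE)),
               tolerance = 1e-10)
  # within-group paired comparison
  wg <- se[se$scope == "within_group" & se$level == "a", ]
  t_w <- (cm["a", 1] - cm["a", 2]) / sqrt(2 * fit$ms_err / 5)
  expect_equal(wg$p, unname(2 * pt(abs(t_w), fit$df_err, lower.tail = FALSE)),
               tolerance = 1e-10)
})
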