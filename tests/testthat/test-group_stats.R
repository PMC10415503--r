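test_that("age quartile groups follow the right-closed boundary convention", {
  ages <- stats::setNames(seq(9, 56, length.out = 48), sprintf("p%02d", 1:48))
  grp <- assign_age_quartiles(ages)
  expect_equal(unname(table(grp)), rep(12L, 4), ignore_attr = TRUE)

  four <- stats::setNames(c(10, 20, 30, 40), letters[1:4])
  expect_identical(unname(assign_age_quartiles(four)), 1:4)

  # right-closed: an age exactly on a cut point belongs to the lower group
  q <- stats::quantile(ages, 0.25, names = FALSE)
  ages2 <- ages
  ages2[1] <- q
  expect_identical(unname(assign_age_quartiles(ages2)[1]), 1L)

  expect_error(assign_age_quartiles(stats::setNames(rep(30, 8), letters[1:8])),
               "degenerate quartiles")
  expect_error(assign_age_quartiles(stats::setNames(c(1, NA), c("a", "b"))),
               "missing age.*b")
})

test_that("the normality gate is calibrated on normal and skewed samples", {
  normal_rate <- mean(vapply(1:1000, function(s) {
    set.seed(s)
    shapiro_wilk_gate(rnorm(48))$normal
  }, logical(1)))
  expect_gte(normal_rate, 0.94)  # nominal level 5%, Monte-Carlo slack

  expon_rate <- mean(vapply(1:200, function(s) {
    set.seed(s)
    shapiro_wilk_gate(rexp(48))$normal
  }, logical(1)))
  expect_lte(expon_rate, 0.05)

  expect_error(shapiro_wilk_gate(rep(1, 10)), "identical")
  expect_error(shapiro_wilk_gate(c(1, 2)), "between 3 and 5000")
})

test_that("the age F statistic matches a normal-equations least-squares oracle", {
  set.seed(48)
  n <- 48
  age <- runif(n, 8, 66)
  sex <- rep(c("male", "female"), c(20, 28))
  score <- 1.4 + 0.002 * age + rnorm(n, 0, 0.01)
  at <- complexity_anova(score, age, sex)
  expect_identical(at$df[1:3], c(1L, 1L, 1L))

  # sequential SS for age = SS(mean-only) - SS(mean+age), via explicit
  # normal equations rather than lm()
  x0 <- matrix(1, n)
  x1 <- cbind(1, age)
  rss <- function(x) {
    beta <- solve(t(x) %*% x, t(x) %*% score)
    sum((score - x %*% beta)^2)
  }
  sexn <- as.numeric(sex == "male")
  x_full <- cbind(1, age, sexn, age * sexn)
  df_res <- as.integer(n - 4)
  f_age <- ((rss(x0) - rss(x1)) / 1) / (rss(x_full) / df_res)
  expect_equal(at$f[1], f_age, tolerance = 1e-9)
  expect_identical(at$df[4], df_res)
})

test_that("with sex as the only predictor the ANOVA reduces to the pooled t test", {
  set.seed(12)
  n <- 40
  sex <- rep(c("male", "female"), each = n / 2)
  score <- rnorm(n) + 0.8 * (sex == "male")
  # pooled t by hand
  g1 <- score[sex == "male"]; g2 <- score[sex == "female"]
  sp2 <- ((length(g1) - 1) * var(g1) + (length(g2) - 1) * var(g2)) / (n - 2)
  tstat <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
  at <- complexity_anova(score, NULL, sex)
  expect_identical(at$term, c("sex", "residuals"))
  expect_equal(at$f[1], tstat^2, tolerance = 1e-9)
  expect_error(complexity_anova(score, NULL, rep("male", n)), "both sexes")
})

test_that("permuting age labels destroys the age effect", {
  set.seed(77)
  n <- 48
  age <- runif(n, 8, 66)
  sex <- sample(rep(c("male", "female"), c(20, 28)))
  score <- 1.4 + 0.003 * age + rnorm(n, 0, 0.02)
  f_obs <- complexity_anova(score, age, sex)$f[1]
  f_perm <- vapply(1:200, function(i)
    complexity_anova(score, sample(age), sex)$f[1], numeric(1))
  # observed F should sit far in the permutation tail
  expect_lt(mean(f_perm >= f_obs), 0.01)
  # permuted F behaves like its null: median near the F(1, n-4) median
  expect_lt(abs(stats::median(f_perm) - stats::qf(0.5, 1, n - 4)), 0.35)
})

test_that("holm adjustment matches hand arithmetic and the step-down oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(1:6, 1))
    adj <- holm_adjust(p)
    expect_true(all(adj >= p))
    for (alpha in runif(8)) {
      expect_identical(adj < alpha, holm_reject_oracle(p, alpha))
    }
  }
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("pairwise Welch tests match the closed-form statistic", {
  set.seed(21)
  g1 <- rnorm(12, 0, 1)
  g2 <- rnorm(15, 0.3, 2)
  rep_ <- pairwise_group_tests(c(g1, g2), rep(c(1, 2), c(12, 15)))
  se <- sqrt(var(g1) / 12 + var(g2) / 15)
  tstat <- (mean(g1) - mean(g2)) / se
  df <- se^4 / ((var(g1) / 12)^2 / 11 + (var(g2) / 15)^2 / 14)
  p <- 2 * stats::pt(-abs(tstat), df)
  expect_equal(rep_$t[1], tstat, tolerance = 1e-9)
  expect_equal(rep_$p_raw[1], p, tolerance = 1e-9)

  # exactly duplicated data: zero t statistic, p = 1
  dup <- pairwise_group_tests(c(g1, g1), rep(c(1, 2), each = 12))
  expect_equal(dup$p_raw[1], 1)

  # well-separated groups: all six adjusted comparisons significant
  set.seed(5)
  scores <- unlist(lapply(1:4, function(g) rnorm(12, g, 0.1)))
  all4 <- pairwise_group_tests(scores, rep(1:4, each = 12))
  expect_identical(nrow(all4), 6L)
  expect_true(all(all4$significant))
  expect_true(all(all4$p_holm >= all4$p_raw))

  expect_error(pairwise_group_tests(1:5, c(1, 1, 1, 1, 2)), "at least 2")
})

test_that("icc handles agreement, offsets, and independent sessions correctly", {
  set.seed(9)
  s1 <- stats::setNames(rnorm(20, 10, 2), sprintf("s%02d", 1:20))
  expect_equal(intra_rater_icc(s1, s1)$icc, 1.0)

  # constant offset: absolute agreement strictly below consistency
  off <- intra_rater_icc(s1, s1 + 3)
  expect_lt(off$icc, off$icc_consistency)

  # hand mean-squares oracle on a small table
  s2 <- s1 + rnorm(20, 0, 0.5)
  rep_ <- intra_rater_icc(s1, s2)
  m <- cbind(s1, s2)
  a <- stats::anova(stats::lm(as.vector(m) ~
                                factor(rep(1:20, 2)) + factor(rep(1:2, each = 20))))
  msr <- a$`Mean Sq`[1]; msc <- a$`Mean Sq`[2]; mse <- a$`Mean Sq`[3]
  icc_oracle <- (msr - mse) / (msr + mse + 2 * (msc - mse) / 20)
  expect_equal(rep_$icc, icc_oracle, tolerance = 1e-9)

  # independent sessions: mean ICC near zero
  iccs <- vapply(1:200, function(s) {
    set.seed(s)
    a <- stats::setNames(rnorm(50), sprintf("x%02d", 1:50))
    b <- stats::setNames(rnorm(50), sprintf("x%02d", 1:50))
    intra_rater_icc(a, b)$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs)), 0.1)

  expect_error(intra_rater_icc(s1, stats::setNames(rnorm(3), c("a", "b", "c"))),
               "ids differ")
})
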