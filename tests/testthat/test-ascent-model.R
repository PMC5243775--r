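test_that("single binary predictor recovers the closed-form log odds ratio", {
  # 2x2 table with counts a, b, c, d
  tab <- list(a = 15, b = 9, c = 6, d = 20)
  x <- c(rep(1, tab$a + tab$b), rep(0, tab$c + tab$d))
  y <- c(rep(1, tab$a), rep(0, tab$b), rep(1, tab$c), rep(0, tab$d))
  fit <- fit_logit(matrix(x, dimnames = list(NULL, "exposed")), y)
  expect_equal(unname(fit$coefficients["exposed"]),
               log(tab$a * tab$d / (tab$b * tab$c)), tolerance = 1e-6)
  expect_equal(fit$intercept, log(tab$c / tab$d), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separation_warning)
})

test_that("IRLS matches independent likelihood maximization on small instances", {
  for (seed in 1:5) {
    sim <- simulate_logit_data(seed, n = 50)
    fit <- fit_logit(sim$design, sim$outcome)
    oracle <- optim_logit(sim$design, sim$outcome)
    expect_equal(unname(coef(fit)), oracle, tolerance = 1e-4)
  }
})

test_that("LR chi-square is calibrated under the null (Monte Carlo)", {
  n_rep <- 200
  below <- logical(n_rep)
  set.seed(97)
  for (r in seq_len(n_rep)) {
    x <- matrix(rnorm(500 * 2), 500, 2)
    y <- rbinom(500, 1, 0.4)  # independent of the predictors
    fit <- fit_logit(x, y)
    below[r] <- fit$lr_chi2 < qchisq(0.95, df = 2)
  }
  expect_gte(mean(below), 0.9)
})

test_that("perfect separation is flagged and reported at the capped solution", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), dimnames = list(NULL, "x"))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_logit(x, y)
  expect_true(fit$separation_warning)
  expect_equal(max(abs(coef(fit))), fit$coef_cap)
  expect_true(all(abs(coef(fit)) <= fit$coef_cap + 1e-9))
  # the capped fit still classifies perfectly and reports finite deviance/AIC
  expect_equal(fit$pct_correct, 100)
  expect_true(is.finite(fit$deviance) && is.finite(fit$aic))
})

test_that("one-class outcomes give a flagged degenerate fit, not an error", {
  x <- matrix(rnorm(20), dimnames = list(NULL, "x"))
  fit <- fit_logit(x, rep(1, 20))
  expect_true(fit$degenerate)
  expect_true(fit$separation_warning)
  expect_false(fit$converged)
  expect_equal(unname(fit$coefficients), 0)
  expect_true(is.finite(fit$deviance))
})

test_that("logit invariants hold: deviance, AIC, LR df", {
  sim <- simulate_logit_data(3, n = 200, betas = c(0.8, -0.4))
  fit <- fit_logit(sim$design, sim$outcome)
  expect_equal(fit$deviance, -2 * fit$log_likelihood)
  expect_gte(fit$deviance, 0)
  expect_equal(fit$aic, fit$deviance + 2 * (length(fit$coefficients) + 1))
  expect_equal(fit$lr_df, ncol(sim$design))
  # predict() agrees with the stored fitted values
  expect_equal(predict(fit, sim$design), fit$fitted)
  expect_equal(predict(fit, sim$design, type = "class"),
               as.numeric(fit$fitted > 0.5))
})

test_that("formula interface matches the matrix interface", {
  sim <- simulate_logit_data(11, n = 120)
  df <- data.frame(y = sim$outcome, sim$design)
  f1 <- ascent_logit(y ~ x1 + x2, df)
  f2 <- fit_logit(sim$design, sim$outcome)
  expect_equal(coef(f1), coef(f2))
  expect_equal(f1$aic, f2$aic)
  # residuals sum behavior: response residuals sum to ~0 at the MLE
  expect_lt(abs(sum(residuals(f1, type = "response"))), 1e-6)
})

test_that("Hosmer-Lemeshow statistic is zero for perfectly calibrated groups", {
  # 10 groups of 20 with constant p per group, chosen so that the observed
  # count equals the expected count exactly in every group
  group_p <- round(seq(0.05, 0.95, length.out = 10) * 20) / 20
  p <- rep(group_p, each = 20)
  y <- unlist(lapply(group_p, function(pr) {
    n1 <- round(20 * pr)
    c(rep(1, n1), rep(0, 20 - n1))
  }))
  gof <- hosmer_lemeshow(p, y, n_groups = 10)
  expect_equal(gof$statistic, 0, tolerance = 1e-12)
  expect_equal(gof$df, 8)
  expect_equal(nrow(gof$group_table), 10)
})

test_that("Hosmer-Lemeshow p-values are near-uniform for a well-specified model", {
  n_rep <- 200
  pvals <- numeric(n_rep)
  set.seed(131)
  for (r in seq_len(n_rep)) {
    x <- rnorm(1000)
    y <- rbinom(1000, 1, plogis(-0.3 + 0.9 * x))
    fit <- fit_logit(matrix(x, dimnames = list(NULL, "x")), y)
    pvals[r] <- hosmer_lemeshow(fit$fitted, y)$p_value
  }
  ks <- max(abs(sort(pvals) - seq_len(n_rep) / n_rep))
  expect_lt(ks, 0.1)
})

test_that("degenerate risk groups are merged, not crashed on", {
  p <- c(rep(0, 30), runif(70, 0.2, 0.8))
  y <- rbinom(100, 1, p)
  expect_message(gof <- hosmer_lemeshow(p, y, n_groups = 10), "merged")
  expect_true(is.finite(gof$statistic))
  expect_equal(gof$df, nrow(gof$group_table) - 2)
})

test_that("spearman_matrix equals the rank-correlation oracle, ties included", {
  expect_equal(spearman_matrix(data.frame(a = 1:10, b = 1:10))["a", "b"], 1)
  expect_equal(spearman_matrix(data.frame(a = 1:10, b = 10:1))["a", "b"], -1)

  set.seed(17)
  cols <- data.frame(u = sample(1:5, 40, TRUE),   # heavy ties
                     v = rnorm(40),
                     w = sample(1:3, 40, TRUE))
  got <- spearman_matrix(cols)
  want <- cor(cols, method = "spearman")
  expect_equal(unclass(got)[, ], want, tolerance = 1e-12,
               ignore_attr = TRUE)

  const <- data.frame(a = rnorm(10), b = rep(2, 10))
  expect_warning(m <- spearman_matrix(const), "constant")
  expect_true(is.na(m["a", "b"]))
  expect_equal(attr(m, "constant_columns"), "b")
  expect_error(spearman_matrix(data.frame(a = 1:2, b = 2:1)), "n >= 3")
})

test_that("subset table enumerates all nonempty subsets with honest AICs", {
  sim <- simulate_logit_data(23, n = 150)
  tab <- subset_model_table(sim$design, sim$outcome)
  expect_equal(nrow(tab), 3)  # 2^2 - 1
  expect_equal(tab$df, c(2, 1, 1))
  expect_true(!is.unsorted(tab$aic[tab$df == 1]))

  # AIC identity on every row, and each row equals a from-scratch refit
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$aic[i], tab$deviance[i] + 2 * (tab$df[i] + 1))
    vars <- strsplit(tab$variables[i], "+", fixed = TRUE)[[1]]
    refit <- fit_logit(sim$design[, vars, drop = FALSE], sim$outcome)
    expect_equal(tab$aic[i], refit$aic)
  }
})

test_that("a dominant predictor wins the single-predictor AIC race", {
  set.seed(29)
  n <- 500
  a <- rnorm(n); b <- rnorm(n); c_ <- rnorm(n)
  y <- rbinom(n, 1, plogis(2.5 * a))
  design <- cbind(a = a, b = b, c = c_)
  tab <- subset_model_table(design, y)
  singles <- tab[tab$df == 1, ]
  expect_equal(singles$variables[which.min(singles$aic)], "a")
  expect_error(subset_model_table(matrix(0, 2, 13), rep(0:1, 1)), "12")
})

test_that("moment_check computes standard sample moments and flags", {
  sym <- c(-3, -1, 0, 1, 3)
  mc <- moment_check(sym)
  expect_equal(mc$skewness, 0)
  expect_equal(mc$mean, 0)
  expect_true(is.na(mc$flag))

  set.seed(37)
  norm <- rnorm(10000)
  mc <- moment_check(norm)
  expect_lt(abs(mc$skewness), 0.08)
  expect_lt(abs(mc$excess_kurtosis), 0.15)

  expo <- rexp(10000)
  mc <- moment_check(expo)
  expect_equal(mc$skewness, 2, tolerance = 0.15)
  expect_match(mc$flag, "mean may not represent")

  mc <- moment_check(rep(5, 10))
  expect_match(mc$flag, "zero variance")
  expect_error(moment_check(c(1, 2, 3)), "at least 4")
})

test_that("simulate() draws outcomes at the fitted probabilities", {
  sim <- simulate_logit_data(43, n = 300)
  fit <- fit_logit(sim$design, sim$outcome)
  draws <- simulate(fit, nsim = 50, seed = 7)
  expect_equal(dim(draws), c(300, 50))
  expect_true(all(unlist(draws) %in% 0:1))
  # mean simulated success rate tracks the mean fitted probability
  expect_equal(mean(unlist(draws)), mean(fit$fitted), tolerance = 0.05)
})
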