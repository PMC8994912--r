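ref_episode <- function(n = 1) {
  base <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)), complication_class = "eye",
    episode_type = "incident", woman = 0, age_c75_per10 = 0,
    t2d_duration_per5 = 0, died_within_1y = 0, n_prior_same_class = 0L,
    high_prior_cost = 0L, year1_eur = 1000)
  for (cls in comorbidity_classes()) base[[cls]] <- 0
  base
}

test_that("the design matrix applies the stated covariate transforms", {
  d <- ref_episode(3)
  d$woman <- c(0, 1, 1)
  d$age_c75_per10 <- c(0, 1, -0.5)      # ages 75, 85, 70
  d$t2d_duration_per5 <- c(0, 2, 1)     # durations 0, 10, 5 years
  spec <- model_spec("eye", "incident")
  des <- suppressWarnings(build_design(d, spec))  # constant flags drop
  expect_equal(colnames(des$X)[1], "(Intercept)")
  # reference profile row: intercept only
  expect_equal(unname(des$X[1, ]), c(1, rep(0, ncol(des$X) - 1)))
  expect_equal(des$X[2, "age_c75_per10"], 1.0, ignore_attr = TRUE)
  expect_equal(des$X[3, "t2d_duration_per5"], 1.0, ignore_attr = TRUE)
  # hand-built rows
  expect_equal(unname(des$X[, "woman"]), d$woman)
  expect_equal(des$y, d$year1_eur)
})

test_that("zero-cost rows and zero-variance covariates are dropped", {
  d <- ref_episode(20)
  d$woman <- rep(c(0, 1), 10)
  d$year1_eur <- c(0, rep(1000, 19))
  spec <- model_spec("eye", "incident")
  expect_message(
    expect_warning(des <- build_design(d, spec), "dementia"),
    "dropped 1 zero-cost")
  expect_equal(nrow(des$X), 19)
  expect_false("dementia" %in% colnames(des$X))
  expect_true("woman" %in% colnames(des$X))
  expect_true("dementia" %in% des$dropped_covariates)
})

test_that("incident specs exclude recurrence covariates; recurrent add them", {
  inc <- model_spec("eye", "incident")
  rec <- model_spec("eye", "recurrent")
  expect_false(any(c("n_earlier_episodes", "high_prior_cost",
                     "diabetes_with_chronic_complications") %in%
                     inc$covariates))
  expect_true(all(c("n_earlier_episodes", "high_prior_cost",
                    "diabetes_with_chronic_complications") %in%
                    rec$covariates))
})

test_that("intercept-only gamma log-link MLE equals the sample mean", {
  set.seed(1)
  y <- rgamma(400, shape = 2, scale = 3000)
  fit <- fit_gamma_glm(matrix(1, 400, 1, dimnames = list(NULL, "(Intercept)")),
                       y)
  expect_equal(exp(fit$beta[[1]]), mean(y), tolerance = 1e-11)
  expect_equal(predict_mean(fit), mean(y), tolerance = 1e-11)
})

test_that("coefficients recover the truth and ignore row duplication", {
  set.seed(2)
  beta <- c(log(9000), -0.2, -0.15, 0.05, 0.4)
  sim <- gamma_design_sim(2000, beta)
  fit <- fit_gamma_glm(sim$X, sim$y)
  se <- sqrt(diag(fit$vcov_sandwich))
  expect_true(all(abs(fit$beta - beta) < 3 * se))
  dup <- fit_gamma_glm(rbind(sim$X, sim$X), c(sim$y, sim$y))
  expect_equal(dup$beta, fit$beta, tolerance = 1e-8)
})

test_that("degenerate designs fail loudly", {
  X <- cbind(`(Intercept)` = 1, a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(fit_gamma_glm(X, c(1, 2, 3, 4)), "collinear.*b")
  expect_error(fit_gamma_glm(matrix(1, 3, 1), c(0, 1, 2)), "positive")
})

test_that("singleton-cluster sandwich equals a hand-rolled HC estimator", {
  set.seed(3)
  sim <- gamma_design_sim(300, c(log(5000), -0.3, 0.1))
  fit <- fit_gamma_glm(sim$X, sim$y)
  mu <- exp(drop(sim$X %*% fit$beta))
  r <- (sim$y - mu) / mu
  A_inv <- solve(crossprod(sim$X))
  S <- sim$X * r
  n <- nrow(sim$X)
  oracle <- A_inv %*% crossprod(S) %*% A_inv * n / (n - 1)
  expect_equal(unname(fit$vcov_sandwich), unname(oracle), tolerance = 1e-6)
  expect_equal(fit$vcov_sandwich, t(fit$vcov_sandwich))
  expect_true(all(diag(fit$vcov_sandwich) >= 0))
  expect_true(all(eigen(fit$vcov_sandwich, only.values = TRUE)$values >
                    -1e-12))
})

test_that("duplicating every singleton cluster shrinks SEs by ~1/sqrt(2)", {
  set.seed(4)
  sim <- gamma_design_sim(500, c(log(5000), -0.3))
  f1 <- fit_gamma_glm(sim$X, sim$y)
  f2 <- fit_gamma_glm(rbind(sim$X, sim$X), c(sim$y, sim$y))
  ratio <- sqrt(diag(f2$vcov_sandwich)) / sqrt(diag(f1$vcov_sandwich))
  expect_equal(unname(ratio), rep(1 / sqrt(2), 2), tolerance = 0.01)
})

test_that("cluster-correlated data widen sandwich SEs over model SEs", {
  set.seed(5)
  g <- 150; m <- 4
  u <- rnorm(g, 0, 0.6)
  X <- cbind(`(Intercept)` = 1, woman = rbinom(g * m, 1, 0.5))
  mu <- exp(log(5000) + 0.3 * X[, 2] + rep(u, each = m))
  y <- rgamma(g * m, 2, scale = mu / 2)
  fit <- fit_gamma_glm(X, y, clusters = rep(seq_len(g), each = m))
  expect_equal(fit$n_clusters, g)
  expect_gt(sqrt(fit$vcov_sandwich[1, 1]), sqrt(fit$vcov_model[1, 1]))
  sim3 <- gamma_design_sim(100, c(log(5000), -0.3, 0.1))
  f3 <- fit_gamma_glm(sim3$X, sim3$y)
  expect_warning(sandwich_covariance(f3, rep(1:2, 50)), "fewer clusters")
})

test_that("McFadden R2 is 1 - ll/ll0, zero for the null model", {
  set.seed(6)
  sim <- gamma_design_sim(500, c(log(5000), -0.5, 0.3))
  fit <- fit_gamma_glm(sim$X, sim$y)
  expect_equal(mcfadden_r2(fit), 1 - fit$loglik / fit$loglik_null)
  expect_gt(mcfadden_r2(fit), 0)
  expect_lt(mcfadden_r2(fit), 1)
  null <- fit_gamma_glm(sim$X[, 1, drop = FALSE], sim$y)
  expect_equal(mcfadden_r2(null), 0, tolerance = 1e-10)
})

test_that("the coefficient table exponentiates and stars by sandwich p-values", {
  set.seed(7)
  sim <- gamma_design_sim(800, c(log(5000), -0.4, 0, 0))
  fit <- fit_gamma_glm(sim$X, sim$y)
  tab <- coefficient_table(fit)
  expect_equal(tab$estimate, unname(exp(fit$beta)))
  # independent normal-tail p-values
  p <- 2 * pnorm(-abs(fit$beta / sqrt(diag(fit$vcov_sandwich))))
  expect_equal(tab$p_value, unname(p))
  expect_equal(tab$stars,
               unname(ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
})

test_that("predict_mean composes intercept euros with active coefficients", {
  fit <- list(beta = c(`(Intercept)` = log(1000), woman = log(0.8),
                       age_c75_per10 = log(1.1)))
  class(fit) <- "gamma_cost_fit"
  expect_equal(predict_mean(fit), 1000)
  expect_equal(predict_mean(fit, c(woman = 1)), 800)
  expect_equal(predict_mean(fit, c(woman = 1, age_c75_per10 = 2)),
               1000 * 0.8 * 1.1^2)
  expect_error(predict_mean(fit, c(shoe_size = 4)), "shoe_size")
})

test_that("AMEs obey the log-link identity and the counterfactual oracle", {
  set.seed(8)
  sim <- gamma_design_sim(600, c(log(5000), 0.3, -0.2, 0, 0.5))
  fit <- fit_gamma_glm(sim$X, sim$y)
  ame <- average_marginal_effects(fit)
  mu <- exp(drop(sim$X %*% fit$beta))
  # continuous: beta_j * mean prediction
  for (j in c("age_c75_per10", "t2d_duration_per5")) {
    expect_equal(ame$ame_eur[ame$term == j], fit$beta[[j]] * mean(mu),
                 tolerance = 1e-8)
  }
  # binary: brute-force counterfactual difference row by row
  for (j in c("woman", "died_within_1y")) {
    X1 <- sim$X; X1[, j] <- 1
    X0 <- sim$X; X0[, j] <- 0
    cf <- mean(exp(drop(X1 %*% fit$beta)) - exp(drop(X0 %*% fit$beta)))
    expect_equal(ame$ame_eur[ame$term == j], cf, tolerance = 1e-8)
  }
  # a zero coefficient has zero AME
  fit0 <- fit
  fit0$beta["t2d_duration_per5"] <- 0
  ame0 <- average_marginal_effects(fit0, sim$X)
  expect_equal(ame0$ame_eur[ame0$term == "t2d_duration_per5"], 0)
})

test_that("predictions are scale-equivariant in the response", {
  set.seed(9)
  sim <- gamma_design_sim(400, c(log(5000), -0.3, 0.2))
  f1 <- fit_gamma_glm(sim$X, sim$y)
  f2 <- fit_gamma_glm(sim$X, 10 * sim$y)
  expect_equal(exp(f2$beta[[1]]), 10 * exp(f1$beta[[1]]), tolerance = 1e-6)
  expect_equal(f2$beta[-1], f1$beta[-1], tolerance = 1e-6)
})

test_that("one failing model does not abort the other eleven", {
  set.seed(10)
  d <- ref_episode(80)
  d$woman <- rbinom(80, 1, 0.5)
  d$year1_eur <- rgamma(80, 2, scale = 3000)
  d$complication_class <- "eye"
  # a second class with too few episodes to fit
  d2 <- ref_episode(2)
  d2$complication_class <- "nephropathy"
  res <- suppressWarnings(suppressMessages(
    fit_complication_models(rbind(d, d2), min_n = 30)))
  expect_s3_class(res$fits[["eye:incident"]], "gamma_cost_fit")
  expect_null(res$fits[["nephropathy:incident"]])
  expect_match(res$fit_stats$error[res$fit_stats$model == "nephropathy:incident"],
               "min_n")
  expect_equal(nrow(res$fit_stats), 12L)
})
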