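#' Predictive simulation of one-year cost distributions
#'
#' Coefficient uncertainty is propagated by drawing coefficient vectors from
#' a multivariate normal centred at the estimates: `b + L z` with `L L' =
#' Sigma` the (lower-triangular) Cholesky factor of the chosen covariance
#' and `z` standard normal. Each draw yields a predicted mean cost
#' `exp(x'b_draw)` for the requested profile; outcome-level gamma noise can
#' be added on top.
#'
#' @name predictive_simulator
NULL

profile_x <- function(beta, profile) {
  profile <- unlist(profile)
  terms <- setdiff(names(beta), "(Intercept)")
  unknown <- setdiff(names(profile), terms)
  if (length(unknown) > 0) {
    stop("unknown covariate(s) in profile: ", paste(unknown, collapse = ", "))
  }
  x <- stats::setNames(numeric(length(terms)), terms)
  x[names(profile)] <- profile
  c(`(Intercept)` = 1, x)
}

#' Draw coefficient vectors via the Cholesky factor of the covariance
#'
#' A numerically semi-definite covariance gets a tiny diagonal jitter
#' (1e-10 of the mean diagonal, logged); an all-zero covariance yields
#' degenerate draws equal to `beta`.
#'
#' @param beta Coefficient vector (log scale).
#' @param Sigma Symmetric PSD covariance matrix.
#' @param n_draws Number of draws (>= 1).
#' @param seed RNG seed.
#' @return Matrix `n_draws` x `length(beta)`.
#' @export
draw_coefficients <- function(beta, Sigma, n_draws, seed = 1L) {
  stopifnot(n_draws >= 1, nrow(Sigma) == length(beta),
            ncol(Sigma) == length(beta))
  if (max(abs(Sigma - t(Sigma))) > 1e-8 * max(1, max(abs(Sigma)))) {
    stop("Sigma must be symmetric")
  }
  k <- length(beta)
  if (max(abs(Sigma)) == 0) {
    L <- matrix(0, k, k)
  } else {
    L <- tryCatch(t(chol(Sigma)), error = function(e) NULL)
    if (is.null(L)) {
      jit <- 1e-10 * mean(diag(Sigma))
      message("draw_coefficients: covariance not PD, adding jitter ", jit)
      L <- tryCatch(t(chol(Sigma + diag(jit, k))), error = function(e) {
        stop("covariance not positive semi-definite even after jitter")
      })
    }
  }
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_draws * k), n_draws, k)
  draws <- sweep(Z %*% t(L), 2, beta, `+`)
  colnames(draws) <- names(beta)
  draws
}

#' Simulate the distribution of predicted one-year costs for a profile
#'
#' @param fit A `gamma_cost_fit`.
#' @param profile Named covariate values (reference = empty profile).
#' @param n_draws Number of coefficient draws.
#' @param seed RNG seed.
#' @param include_outcome_noise If TRUE, draw the outcome from the gamma
#'   family at the fitted shape around each predicted mean (patient-level
#'   variation); default is coefficient uncertainty only.
#' @param covariance `"sandwich"` (default) or `"model"`.
#' @return Object of class `cost_distribution_summary`: mean, sd, quantiles
#'   (2.5/25/50/75/97.5%), n_draws, seed, plus the raw `draws`.
#' @export
simulate_cost_distribution <- function(fit, profile = c(), n_draws = 10000,
                                       seed = 1L,
                                       include_outcome_noise = FALSE,
                                       covariance = c("sandwich", "model")) {
  covariance <- match.arg(covariance)
  Sigma <- if (covariance == "sandwich") fit$vcov_sandwich else fit$vcov_model
  x <- profile_x(fit$beta, profile)
  draws_b <- draw_coefficients(fit$beta, Sigma, n_draws, seed)
  pred <- exp(drop(draws_b %*% x))
  if (include_outcome_noise) {
    pred <- stats::rgamma(n_draws, shape = fit$shape,
                          scale = pred / fit$shape)
  }
  qs <- stats::quantile(pred, c(0.025, 0.25, 0.5, 0.75, 0.975))
  structure(
    list(mean = mean(pred), sd = stats::sd(pred), quantiles = qs,
         n_draws = n_draws, seed = seed,
         include_outcome_noise = include_outcome_noise,
         covariance = covariance, draws = pred),
    class = "cost_distribution_summary")
}

#' @export
print.cost_distribution_summary <- function(x, ...) {
  cat(sprintf("Simulated one-year cost distribution (%d draws, %s covariance%s)\n",
              x$n_draws, x$covariance,
              if (x$include_outcome_noise) ", outcome noise" else ""))
  cat(sprintf("  mean %0.2f EUR, sd %0.2f\n", x$mean, x$sd))
  print(round(x$quantiles, 2))
  invisible(x)
}

#' Refit a model on a user-selected covariate subset
#'
#' The interactive-analysis primitive: fit the same gamma log-link model
#' using only the requested covariates (an empty subset gives the
#' intercept-only model). The returned fit plugs into
#' [simulate_cost_distribution()].
#'
#' @param episodes Included episodes of one class and episode type, with
#'   covariates and `year1_eur`.
#' @param class Complication class.
#' @param episode_type `"incident"` or `"recurrent"`.
#' @param covariates Character vector, subset of the full spec's covariates.
#' @return A `gamma_cost_fit`.
#' @export
refit_subset_model <- function(episodes, class, episode_type, covariates) {
  full <- model_spec(class, episode_type)
  extra <- setdiff(covariates, full$covariates)
  if (length(extra) > 0) {
    stop("covariate(s) not in the model spec: ", paste(extra, collapse = ", "))
  }
  spec <- full
  spec$covariates <- covariates
  sub <- episodes[episodes$complication_class == class &
                    episodes$episode_type == episode_type, , drop = FALSE]
  if (length(covariates) == 0L) {
    y <- sub$year1_eur
    y <- y[!is.na(y) & y > 0]
    return(fit_gamma_glm(matrix(1, length(y), 1,
                                dimnames = list(NULL, "(Intercept)")),
                         y, sub$patient_id[!is.na(sub$year1_eur) &
                                             sub$year1_eur > 0]))
  }
  des <- build_design(sub, spec)
  fit_gamma_glm(des$X, des$y, des$clusters)
}
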