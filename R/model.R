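#' Gamma log-link cost regression
#'
#' One-year episode costs are positive and right-skewed, so they are
#' modelled with a gamma GLM and log link, `E[y | x] = exp(x'b)`: covariate
#' effects are multiplicative and the exponentiated coefficients read as
#' cost ratios against the reference profile (75-year-old man, newly
#' diagnosed, no recorded comorbidity, alive one year after the event).
#' Inference uses a cluster-robust sandwich covariance with patients as
#' clusters, since one patient can contribute several recurrent episodes of
#' the same class.
#'
#' @name cost_model
NULL

#' Covariate list for one complication-class model
#'
#' Incident models use demographics, one-year death and the comorbidity
#' flags (without `diabetes_with_chronic_complications`, whose definition
#' overlaps the outcome's own complication for first events). Recurrent
#' models add the number of earlier same-class episodes, the high previous
#' cost indicator and the diabetes-with-chronic-complications flag.
#'
#' @param class Complication class.
#' @param episode_type `"incident"` or `"recurrent"`.
#' @return list with `class`, `episode_type`, `covariates`, `cluster`.
#' @export
model_spec <- function(class, episode_type = c("incident", "recurrent")) {
  episode_type <- match.arg(episode_type)
  class <- match.arg(class, complication_classes())
  base <- c("woman", "age_c75_per10", "t2d_duration_per5", "died_within_1y")
  como <- setdiff(comorbidity_classes(), "diabetes_with_chronic_complications")
  covs <- if (episode_type == "incident") {
    c(base, como)
  } else {
    c(base, "n_earlier_episodes", "high_prior_cost", como,
      "diabetes_with_chronic_complications")
  }
  list(class = class, episode_type = episode_type, covariates = covs,
       cluster = "patient_id")
}

#' Build the design matrix, response and cluster vector for one model
#'
#' Rows with zero (or missing) year-1 cost are dropped with a logged count —
#' the gamma family has positive support. Covariates with zero variance in
#' the remaining rows are dropped with a warning naming them (they are
#' inestimable, like a comorbidity never observed in a class).
#'
#' @param data Episode table restricted to the model's class and type, with
#'   covariates and `year1_eur`. `n_earlier_episodes` is taken from
#'   `n_prior_same_class` when absent.
#' @param spec A [model_spec()].
#' @return list `X` (with intercept column first), `y`, `clusters`,
#'   `dropped_zero_cost`, `dropped_covariates`.
#' @export
build_design <- function(data, spec) {
  if (is.null(data$n_earlier_episodes) &&
      "n_earlier_episodes" %in% spec$covariates) {
    data$n_earlier_episodes <- data$n_prior_same_class
  }
  miss <- setdiff(spec$covariates, names(data))
  if (length(miss) > 0) stop("missing covariate column(s): ",
                             paste(miss, collapse = ", "))
  keep <- !is.na(data$year1_eur) & data$year1_eur > 0
  n_zero <- sum(!keep)
  if (n_zero > 0) {
    message(sprintf("build_design: dropped %d zero-cost episode(s)", n_zero))
  }
  data <- data[keep, , drop = FALSE]
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, spec$covariates, drop = FALSE]))
  const <- apply(X[, -1, drop = FALSE], 2, function(v) {
    length(unique(v)) < 2L
  })
  if (any(const)) {
    warning("dropping zero-variance covariate(s): ",
            paste(names(const)[const], collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  list(X = X, y = data$year1_eur,
       clusters = data[[spec$cluster]] %||% seq_len(nrow(data)),
       dropped_zero_cost = n_zero,
       dropped_covariates = names(const)[const])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a gamma GLM with log link
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm`), convergence tolerance 1e-8, at most 100 iterations. The
#' shape is estimated from the deviance (`n / deviance`); it does not affect
#' the coefficient estimates under the log link. The null (intercept-only)
#' log-likelihood is stored for McFadden's pseudo-R².
#'
#' @param X Design matrix, intercept column first, full column rank.
#' @param y Strictly positive response (year-1 costs in euros).
#' @param clusters Cluster ids (patients); default singletons.
#' @return Object of class `gamma_cost_fit`.
#' @export
fit_gamma_glm <- function(X, y, clusters = NULL) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (any(y <= 0)) stop("y must be strictly positive")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$.y <- y
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  fit <- stats::glm(.y ~ ., data = df, family = stats::Gamma(link = "log"),
                    control = ctrl)
  if (!fit$converged) {
    stop("gamma GLM did not converge in ", fit$iter, " iterations")
  }
  null_fit <- stats::glm(.y ~ 1, data = df,
                         family = stats::Gamma(link = "log"), control = ctrl)
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  vc_model <- stats::vcov(fit)
  dimnames(vc_model) <- list(colnames(X), colnames(X))
  clusters <- clusters %||% seq_along(y)
  vc_sand <- sandwich_covariance(fit, clusters)
  dimnames(vc_sand) <- dimnames(vc_model)
  dispersion <- fit$deviance / length(y)  # deviance-based
  structure(
    list(glm = fit, beta = beta, vcov_model = vc_model,
         vcov_sandwich = vc_sand, shape = 1 / dispersion,
         dispersion = dispersion,
         loglik = as.numeric(stats::logLik(fit)),
         loglik_null = as.numeric(stats::logLik(null_fit)),
         n = length(y), n_clusters = length(unique(clusters)),
         iterations = fit$iter, converged = fit$converged,
         clusters = clusters),
    class = "gamma_cost_fit")
}

#' @export
print.gamma_cost_fit <- function(x, ...) {
  cat(sprintf("Gamma log-link cost model: n = %d, clusters = %d, shape = %.3f\n",
              x$n, x$n_clusters, x$shape))
  cat(sprintf("  intercept %0.2f EUR, pseudo-R2 %0.3f\n",
              exp(x$beta[[1]]), mcfadden_r2(x)))
  invisible(x)
}

#' Cluster-robust sandwich covariance
#'
#' Delegates to `sandwich::vcovCL`: meat from within-cluster sums of score
#' contributions, bread from the inverse information, with the G/(G-1)
#' small-sample cluster adjustment. With every cluster a singleton this is
#' the ordinary heteroskedasticity-robust estimator (up to n/(n-1)).
#'
#' @param fit A `glm` or `gamma_cost_fit`.
#' @param clusters Cluster id vector, one per observation.
#' @return Covariance matrix of the coefficients.
#' @export
sandwich_covariance <- function(fit, clusters) {
  if (inherits(fit, "gamma_cost_fit")) fit <- fit$glm
  k <- length(stats::coef(fit))
  g <- length(unique(clusters))
  if (g < k) {
    warning("fewer clusters (", g, ") than coefficients (", k,
            "); sandwich covariance may be deficient")
  }
  sandwich::vcovCL(fit, cluster = clusters)
}

#' McFadden's pseudo-R-squared
#'
#' `1 - loglik(model) / loglik(null)` from the stored log-likelihoods.
#'
#' @param fit A `gamma_cost_fit`.
#' @export
mcfadden_r2 <- function(fit) {
  if (fit$loglik_null == 0) stop("null log-likelihood is zero")
  1 - fit$loglik / fit$loglik_null
}

#' Exponentiated coefficient table with sandwich-based significance stars
#'
#' The intercept row is `exp(b0)`, the predicted one-year cost in euros for
#' the reference profile; other rows are exponentiated coefficients (cost
#' ratios). P-values come from the normal approximation on the log scale
#' using sandwich standard errors; stars: `**` p < 0.01, `*` p < 0.05.
#'
#' @param fit A `gamma_cost_fit`.
#' @return data.frame: term, estimate, se_log, p_value, stars.
#' @export
coefficient_table <- function(fit) {
  se <- sqrt(diag(fit$vcov_sandwich))
  z <- fit$beta / se
  p <- 2 * stats::pnorm(-abs(z))
  stars <- ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))
  data.frame(term = names(fit$beta), estimate = exp(fit$beta),
             se_log = se, p_value = p, stars = stars, row.names = NULL)
}

#' Predicted mean one-year cost for a covariate profile
#'
#' `exp(x'b)`: the intercept euros times the exponentiated coefficient of
#' every active covariate raised to its value. Covariates absent from the
#' profile sit at their reference value 0; unknown profile entries are an
#' error.
#'
#' @param fit A `gamma_cost_fit` or `published_cost_model`.
#' @param profile Named numeric vector / list of covariate values.
#' @return Predicted mean cost in euros.
#' @export
predict_mean <- function(fit, profile = c()) {
  beta <- if (inherits(fit, "gamma_cost_fit") ||
              inherits(fit, "published_cost_model")) fit$beta else fit
  profile <- unlist(profile)
  terms <- setdiff(names(beta), "(Intercept)")
  unknown <- setdiff(names(profile), terms)
  if (length(unknown) > 0) {
    stop("unknown covariate(s) in profile: ", paste(unknown, collapse = ", "))
  }
  x <- stats::setNames(numeric(length(terms)), terms)
  x[names(profile)] <- profile
  unname(exp(beta[["(Intercept)"]] + sum(beta[terms] * x)))
}

#' Average marginal effects on the euro scale
#'
#' For a continuous covariate j the AME is the sample mean of
#' `b_j * exp(x_i'b)` (the derivative of the mean under the log link); for
#' a binary covariate it is the mean counterfactual difference
#' `exp(x_i'b | x_j = 1) - exp(x_i'b | x_j = 0)`.
#'
#' @param fit A `gamma_cost_fit`.
#' @param X Design matrix (intercept first); defaults to the fitting design.
#' @return data.frame: term, ame_eur, type.
#' @export
average_marginal_effects <- function(fit, X = NULL) {
  if (is.null(X)) {
    X <- stats::model.matrix(fit$glm)
    colnames(X) <- names(fit$beta)
  }
  eta <- drop(X %*% fit$beta)
  mu <- exp(eta)
  terms <- setdiff(names(fit$beta), "(Intercept)")
  res <- lapply(terms, function(j) {
    xj <- X[, j]
    if (all(xj %in% c(0, 1))) {
      b <- fit$beta[[j]]
      mu0 <- exp(eta - b * xj)        # x_j forced to 0
      data.frame(term = j, ame_eur = mean(mu0 * exp(b) - mu0),
                 type = "binary")
    } else {
      data.frame(term = j, ame_eur = fit$beta[[j]] * mean(mu),
                 type = "continuous")
    }
  })
  do.call(rbind, res)
}

#' Fit all per-(class, episode type) models independently
#'
#' One gamma model per complication class and episode type present in the
#' data; a failing model (too few episodes, degenerate design) is recorded
#' and does not abort the others.
#'
#' @param episodes Included episodes with covariates and `year1_eur`.
#' @param min_n Minimum episodes required to attempt a fit.
#' @return list with `fits` (named list of `gamma_cost_fit` or NULL) and
#'   `fit_stats` (data.frame: model, n, n_clusters, pseudo-R², shape,
#'   converged, error).
#' @export
fit_complication_models <- function(episodes, min_n = 30) {
  keys <- expand.grid(class = complication_classes(),
                      episode_type = c("incident", "recurrent"),
                      stringsAsFactors = FALSE)
  fits <- list()
  stats_rows <- list()
  for (i in seq_len(nrow(keys))) {
    cls <- keys$class[i]; ty <- keys$episode_type[i]
    key <- paste(cls, ty, sep = ":")
    sub <- episodes[episodes$complication_class == cls &
                      episodes$episode_type == ty, , drop = FALSE]
    row <- data.frame(model = key, n = nrow(sub), n_clusters = NA_integer_,
                      mcfadden_r2 = NA_real_, shape = NA_real_,
                      converged = FALSE, error = NA_character_)
    fits[[key]] <- NULL
    if (nrow(sub) >= min_n) {
      res <- tryCatch({
        spec <- model_spec(cls, ty)
        des <- build_design(sub, spec)
        fit_gamma_glm(des$X, des$y, des$clusters)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        fits[[key]] <- res
        row$n <- res$n
        row$n_clusters <- res$n_clusters
        row$mcfadden_r2 <- mcfadden_r2(res)
        row$shape <- res$shape
        row$converged <- res$converged
      }
    } else {
      row$error <- sprintf("only %d episodes (min_n = %d)", nrow(sub), min_n)
    }
    stats_rows[[key]] <- row
  }
  list(fits = fits, fit_stats = do.call(rbind, c(stats_rows,
                                                 make.row.names = FALSE)))
}
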