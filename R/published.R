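#' Printed regression tables and cohort counts
#'
#' The exponentiated coefficient tables, per-class episode counts and
#' descriptive rows printed in the source study are shipped as plain-text
#' data so worked examples (reference-profile predictions, the crude
#' incidence rate, the class-count partition) can be recomputed from them.
#'
#' @name published
NULL

#' Read the printed coefficient tables
#' @return Long data.frame: episode_type, term, one column per class.
#' @export
published_model_tables <- function() {
  path <- system.file("extdata", "published_models.csv", package = "epicost",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a usable model object from a printed coefficient column
#'
#' Reconstructs a log-scale coefficient vector from the printed table of one
#' complication class and episode type: the intercept (euros) becomes
#' `log(intercept)`, every other printed value is an exponentiated
#' coefficient and becomes its log. A printed `NA` (covariate dropped for
#' zero variance) is treated as no effect.
#'
#' @param class One of [complication_classes()].
#' @param episode_type `"incident"` or `"recurrent"`.
#' @return Object of class `published_cost_model` with elements `beta`
#'   (named, log scale), `class`, `episode_type`, `n`, `mcfadden_r2`.
#' @export
published_model <- function(class, episode_type = c("incident", "recurrent")) {
  episode_type <- match.arg(episode_type)
  class <- match.arg(class, complication_classes())
  tab <- published_model_tables()
  tab <- tab[tab$episode_type == episode_type, c("term", class)]
  val <- stats::setNames(tab[[class]], tab$term)
  meta <- c("n", "mcfadden_r2")
  coef_terms <- setdiff(names(val), meta)
  beta <- log(ifelse(is.na(val[coef_terms]), 1, val[coef_terms]))
  names(beta) <- sub("^intercept_eur$", "(Intercept)", coef_terms)
  structure(
    list(beta = beta, class = class, episode_type = episode_type,
         n = unname(val["n"]), mcfadden_r2 = unname(val["mcfadden_r2"])),
    class = "published_cost_model")
}

#' @export
print.published_cost_model <- function(x, ...) {
  cat(sprintf("Printed gamma log-link cost model: %s, %s (n = %d)\n",
              x$class, x$episode_type, as.integer(x$n)))
  cat(sprintf("  intercept %0.2f EUR, %d covariates, pseudo-R2 %0.3f\n",
              exp(x$beta[["(Intercept)"]]), length(x$beta) - 1L, x$mcfadden_r2))
  invisible(x)
}

#' Read the printed per-class episode counts and person-years
#' @return Named numeric vector.
#' @export
published_counts <- function() {
  path <- system.file("extdata", "published_counts.csv", package = "epicost",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(d$value, d$quantity)
}

#' Read the printed descriptive rows (n and number of men per group)
#' @return data.frame with episode_type, complication_class, n, men_n and
#'   the printed percentage.
#' @export
published_descriptives <- function() {
  path <- system.file("extdata", "published_descriptives.csv",
                      package = "epicost", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
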