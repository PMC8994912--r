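#' End-to-end analysis pipeline
#'
#' `run_pipeline()` chains the whole analysis: obtain a registry (simulate
#' one or read a directory), map diagnosis codes to classes, build and
#' classify episodes, attach comorbidity flags and demographic covariates,
#' window and deflate costs, derive recurrence covariates, restrict to the
#' inclusion window, fit the twelve gamma cost models and emit the
#' descriptive and model tables, with an attrition log at every filtering
#' step.
#'
#' @name pipeline
NULL

#' Run the full pipeline
#'
#' @param input A [sim_config()] (a registry is simulated) or a directory
#'   path holding registry CSVs — exactly one source.
#' @param code_config Path to the code-map YAML.
#' @param inclusion_start,inclusion_end Inclusion window for episode index
#'   dates (inclusive).
#' @param episode_rule Episode grouping rule, see [build_episodes()].
#' @param history_scope Incident/recurrent history scope, see
#'   [classify_episodes()].
#' @param index A `price_index`; defaults to the simulated registry's own
#'   index, or an identity index over the years seen in the cost table.
#' @param out_dir If non-NULL, tables are written there as CSV
#'   (episodes.csv, episode_costs.csv, descriptives.csv,
#'   window_comparison.csv, models.csv, ame.csv, fit_stats.csv,
#'   attrition.csv).
#' @param min_n Minimum episodes per model.
#' @return list: `registry`, `episodes` (all, classified),
#'   `included` (modelling table), `models`, `fit_stats`, `tables`
#'   (descriptives, window_comparison, models, ame), `attrition`,
#'   `person_years`, `incidence_rate`.
#' @export
run_pipeline <- function(input,
                         code_config = default_code_config(),
                         inclusion_start = as.Date("2012-01-01"),
                         inclusion_end = as.Date("2016-12-31"),
                         episode_rule = c("from_index", "rolling_gap"),
                         history_scope = c("any_class", "same_class"),
                         index = NULL,
                         out_dir = NULL,
                         min_n = 30) {
  episode_rule <- match.arg(episode_rule)
  history_scope <- match.arg(history_scope)
  attrition <- list()
  note <- function(step, n) {
    attrition[[length(attrition) + 1L]] <<- data.frame(step = step, n = n)
    message(sprintf("pipeline: %-28s %d", step, n))
  }
  registry <- if (inherits(input, "sim_config")) {
    simulate_registry(input)
  } else if (is.character(input)) {
    read_registry(input)
  } else {
    stop("input must be a sim_config or a registry directory path")
  }
  if (is.null(index)) {
    index <- registry$price_index %||% {
      yrs <- unique(registry$costs$price_year)
      if (length(yrs) == 0) yrs <- 2019
      price_index(stats::setNames(rep(1, length(yrs)), sort(yrs)),
                  reference_year = 2019)
    }
  }
  maps <- load_code_maps(code_config)
  note("patients", nrow(registry$patients))
  note("patients_with_t2d",
       sum(!is.na(registry$patients$t2d_diagnosis_date)))
  note("diagnosis_events", nrow(registry$diagnoses))
  class_events <- extract_class_events(registry$diagnoses,
                                       maps$complication)
  note("complication_events", nrow(class_events))
  episodes <- build_all_episodes(class_events, rule = episode_rule)
  note("episodes_all", nrow(episodes))
  episodes <- classify_episodes(episodes, registry$patients,
                                history_scope = history_scope)
  note("episodes_diabetic",
       sum(episodes$episode_type %in% c("incident", "recurrent")))
  episodes <- episode_covariates(episodes, registry$patients)
  episodes <- flag_comorbidities(registry$diagnoses, episodes,
                                 maps$comorbidity)
  episodes <- window_costs(registry$costs, episodes, index)
  episodes <- add_recurrence_covariates(episodes)
  included <- filter_included(episodes, registry$patients,
                              inclusion_start, inclusion_end)
  note("episodes_included", nrow(included))
  py <- person_years(registry$patients, inclusion_start, inclusion_end)
  rate <- if (py > 0) incidence_rate(nrow(included), py) else NA_real_
  mod <- fit_complication_models(included, min_n = min_n)
  note("models_fit", sum(!vapply(mod$fits, is.null, logical(1))))
  tables <- list(
    descriptives = descriptive_table(included),
    window_comparison = window_comparison_table(included),
    models = models_table(mod$fits),
    ame = ame_table(mod$fits))
  attrition <- do.call(rbind, attrition)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE, na = "")
    ep_out <- episodes; ep_out$index_date <- format(ep_out$index_date)
    ep_out$last_member_date <- format(ep_out$last_member_date)
    wr(ep_out, "episodes.csv")
    cost_cols <- c("patient_id", "complication_class", "index_date",
                   "episode_type",
                   grep("_eur$|^year1_|^pre_year_|^year2_", names(ep_out),
                        value = TRUE))
    wr(ep_out[, unique(cost_cols)], "episode_costs.csv")
    wr(tables$descriptives, "descriptives.csv")
    wr(tables$window_comparison, "window_comparison.csv")
    wr(tables$models, "models.csv")
    wr(tables$ame, "ame.csv")
    wr(mod$fit_stats, "fit_stats.csv")
    wr(attrition, "attrition.csv")
  }
  invisible(list(registry = registry, episodes = episodes,
                 included = included, models = mod$fits,
                 fit_stats = mod$fit_stats, tables = tables,
                 attrition = attrition, person_years = py,
                 incidence_rate = rate, price_index = index))
}

group_stats <- function(sub) {
  ms <- function(v) c(mean = mean(v), sd = stats::sd(v))
  n <- nrow(sub)
  men <- sum(sub$woman == 0)
  age <- ms(sub$age_c75_per10 * 10 + 75)
  dur <- ms(sub$t2d_duration_per5 * 5)
  data.frame(
    n = n, age_mean = age["mean"], age_sd = age["sd"],
    men_n = men, men_pct = round(100 * men / n, 1),
    t2d_duration_mean = dur["mean"], t2d_duration_sd = dur["sd"],
    outpatient_visits_mean = mean(sub$year1_outpatient_visits),
    outpatient_visits_sd = stats::sd(sub$year1_outpatient_visits),
    inpatient_days_mean = mean(sub$year1_inpatient_days),
    inpatient_days_sd = stats::sd(sub$year1_inpatient_days),
    year1_cost_mean = mean(sub$year1_eur),
    year1_cost_sd = stats::sd(sub$year1_eur), row.names = NULL)
}

#' Descriptive table stratified by episode type and complication class
#'
#' One row per (episode type, class): n, mean (SD) age at index, number
#' and percentage of men, mean (SD) T2D duration, mean (SD) outpatient
#' visits and inpatient days in year 1, and mean (SD) one-year cost.
#' Within each episode type, classes are ordered by decreasing mean cost.
#' Empty groups keep `n = 0` with absent statistics; a single-episode
#' group has `NA` SDs.
#'
#' @param included Included episodes with covariates and windowed costs.
#' @return data.frame of descriptive rows.
#' @export
descriptive_table <- function(included) {
  rows <- list()
  for (ty in c("incident", "recurrent")) {
    for (cls in complication_classes()) {
      sub <- included[included$episode_type == ty &
                        included$complication_class == cls, , drop = FALSE]
      row <- if (nrow(sub) == 0L) {
        data.frame(n = 0L, age_mean = NA_real_, age_sd = NA_real_,
                   men_n = NA_integer_, men_pct = NA_real_,
                   t2d_duration_mean = NA_real_, t2d_duration_sd = NA_real_,
                   outpatient_visits_mean = NA_real_,
                   outpatient_visits_sd = NA_real_,
                   inpatient_days_mean = NA_real_,
                   inpatient_days_sd = NA_real_,
                   year1_cost_mean = NA_real_, year1_cost_sd = NA_real_)
      } else {
        group_stats(sub)
      }
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(episode_type = ty, complication_class = cls), row)
    }
  }
  out <- do.call(rbind, rows)
  o <- order(out$episode_type, -ifelse(is.na(out$year1_cost_mean), -Inf,
                                       out$year1_cost_mean))
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean costs in the pre, first and second year windows per group
#'
#' @param included Included episodes with windowed costs.
#' @return data.frame: episode_type, complication_class, n, mean cost per
#'   window.
#' @export
window_comparison_table <- function(included) {
  rows <- list()
  for (ty in c("incident", "recurrent")) {
    for (cls in complication_classes()) {
      sub <- included[included$episode_type == ty &
                        included$complication_class == cls, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        episode_type = ty, complication_class = cls, n = nrow(sub),
        pre_year_mean = if (nrow(sub)) mean(sub$pre_year_eur) else NA_real_,
        year1_mean = if (nrow(sub)) mean(sub$year1_eur) else NA_real_,
        year2_mean = if (nrow(sub)) mean(sub$year2_eur) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

models_table <- function(fits) {
  rows <- lapply(names(fits), function(key) {
    if (is.null(fits[[key]])) return(NULL)
    cbind(model = key, coefficient_table(fits[[key]]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(model = character(), term = character(),
                      estimate = numeric(), se_log = numeric(),
                      p_value = numeric(), stars = character())
  }
  out
}

ame_table <- function(fits) {
  rows <- lapply(names(fits), function(key) {
    if (is.null(fits[[key]])) return(NULL)
    cbind(model = key, average_marginal_effects(fits[[key]]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(model = character(), term = character(),
                      ame_eur = numeric(), type = character())
  }
  out
}
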