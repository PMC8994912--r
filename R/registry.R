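#' Synthetic hospital registry with known ground truth
#'
#' Generates patient, diagnosis and cost tables with the statistical
#' structure the downstream analysis assumes: per-class complication index
#' dates from a renewal process whose gaps exceed the episode window (so
#' the true episode structure is unambiguous), in-window repeat diagnoses
#' that must be absorbed into the same episode, comorbidity codes planted
#' in the two-year pre-index window, death within a year of an episode that
#' truncates all later history, and one-year episode costs drawn from a
#' gamma distribution whose log-mean is linear in the episode covariates.
#' A truth sidecar carries the planned episodes, their covariates and the
#' drawn costs, so recovery by the pipeline is checkable exactly.
#'
#' @name synthetic_registry
NULL

#' Simulation configuration
#'
#' Defaults follow the study conditions the analysis targets: a 1996-2017
#' event timeline with a 2012-2016 inclusion window, per-class episode
#' hazards proportional to the published per-class episode counts over the
#' published person-years, true log-scale coefficients equal to the log of
#' the published exponentiated coefficient tables, and gamma shape 2
#' (coefficient of variation ~0.71, a typical skew for one-year hospital
#' cost sums).
#'
#' @param n_patients Cohort size (> 0).
#' @param rng_seed Integer seed; the whole generator is deterministic in it.
#' @param study_start,study_end Event timeline (Dates).
#' @param p_female Probability a patient is female.
#' @param age_mean,age_sd Age (years) at the start of the inclusion era.
#' @param p_no_t2d Fraction of patients without a T2D diagnosis date.
#' @param p_in_catchment Fraction living in the catchment area.
#' @param class_hazards Named episodes/person-year rate per complication
#'   class.
#' @param max_repeats Max extra same-class diagnoses inside an episode.
#' @param comorbidity_prevalence Named per-episode probability that a
#'   comorbidity code of each class is planted in the pre-index window.
#' @param true_coefficients Named list `"<class>:<type>"` of log-scale
#'   coefficient vectors; default is the log of the printed tables.
#' @param gamma_shape Gamma shape of one-year episode costs (> 0).
#' @param p_death_1y Probability of death within one year of an episode.
#' @param frac_external Fraction of non-index diagnosis events recorded at
#'   other providers.
#' @param background_rate_per_year Poisson rate of non-episode cost records.
#' @param background_mean_eur Mean amount of a background cost record.
#' @param price_inflation Annual rate of the synthetic price index
#'   (deflation to 2019 euros is exercised when > 0).
#' @param gap_mode `"safe"` (renewal gaps strictly exceed the episode
#'   window) or `"adversarial"` (gaps straddle the window boundary, for
#'   stress-testing the episode builder).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 2000,
                       rng_seed = 1L,
                       study_start = as.Date("1996-01-01"),
                       study_end = as.Date("2017-12-31"),
                       p_female = 0.45,
                       age_mean = 66, age_sd = 13,
                       p_no_t2d = 0.02,
                       p_in_catchment = 0.95,
                       class_hazards = c(cerebrovascular = 0.0216,
                                         cardiovascular = 0.0703,
                                         nephropathy = 0.0097,
                                         foot_disorder = 0.0220,
                                         eye = 0.0300,
                                         neurological = 0.0035),
                       max_repeats = 3L,
                       comorbidity_prevalence = c(
                         myocardial_infarction = 0.05,
                         congestive_heart_failure = 0.10,
                         peripheral_vascular_disease = 0.06,
                         cerebrovascular_disease = 0.06,
                         dementia = 0.04,
                         chronic_pulmonary_disease = 0.08,
                         rheumatological_disease = 0.04,
                         peptic_ulcer_disease = 0.02,
                         any_chronic_liver_disease = 0.02,
                         diabetes_with_chronic_complications = 0.12,
                         moderate_severe_renal_disease = 0.07,
                         any_malignancy = 0.08),
                       true_coefficients = NULL,
                       gamma_shape = 2,
                       p_death_1y = 0.10,
                       frac_external = 0.10,
                       background_rate_per_year = 0.5,
                       background_mean_eur = 200,
                       price_inflation = 0.02,
                       gap_mode = c("safe", "adversarial")) {
  gap_mode <- match.arg(gap_mode)
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be a positive integer")
  }
  stopifnot(gamma_shape > 0,
            all(c(p_female, p_no_t2d, p_in_catchment, p_death_1y,
                  frac_external) >= 0),
            all(c(p_female, p_no_t2d, p_in_catchment, p_death_1y,
                  frac_external) <= 1),
            all(comorbidity_prevalence >= 0 & comorbidity_prevalence <= 1),
            all(class_hazards >= 0))
  miss <- setdiff(complication_classes(), names(class_hazards))
  if (length(miss) > 0) stop("class_hazards missing: ",
                             paste(miss, collapse = ", "))
  miss <- setdiff(comorbidity_classes(), names(comorbidity_prevalence))
  if (length(miss) > 0) stop("comorbidity_prevalence missing: ",
                             paste(miss, collapse = ", "))
  if (is.null(true_coefficients)) {
    true_coefficients <- list()
    for (cls in complication_classes()) {
      for (ty in c("incident", "recurrent")) {
        true_coefficients[[paste(cls, ty, sep = ":")]] <-
          published_model(cls, ty)$beta
      }
    }
  }
  structure(
    list(n_patients = as.integer(n_patients), rng_seed = as.integer(rng_seed),
         study_start = as.Date(study_start), study_end = as.Date(study_end),
         p_female = p_female, age_mean = age_mean, age_sd = age_sd,
         p_no_t2d = p_no_t2d, p_in_catchment = p_in_catchment,
         class_hazards = class_hazards[complication_classes()],
         max_repeats = as.integer(max_repeats),
         comorbidity_prevalence =
           comorbidity_prevalence[comorbidity_classes()],
         true_coefficients = true_coefficients, gamma_shape = gamma_shape,
         p_death_1y = p_death_1y, frac_external = frac_external,
         background_rate_per_year = background_rate_per_year,
         background_mean_eur = background_mean_eur,
         price_inflation = price_inflation, gap_mode = gap_mode),
    class = "sim_config")
}

#' Generate the patient cohort
#'
#' @param config A [sim_config()].
#' @return data.frame: `patient_id`, `sex`, `birth_date`,
#'   `t2d_diagnosis_date` (NA for a small non-diabetic fraction),
#'   `death_date` (NA here; set by [generate_event_history()]),
#'   `in_catchment`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$rng_seed)
  n <- config$n_patients
  era0 <- as.Date("2012-01-01")
  age <- pmin(95, pmax(35, stats::rnorm(n, config$age_mean, config$age_sd)))
  birth <- era0 - round(age * 365.25)
  onset_lo <- as.numeric(config$study_start)
  onset_hi <- as.numeric(min(config$study_end, as.Date("2016-12-31")))
  t2d <- as.Date(round(stats::runif(n, onset_lo, onset_hi)),
                 origin = "1970-01-01")
  t2d <- pmax(t2d, birth + 18 * 365)  # no childhood T2D onsets
  t2d[stats::runif(n) < config$p_no_t2d] <- NA
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    sex = ifelse(stats::runif(n) < config$p_female, "female", "male"),
    birth_date = birth,
    t2d_diagnosis_date = t2d,
    death_date = as.Date(rep(NA_real_, n), origin = "1970-01-01"),
    in_catchment = stats::runif(n) < config$p_in_catchment,
    stringsAsFactors = FALSE)
}

# Planned per-class index dates for one patient (renewal process).
plan_index_dates <- function(config, rate_py) {
  if (rate_py <= 0) return(numeric())
  t0 <- as.numeric(config$study_start)
  t1 <- as.numeric(config$study_end)
  rate_day <- rate_py / 365.25
  out <- numeric()
  t <- t0 + stats::rexp(1, rate_day)
  while (t <= t1) {
    out <- c(out, round(t))
    gap <- if (config$gap_mode == "safe") {
      EPISODE_WINDOW_DAYS + 1 + stats::rexp(1, rate_day)
    } else {
      EPISODE_WINDOW_DAYS + sample(-30:30, 1)
    }
    t <- t + gap
  }
  out
}

#' Generate diagnosis events and the ground-truth episode plan
#'
#' Per patient and class, index dates come from a renewal process with
#' inter-event gaps exceeding the episode window; each planned episode gets
#' 0 to `max_repeats` in-window repeat diagnoses of the same class (to be
#' absorbed, not to open new episodes). Comorbidity codes are planted in
#' the two-year pre-index window with the configured prevalences. Death
#' within one year of an episode is drawn per episode and truncates all
#' later events and episodes. Truth covariates (including comorbidity
#' flags) are recomputed from the planted events by a brute-force window
#' scan, so they are exactly what a correct builder should recover.
#'
#' @param config A [sim_config()].
#' @param patients Cohort from [generate_cohort()].
#' @return list: `events` (diagnosis table), `patients` (with `death_date`
#'   filled in), `truth` (planned episodes with covariates).
#' @export
generate_event_history <- function(config, patients) {
  set.seed(config$rng_seed + 1L)
  classes <- complication_classes()
  prefixes <- c(cerebrovascular = "CER", cardiovascular = "CAR",
                nephropathy = "NEP", foot_disorder = "FOO",
                eye = "EYE", neurological = "NEU")
  como_prefix <- c(myocardial_infarction = "CMMI",
                   congestive_heart_failure = "CMCHF",
                   peripheral_vascular_disease = "CMPVD",
                   cerebrovascular_disease = "CMCVD", dementia = "CMDEM",
                   chronic_pulmonary_disease = "CMPUL",
                   rheumatological_disease = "CMRHE",
                   peptic_ulcer_disease = "CMULC",
                   any_chronic_liver_disease = "CMLIV",
                   diabetes_with_chronic_complications = "CMDCC",
                   moderate_severe_renal_disease = "CMREN",
                   any_malignancy = "CMMAL")
  lookback_days <- round(15 * 365.25)
  ev_pid <- list(); ev_day <- list(); ev_code <- list(); ev_index <- list()
  tr <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    # 1. plan index dates per class, merge chronologically
    plan <- do.call(rbind, lapply(classes, function(cls) {
      d <- plan_index_dates(config, config$class_hazards[[cls]])
      if (length(d) == 0L) return(NULL)
      data.frame(class = cls, day = d)
    }))
    if (is.null(plan) || nrow(plan) == 0L) next
    plan <- plan[order(plan$day, plan$class), , drop = FALSE]
    # 2. death truncation: walk episodes in time order
    death_day <- Inf
    keep <- rep(TRUE, nrow(plan))
    for (j in seq_len(nrow(plan))) {
      if (plan$day[j] > death_day) { keep[j] <- FALSE; next }
      if (stats::runif(1) < config$p_death_1y && is.infinite(death_day)) {
        death_day <- plan$day[j] + sample(30:364, 1)
      }
    }
    plan <- plan[keep, , drop = FALSE]
    if (is.finite(death_day)) {
      patients$death_date[i] <- as.Date(death_day, origin = "1970-01-01")
    }
    if (nrow(plan) == 0L) next
    # 3. complication diagnosis events: index + in-window repeats
    for (j in seq_len(nrow(plan))) {
      d0 <- plan$day[j]
      n_rep <- sample(0:config$max_repeats, 1)
      reps <- if (n_rep > 0) {
        unique(d0 + sample(seq_len(EPISODE_WINDOW_DAYS - 1L), n_rep))
      } else numeric()
      reps <- reps[reps <= min(death_day, Inf)]
      days <- c(d0, reps)
      codes <- paste0(prefixes[[plan$class[j]]],
                      sprintf("%02d", sample(10:99, length(days),
                                             replace = TRUE)))
      ev_pid[[length(ev_pid) + 1L]] <- rep(pid, length(days))
      ev_day[[length(ev_day) + 1L]] <- days
      ev_code[[length(ev_code) + 1L]] <- codes
      ev_index[[length(ev_index) + 1L]] <- c(TRUE, rep(FALSE, length(days) - 1L))
    }
    # 4. plant comorbidity events in the pre-index window of each episode
    for (j in seq_len(nrow(plan))) {
      draw <- stats::runif(length(config$comorbidity_prevalence)) <
        config$comorbidity_prevalence
      if (any(draw)) {
        cls_hit <- names(config$comorbidity_prevalence)[draw]
        days <- plan$day[j] - sample(seq_len(COMORBIDITY_WINDOW_DAYS),
                                     length(cls_hit), replace = TRUE)
        days <- days[days <= death_day]
        cls_hit <- cls_hit[seq_along(days)]
        if (length(days) > 0) {
          ev_pid[[length(ev_pid) + 1L]] <- rep(pid, length(days))
          ev_day[[length(ev_day) + 1L]] <- days
          ev_code[[length(ev_code) + 1L]] <-
            paste0(como_prefix[cls_hit], sample(1:9, length(days),
                                                replace = TRUE))
          ev_index[[length(ev_index) + 1L]] <- rep(FALSE, length(days))
        }
      }
    }
    # 5. truth rows: type, priors, death flag (flags added after planting)
    t2d_day <- as.numeric(patients$t2d_diagnosis_date[i])
    for (j in seq_len(nrow(plan))) {
      d0 <- plan$day[j]
      in_horizon <- plan$day < d0 & plan$day >= d0 - lookback_days
      ty <- if (is.na(t2d_day)) "nondiabetic"
      else if (d0 < t2d_day) "prediabetic"
      else if (any(in_horizon)) "recurrent" else "incident"
      tr[[length(tr) + 1L]] <- data.frame(
        patient_id = pid, complication_class = plan$class[j],
        index_date = as.Date(d0, origin = "1970-01-01"),
        episode_type = ty,
        n_prior_same_class = sum(in_horizon & plan$class == plan$class[j]),
        n_prior_any_class = sum(in_horizon),
        died_within_1y = as.integer(is.finite(death_day) &&
                                      death_day >= d0 &&
                                      death_day < d0 + EPISODE_WINDOW_DAYS),
        stringsAsFactors = FALSE)
    }
  }
  if (length(tr) == 0L) {
    return(list(events = data.frame(patient_id = character(),
                                    event_date = as.Date(character()),
                                    code = character(),
                                    provider = character()),
                patients = patients,
                truth = data.frame()))
  }
  events <- data.frame(
    patient_id = unlist(ev_pid),
    event_date = as.Date(unlist(ev_day), origin = "1970-01-01"),
    code = unlist(ev_code),
    is_index = unlist(ev_index),
    stringsAsFactors = FALSE)
  events$provider <- ifelse(
    !events$is_index & stats::runif(nrow(events)) < config$frac_external,
    "other", "index_hospital")
  events$is_index <- NULL
  events <- events[order(events$patient_id, events$event_date, events$code), ]
  rownames(events) <- NULL
  truth <- do.call(rbind, tr)
  # demographic covariates + brute-force comorbidity flags from the events
  truth <- episode_covariates(truth, patients)
  como_map <- load_quiet_comorbidity_map()
  truth <- flag_comorbidities_bruteforce(events, truth, como_map)
  list(events = events, patients = patients, truth = truth)
}

load_quiet_comorbidity_map <- function() {
  suppressMessages(load_code_maps(default_code_config()))$comorbidity
}

# Independent, deliberately naive window scan used to stamp truth flags.
flag_comorbidities_bruteforce <- function(events, episodes, map,
                                          window_days = COMORBIDITY_WINDOW_DAYS) {
  for (cls in names(map)) episodes[[cls]] <- 0L
  for (i in seq_len(nrow(episodes))) {
    d0 <- as.numeric(episodes$index_date[i])
    sel <- events$patient_id == episodes$patient_id[i] &
      as.numeric(events$event_date) >= d0 - window_days &
      as.numeric(events$event_date) < d0
    for (code in events$code[sel]) {
      for (cls in classify_code(code, map)) episodes[[cls]][i] <- 1L
    }
  }
  episodes
}

#' Generate admission cost records from the episode plan
#'
#' Each planned episode's one-year total cost (2019 euros) is drawn from a
#' gamma distribution with mean `exp(x' beta_true)` (prediabetic and
#' non-diabetic episodes use the class's incident intercept alone) and the
#' configured shape, then split over 3-8 dated admission records inside
#' `[index, index + 365)` (truncated at death) across resource categories.
#' Record amounts are expressed in their accounting year's price level
#' (nominal euros), so deflation back to 2019 euros is exercised; the
#' deflated record sum of an episode equals the drawn cost exactly.
#' Low-intensity background (non-episode) records are added per patient.
#'
#' @param config A [sim_config()].
#' @param patients Cohort with death dates.
#' @param truth Episode plan from [generate_event_history()].
#' @return list: `costs` (cost record table), `truth` (with
#'   `high_prior_cost`, `true_mean_eur`, `drawn_cost_eur` added).
#' @export
generate_costs <- function(config, patients, truth) {
  set.seed(config$rng_seed + 2L)
  years <- seq(as.integer(format(config$study_start, "%Y")),
               as.integer(format(config$study_end, "%Y")) + 2L)
  pidx <- constant_inflation_index(years, config$price_inflation)
  cat_weights <- c(inpatient_ward_days = 0.45, outpatient_visits = 0.15,
                   surgical_procedures = 0.12, emergency_visits = 0.06,
                   laboratory = 0.08, medications = 0.08,
                   other_procedures = 0.04, other = 0.02)
  rows <- list()
  adm <- 0L
  n_ep <- if (is.null(truth) || nrow(truth) == 0L) 0L else nrow(truth)
  if (n_ep > 0L) {
    truth$high_prior_cost <- 0L
    truth$true_mean_eur <- NA_real_
    truth$drawn_cost_eur <- NA_real_
    o <- order(truth$patient_id, truth$complication_class, truth$index_date)
    prev_cost <- stats::setNames(
      rep(NA_real_, 0), character())
    for (i in o) {
      key <- paste(truth$patient_id[i], truth$complication_class[i])
      prev <- if (key %in% names(prev_cost)) prev_cost[[key]] else NA_real_
      truth$high_prior_cost[i] <- high_prior_cost_flag(prev)
      ty <- truth$episode_type[i]
      bt <- config$true_coefficients[[paste(truth$complication_class[i],
                                            if (ty == "recurrent")
                                              "recurrent" else "incident",
                                            sep = ":")]]
      if (ty %in% c("incident", "recurrent")) {
        x <- stats::setNames(numeric(length(bt)), names(bt))
        x[["(Intercept)"]] <- 1
        for (nm in setdiff(names(bt), "(Intercept)")) {
          x[[nm]] <- if (nm == "n_earlier_episodes") {
            truth$n_prior_same_class[i]
          } else truth[[nm]][i]
        }
        mu <- exp(sum(bt * x))
      } else {
        mu <- exp(bt[["(Intercept)"]])
      }
      total <- stats::rgamma(1, shape = config$gamma_shape,
                             scale = mu / config$gamma_shape)
      truth$true_mean_eur[i] <- mu
      truth$drawn_cost_eur[i] <- total
      prev_cost[[key]] <- total
      # split into dated admission records
      d0 <- as.numeric(truth$index_date[i])
      dd <- patients$death_date[match(truth$patient_id[i],
                                      patients$patient_id)]
      last_day <- min(d0 + EPISODE_WINDOW_DAYS - 1L,
                      if (is.na(dd)) Inf else as.numeric(dd))
      m <- sample(3:8, 1)
      share <- stats::rgamma(m, 1); share <- share / sum(share)
      days <- d0 + sort(sample(0:(last_day - d0), m, replace = TRUE))
      cats <- sample(names(cat_weights), m, replace = TRUE,
                     prob = cat_weights)
      units <- integer(m)
      units[cats == "inpatient_ward_days"] <-
        sample(1:7, sum(cats == "inpatient_ward_days"), replace = TRUE)
      units[cats == "outpatient_visits"] <- 1L
      yr <- as.integer(format(as.Date(days, origin = "1970-01-01"), "%Y"))
      adm <- adm + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = truth$patient_id[i],
        admission_id = sprintf("A%07d-%d", adm, seq_len(m)),
        accounting_date = as.Date(days, origin = "1970-01-01"),
        resource_category = cats,
        amount_eur = (total * share) / deflate(1, yr, pidx),
        price_year = yr, units = units, stringsAsFactors = FALSE)
    }
  }
  # background, non-episode costs at low intensity
  if (config$background_rate_per_year > 0) {
    span_y <- as.numeric(config$study_end - config$study_start) / 365.25
    for (i in seq_len(nrow(patients))) {
      end_day <- min(as.numeric(config$study_end),
                     if (is.na(patients$death_date[i])) Inf
                     else as.numeric(patients$death_date[i]))
      n_bg <- stats::rpois(1, config$background_rate_per_year * span_y)
      if (n_bg == 0L) next
      days <- round(stats::runif(n_bg, as.numeric(config$study_start),
                                 end_day))
      amt <- stats::rexp(n_bg, 1 / config$background_mean_eur)
      yr <- as.integer(format(as.Date(days, origin = "1970-01-01"), "%Y"))
      adm <- adm + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patients$patient_id[i],
        admission_id = sprintf("B%07d-%d", adm, seq_len(n_bg)),
        accounting_date = as.Date(days, origin = "1970-01-01"),
        resource_category = "other", amount_eur = amt / deflate(1, yr, pidx),
        price_year = yr, units = 0L, stringsAsFactors = FALSE)
    }
  }
  costs <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(patient_id = character(), admission_id = character(),
               accounting_date = as.Date(character()),
               resource_category = character(), amount_eur = numeric(),
               price_year = integer(), units = integer())
  }
  costs <- costs[order(costs$patient_id, costs$accounting_date), ]
  rownames(costs) <- NULL
  list(costs = costs, truth = truth)
}

#' Run the whole generator
#'
#' @param config A [sim_config()].
#' @return list: `patients`, `diagnoses`, `costs`, `truth`, `config`,
#'   `price_index`.
#' @export
simulate_registry <- function(config = sim_config()) {
  patients <- generate_cohort(config)
  hist <- generate_event_history(config, patients)
  cst <- generate_costs(config, hist$patients, hist$truth)
  years <- seq(as.integer(format(config$study_start, "%Y")),
               as.integer(format(config$study_end, "%Y")) + 2L)
  list(patients = hist$patients, diagnoses = hist$events,
       costs = cst$costs, truth = cst$truth, config = config,
       price_index = constant_inflation_index(years, config$price_inflation))
}
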