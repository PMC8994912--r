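#' Episode construction from dated diagnosis events
#'
#' A complication episode is anchored at an index event — the first
#' qualifying diagnosis of a class — and absorbs all repeat diagnoses of the
#' same class within one year (365 days) of the index. Episodes are then
#' classified as prediabetic (index before the T2D diagnosis), incident (no
#' prior complication history within the look-back horizon) or recurrent.
#'
#' @name episode_builder
NULL

EPISODE_WINDOW_DAYS <- 365L
COMORBIDITY_WINDOW_DAYS <- 730L

#' Extract per-(patient, class) sorted event-date streams
#'
#' Events whose code classifies into a complication class enter that class's
#' stream; an event matching several classes enters each. Same-day
#' duplicates within a stream collapse to one date.
#'
#' @param events data.frame with `patient_id`, `event_date` (Date), `code`.
#' @param map Complication `code_map`.
#' @return data.frame `patient_id`, `complication_class`, `event_date`,
#'   sorted within stream.
#' @export
extract_class_events <- function(events, map) {
  stopifnot(all(c("patient_id", "event_date", "code") %in% names(events)))
  if (nrow(events) == 0L) {
    return(data.frame(patient_id = character(), complication_class = character(),
                      event_date = as.Date(character())))
  }
  hits <- classify_codes_matrix(events$code, map)
  out <- do.call(rbind, lapply(colnames(hits), function(cls) {
    sel <- hits[, cls]
    if (!any(sel)) return(NULL)
    data.frame(patient_id = events$patient_id[sel],
               complication_class = cls,
               event_date = events$event_date[sel])
  }))
  if (is.null(out)) {
    return(data.frame(patient_id = character(), complication_class = character(),
                      event_date = as.Date(character())))
  }
  out <- unique(out)
  out[order(out$patient_id, out$complication_class, out$event_date), ,
      drop = FALSE]
}

#' Group sorted event dates into episodes
#'
#' Two grouping rules are available. `from_index` (default): the first date
#' opens an episode and every later date joins it while `date - index <
#' window_days`, otherwise it opens a new episode; consecutive index dates
#' are therefore at least `window_days` apart. `rolling_gap`: a date opens a
#' new episode when the gap since the *previous event* (not the index) is at
#' least `window_days`.
#'
#' @param dates Sorted, unique Date (or integer day) vector.
#' @param window_days Episode window length in days.
#' @param rule `"from_index"` or `"rolling_gap"`.
#' @return list with `index` (index dates), `episode` (integer episode id
#'   per input date, 1-based).
#' @export
build_episodes <- function(dates, window_days = EPISODE_WINDOW_DAYS,
                           rule = c("from_index", "rolling_gap")) {
  rule <- match.arg(rule)
  if (length(dates) == 0L) return(list(index = dates, episode = integer()))
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("dates must be sorted strictly ascending")
  }
  d <- as.numeric(dates)
  ep <- integer(length(d))
  ep[1L] <- 1L
  anchor <- d[1L]  # index date (from_index) or previous event (rolling_gap)
  for (i in seq_along(d)[-1L]) {
    if (d[i] - anchor < window_days) {
      ep[i] <- ep[i - 1L]
      if (rule == "rolling_gap") anchor <- d[i]
    } else {
      ep[i] <- ep[i - 1L] + 1L
      anchor <- d[i]
    }
  }
  list(index = dates[!duplicated(ep)], episode = ep)
}

#' Build episodes for every (patient, class) stream
#'
#' @param class_events Output of [extract_class_events()].
#' @inheritParams build_episodes
#' @return data.frame: one row per episode with `patient_id`,
#'   `complication_class`, `index_date`, `n_member_events` (repeat
#'   diagnoses absorbed, including the index), `last_member_date`.
#' @export
build_all_episodes <- function(class_events,
                               window_days = EPISODE_WINDOW_DAYS,
                               rule = c("from_index", "rolling_gap")) {
  rule <- match.arg(rule)
  if (nrow(class_events) == 0L) {
    return(data.frame(patient_id = character(), complication_class = character(),
                      index_date = as.Date(character()),
                      n_member_events = integer(),
                      last_member_date = as.Date(character())))
  }
  key <- interaction(class_events$patient_id, class_events$complication_class,
                     drop = TRUE)
  pieces <- lapply(split(class_events, key), function(s) {
    s <- s[order(s$event_date), , drop = FALSE]
    b <- build_episodes(s$event_date, window_days, rule)
    data.frame(patient_id = s$patient_id[1L],
               complication_class = s$complication_class[1L],
               index_date = b$index,
               n_member_events = as.integer(table(b$episode)),
               last_member_date = as.Date(tapply(as.numeric(s$event_date),
                                                 b$episode, max),
                                          origin = "1970-01-01"))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$patient_id, out$index_date, out$complication_class), ,
      drop = FALSE]
}

#' Classify episodes as prediabetic, incident or recurrent
#'
#' Prediabetic: index date before the patient's T2D diagnosis. Among
#' diabetic episodes, incident means no earlier episode within the look-back
#' horizon under the chosen history scope (`any_class` counts episodes of
#' every complication class, `same_class` only the episode's own class);
#' otherwise recurrent. Prediabetic episodes count toward the history.
#' Patients without a T2D diagnosis date get `episode_type = "nondiabetic"`
#' and are dropped by [filter_included()].
#'
#' @param episodes data.frame from [build_all_episodes()].
#' @param patients data.frame with `patient_id`, `t2d_diagnosis_date`.
#' @param lookback_years Look-back horizon for the history, in years.
#' @param history_scope `"any_class"` (default) or `"same_class"`.
#' @return episodes with `episode_type`, `n_prior_same_class`,
#'   `n_prior_any_class` added.
#' @export
classify_episodes <- function(episodes, patients, lookback_years = 15,
                              history_scope = c("any_class", "same_class")) {
  history_scope <- match.arg(history_scope)
  lookback_days <- round(lookback_years * 365.25)
  t2d <- patients$t2d_diagnosis_date[match(episodes$patient_id,
                                           patients$patient_id)]
  episodes <- episodes[order(episodes$patient_id, episodes$index_date,
                             episodes$complication_class), , drop = FALSE]
  n <- nrow(episodes)
  episodes$episode_type <- rep(NA_character_, n)
  episodes$n_prior_same_class <- integer(n)
  episodes$n_prior_any_class <- integer(n)
  if (n == 0L) return(episodes)
  for (rows in split(seq_len(n), episodes$patient_id)) {
    idx <- as.numeric(episodes$index_date[rows])
    cls <- episodes$complication_class[rows]
    pt2d <- t2d[rows[1L]]
    for (j in seq_along(rows)) {
      in_horizon <- idx < idx[j] & idx >= idx[j] - lookback_days
      same <- in_horizon & cls == cls[j]
      episodes$n_prior_same_class[rows[j]] <- sum(same)
      episodes$n_prior_any_class[rows[j]] <- sum(in_horizon)
      if (is.na(pt2d)) {
        episodes$episode_type[rows[j]] <- "nondiabetic"
      } else if (idx[j] < as.numeric(pt2d)) {
        episodes$episode_type[rows[j]] <- "prediabetic"
      } else {
        prior <- if (history_scope == "any_class") any(in_horizon) else any(same)
        episodes$episode_type[rows[j]] <- if (prior) "recurrent" else "incident"
      }
    }
  }
  episodes
}

#' Flag comorbidities in the two-year pre-index window
#'
#' A flag is set iff some event with a code of that comorbidity class falls
#' in the half-open window `[index - window_days, index)` — the index date
#' itself is excluded.
#'
#' @param events Full diagnosis event table (`patient_id`, `event_date`,
#'   `code`).
#' @param episodes Episode table with `patient_id`, `index_date`.
#' @param map Comorbidity `code_map`.
#' @param window_days Pre-index screening window, days.
#' @return episodes with one 0/1 column per comorbidity class appended.
#' @export
flag_comorbidities <- function(events, episodes, map,
                               window_days = COMORBIDITY_WINDOW_DAYS) {
  classes <- names(map)
  flags <- matrix(0L, nrow(episodes), length(classes),
                  dimnames = list(NULL, classes))
  if (nrow(episodes) > 0L && nrow(events) > 0L) {
    hits <- classify_codes_matrix(events$code, map)
    keep <- rowSums(hits) > 0
    ev <- data.frame(patient_id = events$patient_id[keep],
                     day = as.numeric(events$event_date[keep]))
    hits <- hits[keep, , drop = FALSE]
    by_pat <- split(seq_len(nrow(ev)), ev$patient_id)
    for (i in seq_len(nrow(episodes))) {
      rows <- by_pat[[as.character(episodes$patient_id[i])]]
      if (is.null(rows)) next
      d0 <- as.numeric(episodes$index_date[i])
      inw <- ev$day[rows] >= d0 - window_days & ev$day[rows] < d0
      if (any(inw)) {
        flags[i, ] <- as.integer(colSums(hits[rows[inw], , drop = FALSE]) > 0)
      }
    }
  }
  cbind(episodes, as.data.frame(flags))
}

#' Restrict to analysable episodes
#'
#' Keeps diabetic (incident or recurrent) episodes whose index date lies in
#' the inclusion window (both endpoints inclusive) and whose patient lives
#' in the catchment area.
#'
#' @param episodes Classified episode table.
#' @param patients Patient table with `in_catchment`.
#' @param window_start,window_end Inclusion window (Dates, inclusive).
#' @return Filtered episode table.
#' @export
filter_included <- function(episodes, patients, window_start, window_end) {
  catch <- patients$in_catchment[match(episodes$patient_id,
                                       patients$patient_id)]
  keep <- episodes$episode_type %in% c("incident", "recurrent") &
    episodes$index_date >= as.Date(window_start) &
    episodes$index_date <= as.Date(window_end) &
    !is.na(catch) & catch
  episodes[keep, , drop = FALSE]
}

#' Demographic and timing covariates for each episode
#'
#' Age at index is centred at 75 years and scaled to decades; T2D duration
#' at index is in 5-year units; `died_within_1y` flags death in
#' `[index, index + 365)`.
#'
#' @param episodes Episode table.
#' @param patients Patient table with `sex`, `birth_date`,
#'   `t2d_diagnosis_date`, `death_date`.
#' @return episodes with `woman`, `age_c75_per10`, `t2d_duration_per5`,
#'   `died_within_1y` added.
#' @export
episode_covariates <- function(episodes, patients) {
  m <- match(episodes$patient_id, patients$patient_id)
  idx <- as.numeric(episodes$index_date)
  episodes$woman <- as.integer(patients$sex[m] == "female")
  episodes$age_c75_per10 <-
    ((idx - as.numeric(patients$birth_date[m])) / 365.25 - 75) / 10
  episodes$t2d_duration_per5 <-
    (idx - as.numeric(patients$t2d_diagnosis_date[m])) / 365.25 / 5
  dd <- as.numeric(patients$death_date[m])
  episodes$died_within_1y <-
    as.integer(!is.na(dd) & dd >= idx & dd < idx + EPISODE_WINDOW_DAYS)
  episodes
}

#' Person-years of follow-up over a calendar window
#'
#' Each patient contributes from `max(window start, T2D diagnosis)` to
#' `min(window end, death)`, in 365.25-day years; patients without a T2D
#' diagnosis or outside the catchment area contribute nothing.
#'
#' @param patients Patient table.
#' @param window_start,window_end Follow-up window (Dates, inclusive).
#' @return Total person-years (numeric scalar).
#' @export
person_years <- function(patients, window_start, window_end) {
  entry <- pmax(as.numeric(as.Date(window_start)),
                as.numeric(patients$t2d_diagnosis_date))
  exit <- as.numeric(as.Date(window_end))
  exit <- ifelse(is.na(patients$death_date), exit,
                 pmin(exit, as.numeric(patients$death_date)))
  py <- pmax(0, exit - entry) / 365.25
  py[is.na(py) | !patients$in_catchment] <- 0
  sum(py)
}

#' Crude incidence rate per 100 person-years
#'
#' @param n_episodes Episode count.
#' @param person_years Person-years at risk (> 0).
#' @return Rate per 100 person-years, rounded to one decimal.
#' @export
incidence_rate <- function(n_episodes, person_years) {
  if (person_years <= 0) stop("person_years must be positive")
  round(100 * n_episodes / person_years, 1)
}
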