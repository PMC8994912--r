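#' Cost deflation and episode windowing
#'
#' Admission costs are time-stamped to their accounting/discharge date,
#' deflated to reference-year (2019) euros, and summed into three half-open
#' windows around each episode: the year preceding the index
#' (`[index - 365, index)`), the first year (`[index, index + 365)`, the
#' primary outcome) and the second year (`[index + 365, index + 730)`).
#'
#' @name cost_attribution
NULL

RESOURCE_CATEGORIES <- c("inpatient_ward_days", "outpatient_visits",
                         "surgical_procedures", "emergency_visits",
                         "laboratory", "medications", "other_procedures",
                         "other")

#' Construct a health-care price index
#'
#' @param deflators Numeric vector, names = calendar years; each value
#'   multiplies that year's euros into reference-year euros.
#' @param reference_year Year whose deflator must be 1.
#' @return Named numeric vector of class `price_index`.
#' @export
price_index <- function(deflators, reference_year = 2019) {
  stopifnot(is.numeric(deflators), !is.null(names(deflators)),
            all(deflators > 0))
  ref <- as.character(reference_year)
  if (ref %in% names(deflators) &&
      abs(deflators[[ref]] - 1) > 1e-12) {
    stop("reference year ", reference_year, " must have deflator 1")
  }
  structure(deflators, class = "price_index", reference_year = reference_year)
}

#' Constant-inflation price index covering a year range
#'
#' Deflator for year y is `(1 + annual_rate)^(reference_year - y)`.
#'
#' @param years Integer vector of calendar years to cover.
#' @param annual_rate Annual health-care price inflation rate.
#' @param reference_year Reference price year.
#' @export
constant_inflation_index <- function(years, annual_rate = 0.02,
                                     reference_year = 2019) {
  defl <- (1 + annual_rate)^(reference_year - years)
  price_index(stats::setNames(defl, years), reference_year)
}

#' Deflate an amount to reference-year euros
#'
#' @param amount Amount(s) in `price_year` euros.
#' @param price_year Calendar year(s) of the amounts.
#' @param index A `price_index` covering every `price_year`.
#' @return Amounts in reference-year euros.
#' @export
deflate <- function(amount, price_year, index) {
  key <- as.character(price_year)
  miss <- setdiff(unique(key), names(index))
  if (length(miss) > 0) {
    stop("price index has no deflator for year(s) ",
         paste(miss, collapse = ", "), "; covered: ",
         paste(names(index), collapse = ", "))
  }
  unname(amount * unclass(index)[key])
}

#' Sum deflated costs into the three episode windows
#'
#' Each cost record is assigned by accounting date to exactly one of the
#' half-open windows pre (`[index-365, index)`), year 1
#' (`[index, index+365)`) or year 2 (`[index+365, index+730)`); records
#' outside all three are ignored. Amounts are deflated before summing and a
#' per-resource-category breakdown of each window is kept, together with
#' summed units (days/visits) for inpatient ward days and outpatient visits
#' in year 1.
#'
#' @param costs data.frame: `patient_id`, `accounting_date` (Date),
#'   `resource_category`, `amount_eur`, `price_year`, optionally `units`.
#' @param episodes Episode table with `patient_id`, `index_date`.
#' @param index A `price_index`.
#' @param window_days Window length in days.
#' @return episodes with `pre_year_eur`, `year1_eur`, `year2_eur`, one
#'   `<window>_<category>` column per resource category, and
#'   `year1_inpatient_days`, `year1_outpatient_visits` unit sums.
#' @export
window_costs <- function(costs, episodes, index,
                         window_days = EPISODE_WINDOW_DAYS) {
  wins <- c("pre_year", "year1", "year2")
  cat_cols <- as.vector(outer(wins, RESOURCE_CATEGORIES, paste, sep = "_"))
  for (col in c(paste0(wins, "_eur"), cat_cols,
                "year1_inpatient_days", "year1_outpatient_visits")) {
    episodes[[col]] <- rep(0, nrow(episodes))
  }
  if (nrow(costs) == 0L || nrow(episodes) == 0L) return(episodes)
  if (is.null(costs$units)) costs$units <- 0
  costs$real_eur <- deflate(costs$amount_eur, costs$price_year, index)
  costs$day <- as.numeric(costs$accounting_date)
  by_pat <- split(costs, costs$patient_id)
  cat_idx <- match(RESOURCE_CATEGORIES, RESOURCE_CATEGORIES)
  for (i in seq_len(nrow(episodes))) {
    cc <- by_pat[[as.character(episodes$patient_id[i])]]
    if (is.null(cc)) next
    d0 <- as.numeric(episodes$index_date[i])
    off <- cc$day - d0
    win <- rep(NA_character_, nrow(cc))
    win[off >= -window_days & off < 0] <- "pre_year"
    win[off >= 0 & off < window_days] <- "year1"
    win[off >= window_days & off < 2 * window_days] <- "year2"
    for (w in wins) {
      sel <- !is.na(win) & win == w
      if (!any(sel)) next
      episodes[[paste0(w, "_eur")]][i] <- sum(cc$real_eur[sel])
      tot <- tapply(cc$real_eur[sel], factor(cc$resource_category[sel],
                                             RESOURCE_CATEGORIES), sum)
      tot[is.na(tot)] <- 0
      episodes[i, paste0(w, "_", RESOURCE_CATEGORIES)] <- as.numeric(tot)
    }
    y1 <- !is.na(win) & win == "year1"
    episodes$year1_inpatient_days[i] <-
      sum(cc$units[y1 & cc$resource_category == "inpatient_ward_days"])
    episodes$year1_outpatient_visits[i] <-
      sum(cc$units[y1 & cc$resource_category == "outpatient_visits"])
  }
  episodes
}

#' Approximate external-provider costs from treatment days and unit prices
#'
#' @param days_by_category Named numeric vector: treatment days (or visit
#'   counts) per category.
#' @param unit_prices Named numeric vector: published unit price per
#'   category-day.
#' @return Total imputed cost in euros.
#' @export
impute_external_costs <- function(days_by_category, unit_prices) {
  if (length(days_by_category) == 0L) return(0)
  miss <- setdiff(names(days_by_category), names(unit_prices))
  if (length(miss) > 0) {
    stop("no unit price for category(ies): ", paste(miss, collapse = ", "))
  }
  sum(days_by_category * unit_prices[names(days_by_category)])
}

#' Indicator for an exceptionally expensive previous episode
#'
#' 1 iff the previous same-class episode's one-year cost strictly exceeds
#' the threshold; 0 when there is no previous episode.
#'
#' @param previous_year1_eur Previous episode's year-1 cost (NA if none).
#' @param threshold Cut point in euros.
#' @return Integer 0/1 vector.
#' @export
high_prior_cost_flag <- function(previous_year1_eur, threshold = 50000) {
  as.integer(!is.na(previous_year1_eur) & previous_year1_eur > threshold)
}

#' Add recurrence covariates from each episode's same-class predecessor
#'
#' Orders episodes within (patient, class) by index date and derives
#' `high_prior_cost` from the immediately preceding episode's year-1 cost.
#'
#' @param episodes Episode table with `year1_eur` already attached.
#' @param threshold Euro cut point passed to [high_prior_cost_flag()].
#' @return episodes with `high_prior_cost` added.
#' @export
add_recurrence_covariates <- function(episodes, threshold = 50000) {
  episodes$high_prior_cost <- rep(0L, nrow(episodes))
  if (nrow(episodes) == 0L) return(episodes)
  o <- order(episodes$patient_id, episodes$complication_class,
             episodes$index_date)
  key <- paste(episodes$patient_id, episodes$complication_class)[o]
  prev <- c(NA, episodes$year1_eur[o][-length(o)])
  prev[c(TRUE, key[-1] != key[-length(key)])] <- NA
  episodes$high_prior_cost[o] <- high_prior_cost_flag(prev, threshold)
  episodes
}

#' Empirical percentile rank of a cost threshold
#'
#' Diagnostic for the fixed high-cost cut point: where the threshold sits in
#' the observed year-1 cost distribution, using the linear-interpolation
#' convention that inverts the type-7 sample quantile (ties averaged).
#'
#' @param year1_costs Non-empty numeric vector of one-year costs.
#' @param threshold Euro threshold.
#' @return Percentile in `[0, 100]`.
#' @export
threshold_percentile_check <- function(year1_costs, threshold) {
  if (length(year1_costs) == 0L) stop("year1_costs must be non-empty")
  x <- sort(year1_costs)
  if (threshold >= x[length(x)]) return(100)
  if (threshold <= x[1L]) return(0)
  p <- seq(0, 1, length.out = length(x))
  100 * stats::approx(x, p, xout = threshold, ties = mean)$y
}
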