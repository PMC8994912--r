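# Independent oracles used across tests: deliberately naive formulations,
# kept separate from the implementations they check.

# Double loop over (class, pattern) pairs.
oracle_classify <- function(code, map) {
  norm <- function(x) gsub(".", "", toupper(x), fixed = TRUE)
  code <- norm(code)
  hits <- character()
  for (cls in names(map)) {
    for (p in map[[cls]]) {
      if (substr(code, 1, nchar(norm(p))) == norm(p)) {
        hits <- c(hits, cls)
        break
      }
    }
  }
  hits
}

# From-index rule by repeated min-search: the next index is the earliest
# date at least `window` after the current index.
oracle_from_index <- function(days, window = 365) {
  idx <- numeric()
  remaining <- sort(days)
  while (length(remaining) > 0) {
    idx <- c(idx, remaining[1])
    remaining <- remaining[remaining >= remaining[1] + window]
  }
  idx
}

# Rolling-gap rule by splitting at consecutive gaps >= window.
oracle_rolling_gap <- function(days, window = 365) {
  d <- sort(days)
  brk <- c(TRUE, diff(d) >= window)
  d[brk]
}

random_day_set <- function(max_n = 8, span = 2000) {
  n <- sample(1:max_n, 1)
  sort(sample(0:span, n))
}

# Minimal hand-built registry for boundary tests.
tiny_patients <- function(n = 1, t2d = as.Date("2000-01-01"),
                          death = as.Date(NA)) {
  data.frame(patient_id = sprintf("P%02d", seq_len(n)), sex = "male",
             birth_date = as.Date("1940-06-15"),
             t2d_diagnosis_date = t2d, death_date = death,
             in_catchment = TRUE, stringsAsFactors = FALSE)
}

identity_index <- function(years = 1996:2019) {
  price_index(stats::setNames(rep(1, length(years)), years))
}

cost_rec <- function(pid, dates, amounts, category = "other",
                     years = NULL, units = 0) {
  data.frame(patient_id = pid, admission_id = paste0("A", seq_along(dates)),
             accounting_date = as.Date(dates),
             resource_category = category, amount_eur = amounts,
             price_year = years %||% as.integer(format(as.Date(dates), "%Y")),
             units = units, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gamma design + response generator for direct model-recovery checks.
gamma_design_sim <- function(n, beta, shape = 2) {
  X <- cbind(`(Intercept)` = 1,
             woman = stats::rbinom(n, 1, 0.45),
             age_c75_per10 = stats::rnorm(n, 0, 1),
             t2d_duration_per5 = stats::rgamma(n, 2, 1),
             died_within_1y = stats::rbinom(n, 1, 0.1))
  X <- X[, seq_along(beta), drop = FALSE]
  mu <- exp(drop(X %*% beta))
  list(X = X, y = stats::rgamma(n, shape = shape, scale = mu / shape))
}
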