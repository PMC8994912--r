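#' Write and read a registry directory
#'
#' The registry is exchanged as flat CSV with ISO-8601 dates and empty
#' cells for absent values: `patients.csv`, `diagnoses.csv`, `costs.csv`,
#' plus the ground-truth sidecar `truth.csv` and the generating config
#' echoed to `config_used.yaml` (seed included) when present.
#'
#' @name registry_io
NULL

REGISTRY_SCHEMAS <- list(
  patients = list(file = "patients.csv",
                  cols = c("patient_id", "sex", "birth_date",
                           "t2d_diagnosis_date", "death_date",
                           "in_catchment"),
                  dates = c("birth_date", "t2d_diagnosis_date",
                            "death_date")),
  diagnoses = list(file = "diagnoses.csv",
                   cols = c("patient_id", "event_date", "code", "provider"),
                   dates = "event_date"),
  costs = list(file = "costs.csv",
               cols = c("patient_id", "admission_id", "accounting_date",
                        "resource_category", "amount_eur", "price_year"),
               dates = "accounting_date"))

#' Write registry tables to a directory
#'
#' @param registry list with `patients`, `diagnoses`, `costs`, optionally
#'   `truth` and `config`.
#' @param directory Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_registry <- function(registry, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(REGISTRY_SCHEMAS)) {
    tab <- registry[[nm]]
    stopifnot(!is.null(tab))
    for (dc in intersect(REGISTRY_SCHEMAS[[nm]]$dates, names(tab))) {
      tab[[dc]] <- format(tab[[dc]], "%Y-%m-%d")
    }
    utils::write.csv(tab, file.path(directory, REGISTRY_SCHEMAS[[nm]]$file),
                     row.names = FALSE, na = "")
  }
  if (!is.null(registry$truth) && nrow(registry$truth) > 0) {
    tr <- registry$truth
    tr$index_date <- format(tr$index_date, "%Y-%m-%d")
    utils::write.csv(tr, file.path(directory, "truth.csv"),
                     row.names = FALSE, na = "")
  }
  if (!is.null(registry$config)) {
    cfg <- registry$config
    echo <- lapply(unclass(cfg), function(v) {
      if (inherits(v, "Date")) format(v, "%Y-%m-%d")
      else if (is.list(v)) lapply(v, as.list)
      else if (!is.null(names(v))) as.list(v)
      else v
    })
    yaml::write_yaml(echo, file.path(directory, "config_used.yaml"))
  }
  invisible(directory)
}

#' Read registry tables from a directory
#'
#' Validates that every required column is present, naming the column and
#' file otherwise; parses ISO dates and empty cells as NA.
#'
#' @param directory Directory holding the registry CSVs.
#' @return list with `patients`, `diagnoses`, `costs`, and `truth` when the
#'   sidecar exists.
#' @export
read_registry <- function(directory) {
  out <- list()
  for (nm in names(REGISTRY_SCHEMAS)) {
    sch <- REGISTRY_SCHEMAS[[nm]]
    path <- file.path(directory, sch$file)
    if (!file.exists(path)) stop("registry file missing: ", path)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(sch$cols, names(tab))
    if (length(miss) > 0) {
      stop(sch$file, ": missing required column(s): ",
           paste(miss, collapse = ", "))
    }
    for (dc in sch$dates) tab[[dc]] <- as.Date(tab[[dc]])
    out[[nm]] <- tab
  }
  tp <- file.path(directory, "truth.csv")
  if (file.exists(tp)) {
    tr <- utils::read.csv(tp, stringsAsFactors = FALSE)
    tr$index_date <- as.Date(tr$index_date)
    out$truth <- tr
  }
  out
}
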