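#' Complication and comorbidity code maps
#'
#' Diagnosis codes are mapped onto six diabetic complication classes and onto
#' a modified set of Charlson comorbidity classes. The modification drops
#' HIV/AIDS, hemiplegia/paraplegia and uncomplicated diabetes (everyone in
#' the cohort has type 2 diabetes), merges the two liver classes into
#' `any_chronic_liver_disease` and the two malignancy classes into
#' `any_malignancy`, and keeps `diabetes_with_chronic_complications`.
#'
#' @name code_maps
NULL

#' The six complication classes
#' @return Character vector of class names, fixed order.
#' @export
complication_classes <- function() {
  c("cerebrovascular", "cardiovascular", "nephropathy",
    "foot_disorder", "eye", "neurological")
}

#' The modified Charlson comorbidity classes
#' @return Character vector of the 12 retained class names.
#' @export
comorbidity_classes <- function() {
  c("myocardial_infarction", "congestive_heart_failure",
    "peripheral_vascular_disease", "cerebrovascular_disease", "dementia",
    "chronic_pulmonary_disease", "rheumatological_disease",
    "peptic_ulcer_disease", "any_chronic_liver_disease",
    "diabetes_with_chronic_complications", "moderate_severe_renal_disease",
    "any_malignancy")
}

normalize_code <- function(x) gsub(".", "", toupper(x), fixed = TRUE)

new_code_map <- function(entries, expected_classes, kind) {
  if (!is.list(entries) || is.null(names(entries))) {
    stop(kind, ": entries must be a named list of pattern vectors")
  }
  unknown <- setdiff(names(entries), expected_classes)
  if (length(unknown) > 0) {
    stop(kind, ": unknown class name(s): ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(expected_classes, names(entries))
  if (length(missing) > 0) {
    stop(kind, ": missing class(es): ", paste(missing, collapse = ", "))
  }
  entries <- entries[expected_classes]
  entries <- lapply(entries, function(p) {
    p <- as.character(unlist(p))
    if (any(!nzchar(p))) stop(kind, ": empty pattern string")
    normalize_code(p)
  })
  for (cls in names(entries)) {
    dup <- unique(entries[[cls]][duplicated(entries[[cls]])])
    if (length(dup) > 0) {
      stop(kind, ": duplicate pattern(s) under ", cls, ": ",
           paste(dup, collapse = ", "))
    }
  }
  structure(entries, class = "code_map", kind = kind)
}

#' Load complication and comorbidity code maps from a YAML config
#'
#' The config has two top-level sections, `complication_codes` and
#' `comorbidity_codes`, each mapping a class name to a list of code
#' patterns. A pattern matches a code exactly or as a prefix; matching is
#' case-insensitive and ignores the ICD-10 dot, so pattern `"I63"` matches
#' `"I63.9"`.
#'
#' @param config_path Path to the YAML file.
#' @return List with elements `complication` and `comorbidity`, each a
#'   validated `code_map`.
#' @export
load_code_maps <- function(config_path) {
  if (!file.exists(config_path)) stop("config file not found: ", config_path)
  cfg <- yaml::read_yaml(config_path)
  for (section in c("complication_codes", "comorbidity_codes")) {
    if (is.null(cfg[[section]])) stop("config missing section: ", section)
  }
  comp <- new_code_map(cfg$complication_codes, complication_classes(),
                       "complication_codes")
  como <- new_code_map(cfg$comorbidity_codes, comorbidity_classes(),
                       "comorbidity_codes")
  message(sprintf("loaded code maps: %d complication patterns, %d comorbidity patterns",
                  sum(lengths(comp)), sum(lengths(como))))
  list(complication = comp, comorbidity = como)
}

#' Classify a diagnosis code against a code map
#'
#' A class is returned iff one of its patterns equals the normalized code or
#' is a prefix of it. Unmatched codes yield an empty character vector.
#'
#' @param code Non-empty code string.
#' @param map A `code_map`.
#' @return Character vector (possibly empty) of matching class names.
#' @export
classify_code <- function(code, map) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  code <- normalize_code(code)
  hit <- vapply(map, function(patterns) {
    any(startsWith(code, patterns))
  }, logical(1))
  names(map)[hit]
}

#' Vectorised code classification
#'
#' Returns, for each code, the single-class label used by the episode
#' builder's event streams: codes are matched against every pattern and a
#' logical matrix (codes x classes) is produced.
#'
#' @param codes Character vector of codes.
#' @param map A `code_map`.
#' @return Logical matrix with one row per code, one column per class.
#' @export
classify_codes_matrix <- function(codes, map) {
  codes <- normalize_code(codes)
  out <- vapply(map, function(patterns) {
    if (length(patterns) == 0L) return(rep(FALSE, length(codes)))
    m <- rep(FALSE, length(codes))
    for (p in patterns) m <- m | startsWith(codes, p)
    m
  }, logical(length(codes)))
  if (length(codes) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(map)))
  out
}

#' Path to the synthetic code-map config shipped with the package
#' @return File path.
#' @export
default_code_config <- function() {
  system.file("extdata", "codes_synthetic.yaml", package = "epicost",
              mustWork = TRUE)
}
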