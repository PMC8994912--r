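default_maps <- suppressMessages(load_code_maps(default_code_config()))

test_that("build_episodes follows the from-index and rolling-gap rules", {
  expect_equal(build_episodes(c(0))$index, 0)
  b <- build_episodes(c(0, 100, 400))
  expect_equal(b$index, c(0, 400))
  expect_equal(b$episode, c(1L, 1L, 2L))
  # the two clauses disagree on {0, 300, 600}: from-index splits at 600,
  # a rolling gap never sees a 365-day silence
  expect_equal(build_episodes(c(0, 300, 600))$index,
               oracle_from_index(c(0, 300, 600)))
  expect_equal(build_episodes(c(0, 300, 600))$index, c(0, 600))
  expect_equal(build_episodes(c(0, 300, 600), rule = "rolling_gap")$index,
               oracle_rolling_gap(c(0, 300, 600)))
  expect_equal(build_episodes(c(0, 300, 600), rule = "rolling_gap")$index, 0)
  expect_error(build_episodes(c(5, 1)), "sorted")
})

test_that("both episode rules match their brute-force oracles on random sets", {
  set.seed(202)
  for (i in 1:200) {
    d <- random_day_set()
    expect_equal(build_episodes(d)$index, oracle_from_index(d))
    expect_equal(build_episodes(d, rule = "rolling_gap")$index,
                 oracle_rolling_gap(d))
    # partition property: every date belongs to exactly one episode
    expect_length(build_episodes(d)$episode, length(d))
  }
})

test_that("class streams collect, dedupe and split events correctly", {
  ev <- data.frame(
    patient_id = "P01",
    event_date = as.Date(c("2014-01-01", "2014-01-01", "2014-03-01")),
    code = c("CER11", "CER12", "EYE20"))
  ce <- extract_class_events(ev, default_maps$complication)
  expect_equal(nrow(ce[ce$complication_class == "cerebrovascular", ]), 1L)
  expect_equal(nrow(ce[ce$complication_class == "eye", ]), 1L)
  # an event matching two classes appears in both streams
  two <- list(cerebrovascular = "I6", cardiovascular = "I63",
              nephropathy = "N", foot_disorder = "F", eye = "H",
              neurological = "G")
  map2 <- suppressMessages(
    load_code_maps({
      p <- tempfile(fileext = ".yaml")
      como <- stats::setNames(as.list(paste0("X", 1:12)),
                              comorbidity_classes())
      yaml::write_yaml(list(complication_codes = two,
                            comorbidity_codes = como), p)
      p
    }))$complication
  ev2 <- data.frame(patient_id = "P01",
                    event_date = as.Date("2014-01-01"), code = "I639")
  ce2 <- extract_class_events(ev2, map2)
  expect_setequal(ce2$complication_class,
                  c("cerebrovascular", "cardiovascular"))
})

test_that("episode count is invariant to input event order", {
  set.seed(7)
  ev <- data.frame(
    patient_id = sample(c("P01", "P02"), 30, TRUE),
    event_date = as.Date("2010-01-01") + sample(0:2000, 30, TRUE),
    code = paste0(sample(c("CER", "EYE"), 30, TRUE), 10:39))
  ep1 <- build_all_episodes(extract_class_events(ev, default_maps$complication))
  ep2 <- build_all_episodes(extract_class_events(ev[sample(30), ],
                                                 default_maps$complication))
  expect_equal(ep1, ep2)
})

test_that("episode typing honours T2D timing and the history scope", {
  pats <- tiny_patients(t2d = as.Date("2010-01-01"))
  ep <- data.frame(patient_id = "P01",
                   complication_class = c("cardiovascular", "eye"),
                   index_date = as.Date(c("2012-01-01", "2013-06-01")))
  any_scope <- classify_episodes(ep, pats, history_scope = "any_class")
  same_scope <- classify_episodes(ep, pats, history_scope = "same_class")
  expect_equal(any_scope$episode_type, c("incident", "recurrent"))
  expect_equal(same_scope$episode_type, c("incident", "incident"))
  expect_equal(any_scope$n_prior_any_class, c(0L, 1L))
  expect_equal(any_scope$n_prior_same_class, c(0L, 0L))
  # before the T2D diagnosis the episode is prediabetic under either scope
  ep$index_date[1] <- as.Date("2005-01-01")
  expect_equal(classify_episodes(ep, pats)$episode_type[1], "prediabetic")
  expect_equal(classify_episodes(ep, pats,
                                 history_scope = "same_class")$episode_type[1],
               "prediabetic")
  # a prediabetic predecessor still counts toward the history
  expect_equal(classify_episodes(ep, pats)$episode_type[2], "recurrent")
  # no T2D diagnosis: episodes flagged nondiabetic, excluded downstream
  pats$t2d_diagnosis_date <- as.Date(NA)
  nd <- classify_episodes(ep, pats)
  expect_true(all(nd$episode_type == "nondiabetic"))
  expect_equal(nrow(filter_included(nd, pats, "2000-01-01", "2020-12-31")),
               0L)
})

test_that("prior episodes beyond the look-back horizon do not recur", {
  pats <- tiny_patients(t2d = as.Date("1980-01-01"))
  ep <- data.frame(patient_id = "P01",
                   complication_class = "cardiovascular",
                   index_date = as.Date(c("1996-01-01", "2014-01-01")))
  cl <- classify_episodes(ep, pats, lookback_years = 15)
  expect_equal(cl$episode_type, c("incident", "incident"))
  cl2 <- classify_episodes(ep, pats, lookback_years = 30)
  expect_equal(cl2$episode_type, c("incident", "recurrent"))
})

test_that("comorbidity window is half-open: [index - 730, index)", {
  pats <- tiny_patients()
  idx <- as.Date("2014-06-01")
  ep <- data.frame(patient_id = "P01", complication_class = "eye",
                   index_date = idx)
  for (case in list(list(off = -1, flag = 1L), list(off = 0, flag = 0L),
                    list(off = -730, flag = 1L),
                    list(off = -731, flag = 0L))) {
    ev <- data.frame(patient_id = "P01", event_date = idx + case$off,
                     code = "CMCHF1")
    fl <- flag_comorbidities(ev, ep, default_maps$comorbidity)
    expect_equal(fl$congestive_heart_failure, case$flag,
                 label = paste("offset", case$off))
  }
})

test_that("comorbidity flags agree with a brute-force scan on random histories", {
  set.seed(303)
  prefixes <- c("CMMI", "CMCHF", "CMDEM", "CMMAL")
  classes <- c("myocardial_infarction", "congestive_heart_failure",
               "dementia", "any_malignancy")
  for (i in 1:30) {
    ev <- data.frame(
      patient_id = "P01",
      event_date = as.Date("2010-01-01") + sample(0:3000, 15, TRUE),
      code = paste0(sample(prefixes, 15, TRUE), sample(1:9, 15, TRUE)))
    ep <- data.frame(patient_id = "P01", complication_class = "eye",
                     index_date = as.Date("2010-01-01") + sample(0:3000, 3))
    got <- flag_comorbidities(ev, ep, default_maps$comorbidity)
    for (j in seq_len(nrow(ep))) {
      for (k in seq_along(classes)) {
        inw <- ev$event_date >= ep$index_date[j] - 730 &
          ev$event_date < ep$index_date[j] &
          startsWith(ev$code, prefixes[k])
        expect_equal(got[[classes[k]]][j], as.integer(any(inw)))
      }
    }
  }
})

test_that("the inclusion filter keeps diabetic in-window catchment episodes", {
  pats <- tiny_patients(n = 2)
  pats$in_catchment[2] <- FALSE
  ep <- data.frame(
    patient_id = c("P01", "P01", "P01", "P02"),
    complication_class = "eye",
    index_date = as.Date(c("2013-05-01", "2016-12-31", "2011-12-31",
                           "2014-01-01")),
    episode_type = c("prediabetic", "incident", "incident", "recurrent"))
  kept <- filter_included(ep, pats, "2012-01-01", "2016-12-31")
  # prediabetic excluded even in-window; last window day included;
  # pre-window excluded; out-of-catchment excluded
  expect_equal(kept$index_date, as.Date("2016-12-31"))
})

test_that("person-years truncate at death and respect entry at diagnosis", {
  p <- tiny_patients(t2d = as.Date("2000-01-01"))
  expect_equal(person_years(p, "2015-01-01", "2016-01-01"), 365 / 365.25)
  p$death_date <- as.Date("2015-07-02")  # ~half the window
  expect_equal(person_years(p, "2015-01-01", "2016-01-01"), 182 / 365.25)
  # diagnosis mid-window delays entry
  p2 <- tiny_patients(t2d = as.Date("2015-07-02"))
  expect_equal(person_years(p2, "2015-01-01", "2016-01-01"), 183 / 365.25)
  # brute-force per-patient sum on a small mixed cohort
  ps <- rbind(p, p2)
  expect_equal(person_years(ps, "2015-01-01", "2016-01-01"),
               (182 + 183) / 365.25)
})

test_that("incidence rate is per 100 person-years to one decimal", {
  expect_equal(incidence_rate(1, 100), 1.0)
  expect_equal(incidence_rate(0, 50), 0.0)
  expect_error(incidence_rate(5, 0), "positive")
})
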