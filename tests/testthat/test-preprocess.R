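mk_events <- function(...) {
  rows <- list(...)
  data.frame(patient_id = vapply(rows, `[[`, "", 1),
             event_date = as.Date(vapply(rows, `[[`, "", 2)),
             icd9_code = vapply(rows, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

test_that("three-digit collapsing handles numeric, V and E codes and is idempotent", {
  expect_equal(collapse_icd9("401.9"), "401")
  expect_equal(collapse_icd9("V65.4"), "V65")
  expect_equal(collapse_icd9("401"), "401")
  expect_equal(collapse_icd9("E849.0"), "E849")
  expect_equal(collapse_icd9("v70.0"), "V70")
  expect_equal(collapse_icd9(" 41.0 "), "041")
  expect_true(is.na(collapse_icd9("borked")))
  expect_true(is.na(collapse_icd9("")))
  x <- c("401.9", "V65.4", "E849.0", "041")
  expect_identical(collapse_icd9(collapse_icd9(x)), collapse_icd9(x))
})

test_that("collapse_events drops unparseable rows with a warning and counts them", {
  ev <- mk_events(list("p1", "2000-01-01", "401.9"),
                  list("p1", "2000-02-01", "nonsense"),
                  list("p2", "2000-03-01", "V65.4"))
  expect_warning(out <- collapse_events(ev), "unparseable")
  expect_equal(out$n_rejected, 1)
  expect_equal(out$events$code3, c("401", "V65"))
})

test_that("follow-up filter retains exactly the patients spanning min_years", {
  ev <- mk_events(list("keep", "2000-01-01", "401"),
                  list("keep", "2006-01-01", "250"),
                  list("drop", "2000-01-01", "401"),
                  list("drop", "2003-01-01", "250"))
  out <- filter_followup(ev, 5)
  expect_equal(out$patients, "keep")
  expect_equal(nrow(out$events), 2)
  all_in <- filter_followup(ev, 0)
  expect_setequal(all_in$patients, c("keep", "drop"))
  expect_equal(nrow(filter_followup(ev[0, ], 5)$events), 0)
})

test_that("follow-up retention matches the simulator's realized follow-up", {
  cfg <- sim_config(n_patients = 80, n_codes = 6, n_blocks = 2,
                    followup_years_range = c(2, 10), seed = 21)
  res <- simulate_cohort(cfg)
  coll <- collapse_events(res$events)
  out <- filter_followup(coll$events, 5)
  truth_keep <- names(res$truth$realized_followup)[
    res$truth$realized_followup >= 5]
  expect_setequal(out$patients, truth_keep)
})

test_that("first occurrences take the per-patient minimum date and ignore row order", {
  ev <- mk_events(list("p1", "2000-01-10", "401.0"),
                  list("p1", "2001-02-04", "401.9"),
                  list("p1", "2000-01-10", "250.1"),
                  list("p2", "2000-05-05", "401.9"))
  ev <- collapse_events(ev)$events
  fo <- first_occurrences(ev)
  expect_equal(fo$first_date[fo$patient_id == "p1" & fo$code3 == "401"],
               as.Date("2000-01-10"))
  # coincident same-day pair preserved
  p1 <- fo[fo$patient_id == "p1", ]
  expect_equal(sum(p1$first_date == as.Date("2000-01-10")), 2)
  for (s in 1:5) {
    set.seed(s)
    perm <- ev[sample(nrow(ev)), , drop = FALSE]
    expect_identical(first_occurrences(perm), fo)
  }
})

test_that("network exclusions remove V codes and the excluded numeric ranges", {
  expect_setequal(network_exclusions(c("401", "V65", "780", "997", "650", "250")),
                  c("401", "250"))
  expect_setequal(network_exclusions(c("779", "800")), c("779", "800"))
  expect_equal(network_exclusions("E849"), "E849")
  expect_setequal(network_exclusions(c("630", "679", "799", "996", "999", "629", "680", "995")),
                  c("629", "680", "995"))
  x <- c("401", "250", "E849")
  expect_identical(network_exclusions(network_exclusions(x)), network_exclusions(x))
})

test_that("prevalence filter applies the at-least-threshold boundary", {
  fo <- data.frame(
    patient_id = c(paste0("p", 1:221), paste0("q", 1:220)),
    code3 = c(rep("401", 221), rep("250", 220)),
    first_date = as.Date("2000-01-01"))
  expect_equal(prevalence_filter(fo, 2210, 0.10), "401")
  expect_setequal(prevalence_filter(fo, 2210, 0.05), c("250", "401"))
  expect_error(prevalence_filter(fo, 2210, 0), "threshold")
  expect_error(prevalence_filter(fo, 2210, 1.5), "threshold")
  expect_error(prevalence_filter(fo, 0), "cohort_size")
})

test_that("cohort summary computes ages and follow-up and is duplication invariant", {
  ev <- data.frame(
    patient_id = "p1",
    birth_date = as.Date("1940-01-01"),
    event_date = as.Date(c("2000-01-01", "2010-01-01")),
    icd9_code = c("401.9", "250.0"))
  s <- cohort_summary(ev)
  expect_equal(s$n_patients, 1)
  expect_equal(unname(s$age_first[["median"]]), 60, tolerance = 0.01)
  expect_equal(unname(s$age_last[["median"]]), 70, tolerance = 0.01)
  expect_equal(unname(s$followup_years[["median"]]), 10, tolerance = 0.01)

  cfg <- sim_config(n_patients = 30, n_codes = 6, n_blocks = 2, seed = 3)
  sim <- simulate_cohort(cfg)$events
  s1 <- cohort_summary(sim)
  dup <- sim
  dup$patient_id <- paste0(dup$patient_id, "_copy")
  s2 <- cohort_summary(rbind(sim, dup))
  expect_equal(s2$n_patients, 2 * s1$n_patients)
  # medians are invariant to duplicating every patient (quartile
  # interpolation is not, so only the medians are compared)
  for (f in c("followup_years", "dx_per_patient", "distinct_full_codes",
              "distinct_code3", "age_first", "age_last"))
    expect_equal(s2[[f]][["median"]], s1[[f]][["median"]], tolerance = 1e-12)
})

test_that("median follow-up of the default simulator lies inside the configured range", {
  cfg <- sim_config(n_patients = 60, n_codes = 8, n_blocks = 2, seed = 13)
  res <- simulate_cohort(cfg)
  s <- cohort_summary(res$events)
  expect_gte(s$followup_years[["median"]], cfg$followup_years_range[1] - 0.5)
  expect_lte(s$followup_years[["median"]], cfg$followup_years_range[2])
})

test_that("prevalence table counts encounters and patients with one-decimal percentages", {
  ev <- mk_events(list("p1", "2000-01-01", "401.9"),
                  list("p1", "2000-02-01", "401.0"),
                  list("p2", "2000-01-01", "401.9"),
                  list("p2", "2000-01-05", "V65.4"),
                  list("p3", "2000-01-01", "250.0"))
  ev <- collapse_events(ev)$events
  tab <- prevalence_table(ev)
  expect_equal(tab$code3, c("401", "250", "V65"))  # ties broken by code
  expect_equal(tab$n_encounters[tab$code3 == "401"], 3)
  expect_equal(tab$n_patients[tab$code3 == "401"], 2)
  expect_equal(tab$pct_patients[tab$code3 == "401"], 66.7)
  expect_equal(sum(tab$n_encounters), nrow(ev))
  # V codes included here even though the network excludes them
  expect_true("V65" %in% tab$code3)
  lab <- c("401" = "Essential hypertension")
  tab2 <- prevalence_table(ev, labels = lab)
  expect_equal(tab2$label[tab2$code3 == "401"], "Essential hypertension")
  expect_equal(tab2$label[tab2$code3 == "250"], "250")
})

test_that("percentage arithmetic rounds to one decimal", {
  expect_equal(pct_of_cohort(1999, 2210), 90.5)
  expect_equal(pct_of_cohort(2122, 2210), 96.0)
  expect_equal(pct_of_cohort(c(221, 220), 2210), c(10.0, 10.0))
})

test_that("code-label files round-trip through read_code_labels", {
  path <- system.file("extdata", "icd9_code_labels.tsv", package = "comorbidnet")
  labels <- read_code_labels(path)
  expect_equal(unname(labels["401"]), "Essential hypertension")
  expect_equal(unname(labels["V65"]), "Other persons seeking consultation")
})
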