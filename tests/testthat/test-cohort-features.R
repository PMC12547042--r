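test_that("case-finding requires at least one MS record in any database", {
  tabs <- micro_tables()
  cases <- find_cases(tabs$prescriptions, tabs$admissions, tabs$outpatients)
  # A: DMT prescription; B: DMT prescriptions; C: secondary-diagnosis 340 +
  # rehabilitation encounter; D: primary 340; E: non-DMT drug only; F: lab only
  expect_setequal(cases$patient_id, c("A", "B", "C", "D"))
  expect_false("E" %in% cases$patient_id)
  expect_false("F" %in% cases$patient_id)
  # secondary diagnosis qualifies, and entry is the earliest qualifying date
  expect_equal(cases$entry_date[cases$patient_id == "C"],
               as.Date("2016-04-01"))
  expect_equal(cases$entry_date[cases$patient_id == "D"],
               as.Date("2016-01-10"))
  expect_equal(cases$entry_date[cases$patient_id == "A"],
               as.Date("2016-02-10"))
})

test_that("case-finding is idempotent and independent of row order", {
  tabs <- micro_tables()
  base <- find_cases(tabs$prescriptions, tabs$admissions, tabs$outpatients)
  shuffle <- function(df) df[rev(seq_len(nrow(df))), , drop = FALSE]
  again <- find_cases(shuffle(tabs$prescriptions), shuffle(tabs$admissions),
                      shuffle(tabs$outpatients))
  rownames(again) <- NULL
  expect_identical(base, again)
})

test_that("unparseable dates are reported with their row number", {
  tabs <- micro_tables()
  bad <- tabs$prescriptions
  bad$date <- as.character(bad$date)
  bad$date[2L] <- "not-a-date"
  expect_error(find_cases(bad, tabs$admissions, tabs$outpatients), "row 2")
})

test_that("exclusions separate non-residents from missing demographics", {
  tabs <- micro_tables()
  cases <- find_cases(tabs$prescriptions, tabs$admissions, tabs$outpatients)
  res <- apply_exclusions(cases, tabs$demographics)
  expect_setequal(res$included$patient_id, c("A", "B"))
  rep <- res$report
  expect_equal(rep$n[rep$reason == "non_resident"], 1)        # C
  expect_equal(rep$n[rep$reason == "missing_demographics"], 1) # D (sex NA)
})

test_that("feature windows are half-open six calendar months", {
  cohort <- data.frame(patient_id = "A", entry_date = as.Date("2016-01-01"),
                       sex = "F", birth_year = 1980L,
                       stringsAsFactors = FALSE)
  adm <- data.frame(patient_id = c("A", "A"),
                    admit_date = as.Date(c("2016-06-30", "2016-07-01")),
                    discharge_date = as.Date(c("2016-07-02", "2016-07-03")),
                    icd9_codes = c("340", "340"),
                    emergency_flag = c(0L, 0L), stringsAsFactors = FALSE)
  empty_rx <- data.frame(patient_id = character(),
                         date = as.Date(character()),
                         drug_name = character())
  empty_op <- data.frame(patient_id = character(),
                         date = as.Date(character()),
                         service_category = character())
  f <- build_features(cohort, empty_rx, adm, empty_op)
  # the June 30 admission is inside [2016-01-01, 2016-07-01); July 1 is not
  expect_equal(f$n_admissions, 1)
  expect_equal(f$window_end, as.Date("2016-07-01"))
})

test_that("platform-to-high-efficacy switches are detected directionally", {
  cohort <- data.frame(patient_id = c("A", "B"),
                       entry_date = as.Date(c("2016-01-01", "2016-01-01")),
                       sex = c("F", "M"), birth_year = c(1980L, 1970L),
                       stringsAsFactors = FALSE)
  rx <- data.frame(
    patient_id = c("A", "A", "B", "B"),
    date = as.Date(c("2016-02-01", "2016-05-01",
                     "2016-02-01", "2016-05-01")),
    drug_name = c("glatiramer acetate", "fingolimod",
                  "fingolimod", "glatiramer acetate"),
    stringsAsFactors = FALSE
  )
  empty_adm <- data.frame(patient_id = character(),
                          admit_date = as.Date(character()),
                          discharge_date = as.Date(character()),
                          icd9_codes = character(),
                          emergency_flag = integer())
  empty_op <- data.frame(patient_id = character(),
                         date = as.Date(character()),
                         service_category = character())
  f <- build_features(cohort, rx, empty_adm, empty_op)
  expect_equal(f$switch_platform_to_high[f$patient_id == "A"], 1)
  expect_equal(f$switch_platform_to_high[f$patient_id == "B"], 0)
  expect_equal(f$n_dmt_platform, c(1, 1))
  expect_equal(f$n_dmt_high_efficacy, c(1, 1))
})

test_that("admission counts and lengths sum by hand", {
  cohort <- data.frame(patient_id = "A", entry_date = as.Date("2016-01-01"),
                       sex = "F", birth_year = 1980L,
                       stringsAsFactors = FALSE)
  adm <- data.frame(
    patient_id = c("A", "A"),
    admit_date = as.Date(c("2016-02-01", "2016-03-01")),
    discharge_date = as.Date(c("2016-02-04", "2016-03-05")),
    icd9_codes = c("340", "401.9"),
    emergency_flag = c(1L, 0L), stringsAsFactors = FALSE
  )
  empty_rx <- data.frame(patient_id = character(),
                         date = as.Date(character()),
                         drug_name = character())
  empty_op <- data.frame(patient_id = character(),
                         date = as.Date(character()),
                         service_category = character())
  f <- build_features(cohort, empty_rx, adm, empty_op)
  expect_equal(f$n_admissions, 2)
  expect_equal(f$total_admission_length, 7)
  expect_equal(f$n_ms_admissions, 1)
  expect_equal(f$n_emergency_admissions, 1)
})

test_that("uncatalogued drugs are warned about and counted, never dropped", {
  cohort <- data.frame(patient_id = "A", entry_date = as.Date("2016-01-01"),
                       sex = "F", birth_year = 1980L,
                       stringsAsFactors = FALSE)
  rx <- data.frame(patient_id = "A", date = as.Date("2016-02-01"),
                   drug_name = "mystery drug", stringsAsFactors = FALSE)
  empty_adm <- data.frame(patient_id = character(),
                          admit_date = as.Date(character()),
                          discharge_date = as.Date(character()),
                          icd9_codes = character(),
                          emergency_flag = integer())
  empty_op <- data.frame(patient_id = character(),
                         date = as.Date(character()),
                         service_category = character())
  expect_warning(
    f <- build_features(cohort, rx, empty_adm, empty_op),
    "mystery drug")
  expect_equal(f$n_dmt_other, 1)
})

test_that("feature aggregation equals a brute-force row filter", {
  reg <- small_registry()
  cases <- find_cases(reg$prescriptions, reg$admissions, reg$outpatients)
  excl <- apply_exclusions(cases, reg$demographics)
  feats <- build_features(excl$included, reg$prescriptions, reg$admissions,
                          reg$outpatients)
  set.seed(99)
  sample_ids <- sample(feats$patient_id, 100)
  for (pid in sample_ids) {
    row <- feats[feats$patient_id == pid, ]
    ws <- row$window_start
    we <- row$window_end
    rx <- reg$prescriptions
    in_rx <- rx$patient_id == pid & rx$date >= ws & rx$date < we
    cat_rows <- default_dmt_catalog()
    tier <- cat_rows$efficacy_tier[match(rx$drug_name[in_rx],
                                         cat_rows$drug_name)]
    expect_equal(row$n_dmt_platform, sum(tier == "platform", na.rm = TRUE))
    expect_equal(row$n_dmt_high_efficacy,
                 sum(tier == "high_efficacy", na.rm = TRUE))
    adm <- reg$admissions
    in_adm <- adm$patient_id == pid & adm$admit_date >= ws &
      adm$admit_date < we
    expect_equal(row$n_admissions, sum(in_adm))
    expect_equal(row$total_admission_length,
                 sum(as.numeric(adm$discharge_date[in_adm] -
                                  adm$admit_date[in_adm])))
    op <- reg$outpatients
    in_op <- op$patient_id == pid & op$date >= ws & op$date < we
    expect_equal(row$n_rehabilitation,
                 sum(op$service_category[in_op] == "rehabilitation"))
    expect_equal(row$n_laboratory,
                 sum(op$service_category[in_op] == "laboratory"))
  }
})

test_that("EDSS scores map to classes at the stated boundaries", {
  expect_equal(as.character(edss_class(c(0, 3.0, 3.5, 5.5, 6.0, 9.5))),
               c("C1", "C1", "C2", "C2", "C3", "C3"))
  expect_error(edss_class(3.25), "0.5 steps")
  expect_error(edss_class(10.5), "invalid EDSS")
  expect_error(edss_class(-0.5), "invalid EDSS")
})

test_that("labelling picks the relapse-free assessment nearest the window end", {
  feats <- data.frame(patient_id = c("A", "B", "C"),
                      window_start = as.Date("2016-01-01"),
                      window_end = as.Date("2016-07-01"),
                      stringsAsFactors = FALSE)
  clin <- data.frame(
    patient_id = c("A", "A", "B", "C", "C"),
    visit_date = as.Date(c("2016-06-01", "2016-09-01",   # A: 30 vs 62 days
                           "2016-06-15",                 # B: relapse only
                           "2016-06-21", "2016-07-11")), # C: equidistant (10 d)
    edss = c(2.0, 6.0, 4.0, 3.0, 6.5),
    relapse_flag = c(0L, 0L, 1L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  labs <- label_cohort(feats, clin)
  expect_setequal(labs$patient_id, c("A", "C"))   # B has no eligible visit
  expect_equal(labs$edss[labs$patient_id == "A"], 2.0)
  # tie at 10 days: the earlier assessment wins
  expect_equal(labs$edss[labs$patient_id == "C"], 3.0)
  expect_equal(as.character(labs$class), c("C1", "C1"))
})

test_that("labels recover the latent class exactly on synthetic data", {
  reg <- small_registry()
  cases <- find_cases(reg$prescriptions, reg$admissions, reg$outpatients)
  excl <- apply_exclusions(cases, reg$demographics)
  feats <- build_features(excl$included, reg$prescriptions, reg$admissions,
                          reg$outpatients)
  labs <- label_cohort(feats, reg$clinical_edss)
  expect_gt(nrow(labs), 50)
  pop <- reg$population[match(labs$patient_id, reg$population$patient_id), ]
  f <- feats[match(labs$patient_id, feats$patient_id), ]
  m <- pmax(as.numeric(labs$visit_date - pop$entry_date) / 30.4375, 0)
  latent <- edssprog:::latent_class_at(pop, m)
  expect_identical(as.integer(labs$class), as.integer(latent))
})

test_that("survival samples carry positive times, binary events, no top-class baselines", {
  reg <- small_registry()
  cases <- find_cases(reg$prescriptions, reg$admissions, reg$outpatients)
  excl <- apply_exclusions(cases, reg$demographics)
  feats <- build_features(excl$included, reg$prescriptions, reg$admissions,
                          reg$outpatients)
  samp <- build_survival_samples(feats, reg$clinical_edss)
  expect_gt(nrow(samp), 30)
  expect_true(all(samp$time > 0))
  expect_true(all(samp$event %in% c(0L, 1L)))
  expect_true(all(samp$baseline_class < 3L))
  expect_gt(sum(samp$event), 5)
})
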