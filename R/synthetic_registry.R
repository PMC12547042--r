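# Synthetic linked-registry generator.  Produces the four administrative
# tables (prescriptions, admissions, outpatients, demographics) plus a
# clinical EDSS sub-registry with the statistical structure the downstream
# pipeline assumes, so every stage is testable without any external data.
#
# Reproducibility: all randomness flows from config$seed, with one sub-stream
# per table (seed, seed+1, seed+2) so a table can be regenerated on its own.

#' Simulate the latent patient population
#'
#' Draws the latent state of every patient: demographics, entry date, initial
#' EDSS class, the per-patient monthly progression hazard, and the latent
#' class-transition times (months from entry) that define a piecewise-constant,
#' monotone non-decreasing class trajectory with the top class absorbing.
#' Also flags the patients used to exercise the cohort exclusions:
#' non-residents, missing demographics, and patients with no administrative
#' records at all.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `latent_population`, one row per patient,
#'   with columns `patient_id`, `female`, `age_entry`, `birth_year`,
#'   `entry_date`, `class0`, `rate` (monthly transition hazard), `t_up1`,
#'   `t_up2` (months from entry to the first/second upward class transition,
#'   `Inf` when not applicable), `resident_flag`, `missing_sex`,
#'   `missing_birth_year`, `zero_record`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients

  female <- rbinom(n, 1L, config$female_frac)
  parent_mu <- solve_parent_mean(config$age_mean, config$age_sd, 18, 85)
  age <- rtruncnorm(n, parent_mu, config$age_sd, 18, 85)
  class0 <- sample.int(3L, n, replace = TRUE, prob = config$class_mix)

  span_days <- min(config$entry_span_years * 365,
                   as.numeric(config$study_end - config$study_start) - 365)
  span_days <- max(span_days, 1)
  entry_date <- config$study_start + floor(runif(n, 0, span_days))
  birth_year <- as.integer(format(entry_date, "%Y")) - round(age)

  w <- config$progression_log_hazard_weights
  lp <- w[["age_z"]] * (age - config$age_mean) / config$age_sd +
    w[["female"]] * female
  rate <- config$baseline_hazard_rate * exp(lp)

  t_up1 <- rexp(n, rate)
  t_up2 <- t_up1 + rexp(n, rate)
  t_up1[class0 >= 3L] <- Inf
  t_up2[class0 >= 2L] <- Inf

  # loss to follow-up: records and visits stop at followup_end
  cens_m <- if (config$censor_dropout_rate > 0) {
    rexp(n, config$censor_dropout_rate)
  } else {
    rep(Inf, n)
  }
  followup_end <- pmin(config$study_end,
                       entry_date + round(cens_m * DAYS_PER_MONTH))

  resident_flag <- runif(n) >= config$nonresident_frac
  miss <- runif(n) < config$missing_demog_frac
  miss_which <- runif(n) < 0.5
  zero_record <- runif(n) < config$zero_record_frac

  out <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    female = female,
    age_entry = age,
    birth_year = birth_year,
    entry_date = entry_date,
    followup_end = followup_end,
    class0 = class0,
    rate = rate,
    t_up1 = t_up1,
    t_up2 = t_up2,
    resident_flag = resident_flag,
    missing_sex = miss & miss_which,
    missing_birth_year = miss & !miss_which,
    zero_record = zero_record,
    stringsAsFactors = FALSE
  )
  class(out) <- c("latent_population", "data.frame")
  out
}

# Latent class after `months` months from entry (vectorized over patients).
latent_class_at <- function(patients, months) {
  pmin(patients$class0 +
         (months >= patients$t_up1) + (months >= patients$t_up2), 3L)
}

#' Latent EDSS class of each patient on a calendar date
#'
#' @param patients a `latent_population`.
#' @param date a single calendar date.
#' @return integer vector in 1..3 (class before entry is the entry class).
#' @export
latent_class_on <- function(patients, date) {
  m <- pmax(months_between(patients$entry_date, as.Date(date)), 0)
  latent_class_at(patients, m)
}

#' Simulate healthcare-utilization tables
#'
#' Generates the prescription, hospital-admission, and outpatient tables.
#' Records are drawn in 6-month patient-time periods from entry to the study
#' end; the intensity of every class-dependent component (high-efficacy DMT
#' use, admission counts and lengths, severe-disability discharge codes,
#' rehabilitation and consultation encounters) scales with
#' `config$signal_strength` times the patient's latent class at the start of
#' the period, giving the classifier a learnable signal.  With
#' `signal_strength = 0` the class-conditional distributions are identical.
#' Patients flagged `zero_record` are absent from all three tables.
#'
#' @param patients a `latent_population`.
#' @param config the [sim_config()] used to generate them.
#' @return `list(prescriptions, admissions, outpatients)` of data frames in
#'   the CSV schemas accepted by [find_cases()].
#' @export
simulate_utilization <- function(patients, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  u <- config$utilization
  s <- config$signal_strength
  act <- patients[!patients$zero_record, , drop = FALSE]
  period_days <- 182L
  catalog <- default_dmt_catalog()
  platform_drugs <- catalog$drug_name[catalog$efficacy_tier == "platform"]
  he_drugs <- catalog$drug_name[catalog$efficacy_tier == "high_efficacy"]
  severe_pool <- default_severe_disability_codes()
  generic_pool <- c("401.9", "250.00", "486", "780.79", "466.0")

  rx_parts <- list(); adm_parts <- list(); out_parts <- list()
  k <- 0L
  repeat {
    start <- act$entry_date + k * period_days
    live <- which(start <= act$followup_end)
    if (length(live) == 0L) break
    p <- act[live, , drop = FALSE]
    ps <- start[live]
    cl <- latent_class_at(p, k * period_days / DAYS_PER_MONTH)

    # --- prescriptions ---
    n_rx <- rpois(nrow(p), u$rx_rate)
    if (sum(n_rx) > 0L) {
      i <- rep.int(seq_len(nrow(p)), n_rx)
      dates <- ps[i] + floor(runif(length(i), 0, period_days))
      p_he <- plogis(qlogis(u$high_efficacy_base) +
                       s * u$high_efficacy_slope * (cl[i] - 1L))
      he <- runif(length(i)) < p_he
      drug <- ifelse(he,
                     sample(he_drugs, length(i), replace = TRUE),
                     sample(platform_drugs, length(i), replace = TRUE))
      keep <- dates <= p$followup_end[i]
      rx_parts[[length(rx_parts) + 1L]] <- data.table(
        patient_id = p$patient_id[i][keep],
        date = dates[keep],
        drug_name = drug[keep])
    }

    # --- admissions ---
    n_adm <- rpois(nrow(p), u$adm_base + s * u$adm_slope * (cl - 1L))
    if (sum(n_adm) > 0L) {
      i <- rep.int(seq_len(nrow(p)), n_adm)
      admit <- ps[i] + floor(runif(length(i), 0, period_days))
      los <- 1L + rpois(length(i), u$los_base + s * u$los_slope * (cl[i] - 1L))
      ms_rel <- runif(length(i)) < u$ms_adm_prob
      codes <- ifelse(ms_rel, "340",
                      sample(generic_pool, length(i), replace = TRUE))
      p_sev <- pmin(1, s * u$severe_code_probs[cl[i]])
      sev <- runif(length(i)) < p_sev
      sev_code <- sample(severe_pool, length(i), replace = TRUE)
      codes <- ifelse(sev, paste(codes, sev_code, sep = ";"), codes)
      emerg <- as.integer(runif(length(i)) < u$emergency_prob)
      keep <- admit <= p$followup_end[i]
      adm_parts[[length(adm_parts) + 1L]] <- data.table(
        patient_id = p$patient_id[i][keep],
        admit_date = admit[keep],
        discharge_date = (admit + los)[keep],
        icd9_codes = codes[keep],
        emergency_flag = emerg[keep])
    }

    # --- outpatient encounters ---
    for (cat_name in names(u$outpatient_rates)) {
      r <- u$outpatient_rates[[cat_name]]
      n_out <- rpois(nrow(p), r[["base"]] + s * r[["slope"]] * (cl - 1L))
      if (sum(n_out) == 0L) next
      i <- rep.int(seq_len(nrow(p)), n_out)
      dates <- ps[i] + floor(runif(length(i), 0, period_days))
      keep <- dates <= p$followup_end[i]
      out_parts[[length(out_parts) + 1L]] <- data.table(
        patient_id = p$patient_id[i][keep],
        date = dates[keep],
        service_category = cat_name)
    }
    k <- k + 1L
  }

  finish <- function(parts, empty, keys) {
    dt <- if (length(parts)) rbindlist(parts) else empty
    setorderv(dt, keys)
    setDF(dt)
    dt
  }
  list(
    prescriptions = finish(rx_parts,
      data.table(patient_id = character(), date = as.Date(character()),
                 drug_name = character()),
      c("patient_id", "date", "drug_name")),
    admissions = finish(adm_parts,
      data.table(patient_id = character(), admit_date = as.Date(character()),
                 discharge_date = as.Date(character()),
                 icd9_codes = character(), emergency_flag = integer()),
      c("patient_id", "admit_date")),
    outpatients = finish(out_parts,
      data.table(patient_id = character(), date = as.Date(character()),
                 service_category = character()),
      c("patient_id", "date", "service_category"))
  )
}

#' Simulate the clinical EDSS sub-registry
#'
#' A random `clinical_subset_frac` of eligible (case-findable) patients
#' receives dated EDSS assessments on a roughly 6-monthly grid from entry to
#' the study end.  Every score is drawn from the numeric EDSS range of the
#' patient's latent class on the assessment date (C1: 0-3.0, C2: 3.5-5.5,
#' C3: 6.0-9.5, in 0.5 steps), so clinical labels are exactly
#' class-consistent.  A fraction of assessments carries a relapse flag so
#' relapse-window filtering is exercisable.
#'
#' @param patients a `latent_population`.
#' @param config the [sim_config()].
#' @param eligible_ids patient ids eligible for registry coverage; defaults
#'   to all patients with at least one administrative record.
#' @return data frame with `patient_id`, `visit_date`, `edss`,
#'   `relapse_flag`.
#' @export
simulate_clinical_registry <- function(patients, config, eligible_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  if (is.null(eligible_ids)) {
    eligible_ids <- patients$patient_id[!patients$zero_record]
  }
  covered <- eligible_ids[runif(length(eligible_ids)) <
                            config$clinical_subset_frac]
  p <- patients[patients$patient_id %in% covered, , drop = FALSE]
  if (nrow(p) == 0L) {
    return(data.frame(patient_id = character(),
                      visit_date = as.Date(character()),
                      edss = numeric(), relapse_flag = integer()))
  }
  iv <- config$visit_interval_days
  n_vis <- pmax(1L, floor(as.numeric(p$followup_end - p$entry_date) / iv) + 1L)
  i <- rep.int(seq_len(nrow(p)), n_vis)
  k <- sequence(n_vis) - 1L
  jitter <- ifelse(k == 0L, 0L, sample(-15:15, length(i), replace = TRUE))
  visit <- pmin(p$entry_date[i] + k * iv + jitter, p$followup_end[i])
  m <- pmax(months_between(p$entry_date[i], visit), 0)
  cl <- latent_class_at(p[i, , drop = FALSE], m)
  grids <- list(seq(0, 3, by = 0.5), seq(3.5, 5.5, by = 0.5),
                seq(6, 9.5, by = 0.5))
  pick <- runif(length(i))
  edss <- vapply(seq_along(i), function(j) {
    g <- grids[[cl[j]]]
    g[1L + floor(pick[j] * length(g))]
  }, numeric(1L))
  out <- data.table(
    patient_id = p$patient_id[i],
    visit_date = visit,
    edss = edss,
    relapse_flag = rbinom(length(i), 1L, config$relapse_flag_prob))
  setorderv(out, c("patient_id", "visit_date"))
  setDF(out)
  out
}

#' Generate a complete linked synthetic registry
#'
#' Runs [simulate_population()], [simulate_utilization()] and
#' [simulate_clinical_registry()] and assembles the demographics table
#' (with missing-field injection for excluded-patient testing).
#'
#' @param config a [sim_config()].
#' @return a list of class `ms_registry` with elements `population` (latent
#'   truth), `prescriptions`, `admissions`, `outpatients`, `demographics`,
#'   `clinical_edss`, and `config`.
#' @export
simulate_registry <- function(config) {
  pop <- simulate_population(config)
  util <- simulate_utilization(pop, config)
  clin <- simulate_clinical_registry(pop, config)
  demo <- data.frame(
    patient_id = pop$patient_id,
    sex = ifelse(pop$missing_sex, NA_character_,
                 ifelse(pop$female == 1L, "F", "M")),
    birth_year = ifelse(pop$missing_birth_year, NA_integer_, pop$birth_year),
    resident_flag = pop$resident_flag,
    stringsAsFactors = FALSE
  )
  out <- c(list(population = pop), util,
           list(demographics = demo, clinical_edss = clin, config = config))
  class(out) <- "ms_registry"
  out
}

#' Write the registry tables as CSV files
#'
#' Writes `prescriptions.csv`, `admissions.csv`, `outpatients.csv`,
#' `demographics.csv` and `clinical_edss.csv` to `dir` (ISO-8601 dates).
#' The latent-truth table is not written: real extracts do not have one.
#'
#' @param registry an `ms_registry` from [simulate_registry()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(registry, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("prescriptions", "admissions", "outpatients",
                "demographics", "clinical_edss")) {
    fwrite(registry[[tab]], file.path(dir, paste0(tab, ".csv")))
  }
  invisible(dir)
}

#' Read registry tables from a directory of CSV files
#'
#' Accepts the same schemas for real administrative extracts as for
#' synthetic ones; dates must be ISO-8601.
#'
#' @param dir directory containing the five CSV files of [write_registry()].
#' @return a list with `prescriptions`, `admissions`, `outpatients`,
#'   `demographics`, `clinical_edss` (missing files are `NULL`).
#' @export
read_registry <- function(dir) {
  rd <- function(name) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) return(NULL)
    df <- as.data.frame(fread(f))
    for (col in intersect(names(df), c("date", "admit_date",
                                       "discharge_date", "visit_date"))) {
      df[[col]] <- as.Date(df[[col]])
    }
    df
  }
  list(prescriptions = rd("prescriptions"), admissions = rd("admissions"),
       outpatients = rd("outpatients"), demographics = rd("demographics"),
       clinical_edss = rd("clinical_edss"))
}

#' Analytic class-transition table implied by the generator
#'
#' For a closed cohort observed in their latent class on `at_date`, the
#' exponential per-patient transition hazard gives each patient below the top
#' class a closed-form probability `1 - exp(-horizon * rate)` of moving to
#' the adjacent higher class within the horizon.  Aggregating those
#' probabilities yields the expected transition table against which the
#' model-based projection of [project_transitions()] can be benchmarked.
#'
#' @param patients a `latent_population`.
#' @param ids optional subset of patient ids (e.g. the included cohort).
#' @param at_date date defining the current class.
#' @param horizon projection horizon in months.
#' @return a `transition_table` (see [project_transitions()]).
#' @export
true_transition_table <- function(patients, ids = NULL,
                                  at_date = "2021-12-31", horizon = 60) {
  p <- patients
  if (!is.null(ids)) p <- p[p$patient_id %in% ids, , drop = FALSE]
  cl <- latent_class_on(p, at_date)
  p5 <- ifelse(cl < 3L, 1 - exp(-horizon * p$rate), 0)
  expected_transition_matrix(cl, p5)
}
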