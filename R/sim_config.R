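#' Configuration for the synthetic MS registry generator
#'
#' Bundles and validates every knob of the synthetic-registry generator.  The
#' defaults emulate the marginals of a large regional multiple-sclerosis
#' cohort observed through administrative healthcare data: about 64% female,
#' age about 42.5 (SD 13.5) years at entry, a 9% / 62% / 29% split over the
#' three collapsed EDSS classes (<= 3.0; 3.5-5.5; >= 6.0), and clinical EDSS
#' labels available for roughly 22% of case-findable patients.
#'
#' Latent disability progression is a per-patient homogeneous Poisson process
#' over class transitions: each patient carries a constant monthly transition
#' hazard `baseline_hazard_rate * exp(lp)` with `lp` linear in standardized
#' age and sex (`progression_log_hazard_weights`), and moves up one EDSS
#' class per event until the top class, which is absorbing.  The exponential
#' waiting times make a proportional-hazards fit correctly specified, and
#' five-year progression probabilities have the closed form
#' `1 - exp(-60 * rate)` used by [true_transition_table()].
#'
#' `signal_strength` scales every class-dependent component of healthcare
#' utilization; at 0 the three classes have identical utilization
#' distributions, so a downstream classifier can only perform at chance.
#'
#' @param n_patients number of patients to simulate.
#' @param study_start,study_end study window (ISO dates or `Date`).
#' @param female_frac expected proportion of women.
#' @param age_mean,age_sd age-at-entry moments in years; draws are truncated
#'   to 18-85 with the parent mean adjusted so the realized mean matches
#'   `age_mean`.
#' @param class_mix length-3 proportions over EDSS classes (C1, C2, C3);
#'   must be non-negative and sum to 1.
#' @param clinical_subset_frac proportion of case-findable patients covered
#'   by the clinical EDSS registry.
#' @param progression_log_hazard_weights named numeric vector with elements
#'   `age_z` and `female`: log-hazard-ratio weights of the latent
#'   progression hazard.
#' @param baseline_hazard_rate baseline class-transition hazard, events per
#'   month.
#' @param censor_dropout_rate additional random-censoring hazard (per month)
#'   for loss to follow-up; 0 means purely administrative censoring at
#'   `study_end`.
#' @param entry_span_years entry dates are uniform over this many years from
#'   `study_start`, so every patient has follow-up available.
#' @param signal_strength scaling of class-dependent utilization signal;
#'   0 removes all class information from the administrative tables.
#' @param nonresident_frac fraction flagged as non-resident (to exercise the
#'   residency exclusion).
#' @param missing_demog_frac fraction with a missing demographic field (sex
#'   or birth year, to exercise the missing-data exclusion).
#' @param zero_record_frac fraction with no administrative records at all
#'   (must not be case-found).
#' @param relapse_flag_prob probability that a clinical EDSS assessment is
#'   relapse-associated (such assessments are filtered before labelling).
#' @param visit_interval_days spacing of clinical EDSS assessments, days.
#' @param utilization optional list overriding utilization intensities; see
#'   Details in the package vignette.  Elements: `rx_rate` (prescriptions per
#'   6-month period), `high_efficacy_base`/`high_efficacy_slope` (logit
#'   intercept/per-class slope for high-efficacy DMT use), `adm_base`/
#'   `adm_slope` (admissions per period), `los_base`/`los_slope` (extra
#'   length-of-stay days), `ms_adm_prob`, `emergency_prob`,
#'   `severe_code_probs` (per class), `outpatient_rates` (named list of
#'   `c(base, slope)` per service category).
#' @param seed integer seed; together with the config it fully determines
#'   every generated table.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_registry()], [sim_config_from_file()]
#' @export
sim_config <- function(n_patients = 1000L,
                       study_start = "2015-01-01",
                       study_end = "2021-12-31",
                       female_frac = 0.64,
                       age_mean = 42.5,
                       age_sd = 13.5,
                       class_mix = c(0.09, 0.62, 0.29),
                       clinical_subset_frac = 0.22,
                       progression_log_hazard_weights =
                         c(age_z = 0.4, female = -0.3),
                       baseline_hazard_rate = 0.006,
                       censor_dropout_rate = 0,
                       entry_span_years = 5,
                       signal_strength = 1,
                       nonresident_frac = 0.03,
                       missing_demog_frac = 0.05,
                       zero_record_frac = 0.02,
                       relapse_flag_prob = 0.08,
                       visit_interval_days = 182L,
                       utilization = list(),
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    study_start = as.Date(study_start),
    study_end = as.Date(study_end),
    female_frac = female_frac,
    age_mean = age_mean,
    age_sd = age_sd,
    class_mix = as.numeric(class_mix),
    clinical_subset_frac = clinical_subset_frac,
    progression_log_hazard_weights = progression_log_hazard_weights,
    baseline_hazard_rate = baseline_hazard_rate,
    censor_dropout_rate = censor_dropout_rate,
    entry_span_years = entry_span_years,
    signal_strength = signal_strength,
    nonresident_frac = nonresident_frac,
    missing_demog_frac = missing_demog_frac,
    zero_record_frac = zero_record_frac,
    relapse_flag_prob = relapse_flag_prob,
    visit_interval_days = as.integer(visit_interval_days),
    utilization = utils::modifyList(default_utilization(), utilization),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

default_utilization <- function() {
  list(
    rx_rate = 2.2,
    high_efficacy_base = 0.25,
    high_efficacy_slope = 1.8,
    adm_base = 0.08,
    adm_slope = 0.90,
    los_base = 2,
    los_slope = 3.0,
    ms_adm_prob = 0.5,
    emergency_prob = 0.5,
    severe_code_probs = c(0.01, 0.35, 0.90),
    outpatient_rates = list(
      consultation   = c(base = 0.8,  slope = 2.0),
      diagnostic     = c(base = 0.9,  slope = 0.3),
      laboratory     = c(base = 6.0,  slope = 0.0),
      procedure      = c(base = 0.08, slope = 0.0),
      therapeutic    = c(base = 0.01, slope = 0.0),
      rehabilitation = c(base = 0.10, slope = 9.0)
    )
  )
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L)
    fail("n_patients", "must be a positive integer")
  if (cfg$study_end <= cfg$study_start)
    fail("study_end", "must be after study_start")
  if (cfg$female_frac < 0 || cfg$female_frac > 1)
    fail("female_frac", "must be in [0, 1]")
  if (cfg$age_sd <= 0) fail("age_sd", "must be positive")
  if (length(cfg$class_mix) != 3L)
    fail("class_mix", "must have length 3")
  if (any(cfg$class_mix < 0))
    fail("class_mix", "entries must be non-negative")
  if (abs(sum(cfg$class_mix) - 1) > 1e-9)
    fail("class_mix", "must sum to 1 (within 1e-9)")
  if (cfg$clinical_subset_frac <= 0 || cfg$clinical_subset_frac > 1)
    fail("clinical_subset_frac", "must be in (0, 1]")
  w <- cfg$progression_log_hazard_weights
  if (!all(c("age_z", "female") %in% names(w)))
    fail("progression_log_hazard_weights",
         "must be named and include 'age_z' and 'female'")
  if (cfg$baseline_hazard_rate <= 0)
    fail("baseline_hazard_rate", "must be positive (events per month)")
  if (cfg$censor_dropout_rate < 0)
    fail("censor_dropout_rate", "must be non-negative")
  if (cfg$signal_strength < 0)
    fail("signal_strength", "must be non-negative")
  for (f in c("nonresident_frac", "missing_demog_frac", "zero_record_frac",
              "relapse_flag_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) fail(f, "must be in [0, 1]")
  }
  if (cfg$visit_interval_days < 1L)
    fail("visit_interval_days", "must be at least 1 day")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  cfg
}

#' Read a generator configuration from YAML or JSON
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [sim_config()].
#' @return a validated `sim_config`.
#' @export
sim_config_from_file <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$progression_log_hazard_weights)) {
    raw$progression_log_hazard_weights <-
      unlist(raw$progression_log_hazard_weights)
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic MS registry configuration\n")
  cat(sprintf("  patients: %d   study: %s .. %s   seed: %d\n",
              x$n_patients, x$study_start, x$study_end, x$seed))
  cat(sprintf("  female: %.2f   age: %.1f (SD %.1f)   class mix: %s\n",
              x$female_frac, x$age_mean, x$age_sd,
              paste(sprintf("%.2f", x$class_mix), collapse = "/")))
  cat(sprintf("  clinical subset: %.2f   signal: %.2f   baseline hazard: %.4f/mo\n",
              x$clinical_subset_frac, x$signal_strength,
              x$baseline_hazard_rate))
  invisible(x)
}
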