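# Case-finding, exclusions, deterministic linkage by anonymised patient id,
# and construction of 6-month-window feature vectors and EDSS class labels
# from the four linked administrative tables plus the clinical registry.

#' Default catalogue of MS disease-modifying treatments
#'
#' Maps each DMT to a route class (monoclonal antibody / oral / injectable)
#' and an efficacy tier (platform / high-efficacy), following the standard
#' European regulatory grouping.  Users can extend it (e.g. with newer
#' agents such as ofatumumab, already included here) by row-binding entries
#' with the same three columns.
#'
#' @return data frame with columns `drug_name`, `route_class`
#'   (`MAB`/`oral`/`injectable`) and `efficacy_tier`
#'   (`platform`/`high_efficacy`).
#' @export
default_dmt_catalog <- function() {
  cat <- data.frame(
    drug_name = c("alemtuzumab", "natalizumab", "ocrelizumab", "ofatumumab",
                  "cladribine", "dimethyl fumarate", "teriflunomide",
                  "fingolimod",
                  "glatiramer acetate", "interferon beta-1a",
                  "interferon beta-1b", "peg-interferon beta-1a"),
    route_class = c("MAB", "MAB", "MAB", "MAB",
                    "oral", "oral", "oral", "oral",
                    "injectable", "injectable", "injectable", "injectable"),
    efficacy_tier = c("high_efficacy", "high_efficacy", "high_efficacy",
                      "high_efficacy",
                      "high_efficacy", "platform", "platform",
                      "high_efficacy",
                      "platform", "platform", "platform", "platform"),
    stringsAsFactors = FALSE
  )
  validate_dmt_catalog(cat)
}

validate_dmt_catalog <- function(catalog) {
  require_columns(catalog, c("drug_name", "route_class", "efficacy_tier"),
                  "DMT catalog")
  if (anyDuplicated(catalog$drug_name)) {
    stop("DMT catalog assigns more than one row to a drug", call. = FALSE)
  }
  if (!all(catalog$route_class %in% c("MAB", "oral", "injectable"))) {
    stop("DMT catalog route_class must be MAB, oral or injectable",
         call. = FALSE)
  }
  if (!all(catalog$efficacy_tier %in% c("platform", "high_efficacy"))) {
    stop("DMT catalog efficacy_tier must be platform or high_efficacy",
         call. = FALSE)
  }
  catalog
}

#' Default ICD-9 code list flagging severe-disability conditions
#'
#' A documented, user-replaceable convention (paraplegia/quadriplegia,
#' decubitus ulcer, dysphagia, urinary incontinence, wheelchair dependence);
#' real deployments should substitute their validated list.
#'
#' @return character vector of ICD-9-CM codes.
#' @export
default_severe_disability_codes <- function() {
  c("344.0", "344.1", "707.0", "787.20", "788.30", "V46.3")
}

#' Case-finding across the three administrative databases
#'
#' A patient is case-found when they have at least one MS record: an
#' MS-specific DMT prescription, a hospital admission listing ICD-9-CM 340
#' among the discharge diagnoses (primary or secondary), or an outpatient
#' encounter in an MS-specific service-code list.  The per-patient entry
#' date is the earliest qualifying record date.  The result is independent
#' of input row order.
#'
#' @param prescriptions,admissions,outpatients administrative tables in the
#'   schemas of [write_registry()].
#' @param catalog DMT catalogue defining MS-specific prescriptions.
#' @param ms_outpatient_categories service categories treated as MS-specific
#'   for case-finding (configurable; the default treats specialist
#'   consultations and rehabilitation as disease-specific).
#' @return data frame with `patient_id` and `entry_date`, sorted by id.
#' @export
find_cases <- function(prescriptions, admissions, outpatients,
                       catalog = default_dmt_catalog(),
                       ms_outpatient_categories = c("consultation",
                                                    "rehabilitation")) {
  prescriptions <- validate_prescriptions(prescriptions)
  admissions <- validate_admissions(admissions)
  outpatients <- validate_outpatients(outpatients)
  catalog <- validate_dmt_catalog(catalog)

  qual <- list()
  rx <- prescriptions[prescriptions$drug_name %in% catalog$drug_name, ]
  if (nrow(rx)) qual[[1L]] <- data.table(patient_id = rx$patient_id,
                                         date = rx$date)
  ms_adm <- grepl("(^|;)\\s*340\\s*(;|$)", admissions$icd9_codes)
  adm <- admissions[ms_adm, ]
  if (nrow(adm)) qual[[2L]] <- data.table(patient_id = adm$patient_id,
                                          date = adm$admit_date)
  op <- outpatients[outpatients$service_category %in%
                      ms_outpatient_categories, ]
  if (nrow(op)) qual[[3L]] <- data.table(patient_id = op$patient_id,
                                         date = op$date)
  qual <- qual[!vapply(qual, is.null, logical(1L))]
  if (length(qual) == 0L) {
    return(data.frame(patient_id = character(),
                      entry_date = as.Date(character())))
  }
  dt <- rbindlist(qual)
  out <- dt[, .(entry_date = min(date)), by = patient_id]
  setorderv(out, "patient_id")
  setDF(out)
  out
}

#' Apply residency and missing-demographics exclusions
#'
#' Removes case-found patients who are non-resident or have missing sex or
#' birth year (patients absent from the demographics table count as missing
#' demographics).  A patient matching both reasons is counted once, under
#' `non_resident`.
#'
#' @param cases output of [find_cases()].
#' @param demographics demographics table.
#' @return list with `included` (cases joined with sex and birth year) and
#'   `report` (data frame of exclusion reasons and counts).
#' @export
apply_exclusions <- function(cases, demographics) {
  demographics <- validate_demographics(demographics)
  m <- merge(cases, demographics, by = "patient_id", all.x = TRUE,
             sort = TRUE)
  non_res <- !is.na(m$resident_flag) & !m$resident_flag
  miss <- (is.na(m$sex) | is.na(m$birth_year) | is.na(m$resident_flag)) &
    !non_res
  included <- m[!non_res & !miss, c("patient_id", "entry_date", "sex",
                                    "birth_year")]
  rownames(included) <- NULL
  report <- data.frame(
    reason = c("non_resident", "missing_demographics", "included"),
    n = c(sum(non_res), sum(miss), nrow(included))
  )
  list(included = included, report = report)
}

#' Names of the numeric feature columns
#'
#' The fixed covariate schema shared by the classifier and the risk network.
#'
#' @return character vector of column names.
#' @export
feature_columns <- function() {
  c("age", "female",
    "n_dmt_mab", "n_dmt_oral", "n_dmt_injectable",
    "n_dmt_platform", "n_dmt_high_efficacy", "n_dmt_other",
    "therapy_duration", "switch_platform_to_high",
    "n_admissions", "n_ms_admissions", "n_emergency_admissions",
    "total_admission_length",
    "n_consultation", "n_diagnostic", "n_laboratory", "n_procedure",
    "n_therapeutic", "n_rehabilitation",
    "severe_disability_flag")
}

#' Build 6-month-window feature vectors
#'
#' Aggregates, for each included patient, all records whose date falls in the
#' half-open window `[window_start, window_start + 6 calendar months)`:
#' prescription counts by route class and efficacy tier, days on therapy
#' (30-day supply per prescription, overlaps merged, clipped to the window),
#' a platform-to-high-efficacy switch indicator (a platform prescription
#' strictly preceding a high-efficacy one within the window), admission
#' counts (total, MS-related ICD-9 340, emergency) and total length of stay
#' for admissions starting in the window, outpatient counts per service
#' category, and a severe-disability discharge-code flag.  Prescriptions for
#' drugs absent from the catalogue are counted in `n_dmt_other` with a
#' warning, never dropped silently.
#'
#' @param cohort data frame with `patient_id`, `entry_date`, `sex`,
#'   `birth_year` (the `included` element of [apply_exclusions()]).
#' @param prescriptions,admissions,outpatients administrative tables.
#' @param catalog DMT catalogue.
#' @param window_start per-patient window start dates; default the entry
#'   date.  A single date recycles to all patients (used for calendar-year
#'   windows).
#' @param severe_codes ICD-9 codes flagging severe disability.
#' @return data frame with `patient_id`, `window_start`, `window_end` and
#'   the [feature_columns()]; age is window-start year minus birth year and
#'   `female` is 1 for sex `"F"`.
#' @export
build_features <- function(cohort, prescriptions, admissions, outpatients,
                           catalog = default_dmt_catalog(),
                           window_start = NULL,
                           severe_codes = default_severe_disability_codes()) {
  prescriptions <- validate_prescriptions(prescriptions)
  admissions <- validate_admissions(admissions)
  outpatients <- validate_outpatients(outpatients)
  catalog <- validate_dmt_catalog(catalog)
  stopifnot(all(c("patient_id", "entry_date", "sex", "birth_year") %in%
                  names(cohort)))

  ws <- if (is.null(window_start)) cohort$entry_date else
    rep(as.Date(window_start), length.out = nrow(cohort))
  we <- add_months(ws, 6L)
  win <- data.table(patient_id = cohort$patient_id, ws = ws, we = we)
  setkey(win, patient_id)

  zero <- function() numeric(nrow(cohort))
  out <- data.table(
    patient_id = cohort$patient_id,
    window_start = ws,
    window_end = we,
    age = as.integer(format(ws, "%Y")) - cohort$birth_year,
    female = as.numeric(cohort$sex == "F")
  )
  for (col in setdiff(feature_columns(), c("age", "female"))) {
    out[[col]] <- zero()
  }
  setkey(out, patient_id)

  # --- prescriptions in window ---
  rx <- as.data.table(prescriptions)[win, on = "patient_id", nomatch = NULL]
  rx <- rx[date >= ws & date < we]
  if (nrow(rx)) {
    cat_dt <- as.data.table(catalog)
    rx <- cat_dt[rx, on = "drug_name"]
    unknown <- unique(rx$drug_name[is.na(rx$route_class)])
    if (length(unknown)) {
      warning(sprintf("uncatalogued drug(s) counted as 'other': %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
    }
    agg <- rx[, {
      plat_dates <- date[!is.na(efficacy_tier) & efficacy_tier == "platform"]
      he_dates <- date[!is.na(efficacy_tier) &
                         efficacy_tier == "high_efficacy"]
      # union of 30-day supplies clipped to the window
      s <- pmax(as.numeric(date - ws), 0)
      e <- pmin(s + 30, as.numeric(we - ws))
      o <- order(s)
      s <- s[o]; e <- e[o]
      covered <- 0; cur_e <- -Inf
      for (j in seq_along(s)) {
        if (s[j] >= cur_e) {
          covered <- covered + (e[j] - s[j])
          cur_e <- e[j]
        } else if (e[j] > cur_e) {
          covered <- covered + (e[j] - cur_e)
          cur_e <- e[j]
        }
      }
      list(
        n_dmt_mab = sum(route_class == "MAB", na.rm = TRUE),
        n_dmt_oral = sum(route_class == "oral", na.rm = TRUE),
        n_dmt_injectable = sum(route_class == "injectable", na.rm = TRUE),
        n_dmt_platform = length(plat_dates),
        n_dmt_high_efficacy = length(he_dates),
        n_dmt_other = sum(is.na(route_class)),
        therapy_duration = covered,
        switch_platform_to_high = as.numeric(
          length(plat_dates) > 0 && length(he_dates) > 0 &&
            min(plat_dates) < max(he_dates))
      )
    }, by = patient_id]
    cols <- setdiff(names(agg), "patient_id")
    out[agg, on = "patient_id", (cols) := mget(paste0("i.", cols))]
  }

  # --- admissions starting in window ---
  adm <- as.data.table(admissions)[win, on = "patient_id", nomatch = NULL]
  adm <- adm[admit_date >= ws & admit_date < we]
  if (nrow(adm)) {
    code_list <- split_icd9(adm$icd9_codes)
    adm[, `:=`(
      ms_rel = vapply(code_list, function(x) "340" %in% x, logical(1L)),
      severe = vapply(code_list, function(x) any(x %in% severe_codes),
                      logical(1L)),
      los = as.numeric(discharge_date - admit_date)
    )]
    agg <- adm[, list(
      n_admissions = .N,
      n_ms_admissions = sum(ms_rel),
      n_emergency_admissions = sum(emergency_flag == 1),
      total_admission_length = sum(los),
      severe_disability_flag = as.numeric(any(severe))
    ), by = patient_id]
    cols <- setdiff(names(agg), "patient_id")
    out[agg, on = "patient_id", (cols) := mget(paste0("i.", cols))]
  }

  # --- outpatient encounters in window ---
  op <- as.data.table(outpatients)[win, on = "patient_id", nomatch = NULL]
  op <- op[date >= ws & date < we]
  if (nrow(op)) {
    cats <- c("consultation", "diagnostic", "laboratory", "procedure",
              "therapeutic", "rehabilitation")
    agg <- op[service_category %in% cats,
              .N, by = list(patient_id, service_category)]
    if (nrow(agg)) {
      wide <- dcast(agg, patient_id ~ service_category, value.var = "N",
                    fill = 0)
      for (cc in intersect(cats, names(wide))) {
        out[wide, on = "patient_id", (paste0("n_", cc)) := get(paste0("i.", cc))]
      }
    }
  }

  setDF(out)
  out
}

#' Map numeric EDSS scores to the three ordinal classes
#'
#' C1: EDSS <= 3.0 (no to mild disability); C2: 3.5-5.5 (moderate, limited
#' activity); C3: >= 6.0 (severe, ambulatory aid required).  Scores must lie
#' in 0-10 on the 0.5-step grid.
#'
#' @param edss numeric EDSS scores.
#' @return factor with levels `C1`, `C2`, `C3`.
#' @export
edss_class <- function(edss) {
  bad <- which(is.na(edss) | edss < 0 | edss > 10 |
                 abs(edss * 2 - round(edss * 2)) > 1e-9)
  if (length(bad)) {
    stop(sprintf("invalid EDSS value at position %d: %s (must be 0-10 in 0.5 steps)",
                 bad[1L], format(edss[bad[1L]])), call. = FALSE)
  }
  cls <- ifelse(edss <= 3, "C1", ifelse(edss <= 5.5, "C2", "C3"))
  factor(cls, levels = c("C1", "C2", "C3"))
}

#' Attach EDSS class labels from the clinical registry
#'
#' For each patient with features, selects the relapse-free clinical EDSS
#' assessment nearest to the window end (ties broken towards the earlier
#' assessment) and maps it to a class.  Patients with no eligible assessment
#' are omitted from the labelled set (they remain available for
#' whole-population inference).
#'
#' @param features output of [build_features()].
#' @param clinical_edss clinical registry table (`patient_id`, `visit_date`,
#'   `edss`, `relapse_flag`).
#' @return data frame with `patient_id`, `visit_date`, `edss` and `class`.
#' @export
label_cohort <- function(features, clinical_edss) {
  require_columns(clinical_edss, c("patient_id", "visit_date", "edss",
                                   "relapse_flag"), "clinical_edss")
  clin <- clinical_edss
  clin$visit_date <- as_date_strict(clin$visit_date, "clinical_edss$visit_date")
  edss_class(clin$edss)  # validates the whole column
  clin <- clin[clin$relapse_flag == 0, , drop = FALSE]
  dt <- as.data.table(clin)[
    data.table(patient_id = features$patient_id,
               window_end = features$window_end),
    on = "patient_id", nomatch = NULL]
  if (nrow(dt) == 0L) {
    return(data.frame(patient_id = character(),
                      visit_date = as.Date(character()),
                      edss = numeric(),
                      class = factor(character(),
                                     levels = c("C1", "C2", "C3"))))
  }
  dt[, dist := abs(as.numeric(visit_date - window_end))]
  setorderv(dt, c("patient_id", "dist", "visit_date"))
  lab <- dt[, .SD[1L], by = patient_id]
  out <- data.frame(patient_id = lab$patient_id,
                    visit_date = lab$visit_date,
                    edss = lab$edss,
                    class = edss_class(lab$edss),
                    stringsAsFactors = FALSE)
  out[order(out$patient_id), , drop = FALSE]
}

#' Build time-to-progression samples from the clinical registry
#'
#' For each labelled patient the baseline class is the relapse-free
#' assessment nearest to the entry date.  The event is the first relapse-free
#' assessment in a higher class; its time is the midpoint (in months from
#' entry) between the last lower-class assessment and the event assessment,
#' reflecting that the transition occurred between visits.  Patients with no
#' observed transition are censored at their last relapse-free assessment.
#' Patients already in the top class at baseline are excluded (the top class
#' is absorbing), as are patients with no positive follow-up time.
#'
#' @param features output of [build_features()] (defines entry dates).
#' @param clinical_edss clinical registry table.
#' @return data frame with `patient_id`, `baseline_class`, `time` (months,
#'   > 0), `event` (1 = transition to a higher class, 0 = censored).
#' @export
build_survival_samples <- function(features, clinical_edss) {
  require_columns(clinical_edss, c("patient_id", "visit_date", "edss",
                                   "relapse_flag"), "clinical_edss")
  clin <- clinical_edss[clinical_edss$relapse_flag == 0, , drop = FALSE]
  clin$visit_date <- as_date_strict(clin$visit_date, "clinical_edss$visit_date")
  clin$class_num <- as.integer(edss_class(clin$edss))
  dt <- as.data.table(clin)[
    data.table(patient_id = features$patient_id,
               entry = features$window_start),
    on = "patient_id", nomatch = NULL]
  setorderv(dt, c("patient_id", "visit_date"))
  res <- dt[, {
    d_entry <- abs(as.numeric(visit_date - entry[1L]))
    base <- class_num[which.min(d_entry)]
    if (base >= 3L) {
      list(baseline_class = base, time = NA_real_, event = NA_integer_)
    } else {
      hit <- which(class_num > base)
      if (length(hit)) {
        h <- hit[1L]
        prev_date <- if (h > 1L) visit_date[h - 1L] else entry[1L]
        mid <- prev_date + as.numeric(visit_date[h] - prev_date) / 2
        list(baseline_class = base,
             time = months_between(entry[1L], mid),
             event = 1L)
      } else {
        list(baseline_class = base,
             time = months_between(entry[1L], visit_date[.N]),
             event = 0L)
      }
    }
  }, by = patient_id]
  res <- res[!is.na(time) & time > 0]
  setDF(res)
  res
}
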