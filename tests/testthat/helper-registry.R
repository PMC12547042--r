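# Shared synthetic-registry fixtures, generated once per test run.

small_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_registry(
        sim_config(n_patients = 600, clinical_subset_frac = 0.5, seed = 101))
    }
    cache
  }
})

# Hand-built micro tables for exact-value cohort tests.
micro_tables <- function() {
  list(
    prescriptions = data.frame(
      patient_id = c("A", "B", "B", "E"),
      date = as.Date(c("2016-02-10", "2016-02-01", "2016-05-01",
                       "2016-03-01")),
      drug_name = c("natalizumab", "glatiramer acetate", "fingolimod",
                    "vitamin d"),
      stringsAsFactors = FALSE
    ),
    admissions = data.frame(
      patient_id = c("C", "D", "D"),
      admit_date = as.Date(c("2016-04-01", "2016-01-10", "2016-03-10")),
      discharge_date = as.Date(c("2016-04-05", "2016-01-13", "2016-03-14")),
      icd9_codes = c("401.9;340", "340", "340"),
      emergency_flag = c(1L, 0L, 1L),
      stringsAsFactors = FALSE
    ),
    outpatients = data.frame(
      patient_id = c("A", "C", "F"),
      date = as.Date(c("2016-02-15", "2016-04-20", "2016-06-01")),
      service_category = c("consultation", "rehabilitation", "laboratory"),
      stringsAsFactors = FALSE
    ),
    demographics = data.frame(
      patient_id = c("A", "B", "C", "D", "E", "F"),
      sex = c("F", "M", "F", NA, "F", "M"),
      birth_year = c(1980L, 1975L, 1990L, 1985L, 1970L, 1960L),
      resident_flag = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE
    )
  )
}
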