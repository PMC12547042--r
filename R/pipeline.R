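# End-to-end convenience wrapper: simulate (or accept) a linked registry,
# run case-finding, exclusions, feature building and labelling, train the
# classifier and the neural Cox model, and project class transitions over
# the horizon.

#' Run the full disability-estimation pipeline
#'
#' Chains every stage on a registry: [find_cases()], [apply_exclusions()],
#' [build_features()] on entry windows, [label_cohort()],
#' [train_classifier()] (with a held-out classification report),
#' [build_survival_samples()], [train_survival()], [yearly_distribution()],
#' 5-year cumulative-hazard prediction on the projection-year windows,
#' [risk_profiles()] and [project_transitions()].
#'
#' Current classes for the projection are the classifier's predictions on
#' features from the projection year, so the whole (mostly unlabelled)
#' population is covered; clinical labels enter only through training.
#'
#' @param registry an `ms_registry` from [simulate_registry()] (or a list
#'   with the same table elements).
#' @param classifier_cfg a [classifier_config()]; the default uses the
#'   reference architecture with 60 epochs, which reaches a training-loss
#'   plateau on cohorts with a few hundred to a few thousand labelled
#'   patients.
#' @param survival_cfg a [survival_config()].
#' @param horizon projection horizon in months.
#' @param years calendar years for the class-distribution series.
#' @param projection_year calendar year whose January-anchored window
#'   defines the current state for projection.
#' @param catalog DMT catalogue.
#' @return list of class `edssprog_pipeline` with the intermediate objects
#'   (`cases`, `included`, `exclusion_report`, `features`, `labels`,
#'   `classifier`, `classifier_eval`, `survival_samples`, `cox_model`,
#'   `yearly`, `profiles`, `threshold`, `transition`, and the
#'   projection-year `current_features` / `current_classes`).
#' @export
run_pipeline <- function(registry,
                         classifier_cfg = classifier_config(epochs = 60L),
                         survival_cfg = survival_config(),
                         horizon = 60,
                         years = 2016:2021,
                         projection_year = 2021L,
                         catalog = default_dmt_catalog()) {
  cases <- find_cases(registry$prescriptions, registry$admissions,
                      registry$outpatients, catalog = catalog)
  excl <- apply_exclusions(cases, registry$demographics)
  cohort <- excl$included

  features <- build_features(cohort, registry$prescriptions,
                             registry$admissions, registry$outpatients,
                             catalog = catalog)
  labels <- label_cohort(features, registry$clinical_edss)

  classifier <- train_classifier(features, labels, classifier_cfg)
  eval_rep <- NULL
  val_idx <- classifier$report$val_idx
  if (length(val_idx)) {
    dat <- classifier_xy(features, labels)
    pred <- predict_classes(classifier, dat$x[val_idx, , drop = FALSE])
    eval_rep <- classification_report(dat$y[val_idx], pred$class,
                                      seed = classifier_cfg$seed)
  }

  samples <- build_survival_samples(features, registry$clinical_edss)
  cox_model <- train_survival(samples, features, survival_cfg)

  yearly <- yearly_distribution(classifier, cohort,
                                registry$prescriptions,
                                registry$admissions, registry$outpatients,
                                years = years, catalog = catalog)

  proj_ws <- as.Date(sprintf("%d-01-01", projection_year))
  proj_cohort <- cohort[cohort$entry_date <= proj_ws, , drop = FALSE]
  cur_features <- build_features(proj_cohort, registry$prescriptions,
                                 registry$admissions, registry$outpatients,
                                 catalog = catalog, window_start = proj_ws)
  cur_classes <- predict_classes(classifier, cur_features)$class
  haz <- predict_cumulative_hazard(cox_model, cur_features, horizon)

  prof <- risk_profiles(proj_cohort$patient_id, cur_classes, haz$H,
                        seed = survival_cfg$seed)
  transition <- project_transitions(prof, mode = "expected")

  structure(list(
    cases = cases,
    included = cohort,
    exclusion_report = excl$report,
    features = features,
    labels = labels,
    classifier = classifier,
    classifier_eval = eval_rep,
    survival_samples = samples,
    cox_model = cox_model,
    yearly = yearly,
    current_features = cur_features,
    current_classes = cur_classes,
    profiles = prof,
    threshold = prof$threshold,
    transition = transition,
    horizon = horizon,
    projection_year = projection_year
  ), class = "edssprog_pipeline")
}
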