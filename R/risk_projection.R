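# Whole-population class distribution by calendar year, k-means risk
# stratification on the 5-year cumulative hazard, high-risk threshold
# extraction, and projection of class transitions over the horizon with
# Sankey-ready output.

#' Predicted class distribution per calendar year
#'
#' For each requested year, builds 6-month-window features anchored at
#' January 1st for patients active that year (entered by the window start
#' and with at least one administrative record inside the window), applies
#' the classifier, and reports the predicted class proportions.  Years with
#' no active patients are omitted with a warning.
#'
#' @param classifier a trained [train_classifier()] model.
#' @param cohort included cohort (`patient_id`, `entry_date`, `sex`,
#'   `birth_year`).
#' @param prescriptions,admissions,outpatients administrative tables.
#' @param years integer vector of calendar years.
#' @param catalog DMT catalogue.
#' @return data frame with `year`, `n`, and per-class proportions `C1`,
#'   `C2`, `C3` (each row sums to 1).
#' @export
yearly_distribution <- function(classifier, cohort, prescriptions,
                                admissions, outpatients, years,
                                catalog = default_dmt_catalog()) {
  act_dt <- rbindlist(list(
    data.table(patient_id = prescriptions$patient_id,
               date = prescriptions$date),
    data.table(patient_id = admissions$patient_id,
               date = admissions$admit_date),
    data.table(patient_id = outpatients$patient_id,
               date = outpatients$date)))
  rows <- list()
  for (yr in years) {
    ws <- as.Date(sprintf("%d-01-01", yr))
    we <- add_months(ws, 6L)
    active_ids <- unique(act_dt[date >= ws & date < we, patient_id])
    sub <- cohort[cohort$entry_date <= ws &
                    cohort$patient_id %in% active_ids, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning(sprintf("year %d has no active patients; omitted", yr),
              call. = FALSE)
      next
    }
    feats <- build_features(sub, prescriptions, admissions, outpatients,
                            catalog = catalog, window_start = ws)
    pred <- predict_classes(classifier, feats)
    prop <- as.numeric(table(pred$class) / length(pred$class))
    rows[[length(rows) + 1L]] <-
      data.frame(year = yr, n = nrow(sub),
                 C1 = prop[1L], C2 = prop[2L], C3 = prop[3L])
  }
  do.call(rbind, rows)
}

#' One-dimensional k-means clustering of risk values
#'
#' Minimizes the within-cluster sum of squares over `k` clusters by keeping
#' the best of `n_restarts` seeded random starts of [stats::kmeans()] plus
#' one deterministic quantile-based start.  Clusters are relabelled in
#' increasing centroid order, so with `k = 3` the labels low / moderate /
#' high are deterministic.
#'
#' @param values numeric vector (at least `k` distinct values).
#' @param k number of clusters.
#' @param n_restarts random restarts.
#' @param seed RNG seed.
#' @return list of class `kmeans_1d`: `centers` (increasing), `cluster`
#'   (integer assignments, 1 = lowest), `labels` (factor
#'   low/moderate/high when `k = 3`), `values`, `tot_withinss`.
#' @export
kmeans_1d <- function(values, k = 3L, n_restarts = 10L, seed = 1L) {
  values <- as.numeric(values)
  uv <- unique(values)
  if (length(uv) < k) {
    stop(sprintf("need at least %d distinct values for %d clusters", k, k),
         call. = FALSE)
  }
  if (k == 1L) {
    return(structure(list(centers = mean(values),
                          cluster = rep(1L, length(values)),
                          labels = factor(rep(1L, length(values))),
                          values = values,
                          tot_withinss = sum((values - mean(values))^2),
                          k = 1L),
                     class = "kmeans_1d"))
  }
  set.seed(seed)
  best <- NULL
  starts <- c(lapply(seq_len(n_restarts), function(i) sample(uv, k)),
              list(as.numeric(quantile(uv, (seq_len(k) - 0.5) / k,
                                       type = 1))))
  for (st in starts) {
    if (length(unique(st)) < k) next
    km <- suppressWarnings(
      kmeans(values, centers = matrix(st, ncol = 1L), iter.max = 100L))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  o <- order(best$centers)
  relabel <- integer(k)
  relabel[o] <- seq_len(k)
  cluster <- relabel[best$cluster]
  labels <- if (k == 3L) {
    factor(c("low", "moderate", "high")[cluster],
           levels = c("low", "moderate", "high"))
  } else {
    factor(cluster)
  }
  structure(list(centers = as.numeric(best$centers[o]),
                 cluster = cluster, labels = labels, values = values,
                 tot_withinss = best$tot.withinss, k = k),
            class = "kmeans_1d")
}

#' High-risk threshold from ordered risk clusters
#'
#' The threshold is the smallest risk value assigned to the highest cluster;
#' patients at or above it are high-risk.  In one dimension the optimal
#' clusters are contiguous, so the threshold strictly exceeds every value in
#' the lower clusters.
#'
#' @param clusters a [kmeans_1d()] result.
#' @return scalar threshold.
#' @export
risk_threshold <- function(clusters) {
  stopifnot(inherits(clusters, "kmeans_1d"))
  high <- clusters$values[clusters$cluster == clusters$k]
  if (length(high) == 0L) stop("high cluster is empty", call. = FALSE)
  min(high)
}

#' Assemble per-patient risk profiles
#'
#' Combines the current class, the predicted cumulative hazard at the
#' horizon `H`, the implied progression probability `p = 1 - exp(-H)`, and
#' the k-means risk cluster (low/moderate/high) with its threshold.
#'
#' @param patient_id patient identifiers.
#' @param class current EDSS class (factor C1/C2/C3).
#' @param H5 predicted cumulative hazard at the horizon.
#' @param n_restarts,seed passed to [kmeans_1d()].
#' @return list of class `risk_profiles`: `profiles` (data frame),
#'   `threshold`, `clusters`.
#' @export
risk_profiles <- function(patient_id, class, H5, n_restarts = 10L,
                          seed = 1L) {
  stopifnot(length(patient_id) == length(class),
            length(class) == length(H5), all(H5 >= 0))
  cl <- kmeans_1d(H5, k = 3L, n_restarts = n_restarts, seed = seed)
  profiles <- data.frame(
    patient_id = patient_id,
    class = factor(as.character(class), levels = c("C1", "C2", "C3")),
    H5 = H5,
    p5 = 1 - exp(-H5),
    risk_cluster = cl$labels,
    stringsAsFactors = FALSE
  )
  structure(list(profiles = profiles, threshold = risk_threshold(cl),
                 clusters = cl), class = "risk_profiles")
}

# Internal constructor shared with the generator's analytic benchmark:
# expected-flow transition matrix from per-patient current classes and
# progression probabilities.
expected_transition_matrix <- function(class_num, p) {
  n <- length(class_num)
  m <- matrix(0, 3L, 3L, dimnames = list(from = c("C1", "C2", "C3"),
                                         to = c("C1", "C2", "C3")))
  for (c0 in 1:2) {
    in_c <- class_num == c0
    m[c0, c0 + 1L] <- sum(p[in_c]) / n
    m[c0, c0] <- sum(1 - p[in_c]) / n
  }
  m[3L, 3L] <- sum(class_num == 3L) / n
  new_transition_table(m)
}

new_transition_table <- function(m) {
  validate_transition_table(m)
  structure(m, class = c("transition_table", "matrix"))
}

validate_transition_table <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3L, 3L)))
  if (any(m < -1e-12)) stop("transition flows must be non-negative",
                            call. = FALSE)
  if (abs(sum(m) - 1) > 1e-9) stop("transition mass must total 1",
                                   call. = FALSE)
  if (any(m[lower.tri(m)] > 1e-12)) {
    stop("downward flows are not allowed in a progression-only projection",
         call. = FALSE)
  }
  invisible(m)
}

#' Project class transitions over the horizon
#'
#' Converts per-patient risk profiles into a 3x3 transition table of
#' population proportions from the current classes to the projected ones.
#' In `mode = "expected"` (default) each patient below the top class moves
#' to the adjacent higher class with probability `p5` and stays otherwise,
#' so flows are expected population fractions; in `mode = "threshold"`
#' patients move if and only if their hazard reaches the high-risk
#' threshold.  The top class is absorbing; moves are restricted to the
#' adjacent class within the horizon.
#'
#' @param profiles a [risk_profiles()] object (or its `profiles` data frame
#'   plus `threshold` for threshold mode).
#' @param mode `"expected"` or `"threshold"`.
#' @param threshold high-risk threshold; defaults to the one stored in
#'   `profiles`.
#' @return a `transition_table`: 3x3 matrix of proportions with row sums
#'   equal to the current-class marginals and total mass 1.
#' @export
project_transitions <- function(profiles, mode = c("expected", "threshold"),
                                threshold = NULL) {
  mode <- match.arg(mode)
  if (inherits(profiles, "risk_profiles")) {
    threshold <- threshold %||% profiles$threshold
    df <- profiles$profiles
  } else {
    df <- profiles
  }
  cls <- as.integer(factor(as.character(df$class),
                           levels = c("C1", "C2", "C3")))
  p <- switch(mode,
    expected = df$p5,
    threshold = {
      if (is.null(threshold)) {
        stop("threshold mode requires a threshold", call. = FALSE)
      }
      as.numeric(df$H5 >= threshold)
    })
  expected_transition_matrix(cls, p)
}

#' Marginal class distributions of a transition table
#'
#' @param table a `transition_table`.
#' @return list with `from` (current-year marginals, row sums) and `to`
#'   (projected marginals, column sums).
#' @export
transition_marginals <- function(table) {
  validate_transition_table(table)
  list(from = rowSums(table), to = colSums(table))
}

#' Export a transition table as Sankey flow records
#'
#' Emits one `(source_class, target_class, flow)` row per positive flow
#' (an identity table yields the three self-flows only); flows sum to 1.
#' Writable as CSV for plotting.
#'
#' @param table a `transition_table`.
#' @param file optional path to write the records as CSV.
#' @return data frame of flow records (invisibly written to `file` if
#'   given).
#' @export
sankey_export <- function(table, file = NULL) {
  validate_transition_table(table)
  idx <- which(table > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  out <- data.frame(
    source_class = rownames(table)[idx[, 1L]],
    target_class = colnames(table)[idx[, 2L]],
    flow = table[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(file)) fwrite(out, file)
  out
}

#' Rebuild a transition table from Sankey flow records
#'
#' Inverse of [sankey_export()]: unlisted flows are zero.
#'
#' @param flows data frame with `source_class`, `target_class`, `flow`.
#' @return a `transition_table`.
#' @export
sankey_import <- function(flows) {
  lev <- c("C1", "C2", "C3")
  m <- matrix(0, 3L, 3L, dimnames = list(from = lev, to = lev))
  for (r in seq_len(nrow(flows))) {
    m[flows$source_class[r], flows$target_class[r]] <- flows$flow[r]
  }
  new_transition_table(m)
}
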