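# Evaluation statistics: classification metrics with bootstrap confidence
# intervals, Harrell's concordance index, the IPCW (integrated) Brier score,
# and the Kaplan-Meier product-limit estimator.

#' Classification metrics with bootstrap confidence intervals
#'
#' Builds the 3x3 confusion matrix (rows = true class, columns = predicted)
#' and reports accuracy plus macro-averaged precision, recall and F1, with
#' per-class precision, recall (= sensitivity), specificity and F1.
#' 95% confidence intervals come from a seeded patient-level percentile
#' bootstrap.
#'
#' @param true,predicted equal-length class labels (factors or characters
#'   over C1/C2/C3).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @param conf confidence level.
#' @return list of class `classification_report` with elements `confusion`,
#'   `accuracy`, `precision`, `recall`, `f1` (macro), `per_class` (data
#'   frame), and `ci` (data frame of percentile intervals).
#' @export
classification_report <- function(true, predicted, n_boot = 1000L,
                                  seed = 1L, conf = 0.95) {
  if (length(true) == 0L) stop("empty input", call. = FALSE)
  if (length(true) != length(predicted)) {
    stop("true and predicted must have equal length", call. = FALSE)
  }
  lev <- c("C1", "C2", "C3")
  if (!all(as.character(true) %in% lev) ||
        !all(as.character(predicted) %in% lev)) {
    stop("labels must be within C1, C2, C3", call. = FALSE)
  }
  true <- factor(as.character(true), levels = lev)
  predicted <- factor(as.character(predicted), levels = lev)

  point <- classification_point_metrics(true, predicted, lev)

  set.seed(seed)
  n <- length(true)
  boot <- matrix(NA_real_, n_boot, 4L,
                 dimnames = list(NULL, c("accuracy", "precision", "recall",
                                         "f1")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    m <- classification_point_metrics(true[idx], predicted[idx], lev)
    boot[b, ] <- c(m$accuracy, m$precision, m$recall, m$f1)
  }
  alpha <- (1 - conf) / 2
  ci <- data.frame(
    metric = colnames(boot),
    estimate = c(point$accuracy, point$precision, point$recall, point$f1),
    lower = apply(boot, 2L, quantile, probs = alpha, na.rm = TRUE),
    upper = apply(boot, 2L, quantile, probs = 1 - alpha, na.rm = TRUE),
    row.names = NULL
  )
  structure(c(point, list(ci = ci, n = n, n_boot = n_boot)),
            class = "classification_report")
}

classification_point_metrics <- function(true, predicted, lev) {
  cm <- table(true = true, predicted = predicted)
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  per <- lapply(seq_along(lev), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    tn <- total - tp - fp - fn
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else NA_real_
    specificity <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    c(precision = precision, recall = recall, f1 = f1,
      sensitivity = recall, specificity = specificity)
  })
  per_class <- cbind(data.frame(class = lev), do.call(rbind, per))
  list(confusion = cm,
       accuracy = acc,
       precision = mean(per_class$precision, na.rm = TRUE),
       recall = mean(per_class$recall, na.rm = TRUE),
       f1 = mean(per_class$f1, na.rm = TRUE),
       per_class = per_class)
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (n = %d)\n", x$n))
  print(x$confusion)
  cat(sprintf("accuracy %.3f | macro precision %.3f | recall %.3f | F1 %.3f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Over pairs (i, j) with `t_i < t_j` and `event_i = 1`, counts the pair
#' concordant when `risk_i > risk_j`, with half credit for tied risks;
#' pairs whose earlier time is censored are not comparable.
#'
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param risk_scores predicted risks (higher = earlier event expected).
#' @return concordance in [0, 1].
#' @export
concordance_index <- function(times, events, risk_scores) {
  stopifnot(length(times) == length(events),
            length(times) == length(risk_scores))
  earlier <- outer(times, times, "<")
  usable <- earlier & (events == 1)
  n_comp <- sum(usable)
  if (n_comp == 0L) {
    stop("no comparable pairs (need an event with a strictly later time)",
         call. = FALSE)
  }
  conc <- sum(usable & outer(risk_scores, risk_scores, ">"))
  tied <- sum(usable & outer(risk_scores, risk_scores, "=="))
  (conc + 0.5 * tied) / n_comp
}

#' Kaplan-Meier product-limit estimator
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @return object of class `km_curve`: data frame fields `time`, `n_risk`,
#'   `n_event`, `survival` (after each distinct event time), plus `surv_at`,
#'   a right-continuous evaluator with S(0) = 1.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("empty sample", call. = FALSE)
  if (any(times < 0)) stop("negative times are invalid", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  ord <- order(times)
  t_sorted <- times[ord]
  e_sorted <- events[ord]
  ut <- unique(t_sorted[e_sorted == 1])
  n <- length(times)
  n_risk <- vapply(ut, function(t) sum(t_sorted >= t), numeric(1L))
  n_event <- vapply(ut, function(t) sum(t_sorted == t & e_sorted == 1),
                    numeric(1L))
  surv <- cumprod(1 - n_event / n_risk)
  est <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    survival = surv)
  structure(list(
    time = ut, n_risk = n_risk, n_event = n_event, survival = surv,
    table = est,
    surv_at = function(t) c(1, surv)[findInterval(t, ut) + 1L]
  ), class = "km_curve")
}

# S(t-) evaluator (left limit), needed for IPCW weights at event times.
km_surv_before <- function(km, t) {
  idx <- findInterval(t, km$time, left.open = TRUE)
  c(1, km$survival)[idx + 1L]
}

#' Integrated Brier score with censoring weights
#'
#' Computes the Brier score `BS(t)` on a time grid using inverse
#' probability-of-censoring weights from the Kaplan-Meier estimate of the
#' censoring distribution `G`: subjects with an event by `t` contribute
#' `S(t|x)^2 / G(t_i-)`, subjects still at risk contribute
#' `(1 - S(t|x))^2 / G(t)`.  The integrated score is the trapezoid average
#' of `BS(t)` over the grid.  Subjects whose required censoring weight is
#' zero are excluded with a warning.
#'
#' @param surv matrix of predicted survival probabilities, rows = subjects,
#'   columns = grid times.
#' @param times,events follow-up data for the same subjects.
#' @param grid increasing evaluation times spanning the follow-up range;
#'   defaults to 100 evenly spaced points between the first and last
#'   observed event times.
#' @return scalar IBS with attributes `grid` and `bs` (the per-time Brier
#'   scores).
#' @export
integrated_brier_score <- function(surv, times, events, grid = NULL) {
  if (is.null(grid)) {
    ev <- sort(unique(times[events == 1]))
    if (length(ev) < 2L) stop("need at least two event times for the default grid",
                              call. = FALSE)
    grid <- seq(min(ev), max(ev), length.out = 100L)
  }
  surv <- as.matrix(surv)
  if (nrow(surv) != length(times) || ncol(surv) != length(grid)) {
    stop("surv must be a (subjects x grid) matrix of predicted survival",
         call. = FALSE)
  }
  cens_km <- kaplan_meier(times, 1 - events)
  g_at_event <- km_surv_before(cens_km, times)   # G(t_i-)
  g_at_grid <- cens_km$surv_at(grid)             # G(t)
  dropped <- FALSE
  bs <- numeric(length(grid))
  for (j in seq_along(grid)) {
    t <- grid[j]
    had_event <- times <= t & events == 1
    at_risk <- times > t
    w <- numeric(length(times))
    contrib <- numeric(length(times))
    contrib[had_event] <- surv[had_event, j]^2
    w[had_event] <- g_at_event[had_event]
    contrib[at_risk] <- (1 - surv[at_risk, j])^2
    w[at_risk] <- g_at_grid[j]
    use <- (had_event | at_risk)
    bad <- use & w <= 0
    if (any(bad)) {
      dropped <- TRUE
      use <- use & !bad
    }
    bs[j] <- sum(contrib[use] / w[use]) / length(times)
  }
  if (dropped) {
    warning("subjects with zero censoring-survival weight excluded from the Brier score",
            call. = FALSE)
  }
  ibs <- trapezoid(grid, bs) /
    if (length(grid) > 1L) diff(range(grid)) else 1
  structure(ibs, grid = grid, bs = bs)
}
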