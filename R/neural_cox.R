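# Hybrid progression model: a feed-forward risk network g(x) trained with
# the negative log Cox partial likelihood (Breslow convention for ties),
# plus the Breslow baseline cumulative hazard turning scores into absolute
# cumulative hazards H(t|x) = H0(t) * exp(g(x)).

#' Negative log Cox partial likelihood
#'
#' Computes `-sum over events [g_i - log sum_{j in R(t_i)} exp(g_j)]` with
#' risk set `R(t) = {j : t_j >= t}` and the Breslow convention for tied
#' event times (all ties share the full risk-set sum).  Translation of all
#' scores by a constant leaves the value unchanged.
#'
#' @param risk_scores numeric vector of model scores g.
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators; at least one event is required.
#' @return non-negative scalar loss.
#' @export
cox_loss <- function(risk_scores, times, events) {
  check_survival_vectors(risk_scores, times, events)
  parts <- cox_riskset_parts(risk_scores, times, events)
  with(parts, -sum(g_sorted[e_sorted == 1] - log(S[e_sorted == 1])))
}

check_survival_vectors <- function(risk_scores, times, events) {
  if (!(length(risk_scores) == length(times) &&
          length(times) == length(events))) {
    stop("risk_scores, times, events must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("times must be positive and finite", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) {
    stop("events must be 0/1", call. = FALSE)
  }
  if (sum(events) < 1) {
    stop("Cox partial likelihood undefined with zero events", call. = FALSE)
  }
  invisible(TRUE)
}

# Shared machinery: sorts by time, computes per-observation risk-set sums
# (ties grouped), in a numerically centred exp scale.
cox_riskset_parts <- function(risk_scores, times, events) {
  ord <- order(times)
  t_sorted <- times[ord]
  e_sorted <- events[ord]
  g_raw <- risk_scores[ord]
  shift <- max(g_raw)
  g_sorted <- g_raw - shift          # shift cancels in g - log S
  w <- exp(g_sorted)
  rs <- rev(cumsum(rev(w)))
  grp <- match(t_sorted, t_sorted)   # first index of each tie group
  S <- rs[grp]
  list(ord = ord, t_sorted = t_sorted, e_sorted = e_sorted,
       g_sorted = g_sorted, w = w, grp = grp, S = S)
}

# Gradient of cox_loss with respect to the risk scores (original order).
cox_loss_grad <- function(risk_scores, times, events) {
  parts <- cox_riskset_parts(risk_scores, times, events)
  with(parts, {
    ug <- unique(grp)
    d <- vapply(ug, function(i) sum(e_sorted[grp == i]), numeric(1L))
    term <- d / S[ug]
    cum_term <- cumsum(term)
    cum_w <- cum_term[match(grp, ug)]
    grad_sorted <- -e_sorted + w * cum_w
    grad <- numeric(length(grad_sorted))
    grad[ord] <- grad_sorted
    grad
  })
}

#' Survival-model configuration
#'
#' Defaults follow the reference risk network for this task: three ReLU
#' hidden layers of 32, 32 and 16 units, a linear 1-unit score output, Adam
#' optimization of the full-batch Cox partial likelihood with early stopping
#' on validation loss, and 5-fold cross-validation with a 60/20/20
#' train/validation/test split of the total sample (each fold's 20% is the
#' test subset; the remaining 80% is split 3:1 into train and validation).
#' `hidden_sizes = integer(0)` gives a linear risk score, i.e. a classical
#' Cox model fitted by gradient descent.
#'
#' @param hidden_sizes integer vector of hidden widths (possibly empty).
#' @param learning_rate Adam learning rate.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience: training stops when validation
#'   loss has not improved by `tol` for this many consecutive epochs.
#' @param tol minimum improvement of (per-event) validation loss.
#' @param l2 L2 penalty on weights.
#' @param cv_folds number of outer cross-validation folds; 0 disables
#'   cross-validation (only the final fit is produced).
#' @param split length-3 train/validation/test fractions, summing to 1.
#' @param seed integer seed; fixes fold assignment, splits, initialization.
#' @return an object of class `survival_config`.
#' @export
survival_config <- function(hidden_sizes = c(32L, 32L, 16L),
                            learning_rate = 0.01,
                            max_epochs = 500L,
                            patience = 10L,
                            tol = 1e-4,
                            l2 = 0,
                            cv_folds = 5L,
                            split = c(0.60, 0.20, 0.20),
                            seed = 1L) {
  cfg <- list(hidden_sizes = as.integer(hidden_sizes),
              learning_rate = learning_rate,
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), tol = tol, l2 = l2,
              cv_folds = as.integer(cv_folds), split = as.numeric(split),
              seed = as.integer(seed))
  if (cfg$learning_rate <= 0)
    stop("invalid survival_config: learning_rate must be > 0", call. = FALSE)
  if (length(cfg$split) != 3L || abs(sum(cfg$split) - 1) > 1e-9 ||
        any(cfg$split <= 0))
    stop("invalid survival_config: split fractions must be positive and sum to 1",
         call. = FALSE)
  if (cfg$l2 < 0)
    stop("invalid survival_config: l2 must be >= 0", call. = FALSE)
  class(cfg) <- "survival_config"
  cfg
}

survival_xy <- function(samples, features = NULL) {
  if (is.matrix(samples$x %||% NULL)) {
    return(list(x = samples$x, time = samples$time, event = samples$event,
                id = samples$patient_id %||% rownames(samples$x)))
  }
  stopifnot(is.data.frame(samples), is.data.frame(features))
  m <- merge(features, samples[, c("patient_id", "time", "event")],
             by = "patient_id", sort = TRUE)
  x <- as.matrix(m[, feature_columns(), drop = FALSE])
  rownames(x) <- m$patient_id
  list(x = x, time = m$time, event = m$event, id = m$patient_id)
}

# Event-stratified fold assignment (folds balanced on the event indicator).
stratified_folds <- function(event, k) {
  fold <- integer(length(event))
  for (v in unique(event)) {
    idx <- sample(which(event == v))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# One early-stopped fit on (train, validation); returns net + scaler +
# loss history.  Full-batch updates: Cox risk sets are global, so
# mini-batching would bias the partial likelihood.
fit_cox_net <- function(xtr, ttr, etr, xval, tval, eval_, config) {
  if (sum(etr) < 2) {
    stop("training split has fewer than 2 events; use stratified-by-event folds",
         call. = FALSE)
  }
  scaler <- fit_scaler(xtr)
  xs <- apply_scaler(xtr, scaler)
  xv <- if (length(tval)) apply_scaler(xval, scaler) else NULL
  net <- net_init(ncol(xtr), config$hidden_sizes, 1L)
  opt <- adam_init(net)
  n_ev <- sum(etr)
  best <- list(net = net, loss = Inf, epoch = 0L)
  wait <- 0L
  history <- numeric(0)
  for (ep in seq_len(config$max_epochs)) {
    fwd <- net_forward(net, xs)
    g <- as.numeric(fwd$out)
    delta <- matrix(cox_loss_grad(g, ttr, etr) / n_ev, ncol = 1L)
    grads <- net_backward(net, fwd, delta, l2 = config$l2)
    upd <- adam_step(net, grads, opt, config$learning_rate)
    net <- upd$net
    opt <- upd$state
    monitor <- if (!is.null(xv) && sum(eval_) > 0) {
      gv <- as.numeric(net_forward(net, xv)$out)
      cox_loss(gv, tval, eval_) / sum(eval_)
    } else {
      cox_loss(as.numeric(net_forward(net, xs)$out), ttr, etr) / n_ev
    }
    history <- c(history, monitor)
    if (monitor < best$loss - config$tol) {
      best <- list(net = net, loss = monitor, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  list(net = best$net, scaler = scaler, history = history,
       best_epoch = best$epoch, val_loss = best$loss)
}

#' Train the neural Cox progression model
#'
#' Runs event-stratified k-fold cross-validation (each fold: 20% test, the
#' rest split into train and validation for early stopping), reporting the
#' concordance index and integrated Brier score per fold, then refits the
#' final model on the full data (with an internal stratified
#' train/validation split for early stopping) and estimates the Breslow
#' baseline cumulative hazard from the final fit.  Deterministic given
#' `config$seed`.
#'
#' @param samples either the data frame from [build_survival_samples()]
#'   (then `features` must be supplied) or a list with elements `x`
#'   (matrix), `time`, `event`.
#' @param features [build_features()] output matching `samples$patient_id`.
#' @param config a [survival_config()].
#' @return an object of class `neural_cox` with the fitted network, scaler,
#'   Breslow baseline (`breslow$time`, `breslow$H0`), per-fold metrics, and
#'   training history.
#' @export
train_survival <- function(samples, features = NULL,
                           config = survival_config()) {
  stopifnot(inherits(config, "survival_config"))
  dat <- survival_xy(samples, features)
  x <- dat$x
  time <- dat$time
  event <- dat$event
  check_survival_vectors(numeric(length(time)), time, event)

  set.seed(config$seed)
  fold_metrics <- NULL
  if (config$cv_folds >= 2L) {
    fold <- stratified_folds(event, config$cv_folds)
    rows <- lapply(seq_len(config$cv_folds), function(f) {
      test <- which(fold == f)
      rest <- which(fold != f)
      if (sum(event[test]) == 0)
        stop("fold without events; use stratified-by-event folds",
             call. = FALSE)
      tr_frac <- config$split[1L] / (config$split[1L] + config$split[2L])
      ev_f <- factor(event[rest])
      tr_local <- stratified_split(ev_f, tr_frac)
      tr <- rest[tr_local]
      va <- setdiff(rest, tr)
      fit <- fit_cox_net(x[tr, , drop = FALSE], time[tr], event[tr],
                         x[va, , drop = FALSE], time[va], event[va], config)
      g_test <- as.numeric(net_forward(
        fit$net, apply_scaler(x[test, , drop = FALSE], fit$scaler))$out)
      ci <- concordance_index(time[test], event[test], g_test)
      g_tr <- as.numeric(net_forward(
        fit$net, apply_scaler(x[tr, , drop = FALSE], fit$scaler))$out)
      bh <- breslow_hazard(g_tr, time[tr], event[tr])
      ev_times <- sort(unique(time[test][event[test] == 1]))
      ibs <- NA_real_
      if (length(ev_times) >= 2L) {
        grid <- seq(min(ev_times), max(ev_times), length.out = 100L)
        surv <- outer(exp(g_test), breslow_H0_at(bh, grid),
                      function(r, h) exp(-h * r))
        ibs <- as.numeric(integrated_brier_score(surv, time[test],
                                                 event[test], grid))
      }
      data.frame(fold = f, n_test = length(test),
                 events_test = sum(event[test]),
                 c_index = ci, ibs = ibs, best_epoch = fit$best_epoch)
    })
    fold_metrics <- do.call(rbind, rows)
  }

  # final refit: all data as the training+validation portion
  tr_frac <- config$split[1L] / (config$split[1L] + config$split[2L])
  tr <- stratified_split(factor(event), tr_frac)
  va <- setdiff(seq_along(time), tr)
  fit <- fit_cox_net(x[tr, , drop = FALSE], time[tr], event[tr],
                     x[va, , drop = FALSE], time[va], event[va], config)
  g_all <- as.numeric(net_forward(fit$net, apply_scaler(x, fit$scaler))$out)
  bh <- breslow_hazard(g_all, time, event)

  structure(list(
    net = fit$net,
    scaler = fit$scaler,
    feature_names = colnames(x),
    config = config,
    breslow = bh,
    fold_metrics = fold_metrics,
    history = fit$history,
    n = length(time),
    n_events = sum(event)
  ), class = "neural_cox")
}

#' Risk scores g(x) of a fitted model
#'
#' @param model a `neural_cox`.
#' @param features feature data frame or matrix with the training schema.
#' @return numeric vector of scores (log relative hazards).
#' @export
risk_score <- function(model, features) {
  stopifnot(inherits(model, "neural_cox"))
  x <- if (is.matrix(features)) features else
    as.matrix(features[, model$feature_names, drop = FALSE])
  check_schema(colnames(x), model$feature_names)
  x <- x[, model$feature_names, drop = FALSE]
  as.numeric(net_forward(model$net, apply_scaler(x, model$scaler))$out)
}

#' Breslow baseline cumulative hazard
#'
#' `H0(t) = sum over event times t_i <= t of d_i / sum_{j in R(t_i)}
#' exp(g_j)`, where `d_i` counts events at `t_i`.  With all scores equal to
#' zero this reduces to the Nelson-Aalen estimator.
#'
#' @param risk_scores fitted scores on the estimation sample.
#' @param times,events the estimation sample's follow-up data.
#' @return an object of class `breslow` with `time` (unique event times),
#'   `H0` (cumulative baseline hazard after each time), and the maximum
#'   observed follow-up.
#' @export
breslow_hazard <- function(risk_scores, times, events) {
  check_survival_vectors(risk_scores, times, events)
  ord <- order(times)
  t_sorted <- times[ord]
  e_sorted <- events[ord]
  w <- exp(risk_scores[ord])
  rs <- rev(cumsum(rev(w)))
  grp <- match(t_sorted, t_sorted)
  ev_grp <- unique(grp[e_sorted == 1])
  d <- vapply(ev_grp, function(i) sum(e_sorted[grp == i]), numeric(1L))
  inc <- d / rs[ev_grp]
  structure(list(time = t_sorted[ev_grp], H0 = cumsum(inc),
                 max_time = max(times)), class = "breslow")
}

# Evaluate H0 at arbitrary times (right-continuous step function, 0 before
# the first event time).
breslow_H0_at <- function(bh, t) {
  idx <- findInterval(t, bh$time)
  c(0, bh$H0)[idx + 1L]
}

#' Predict cumulative hazard and survival at a horizon
#'
#' `H(horizon | x) = H0(horizon) * exp(g(x))`; the survival probability
#' `S = exp(-H)` is returned alongside.  A horizon beyond the last observed
#' follow-up time uses the last Breslow step, with a warning.
#'
#' @param model a fitted `neural_cox`.
#' @param features feature rows (data frame or matrix, training schema).
#' @param horizon non-negative horizon in months (e.g. 60 for 5 years).
#' @return data frame with `H` (cumulative hazard) and `S` (survival), plus
#'   `patient_id` when the input carried one.
#' @export
predict_cumulative_hazard <- function(model, features, horizon) {
  stopifnot(inherits(model, "neural_cox"), length(horizon) == 1L,
            horizon >= 0)
  if (horizon > model$breslow$max_time) {
    warning(sprintf(
      "horizon %.1f exceeds the last observed time %.1f; using the last baseline-hazard step",
      horizon, model$breslow$max_time), call. = FALSE)
  }
  g <- risk_score(model, features)
  H <- breslow_H0_at(model$breslow, horizon) * exp(g)
  out <- data.frame(H = H, S = exp(-H))
  if (!is.matrix(features) && "patient_id" %in% names(features)) {
    out <- cbind(patient_id = features$patient_id, out)
  }
  out
}

#' Predicted survival curves on a time grid
#'
#' @param model a fitted `neural_cox`.
#' @param features feature rows.
#' @param times evaluation times (months).
#' @return matrix (rows = patients, columns = `times`) of S(t|x).
#' @export
predict_survival <- function(model, features, times) {
  g <- risk_score(model, features)
  h0 <- breslow_H0_at(model$breslow, times)
  outer(exp(g), h0, function(r, h) exp(-h * r))
}

#' Coefficients of a linear (no hidden layer) risk network
#'
#' Only defined when the model was fitted with `hidden_sizes = integer(0)`;
#' returns the weights rescaled to the original covariate units, directly
#' comparable to classical Cox log hazard ratios.
#'
#' @param object a `neural_cox` with no hidden layers.
#' @param ... unused.
#' @return named numeric vector of log hazard ratios.
#' @export
coef.neural_cox <- function(object, ...) {
  if (length(object$config$hidden_sizes) != 0L) {
    stop("coefficients are only defined for a linear risk network",
         call. = FALSE)
  }
  beta <- as.numeric(object$net[[1L]]$W) / object$scaler$scale
  names(beta) <- object$feature_names
  beta
}
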