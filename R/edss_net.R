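# Three-class feed-forward EDSS classifier: two ReLU hidden layers, softmax
# output, categorical cross-entropy, Adam with mini-batches, dropout and L2.

#' Classifier configuration
#'
#' Defaults follow the reference architecture for this task: hidden layers of
#' 64 and 32 ReLU units, a 3-unit softmax output, Adam with learning rate
#' 0.001 and batch size 32, dropout 0.2, 10 training epochs and a stratified
#' 70/30 train/validation split.  The L2 strength defaults to 1e-4 (the
#' penalty is applied to weights, not biases).
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param learning_rate Adam learning rate (> 0).
#' @param batch_size mini-batch size.
#' @param dropout_rate dropout probability on hidden activations, in [0, 1).
#' @param l2 L2 regularization strength (>= 0).
#' @param epochs number of training epochs.
#' @param train_frac fraction of labelled data used for training (the rest
#'   is the validation split), in (0, 1).
#' @param seed integer seed controlling the split, initialization, shuffling
#'   and dropout; fixing it makes training deterministic.
#' @param grid optional named list of candidate values for [grid_search()];
#'   recognised names: `learning_rate`, `batch_size`, `hidden1`, `hidden2`.
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(hidden_sizes = c(64L, 32L),
                              learning_rate = 0.001,
                              batch_size = 32L,
                              dropout_rate = 0.2,
                              l2 = 1e-4,
                              epochs = 10L,
                              train_frac = 0.70,
                              seed = 1L,
                              grid = NULL) {
  cfg <- list(hidden_sizes = as.integer(hidden_sizes),
              learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              dropout_rate = dropout_rate, l2 = l2,
              epochs = as.integer(epochs), train_frac = train_frac,
              seed = as.integer(seed), grid = grid)
  if (!is.null(cfg$hidden_sizes) && any(cfg$hidden_sizes < 1L))
    stop("invalid classifier_config: hidden_sizes must be positive",
         call. = FALSE)
  if (cfg$learning_rate <= 0)
    stop("invalid classifier_config: learning_rate must be > 0",
         call. = FALSE)
  if (cfg$batch_size < 1L)
    stop("invalid classifier_config: batch_size must be >= 1", call. = FALSE)
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("invalid classifier_config: dropout_rate must be in [0, 1)",
         call. = FALSE)
  if (cfg$l2 < 0)
    stop("invalid classifier_config: l2 must be >= 0", call. = FALSE)
  if (cfg$epochs < 1L)
    stop("invalid classifier_config: epochs must be >= 1", call. = FALSE)
  if (cfg$train_frac <= 0 || cfg$train_frac >= 1)
    stop("invalid classifier_config: train_frac must be in (0, 1)",
         call. = FALSE)
  class(cfg) <- "classifier_config"
  cfg
}

# Coerce (features, labels) to an aligned (x matrix, y factor) pair.
classifier_xy <- function(features, labels) {
  if (is.matrix(features)) {
    x <- features
    y <- if (is.factor(labels)) labels else factor(labels)
  } else {
    stopifnot(is.data.frame(features), is.data.frame(labels))
    m <- merge(features, labels[, c("patient_id", "class")],
               by = "patient_id", sort = TRUE)
    x <- as.matrix(m[, feature_columns(), drop = FALSE])
    rownames(x) <- m$patient_id
    y <- factor(m$class, levels = c("C1", "C2", "C3"))
  }
  if (nrow(x) == 0L) stop("no labelled samples", call. = FALSE)
  list(x = x, y = y)
}

stratified_split <- function(y, frac) {
  train_idx <- integer(0)
  for (lev in levels(y)) {
    idx <- which(y == lev)
    n_tr <- round(length(idx) * frac)
    train_idx <- c(train_idx, sample(idx)[seq_len(n_tr)])
  }
  sort(train_idx)
}

#' Train the three-class EDSS classifier
#'
#' Splits the labelled cohort into stratified training and validation sets,
#' standardizes features using training-split statistics only, and trains
#' the softmax network by mini-batch Adam on the categorical cross-entropy
#' with dropout and L2.  Fully deterministic given `config$seed`.
#'
#' @param features [build_features()] output, or a plain numeric matrix.
#' @param labels [label_cohort()] output, or a factor aligned with the
#'   matrix rows.
#' @param config a [classifier_config()].
#' @return an object of class `edss_classifier` carrying the fitted network,
#'   the training-split scaler, the feature schema, and a training `report`
#'   (split indices, per-epoch training loss, validation accuracy).
#' @export
train_classifier <- function(features, labels,
                             config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  dat <- classifier_xy(features, labels)
  x <- dat$x
  y <- dat$y
  lev <- levels(y)

  set.seed(config$seed)
  train_idx <- stratified_split(y, config$train_frac)
  val_idx <- setdiff(seq_len(nrow(x)), train_idx)
  ytr <- y[train_idx]
  missing_cls <- lev[!(lev %in% unique(as.character(ytr)))]
  if (length(missing_cls)) {
    stop(sprintf(
      "class %s absent from the training split; use a stratified resplit or provide more labelled data",
      paste(missing_cls, collapse = ", ")), call. = FALSE)
  }

  scaler <- fit_scaler(x[train_idx, , drop = FALSE])
  xtr <- apply_scaler(x[train_idx, , drop = FALSE], scaler)
  xval <- apply_scaler(x[val_idx, , drop = FALSE], scaler)
  ytr_onehot <- diag(length(lev))[as.integer(ytr), , drop = FALSE]

  net <- net_init(ncol(x), config$hidden_sizes, length(lev))
  opt <- adam_init(net)
  n_tr <- nrow(xtr)
  epoch_loss <- numeric(config$epochs)
  val_acc <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = config$batch_size)
    losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- perm[starts[bi]:min(starts[bi] + config$batch_size - 1L, n_tr)]
      xb <- xtr[rows, , drop = FALSE]
      yb <- ytr_onehot[rows, , drop = FALSE]
      fwd <- net_forward(net, xb, dropout = config$dropout_rate,
                         training = TRUE)
      p <- softmax_rows(fwd$out)
      losses[bi] <- -mean(log(pmax(rowSums(p * yb), 1e-12))) +
        net_l2_penalty(net, config$l2) / n_tr
      delta <- (p - yb) / nrow(xb)
      grads <- net_backward(net, fwd, delta, l2 = config$l2 / n_tr)
      upd <- adam_step(net, grads, opt, config$learning_rate)
      net <- upd$net
      opt <- upd$state
    }
    epoch_loss[ep] <- mean(losses)
    if (length(val_idx)) {
      pv <- softmax_rows(net_forward(net, xval)$out)
      val_acc[ep] <- mean(lev[max.col(pv, ties.method = "first")] ==
                            as.character(y[val_idx]))
    } else {
      val_acc[ep] <- NA_real_
    }
  }

  structure(list(
    net = net,
    scaler = scaler,
    feature_names = colnames(x),
    levels = lev,
    config = config,
    report = list(train_idx = train_idx, val_idx = val_idx,
                  epoch_loss = epoch_loss, val_accuracy = val_acc)
  ), class = "edss_classifier")
}

#' Predict class probabilities
#'
#' Applies the trained softmax network (dropout inactive) to new feature
#' rows; usable on the unlabelled whole population.  Every probability row
#' is non-negative and sums to one.
#'
#' @param model an `edss_classifier`.
#' @param features [build_features()] output or a numeric matrix with the
#'   training-time columns; a schema mismatch raises an error listing the
#'   missing/extra columns.
#' @return list with `probabilities` (n x 3 matrix, columns named by class),
#'   `class` (factor of argmax predictions) and `patient_id` (when the input
#'   carried one).
#' @export
predict_classes <- function(model, features) {
  stopifnot(inherits(model, "edss_classifier"))
  pid <- NULL
  if (is.matrix(features)) {
    x <- features
    if (is.null(colnames(x)) && ncol(x) == length(model$feature_names)) {
      colnames(x) <- model$feature_names
    }
  } else {
    pid <- features$patient_id
    non_feature <- c("patient_id", "window_start", "window_end")
    cols <- setdiff(names(features), non_feature)
    check_schema(cols, model$feature_names)
    x <- as.matrix(features[, model$feature_names, drop = FALSE])
  }
  check_schema(colnames(x), model$feature_names)
  x <- x[, model$feature_names, drop = FALSE]
  p <- softmax_rows(net_forward(model$net, apply_scaler(x, model$scaler))$out)
  colnames(p) <- model$levels
  cls <- factor(model$levels[max.col(p, ties.method = "first")],
                levels = model$levels)
  list(probabilities = p, class = cls, patient_id = pid)
}

#' Exhaustive hyperparameter grid search
#'
#' Trains one classifier per point of the Cartesian grid (all with the same
#' seed, hence the same stratified split) and returns the configuration with
#' the highest validation accuracy; ties resolve to the earliest grid row.
#' Grid axes: `learning_rate`, `batch_size`, `hidden1`, `hidden2`.
#'
#' @param features,labels as in [train_classifier()].
#' @param config a [classifier_config()] whose `grid` is a non-empty named
#'   list of candidate values.
#' @return list with `best_config`, `best_model`, and `scores` (one row per
#'   grid point with its validation accuracy).
#' @export
grid_search <- function(features, labels, config) {
  stopifnot(inherits(config, "classifier_config"))
  grid <- config$grid
  if (is.null(grid) || length(grid) == 0L) {
    stop("grid_search requires a non-empty config$grid", call. = FALSE)
  }
  allowed <- c("learning_rate", "batch_size", "hidden1", "hidden2")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) {
    stop(sprintf("unknown grid axis: %s (allowed: %s)",
                 paste(bad, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  if (any(vapply(grid, length, integer(1L)) == 0L)) {
    stop("empty candidate list in grid", call. = FALSE)
  }
  tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  scores <- numeric(nrow(tab))
  models <- vector("list", nrow(tab))
  for (r in seq_len(nrow(tab))) {
    cand <- config
    if (!is.null(tab$learning_rate)) cand$learning_rate <- tab$learning_rate[r]
    if (!is.null(tab$batch_size)) cand$batch_size <- as.integer(tab$batch_size[r])
    hs <- cand$hidden_sizes
    if (!is.null(tab$hidden1)) hs[1L] <- as.integer(tab$hidden1[r])
    if (!is.null(tab$hidden2) && length(hs) >= 2L)
      hs[2L] <- as.integer(tab$hidden2[r])
    cand$hidden_sizes <- hs
    cand$grid <- NULL
    cand <- do.call(classifier_config, cand[setdiff(names(cand), "grid")])
    fit <- train_classifier(features, labels, cand)
    scores[r] <- fit$report$val_accuracy[length(fit$report$val_accuracy)]
    models[[r]] <- fit
  }
  best <- which.max(scores)
  tab$val_accuracy <- scores
  list(best_config = models[[best]]$config,
       best_model = models[[best]],
       scores = tab)
}
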