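# Gradient-boosted regression head and evaluation metrics.

#' Gradient boosting regressor configuration
#'
#' Defaults mirror the production settings for persistent commutative
#' algebra descriptors: 20,000 trees (30,000 for external embedding
#' features), depth 7, minimum split size 5, learning rate 0.002,
#' square-root feature sampling per node, 80% row subsampling, and 20
#' independently seeded repetitions whose predictions are averaged. The
#' `reduced` preset (200 trees, 2 repetitions, learning rate 0.05) keeps
#' the same model family at desk scale for tests and examples.
#'
#' @param n_estimators number of boosting rounds
#' @param max_depth maximum tree depth
#' @param min_samples_split minimum samples to split an internal node
#' @param learning_rate shrinkage per round
#' @param max_features `"sqrt"` for square-root feature sampling per node
#' @param subsample row subsampling fraction
#' @param repetitions independently seeded fits averaged per prediction
#' @param seed master seed; repetition `k` uses `seed + k - 1`
#' @param reduced use the desk-scale preset?
#' @return a `regressor_config`
#' @export
regressor_config <- function(n_estimators = 20000L, max_depth = 7L,
                             min_samples_split = 5L, learning_rate = 0.002,
                             max_features = "sqrt", subsample = 0.8,
                             repetitions = 20L, seed = 1L, reduced = FALSE) {
  if (reduced) {
    n_estimators <- 200L
    repetitions <- 2L
    learning_rate <- 0.05
  }
  stopifnot(n_estimators >= 1L, max_depth >= 1L, min_samples_split >= 1L,
            learning_rate > 0, subsample > 0, subsample <= 1,
            repetitions >= 1L)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 learning_rate = learning_rate,
                 max_features = max_features,
                 subsample = subsample,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "regressor_config")
}

.xgb_params <- function(cfg, p) {
  colsample <- if (identical(cfg$max_features, "sqrt")) {
    max(sqrt(p) / p, 1 / p)
  } else 1
  list(objective = "reg:squarederror",
       eta = cfg$learning_rate,
       max_depth = cfg$max_depth,
       subsample = cfg$subsample,
       colsample_bynode = colsample,
       min_child_weight = cfg$min_samples_split,
       nthread = 1L)
}

.fit_one <- function(train_x, train_y, cfg, rep_seed) {
  set.seed(rep_seed)
  params <- .xgb_params(cfg, ncol(train_x))
  params$base_score <- mean(train_y)
  xgboost::xgb.train(
    params = params,
    data = xgboost::xgb.DMatrix(train_x, label = train_y, nthread = 1L),
    nrounds = cfg$n_estimators, verbose = 0)
}

#' Train gradient-boosted models and predict
#'
#' Fits `cfg$repetitions` independently seeded gradient boosting models
#' (seeds `cfg$seed + 0 .. repetitions - 1`) and returns the average of
#' their predictions on `test_x`. Deterministic given the configuration.
#'
#' @param train_x,test_x numeric feature matrices with equal column counts
#' @param train_y numeric labels, one per training row
#' @param cfg a [regressor_config()]
#' @return numeric prediction vector of length `nrow(test_x)`
#' @export
train_predict <- function(train_x, train_y, test_x, cfg = regressor_config()) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  if (nrow(train_x) != length(train_y)) stop("train_x rows != length(train_y)")
  if (ncol(train_x) != ncol(test_x)) stop("train/test column mismatch")
  if (anyNA(train_x) || anyNA(train_y) || anyNA(test_x)) {
    stop("missing values are not supported")
  }
  preds <- lapply(seq_len(cfg$repetitions), function(k) {
    fit <- .fit_one(train_x, train_y, cfg, cfg$seed + k - 1L)
    stats::predict(fit, xgboost::xgb.DMatrix(test_x, nthread = 1L))
  })
  consensus(preds)
}

#' Train the repetition ensemble and return the fitted models
#'
#' @inheritParams train_predict
#' @return list of fitted boosters with the config attached as an attribute
#' @export
train_ensemble <- function(train_x, train_y, cfg = regressor_config()) {
  train_x <- as.matrix(train_x)
  if (nrow(train_x) != length(train_y)) stop("train_x rows != length(train_y)")
  fits <- lapply(seq_len(cfg$repetitions), function(k) {
    .fit_one(train_x, train_y, cfg, cfg$seed + k - 1L)
  })
  attr(fits, "config") <- cfg
  fits
}

#' Predict with a fitted repetition ensemble
#' @param fits output of [train_ensemble()]
#' @param test_x feature matrix
#' @return averaged prediction vector
#' @export
predict_ensemble <- function(fits, test_x) {
  test_x <- as.matrix(test_x)
  consensus(lapply(fits, function(f) stats::predict(f, xgboost::xgb.DMatrix(test_x, nthread = 1L))))
}

#' Consensus (elementwise mean) of prediction vectors
#'
#' Used both across seeded repetitions and across models (e.g. the
#' element-specific and category-specific branches).
#'
#' @param predictions list of equal-length numeric vectors
#' @return numeric vector
#' @export
consensus <- function(predictions) {
  if (length(predictions) < 1L) stop("need at least one prediction vector")
  len <- unique(lengths(predictions))
  if (length(len) != 1L) stop("prediction vectors have unequal lengths")
  Reduce(`+`, predictions) / length(predictions)
}

#' Pearson correlation coefficient
#' @param y_true,y_pred numeric vectors of equal length >= 2, each with
#'   nonzero variance
#' @return correlation in `[-1, 1]`
#' @export
pcc <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least two observations")
  if (stats::var(y_true) == 0 || stats::var(y_pred) == 0) {
    stop("zero variance input")
  }
  stats::cor(y_true, y_pred)
}

#' Root mean squared error
#' @param y_true,y_pred numeric vectors of equal length
#' @return non-negative scalar
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  sqrt(mean((y_true - y_pred)^2))
}

#' Convert pKd values to binding free energies (kcal/mol)
#'
#' Elementwise multiplication by 1.3633 (RT ln 10 at room temperature).
#' @param values numeric vector of pKd values
#' @return numeric vector in kcal/mol
#' @export
pkd_to_kcal <- function(values) values * 1.3633

#' Deterministic train/test split indices
#' @param n number of samples
#' @param test_fraction fraction held out
#' @param seed integer seed
#' @return list with integer vectors `train` and `test`
#' @export
train_test_split <- function(n, test_fraction = 0.25, seed = 1L) {
  .with_seed(seed, {
    test <- sort(sample.int(n, max(1L, round(n * test_fraction))))
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Evaluation report
#' @param y_true,y_pred numeric vectors
#' @param units label units (`"pKd"` or `"kcal/mol"`)
#' @return list with `pcc`, `rmse`, `units`, `n`
#' @export
evaluation_report <- function(y_true, y_pred, units = "pKd") {
  list(pcc = pcc(y_true, y_pred), rmse = rmse(y_true, y_pred),
       units = units, n = length(y_true))
}
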