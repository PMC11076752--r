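#' Decide whether hyperparameter search may run
#'
#' Hyperparameter search is only worthwhile on datasets large enough to
#' support an honest train/validation split, so it is gated on three
#' conditions, all of which must hold: more than 50 samples, a
#' sample-to-feature ratio of at least 4, and at most 100 columns
#' containing missing values. When the gate denies, predefined parameters
#' are used instead.
#'
#' @param n_samples,n_features,n_missing_columns Positive integers.
#' @return A one-row tibble: `n_samples`, `n_features`,
#'   `n_missing_columns`, `allowed`, and a `reasons` list-column naming
#'   every violated condition (empty when allowed).
#' @export
gate_hyperparameter_search <- function(n_samples, n_features,
                                       n_missing_columns) {
  stopifnot(n_samples >= 1, n_features >= 1, n_missing_columns >= 0)
  reasons <- character()
  if (!(n_samples > 50)) reasons <- c(reasons, "samples")
  if (!(n_samples / n_features >= 4)) reasons <- c(reasons, "ratio")
  if (!(n_missing_columns <= 100)) reasons <- c(reasons, "missing_columns")
  tibble::tibble(
    n_samples = as.integer(n_samples),
    n_features = as.integer(n_features),
    n_missing_columns = as.integer(n_missing_columns),
    allowed = length(reasons) == 0,
    reasons = list(reasons))
}

#' Select the learner for a column type
#'
#' Continuous columns are imputed by a regressor, categorical (including
#' Boolean) columns by a classifier. Excluded columns are never imputed.
#'
#' @param type Column type from the preprocessing profile.
#' @return `"regressor"` or `"classifier"`.
#' @export
select_learner <- function(type) {
  switch(type,
    continuous = "regressor",
    categorical = "classifier",
    stop("column of type '", type, "' is never imputed"))
}

#' Predefined gradient-boosting parameters
#'
#' Fixed, deterministic defaults used whenever the hyperparameter-search
#' gate denies or tuning is switched off: 300 trees of depth 6, learning
#' rate 0.1, internal row subsample 0.8, column subsample 0.8, minimum
#' child weight 1, L2 regularization 1.
#'
#' @param learner `"regressor"` or `"classifier"`.
#' @return A named list of parameters (`objective` is
#'   `"squared_error"` or `"multiclass_logloss"`).
#' @export
predefined_params <- function(learner = c("regressor", "classifier")) {
  learner <- match.arg(learner)
  list(learning_rate = 0.1, max_depth = 6L, n_estimators = 300L,
       internal_subsample = 0.8, colsample = 0.8, min_child_weight = 1,
       l2_regularization = 1.0,
       objective = if (learner == "regressor") "squared_error"
                   else "multiclass_logloss")
}

# draw one candidate from the search space (log-uniform where scales span
# decades)
sample_candidate <- function(learner) {
  list(
    learning_rate = exp(stats::runif(1, log(0.01), log(0.3))),
    max_depth = sample(3:9, 1),
    n_estimators = sample(100:600, 1),
    internal_subsample = stats::runif(1, 0.6, 0.9),
    colsample = stats::runif(1, 0.5, 1.0),
    min_child_weight = stats::runif(1, 1, 10),
    l2_regularization = exp(stats::runif(1, log(1e-3), log(10))),
    objective = if (learner == "regressor") "squared_error"
                else "multiclass_logloss")
}

as_xgb_params <- function(params, n_classes = NULL) {
  p <- list(eta = params$learning_rate,
            max_depth = params$max_depth,
            subsample = params$internal_subsample,
            colsample_bytree = params$colsample,
            min_child_weight = params$min_child_weight,
            lambda = params$l2_regularization,
            nthread = 1,
            verbosity = 0)
  if (params$objective == "squared_error") {
    p$objective <- "reg:squarederror"
  } else {
    p$objective <- "multi:softprob"
    p$num_class <- n_classes
  }
  p
}

fit_xgb <- function(X, y, params, n_classes = NULL, nrounds = NULL,
                    watch = NULL, early_stopping = NULL, seed = 1) {
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  args <- list(params = as_xgb_params(params, n_classes), data = dtrain,
               nrounds = if (is.null(nrounds)) params$n_estimators else nrounds,
               verbose = 0)
  if (!is.null(watch)) {
    args$evals <- list(val = watch)
    args$early_stopping_rounds <- early_stopping
  }
  do.call(xgboost::xgb.train, args)
}

#' Tune gradient-boosting parameters by sequential random search
#'
#' Samples `n_trials` candidates from the search space (learning rate
#' log-uniform on \[0.01, 0.3\], depth 3–9, 100–600 trees, internal
#' subsample \[0.6, 0.9\], column subsample \[0.5, 1\], minimum child weight
#' \[1, 10\], L2 log-uniform on \[1e-3, 10\]), fits each on a seeded 80/20
#' train/validation split with early stopping, and returns the candidate
#' with the lowest validation RMSE (regressor) or multiclass log-loss
#' (classifier). Deterministic given `seed`.
#'
#' @param X Numeric feature matrix of the observed rows.
#' @param y Numeric target (values, or class codes for a classifier).
#' @param learner `"regressor"` or `"classifier"`.
#' @param n_trials Number of candidates (>= 1).
#' @param seed Integer seed.
#' @return The best candidate as a parameter list (see
#'   [predefined_params()]) with attribute `"val_score"`.
#' @export
tune_params <- function(X, y, learner = c("regressor", "classifier"),
                        n_trials = 20, seed = 1) {
  learner <- match.arg(learner)
  stopifnot(nrow(X) >= 20, n_trials >= 1)
  n_classes <- NULL
  if (learner == "classifier") {
    n_classes <- as.integer(max(y)) + 1L
    if (length(unique(y)) < 2) stop("single-class target: nothing to tune")
  }
  set.seed(seed)
  n <- nrow(X)
  val_idx <- sample(n, max(1L, round(0.2 * n)))
  dval <- xgboost::xgb.DMatrix(X[val_idx, , drop = FALSE], label = y[val_idx])
  Xtr <- X[-val_idx, , drop = FALSE]; ytr <- y[-val_idx]

  best <- NULL; best_score <- Inf
  for (t in seq_len(n_trials)) {
    set.seed(seed + t)
    cand <- sample_candidate(learner)
    fit <- fit_xgb(Xtr, ytr, cand, n_classes = n_classes,
                   watch = dval, early_stopping = 20L, seed = seed + t)
    log <- attributes(fit)$evaluation_log
    score <- min(log[[2]])
    if (score < best_score) { best_score <- score; best <- cand }
  }
  attr(best, "val_score") <- best_score
  best
}

#' Fit a subsampled ensemble and aggregate its predictions
#'
#' Trains `n_models` gradient-boosted models, each on an independent 70%
#' row-subsample (without replacement) of the observed rows, and
#' aggregates: a regressor averages the model predictions, a classifier
#' averages the per-class probability vectors and takes the argmax, with
#' ties broken toward the smallest class code. Degenerate targets (fewer
#' than 10 observed rows, or a single observed class) raise a condition of
#' class `bf_fallback` so the caller can substitute pre-imputed values.
#'
#' @param X Feature matrix of observed rows.
#' @param y Target over observed rows (numeric values or class codes).
#' @param X_pred Feature matrix of the rows to predict.
#' @param learner `"regressor"` or `"classifier"`.
#' @param params Parameter list ([predefined_params()] / [tune_params()]).
#' @param n_models Ensemble size in \[3, 9\].
#' @param seed Integer seed; model `m` uses `seed + m`.
#' @param n_classes Total class count for a classifier (codes
#'   `0..n_classes-1`).
#' @return A list with `aggregate` (length `nrow(X_pred)`) and
#'   `per_model` (matrix, rows to predict x models; class codes for a
#'   classifier).
#' @export
fit_ensemble_predict <- function(X, y, X_pred, learner, params,
                                 n_models = 3, seed = 1, n_classes = NULL) {
  stopifnot(n_models >= 3, n_models <= 9)
  n <- nrow(X)
  if (n < 10) {
    stop(structure(class = c("bf_fallback", "error", "condition"),
                   list(message = "fewer than 10 observed rows", call = NULL)))
  }
  if (learner == "classifier") {
    if (is.null(n_classes)) n_classes <- as.integer(max(y)) + 1L
    if (length(unique(y)) < 2) {
      stop(structure(class = c("bf_fallback", "error", "condition"),
                     list(message = "single observed class", call = NULL)))
    }
  }
  n_sub <- max(1L, floor(0.7 * n))
  per_model <- matrix(NA_real_, nrow(X_pred), n_models)
  prob_sum <- if (learner == "classifier")
    matrix(0, nrow(X_pred), n_classes) else NULL

  for (m in seq_len(n_models)) {
    set.seed(seed + m)
    rows <- sample(n, n_sub)
    fit <- fit_xgb(X[rows, , drop = FALSE], y[rows], params,
                   n_classes = n_classes, seed = seed + m)
    pred <- predict(fit, xgboost::xgb.DMatrix(X_pred))
    if (learner == "classifier") {
      prob <- matrix(as.numeric(pred), nrow(X_pred), n_classes)
      prob_sum <- prob_sum + prob
      per_model[, m] <- max.col(prob, ties.method = "first") - 1
    } else {
      per_model[, m] <- pred
    }
  }

  aggregate <- if (learner == "classifier") {
    max.col(prob_sum / n_models, ties.method = "first") - 1
  } else {
    rowMeans(per_model)
  }
  list(aggregate = aggregate, per_model = per_model)
}

# Impute one column in place: build features from the transformed matrix
# minus the target column, train on rows observed in the target, predict
# the missing rows, and write the aggregate back into the encoded and
# clean tables. Tuned parameters are cached per column so later iterations
# reuse them. Returns the updated state plus a record row (NULL when the
# column has nothing to impute).
impute_column <- function(col, state, config, iteration) {
  prof <- state$profiles[state$profiles$column == col, ]
  if (prof$type == "excluded") stop("excluded column '", col, "' is never imputed")
  # the original missingness mask: these cells are re-predicted every pass
  miss <- state$miss_mask[, col]
  if (!any(miss)) return(state)

  typed <- state$profiles$column[state$profiles$type != "excluded"]
  feat_cols <- setdiff(typed, col)
  X_all <- state$transformed[, feat_cols, drop = FALSE]
  # later columns in the same pass see earlier fresh imputations
  for (fc in feat_cols) {
    filled <- state$encoded[[fc]]
    upd <- !is.na(filled)
    X_all[upd, fc] <- filled[upd]
  }
  y_obs <- state$encoded[[col]][!miss]
  learner <- select_learner(prof$type)
  n_classes <- if (prof$type == "categorical")
    length(prof$categories[[1]]) else NULL

  col_idx <- match(col, state$profiles$column)
  params <- state$params_cache[[col]]
  tuned <- FALSE
  if (is.null(params)) {
    use_tuning <- isTRUE(config$use_tuning) && state$gate$allowed &&
      sum(!miss) >= 20 &&
      !(learner == "classifier" && length(unique(y_obs)) < 2)
    if (use_tuning) {
      params <- tryCatch(
        tune_params(X_all[!miss, , drop = FALSE], y_obs, learner,
                    n_trials = config$n_trials,
                    seed = config$master_seed + 1000L + col_idx),
        error = function(e) NULL)
      tuned <- !is.null(params)
    }
    if (is.null(params)) params <- predefined_params(learner)
    attr(params, "tuned") <- tuned
    state$params_cache[[col]] <- params
  }

  res <- tryCatch(
    fit_ensemble_predict(
      X_all[!miss, , drop = FALSE], y_obs, X_all[miss, , drop = FALSE],
      learner, params, n_models = config$n_models,
      seed = config$master_seed + 2000L + col_idx * 10L + iteration,
      n_classes = n_classes),
    bf_fallback = function(e) e)

  if (inherits(res, "bf_fallback")) {
    fill <- state$pre_imputed[[col]][miss]
    reason <- conditionMessage(res)
  } else {
    fill <- res$aggregate
    reason <- NA_character_
  }
  state$encoded[[col]][miss] <- fill
  state$clean[[col]][miss] <- if (prof$type == "categorical") {
    decode_categorical(fill, prof$categories[[1]], name = col)
  } else fill

  rec <- tibble::tibble(
    column = col, iteration = iteration, learner = learner,
    n_missing = sum(miss),
    tuned = isTRUE(attr(state$params_cache[[col]], "tuned")),
    n_models = as.integer(config$n_models),
    fallback = reason)
  state$records <- dplyr::bind_rows(state$records, rec)
  state
}
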