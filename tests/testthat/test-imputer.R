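test_that("the tuning gate enforces all three dataset-size conditions", {
  ok <- gate_hyperparameter_search(60, 10, 5)
  expect_true(ok$allowed)
  expect_length(ok$reasons[[1]], 0)

  at_boundary <- gate_hyperparameter_search(50, 5, 5)
  expect_false(at_boundary$allowed)
  expect_equal(at_boundary$reasons[[1]], "samples")

  multi <- gate_hyperparameter_search(400, 101, 101)
  expect_false(multi$allowed)
  expect_setequal(multi$reasons[[1]], c("ratio", "missing_columns"))

  # ratio of exactly 4 and exactly 100 missing columns are allowed
  expect_true(gate_hyperparameter_search(400, 100, 100)$allowed)
})

test_that("the gate is monotone in samples and missing columns", {
  set.seed(2)
  for (rep in 1:30) {
    n <- sample(10:200, 1); p <- sample(2:60, 1); m <- sample(1:120, 1)
    g0 <- gate_hyperparameter_search(n, p, m)$allowed
    # raising samples (others fixed) never flips allowed -> denied
    if (g0) expect_true(gate_hyperparameter_search(n + sample(1:50, 1), p, m)$allowed)
    # raising missing columns never flips denied -> allowed
    if (!g0) expect_false(gate_hyperparameter_search(n, p, m + sample(1:50, 1))$allowed)
  }
})

test_that("learner dispatch maps types to regressor/classifier and rejects excluded", {
  expect_equal(select_learner("continuous"), "regressor")
  expect_equal(select_learner("categorical"), "classifier")
  expect_error(select_learner("excluded"), "never imputed")
})

test_that("predefined parameters are fixed and objective-matched", {
  r <- predefined_params("regressor")
  c <- predefined_params("classifier")
  expect_equal(r$objective, "squared_error")
  expect_equal(c$objective, "multiclass_logloss")
  expect_identical(r[setdiff(names(r), "objective")],
                   c[setdiff(names(c), "objective")])
  expect_identical(predefined_params("regressor"), r)
})

test_that("random search is seeded-deterministic and beats defaults on a linear target", {
  set.seed(1)
  X <- matrix(rnorm(100 * 4), 100, 4)
  y <- 3 * X[, 1] - 2 * X[, 2]  # noiseless linear target
  p1 <- tune_params(X, y, "regressor", n_trials = 3, seed = 7)
  p2 <- tune_params(X, y, "regressor", n_trials = 3, seed = 7)
  expect_identical(p1, p2)

  best <- tune_params(X, y, "regressor", n_trials = 50, seed = 7)
  # evaluate both candidates on the same held-out split
  set.seed(99)
  val <- sample(100, 20)
  rmse_of <- function(params) {
    fit <- boostfill:::fit_xgb(X[-val, ], y[-val], params, seed = 1)
    sqrt(mean((predict(fit, xgboost::xgb.DMatrix(X[val, ])) - y[val])^2))
  }
  expect_lte(rmse_of(best), rmse_of(predefined_params("regressor")))
})

test_that("a single-trial search returns its one sampled candidate", {
  set.seed(1)
  X <- matrix(rnorm(80), 20, 4); y <- rnorm(20)
  p <- tune_params(X, y, "regressor", n_trials = 1, seed = 5)
  expect_type(p, "list")
  expect_true(p$learning_rate >= 0.01 && p$learning_rate <= 0.3)
  expect_true(p$max_depth %in% 3:9)
})

test_that("the ensemble aggregates by mean and stays within per-model bounds", {
  set.seed(2)
  X <- matrix(rnorm(200 * 5), 200, 5)
  y <- X[, 3]  # target duplicated from a feature column
  res <- fit_ensemble_predict(X[1:150, ], y[1:150], X[151:200, ],
                              "regressor", predefined_params("regressor"),
                              n_models = 3, seed = 4)
  expect_equal(dim(res$per_model), c(50, 3))
  expect_true(all(res$aggregate >= apply(res$per_model, 1, min) - 1e-12))
  expect_true(all(res$aggregate <= apply(res$per_model, 1, max) + 1e-12))
  expect_equal(res$aggregate, rowMeans(res$per_model))
  rng <- diff(range(y))
  rmse <- sqrt(mean((res$aggregate - y[151:200])^2))
  expect_lt(rmse, 0.05 * rng)
})

test_that("classifier aggregation averages probabilities and stays in the code set", {
  set.seed(3)
  X <- matrix(rnorm(120 * 4), 120, 4)
  y <- as.numeric(X[, 1] + 0.1 * rnorm(120) > 0)
  res <- fit_ensemble_predict(X[1:100, ], y[1:100], X[101:120, ],
                              "classifier", predefined_params("classifier"),
                              n_models = 3, seed = 4, n_classes = 2)
  expect_true(all(res$aggregate %in% c(0, 1)))
  expect_gt(mean(res$aggregate == y[101:120]), 0.8)
})

test_that("degenerate targets signal the fallback condition", {
  X <- matrix(rnorm(40), 8, 5)
  expect_error(
    fit_ensemble_predict(X, rnorm(8), X, "regressor",
                         predefined_params("regressor"), 3, seed = 1),
    class = "bf_fallback")
  X2 <- matrix(rnorm(60), 12, 5)
  expect_error(
    fit_ensemble_predict(X2, rep(0, 12), X2, "classifier",
                         predefined_params("classifier"), 3, seed = 1,
                         n_classes = 1),
    class = "bf_fallback")
  expect_error(
    fit_ensemble_predict(X2, rnorm(12), X2, "regressor",
                         predefined_params("regressor"), n_models = 2,
                         seed = 1))
})

test_that("categorical imputations lie in the observed category set", {
  syn <- generate_synthetic(n_rows = 60, n_cont = 5, n_cat = 2, n_bool = 1,
                            latent_rank = 2, seed = 21)
  mk <- mask_mcar(syn$data, 0.2, seed = 22)
  fit <- boostfill(mk$masked, n_iterations = 1, master_seed = 23)
  for (cn in c("cat_01", "cat_02", "bool_01")) {
    observed <- unique(na.omit(mk$masked[[cn]]))
    expect_true(all(fit$imputed_clean[[cn]] %in% observed), info = cn)
  }
})

test_that("imputation of a low-rank continuous column beats mean fill on its mask", {
  syn <- generate_synthetic(n_rows = 120, n_cont = 8, n_cat = 0, n_bool = 0,
                            latent_rank = 2, seed = 31)
  mk <- mask_mcar(syn$data, 0.2, seed = 32)
  fit <- boostfill(mk$masked, n_iterations = 1, master_seed = 33)
  j <- "cont_01"
  m <- mk$mask[, j]
  truth <- syn$truth[[j]][m]
  mean_fill <- mean(mk$masked[[j]], na.rm = TRUE)
  rmse_fit <- sqrt(mean((fit$imputed_clean[[j]][m] - truth)^2))
  rmse_mean <- sqrt(mean((mean_fill - truth)^2))
  expect_lt(rmse_fit, rmse_mean)
})
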