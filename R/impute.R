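#' Build and validate an imputation configuration
#'
#' Collects every user knob of the engine and validates ranges: the
#' ensemble size must lie in \[3, 9\] and the iteration count in \[1, 9\].
#'
#' @param impute_zeros Treat zeros as missing.
#' @param pre_impute_strategy `"column_mean"`, `"knn"` or `"mix_type"`.
#' @param knn_k Neighbour count for kNN pre-imputation.
#' @param mf_method `"auto"`, `"nmf"`, `"svd"` or `"off"`.
#' @param mf_mode `"nan_only"` or `"full"`.
#' @param mf_rank Factorization rank or `"auto"`.
#' @param subgroup_size Optional column-block width for the factorization.
#' @param n_models Ensemble size, 3–9.
#' @param n_iterations Refinement passes, 1–9 (default 3; the marginal gain
#'   beyond a few passes is small).
#' @param use_tuning Run hyperparameter search where the gate allows it.
#' @param n_trials Search trials per column when tuning.
#' @param master_seed Integer master seed; all randomness derives from it.
#' @return A validated list of class `bf_config`.
#' @export
bf_config <- function(impute_zeros = FALSE,
                      pre_impute_strategy = c("column_mean", "knn", "mix_type"),
                      knn_k = 5,
                      mf_method = c("auto", "nmf", "svd", "off"),
                      mf_mode = c("nan_only", "full"),
                      mf_rank = "auto",
                      subgroup_size = NULL,
                      n_models = 3,
                      n_iterations = 3,
                      use_tuning = FALSE,
                      n_trials = 20,
                      master_seed = 42) {
  cfg <- list(
    impute_zeros = isTRUE(impute_zeros),
    pre_impute_strategy = match.arg(pre_impute_strategy),
    knn_k = as.integer(knn_k),
    mf_method = match.arg(mf_method),
    mf_mode = match.arg(mf_mode),
    mf_rank = mf_rank,
    subgroup_size = if (is.null(subgroup_size)) NULL else as.integer(subgroup_size),
    n_models = as.integer(n_models),
    n_iterations = as.integer(n_iterations),
    use_tuning = isTRUE(use_tuning),
    n_trials = as.integer(n_trials),
    master_seed = as.integer(master_seed))
  validate_config(cfg)
}

#' Validate an imputation configuration
#'
#' @param config A list as built by [bf_config()].
#' @return The config, invisibly unchanged, or an error naming the
#'   offending field and its legal range.
#' @export
validate_config <- function(config) {
  if (config$n_models < 3 || config$n_models > 9) {
    stop("n_models must be between 3 and 9, got ", config$n_models)
  }
  if (config$n_iterations < 1 || config$n_iterations > 9) {
    stop("n_iterations must be between 1 and 9, got ", config$n_iterations)
  }
  if (config$knn_k < 1) stop("knn_k must be at least 1, got ", config$knn_k)
  if (config$n_trials < 1) stop("n_trials must be at least 1, got ", config$n_trials)
  structure(config, class = "bf_config")
}

#' Impute missing values in a mixed-type table
#'
#' The end-to-end engine: preprocess (token normalization, 60% majority
#' typing, label encoding, pre-imputation), low-rank matrix-factorization
#' completion of the pre-imputed matrix, then per-column gradient-boosted
#' ensemble imputation refined over sequential passes. Within each pass,
#' columns are visited in ascending order of missing count and updates are
#' in place, so later columns see the fresh imputations of earlier ones;
#' parameters tuned in the first pass are cached and reused. Observed
#' cells are never altered.
#'
#' @param data A data frame of raw cells, or a path handled by
#'   [read_mixed_table()] upstream.
#' @param ... Configuration knobs passed to [bf_config()].
#' @param id_col Optional identifier column carried through untouched.
#' @param config A ready-made [bf_config()]; overrides `...`.
#' @return An object of class `boostfill`: a list with `imputed_clean`
#'   (original value space, categories as text), `imputed_encoded`,
#'   `records` (one row per column per pass), `per_iteration_change`
#'   (mean absolute change of imputed cells per pass), `profiles`,
#'   `excluded_columns`, `gate`, `factorization` and `config`.
#' @examples
#' tab <- generate_synthetic(n_rows = 60, n_cont = 4, n_cat = 2,
#'                           n_bool = 0, seed = 1)$data
#' masked <- mask_mcar(tab, fraction = 0.1, seed = 2)$masked
#' fit <- boostfill(masked, n_iterations = 1, master_seed = 7)
#' glance(fit)
#' @export
boostfill <- function(data, ..., id_col = NULL, config = NULL) {
  if (is.null(config)) config <- bf_config(...)
  config <- validate_config(config)
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }

  prep <- preprocess(data, id_col = id_col,
                     impute_zeros = config$impute_zeros,
                     strategy = config$pre_impute_strategy,
                     k = config$knn_k)
  profiles <- prep$profiles
  typed <- profiles$column[profiles$type != "excluded"]
  excluded <- profiles$column[profiles$type == "excluded"]
  if (!length(typed)) {
    warning("no typed columns: nothing to impute")
    return(structure(
      list(imputed_clean = prep$clean, imputed_encoded = prep$encoded,
           records = tibble::tibble(), per_iteration_change = numeric(),
           profiles = profiles, excluded_columns = excluded,
           gate = NULL, factorization = NULL, config = config,
           ids = prep$ids, id_col = prep$id_col),
      class = "boostfill"))
  }

  pre_mat <- as.matrix(as.data.frame(prep$pre_imputed)[typed])
  storage.mode(pre_mat) <- "double"
  mask <- is.na(as.matrix(as.data.frame(prep$encoded)[typed]))
  fact <- mf_complete(pre_mat, mask,
                      method = config$mf_method, rank = config$mf_rank,
                      mode = config$mf_mode,
                      subgroup_size = config$subgroup_size,
                      seed = config$master_seed + 1L)

  miss_cols <- profiles$column[profiles$type != "excluded" &
                                 profiles$n_missing > 0]
  ord <- order(profiles$n_missing[match(miss_cols, profiles$column)],
               match(miss_cols, profiles$column))
  miss_cols <- miss_cols[ord]

  gate <- gate_hyperparameter_search(
    n_samples = nrow(prep$clean), n_features = length(typed),
    n_missing_columns = length(miss_cols))

  miss_mask <- mask
  colnames(miss_mask) <- typed
  state <- list(clean = prep$clean, encoded = prep$encoded,
                pre_imputed = prep$pre_imputed, profiles = profiles,
                transformed = fact$transformed, gate = gate,
                miss_mask = miss_mask, params_cache = list(), records = NULL)

  prev_fill <- fact$transformed[mask]
  changes <- numeric(0)
  for (it in seq_len(config$n_iterations)) {
    for (col in miss_cols) state <- impute_column(col, state, config, it)
    cur_fill <- as.matrix(as.data.frame(state$encoded)[typed])[mask]
    changes <- c(changes,
                 if (length(cur_fill)) mean(abs(cur_fill - prev_fill)) else 0)
    prev_fill <- cur_fill
  }

  structure(
    list(imputed_clean = state$clean,
         imputed_encoded = state$encoded,
         records = if (is.null(state$records)) tibble::tibble() else state$records,
         per_iteration_change = changes,
         profiles = profiles,
         excluded_columns = excluded,
         gate = gate,
         factorization = fact[c("method_used", "rank_used",
                                "n_outer_iters", "final_rel_change")],
         config = config,
         ids = prep$ids, id_col = prep$id_col),
    class = "boostfill")
}

#' @export
print.boostfill <- function(x, ...) {
  cat("<boostfill> ", nrow(x$imputed_clean), " rows x ",
      ncol(x$imputed_clean), " columns; ",
      sum(x$profiles$n_missing), " cells imputed over ",
      x$config$n_iterations, " pass(es)\n", sep = "")
  if (!is.null(x$factorization)) {
    cat("  factorization: ", x$factorization$method_used,
        " (rank ", x$factorization$rank_used, ")\n", sep = "")
  }
  if (length(x$excluded_columns)) {
    cat("  excluded columns: ", paste(x$excluded_columns, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Per-column imputation records of a fit
#'
#' @param x A `boostfill` object.
#' @param ... Unused.
#' @return A tibble with one row per imputed column per pass: `column`,
#'   `iteration`, `learner`, `n_missing`, `tuned`, `n_models`, `fallback`.
#' @export
tidy.boostfill <- function(x, ...) {
  tibble::as_tibble(x$records)
}

#' One-row summary of an imputation fit
#'
#' @param x A `boostfill` object.
#' @param ... Unused.
#' @return A one-row tibble: table shape, missing-cell count, iteration
#'   count, final per-pass change, factorization method and rank, and
#'   whether the tuning gate allowed hyperparameter search.
#' @export
glance.boostfill <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x$imputed_clean),
    n_cols = ncol(x$imputed_clean),
    n_missing_cells = sum(x$profiles$n_missing),
    n_excluded = length(x$excluded_columns),
    n_iterations = x$config$n_iterations,
    final_change = if (length(x$per_iteration_change))
      x$per_iteration_change[length(x$per_iteration_change)] else NA_real_,
    mf_method = if (is.null(x$factorization)) NA_character_
                else x$factorization$method_used,
    mf_rank = if (is.null(x$factorization)) NA_integer_
              else x$factorization$rank_used,
    gate_allowed = if (is.null(x$gate)) NA else x$gate$allowed)
}

#' Turn an object into a tidy tibble
#'
#' @param x An object.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of an object
#'
#' @param x An object.
#' @param ... Method-specific arguments.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot the per-pass refinement trajectory
#'
#' Shows the mean absolute change of imputed cells at each refinement
#' pass; a decreasing curve indicates the feedback loop is stabilizing.
#'
#' @param object A `boostfill` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boostfill <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$per_iteration_change),
    change = object$per_iteration_change)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$change)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$iteration) +
    ggplot2::labs(x = "refinement pass",
                  y = "mean |change| of imputed cells",
                  title = "Iterative refinement trajectory") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
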