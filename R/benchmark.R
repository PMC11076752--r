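#' Mask cells completely at random
#'
#' Draws masked positions uniformly among the observed cells, either
#' globally (one draw over all eligible cells) or per column. The realized
#' count is `round(fraction * n_eligible)`, and at least 1 when
#' `fraction > 0`. Already-missing cells are never targeted, and a column
#' is never left without observed values.
#'
#' @param data A data frame (typically fully observed synthetic data).
#' @param fraction Fraction of observed cells to mask, in \[0, 1).
#' @param scope `"global"` or `"per_column"`.
#' @param seed Integer seed.
#' @return A list with `masked` (the tibble with masked cells set to
#'   `NA`) and `mask` (logical matrix, `TRUE` at masked positions).
#' @export
mask_mcar <- function(data, fraction, scope = c("global", "per_column"),
                      seed = 1) {
  scope <- match.arg(scope)
  stopifnot(is.data.frame(data), fraction >= 0, fraction < 1)
  data <- tibble::as_tibble(data)
  obs <- !is.na(as.matrix(data))
  mask <- matrix(FALSE, nrow(data), ncol(data),
                 dimnames = dimnames(obs))
  set.seed(seed)
  if (fraction > 0) {
    if (scope == "global") {
      eligible <- which(obs)
      n_mask <- max(1L, round(fraction * length(eligible)))
      mask[sample(eligible, n_mask)] <- TRUE
    } else {
      for (j in seq_len(ncol(data))) {
        eligible <- which(obs[, j])
        if (!length(eligible)) next
        n_mask <- max(1L, round(fraction * length(eligible)))
        mask[eligible[sample.int(length(eligible), n_mask)], j] <- TRUE
      }
    }
    starved <- colSums(obs & !mask) == 0 & colSums(obs) > 0
    if (any(starved)) {
      stop("masking would leave column '",
           names(data)[which(starved)[1]], "' with no observed values")
    }
  }
  masked <- data
  for (j in seq_len(ncol(data))) masked[[j]][mask[, j]] <- NA
  list(masked = masked, mask = mask)
}

#' Apply a schedule of masking levels
#'
#' Produces one independently masked dataset per level, with per-level
#' seeds derived from the master seed. The default schedule is the
#' 1%–25% ladder in 1% steps (25 datasets).
#'
#' @param data A fully observed data frame.
#' @param fractions Numeric vector of masking fractions.
#' @param scope Passed to [mask_mcar()].
#' @param seed Master seed; level `i` uses `seed + i`.
#' @return A list of [mask_mcar()] results, one per fraction, each with
#'   the `fraction` recorded.
#' @export
mask_schedule <- function(data, fractions = (1:25) / 100,
                          scope = "global", seed = 1) {
  if (anyNA(data)) stop("mask_schedule requires a fully observed table")
  purrr::imap(fractions, function(f, i) {
    res <- mask_mcar(data, f, scope = scope, seed = seed + i)
    res$fraction <- f
    res
  })
}

#' Score an imputed table against ground truth on masked cells
#'
#' Computes, over masked cells only, the root-mean-square error for
#' continuous columns and the proportion of exactly recovered categories
#' for categorical (including Boolean) columns. Excluded columns are
#' ignored. Symmetric to row/column permutations of its aligned inputs.
#'
#' @param imputed The imputed table (original value space).
#' @param truth The ground-truth table.
#' @param mask Logical matrix from [mask_mcar()].
#' @param profiles Profile tibble (from [preprocess()] or a `boostfill`
#'   fit) giving each column's type.
#' @return A one-row tibble: `rmse_continuous`, `accuracy_categorical`,
#'   `n_masked_continuous`, `n_masked_categorical`.
#' @export
score_imputation <- function(imputed, truth, mask, profiles) {
  stopifnot(all(dim(imputed) == dim(truth)),
            all(dim(mask) == dim(truth)))
  if (!any(mask)) stop("empty mask: nothing to score")
  cols <- names(truth)
  sq <- c(); hits <- c()
  for (j in seq_along(cols)) {
    type <- profiles$type[match(cols[j], profiles$column)]
    m <- mask[, j]
    if (!any(m) || is.na(type) || type == "excluded") next
    if (type == "continuous") {
      d <- as.numeric(imputed[[j]][m]) - as.numeric(truth[[j]][m])
      sq <- c(sq, d^2)
    } else {
      hits <- c(hits, as.character(imputed[[j]][m]) ==
                      as.character(truth[[j]][m]))
    }
  }
  tibble::tibble(
    rmse_continuous = if (length(sq)) sqrt(mean(sq)) else NA_real_,
    accuracy_categorical = if (length(hits)) mean(hits) else NA_real_,
    n_masked_continuous = length(sq),
    n_masked_categorical = length(hits))
}

#' Export masked-cell values for density comparison
#'
#' Collects, per masked cell, the ground-truth and imputed values in tidy
#' long form, suitable for density overlays of truth versus imputation.
#'
#' @inheritParams score_imputation
#' @return A tibble with columns `column`, `type`, `truth`, `imputed`
#'   (values as text for categorical columns).
#' @export
density_export <- function(imputed, truth, mask, profiles) {
  rows <- purrr::map(names(truth), function(cn) {
    j <- match(cn, names(truth))
    type <- profiles$type[match(cn, profiles$column)]
    m <- mask[, j]
    if (!any(m) || is.na(type) || type == "excluded") return(NULL)
    tibble::tibble(column = cn, type = type,
                   truth = as.character(truth[[j]][m]),
                   imputed = as.character(imputed[[j]][m]))
  })
  dplyr::bind_rows(rows)
}

# column-mean / kNN baseline fills in original value space, reusing the
# preprocessing machinery so the baselines share typing and decoding
baseline_fill <- function(masked, strategy, k = 5) {
  prep <- preprocess(masked, strategy = strategy, k = k)
  out <- prep$clean
  for (j in seq_len(ncol(out))) {
    cn <- names(out)[j]
    type <- prep$profiles$type[j]
    if (type == "excluded") next
    miss <- is.na(prep$encoded[[cn]])
    if (!any(miss)) next
    fill <- prep$pre_imputed[[cn]][miss]
    out[[cn]][miss] <- if (type == "categorical") {
      decode_categorical(fill, prep$profiles$categories[[j]], name = cn)
    } else fill
  }
  out
}

#' Benchmark the imputation engine against baselines under MCAR masking
#'
#' For each masking fraction: masks the fully observed table, runs the
#' full engine plus the column-mean and kNN baselines on the masked copy,
#' and scores every method on the masked cells against ground truth.
#'
#' @param data A fully observed data frame (e.g. from
#'   [generate_synthetic()]).
#' @param fractions Masking fractions to evaluate.
#' @param scope Masking scope, see [mask_mcar()].
#' @param seed Master seed (drives masking and the engine).
#' @param config A [bf_config()] for the engine (its `master_seed` is
#'   re-derived from `seed`).
#' @param knn_k Neighbour count for the kNN baseline.
#' @return An object of class `bf_benchmark`: a tibble with columns
#'   `fraction`, `method`, `metric`, `value`, plus attributes carrying the
#'   per-fraction density exports.
#' @export
benchmark_imputation <- function(data, fractions = c(0.1, 0.2, 0.3, 0.4),
                                 scope = "global", seed = 1,
                                 config = bf_config(), knn_k = 5) {
  stopifnot(!anyNA(data))
  densities <- list()
  res <- purrr::imap(fractions, function(f, i) {
    mk <- mask_mcar(data, f, scope = scope, seed = seed + i)
    cfg <- config
    cfg$master_seed <- as.integer(seed + 100L + i)
    fit <- boostfill(mk$masked, config = cfg)
    profiles <- fit$profiles
    fills <- list(
      boostfill = fit$imputed_clean,
      column_mean = baseline_fill(mk$masked, "column_mean"),
      knn = baseline_fill(mk$masked, "knn", k = knn_k))
    densities[[as.character(f)]] <<-
      density_export(fills$boostfill, data, mk$mask, profiles)
    purrr::imap(fills, function(tab, method) {
      score_imputation(tab, data, mk$mask, profiles) |>
        dplyr::mutate(fraction = f, method = method, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  long <- res |>
    tidyr::pivot_longer(c("rmse_continuous", "accuracy_categorical"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("fraction", "method", "metric", "value") |>
    dplyr::filter(!is.na(.data$value))
  structure(long, class = c("bf_benchmark", class(long)),
            densities = densities)
}

#' Plot benchmark metrics across masking levels
#'
#' @param object A `bf_benchmark` tibble.
#' @param ... Unused.
#' @return A ggplot object: one panel per metric, one line per method.
#' @export
autoplot.bf_benchmark <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fraction, y = .data$value,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "masked fraction", y = NULL,
                  title = "Masked-cell recovery by method") +
    ggplot2::theme_minimal()
}
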