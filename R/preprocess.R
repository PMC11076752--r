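#' Missing-value token aliases
#'
#' Spreadsheet exports and hand-edited tables encode missingness with a zoo
#' of tokens. This closed set (plus empty and whitespace-only strings) is
#' normalized to `NA` before any typing or imputation happens. Matching is
#' exact after stripping surrounding whitespace; it is deliberately not
#' case-insensitive beyond the spellings listed, so that e.g. the category
#' label "na" in a biological annotation column survives if it is not one of
#' the listed spellings.
#'
#' @return Character vector of tokens treated as missing.
#' @export
missing_tokens <- function() {
  c("NaN", "NAN", "Nan", "nan", "NA", "#NA", "N/A", "NA#",
    "#VALUE!", "#DIV/0!")
}

# A cell (already whitespace-stripped) counts as missing if it is NA, one of
# the alias tokens, or empty.
is_missing_token <- function(x) {
  is.na(x) | x == "" | x %in% missing_tokens()
}

#' Normalize missing-value tokens to NA
#'
#' Every cell whose whitespace-stripped text equals one of
#' [missing_tokens()], or is empty/whitespace-only, becomes `NA`. All other
#' cells are left untouched (numeric cells keep their numeric type; `NaN`
#' values in numeric columns become `NA`). Idempotent.
#'
#' @param data A data frame; columns may be numeric, character, logical or
#'   factor.
#' @param tokens Character vector of alias tokens (default
#'   [missing_tokens()]).
#' @return A tibble of the same shape.
#' @export
normalize_missing_tokens <- function(data, tokens = missing_tokens()) {
  stopifnot(is.data.frame(data))
  out <- purrr::map(data, function(col) {
    if (is.numeric(col)) {
      col[is.nan(col)] <- NA
      return(col)
    }
    x <- trimws(as.character(col))
    x[is.na(x) | x == "" | x %in% tokens] <- NA
    x
  })
  tibble::as_tibble(out)
}

#' Convert zero cells to missing
#'
#' Optionally treats zeros as missing values to be imputed, a common need
#' for expression matrices where zero is a dropout rather than a
#' measurement. Cells (numeric, or text parsing to a number) equal to 0
#' become `NA` when `enabled`; otherwise the input is returned unchanged.
#'
#' @param data A data frame.
#' @param enabled Logical; if `FALSE` this is the identity.
#' @return A tibble of the same shape.
#' @export
zeros_to_missing <- function(data, enabled = FALSE) {
  stopifnot(is.data.frame(data))
  if (!enabled) return(tibble::as_tibble(data))
  out <- purrr::map(data, function(col) {
    if (is.numeric(col)) {
      col[!is.na(col) & col == 0] <- NA
      return(col)
    }
    x <- as.character(col)
    num <- suppressWarnings(as.numeric(x))
    x[!is.na(num) & num == 0] <- NA
    x
  })
  tibble::as_tibble(out)
}

# Boolean tokens are a 2-class categorical; they are listed here so that a
# logical column read from text is typed as categorical, never coerced to
# 0/1 continuous.
boolean_tokens <- function() c("TRUE", "FALSE", "True", "False", "true", "false")

#' Classify a column as continuous, categorical or excluded
#'
#' Applies the strict majority rule: over the non-missing cells, if the
#' fraction parseable as finite numbers exceeds 60% the column is
#' continuous and non-numeric cells are coerced to `NA`; if the fraction of
#' non-numeric tokens exceeds 60% it is categorical and numeric cells are
#' coerced to `NA`; otherwise (including an exact 60/40 split) the column is
#' excluded and passed through untouched, never imputed. Boolean tokens
#' count as categorical. Fractions are computed over non-missing cells so
#' that missingness alone cannot change a column's type.
#'
#' @param values A vector of cells (character or numeric), `NA` = missing.
#' @param name Column name used in messages.
#' @return A list with `type` ("continuous", "categorical" or "excluded"),
#'   `values` (the coerced column: numeric for continuous, character
#'   otherwise), `n_coerced` (minority cells turned into `NA`) and
#'   `categories` (sorted observed categories, categorical only).
#' @export
classify_column <- function(values, name = "column") {
  if (length(values) == 0) stop("empty column: ", name)
  if (is.numeric(values)) {
    return(list(type = "continuous", values = as.numeric(values),
                n_coerced = 0L, categories = NULL))
  }
  x <- as.character(values)
  obs <- !is.na(x)
  if (!any(obs)) {
    warning("column '", name, "' has no observed values; excluded")
    return(list(type = "excluded", values = x, n_coerced = 0L,
                categories = NULL))
  }
  # booleans are non-numeric tokens already, but make the intent explicit
  num <- suppressWarnings(as.numeric(x))
  num[x %in% boolean_tokens()] <- NA
  is_num <- obs & !is.na(num) & is.finite(num)
  p_num <- sum(is_num) / sum(obs)
  p_cat <- (sum(obs) - sum(is_num)) / sum(obs)
  if (p_num > 0.60) {
    vals <- num
    list(type = "continuous", values = vals,
         n_coerced = sum(obs & !is_num), categories = NULL)
  } else if (p_cat > 0.60) {
    vals <- x
    vals[is_num] <- NA
    cats <- sort(unique(vals[!is.na(vals)]), method = "radix")
    list(type = "categorical", values = vals,
         n_coerced = sum(is_num), categories = cats)
  } else {
    list(type = "excluded", values = x, n_coerced = 0L, categories = NULL)
  }
}

#' Encode a categorical column as integer codes
#'
#' Observed categories are mapped to codes `0..K-1` in lexicographic
#' (C-locale) order of category text, so the encoding is deterministic
#' across runs and platforms. `NA` stays `NA`.
#'
#' @param values Character vector of category cells.
#' @param categories Sorted category vector (as produced by
#'   [classify_column()]); defaults to the sorted observed values.
#' @return Numeric vector of codes with `NA` preserved.
#' @export
encode_categorical <- function(values, categories = NULL) {
  x <- as.character(values)
  if (is.null(categories)) {
    categories <- sort(unique(x[!is.na(x)]), method = "radix")
  }
  codes <- match(x, categories) - 1
  bad <- !is.na(x) & is.na(codes)
  if (any(bad)) {
    stop("unknown category '", x[which(bad)[1]], "' during encoding")
  }
  as.numeric(codes)
}

#' Decode integer codes back to category text
#'
#' Exact inverse of [encode_categorical()]. Codes are rounded to the
#' nearest integer before lookup so that ensemble-averaged class indices
#' decode cleanly.
#'
#' @param codes Numeric vector of codes.
#' @param categories The category vector the codes index into.
#' @param name Column name for error messages.
#' @return Character vector of category text with `NA` preserved.
#' @export
decode_categorical <- function(codes, categories, name = "column") {
  idx <- as.integer(round(codes)) + 1L
  bad <- !is.na(idx) & (idx < 1L | idx > length(categories))
  if (any(bad)) {
    stop("code ", codes[which(bad)[1]], " has no category in column '",
         name, "'")
  }
  out <- categories[idx]
  out[is.na(codes)] <- NA
  out
}

# modal code with ties broken toward the smallest code
modal_code <- function(codes) {
  tab <- table(codes[!is.na(codes)])
  as.numeric(names(tab)[which.max(tab)])
}

# Min-max scale the columns of a numeric matrix to [0, 1]; constant columns
# map to 0. Returns the scaled matrix plus the ranges needed to invert.
minmax_scale <- function(mat) {
  lo <- apply(mat, 2, min, na.rm = TRUE)
  hi <- apply(mat, 2, max, na.rm = TRUE)
  rng <- hi - lo
  rng[rng == 0 | !is.finite(rng)] <- 1
  scaled <- sweep(sweep(mat, 2, lo, "-"), 2, rng, "/")
  list(scaled = scaled, lo = lo, rng = rng)
}

minmax_unscale <- function(scaled, sc) {
  sweep(sweep(scaled, 2, sc$rng, "*"), 2, sc$lo, "+")
}

# k-nearest-neighbour fill on an encoded numeric matrix. Distances are
# Euclidean over the typed columns of the mean/mode-filled, min-max-scaled
# matrix; the fill for a missing cell uses the k nearest other rows that
# have an observed value in the target column (neighbour mean for
# continuous, neighbour majority code for categorical, ties toward the
# smallest code).
knn_fill <- function(encoded_mat, base_fill, types, k) {
  sc <- minmax_scale(base_fill)
  d2 <- as.matrix(stats::dist(sc$scaled))^2
  out <- encoded_mat
  for (j in seq_len(ncol(encoded_mat))) {
    miss <- which(is.na(encoded_mat[, j]))
    if (!length(miss)) next
    donors <- which(!is.na(encoded_mat[, j]))
    for (i in miss) {
      ord <- donors[order(d2[i, donors], donors)]
      nb <- ord[seq_len(min(k, length(ord)))]
      vals <- encoded_mat[nb, j]
      out[i, j] <- if (types[j] == "categorical") modal_code(vals)
                   else mean(vals)
    }
  }
  out
}

#' Fill missing cells of an encoded table with a simple strategy
#'
#' Produces the pre-imputed table that seeds the factorization and boosting
#' stages. Three strategies are offered: `"column_mean"` fills continuous
#' columns with the column mean and categorical columns with the modal code
#' (ties toward the smallest code); `"knn"` fills every typed column from
#' the `k` nearest rows (Euclidean distance over the mean/mode-filled,
#' min-max-scaled typed columns); `"mix_type"` uses the column mean for
#' continuous columns and kNN for categorical ones. Excluded columns are
#' untouched and observed cells are never modified.
#'
#' @param encoded A data frame of encoded (numeric) typed columns; excluded
#'   columns may be character and are passed through.
#' @param profiles Profile tibble from [preprocess()] (columns `column`,
#'   `type`).
#' @param strategy One of `"column_mean"`, `"knn"`, `"mix_type"`.
#' @param k Neighbour count for the kNN strategies.
#' @return A tibble with no `NA` left in typed columns.
#' @export
pre_impute <- function(encoded, profiles,
                       strategy = c("column_mean", "knn", "mix_type"),
                       k = 5) {
  strategy <- match.arg(strategy)
  stopifnot(k >= 1)
  typed <- profiles$column[profiles$type != "excluded"]
  if (!length(typed)) return(tibble::as_tibble(encoded))
  types <- profiles$type[match(typed, profiles$column)]
  mat <- as.matrix(as.data.frame(encoded)[typed])
  storage.mode(mat) <- "double"

  empty <- typed[colSums(!is.na(mat)) == 0]
  if (length(empty)) {
    stop("no observed value to impute from in column '", empty[1], "'")
  }

  mean_mode <- mat
  for (j in seq_along(typed)) {
    miss <- is.na(mat[, j])
    if (!any(miss)) next
    fill <- if (types[j] == "categorical") modal_code(mat[, j])
            else mean(mat[, j], na.rm = TRUE)
    mean_mode[miss, j] <- fill
  }

  filled <- switch(strategy,
    column_mean = mean_mode,
    knn = knn_fill(mat, mean_mode, types, k),
    mix_type = {
      f <- knn_fill(mat, mean_mode, types, k)
      cont <- types == "continuous"
      f[, cont] <- mean_mode[, cont, drop = FALSE]
      f
    })

  out <- tibble::as_tibble(encoded)
  for (j in seq_along(typed)) out[[typed[j]]] <- filled[, j]
  out
}

#' Preprocess a raw mixed-type table
#'
#' The standalone entry point of the preprocessing stage. Normalizes
#' missing-value tokens, optionally converts zeros to missing, classifies
#' every column by the strict 60% majority rule, label-encodes categorical
#' columns, and fills remaining gaps with the chosen pre-imputation
#' strategy. Returns the three aligned tables the rest of the engine runs
#' on.
#'
#' @param data A data frame of raw cells (typically from
#'   [read_mixed_table()]).
#' @param id_col Optional name of an identifier column carried through
#'   untouched and never typed or imputed.
#' @param impute_zeros Treat zeros as missing (see [zeros_to_missing()]).
#' @param strategy,k Pre-imputation strategy and neighbour count
#'   (see [pre_impute()]).
#' @param tokens Missing-token alias set.
#' @return An object of class `bf_preprocess`: a list with `clean` (original
#'   value space, invalid tokens as `NA`), `encoded` (categoricals as
#'   integer codes), `pre_imputed` (encoded with no `NA` in typed columns),
#'   and `profiles` (one row per column: `column`, `type`, `n_missing`,
#'   `n_coerced`, `categories` list-column).
#' @export
preprocess <- function(data, id_col = NULL, impute_zeros = FALSE,
                       strategy = c("column_mean", "knn", "mix_type"),
                       k = 5, tokens = missing_tokens()) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(data), nrow(data) > 0, ncol(data) > 0)
  if (anyDuplicated(names(data))) stop("duplicated column names in input")
  data <- tibble::as_tibble(data)
  ids <- NULL
  if (!is.null(id_col)) {
    if (!id_col %in% names(data)) stop("id column '", id_col, "' not found")
    ids <- data[[id_col]]
    if (anyDuplicated(ids)) stop("duplicated row identifiers in '", id_col, "'")
    data <- data[setdiff(names(data), id_col)]
  }

  norm <- normalize_missing_tokens(data, tokens)
  norm <- zeros_to_missing(norm, impute_zeros)

  cls <- purrr::imap(norm, classify_column)
  profiles <- tibble::tibble(
    column = names(norm),
    type = unname(purrr::map_chr(cls, "type")),
    n_missing = unname(purrr::map_int(cls, ~ sum(is.na(.x$values)))),
    n_coerced = unname(purrr::map_int(cls, ~ as.integer(.x$n_coerced))),
    categories = purrr::map(cls, "categories")
  )

  clean <- tibble::as_tibble(purrr::map(cls, "values"))
  encoded <- clean
  for (j in which(profiles$type == "categorical")) {
    encoded[[j]] <- encode_categorical(clean[[j]], profiles$categories[[j]])
  }

  pre_imputed <- pre_impute(encoded, profiles, strategy = strategy, k = k)

  structure(
    list(clean = clean, encoded = encoded, pre_imputed = pre_imputed,
         profiles = profiles, ids = ids, id_col = id_col),
    class = "bf_preprocess")
}

#' @export
print.bf_preprocess <- function(x, ...) {
  tab <- table(factor(x$profiles$type,
                      levels = c("continuous", "categorical", "excluded")))
  cat("<bf_preprocess> ", nrow(x$clean), " rows x ", ncol(x$clean),
      " columns (", tab[["continuous"]], " continuous, ",
      tab[["categorical"]], " categorical, ",
      tab[["excluded"]], " excluded); ",
      sum(x$profiles$n_missing), " missing cells\n", sep = "")
  invisible(x)
}
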