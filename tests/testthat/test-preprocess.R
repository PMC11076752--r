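test_that("alias tokens, empty and whitespace-only cells become NA", {
  col <- c(missing_tokens(), "", "   ", "  NA  ", "1.5", "value", "0")
  out <- normalize_missing_tokens(tibble::tibble(x = col))
  n_alias <- length(missing_tokens()) + 3
  expect_true(all(is.na(out$x[seq_len(n_alias)])))
  expect_equal(out$x[(n_alias + 1):length(col)], c("1.5", "value", "0"))
  # numeric columns: NaN normalized, values untouched
  num <- normalize_missing_tokens(tibble::tibble(y = c(1, NaN, 0)))
  expect_identical(num$y, c(1, NA, 0))
})

test_that("token normalization is idempotent", {
  raw <- make_mixed_raw()
  once <- normalize_missing_tokens(raw)
  expect_identical(normalize_missing_tokens(once), once)
})

test_that("zero conversion obeys the enabled flag and spares nonzeros", {
  df <- tibble::tibble(x = c(0, 0.001, 5), y = c("0", "a", "0.0"))
  on_ <- zeros_to_missing(df, TRUE)
  expect_identical(on_$x, c(NA, 0.001, 5))
  expect_identical(on_$y, c(NA, "a", NA))
  expect_identical(zeros_to_missing(df, FALSE), df)
})

test_that("column typing follows the strict majority rule", {
  cases <- list(
    list(v = c(rep("t", 8), "1", "2"), type = "categorical", coerced = 2L),
    list(v = as.character(1:10), type = "continuous", coerced = 0L),
    list(v = c(rep("t", 6), as.character(1:4)), type = "excluded", coerced = 0L),
    list(v = c("TRUE", "FALSE", "TRUE", "1"), type = "categorical", coerced = 1L),
    list(v = c("7", "8", NA, NA, NA), type = "continuous", coerced = 0L))
  for (cs in cases) {
    got <- classify_column(cs$v)
    expect_equal(got$type, cs$type, info = paste(cs$v, collapse = ","))
    expect_equal(got$n_coerced, cs$coerced)
  }
  expect_warning(all_na <- classify_column(c(NA_character_, NA)), "no observed")
  expect_equal(all_na$type, "excluded")
})

test_that("typing is a deterministic function of the cell-kind multiset", {
  set.seed(7)
  for (rep in 1:20) {
    n_num <- sample(0:12, 1); n_txt <- sample(0:12, 1); n_na <- sample(0:4, 1)
    if (n_num + n_txt == 0) n_num <- 1
    v <- sample(c(as.character(seq_len(n_num)),
                  paste0("t", seq_len(n_txt)), rep(NA, n_na)))
    a <- classify_column(v)
    b <- classify_column(sample(v))
    expect_equal(a$type, b$type)
    expect_equal(a$n_coerced, b$n_coerced)
  }
})

test_that("label encoding is lexicographic and round-trips exactly", {
  enc <- encode_categorical(c("b", "a", "b", NA))
  expect_equal(enc, c(1, 0, 1, NA))
  expect_equal(encode_categorical(c("x", "x")), c(0, 0))
  set.seed(3)
  for (rep in 1:10) {
    cats <- paste0("lvl", sample(20, sample(2:6, 1)))
    v <- sample(c(sample(cats, 15, replace = TRUE), NA, NA))
    sorted <- sort(unique(v[!is.na(v)]), method = "radix")
    codes <- encode_categorical(v, sorted)
    expect_identical(decode_categorical(codes, sorted), v)
  }
  expect_error(decode_categorical(5, c("a", "b")), "no category")
})

test_that("column-mean fill uses the mean and the smallest modal code", {
  prof <- tibble::tibble(column = c("num", "cat"),
                         type = c("continuous", "categorical"))
  enc <- tibble::tibble(num = c(1, 2, NA, 3), cat = c(0, 0, 1, 1))
  out <- pre_impute(enc, prof, "column_mean")
  expect_equal(out$num[3], 2)
  enc2 <- tibble::tibble(num = c(1, 1, 1, 1), cat = c(0, 1, NA, NA))
  out2 <- pre_impute(enc2, prof, "column_mean")
  expect_equal(out2$cat[3:4], c(0, 0))  # tie broken toward smallest code
  expect_error(
    pre_impute(tibble::tibble(num = c(NA_real_, NA), cat = c(0, 1)), prof),
    "num")
})

test_that("knn fill matches a brute-force nearest-neighbour oracle", {
  prof <- tibble::tibble(column = c("a", "b"),
                         type = c("continuous", "continuous"))
  enc <- tibble::tibble(a = c(0, 0.1, 10, NA), b = c(1, 1.1, 9, 1.05))
  out <- pre_impute(enc, prof, "knn", k = 2)
  # oracle: mean/mode-filled, min-max scaled matrix, exhaustive distances
  filled <- cbind(a = c(0, 0.1, 10, mean(c(0, 0.1, 10))), b = enc$b)
  sc <- apply(filled, 2, function(x) (x - min(x)) / (max(x) - min(x)))
  d <- as.matrix(dist(sc))
  nb <- order(d[4, 1:3])[1:2]
  expect_equal(out$a[4], mean(enc$a[nb]))
  expect_equal(out$a[1:3], enc$a[1:3])  # observed untouched
})

test_that("pre_impute never modifies an observed cell", {
  set.seed(11)
  for (strategy in c("column_mean", "knn", "mix_type")) {
    syn <- generate_synthetic(n_rows = 40, n_cont = 4, n_cat = 2,
                              n_bool = 1, seed = 5)
    mk <- mask_mcar(syn$data, 0.2, seed = 6)
    prep <- preprocess(mk$masked, strategy = strategy, k = 3)
    obs <- !is.na(as.matrix(prep$encoded))
    enc <- as.matrix(prep$encoded); pre <- as.matrix(prep$pre_imputed)
    expect_equal(pre[obs], enc[obs], info = strategy)
    expect_false(anyNA(pre))
  }
})

test_that("preprocess yields three aligned tables and honours exclusion", {
  prep <- preprocess(make_mixed_raw())
  expect_s3_class(prep, "bf_preprocess")
  expect_equal(dim(prep$clean), dim(prep$encoded))
  expect_equal(dim(prep$encoded), dim(prep$pre_imputed))
  expect_equal(names(prep$clean), names(prep$encoded))
  prof <- prep$profiles
  expect_equal(prof$type[prof$column == "mixed"], "excluded")
  # the 50/50 column is carried through untouched in all three outputs
  expect_identical(prep$clean$mixed, make_mixed_raw()$mixed)
  expect_identical(prep$pre_imputed$mixed, make_mixed_raw()$mixed)
  # alias cells became missing, then pre-imputed in typed columns
  typed <- prof$column[prof$type != "excluded"]
  expect_false(anyNA(as.matrix(prep$pre_imputed[typed])))
})

test_that("a table with no missing cells passes through unchanged", {
  df <- tibble::tibble(x = c(1, 2, 3), grp = c("a", "b", "a"))
  prep <- preprocess(df)
  expect_equal(prep$clean$x, df$x)
  expect_equal(prep$clean$grp, df$grp)
  expect_identical(prep$pre_imputed, prep$encoded)
})
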