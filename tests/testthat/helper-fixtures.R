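# small in-code fixtures shared across test files

# a raw table exercising every column kind: clean continuous, continuous
# with alias tokens, categorical, Boolean, and a 50/50 mixed column that
# the typing rule must exclude
make_mixed_raw <- function() {
  tibble::tibble(
    conc = c("1.5", "2.5", "NA", "4.5", "5.0", "3.0"),
    dose = c(10, 20, NaN, 40, 50, 30),
    arm = c("treated", "control", "#DIV/0!", "treated", "control", "treated"),
    resp = c("TRUE", "FALSE", "TRUE", "", "FALSE", "TRUE"),
    mixed = c("a", "b", "c", "1", "2", "3"))
}

# closed-form completion of a single masked cell of a rank-1 matrix:
# M[i, j] = M[i, k] * M[l, j] / M[l, k]
rank1_oracle <- function(M, i, j) {
  k <- if (j == 1) 2 else 1
  l <- if (i == 1) 2 else 1
  M[i, k] * M[l, j] / M[l, k]
}

# positive rank-1 matrix with one masked cell, pre-filled by column mean
rank1_case <- function(n = 8, p = 5, i = 2, j = 3, seed = 1, flip_row = NULL) {
  set.seed(seed)
  u <- stats::runif(n, 0.5, 2); v <- stats::runif(p, 0.5, 2)
  M <- u %*% t(v)
  if (!is.null(flip_row)) M[flip_row, ] <- -M[flip_row, ]
  pre <- M
  pre[i, j] <- mean(M[-i, j])
  mask <- matrix(FALSE, n, p)
  mask[i, j] <- TRUE
  list(M = M, pre = pre, mask = mask, i = i, j = j)
}

expect_tables_equal <- function(a, b) {
  expect_equal(dim(a), dim(b))
  for (cn in names(a)) {
    av <- a[[cn]]; bv <- b[[cn]]
    expect_equal(is.na(av), is.na(bv), info = cn)
    ok <- !is.na(av)
    if (is.numeric(av) && is.numeric(bv)) {
      expect_equal(av[ok], bv[ok], info = cn)
    } else {
      expect_equal(as.character(av)[ok], as.character(bv)[ok], info = cn)
    }
  }
}
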