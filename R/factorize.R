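#' Choose the factorization method for a matrix
#'
#' Non-negative matrix factorization respects the range of count-like and
#' label-encoded data, so it is used whenever every observed value is
#' non-negative; matrices with any negative observed value fall back to
#' truncated SVD, which is defined for any real matrix.
#'
#' @param mat Numeric matrix (pre-imputed; no `NA` expected, but tolerated).
#' @param mask Optional logical matrix marking originally-missing cells;
#'   masked cells are ignored for the sign check.
#' @return `"nmf"` or `"svd"`.
#' @export
choose_method <- function(mat, mask = NULL) {
  obs <- mat
  if (!is.null(mask)) obs[mask] <- NA
  if (!any(is.finite(obs))) stop("matrix has no observed value")
  if (all(obs >= 0, na.rm = TRUE)) "nmf" else "svd"
}

resolve_rank <- function(rank, n, p) {
  if (identical(rank, "auto") || is.null(rank)) {
    rank <- max(1L, min(8L, n - 1L, p - 1L))
  }
  rank <- as.integer(rank)
  if (rank < 1 || rank > min(n, p)) {
    stop("rank ", rank, " out of range for a ", n, "x", p, " matrix")
  }
  rank
}

# Multiplicative-update NMF (Frobenius objective). X must be complete and
# non-negative. Deterministic given seed. Returns the rank-r reconstruction.
nmf_reconstruct <- function(X, rank, seed, max_iter = 500, tol = 1e-4) {
  if (any(X < 0)) stop("NMF requires a non-negative matrix; use svd")
  n <- nrow(X); p <- ncol(X)
  eps <- .Machine$double.eps
  set.seed(seed)
  scale0 <- sqrt(mean(X) / rank + eps)
  W <- matrix(stats::runif(n * rank, 0, 1), n, rank) * scale0
  H <- matrix(stats::runif(rank * p, 0, 1), rank, p) * scale0
  obj_old <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    H <- H * (crossprod(W, X) / (crossprod(W, WH) + eps))
    WH <- W %*% H
    W <- W * (X %*% t(H)) / (WH %*% t(H) + eps)
    obj <- sum((X - W %*% H)^2)
    if (is.finite(obj_old) && (obj_old - obj) <= tol * max(obj_old, eps)) break
    obj_old <- obj
  }
  W %*% H
}

# Column-mean-centered truncated SVD reconstruction of a complete matrix.
svd_reconstruct <- function(X, rank) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu, "-")
  sv <- svd(Xc, nu = rank, nv = rank)
  d <- sv$d[seq_len(rank)]
  rec <- sv$u %*% (d * t(sv$v))
  sweep(rec, 2, mu, "+")
}

# Columns of a non-negative matrix scaled by their maximum land in [0, 1];
# unlike a full min-max transform, the pure rescaling preserves low-rank
# structure (an affine shift would raise the rank by one).
max_scale <- function(mat) {
  hi <- apply(mat, 2, max)
  hi[hi == 0 | !is.finite(hi)] <- 1
  list(scaled = sweep(mat, 2, hi, "/"), hi = hi)
}
max_unscale <- function(scaled, sc) sweep(scaled, 2, sc$hi, "*")

# Outer completion loop shared by both methods: fit on the current matrix,
# refill ONLY the masked cells from the reconstruction, and stop when the
# relative change on those cells drops below tol. NMF runs on columns
# scaled to [0, 1] by their maxima (so label codes and wide continuous
# columns share scale) and refills are clipped at zero; SVD reconstructions
# are not clipped.
complete_loop <- function(mat, mask, method, rank, max_outer_iters, tol,
                          seed) {
  n_it <- 0L; rel <- NA_real_
  if (any(mask)) {
    for (it in seq_len(max_outer_iters)) {
      rec <- if (method == "nmf") {
        sc <- max_scale(mat)
        r <- nmf_reconstruct(sc$scaled, rank, seed = seed + it - 1L)
        max_unscale(pmax(r, 0), sc)
      } else {
        svd_reconstruct(mat, rank)
      }
      old <- mat[mask]
      new <- rec[mask]
      if (method == "nmf") new <- pmax(new, 0)
      rel <- sum(abs(new - old)) / (sum(abs(old)) + .Machine$double.eps)
      mat[mask] <- new
      n_it <- it
      if (rel < tol) break
    }
  }
  list(mat = mat, n_outer_iters = n_it, final_rel_change = rel)
}

#' Low-rank completion of a pre-imputed matrix
#'
#' Iteratively refines the cells that were originally missing: the current
#' matrix is factorized at the given rank, the masked cells are overwritten
#' with the low-rank reconstruction, and the loop repeats until the
#' relative change on those cells falls below `tol` or `max_outer_iters`
#' is reached. Observed cells are never altered inside the loop. With
#' `mode = "nan_only"` the returned matrix equals the input on every
#' observed cell; `mode = "full"` returns the final reconstruction
#' everywhere, which additionally smooths (denoises) observed cells.
#' Optional sub-grouping partitions columns into contiguous blocks of at
#' most `subgroup_size` and completes each block independently, bounding
#' the factorization width on very wide tables.
#'
#' @param mat Numeric matrix with pre-imputed fills in the masked cells.
#' @param mask Logical matrix, `TRUE` where the cell was originally
#'   missing.
#' @param method `"auto"` (sign-based dispatch via [choose_method()]),
#'   `"nmf"`, `"svd"`, or `"off"` (identity).
#' @param rank Factorization rank, or `"auto"` for
#'   `min(8, n_rows - 1, n_cols - 1)`.
#' @param mode `"nan_only"` or `"full"` (see above).
#' @param max_outer_iters,tol Outer-loop cap and relative-change tolerance
#'   on the refilled cells.
#' @param subgroup_size Optional maximum width of independent column
#'   blocks.
#' @param seed Integer seed for the NMF initialization.
#' @return A list with `transformed` (complete numeric matrix),
#'   `method_used`, `rank_used`, `n_outer_iters` and `final_rel_change`.
#' @export
mf_complete <- function(mat, mask, method = c("auto", "nmf", "svd", "off"),
                        rank = "auto", mode = c("nan_only", "full"),
                        max_outer_iters = 10, tol = 1e-4,
                        subgroup_size = NULL, seed = 1) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  stopifnot(is.matrix(mat), is.logical(mask), all(dim(mat) == dim(mask)))
  if (anyNA(mat)) stop("matrix must be pre-imputed (no NA) before completion")

  if (method == "off") {
    return(list(transformed = mat, method_used = "off", rank_used = NA_integer_,
                n_outer_iters = 0L, final_rel_change = NA_real_))
  }
  if (method == "auto") method <- choose_method(mat, mask)
  if (method == "nmf" && any(mat[!mask] < 0)) {
    stop("negative observed values: NMF not applicable, use method = 'svd'")
  }

  blocks <- if (is.null(subgroup_size)) list(seq_len(ncol(mat))) else {
    split(seq_len(ncol(mat)),
          ceiling(seq_len(ncol(mat)) / as.integer(subgroup_size)))
  }

  out <- mat
  n_it <- 0L; rel <- NA_real_
  full_rec <- mat
  for (b in blocks) {
    sub <- mat[, b, drop = FALSE]
    r <- resolve_rank(rank, nrow(sub), ncol(sub))
    res <- complete_loop(sub, mask[, b, drop = FALSE], method, r,
                         max_outer_iters, tol, seed)
    out[, b] <- res$mat
    n_it <- max(n_it, res$n_outer_iters)
    if (!is.na(res$final_rel_change)) {
      rel <- if (is.na(rel)) res$final_rel_change else max(rel, res$final_rel_change)
    }
    if (mode == "full") {
      full_rec[, b] <- if (method == "nmf") {
        sc <- max_scale(res$mat)
        max_unscale(pmax(nmf_reconstruct(sc$scaled, r, seed = seed + 10000L), 0), sc)
      } else {
        svd_reconstruct(res$mat, r)
      }
    }
  }

  transformed <- if (mode == "full") full_rec else out
  list(transformed = transformed, method_used = method,
       rank_used = resolve_rank(rank, nrow(mat),
                                if (is.null(subgroup_size)) ncol(mat)
                                else min(ncol(mat), subgroup_size)),
       n_outer_iters = n_it, final_rel_change = rel)
}
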