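#' Generate a synthetic mixed-type table with latent low-rank structure
#'
#' Emulates the kind of table the engine targets: a block of non-negative
#' continuous columns with exact low-rank structure (`W %*% H`, entries of
#' `W` and `H` drawn as absolute Gaussians) plus additive Gaussian noise,
#' and categorical/Boolean columns derived by quantile-thresholding the
#' latent row factors, so every column carries mutual signal and is
#' predictable from the others. Fully observed; pair with [mask_mcar()]
#' to create benchmark inputs with known ground truth.
#'
#' @param n_rows Number of sample rows.
#' @param n_cont,n_cat,n_bool Counts of continuous, categorical and
#'   Boolean columns.
#' @param latent_rank Rank of the continuous block (must not exceed
#'   `min(n_rows, n_cont)`).
#' @param noise_sd Standard deviation of the additive noise; `NULL`
#'   defaults to 5% of the noiseless block's value range.
#' @param n_classes Classes per categorical column.
#' @param seed Integer seed; generation is deterministic.
#' @return A list with `data` (the fully observed tibble: continuous
#'   columns `cont_*` numeric, categorical `cat_*` and Boolean `bool_*`
#'   character), `truth` (identical to `data`; kept for scoring after
#'   masking), `latent` (`W`, `H`) and `noiseless` (the exact low-rank
#'   continuous block).
#' @export
generate_synthetic <- function(n_rows = 200, n_cont = 10, n_cat = 4,
                               n_bool = 2, latent_rank = 3,
                               noise_sd = NULL, n_classes = 3, seed = 1) {
  stopifnot(n_rows >= 2, n_cont >= 1, latent_rank >= 1, n_classes >= 2)
  if (latent_rank > min(n_rows, n_cont)) {
    stop("latent_rank must not exceed min(n_rows, n_cont)")
  }
  set.seed(seed)
  W <- matrix(abs(stats::rnorm(n_rows * latent_rank)), n_rows, latent_rank)
  H <- matrix(abs(stats::rnorm(latent_rank * n_cont)), latent_rank, n_cont)
  noiseless <- W %*% H
  if (is.null(noise_sd)) {
    noise_sd <- 0.05 * (max(noiseless) - min(noiseless))
  }
  cont <- noiseless +
    matrix(stats::rnorm(n_rows * n_cont, sd = noise_sd), n_rows, n_cont)

  out <- tibble::as_tibble(as.data.frame(cont))
  names(out) <- sprintf("cont_%02d", seq_len(n_cont))

  # categorical/Boolean columns follow the latent factors via quantile
  # thresholds, so they are informative about (and informed by) the
  # continuous block
  if (n_cat > 0) {
    for (j in seq_len(n_cat)) {
      f <- W[, (j - 1) %% latent_rank + 1]
      qs <- stats::quantile(f, probs = seq_len(n_classes - 1) / n_classes)
      cls <- findInterval(f, qs) + 1L
      out[[sprintf("cat_%02d", j)]] <- letters[cls]
    }
  }
  if (n_bool > 0) {
    for (j in seq_len(n_bool)) {
      f <- W[, (n_cat + j - 1) %% latent_rank + 1]
      out[[sprintf("bool_%02d", j)]] <-
        ifelse(f > stats::median(f), "TRUE", "FALSE")
    }
  }

  list(data = out, truth = out, latent = list(W = W, H = H),
       noiseless = noiseless)
}
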