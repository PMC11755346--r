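# Cross-validated tuning of the L2 regularization coefficient.

#' Tune the L2 coefficient by k-fold cross-validation
#'
#' Samples (not pairs) are partitioned into `k` folds, stratified by cancer
#' type; for every alpha on the grid, the model is trained on k-1 folds and
#' its MSE recorded on the held-out fold. Fold membership, weight
#' initialization and batch order are shared across alphas, so the grid is
#' compared on paired folds. The selected alpha minimizes the mean
#' validation MSE; exact ties go to the larger alpha (the stronger
#' regularization).
#'
#' @param pairs Training `pair_dataset` (index must carry `cancer_type`).
#' @param alpha_grid Candidate coefficients; default is the six powers
#'   `1, 1e-1, ..., 1e-5`.
#' @param k Number of folds (>= 2). Default 10.
#' @param config Base [model_config()]; its `l2_alpha` is overridden by the
#'   grid. Use a reduced `epochs` here to bound runtime.
#' @param seed Seed for the fold assignment; defaults to `config$seed`.
#' @return A `ttrec_cv` object: per-fold MSE matrix, per-alpha mean/sd
#'   summary, the selected `best_alpha`, and the fold assignment.
#' @export
cv_tune_alpha <- function(pairs, alpha_grid = 10^(0:-5), k = 10,
                          config = model_config(), seed = NULL) {
  stopifnot(inherits(pairs, "pair_dataset"))
  if (length(alpha_grid) == 0) abort("alpha_grid must be non-empty")
  if (k < 2) abort("k must be at least 2")
  seed <- seed %||% config$seed

  samples <- dplyr::distinct(pairs$index, .data$sample_id, .data$cancer_type)
  if (anyNA(samples$cancer_type)) {
    abort("cv_tune_alpha needs a cancer_type label for every sample")
  }
  if (nrow(samples) < k) abort("fewer samples than folds")
  folds <- with_seed(derive_seed(seed, 37L), {
    out <- integer(nrow(samples))
    for (ct in unique(samples$cancer_type)) {
      idx <- sample(which(samples$cancer_type == ct))
      out[idx] <- rep_len(sample.int(k), length(idx))
    }
    out
  })
  fold_of_pair <- folds[match(pairs$index$sample_id, samples$sample_id)]
  if (any(tabulate(fold_of_pair, nbins = k) == 0)) {
    abort("a cross-validation fold received zero pairs; reduce k")
  }

  mse <- matrix(NA_real_, nrow = k, ncol = length(alpha_grid),
                dimnames = list(paste0("fold", seq_len(k)),
                                format(alpha_grid, scientific = TRUE)))
  for (j in seq_len(k)) {
    tr <- pairs_subset(pairs, which(fold_of_pair != j))
    va <- pairs_subset(pairs, which(fold_of_pair == j))
    for (a in seq_along(alpha_grid)) {
      cfg <- config
      cfg$l2_alpha <- alpha_grid[a]
      cfg$seed <- derive_seed(seed, 100L + j)  # paired across alphas
      fit <- train_recommender(tr, cfg)
      pred <- predict(fit, va)
      mse[j, a] <- mean((pred - va$y)^2)
    }
  }

  means <- colMeans(mse)
  best <- which(means == min(means))
  best_alpha <- max(alpha_grid[best])  # tie -> stronger regularization
  structure(list(
    alpha_grid = alpha_grid,
    mse = mse,
    summary = tibble::tibble(alpha = alpha_grid, mean_mse = means,
                             sd_mse = apply(mse, 2, stats::sd)),
    best_alpha = best_alpha,
    k = k,
    folds = tibble::tibble(sample_id = samples$sample_id, fold = folds)
  ), class = "ttrec_cv")
}

#' @export
print.ttrec_cv <- function(x, ...) {
  cat(sprintf("<ttrec_cv> %d-fold, %d alphas; best alpha = %g (mean MSE %.4g)\n",
              x$k, length(x$alpha_grid), x$best_alpha,
              x$summary$mean_mse[x$summary$alpha == x$best_alpha]))
  print(x$summary)
  invisible(x)
}
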