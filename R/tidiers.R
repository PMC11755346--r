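# broom-style tidiers for the package's fitted objects.

#' Tidy a trained recommender
#'
#' One row per dense layer with its dimensions, parameter count and L2 norm.
#'
#' @param x A `ttrec_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ttrec_model <- function(x, ...) {
  purrr::map_dfr(c("sample", "drug", "post"), function(tower) {
    layers <- x$weights[[tower]]
    if (length(layers) == 0) return(NULL)
    purrr::imap_dfr(layers, function(l, i) {
      tibble::tibble(tower = tower, layer = i,
                     fan_in = nrow(l$W), fan_out = ncol(l$W),
                     n_param = length(l$W) + length(l$b),
                     l2_norm = sqrt(sum(l$W^2)))
    })
  })
}

#' @rdname tidy.ttrec_model
#' @export
glance.ttrec_model <- function(x, ...) {
  tibble::tibble(
    architecture = x$config$architecture,
    n_param = n_params(x),
    l2_alpha = x$config$l2_alpha,
    epochs = x$config$epochs,
    trained = x$trained,
    final_train_mse = if (x$trained) utils::tail(x$history$train_mse, 1) else NA_real_,
    final_val_mse = if (x$trained) utils::tail(x$history$val_mse, 1) else NA_real_
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `ttrec_cv` from [cv_tune_alpha()].
#' @param ... Unused.
#' @return Tibble with `alpha`, `mean_mse`, `sd_mse` per grid point.
#' @export
tidy.ttrec_cv <- function(x, ...) x$summary

#' @rdname tidy.ttrec_cv
#' @export
glance.ttrec_cv <- function(x, ...) {
  tibble::tibble(k = x$k, n_alpha = length(x$alpha_grid), best_alpha = x$best_alpha,
                 best_mean_mse = min(x$summary$mean_mse))
}

#' Tidy an evaluation report
#'
#' Stacks the overall, per-cancer, per-drug and per-cell correlations into
#' one long tibble with a `level` column.
#'
#' @param x A `ttrec_eval` from [grouped_eval()].
#' @param ... Unused.
#' @return A tibble with columns `level`, `cancer_type`, `drug_id`, `r`,
#'   `p`, `n`.
#' @export
tidy.ttrec_eval <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$overall, level = "overall"),
    dplyr::mutate(x$by_cancer, level = "cancer_type"),
    dplyr::mutate(x$by_drug, level = "drug"),
    dplyr::mutate(x$by_cell, level = "cell")
  ) |>
    dplyr::select(dplyr::any_of(c("level", "cancer_type", "drug_id", "r", "p",
                                  "n", "degenerate")))
}

#' @rdname tidy.ttrec_eval
#' @export
glance.ttrec_eval <- function(x, ...) {
  tibble::tibble(r = x$overall$r, p = x$overall$p, n = x$overall$n,
                 n_cancer_types = nrow(x$by_cancer), n_drugs = nrow(x$by_drug))
}

#' Tidy a Kaplan-Meier curve
#'
#' @param x A `km_curve`.
#' @param ... Unused.
#' @return The product-limit table as a tibble.
#' @export
tidy.km_curve <- function(x, ...) x$table

#' Tidy a clinical report
#'
#' The headline statistics as one row per quantity.
#'
#' @param x A `ttrec_clinical`.
#' @param ... Unused.
#' @return Tibble with `statistic`, `value`, `p_value`.
#' @export
tidy.ttrec_clinical <- function(x, ...) {
  rows <- list(
    tibble::tibble(statistic = "logrank_chi2", value = x$logrank$chi2,
                   p_value = x$logrank$p_value),
    tibble::tibble(statistic = "hr_low_vs_high", value = x$cox$hr,
                   p_value = x$cox$p_value)
  )
  for (i in seq_len(nrow(x$rates))) {
    r <- x$rates[i, ]
    rows <- c(rows, list(
      tibble::tibble(statistic = sprintf("rate_low_%g", r$t), value = r$rate_low,
                     p_value = r$p_value),
      tibble::tibble(statistic = sprintf("rate_high_%g", r$t), value = r$rate_high,
                     p_value = r$p_value)))
  }
  for (tr in x$troc) {
    if (!is.null(tr)) {
      rows <- c(rows, list(tibble::tibble(statistic = sprintf("auc_%g", tr$horizon),
                                          value = tr$auc, p_value = NA_real_)))
    }
  }
  if (!is.null(x$ranksum)) {
    rows <- c(rows, list(tibble::tibble(statistic = "ranksum_pd_vs_nonpd",
                                        value = x$ranksum$u,
                                        p_value = x$ranksum$p_value)))
  }
  dplyr::bind_rows(rows)
}
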