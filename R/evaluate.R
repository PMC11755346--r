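# Grouped Pearson-correlation evaluation and feature summaries.

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with the two-sided p-value from the t approximation
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom).
#' Pairs with missing values are dropped. When either vector has zero
#' variance the correlation is undefined: `r` and `p` come back `NA` with
#' `degenerate = TRUE` rather than a numeric lie.
#'
#' @param x,y Equal-length numeric vectors; `n >= 3` for a p-value.
#' @return One-row tibble: `r`, `p`, `n`, `degenerate`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  }
  r <- stats::cov(x, y) / (stats::sd(x) * stats::sd(y))
  r <- max(-1, min(1, r))
  p <- if (n >= 3) {
    if (abs(r) == 1) 0 else {
      tval <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tval), df = n - 2)
    }
  } else NA_real_
  tibble::tibble(r = r, p = p, n = n, degenerate = FALSE)
}

#' Grouped correlation report
#'
#' Pearson correlation between predicted scores and observed responses,
#' overall and within every cancer type, every drug, and every
#' (cancer type, drug) cell. Cells with fewer than `min_n` pairs are
#' reported as missing rather than as unstable numbers.
#'
#' @param scores Predicted score vector.
#' @param y Observed response vector (same length and order).
#' @param cancer_labels,drug_labels Per-pair group labels.
#' @param min_n Minimum group size for reporting a correlation (default 3).
#' @return A `ttrec_eval` object with tibbles `overall`, `by_cancer`,
#'   `by_drug`, `by_cell`.
#' @export
grouped_eval <- function(scores, y, cancer_labels, drug_labels, min_n = 3) {
  n <- length(scores)
  if (length(y) != n || length(cancer_labels) != n || length(drug_labels) != n) {
    abort("scores, y and the label vectors must be aligned (equal length)")
  }
  df <- tibble::tibble(score = as.numeric(scores), y = as.numeric(y),
                       cancer_type = as.character(cancer_labels),
                       drug_id = as.character(drug_labels))
  corr_of <- function(d) {
    if (nrow(d) < min_n) {
      return(tibble::tibble(r = NA_real_, p = NA_real_, n = nrow(d), degenerate = NA))
    }
    pearson_r(d$score, d$y)
  }
  by_group <- function(...) {
    df |>
      dplyr::group_by(...) |>
      dplyr::group_modify(~ corr_of(.x)) |>
      dplyr::ungroup()
  }
  structure(list(
    overall = corr_of(df),
    by_cancer = by_group(.data$cancer_type),
    by_drug = by_group(.data$drug_id),
    by_cell = by_group(.data$cancer_type, .data$drug_id),
    min_n = min_n
  ), class = "ttrec_eval")
}

#' Evaluate a score table
#'
#' Data-frame front end to [grouped_eval()] for the output of
#' [score_pairs()]: expects columns `score`, `y`, `cancer_type`, `drug_id`.
#'
#' @param data Tibble of scored pairs.
#' @param min_n Minimum group size for reporting a correlation.
#' @return A `ttrec_eval` object.
#' @export
evaluate_scores <- function(data, min_n = 3) {
  need <- c("score", "y", "cancer_type", "drug_id")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("evaluate_scores: missing column(s) %s", paste(missing, collapse = ", ")))
  }
  grouped_eval(data$score, data$y, data$cancer_type, data$drug_id, min_n = min_n)
}

#' @export
print.ttrec_eval <- function(x, ...) {
  cat(sprintf("<ttrec_eval> overall r = %.3f (p = %.3g, n = %d)\n",
              x$overall$r, x$overall$p, x$overall$n))
  cat(sprintf("  %d cancer types, %d drugs, %d cells (min n = %d)\n",
              nrow(x$by_cancer), nrow(x$by_drug), nrow(x$by_cell), x$min_n))
  invisible(x)
}

#' Per-gene mutation frequency and expression variability
#'
#' Mutation frequency is the column mean of the binary SNV matrix;
#' expression variability is the coefficient of variation (sample sd / mean)
#' of TPM across samples, reported missing where the mean is zero.
#'
#' @param snv_matrix Binary samples x genes mutation matrix
#'   (see [encode_snv()]).
#' @param expression_matrix TPM samples x genes matrix aligned on the same
#'   samples.
#' @return Tibble with `gene`, `mutation_frequency`, `expression_cv` (full
#'   join over the two gene panels).
#' @export
feature_summary <- function(snv_matrix, expression_matrix) {
  if (!identical(rownames(snv_matrix), rownames(expression_matrix))) {
    abort("snv and expression matrices must be aligned on the same samples")
  }
  mut <- tibble::tibble(gene = colnames(snv_matrix),
                        mutation_frequency = unname(colMeans(snv_matrix)))
  mu <- colMeans(expression_matrix)
  sdv <- apply(expression_matrix, 2, stats::sd)
  cv <- unname(ifelse(mu > 0, sdv / mu, NA_real_))
  expr <- tibble::tibble(gene = colnames(expression_matrix), expression_cv = cv)
  dplyr::full_join(mut, expr, by = "gene")
}
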