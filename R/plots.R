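# ggplot2 autoplot methods for the result objects.

#' Plot a training history
#'
#' Training (and validation, when recorded) MSE per epoch.
#'
#' @param object A trained `ttrec_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ttrec_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch", names_to = "series",
                           values_to = "mse")
  h <- dplyr::filter(h, !is.na(.data$mse))
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "MSE",
                  title = sprintf("%s model training", object$config$architecture)) +
    ggplot2::theme_minimal()
}

#' Plot cross-validation MSE against the regularization coefficient
#'
#' Mean +/- sd validation MSE per alpha on a log-scaled x axis; the
#' selected alpha is marked.
#'
#' @param object A `ttrec_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ttrec_cv <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$alpha, y = .data$mean_mse)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_mse - .data$sd_mse,
                                      ymax = .data$mean_mse + .data$sd_mse),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_alpha, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "L2 coefficient (alpha)", y = "mean validation MSE") +
    ggplot2::theme_minimal()
}

#' Plot per-group correlations of an evaluation report
#'
#' Per-drug and per-cancer-type Pearson r as ordered bar panels.
#'
#' @param object A `ttrec_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ttrec_eval <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::transmute(object$by_drug, label = .data$drug_id, r = .data$r,
                     panel = "by drug"),
    dplyr::transmute(object$by_cancer, label = .data$cancer_type, r = .data$r,
                     panel = "by cancer type")
  )
  d <- dplyr::filter(d, !is.na(.data$r))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$label, .data$r),
                                  y = .data$r)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier curve
#'
#' Step curve of the product-limit estimate with a Greenwood pointwise
#' normal band.
#'
#' @param object A `km_curve`.
#' @param conf Band coverage (default 0.95); `NULL` suppresses the band.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, conf = 0.95, ...) {
  tab <- dplyr::bind_rows(
    tibble::tibble(time = 0, surv = 1, se = 0),
    dplyr::select(object$table, "time", "surv", "se")
  )
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$surv)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "S(t)") +
    ggplot2::theme_minimal()
  if (!is.null(conf)) {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    tab$lo <- pmax(0, tab$surv - z * tab$se)
    tab$hi <- pmin(1, tab$surv + z * tab$se)
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$lo), data = tab,
                                linetype = 3, na.rm = TRUE) +
      ggplot2::geom_step(ggplot2::aes(y = .data$hi), data = tab, linetype = 3,
                         na.rm = TRUE)
  }
  p
}

#' Plot the stratified survival curves of a clinical report
#'
#' @param object A `ttrec_clinical`.
#' @param ... Unused.
#' @return A ggplot with one step curve per score group.
#' @export
autoplot.ttrec_clinical <- function(object, ...) {
  tab <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                                   object$km$low$table),
                  group = "low score"),
    dplyr::mutate(dplyr::bind_rows(tibble::tibble(time = 0, surv = 1),
                                   object$km$high$table),
                  group = "high score")
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time, y = .data$surv,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "progression-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a time-dependent ROC curve
#'
#' @param object A `ttrec_troc`.
#' @param ... Unused.
#' @return A ggplot of sensitivity against 1 - specificity.
#' @export
autoplot.ttrec_troc <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble::tibble(fpr = c(0, 1), sens = c(0, 1), what = "reference"),
    tibble::tibble(fpr = 1 - object$curve$spec, sens = object$curve$sens,
                   what = "ROC")
  )
  ggplot2::ggplot(dplyr::filter(d, .data$what == "ROC"),
                  ggplot2::aes(x = .data$fpr, y = .data$sens)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC %.3f at t = %g", object$auc, object$horizon)) +
    ggplot2::theme_minimal()
}
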