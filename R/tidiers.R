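#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training history
#'
#' @param x a `pathomix_fit`
#' @param ... unused
#' @return tibble with one row per epoch: `epoch`, `loss`, `val_macro_f1`
#' @export
tidy.pathomix_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x a `pathomix_fit`
#' @param ... unused
#' @export
glance.pathomix_fit <- function(x, ...) {
  tibble::tibble(
    model_mode = x$model$cfg$model_mode,
    n_classes = x$model$n_classes,
    n_pathways = ncol(x$model$mask),
    n_genes = nrow(x$model$mask),
    epochs_trained = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_macro_f1 = if (all(is.na(x$history$val_macro_f1))) NA_real_
      else max(x$history$val_macro_f1, na.rm = TRUE))
}

#' Tidy per-fold cross-validation metrics
#'
#' @param x a `pathomix_cv`
#' @param ... unused
#' @return tibble with one row per (repeat, fold)
#' @export
tidy.pathomix_cv <- function(x, ...) x$per_fold

#' One-row cross-validation summary (means and SDs over folds)
#'
#' @param x a `pathomix_cv`
#' @param ... unused
#' @export
glance.pathomix_cv <- function(x, ...) {
  pf <- x$per_fold
  tibble::tibble(
    n_folds = nrow(pf),
    mean_macro_f1 = mean(pf$macro_f1), sd_macro_f1 = stats::sd(pf$macro_f1),
    mean_weighted_f1 = mean(pf$weighted_f1),
    sd_weighted_f1 = stats::sd(pf$weighted_f1),
    mean_auc = mean(pf$auc), sd_auc = stats::sd(pf$auc),
    mean_sens99 = mean(pf$sensitivity_at_spec99),
    sd_sens99 = stats::sd(pf$sensitivity_at_spec99))
}

#' Plot training curves
#'
#' @param object a `pathomix_fit`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pathomix_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `pathomix_cv`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.pathomix_cv <- function(object, ...) {
  pf <- tidyr::pivot_longer(object$per_fold,
                            -c("repeat_id", "fold"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(pf, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "fold value") +
    ggplot2::theme_minimal()
}

#' Bar plot of an importance table
#'
#' @param importance tibble from [shap_importance()]
#' @param top_n number of entities to show
#' @return a ggplot
#' @export
plot_importance <- function(importance, top_n = 15) {
  df <- utils::head(dplyr::arrange(importance, .data$rank), top_n)
  df$entity <- stats::reorder(df$entity, df$shap)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shap, y = .data$entity,
                                   fill = .data$direction > 0)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "#2166ac"),
                               name = "direction > 0") +
    ggplot2::labs(x = "mean |SHAP|", y = NULL) +
    ggplot2::theme_minimal()
}

#' Pie-style bar of modality contributions
#'
#' @param contrib tibble from [modality_contributions()]
#' @return a ggplot
#' @export
plot_modality_contributions <- function(contrib) {
  ggplot2::ggplot(contrib, ggplot2::aes(x = .data$modality,
                                        y = .data$weight)) +
    ggplot2::geom_col(fill = "#4393c3") +
    ggplot2::labs(x = NULL, y = "attention weight") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
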