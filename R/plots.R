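#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_density
#'   geom_boxplot geom_jitter labs theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Training-history curves
#'
#' Train and validation binary cross-entropy per epoch, with the best
#' (restored) epoch marked.
#'
#' @param object A `starnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.starnn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot(h, aes(x = .data$epoch, y = .data$loss, colour = .data$set)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dashed", colour = "grey40") +
    labs(x = "epoch", y = "binary cross-entropy",
         colour = NULL,
         title = sprintf("Training history (best epoch %d)",
                         object$best_epoch)) +
    theme_minimal()
}

#' Per-model metric distributions over repeats
#'
#' @param object A `starnn_metrics` object from [run_experiment()].
#' @param metric Which metric column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.starnn_metrics <- function(object, metric = "auc", ...) {
  d <- as_tibble(unclass(object))
  ggplot(d, aes(x = .data$model, y = .data[[metric]])) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.1, alpha = 0.6) +
    labs(x = NULL, y = metric) +
    theme_minimal()
}

#' Score distributions of cases versus controls
#'
#' Density plot of model output scores by phenotype, the usual view of
#' how well a risk score separates the two groups.
#'
#' @param scores Named numeric scores.
#' @param labels Binary labels aligned with `scores`.
#' @return A ggplot object.
#' @export
plot_score_separation <- function(scores, labels) {
  d <- tibble(score = as.numeric(scores),
              group = ifelse(as.integer(labels) == 1, "case", "control"))
  ggplot(d, aes(x = .data$score, fill = .data$group)) +
    geom_density(alpha = 0.4) +
    labs(x = "model score", y = "density", fill = NULL) +
    theme_minimal()
}
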