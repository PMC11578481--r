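#' Tidy a trained network into per-gene weights
#'
#' One row per gene with the sparse-layer weight of each class block, the
#' gene-node bias, the elementwise gene-layer parameters and (for the
#' no-hidden architecture) the output weight — the quantities used to
#' inspect which genes and variant classes drive the prediction.
#'
#' @param x A `starnn_fit`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, one `w_<block>` per class block,
#'   `bias`, `u`, `c`, and `v` when present.
#' @export
tidy.starnn_fit <- function(x, ...) {
  spec <- x$spec
  if (spec$mode == "unseparated") {
    return(tibble(gene = spec$genes, w = as.numeric(x$params$wg)))
  }
  out <- tibble(gene = spec$genes)
  for (t in seq_along(spec$blocks)) {
    out[[paste0("w_", spec$blocks[t])]] <- x$params$w[t, ]
  }
  out$bias <- x$params$b
  out$u <- x$params$u
  out$c <- x$params$cc
  if (spec$hidden == "none") out$v <- x$params$v
  out
}

#' One-row summary of a trained network
#'
#' @param x A `starnn_fit`.
#' @param ... Unused.
#' @return Tibble with `mode`, `n_genes`, `n_parameters`, `best_epoch`,
#'   `epochs_run`, `best_val_loss`, `final_train_loss`.
#' @export
glance.starnn_fit <- function(x, ...) {
  tibble(mode = x$spec$mode, n_genes = x$spec$n_genes,
         n_parameters = sum(vapply(x$params, length, integer(1))),
         best_epoch = x$best_epoch, epochs_run = nrow(x$history),
         best_val_loss = x$best_val_loss,
         final_train_loss = x$history$train_loss[nrow(x$history)])
}

#' @export
tidy.starnn_enrichment <- function(x, ...) as_tibble(unclass(x))
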