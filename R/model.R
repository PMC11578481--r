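#' Network architecture specification
#'
#' Describes the variant-class-separated sparse network: a masked sparse
#' layer connecting each class-specific variant node to its gene (tanh),
#' an elementwise per-gene layer (relu), and a fully connected sigmoid
#' output. Polygenic score and sex, when present, enter at the output (or
#' hidden) layer, bypassing the gene-resolved layers. An optional hidden
#' layer (relu or linear) can be inserted between the gene layer and the
#' output.
#'
#' @param genes Character vector of gene features.
#' @param mode Class-block layout: `"3to1"` (PTV, MisAB, MisC), `"2to1"`,
#'   `"4to1"`, or `"unseparated"` (the basic-DNN input: one gene block,
#'   dense sigmoid output, no sparse or elementwise layer).
#' @param include_pgs,include_sex Whether the covariate nodes are present.
#' @param hidden `"none"`, `"relu"`, or `"linear"`.
#' @param hidden_width Width of the optional hidden layer.
#' @return Object of class `starnn_spec`.
#' @export
network_spec <- function(genes, mode = c("3to1", "2to1", "4to1",
                                         "unseparated"),
                         include_pgs = TRUE, include_sex = TRUE,
                         hidden = c("none", "relu", "linear"),
                         hidden_width = 64L) {
  mode <- match.arg(mode)
  hidden <- match.arg(hidden)
  blocks <- switch(mode,
                   "3to1" = c("PTV", "MisAB", "MisC"),
                   "2to1" = c("PTV", "MisAB"),
                   "4to1" = c("PTV", "MisAB", "MisC", "SYN"),
                   "unseparated" = "ALL")
  structure(list(genes = genes, mode = mode, blocks = blocks,
                 n_genes = length(genes),
                 include_pgs = include_pgs, include_sex = include_sex,
                 hidden = hidden, hidden_width = as.integer(hidden_width)),
            class = "starnn_spec")
}

#' Sparse-layer connectivity mask
#'
#' The boolean connectivity matrix between variant nodes and gene nodes:
#' shape (number of class blocks x G, G), block-major rows, with exactly
#' one true entry per row (each variant node feeds only its gene) and one
#' true entry per gene column within each class block.
#'
#' @param spec A [network_spec()].
#' @return Sparse logical matrix (variant nodes x genes).
#' @examples
#' m <- build_mask(network_spec(c("G1", "G2"), mode = "3to1"))
#' dim(m)          # 6 x 2
#' Matrix::rowSums(m)  # all 1
#' @export
build_mask <- function(spec) {
  assert_that(inherits(spec, "starnn_spec"), "`spec` must be a network_spec")
  g <- spec$n_genes
  k <- length(spec$blocks)
  Matrix::sparseMatrix(
    i = seq_len(k * g), j = rep(seq_len(g), times = k), x = TRUE,
    dims = c(k * g, g),
    dimnames = list(paste(rep(spec$blocks, each = g),
                          rep(spec$genes, times = k), sep = ":"),
                    spec$genes))
}

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam on binary
#' cross-entropy, initial learning rate `3e-5` with time-based decay
#' `lr(epoch) = lr0 / (1 + (1e-5 / 30) * epoch)`, early stopping when the
#' validation loss has not improved for `patience` epochs, and restoration
#' of the best-validation-loss weights. Batch size, maximum epochs and the
#' initialization scheme (Glorot uniform) are unstated upstream and are
#' package defaults.
#'
#' @param lr0 Initial learning rate.
#' @param decay Decay constant in the schedule above.
#' @param patience Early-stopping patience in epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param seed Seed for initialization and shuffling.
#' @param beta1,beta2,eps Adam moment parameters.
#' @return Object of class `starnn_control`.
#' @export
train_control <- function(lr0 = 3e-5, decay = 1e-5 / 30, patience = 50L,
                          batch_size = 64L, max_epochs = 300L, seed = 42L,
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  assert_that(patience >= 1, "`patience` must be >= 1")
  structure(list(lr0 = lr0, decay = decay, patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "starnn_control")
}

## ---- internals ------------------------------------------------------------

glorot <- function(n, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

# split a block-major input matrix into a list of per-class n x G matrices
split_blocks <- function(x, k, g) {
  lapply(seq_len(k), function(t) x[, ((t - 1) * g + 1):(t * g),
                                   drop = FALSE])
}

n_cov <- function(spec) sum(spec$include_pgs, spec$include_sex)

init_params <- function(spec, seed) {
  set.seed(seed)
  g <- spec$n_genes
  k <- length(spec$blocks)
  nc <- n_cov(spec)
  if (spec$mode == "unseparated") {
    return(list(wg = glorot(g, g + nc, 1), v_cov = glorot(nc, g + nc, 1),
                d = 0))
  }
  p <- list(
    w = matrix(glorot(k * g, k, 1), nrow = k),   # sparse layer, per gene
    b = rep(0, g),
    u = glorot(g, 1, 1),                          # elementwise gene layer
    cc = rep(0.01, g)                             # small positive: live relu
  )
  if (spec$hidden == "none") {
    p$v <- glorot(g, g + nc, 1)
    p$v_cov <- glorot(nc, g + nc, 1)
    p$d <- 0
  } else {
    h <- spec$hidden_width
    p$wh <- matrix(glorot((g + nc) * h, g + nc, h), nrow = g + nc)
    p$bh <- rep(0, h)
    p$vh <- glorot(h, h, 1)
    p$d <- 0
  }
  p
}

relu <- function(x) pmax(x, 0)

# forward pass; keep = TRUE retains intermediates for backprop
nn_forward <- function(params, x, covar, spec, keep = FALSE) {
  nc <- n_cov(spec)
  if (spec$mode == "unseparated") {
    eta <- drop(x %*% params$wg) + params$d
    if (nc > 0) eta <- eta + drop(covar %*% params$v_cov)
    out <- list(eta = eta, yhat = plogis(eta))
    return(out)
  }
  g <- spec$n_genes
  k <- length(spec$blocks)
  xk <- split_blocks(x, k, g)
  s <- matrix(rep(params$b, each = nrow(x)), nrow = nrow(x))
  for (t in seq_len(k)) {
    s <- s + sweep(xk[[t]], 2, params$w[t, ], `*`)
  }
  hh <- tanh(s)
  zpre <- sweep(hh, 2, params$u, `*`)
  zpre <- sweep(zpre, 2, params$cc, `+`)
  z <- relu(zpre)
  if (spec$hidden == "none") {
    eta <- drop(z %*% params$v) + params$d
    if (nc > 0) eta <- eta + drop(covar %*% params$v_cov)
    ah <- NULL; apre <- NULL
  } else {
    a_in <- if (nc > 0) cbind(z, covar) else z
    apre <- sweep(a_in %*% params$wh, 2, params$bh, `+`)
    ah <- if (spec$hidden == "relu") relu(apre) else apre
    eta <- drop(ah %*% params$vh) + params$d
  }
  out <- list(eta = eta, yhat = plogis(eta))
  if (keep) {
    out$h <- hh; out$z <- z; out$zpre <- zpre; out$xk <- xk
    out$ah <- ah; out$apre <- apre
  }
  out
}

bce_loss <- function(yhat, y) {
  eps <- 1e-12
  yhat <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

# loss and gradients for one batch
nn_grad <- function(params, x, covar, y, spec) {
  nc <- n_cov(spec)
  fw <- nn_forward(params, x, covar, spec, keep = TRUE)
  n <- length(y)
  deta <- (fw$yhat - y) / n
  gr <- list()
  if (spec$mode == "unseparated") {
    gr$wg <- drop(crossprod(x, deta))
    if (nc > 0) gr$v_cov <- drop(crossprod(covar, deta))
    gr$d <- sum(deta)
    return(list(grads = gr, loss = bce_loss(fw$yhat, y)))
  }
  g <- spec$n_genes
  k <- length(spec$blocks)
  if (spec$hidden == "none") {
    gr$v <- drop(crossprod(fw$z, deta))
    if (nc > 0) gr$v_cov <- drop(crossprod(covar, deta))
    gr$d <- sum(deta)
    dz <- outer(deta, params$v)
  } else {
    gr$vh <- drop(crossprod(fw$ah, deta))
    gr$d <- sum(deta)
    dah <- outer(deta, params$vh)
    dapre <- if (spec$hidden == "relu") dah * (fw$apre > 0) else dah
    a_in <- if (nc > 0) cbind(fw$z, covar) else fw$z
    gr$wh <- crossprod(a_in, dapre)
    gr$bh <- colSums(dapre)
    da_in <- dapre %*% t(params$wh)
    dz <- da_in[, seq_len(g), drop = FALSE]
  }
  dzpre <- dz * (fw$zpre > 0)
  gr$u <- colSums(dzpre * fw$h)
  gr$cc <- colSums(dzpre)
  dh <- sweep(dzpre, 2, params$u, `*`)
  ds <- dh * (1 - fw$h^2)
  gr$w <- do.call(rbind, lapply(seq_len(k), function(t) {
    colSums(ds * fw$xk[[t]])
  }))
  gr$b <- colSums(ds)
  list(grads = gr, loss = bce_loss(fw$yhat, y))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, ctrl) {
  state$t <- state$t + 1L
  bc1 <- 1 - ctrl$beta1^state$t
  bc2 <- 1 - ctrl$beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- ctrl$beta1 * state$m[[nm]] +
      (1 - ctrl$beta1) * grads[[nm]]
    state$v[[nm]] <- ctrl$beta2 * state$v[[nm]] +
      (1 - ctrl$beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + ctrl$eps)
  }
  list(params = params, state = state)
}

## ---- training -------------------------------------------------------------

#' Train a variant-class-separated network
#'
#' Mini-batch Adam on binary cross-entropy with the time-based learning
#' rate decay, early stopping on validation loss, and restoration of the
#' best-validation weights. The sparse layer is parameterized directly on
#' the mask support (one weight per variant-node-to-gene edge), so
#' masked-out connections are structurally zero at every step.
#'
#' @param input Training [assemble_input()] object.
#' @param labels Named binary vector covering the training samples.
#' @param val_input,val_labels Validation split (disjoint from training).
#' @param spec A [network_spec()] matching `input$mode`; built
#'   automatically from the input when `NULL`.
#' @param control A [train_control()].
#' @return Object of class `starnn_fit`: list with `spec`, `params`,
#'   `best_epoch`, `history` (tibble epoch/lr/train_loss/val_loss),
#'   `control`.
#' @export
train_starnn <- function(input, labels, val_input, val_labels,
                         spec = NULL, control = train_control()) {
  assert_that(inherits(input, "starnn_input"), "`input` is not assembled")
  assert_that(length(intersect(input$samples, val_input$samples)) == 0,
              "train and validation samples overlap")
  if (is.null(spec)) {
    spec <- network_spec(
      input$genes, mode = input$mode,
      include_pgs = "pgs" %in% colnames(input$covariates),
      include_sex = "sex" %in% colnames(input$covariates))
  }
  assert_that(spec$mode == input$mode && all(spec$genes == input$genes),
              "spec does not match assembled input")
  y <- as.numeric(labels[input$samples])
  y_val <- as.numeric(val_labels[val_input$samples])
  assert_that(!anyNA(y) && !anyNA(y_val), "labels missing for some samples")

  params <- init_params(spec, control$seed)
  state <- adam_init(params)
  n <- nrow(input$x)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- vector("list", control$max_epochs)
  stall <- 0L

  for (epoch in seq_len(control$max_epochs)) {
    lr <- control$lr0 / (1 + control$decay * epoch)
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / control$batch_size))
    tr_loss <- 0
    for (bi in batches) {
      cv <- if (is.null(input$covariates)) NULL else
        input$covariates[bi, , drop = FALSE]
      gb <- nn_grad(params, input$x[bi, , drop = FALSE], cv, y[bi], spec)
      if (!is.finite(gb$loss)) {
        abort(sprintf("non-finite training loss at epoch %d", epoch))
      }
      stepped <- adam_step(params, gb$grads, state, lr, control)
      params <- stepped$params
      state <- stepped$state
      tr_loss <- tr_loss + gb$loss * length(bi)
    }
    tr_loss <- tr_loss / n
    val_fw <- nn_forward(params, val_input$x, val_input$covariates, spec)
    val_loss <- bce_loss(val_fw$yhat, y_val)
    hist[[epoch]] <- tibble(epoch = epoch, lr = lr,
                            train_loss = tr_loss, val_loss = val_loss)
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= control$patience) break
    }
  }

  structure(list(spec = spec, params = best$params,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 history = bind_rows(hist), control = control),
            class = "starnn_fit")
}

#' @exportS3Method base::print
print.starnn_fit <- function(x, ...) {
  cat(sprintf(
    "<starnn_fit> mode %s, %d genes%s, hidden %s; best epoch %d (val loss %.4f)\n",
    x$spec$mode, x$spec$n_genes,
    if (n_cov(x$spec) > 0) " + covariates" else "",
    x$spec$hidden, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' Predict from a trained network
#'
#' @param object A `starnn_fit`.
#' @param input An [assemble_input()] object with the same spec layout.
#' @param type `"prob"` for the sigmoid score in (0, 1), `"label"` for the
#'   thresholded class.
#' @param threshold Decision threshold; a score strictly above it is
#'   labelled 1 (a tie at the threshold is 0).
#' @param ... Unused.
#' @return Named numeric (probabilities) or named integer (labels).
#' @export
predict.starnn_fit <- function(object, input, type = c("prob", "label"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  assert_that(ncol(input$x) ==
                length(object$spec$blocks) * object$spec$n_genes,
              "input dimensions do not match the model spec")
  fw <- nn_forward(object$params, input$x, input$covariates, object$spec)
  p <- setNames(fw$yhat, input$samples)
  if (type == "prob") p else predict_labels(p, threshold)
}

#' Threshold scores into class labels
#'
#' Label 1 if and only if the score is strictly above the threshold;
#' a score exactly at the threshold is labelled 0.
#'
#' @param scores Numeric scores in (0, 1).
#' @param threshold Decision threshold (default 0.5).
#' @return Integer labels, preserving names.
#' @export
predict_labels <- function(scores, threshold = 0.5) {
  out <- as.integer(scores > threshold)
  names(out) <- names(scores)
  out
}

#' Full sparse-layer weight matrix
#'
#' Materializes the variant-node x gene weight matrix of the sparse layer.
#' Off-mask entries are structurally zero: the layer stores one weight per
#' permitted edge only.
#'
#' @param fit A trained `starnn_fit`.
#' @return Sparse numeric matrix (variant nodes x genes).
#' @export
sparse_layer_weights <- function(fit) {
  spec <- fit$spec
  assert_that(spec$mode != "unseparated",
              "the unseparated model has no sparse layer")
  g <- spec$n_genes
  k <- length(spec$blocks)
  Matrix::sparseMatrix(
    i = seq_len(k * g), j = rep(seq_len(g), times = k),
    x = as.vector(t(fit$params$w)),
    dims = c(k * g, g),
    dimnames = dimnames(build_mask(spec)))
}
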