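test_that("connectivity mask is block-structured one-to-one", {
  m1 <- build_mask(network_spec("G1", mode = "3to1"))
  expect_equal(dim(m1), c(3L, 1L))
  expect_true(all(as.matrix(m1)))
  spec <- network_spec(sprintf("G%02d", 1:7), mode = "3to1")
  m <- build_mask(spec)
  expect_equal(dim(m), c(21L, 7L))
  expect_equal(unname(Matrix::rowSums(m)), rep(1, 21))
  expect_equal(unname(Matrix::colSums(m)), rep(3, 7))
  m2 <- build_mask(network_spec(sprintf("G%02d", 1:7), mode = "2to1"))
  expect_equal(unname(Matrix::colSums(m2)), rep(2, 7))
})

zero_fit <- function(genes, covar = TRUE) {
  spec <- network_spec(genes, include_pgs = covar, include_sex = covar)
  params <- starnn:::init_params(spec, 1)
  params <- lapply(params, function(p) p * 0)
  structure(list(spec = spec, params = params, best_epoch = 0L,
                 history = tibble::tibble(), control = train_control()),
            class = "starnn_fit")
}

toy_input <- function(x, covar = NULL, genes, blocks) {
  structure(list(x = x, covariates = covar, genes = genes,
                 blocks = blocks, mode = "3to1",
                 samples = rownames(x)),
            class = "starnn_input")
}

test_that("all-zero weights score exactly one half", {
  x <- matrix(rpois(12, 1), nrow = 2,
              dimnames = list(c("s1", "s2"), NULL))
  inp <- toy_input(x, covar = cbind(pgs = c(1.5, -0.3), sex = c(1, 0)),
                   genes = c("gA", "gB"), blocks = c("PTV", "MisAB", "MisC"))
  p <- predict(zero_fit(c("gA", "gB")), inp)
  expect_equal(unname(p), c(0.5, 0.5))
})

test_that("forward pass reproduces hand-computed composition", {
  fit <- zero_fit(c("gA", "gB"))
  fit$params$w <- matrix(c(0.5, -0.3, 0.2, 0.1, 0.4, -0.2), nrow = 3,
                         byrow = TRUE)  # rows: PTV, MisAB, MisC
  fit$params$b <- c(0.05, -0.1)
  fit$params$u <- c(1.2, -0.8)
  fit$params$cc <- c(0.1, 0.3)
  fit$params$v <- c(0.7, -0.5)
  fit$params$v_cov <- c(0.25, -0.4)
  fit$params$d <- 0.15
  xvec <- c(2, 1, 1, 0, 0, 3)   # PTV:gA, PTV:gB, MisAB:gA, ..., MisC:gB
  covar <- c(pgs = 0.8, sex = 1)
  x <- matrix(xvec, nrow = 1, dimnames = list("s1", NULL))
  inp <- toy_input(x, covar = matrix(covar, nrow = 1,
                                     dimnames = list("s1",
                                                     c("pgs", "sex"))),
                   genes = c("gA", "gB"), blocks = c("PTV", "MisAB", "MisC"))
  # hand arithmetic, scalar by scalar
  h <- tanh(c(0.5 * 2 + 0.2 * 1 + 0.4 * 0 + 0.05,
              -0.3 * 1 + 0.1 * 0 + -0.2 * 3 + -0.1))
  z <- pmax(c(1.2, -0.8) * h + c(0.1, 0.3), 0)
  eta <- 0.7 * z[1] - 0.5 * z[2] + 0.25 * 0.8 - 0.4 * 1 + 0.15
  expect_equal(unname(predict(fit, inp)), plogis(eta), tolerance = 1e-12)
})

test_that("masked locality: a variant input touches only its gene", {
  fit <- zero_fit(c("gA", "gB"), covar = FALSE)
  set.seed(61)
  fit$params$w <- matrix(rnorm(6), nrow = 3)
  fit$params$u <- c(1, 1); fit$params$cc <- c(0.2, 0.2)
  fit$params$v <- c(1, 0)   # output reads gene A only
  x0 <- matrix(c(1, 1, 0, 1, 2, 0), nrow = 1, dimnames = list("s1", NULL))
  x1 <- x0
  x1[1, c(2, 4, 6)] <- x1[1, c(2, 4, 6)] + 5   # perturb gene B's variants
  blocks <- c("PTV", "MisAB", "MisC")
  p0 <- predict(fit, toy_input(x0, genes = c("gA", "gB"), blocks = blocks))
  p1 <- predict(fit, toy_input(x1, genes = c("gA", "gB"), blocks = blocks))
  expect_identical(unname(p0), unname(p1))
})

test_that("training separates a separable toy and is deterministic", {
  toy <- separable_toy()
  idx <- seq_along(toy$labels)
  tr <- input_subset(toy$input, toy$input$samples[idx %% 5 != 0])
  va <- input_subset(toy$input, toy$input$samples[idx %% 5 == 0])
  ctl <- train_control(lr0 = 0.01, max_epochs = 60, batch_size = 160,
                       seed = 9)
  fit <- train_starnn(tr, toy$labels, va, toy$labels, control = ctl)
  # loss decreases over the first 10 epochs
  expect_true(all(diff(fit$history$train_loss[1:10]) < 1e-6))
  pred <- predict(fit, tr, type = "label")
  expect_gt(mean(pred == toy$labels[tr$samples]), 0.95)
  # bit-identical refit under the same seed
  fit2 <- train_starnn(tr, toy$labels, va, toy$labels, control = ctl)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
})

test_that("early stopping restores the best-validation weights", {
  toy <- separable_toy()
  idx <- seq_along(toy$labels)
  tr <- input_subset(toy$input, toy$input$samples[idx %% 5 != 0])
  va <- input_subset(toy$input, toy$input$samples[idx %% 5 == 0])
  # anti-correlated validation labels: val loss worsens as training improves
  flipped <- 1 - toy$labels
  ctl <- train_control(lr0 = 0.01, max_epochs = 200, patience = 20,
                       batch_size = 160, seed = 9)
  fit <- train_starnn(tr, toy$labels, va, flipped, control = ctl)
  expect_lt(nrow(fit$history), 200)
  expect_equal(nrow(fit$history), fit$best_epoch + ctl$patience)
  expect_equal(fit$best_val_loss,
               min(fit$history$val_loss))
  expect_equal(fit$history$val_loss[fit$best_epoch], fit$best_val_loss)
})

test_that("learning rate follows the decay schedule", {
  toy <- separable_toy(n = 40)
  tr <- input_subset(toy$input, toy$input$samples[1:30])
  va <- input_subset(toy$input, toy$input$samples[31:40])
  fit <- train_starnn(tr, toy$labels, va, toy$labels,
                      control = train_control(max_epochs = 5))
  expect_equal(fit$history$lr,
               3e-5 / (1 + (1e-5 / 30) * (1:5)))
  expect_true(all(diff(fit$history$lr) < 0))
})

test_that("label thresholding is strict and monotone", {
  expect_equal(unname(predict_labels(c(0.51, 0.49, 0.5))), c(1L, 0L, 0L))
  s <- runif(50)
  expect_true(all(predict_labels(pmin(s + 0.1, 1)) >= predict_labels(s)))
})

test_that("gradients agree with finite differences (hidden layer too)", {
  set.seed(63)
  genes <- c("g1", "g2", "g3")
  for (hidden in c("none", "relu", "linear")) {
    spec <- network_spec(genes, hidden = hidden, hidden_width = 4)
    params <- starnn:::init_params(spec, 2)
    # keep pre-activations clear of the relu kink so central differences
    # probe a locally smooth loss
    params$cc <- rep(0.3, 3)
    if (!is.null(params$bh)) params$bh <- rep(0.2, 4)
    x <- matrix(rpois(5 * 9, 1), nrow = 5)
    covar <- cbind(pgs = rnorm(5), sex = rbinom(5, 1, 0.5))
    y <- c(1, 0, 1, 1, 0)
    fw <- starnn:::nn_forward(params, x, covar, spec, keep = TRUE)
    expect_gt(min(abs(fw$zpre)), 1e-3)
    if (!is.null(fw$apre)) expect_gt(min(abs(fw$apre)), 1e-3)
    gr <- starnn:::nn_grad(params, x, covar, y, spec)$grads
    lossfn <- function(p) {
      fw <- starnn:::nn_forward(p, x, covar, spec)
      starnn:::bce_loss(fw$yhat, y)
    }
    eps <- 1e-6
    for (nm in names(params)) {
      num <- params[[nm]]
      for (i in seq_along(num)) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        num[i] <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      }
      denom <- pmax(abs(num), abs(gr[[nm]]), 1e-8)
      expect_lt(max(abs(num - gr[[nm]]) / denom), 1e-5)
    }
  }
})

test_that("baseline architectures expose the expected shapes", {
  toy <- separable_toy()
  # collapse blocks into the unseparated view
  g <- 2
  xu <- toy$input$x[, 1:g] + toy$input$x[, g + 1:g] + toy$input$x[, 2 * g + 1:g]
  colnames(xu) <- paste0("ALL:", toy$input$genes)
  covar <- cbind(pgs = rnorm(nrow(xu)), sex = rbinom(nrow(xu), 1, 0.5))
  rownames(covar) <- rownames(xu)
  un <- structure(list(x = xu, covariates = covar, genes = toy$input$genes,
                       blocks = "ALL", mode = "unseparated",
                       samples = rownames(xu)), class = "starnn_input")
  idx <- seq_len(nrow(xu))
  tr <- input_subset(un, un$samples[idx %% 5 != 0])
  va <- input_subset(un, un$samples[idx %% 5 == 0])
  dnn <- fit_baseline("basic_dnn", tr, toy$labels, va, toy$labels,
                      control = train_control(lr0 = 0.05, max_epochs = 80,
                                              batch_size = 160))
  # parameter count: one weight per gene + per covariate + bias
  expect_equal(sum(vapply(dnn$fit$params, length, integer(1))),
               length(un$genes) + 2L + 1L)
  expect_gt(mean(predict_labels(predict(dnn, tr)) ==
                   toy$labels[tr$samples]), 0.9)
  lg <- fit_baseline("logistic_l2", tr, toy$labels)
  expect_gt(mean(predict_labels(predict(lg, tr)) ==
                   toy$labels[tr$samples]), 0.9)
  for (kind in c("linear_svc", "decision_tree", "random_forest",
                 "gradient_boosted_trees")) {
    fitb <- fit_baseline(kind, tr, toy$labels)
    p <- predict(fitb, va)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(length(p), length(va$samples))
  }
})
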