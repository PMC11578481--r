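#' Fit a baseline classifier on unseparated gene counts
#'
#' Baselines consume the unseparated input (per-gene cross-class carrier
#' counts) plus the polygenic score and sex, the same information as the
#' sparse network up to the class split.
#'
#' * `basic_dnn` — a single dense sigmoid layer on the gene counts and
#'   covariates (G + 2 weights + 1 bias), trained with the same
#'   Adam/binary-cross-entropy loop as the sparse network.
#' * `logistic_l1`, `logistic_l2` — penalized logistic regression
#'   (glmnet) at inverse regularization strength C = 0.001, mapped to
#'   `lambda = 1 / (C * n)`.
#' * `linear_svc` — linear support-vector classifier (e1071), cost 0.001.
#' * `decision_tree`, `random_forest`, `gradient_boosted_trees` — rpart,
#'   randomForest and xgboost at library defaults.
#'
#' @param kind Baseline family.
#' @param input An [assemble_input()] object with `mode = "unseparated"`
#'   (for `basic_dnn`, a validation split is also required).
#' @param labels Named binary vector.
#' @param val_input,val_labels Validation split, used by `basic_dnn` for
#'   early stopping.
#' @param control [train_control()] for `basic_dnn`.
#' @param C Inverse regularization strength for the penalized models.
#' @return Object of class `starnn_baseline` with a [predict()] method
#'   returning scores in \[0, 1\].
#' @export
fit_baseline <- function(kind = c("basic_dnn", "logistic_l1", "logistic_l2",
                                  "linear_svc", "decision_tree",
                                  "random_forest",
                                  "gradient_boosted_trees"),
                         input, labels, val_input = NULL, val_labels = NULL,
                         control = train_control(), C = 0.001) {
  kind <- match.arg(kind)
  assert_that(input$mode == "unseparated",
              "baselines take the unseparated input")
  x <- cbind(input$x, input$covariates)
  y <- as.numeric(labels[input$samples])
  assert_that(!anyNA(y), "labels missing for some samples")

  fit <- switch(kind,
    basic_dnn = {
      assert_that(!is.null(val_input), "basic_dnn needs a validation split")
      train_starnn(input, labels, val_input, val_labels,
                   spec = network_spec(
                     input$genes, mode = "unseparated",
                     include_pgs = "pgs" %in% colnames(input$covariates),
                     include_sex = "sex" %in% colnames(input$covariates)),
                   control = control)
    },
    logistic_l1 = glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                                 lambda = 1 / (C * length(y))),
    logistic_l2 = glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                                 lambda = 1 / (C * length(y))),
    linear_svc = {
      assert_that(requireNamespace("e1071", quietly = TRUE),
                  "e1071 is required for linear_svc")
      e1071::svm(x, factor(y), kernel = "linear", cost = C, scale = FALSE)
    },
    decision_tree = {
      assert_that(requireNamespace("rpart", quietly = TRUE),
                  "rpart is required for decision_tree")
      df <- data.frame(y = factor(y), x)
      rpart::rpart(y ~ ., data = df, method = "class")
    },
    random_forest = {
      assert_that(requireNamespace("randomForest", quietly = TRUE),
                  "randomForest is required for random_forest")
      randomForest::randomForest(x, factor(y))
    },
    gradient_boosted_trees = {
      assert_that(requireNamespace("xgboost", quietly = TRUE),
                  "xgboost is required for gradient_boosted_trees")
      xgboost::xgb.train(
        params = list(objective = "binary:logistic"),
        data = xgboost::xgb.DMatrix(x, label = y), nrounds = 100,
        verbose = 0)
    })
  structure(list(kind = kind, fit = fit, features = colnames(x)),
            class = "starnn_baseline")
}

#' @export
#' @rdname fit_baseline
#' @param object A `starnn_baseline`.
#' @param ... Unused.
predict.starnn_baseline <- function(object, input, ...) {
  x <- cbind(input$x, input$covariates)
  p <- switch(object$kind,
    basic_dnn = unname(predict(object$fit, input)),
    logistic_l1 = ,
    logistic_l2 = drop(predict(object$fit, x, type = "response")),
    linear_svc = {
      dvm <- attr(predict(object$fit, x, decision.values = TRUE),
                  "decision.values")
      dv <- dvm[, 1]
      # orient so larger means class "1", then squash to (0, 1)
      if (colnames(dvm)[1] == "0/1") dv <- -dv
      plogis(dv)
    },
    decision_tree = predict(object$fit, data.frame(x))[, "1"],
    random_forest = predict(object$fit, x, type = "prob")[, "1"],
    gradient_boosted_trees = predict(object$fit, x))
  setNames(as.numeric(p), input$samples)
}

#' @exportS3Method base::print
print.starnn_baseline <- function(x, ...) {
  cat(sprintf("<starnn_baseline> %s over %d features\n", x$kind,
              length(x$features)))
  invisible(x)
}
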