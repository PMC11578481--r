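#' Run the full pipeline over repeated splits
#'
#' For each of `n_splits` random stratified splits and `n_repeats`
#' training repeats per split (repeat r on split s uses seed
#' `seed + r * n_splits + s`), the harness: computes polygenic scores
#' (z-standardized on the training split only), selects gene features on
#' the training split via the four-matrix union, assembles the model
#' input restricted to the union genes, trains each requested model, and
#' evaluates ROC-AUC, F1, accuracy, precision and recall on the test
#' split at the 0.5 threshold.
#'
#' @param cohort A [simulate_cohort()] cohort (or equivalent list).
#' @param models Character subset of `c("starnn_3to1", "starnn_2to1",
#'   "starnn_4to1", "starnn_nopgs", "basic_dnn", "logistic_l1",
#'   "logistic_l2")`.
#' @param n_repeats,n_splits Repeat structure (the published protocol is
#'   10 repeats on one split).
#' @param seed Base seed.
#' @param control [train_control()] for the neural models.
#' @param featsel_args List of arguments passed on to
#'   [select_features()].
#' @return Object of class `starnn_metrics`: tibble with one row per
#'   repeat x split x model and columns `model`, `split`, `rep`, `seed`,
#'   `n_features`, `auc`, `f1`, `accuracy`, `precision`, `recall`.
#' @export
run_experiment <- function(cohort,
                           models = c("starnn_3to1", "basic_dnn"),
                           n_repeats = 10L, n_splits = 1L, seed = 1L,
                           control = train_control(),
                           featsel_args = list()) {
  known <- c("starnn_3to1", "starnn_2to1", "starnn_4to1", "starnn_nopgs",
             "basic_dnn", "logistic_l1", "logistic_l2")
  assert_that(all(models %in% known),
              paste0("unknown model; choose from ",
                     paste(known, collapse = ", ")))
  labels <- setNames(cohort$samples$phenotype, cohort$samples$sample_id)
  sex <- setNames(cohort$samples$sex, cohort$samples$sample_id)
  ann <- classify_variants(cohort$variants)
  need_syn <- any(models == "starnn_4to1")
  burden <- burden_matrix(
    cohort$genotypes, ann,
    classes = c("PTV", "MisA", "MisB", "MisC", "MisAB",
                if (need_syn) "SYN"),
    genes = sort(unique(ann$gene)))

  rows <- list()
  for (s in seq_len(n_splits)) {
    for (r in seq_len(n_repeats)) {
      run_seed <- seed + r * n_splits + s
      res <- tryCatch(
        run_one(cohort, burden, labels, sex, models, run_seed, control,
                featsel_args),
        error = function(e) {
          warn(sprintf("repeat %d/split %d failed: %s", r, s,
                       conditionMessage(e)))
          NULL
        })
      if (!is.null(res)) {
        rows[[length(rows) + 1L]] <- mutate(res, split = s, rep = r,
                                            seed = run_seed)
      }
    }
  }
  out <- bind_rows(rows)
  class(out) <- c("starnn_metrics", class(out))
  out
}

run_one <- function(cohort, burden, labels, sex, models, run_seed, control,
                    featsel_args) {
  split <- split_samples(names(labels), labels, scheme = "80/10/10",
                         seed = run_seed)
  ids <- split(split$sample_id, split$fold)

  pgs_tbl <- if (!is.null(cohort$common)) {
    standardize_pgs(
      pgs_score(cohort$common$dosages, cohort$common$effects,
                variants = cohort$common$variants),
      reference_ids = ids$train)
  } else NULL
  pgs <- if (!is.null(pgs_tbl)) setNames(pgs_tbl$pgs, pgs_tbl$sample_id)

  feats <- do.call(select_features,
                   c(list(burden = burden, labels = labels,
                          train_ids = ids$train,
                          probe_seed = run_seed), featsel_args))
  genes <- feats$union
  if (length(genes) == 0) abort("feature selection returned no genes")

  sub_input <- function(inp, keep) {
    structure(list(
      x = inp$x[keep, , drop = FALSE],
      covariates = if (is.null(inp$covariates)) NULL else
        inp$covariates[keep, , drop = FALSE],
      genes = inp$genes, blocks = inp$blocks, mode = inp$mode,
      samples = keep), class = "starnn_input")
  }
  ctl <- control
  ctl$seed <- run_seed

  eval_model <- function(model) {
    mode <- switch(model, starnn_2to1 = "2to1", starnn_4to1 = "4to1",
                   basic_dnn = , logistic_l1 = , logistic_l2 =
                     "unseparated", "3to1")
    use_pgs <- if (model == "starnn_nopgs") NULL else pgs
    inp <- assemble_input(burden, pgs = use_pgs, sex = sex, mode = mode,
                          genes = genes)
    tr <- sub_input(inp, ids$train)
    va <- sub_input(inp, ids$val)
    te <- sub_input(inp, ids$test)
    scores <- if (model %in% c("basic_dnn", "logistic_l1", "logistic_l2")) {
      fit <- fit_baseline(model, tr, labels, val_input = va,
                          val_labels = labels, control = ctl)
      predict(fit, te)
    } else {
      fit <- train_starnn(tr, labels, va, labels, control = ctl)
      predict(fit, te)
    }
    y_te <- labels[ids$test]
    bind_cols(tibble(model = model, n_features = feats$n_features,
                     auc = roc_auc(scores, y_te)),
              threshold_metrics(scores, y_te))
  }
  bind_rows(lapply(models, eval_model))
}

#' @exportS3Method base::print
print.starnn_metrics <- function(x, ...) {
  cat(sprintf("<starnn_metrics> %d runs\n", nrow(x)))
  print(glance(x))
  invisible(x)
}

#' @export
#' @rdname run_experiment
#' @param x A `starnn_metrics` object.
#' @param ... Unused.
tidy.starnn_metrics <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Summarise repeated-split metrics
#'
#' Mean and standard deviation of each metric per model, over completed
#' repeats only; invariant to repeat ordering.
#'
#' @param x A `starnn_metrics` object.
#' @param ... Unused.
#' @export
glance.starnn_metrics <- function(x, ...) {
  as_tibble(unclass(x)) |>
    tidyr::pivot_longer(c("auc", "f1", "accuracy", "precision", "recall"),
                        names_to = "metric") |>
    group_by(.data$model, .data$metric) |>
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE),
              n_repeats = sum(!is.na(.data$value)), .groups = "drop")
}
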