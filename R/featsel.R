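#' Univariate ANOVA F scores per gene
#'
#' One-way two-group F statistic of gene burden against the binary label,
#' with p-values from the F(1, N-2) distribution — the classical
#' univariate filter score. A zero-variance gene gets F = 0, p = 1 and is
#' flagged.
#'
#' @param x Numeric matrix samples x genes.
#' @param labels Binary vector (0/1) of length `nrow(x)`.
#' @return Tibble `gene`, `f_stat`, `p_value`, `zero_variance`, in the
#'   column order of `x`.
#' @export
univariate_f_scores <- function(x, labels) {
  assert_that(nrow(x) == length(labels),
              "`labels` length must match rows of `x`")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  assert_that(n1 >= 2 && n0 >= 2, "need at least 2 samples per label")
  n <- n1 + n0
  m1 <- colMeans(x[labels == 1, , drop = FALSE])
  m0 <- colMeans(x[labels == 0, , drop = FALSE])
  mg <- (n1 * m1 + n0 * m0) / n
  ss_between <- n1 * (m1 - mg)^2 + n0 * (m0 - mg)^2
  ss_total <- colSums(sweep(x, 2, mg)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  zero_var <- ss_total < .Machine$double.eps * n
  f <- ifelse(zero_var | ss_within == 0 & ss_between == 0, 0,
              (ss_between / 1) / (ss_within / (n - 2)))
  f[!zero_var & ss_within == 0 & ss_between > 0] <- Inf
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  p[zero_var] <- 1
  tibble(gene = colnames(x) %||% as.character(seq_len(ncol(x))),
         f_stat = unname(f), p_value = unname(p),
         zero_variance = unname(zero_var))
}

#' Family-wise-error univariate selection
#'
#' Keeps genes whose p-value is below `alpha / n_features` (Bonferroni
#' control of the family-wise error rate).
#'
#' @param scores Tibble from [univariate_f_scores()].
#' @param alpha Family-wise error level.
#' @return Character vector of selected genes (possibly empty).
#' @export
select_fwe <- function(scores, alpha = 0.05) {
  s <- as_tibble(scores)
  s$gene[s$p_value < alpha / nrow(s)]
}

#' Percentile univariate selection
#'
#' Keeps the top `percentile`% of genes by F score; ties are broken by
#' stable gene order.
#'
#' @param scores Tibble from [univariate_f_scores()].
#' @param percentile Percentage of genes to keep (0-100].
#' @return Character vector of selected genes.
#' @export
select_percentile <- function(scores, percentile = 10) {
  s <- as_tibble(scores)
  assert_that(percentile > 0 && percentile <= 100,
              "`percentile` must be in (0, 100]")
  k <- as.integer(floor(nrow(s) * percentile / 100 + 1e-9))
  if (k == 0) return(character(0))
  ord <- order(-s$f_stat, seq_len(nrow(s)))
  s$gene[sort(ord[seq_len(k)])]
}

#' Four-matrix univariate feature selection with union
#'
#' Builds the four gene-by-sample matrices used for feature selection —
#' PTV plus all missense, PTV alone, PTV plus MisA, PTV plus MisA plus
#' MisB — scores every gene univariately on the training samples, applies
#' a selector per matrix, and unions the four selections. The final model
#' feature count is the union size plus two (polygenic score and sex).
#'
#' With `selector = "auto"`, both the family-wise-error and percentile
#' rules are applied per matrix and the one whose ridge-logistic probe has
#' the better ROC-AUC on a held-out fifth of the training samples wins
#' that matrix.
#'
#' @param burden A [burden_matrix()] object carrying classes PTV, MisA,
#'   MisB, MisC (e.g. `burden_matrix(..., classes = c("PTV", "MisA",
#'   "MisB", "MisC"))`).
#' @param labels Named binary vector (names = sample ids).
#' @param train_ids Sample ids of the training split; selection never sees
#'   other samples. If `split` is supplied instead, train ids are taken
#'   from it and passing any non-train sample in `train_ids` is an error.
#' @param split Optional split manifest from [split_samples()].
#' @param selector `"auto"`, `"fwe"` or `"percentile"`.
#' @param alpha,percentile Selector hyperparameters.
#' @param probe_seed Seed for the auto-selector probe split.
#' @return Object of class `starnn_features`: list with `union` (sorted
#'   gene vector), `per_matrix` (score tibbles with `selected` flag),
#'   `selector_by_matrix`, `n_features` (= |union| + 2).
#' @export
select_features <- function(burden, labels, train_ids = NULL, split = NULL,
                            selector = c("auto", "fwe", "percentile"),
                            alpha = 0.05, percentile = 10,
                            probe_seed = 1L) {
  selector <- match.arg(selector)
  assert_that(!is.null(names(labels)), "`labels` must be named by sample id")
  if (!is.null(split)) {
    split_train <- split$sample_id[split$fold == "train"]
    if (!is.null(train_ids) && length(setdiff(train_ids, split_train)) > 0) {
      abort("leakage: `train_ids` contains samples outside the train fold")
    }
    train_ids <- split_train
  }
  if (is.null(train_ids)) train_ids <- names(labels)
  assert_that(all(train_ids %in% burden$samples),
              "train ids missing from burden samples")

  compositions <- list(
    PTV_allmis = c("PTV", "MisA", "MisB", "MisC"),
    PTV = "PTV",
    PTV_MisA = c("PTV", "MisA"),
    PTV_MisA_MisB = c("PTV", "MisA", "MisB")
  )
  y <- labels[train_ids]

  pick_one <- function(xmat) {
    scores <- univariate_f_scores(xmat, y)
    if (selector == "fwe") {
      return(list(scores = scores, genes = select_fwe(scores, alpha),
                  selector = "fwe"))
    }
    if (selector == "percentile") {
      return(list(scores = scores,
                  genes = select_percentile(scores, percentile),
                  selector = "percentile"))
    }
    cand <- list(fwe = select_fwe(scores, alpha),
                 percentile = select_percentile(scores, percentile))
    auc <- vapply(cand, function(genes) {
      if (length(genes) == 0) return(0.5)
      probe_auc(xmat[, genes, drop = FALSE], y, probe_seed)
    }, numeric(1))
    best <- names(which.max(auc))
    list(scores = scores, genes = cand[[best]], selector = best)
  }

  per_matrix <- imap(compositions, function(cls, nm) {
    xmat <- t(burden_slice(burden, cls))[train_ids, , drop = FALSE]
    res <- pick_one(xmat)
    res$scores$selected <- res$scores$gene %in% res$genes
    res$scores$matrix <- nm
    res
  })

  union_genes <- sort(unique(unlist(map(per_matrix, "genes"))))
  structure(list(
    union = union_genes,
    per_matrix = map(per_matrix, "scores"),
    selector_by_matrix = map(per_matrix, "selector"),
    n_features = length(union_genes) + 2L,
    train_ids = train_ids
  ), class = "starnn_features")
}

# ridge-logistic probe ROC-AUC on a held-out fifth of the training samples
probe_auc <- function(x, y, seed) {
  set.seed(seed)
  n <- length(y)
  hold <- sort(sample.int(n, max(2L, floor(n / 5))))
  if (length(unique(y[hold])) < 2 || length(unique(y[-hold])) < 2) {
    return(0.5)
  }
  if (ncol(x) == 1) return(roc_auc(x[hold, 1], y[hold]))
  fit <- glmnet::glmnet(x[-hold, , drop = FALSE], y[-hold],
                        family = "binomial", alpha = 0, nlambda = 20)
  pred <- predict(fit, x[hold, , drop = FALSE],
                  s = min(fit$lambda))[, 1]
  roc_auc(pred, y[hold])
}

#' @exportS3Method base::print
print.starnn_features <- function(x, ...) {
  cat(sprintf("<starnn_features> %d union genes (+PGS, sex = %d features)\n",
              length(x$union), x$n_features))
  for (nm in names(x$per_matrix)) {
    cat(sprintf("  %-14s %4d selected (%s)\n", nm,
                sum(x$per_matrix[[nm]]$selected), x$selector_by_matrix[[nm]]))
  }
  invisible(x)
}

#' @export
tidy.starnn_features <- function(x, ...) {
  bind_rows(x$per_matrix)
}
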