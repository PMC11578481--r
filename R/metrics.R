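#' Label-stratified sample split
#'
#' Partitions samples into train/validation/test (80/10/10) or train/test
#' (80/20) folds, stratified by label, with largest-remainder rounding of
#' the per-stratum fold counts.
#'
#' @param sample_ids Character vector of sample ids.
#' @param labels Binary labels aligned with `sample_ids`.
#' @param scheme `"80/10/10"` or `"80/20"`.
#' @param seed Integer seed; the manifest records it.
#' @return Tibble `sample_id`, `label`, `fold`, with attribute `"seed"`.
#' @export
split_samples <- function(sample_ids, labels,
                          scheme = c("80/10/10", "80/20"), seed = 1L) {
  scheme <- match.arg(scheme)
  assert_that(length(sample_ids) == length(labels),
              "ids and labels must align")
  assert_that(length(sample_ids) >= 10, "need at least 10 samples")
  tab <- table(labels)
  assert_that(all(tab >= 3), "every class needs at least 3 samples")
  fracs <- if (scheme == "80/10/10") c(train = 0.8, val = 0.1, test = 0.1)
           else c(train = 0.8, test = 0.2)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  fold <- character(length(sample_ids))
  # per-stratum floors first, then spread the leftover slots towards the
  # folds furthest below their global largest-remainder targets
  targets <- largest_remainder(length(sample_ids), fracs)
  assigned <- setNames(rep(0L, length(fracs)), names(fracs))
  for (lv in names(tab)) {
    idx <- which(labels == lv)
    raw <- length(idx) * fracs / sum(fracs)
    counts <- setNames(as.integer(floor(raw)), names(fracs))
    rem <- length(idx) - sum(counts)
    if (rem > 0) {
      deficit <- targets - (assigned + counts)
      ord <- order(-(raw - floor(raw)), -deficit)
      winners <- names(fracs)[ord[seq_len(rem)]]
      counts[winners] <- counts[winners] + 1L
    }
    assigned <- assigned + counts
    fold[sample(idx)] <- rep(names(fracs), times = counts)
  }
  out <- tibble(sample_id = sample_ids, label = labels, fold = fold)
  attr(out, "seed") <- seed
  attr(out, "scheme") <- scheme
  out
}

#' ROC-AUC by pairwise concordance
#'
#' The probability that a random case scores above a random control, with
#' ties counted one half — computed from mid-ranks, so it equals the
#' exhaustive pairwise comparison exactly.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = case).
#' @return AUC in \[0, 1\]; `NA` with a warning for single-class input.
#' @examples
#' roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warn("ROC-AUC undefined for single-class input")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-table metrics at a threshold
#'
#' F1 (positive class), binary accuracy, precision and recall from the
#' 2x2 confusion table at the given threshold (score strictly above the
#' threshold predicts 1). Precision and F1 are `NA` when no positive
#' predictions are made; recall is `NA` without positive labels.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param threshold Decision threshold.
#' @return One-row tibble `f1`, `accuracy`, `precision`, `recall`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  tibble(f1 = f1, accuracy = (tp + tn) / length(labels),
         precision = precision, recall = recall)
}

#' Score separation between cases and controls
#'
#' Group means plus a two-sided Mann-Whitney-Wilcoxon p-value. When both
#' groups have at most 10 observations the p-value is exact (the null
#' Wilcoxon distribution for tie-free data, full enumeration of rank
#' assignments under ties); otherwise the normal approximation with tie
#' correction is used.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = case).
#' @param exact_max Group-size boundary for the exact branch.
#' @return One-row tibble `mean_case`, `mean_control`, `p_value`,
#'   `method`.
#' @export
score_separation <- function(scores, labels, exact_max = 10) {
  labels <- as.integer(labels)
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  assert_that(length(cs) > 0 && length(ct) > 0,
              "both classes must be present")
  res <- mww_test(cs, ct, exact_max = exact_max)
  tibble(mean_case = mean(cs), mean_control = mean(ct),
         p_value = res$p, method = res$method)
}

# two-sided Mann-Whitney-Wilcoxon; internal engine for score_separation
mww_test <- function(xx, yy, exact_max = 10) {
  n1 <- length(xx); n0 <- length(yy)
  pooled <- c(xx, yy)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 <= exact_max && n0 <= exact_max) {
    ties <- any(duplicated(pooled))
    if (!ties) {
      # exact tail from the null Wilcoxon rank-sum distribution
      lo <- pwilcox(u, n1, n0)
      hi <- pwilcox(u - 1, n1, n0, lower.tail = FALSE)
      return(list(p = min(1, 2 * min(lo, hi)), method = "exact"))
    }
    # ties: enumerate all assignments of n1 of the pooled values to group 1
    combs <- utils::combn(n1 + n0, n1)
    mu <- n1 * n0 / 2
    ustats <- apply(combs, 2, function(ii) sum(r[ii]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(ustats - mu) >= abs(u - mu) - 1e-9)
    return(list(p = p, method = "exact_ties"))
  }
  # normal approximation with tie correction
  mu <- n1 * n0 / 2
  nt <- n1 + n0
  tie_tab <- table(pooled)
  sigma2 <- n1 * n0 / 12 *
    (nt + 1 - sum(tie_tab^3 - tie_tab) / (nt * (nt - 1)))
  if (sigma2 <= 0) return(list(p = 1, method = "approx"))
  # continuity-corrected, as is conventional for the normal approximation
  z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sigma2)
  list(p = min(1, 2 * pnorm(-abs(z))), method = "approx")
}

#' Hypergeometric gene-set overlap
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' (size `n`) and an annotated gene set (size `K`) within a universe of
#' `N` genes. The default (`tail = "inclusive"`) computes
#' \eqn{P(X \ge k)}, the standard enrichment p-value; `tail = "strict"`
#' computes \eqn{P(X > k)}, the convention some tools use, which excludes
#' the observed overlap from the tail.
#'
#' @param N Universe size.
#' @param K Annotated-set size.
#' @param n Query-set size.
#' @param k Observed overlap.
#' @param tail Tail convention, see above.
#' @return One-row tibble of class `starnn_enrichment`: `universe`,
#'   `annotated`, `query`, `overlap`, `expected`, `p_value`, `tail`.
#' @examples
#' hypergeom_overlap(5, 2, 2, 1)$p_value   # 0.7
#' @export
hypergeom_overlap <- function(N, K, n, k,
                              tail = c("inclusive", "strict")) {
  tail <- match.arg(tail)
  assert_that(is_count(N) && is_count(K) && is_count(n) && is_count(k),
              "all overlap counts must be non-negative integers")
  assert_that(K <= N && n <= N, "set sizes cannot exceed the universe")
  assert_that(k <= min(K, n), "overlap cannot exceed either set")
  q <- if (tail == "inclusive") k - 1 else k
  p <- phyper(q, K, N - K, n, lower.tail = FALSE)
  if (tail == "inclusive" && k == 0) p <- 1
  structure(tibble(universe = N, annotated = K, query = n, overlap = k,
                   expected = n * K / N, p_value = p, tail = tail),
            class = c("starnn_enrichment", class(tibble())))
}
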