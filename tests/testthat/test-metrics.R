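test_that("stratified splits honour the fold fractions", {
  ids <- sprintf("s%03d", 1:100)
  labels <- rep(0:1, each = 50)
  sp <- split_samples(ids, labels, seed = 5)
  expect_equal(as.vector(table(sp$fold)[c("train", "val", "test")]),
               c(80L, 10L, 10L))
  # stratification: each fold preserves the label balance
  tab <- table(sp$fold, sp$label)
  expect_equal(unname(tab[, "0"]), unname(tab[, "1"]))
  # rounding at n = 10
  sp10 <- split_samples(sprintf("t%02d", 1:10), rep(0:1, each = 5),
                        seed = 2)
  expect_equal(as.vector(table(sp10$fold)[c("train", "val", "test")]),
               c(8L, 1L, 1L))
  # determinism and disjointness
  sp2 <- split_samples(ids, labels, seed = 5)
  expect_identical(sp, sp2)
  expect_error(split_samples(sprintf("u%d", 1:20), c(rep(0, 18), 1, 1)),
               "at least 3")
  sp80 <- split_samples(ids, labels, scheme = "80/20", seed = 5)
  expect_equal(sort(unique(sp80$fold)), c("test", "train"))
})

test_that("ROC-AUC equals pairwise concordance", {
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5)), 0.5)
  expect_warning(a <- roc_auc(1:3, c(1, 1, 1)), "single-class")
  expect_true(is.na(a))
})

test_that("confusion metrics behave at the boundaries", {
  m <- threshold_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(unlist(m), c(f1 = 1, accuracy = 1, precision = 1,
                            recall = 1))
  m2 <- threshold_metrics(c(0.2, 0.1), c(1, 0))
  expect_true(is.na(m2$precision) && is.na(m2$f1))
  expect_equal(m2$accuracy, 0.5)
  # tie at the threshold predicts the negative class
  m3 <- threshold_metrics(c(0.5, 0.5), c(1, 0), threshold = 0.5)
  expect_equal(m3$recall, 0)
})

test_that("exact rank test matches full enumeration", {
  cases <- c(3, 4, 5); controls <- c(1, 2)
  res <- score_separation(c(cases, controls), c(1, 1, 1, 0, 0))
  # oracle: enumerate all C(5,2)=10 assignments of ranks to the controls
  pooled <- c(cases, controls)
  r <- rank(pooled)
  obs_u <- sum(r[1:3]) - 3 * 4 / 2
  combs <- utils::combn(5, 3)
  us <- apply(combs, 2, function(ii) sum(r[ii]) - 6)
  p_oracle <- mean(abs(us - 3) >= abs(obs_u - 3))
  expect_equal(res$p_value, p_oracle)
  expect_equal(res$method, "exact")
  expect_equal(res$mean_case, 4)
  expect_equal(res$mean_control, 1.5)
  # cross-check against the standard implementation
  wt <- stats::wilcox.test(cases, controls, exact = TRUE)
  expect_equal(res$p_value, wt$p.value)
})

test_that("rank test is invariant to score shifts and handles ties", {
  set.seed(71)
  s <- rnorm(30); y <- rep(0:1, 15)
  p1 <- score_separation(s, y)$p_value
  p2 <- score_separation(s + 100, y)$p_value
  expect_equal(p1, p2)
  tied <- score_separation(c(1, 1, 2, 2, 3), c(1, 1, 0, 0, 0))
  expect_equal(tied$method, "exact_ties")
  expect_true(tied$p_value > 0 && tied$p_value <= 1)
})

test_that("rank-test type-I error is calibrated under the null", {
  set.seed(73)
  pvals <- replicate(1000, {
    s <- rnorm(60)
    score_separation(s, rep(0:1, 30))$p_value
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("hypergeometric overlap matches direct log-space summation", {
  expect_equal(hypergeom_overlap(5, 2, 2, 1)$p_value, 0.7)
  expect_equal(hypergeom_overlap(100, 10, 10, 0)$p_value, 1)
  expect_error(hypergeom_overlap(10, 5, 5, 6), "overlap")
  # oracle: direct summation of the mass function in log space
  direct_tail <- function(N, K, n, k) {
    xs <- k:min(K, n)
    lp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
    exp(matrixStats_logsumexp(lp))
  }
  matrixStats_logsumexp <- function(lp) {
    m <- max(lp); m + log(sum(exp(lp - m)))
  }
  set.seed(75)
  for (i in 1:25) {
    N <- sample(50:2000, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_overlap(N, K, n, k)$p_value,
                 direct_tail(N, K, n, k),
                 tolerance = 1e-10)
  }
})

test_that("strict tail excludes the observed overlap", {
  inc <- hypergeom_overlap(50, 10, 10, 3)
  str <- hypergeom_overlap(50, 10, 10, 3, tail = "strict")
  expect_equal(inc$p_value - str$p_value,
               stats::dhyper(3, 10, 40, 10), tolerance = 1e-12)
})
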