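test_that("univariate F scores match one-way ANOVA", {
  x <- matrix(c(2, 3, 4, 0, 0, 1), ncol = 1,
              dimnames = list(NULL, "g1"))
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- univariate_f_scores(x, labels)
  # independent oracle: lm/anova
  fit <- stats::anova(stats::lm(x[, 1] ~ factor(labels)))
  expect_equal(scores$f_stat, fit$`F value`[1], tolerance = 1e-12)
  expect_equal(scores$p_value, fit$`Pr(>F)`[1], tolerance = 1e-12)
})

test_that("F scores are scale invariant and null-centred", {
  set.seed(51)
  x <- matrix(rpois(400, 1), ncol = 4,
              dimnames = list(NULL, paste0("g", 1:4)))
  labels <- rep(0:1, each = 50)
  a <- univariate_f_scores(x, labels)
  b <- univariate_f_scores(2 * x, labels)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  # identical distributions in both groups: F approximately central
  x_null <- rbind(x[1:50, ], x[1:50, ])
  f_null <- univariate_f_scores(x_null, labels)
  expect_true(all(f_null$f_stat < 1e-20))
  # zero-variance genes are flagged with F = 0, p = 1
  x_const <- cbind(x, g5 = 7)
  s <- univariate_f_scores(x_const, labels)
  expect_true(s$zero_variance[5])
  expect_equal(s$f_stat[5], 0)
  expect_equal(s$p_value[5], 1)
})

test_that("selection rules follow the Bonferroni and percentile contracts", {
  scores <- tibble::tibble(gene = c("g1", "g2", "g3"),
                           f_stat = c(30, 8, 0.5),
                           p_value = c(1e-6, 0.01, 0.5))
  expect_equal(select_fwe(scores, alpha = 0.05), c("g1", "g2"))
  expect_equal(select_fwe(scores, alpha = 1e-6), character(0))
  set.seed(53)
  many <- tibble::tibble(gene = sprintf("g%02d", 1:50),
                         f_stat = runif(50), p_value = runif(50))
  expect_equal(length(select_percentile(many, 10)), 5)
  expect_setequal(select_percentile(many, 100), many$gene)
  # nestedness
  for (k in c(10, 30, 60)) {
    expect_true(all(select_percentile(many, k) %in%
                      select_percentile(many, k + 20)))
  }
  # stable tie-break by gene order
  tied <- tibble::tibble(gene = c("a", "b", "c"), f_stat = c(1, 1, 1),
                         p_value = 0.5)
  expect_equal(select_percentile(tied, 67), c("a", "b"))
})

test_that("four-matrix union recovers planted genes and counts features", {
  co <- simulate_cohort(sim_config(
    n_samples = 1500, n_genes = 80, n_planted_genes = 10,
    effect_by_class = c(PTV = 2, MisA = 0, MisB = 0, MisC = 0, SYN = 0),
    qc_noise = qc_noise_control(enabled = FALSE), seed = 55))
  ann <- classify_variants(co$variants)
  b <- burden_matrix(co$genotypes, ann,
                     classes = c("PTV", "MisA", "MisB", "MisC"))
  labels <- stats::setNames(co$samples$phenotype, co$samples$sample_id)
  feats <- select_features(b, labels)
  expect_equal(feats$n_features, length(feats$union) + 2L)
  expect_gt(mean(co$truth$planted_genes %in% feats$union), 0.5)
  # union is the deduplicated set union of the per-matrix selections
  per <- lapply(feats$per_matrix, function(s) s$gene[s$selected])
  expect_setequal(feats$union, unique(unlist(per)))
})

test_that("selection refuses samples outside the training fold", {
  co <- tiny_cohort(n_samples = 60, n_genes = 10, seed = 57)
  ann <- classify_variants(co$variants)
  b <- burden_matrix(co$genotypes, ann,
                     classes = c("PTV", "MisA", "MisB", "MisC"))
  labels <- stats::setNames(co$samples$phenotype, co$samples$sample_id)
  sp <- split_samples(co$samples$sample_id, co$samples$phenotype, seed = 3)
  test_ids <- sp$sample_id[sp$fold == "test"]
  expect_error(
    select_features(b, labels, split = sp,
                    train_ids = c(sp$sample_id[sp$fold == "train"],
                                  test_ids[1])),
    "leakage")
})
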