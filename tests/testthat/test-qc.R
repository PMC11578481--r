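make_call <- function(gt = "het", dp = 60, gq = 50, ad_ref = 30,
                      ad_alt = 30, pl_homref = 60, pl_het = 0,
                      chrom = "chr1", sample_sex = 1) {
  tibble::tibble(gt = gt, dp = dp, gq = gq, ad_ref = ad_ref,
                 ad_alt = ad_alt, pl_homref = pl_homref, pl_het = pl_het,
                 chrom = chrom, sample_sex = sample_sex)
}

test_that("genotype filters fire on the documented thresholds", {
  # depth bounds
  expect_equal(genotype_qc(make_call(dp = 9))$reason, "depth")
  expect_equal(genotype_qc(make_call(dp = 1001))$reason, "depth")
  expect_true(genotype_qc(make_call(dp = 10))$kept)
  # clean hom_ref passes everything
  res <- genotype_qc(make_call(gt = "hom_ref", dp = 60, gq = 50,
                               ad_ref = 57, ad_alt = 3))
  expect_true(res$kept)
  # hom_ref with high alt balance and low GQ fails; high GQ rescues it
  expect_equal(genotype_qc(make_call(gt = "hom_ref", gq = 20, ad_ref = 48,
                                     ad_alt = 12))$reason, "homref_ab_gq")
  expect_true(genotype_qc(make_call(gt = "hom_ref", gq = 40, ad_ref = 48,
                                    ad_alt = 12))$kept)
  # het with low allele balance: PL decides
  expect_equal(genotype_qc(make_call(ad_ref = 48, ad_alt = 12,
                                     pl_het = 10))$reason, "het_ab_pl")
  expect_true(genotype_qc(make_call(ad_ref = 48, ad_alt = 12,
                                    pl_het = 40))$kept)
  # hom_alt with poor balance and likely-reference PL
  expect_equal(genotype_qc(make_call(gt = "hom_alt", ad_ref = 18,
                                     ad_alt = 42, pl_homref = 10))$reason,
               "homalt_ab_pl")
  # chromosome Y call in a female sample
  expect_equal(genotype_qc(make_call(chrom = "chrY",
                                     sample_sex = 0))$reason, "chrY_female")
  expect_true(genotype_qc(make_call(chrom = "chrY", sample_sex = 1))$kept)
})

test_that("undefined allele balance skips the AB clause but not depth", {
  res <- genotype_qc(make_call(gt = "het", ad_ref = 0, ad_alt = 0,
                               pl_het = 5))
  expect_true(res$kept)
  res <- genotype_qc(make_call(gt = "het", dp = 5, ad_ref = 0, ad_alt = 0))
  expect_equal(res$reason, "depth")
})

test_that("kept and reason are mutually consistent", {
  set.seed(3)
  calls <- tibble::tibble(
    gt = sample(c("hom_ref", "het", "hom_alt", "missing"), 200, TRUE),
    dp = sample(c(5, 60, 1500), 200, TRUE),
    gq = sample(c(10, 50), 200, TRUE),
    ad_ref = sample(0:60, 200, TRUE), ad_alt = sample(0:60, 200, TRUE),
    pl_homref = sample(c(5, 60), 200, TRUE),
    pl_het = sample(c(5, 60), 200, TRUE),
    chrom = sample(c("chr1", "chrY"), 200, TRUE),
    sample_sex = sample(0:1, 200, TRUE))
  res <- genotype_qc(calls)
  expect_true(all(is.na(res$reason[res$kept])))
  expect_true(all(!is.na(res$reason[!res$kept])))
  expect_equal(sum(!res$kept), sum(table(res$reason)))
})

test_that("sample filters apply the call-rate, GQ and depth thresholds", {
  stats_tbl <- tibble::tibble(
    sample_id = c("a", "b", "c", "d", "e"),
    call_rate = c(0.95, 0.89, 0.95, 0.95, NA),
    mean_gq = c(45, 45, 19, 45, NA),
    mean_dp = c(40, 40, 40, 9.5, NA))
  res <- sample_qc(stats_tbl)
  expect_equal(res$kept, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(res$reason[2:5],
               c("call_rate", "mean_gq", "mean_dp", "no_sites"))
})

test_that("exact HWE test matches enumeration and handles edge cases", {
  expect_lt(hwe_exact_test(50, 0, 50), 1e-12)
  expect_gte(hwe_exact_test(25, 50, 25), 0.5)
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 77), 1)
  # spot agreement with the log-factorial enumeration oracle
  for (cnt in list(c(10, 5, 3), c(40, 12, 1), c(3, 3, 3), c(0, 10, 0))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-12)
  }
})

test_that("variant filters distinguish the rare and common paths", {
  v <- tibble::tibble(variant_id = c("a", "b", "c"),
                      call_rate = c(1.0, 0.95, 0.5),
                      hwe_p = c(1e-13, 0.5, 0.5))
  res <- variant_qc(v)
  expect_equal(res$kept, c(FALSE, TRUE, FALSE))
  expect_equal(res$reason[c(1, 3)], c("hwe", "call_rate"))
  # literal threshold retains low call-rate sites
  res_lit <- variant_qc(v, paper_literal = TRUE)
  expect_equal(res_lit$kept, c(FALSE, TRUE, TRUE))
  # common path: stricter HWE, 10% missingness cap
  vc <- tibble::tibble(variant_id = c("a", "b"),
                       call_rate = c(0.95, 0.85),
                       hwe_p = c(1e-7, 0.5))
  res_c <- variant_qc(vc, path = "common")
  expect_equal(res_c$kept, c(FALSE, FALSE))
  expect_equal(res_c$reason, c("hwe", "missingness"))
})

test_that("the QC cascade is idempotent on clean data", {
  co <- tiny_cohort(n_samples = 60, n_genes = 10, seed = 23,
                    qc_noise = qc_noise_control(corrupt_frac = c(
                      depth_low = 0, depth_high = 0, homref_ab_gq = 0,
                      homalt_ab_pl = 0, het_ab_pl = 0),
                      missing_rate = 0))
  once <- cohort_qc(co)
  twice <- cohort_qc(once$cohort)
  expect_identical(once$cohort$genotypes, twice$cohort$genotypes)
  expect_identical(dim(once$cohort$genotypes), dim(co$genotypes))
})
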