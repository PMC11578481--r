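#' Quality-control field noise settings for the cohort generator
#'
#' Controls whether per-call QC surfaces (DP, GQ, AD, PL) are generated and
#' how many calls are deliberately corrupted so that each genotype filter
#' has a known kill set. Baseline fields are drawn comfortably inside every
#' filter threshold (depth clipped to \[15, 900\], GQ and PL floors at 40),
#' so the only calls a filter removes are the ones corrupted for it.
#'
#' @param enabled Generate QC field matrices at all. Large cohorts used only
#'   for burden/model work can turn this off; the genotype matrix is
#'   unaffected.
#' @param dp_mean,dp_size Negative-binomial read-depth model (mean, size).
#' @param error_rate Per-read sequencing error rate used for allele-balance
#'   draws on homozygous calls.
#' @param corrupt_frac Named numeric: fraction of eligible calls corrupted
#'   to violate each genotype filter. Names from
#'   `c("depth_low", "depth_high", "homref_ab_gq", "homalt_ab_pl", "het_ab_pl")`.
#' @param missing_rate Fraction of genotype calls set to missing.
#'
#' @return A list of class `starnn_qc_noise`.
#' @export
qc_noise_control <- function(enabled = TRUE,
                             dp_mean = 60,
                             dp_size = 10,
                             error_rate = 0.02,
                             corrupt_frac = c(depth_low = 0.002,
                                              depth_high = 0.002,
                                              homref_ab_gq = 0.002,
                                              homalt_ab_pl = 0.002,
                                              het_ab_pl = 0.002),
                             missing_rate = 0.005) {
  assert_that(is_fraction(missing_rate), "`missing_rate` must be in [0, 1]")
  assert_that(all(corrupt_frac >= 0 & corrupt_frac < 0.1),
              "`corrupt_frac` entries must be small fractions")
  structure(list(enabled = isTRUE(enabled), dp_mean = dp_mean,
                 dp_size = dp_size, error_rate = error_rate,
                 corrupt_frac = corrupt_frac, missing_rate = missing_rate),
            class = "starnn_qc_noise")
}

#' Simulation configuration for a synthetic exome cohort
#'
#' Defines a case-control cohort with per-gene rare variants in five
#' functional classes (PTV, MisA, MisB, MisC, synonymous), a set of planted
#' effect genes, a polygenic liability component backed by simulated common
#' variants, and a sex effect. Phenotypes are drawn from a logistic
#' liability model
#' \deqn{y_j \sim \mathrm{Bern}(\mathrm{logit}^{-1}(\alpha + \beta_{sex} s_j
#'   + \beta_{pgs} z_j + \sum_t \beta_t B_{tj}))}
#' where \eqn{B_{tj}} is sample \eqn{j}'s carrier burden of class-\eqn{t}
#' variants over the planted genes and \eqn{\alpha} is solved by bisection
#' so the expected prevalence equals `base_rate`.
#'
#' @param n_samples,n_genes Cohort and gene-universe sizes.
#' @param variants_per_gene Named numeric, mean (Poisson) variant count per
#'   gene for each class in [VARIANT_CLASSES].
#' @param maf_range_rare,maf_range_common Allele-frequency ranges (uniform)
#'   for rare exonic and common variants; the rare upper bound must respect
#'   the 1% rare-variant definition.
#' @param n_common_variants Number of common variants backing the polygenic
#'   score.
#' @param n_planted_genes Number of genes that carry true class effects.
#' @param effect_by_class Named numeric, log-odds per carried variant of
#'   each class within planted genes.
#' @param beta_pgs Log-odds per standard deviation of polygenic liability.
#' @param beta_sex Log-odds for male (sex = 1) versus female (sex = 0).
#' @param base_rate Target prevalence.
#' @param qc_noise A [qc_noise_control()] object.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return A list of class `starnn_sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_samples = 4000,
                       n_genes = 500,
                       variants_per_gene = c(PTV = 3, MisA = 1, MisB = 2,
                                             MisC = 3, SYN = 3),
                       maf_range_rare = c(5e-4, 5e-3),
                       maf_range_common = c(0.05, 0.5),
                       n_common_variants = 100,
                       n_planted_genes = 20,
                       effect_by_class = c(PTV = 1.5, MisA = 0, MisB = 0,
                                           MisC = 0, SYN = 0),
                       beta_pgs = 0.3,
                       beta_sex = 0.5,
                       base_rate = 0.39,
                       qc_noise = qc_noise_control(),
                       seed = 1L) {
  assert_that(is_count(n_samples) && n_samples > 0,
              "`n_samples` must be a positive count")
  assert_that(is_count(n_genes) && n_genes > 0,
              "`n_genes` must be a positive count")
  assert_that(is_count(n_planted_genes) && n_planted_genes <= n_genes,
              "`n_planted_genes` must be a count <= `n_genes`")
  assert_that(is_fraction(base_rate) && base_rate > 0 && base_rate < 1,
              "`base_rate` must be a fraction in (0, 1)")
  assert_that(is_fraction(maf_range_rare) && maf_range_rare[2] <= 0.01,
              "`maf_range_rare` upper bound must not exceed 0.01")
  assert_that(is_fraction(maf_range_common),
              "`maf_range_common` must lie in [0, 1]")
  assert_that(all(VARIANT_CLASSES %in% names(variants_per_gene)),
              "`variants_per_gene` needs one mean per variant class")
  missing_eff <- setdiff(VARIANT_CLASSES, names(effect_by_class))
  effect_by_class[missing_eff] <- 0
  assert_that(inherits(qc_noise, "starnn_qc_noise"),
              "`qc_noise` must come from qc_noise_control()")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 variants_per_gene = variants_per_gene[VARIANT_CLASSES],
                 maf_range_rare = maf_range_rare,
                 maf_range_common = maf_range_common,
                 n_common_variants = as.integer(n_common_variants),
                 n_planted_genes = as.integer(n_planted_genes),
                 effect_by_class = effect_by_class[VARIANT_CLASSES],
                 beta_pgs = beta_pgs, beta_sex = beta_sex,
                 base_rate = base_rate, qc_noise = qc_noise,
                 seed = as.integer(seed)),
            class = "starnn_sim_config")
}
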