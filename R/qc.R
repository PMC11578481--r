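#' Genotype-level quality control
#'
#' Applies the genotype filter cascade to a tidy table of calls. A call is
#' dropped if (in order):
#' 1. it sits on chromosome Y in a female sample;
#' 2. read depth is below 10 or above 1000;
#' 3. homozygous-reference with allele balance above 0.1 and genotype
#'    quality below 25;
#' 4. homozygous-alternate with allele balance below 0.9 and the
#'    homozygous-reference PL below 25;
#' 5. heterozygous or hemizygous with allele balance below 0.25 and the
#'    heterozygous PL below 25.
#'
#' Allele balance is `ad_alt / (ad_ref + ad_alt)`; when AD is absent or
#' sums to zero the balance-dependent clause is skipped (the filter cannot
#' fire) while depth and quality clauses still apply. Each dropped call
#' carries the first matching rule as its reason.
#'
#' @param calls Tibble with columns `gt` (one of `"hom_ref"`, `"het"`,
#'   `"hom_alt"`, `"hemi"`, `"missing"`), `dp`, `gq`, `ad_ref`, `ad_alt`,
#'   `pl_homref`, `pl_het`, `chrom`, `sample_sex` (1 = male, 0 = female).
#'   Missing columns are treated as absent fields.
#' @return The input tibble with `kept` (logical) and `reason` (character,
#'   `NA` when kept) columns appended.
#' @export
genotype_qc <- function(calls) {
  calls <- as_tibble(calls)
  need <- c("gt", "dp")
  assert_that(all(need %in% names(calls)),
              "`calls` must have at least `gt` and `dp` columns")
  nr <- nrow(calls)
  col <- function(nm) if (nm %in% names(calls)) calls[[nm]] else
    rep(NA_real_, nr)
  gt <- calls$gt
  dp <- calls$dp
  gq <- col("gq"); ad_ref <- col("ad_ref"); ad_alt <- col("ad_alt")
  pl_homref <- col("pl_homref"); pl_het <- col("pl_het")
  chrom <- if ("chrom" %in% names(calls)) calls$chrom else rep(NA, nr)
  sex <- col("sample_sex")

  ad_sum <- ad_ref + ad_alt
  ab <- ifelse(!is.na(ad_sum) & ad_sum > 0, ad_alt / ad_sum, NA_real_)
  live <- gt != "missing"

  reason <- rep(NA_character_, nr)
  hit <- function(cond) live & is.na(reason) & !is.na(cond) & cond
  reason[hit(chrom %in% c("Y", "chrY") & sex == 0)] <- "chrY_female"
  reason[hit(dp < 10 | dp > 1000)] <- "depth"
  reason[hit(gt == "hom_ref" & ab > 0.1 & gq < 25)] <- "homref_ab_gq"
  reason[hit(gt == "hom_alt" & ab < 0.9 & pl_homref < 25)] <- "homalt_ab_pl"
  reason[hit(gt %in% c("het", "hemi") & ab < 0.25 & pl_het < 25)] <-
    "het_ab_pl"

  calls$kept <- is.na(reason)
  calls$reason <- reason
  calls
}

#' Sample-level quality control
#'
#' Excludes samples with call rate below 90%, mean genotype quality below
#' 20, or mean genotype depth below 10. Call rate is the non-missing
#' fraction over retained variant sites after genotype QC; means are over
#' non-missing calls.
#'
#' @param sample_stats Tibble with columns `sample_id`, `call_rate`,
#'   `mean_gq`, `mean_dp`.
#' @param min_call_rate,min_mean_gq,min_mean_dp Thresholds.
#' @return Input with `kept`/`reason` columns; a sample with no sites
#'   (`call_rate` `NA` or 0 denominator) is excluded with reason
#'   `"no_sites"`.
#' @export
sample_qc <- function(sample_stats, min_call_rate = 0.9, min_mean_gq = 20,
                      min_mean_dp = 10) {
  s <- as_tibble(sample_stats)
  reason <- rep(NA_character_, nrow(s))
  hit <- function(cond) is.na(reason) & !is.na(cond) & cond
  reason[is.na(s$call_rate)] <- "no_sites"
  reason[hit(s$call_rate < min_call_rate)] <- "call_rate"
  reason[hit(s$mean_gq < min_mean_gq)] <- "mean_gq"
  reason[hit(s$mean_dp < min_mean_dp)] <- "mean_dp"
  s$kept <- is.na(reason)
  s$reason <- reason
  s
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the total probability of heterozygote counts whose conditional
#' probability does not exceed that of the observed count (ties included).
#' Probabilities are computed by the standard recurrence over heterozygote
#' counts in a single pass, so sites with thousands of samples are exact
#' and fast. A monomorphic site returns 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts at the site.
#' @return Two-sided exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit
#' hwe_exact_test(25, 50, 25)   # modal configuration
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  assert_that(is_count(n_hom_ref) && is_count(n_het) && is_count(n_hom_alt),
              "genotype counts must be non-negative integers")
  n <- n_hom_ref + n_het + n_hom_alt
  assert_that(n > 0, "total genotype count must be positive")
  n_a <- 2 * n_hom_alt + n_het          # minor-allele copies (either allele)
  n_A <- 2 * n_hom_ref + n_het
  rare <- min(n_a, n_A)
  if (rare == 0) return(1)

  # possible het counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_ra(h) * n_ca(h) / ((h+2)*(h+1))
  # where n_ra, n_ca are rare/common homozygote counts at h hets
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    n_ra <- (rare - h) / 2
    n_ca <- (2 * n - rare - h) / 2
    lp[i] <- lp[i - 1] + log(4 * n_ra * n_ca) - log((h + 2) * (h + 1))
  }
  lp <- lp - max(lp)
  p_all <- exp(lp) / sum(exp(lp))
  obs <- match(n_het, hets)
  assert_that(!is.na(obs), "inconsistent genotype counts")
  p <- sum(p_all[p_all <= p_all[obs] * (1 + 1e-9)])
  min(p, 1)
}

#' Variant-level quality control
#'
#' Retains variants passing a call-rate threshold and the exact
#' Hardy-Weinberg test. The rare-variant path (default) requires HWE
#' p > 1e-12; the common-variant path requires HWE p >= 1e-6 and
#' missingness <= 10%.
#'
#' @param variant_stats Tibble with columns `variant_id`, `call_rate`,
#'   `hwe_p`.
#' @param min_call_rate Call-rate threshold; the conventional default is
#'   0.9. `paper_literal = TRUE` uses the literal 0.1 instead.
#' @param path `"rare"` or `"common"`.
#' @param paper_literal Use the literal call-rate threshold of 0.1.
#' @return Input with `kept`/`reason` columns.
#' @export
variant_qc <- function(variant_stats, min_call_rate = 0.9,
                       path = c("rare", "common"), paper_literal = FALSE) {
  path <- match.arg(path)
  v <- as_tibble(variant_stats)
  if (paper_literal) min_call_rate <- 0.1
  reason <- rep(NA_character_, nrow(v))
  hit <- function(cond) is.na(reason) & !is.na(cond) & cond
  if (path == "rare") {
    reason[hit(!(v$call_rate > min_call_rate))] <- "call_rate"
    reason[hit(!(v$hwe_p > 1e-12))] <- "hwe"
  } else {
    reason[hit((1 - v$call_rate) > 0.10)] <- "missingness"
    reason[hit(v$hwe_p < 1e-6)] <- "hwe"
  }
  v$kept <- is.na(reason)
  v$reason <- reason
  v
}

#' Run the full QC cascade on a cohort
#'
#' Applies genotype, sample, and variant QC in order (dropped genotypes
#' count as missing for the later stages) and returns the filtered cohort
#' together with a per-stage report. Re-running on already-clean data is a
#' no-op.
#'
#' @param cohort A [simulate_cohort()] cohort or a compatible list with
#'   `genotypes`, `samples`, `variants`, and optional `qc` field matrices.
#' @param ... Passed to [variant_qc()] (e.g. `paper_literal`).
#' @return List with `cohort` (filtered), `report` (tibble stage/reason/n),
#'   and `genotype_reasons` (tibble of dropped calls, when QC fields were
#'   present).
#' @export
cohort_qc <- function(cohort, ...) {
  geno <- cohort$genotypes
  report <- list()
  genotype_reasons <- NULL

  if (!is.null(cohort$qc)) {
    q <- cohort$qc
    gt_chr <- matrix(c("hom_ref", "het", "hom_alt")[geno + 1L],
                     nrow = nrow(geno))
    gt_chr[is.na(geno)] <- "missing"
    sex_lookup <- setNames(cohort$samples$sex, cohort$samples$sample_id)
    calls <- tibble(
      sample_id = rep(rownames(geno), times = ncol(geno)),
      variant_id = rep(colnames(geno), each = nrow(geno)),
      gt = as.vector(gt_chr),
      dp = as.vector(q$dp), gq = as.vector(q$gq),
      ad_ref = as.vector(q$ad_ref), ad_alt = as.vector(q$ad_alt),
      pl_homref = as.vector(q$pl_homref), pl_het = as.vector(q$pl_het),
      chrom = rep(cohort$variants$chrom[match(colnames(geno),
                                              cohort$variants$variant_id)],
                  each = nrow(geno)),
      sample_sex = sex_lookup[rep(rownames(geno), times = ncol(geno))]
    )
    res <- genotype_qc(calls)
    drop_idx <- which(!res$kept)
    geno[drop_idx] <- NA_integer_
    genotype_reasons <- res[drop_idx, c("sample_id", "variant_id", "reason")]
    report$genotype <- dplyr::count(genotype_reasons, .data$reason,
                                    name = "n")
  }

  # sample stage
  call_rate <- rowMeans(!is.na(geno))
  if (!is.null(cohort$qc)) {
    gq_na <- cohort$qc$gq; gq_na[is.na(geno)] <- NA
    dp_na <- cohort$qc$dp; dp_na[is.na(geno)] <- NA
    mean_gq <- rowMeans(gq_na, na.rm = TRUE)
    mean_dp <- rowMeans(dp_na, na.rm = TRUE)
  } else {
    mean_gq <- rep(Inf, nrow(geno)); mean_dp <- rep(Inf, nrow(geno))
  }
  s_res <- sample_qc(tibble(sample_id = rownames(geno),
                            call_rate = call_rate,
                            mean_gq = mean_gq, mean_dp = mean_dp))
  keep_s <- s_res$kept
  report$sample <- dplyr::count(filter(s_res, !.data$kept), .data$reason,
                                name = "n")
  geno <- geno[keep_s, , drop = FALSE]

  # variant stage
  v_call_rate <- colMeans(!is.na(geno))
  hwe_p <- vapply(seq_len(ncol(geno)), function(j) {
    gcount <- tabulate(geno[, j] + 1L, nbins = 3L)
    if (sum(gcount) == 0) return(1)
    hwe_exact_test(gcount[1], gcount[2], gcount[3])
  }, numeric(1))
  v_res <- variant_qc(tibble(variant_id = colnames(geno),
                             call_rate = v_call_rate, hwe_p = hwe_p), ...)
  keep_v <- v_res$kept
  report$variant <- dplyr::count(filter(v_res, !.data$kept), .data$reason,
                                 name = "n")
  geno <- geno[, keep_v, drop = FALSE]

  out <- cohort
  out$genotypes <- geno
  out$samples <- cohort$samples[keep_s, ]
  out$variants <- cohort$variants[
    cohort$variants$variant_id %in% colnames(geno), ]
  if (!is.null(out$qc)) {
    out$qc <- lapply(out$qc, function(mm) mm[keep_s, keep_v, drop = FALSE])
  }
  if (!is.null(out$common)) {
    out$common$dosages <- out$common$dosages[keep_s, , drop = FALSE]
  }
  report_tbl <- bind_rows(imap(report, ~ mutate(.x, stage = .y)))
  list(cohort = out, report = report_tbl,
       genotype_reasons = genotype_reasons)
}
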