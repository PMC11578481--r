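#' Simulate a synthetic exome cohort
#'
#' Draws genotypes per variant from `Binomial(2, MAF)` under Hardy-Weinberg
#' equilibrium, assigns each variant to a gene and a functional class,
#' plants per-class log-odds effects on a random subset of genes, builds a
#' polygenic liability from simulated common variants, and draws binary
#' phenotypes from the logistic liability model described in
#' [sim_config()]. When `config$qc_noise$enabled`, per-call DP/GQ/AD/PL
#' surfaces are generated with a recorded set of corrupted calls so each
#' genotype QC rule has a known kill set.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `starnn_cohort`: a list with
#' \describe{
#'   \item{samples}{tibble `sample_id`, `sex` (1 = male), `phenotype`.}
#'   \item{variants}{tibble of rare-variant annotations: `variant_id`,
#'     `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, `mpc`,
#'     `maf_true`, `maf_cohort`, `maf_external`.}
#'   \item{genotypes}{integer matrix samples x variants, 0/1/2 with `NA`
#'     for missing.}
#'   \item{common}{list with common-variant `dosages`, `variants` and an
#'     `effects` table for polygenic scoring.}
#'   \item{qc}{per-call QC field matrices, or `NULL`.}
#'   \item{truth}{planted genes, true effects, intercept, liabilities and
#'     the planted QC violations.}
#' }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 200, n_genes = 40,
#'                                      n_planted_genes = 5, seed = 7))
#' table(cohort$samples$phenotype)
#' @export
simulate_cohort <- function(config) {
  assert_that(inherits(config, "starnn_sim_config"),
              "`config` must come from sim_config()")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_samples
  g <- config$n_genes
  genes <- sprintf("G%04d", seq_len(g))

  ## variant layout: one synthetic contig, genes non-overlapping
  counts <- lapply(VARIANT_CLASSES, function(cls) {
    rpois(g, config$variants_per_gene[[cls]])
  })
  names(counts) <- VARIANT_CLASSES
  per_gene_total <- Reduce(`+`, counts)
  m <- sum(per_gene_total)
  assert_that(m > 0, "degenerate config: no variants drawn")

  gene_of <- rep(genes, times = per_gene_total)
  class_of <- unlist(lapply(seq_len(g), function(i) {
    rep(VARIANT_CLASSES, times = vapply(counts, `[`, integer(1), i))
  }), use.names = FALSE)
  # gene i occupies a 10kb window starting at (i-1)*10000 + 1
  gene_start <- setNames((seq_len(g) - 1L) * 10000L + 1L, genes)
  pos <- gene_start[gene_of] +
    unlist(lapply(per_gene_total, function(k) sort(sample.int(9999L, k))),
           use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  variant_id <- sprintf("chr1:%d:%s:%s", pos, ref, alt)

  maf <- runif(m, config$maf_range_rare[1], config$maf_range_rare[2])
  geno <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n,
                 dimnames = list(sprintf("S%05d", seq_len(n)), variant_id))

  mpc <- rep(NA_real_, m)
  mpc[class_of == "MisA"] <- runif(sum(class_of == "MisA"), 2, 5)
  mpc[class_of == "MisB"] <- runif(sum(class_of == "MisB"), 1, 2)
  mpc[class_of == "MisC"] <- runif(sum(class_of == "MisC"), 0, 1)
  consequence <- c(PTV = NA, MisA = "missense", MisB = "missense",
                   MisC = "missense", SYN = "synonymous")[class_of]
  consequence[class_of == "PTV"] <-
    sample(c("nonsense", "frameshift", "canonical_splice"),
           sum(class_of == "PTV"), replace = TRUE)

  variants <- tibble(
    variant_id = variant_id, chrom = "chr1", pos = as.integer(pos),
    ref = ref, alt = alt, gene = gene_of, consequence = consequence,
    mpc = mpc, class_true = class_of, maf_true = maf,
    maf_cohort = colMeans(geno) / 2,
    # external reference frequency: same regime, independent noise, kept rare
    maf_external = pmin(maf * exp(rnorm(m, 0, 0.2)), 0.0099)
  )

  ## common variants backing the polygenic score
  mc <- config$n_common_variants
  common <- NULL
  z <- rnorm(n)
  if (mc > 0) {
    maf_c <- runif(mc, config$maf_range_common[1], config$maf_range_common[2])
    cref <- sample(bases, mc, replace = TRUE)
    calt <- vapply(cref, function(r) sample(setdiff(bases, r), 1L),
                   character(1))
    cid <- sprintf("chr2:%d:%s:%s", seq_len(mc) * 5000L, cref, calt)
    dos <- matrix(rbinom(n * mc, 2L, rep(maf_c, each = n)), nrow = n,
                  dimnames = list(rownames(geno), cid))
    beta <- rnorm(mc, 0, 1)
    raw <- drop(dos %*% beta)
    if (sd(raw) > 0) z <- (raw - mean(raw)) / sd(raw)
    common <- list(
      dosages = dos,
      variants = tibble(variant_id = cid, chrom = "chr2",
                        pos = seq_len(mc) * 5000L, ref = cref, alt = calt,
                        maf_true = maf_c),
      effects = tibble(variant_id = cid, effect_allele = calt, beta = beta)
    )
  }

  ## liability model
  sex <- rbinom(n, 1L, 0.5)
  planted <- sort(sample(genes, config$n_planted_genes))
  burden_term <- numeric(n)
  for (cls in VARIANT_CLASSES) {
    eff <- config$effect_by_class[[cls]]
    if (eff == 0) next
    idx <- which(class_of == cls & gene_of %in% planted)
    if (length(idx) == 0) next
    burden_term <- burden_term + eff * rowSums(geno[, idx, drop = FALSE] > 0)
  }
  offset <- config$beta_sex * sex + config$beta_pgs * z + burden_term
  alpha <- solve_intercept(offset, config$base_rate)
  eta <- alpha + offset
  phenotype <- rbinom(n, 1L, plogis(eta))

  ## missingness and QC surfaces
  qc <- NULL
  violations <- tibble(sample_id = character(), variant_id = character(),
                       rule = character())
  if (config$qc_noise$missing_rate > 0) {
    miss <- runif(n * m) < config$qc_noise$missing_rate
    geno[miss] <- NA_integer_
  }
  if (config$qc_noise$enabled) {
    fields <- simulate_qc_fields(geno, config$qc_noise)
    qc <- fields$qc
    violations <- fields$violations
  }

  structure(list(
    samples = tibble(sample_id = rownames(geno), sex = sex,
                     phenotype = phenotype),
    variants = variants,
    genotypes = geno,
    common = common,
    qc = qc,
    truth = list(planted_genes = planted,
                 effect_by_class = config$effect_by_class,
                 alpha = alpha, z = z, eta = eta,
                 qc_violations = violations),
    config = config
  ), class = "starnn_cohort")
}

#' @exportS3Method base::print
print.starnn_cohort <- function(x, ...) {
  cat(sprintf("<starnn_cohort> %d samples x %d rare variants (%d genes)\n",
              nrow(x$genotypes), ncol(x$genotypes), x$config$n_genes))
  cat(sprintf("  cases: %d (%.1f%%), planted genes: %d, common variants: %d\n",
              sum(x$samples$phenotype),
              100 * mean(x$samples$phenotype),
              length(x$truth$planted_genes),
              if (is.null(x$common)) 0L else ncol(x$common$dosages)))
  invisible(x)
}

# Solve the liability intercept by bisection so that
# mean(plogis(alpha + offset)) = target, to tol on the prevalence scale.
solve_intercept <- function(offset, target, tol = 1e-3) {
  f <- function(a) mean(plogis(a + offset)) - target
  lo <- -30; hi <- 30
  assert_that(f(lo) < 0 && f(hi) > 0, "intercept bracket failed")
  while (TRUE) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol || (hi - lo) < 1e-10) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
}

# Per-call QC surfaces with planted filter violations.
# Baseline draws sit inside every filter: DP clipped to [15, 900],
# GQ/PL floors at 40, allele balance near its genotype expectation.
simulate_qc_fields <- function(geno, noise) {
  n <- nrow(geno); m <- ncol(geno)
  dims <- dimnames(geno)
  dp <- matrix(pmin(pmax(rnbinom(n * m, size = noise$dp_size,
                                 mu = noise$dp_mean), 15L), 900L), nrow = n)
  gq <- matrix(40L + rpois(n * m, 25L), nrow = n)
  p_alt <- matrix(noise$error_rate, n, m)
  p_alt[geno == 1L] <- 0.5
  p_alt[geno == 2L] <- 1 - noise$error_rate
  ad_alt <- matrix(rbinom(n * m, as.vector(dp), as.vector(p_alt)), nrow = n)
  # a called het's own PL is 0, so the het filter reduces to its allele-
  # balance clause; clamp baseline het AB into [0.3, 0.7] so only planted
  # violations can fire it
  het <- which(geno == 1L)
  ad_alt[het] <- pmin(pmax(ad_alt[het], ceiling(0.3 * dp[het])),
                      floor(0.7 * dp[het]))
  ad_ref <- dp - ad_alt
  pl_homref <- matrix(40L + rpois(n * m, 60L), nrow = n)
  pl_het <- matrix(40L + rpois(n * m, 60L), nrow = n)
  pl_homalt <- matrix(40L + rpois(n * m, 60L), nrow = n)
  # the called genotype's own likelihood is the PL zero point
  pl_homref[geno == 0L] <- 0L
  pl_het[geno == 1L] <- 0L
  pl_homalt[geno == 2L] <- 0L

  observed <- which(!is.na(geno))
  taken <- integer(0)
  viol <- list()
  pick <- function(eligible, frac) {
    eligible <- setdiff(eligible, taken)
    k <- min(length(eligible), ceiling(frac * n * m))
    if (k == 0) return(integer(0))
    sample(eligible, k)
  }
  record <- function(cells, rule) {
    taken <<- c(taken, cells)
    viol[[rule]] <<- tibble(
      sample_id = dims[[1]][(cells - 1L) %% n + 1L],
      variant_id = dims[[2]][(cells - 1L) %/% n + 1L],
      rule = rule)
  }
  frac <- noise$corrupt_frac

  cells <- pick(observed, frac[["depth_low"]])
  if (length(cells)) {
    dp[cells] <- sample(0:9, length(cells), replace = TRUE)
    ad_alt[cells] <- pmin(ad_alt[cells], dp[cells])
    ad_ref[cells] <- dp[cells] - ad_alt[cells]
    record(cells, "depth_low")
  }
  cells <- pick(observed, frac[["depth_high"]])
  if (length(cells)) {
    dp[cells] <- sample(1001:2000, length(cells), replace = TRUE)
    ad_ref[cells] <- dp[cells] - ad_alt[cells]
    record(cells, "depth_high")
  }
  cells <- pick(which(geno == 0L), frac[["homref_ab_gq"]])
  if (length(cells)) {
    ad_alt[cells] <- pmax(1L, round(0.3 * dp[cells]))
    ad_ref[cells] <- dp[cells] - ad_alt[cells]
    gq[cells] <- sample(0:24, length(cells), replace = TRUE)
    record(cells, "homref_ab_gq")
  }
  cells <- pick(which(geno == 2L), frac[["homalt_ab_pl"]])
  if (length(cells)) {
    ad_ref[cells] <- pmax(1L, round(0.3 * dp[cells]))
    ad_alt[cells] <- dp[cells] - ad_ref[cells]
    pl_homref[cells] <- sample(1:24, length(cells), replace = TRUE)
    record(cells, "homalt_ab_pl")
  }
  cells <- pick(which(geno == 1L), frac[["het_ab_pl"]])
  if (length(cells)) {
    ad_alt[cells] <- pmax(0L, round(0.1 * dp[cells]))
    ad_ref[cells] <- dp[cells] - ad_alt[cells]
    pl_het[cells] <- sample(1:24, length(cells), replace = TRUE)
    record(cells, "het_ab_pl")
  }

  qc <- lapply(list(dp = dp, gq = gq, ad_ref = ad_ref, ad_alt = ad_alt,
                    pl_homref = pl_homref, pl_het = pl_het,
                    pl_homalt = pl_homalt),
               function(mm) { dimnames(mm) <- dims; mm })
  list(qc = qc, violations = bind_rows(viol))
}
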