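#' Compute per-sample polygenic scores
#'
#' Scores each sample as a weighted sum of effect-allele dosages over
#' common variants: \eqn{s_j = \sum_m \beta_m d_{mj}}. In
#' `"mean_per_allele"` mode (the default, matching the conventional
#' scorer's semantics) the sum is divided by twice the number of
#' non-missing scored variants for the sample. The effect allele is
#' matched strand-naively against the variant's ALT/REF: when it equals
#' REF the dosage is reflected (`2 - d`). A missing dosage is imputed as
#' twice the effect-allele frequency among observed calls. Effect-table
#' rows whose variant or allele cannot be matched are skipped and counted.
#'
#' @param dosages Numeric matrix samples x variants of ALT-allele dosages
#'   (0/1/2, `NA` missing), variant ids as column names.
#' @param effects Tibble with columns `variant_id`, `effect_allele`,
#'   `beta`.
#' @param variants Optional tibble with `variant_id`, `ref`, `alt` for
#'   allele matching; without it every effect allele is assumed to be ALT.
#' @param mode `"mean_per_allele"` or `"sum"`.
#' @return Tibble `sample_id`, `pgs`, `n_variants_used`, with attribute
#'   `"skipped"` (number of unmatched effect rows). A sample with no
#'   observed scored variant gets `NA` and a warning.
#' @examples
#' d <- matrix(c(1, 2, 0, 1), nrow = 2,
#'             dimnames = list(c("s1", "s2"), c("v1", "v2")))
#' eff <- tibble::tibble(variant_id = c("v1", "v2"),
#'                       effect_allele = c("A", "A"), beta = c(0.5, -0.2))
#' pgs_score(d, eff, mode = "sum")
#' @export
pgs_score <- function(dosages, effects, variants = NULL,
                      mode = c("mean_per_allele", "sum")) {
  mode <- match.arg(mode)
  eff <- as_tibble(effects)
  assert_that(all(c("variant_id", "effect_allele", "beta") %in% names(eff)),
              "`effects` needs variant_id, effect_allele, beta")
  assert_that(!any(duplicated(eff$variant_id)),
              "duplicate variant ids in effect table")
  assert_that(all(is.finite(eff$beta)), "effect sizes must be finite")

  hit <- match(eff$variant_id, colnames(dosages))
  skipped <- sum(is.na(hit))
  eff <- eff[!is.na(hit), , drop = FALSE]
  d <- dosages[, hit[!is.na(hit)], drop = FALSE]

  flip <- rep(FALSE, nrow(eff))
  if (!is.null(variants)) {
    v <- as_tibble(variants)
    vi <- match(eff$variant_id, v$variant_id)
    is_alt <- eff$effect_allele == v$alt[vi]
    is_ref <- eff$effect_allele == v$ref[vi]
    unmatched <- !is_alt & !is_ref
    skipped <- skipped + sum(unmatched, na.rm = TRUE)
    keep <- which(!unmatched)
    eff <- eff[keep, , drop = FALSE]
    d <- d[, keep, drop = FALSE]
    flip <- is_ref[keep]
  }
  if (any(flip)) d[, flip] <- 2 - d[, flip]

  # impute missing dosage at 2 * effect-allele frequency
  eaf <- colMeans(d, na.rm = TRUE) / 2
  observed <- !is.na(d)
  for (j in which(colSums(!observed) > 0)) {
    d[!observed[, j], j] <- 2 * eaf[j]
  }
  score <- drop(d %*% eff$beta)
  n_used <- rowSums(observed)
  if (mode == "mean_per_allele") {
    score <- ifelse(n_used > 0, score / (2 * n_used), NA_real_)
  } else {
    score[n_used == 0] <- NA_real_
  }
  if (any(n_used == 0)) {
    warn(sprintf("%d samples had no observed scored variants",
                 sum(n_used == 0)))
  }
  out <- tibble(sample_id = rownames(dosages), pgs = unname(score),
                n_variants_used = unname(as.integer(n_used)))
  attr(out, "skipped") <- skipped
  out
}

#' Z-standardize polygenic scores without leakage
#'
#' Centers and scales scores using statistics from a reference subset
#' (typically the training split), so validation and test scores are
#' transformed with training-only parameters.
#'
#' @param scores Tibble from [pgs_score()].
#' @param reference_ids Sample ids whose scores define mean and SD;
#'   defaults to all samples.
#' @return Input tibble with `pgs` replaced by its z-score and attributes
#'   `"center"`/`"scale"` recording the reference statistics.
#' @export
standardize_pgs <- function(scores, reference_ids = NULL) {
  s <- as_tibble(scores)
  ref <- if (is.null(reference_ids)) s$pgs else
    s$pgs[s$sample_id %in% reference_ids]
  ctr <- mean(ref, na.rm = TRUE)
  scl <- sd(ref, na.rm = TRUE)
  assert_that(is.finite(scl) && scl > 0,
              "reference scores have zero variance")
  s$pgs <- (s$pgs - ctr) / scl
  attr(s, "center") <- ctr
  attr(s, "scale") <- scl
  s
}
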