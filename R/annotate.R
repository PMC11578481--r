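#' Classify variants into functional tiers
#'
#' Assigns each annotated variant to exactly one class: nonsense,
#' frameshift and canonical splice-site consequences become `PTV`;
#' missense variants are tiered by MPC score (`MisA`: MPC > 2, `MisB`:
#' 1 < MPC <= 2, `MisC`: 0 <= MPC <= 1 — boundaries resolved right-open on
#' the damaging side); synonymous variants become `SYN`; anything else,
#' including missense with a missing or negative MPC, is `EXCLUDED`.
#' `MisAB` (MisA plus MisB) is formed downstream at burden aggregation.
#'
#' @param annotations Tibble with columns `consequence` and `mpc` (MPC may
#'   be `NA` for non-missense rows).
#' @return The input tibble with a `class` column appended.
#' @examples
#' classify_variants(tibble::tibble(
#'   consequence = c("frameshift", "missense", "missense", "synonymous"),
#'   mpc = c(NA, 2.5, 0.5, NA)))
#' @export
classify_variants <- function(annotations) {
  a <- as_tibble(annotations)
  assert_that(all(c("consequence", "mpc") %in% names(a)),
              "`annotations` needs `consequence` and `mpc` columns")
  cls <- rep("EXCLUDED", nrow(a))
  cls[a$consequence %in% c("nonsense", "frameshift", "canonical_splice")] <-
    "PTV"
  cls[a$consequence == "synonymous"] <- "SYN"
  mis <- a$consequence == "missense" & !is.na(a$mpc) & a$mpc >= 0
  cls[mis & a$mpc > 2] <- "MisA"
  cls[mis & a$mpc > 1 & a$mpc <= 2] <- "MisB"
  cls[mis & a$mpc <= 1] <- "MisC"
  a$class <- cls
  a
}

#' Rare-variant filter
#'
#' Retains variants rare both in-cohort and in the external reference
#' (both minor allele frequencies below `maf_max`), with adequate site
#' quality (mean genotype quality at least `min_gq`, call rate at least
#' `min_call_rate`), and — by default — excludes synonymous variants from
#' the model input. A missing external frequency is treated as unknown and
#' the variant is dropped (conservative); the drop counts per criterion
#' are attached as the `"drop_counts"` attribute.
#'
#' @param annotations Classified annotation tibble with columns
#'   `maf_cohort`, `maf_external`, and (optionally) `gq_mean`,
#'   `call_rate`, `class`.
#' @param maf_max Rarity threshold on both frequencies (default 1%).
#' @param min_gq,min_call_rate Site-quality thresholds.
#' @param exclude_synonymous Drop `SYN`-class variants.
#' @return The retained rows, with attribute `drop_counts`.
#' @export
rare_filter <- function(annotations, maf_max = 0.01, min_gq = 25,
                        min_call_rate = 0.9, exclude_synonymous = TRUE) {
  a <- as_tibble(annotations)
  assert_that(all(c("maf_cohort", "maf_external") %in% names(a)),
              "`annotations` needs `maf_cohort` and `maf_external`")
  nr <- nrow(a)
  col <- function(nm, default) if (nm %in% names(a)) a[[nm]] else
    rep(default, nr)
  gq <- col("gq_mean", Inf)
  cr <- col("call_rate", 1)
  cls <- col("class", NA_character_)

  reason <- rep(NA_character_, nr)
  hit <- function(cond) is.na(reason) & !is.na(cond) & cond
  reason[hit(!(a$maf_cohort < maf_max))] <- "maf_cohort"
  reason[is.na(reason) & is.na(a$maf_external)] <- "maf_external_unknown"
  reason[hit(!(a$maf_external < maf_max))] <- "maf_external"
  reason[hit(gq < min_gq)] <- "gq"
  reason[hit(cr < min_call_rate)] <- "call_rate"
  if (exclude_synonymous) reason[hit(cls == "SYN")] <- "synonymous"

  if (any(reason %in% "maf_external_unknown")) {
    warn(sprintf("%d variants dropped for unknown external MAF",
                 sum(reason %in% "maf_external_unknown")))
  }
  kept <- a[is.na(reason), , drop = FALSE]
  drops <- table(reason[!is.na(reason)])
  attr(kept, "drop_counts") <- tibble(reason = names(drops),
                                      n = as.integer(drops))
  kept
}
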