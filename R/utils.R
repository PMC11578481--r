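#' Variant functional classes
#'
#' Canonical class labels used throughout the package. `PTV` covers
#' nonsense, frameshift and canonical splice-site variants; `MisA`, `MisB`
#' and `MisC` are the MPC missense tiers (MPC > 2, 1 < MPC <= 2, MPC <= 1);
#' `SYN` is synonymous; `EXCLUDED` is the sink for unclassifiable variants.
#' `MisAB` (the union of MisA and MisB) exists only downstream, at burden
#' aggregation.
#'
#' @format Character vector of the five primary class labels.
#' @export
VARIANT_CLASSES <- c("PTV", "MisA", "MisB", "MisC", "SYN")

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_fraction <- function(x) is.numeric(x) && all(!is.na(x)) &&
  all(x >= 0 & x <= 1)

# largest-remainder apportionment of n into parts proportional to fracs
largest_remainder <- function(n, fracs) {
  raw <- n * fracs / sum(fracs)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}
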