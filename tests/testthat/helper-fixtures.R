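# shared builders for small in-code fixtures

tiny_cohort <- function(n_samples = 200, n_genes = 30, seed = 11, ...) {
  simulate_cohort(sim_config(n_samples = n_samples, n_genes = n_genes,
                             n_planted_genes = min(5, n_genes),
                             n_common_variants = 20, seed = seed, ...))
}

# assemble a starnn_input restricted to a sample subset
input_subset <- function(inp, keep) {
  structure(list(x = inp$x[keep, , drop = FALSE],
                 covariates = if (is.null(inp$covariates)) NULL else
                   inp$covariates[keep, , drop = FALSE],
                 genes = inp$genes, blocks = inp$blocks, mode = inp$mode,
                 samples = keep),
            class = "starnn_input")
}

# a linearly separable two-gene toy with an informative burden pattern
separable_toy <- function(n = 200, seed = 5) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  ptv <- cbind(gA = ifelse(y == 1, 2, 0) + rbinom(n, 1, 0.05),
               gB = rbinom(n, 1, 0.1))
  misab <- matrix(rbinom(2 * n, 1, 0.1), ncol = 2,
                  dimnames = list(NULL, c("gA", "gB")))
  misc <- matrix(rbinom(2 * n, 1, 0.1), ncol = 2,
                 dimnames = list(NULL, c("gA", "gB")))
  ids <- sprintf("T%03d", seq_len(n))
  x <- cbind(ptv, misab, misc)
  colnames(x) <- c("PTV:gA", "PTV:gB", "MisAB:gA", "MisAB:gB",
                   "MisC:gA", "MisC:gB")
  rownames(x) <- ids
  inp <- structure(list(x = x, covariates = NULL, genes = c("gA", "gB"),
                        blocks = c("PTV", "MisAB", "MisC"), mode = "3to1",
                        samples = ids),
                   class = "starnn_input")
  list(input = inp, labels = stats::setNames(y, ids))
}

# direct log-factorial enumeration of the conditional HWE distribution;
# an independent route from the recurrence used by hwe_exact_test()
hwe_enum_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- 2 * n_hom_alt + n_het
  rare <- min(n_alt, 2 * n - n_alt)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    nr <- (rare - h) / 2
    nc <- n - nr - h
    lgamma(n + 1) - lgamma(nr + 1) - lgamma(h + 1) - lgamma(nc + 1) +
      h * log(2) -
      (lgamma(2 * n + 1) - lgamma(rare + 1) - lgamma(2 * n - rare + 1))
  }, numeric(1))
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  obs <- match(n_het, hets)
  min(1, sum(p_all[p_all <= p_all[obs] * (1 + 1e-9)]))
}
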