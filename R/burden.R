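#' Aggregate genotypes into gene-by-sample burden matrices
#'
#' For each variant class, the burden of gene \eqn{i} in sample \eqn{j} is
#' the number of class-matching variants in the gene that the sample
#' carries: \eqn{G_{ij} = \sum_k V_{kj}} with \eqn{V_{kj} = 1} when the
#' genotype is heterozygous or homozygous-alternate (a carrier indicator,
#' not an allele dosage; `dosage = TRUE` switches to 0/1/2 dosage for
#' sensitivity analysis). Missing genotypes contribute 0, and genes with no
#' variants of a class hold 0.
#'
#' @param genotypes Integer matrix samples x variants (0/1/2, `NA`
#'   missing) with variant ids as column names.
#' @param annotations Classified annotation tibble (see
#'   [classify_variants()]) with `variant_id`, `gene`, `class`.
#' @param classes Classes to aggregate; defaults to the primary tiers.
#'   `"MisAB"` is accepted and formed as MisA + MisB.
#' @param genes Gene universe defining the row set; defaults to all genes
#'   in `annotations`, sorted.
#' @param dosage Count alternate alleles instead of carriers.
#' @return Object of class `starnn_burden`: list with `classes`, `genes`,
#'   `samples` and `values`, a named list of gene x sample sparse matrices.
#' @examples
#' geno <- matrix(c(1L, 0L, 2L, 0L), nrow = 2,
#'                dimnames = list(c("s1", "s2"), c("v1", "v2")))
#' ann <- tibble::tibble(variant_id = c("v1", "v2"),
#'                       gene = c("G1", "G1"), class = c("PTV", "PTV"))
#' burden_matrix(geno, ann, classes = "PTV")$values$PTV
#' @export
burden_matrix <- function(genotypes, annotations,
                          classes = c("PTV", "MisAB", "MisC"),
                          genes = NULL, dosage = FALSE) {
  a <- as_tibble(annotations)
  assert_that(all(c("variant_id", "gene", "class") %in% names(a)),
              "`annotations` needs variant_id, gene and class columns")
  vids <- colnames(genotypes)
  assert_that(!is.null(vids), "`genotypes` must have variant-id colnames")
  a <- a[match(vids, a$variant_id), , drop = FALSE]
  unknown <- vids[is.na(a$gene)]
  if (length(unknown) > 0) {
    abort(paste0("variants without a gene assignment: ",
                 paste(head(unknown, 5), collapse = ", "),
                 if (length(unknown) > 5) ", ..."))
  }
  if (is.null(genes)) genes <- sort(unique(a$gene))
  assert_that(all(a$gene %in% genes), "annotation genes outside universe")

  val <- genotypes
  val[is.na(val)] <- 0L
  carrier <- if (dosage) val else (val > 0) + 0L
  # variants x genes incidence, then one sparse product per class
  slice <- function(cls_members) {
    idx <- which(a$class %in% cls_members)
    out <- Matrix::Matrix(0, nrow = length(genes), ncol = nrow(genotypes),
                          dimnames = list(genes, rownames(genotypes)),
                          sparse = TRUE)
    if (length(idx) > 0) {
      inc <- Matrix::sparseMatrix(
        i = idx, j = match(a$gene[idx], genes), x = 1,
        dims = c(length(vids), length(genes)))
      out <- methods::as(
        Matrix::t(inc) %*%
          Matrix::t(Matrix::Matrix(carrier, sparse = TRUE)), "CsparseMatrix")
      dimnames(out) <- list(genes, rownames(genotypes))
    }
    out
  }
  members <- lapply(classes, function(cl) {
    if (cl == "MisAB") c("MisA", "MisB") else cl
  })
  values <- lapply(members, slice)
  names(values) <- classes
  structure(list(classes = classes, genes = genes,
                 samples = rownames(genotypes), values = values,
                 dosage = dosage),
            class = "starnn_burden")
}

#' @exportS3Method base::print
print.starnn_burden <- function(x, ...) {
  nz <- sum(vapply(x$values, function(v) Matrix::nnzero(v), numeric(1)))
  tot <- length(x$genes) * length(x$samples) * length(x$classes)
  cat(sprintf(
    "<starnn_burden> %d classes x %d genes x %d samples (%.2f%% nonzero)\n",
    length(x$classes), length(x$genes), length(x$samples), 100 * nz / tot))
  invisible(x)
}

#' Extract one class slice of a burden object
#'
#' @param burden A [burden_matrix()] object.
#' @param class One class name present in `burden$classes`, or a character
#'   vector of primary classes to sum on the fly.
#' @return Dense gene x sample matrix.
#' @export
burden_slice <- function(burden, class) {
  if (length(class) == 1 && class %in% burden$classes) {
    return(as.matrix(burden$values[[class]]))
  }
  Reduce(`+`, lapply(class, function(cl) as.matrix(burden$values[[cl]])))
}

#' Assemble model input from burden slices, polygenic score and sex
#'
#' Lays out the per-sample input vector of the sparse network. Mode
#' `"3to1"` concatenates the PTV, MisAB and MisC gene blocks (3G variant
#' nodes), `"2to1"` drops MisC, `"4to1"` adds the synonymous block, and
#' `"unseparated"` sums the three primary blocks into a single gene block
#' (the basic-DNN input). PGS and sex are carried separately so the model
#' can route them around the sparse layer.
#'
#' @param burden A [burden_matrix()] object containing the needed classes.
#' @param pgs Named numeric of per-sample polygenic scores (names =
#'   sample ids), or `NULL` to omit.
#' @param sex Named integer of per-sample sex indicators, or `NULL`.
#' @param mode Input layout.
#' @param genes Optional gene subset (e.g. the selected features); order
#'   is taken from this argument.
#' @return Object of class `starnn_input`: list with `x` (samples x
#'   variant-node matrix, block-major with `class:gene` column names),
#'   `covariates` (samples x 0..2 matrix), `genes`, `blocks`, `mode`.
#' @export
assemble_input <- function(burden, pgs = NULL, sex = NULL,
                           mode = c("3to1", "2to1", "4to1", "unseparated"),
                           genes = NULL) {
  mode <- match.arg(mode)
  blocks <- switch(mode,
                   "3to1" = c("PTV", "MisAB", "MisC"),
                   "2to1" = c("PTV", "MisAB"),
                   "4to1" = c("PTV", "MisAB", "MisC", "SYN"),
                   "unseparated" = "ALL")
  if (is.null(genes)) genes <- burden$genes
  assert_that(all(genes %in% burden$genes), "unknown genes requested")
  samples <- burden$samples

  get_block <- function(cls) {
    sl <- if (cls == "ALL") {
      burden_slice(burden, c("PTV", "MisAB", "MisC"))
    } else {
      assert_that(cls %in% burden$classes,
                  paste0("burden object lacks class ", cls))
      as.matrix(burden$values[[cls]])
    }
    out <- t(sl[genes, , drop = FALSE])
    colnames(out) <- paste(cls, genes, sep = ":")
    out
  }
  x <- do.call(cbind, lapply(blocks, get_block))

  covariates <- NULL
  if (!is.null(pgs)) {
    assert_that(!is.null(names(pgs)) && all(samples %in% names(pgs)),
                "`pgs` must be named by sample id and cover all samples")
    covariates <- cbind(pgs = pgs[samples])
  }
  if (!is.null(sex)) {
    assert_that(!is.null(names(sex)) && all(samples %in% names(sex)),
                "`sex` must be named by sample id and cover all samples")
    covariates <- cbind(covariates, sex = sex[samples])
  }
  if (!is.null(covariates)) rownames(covariates) <- samples

  structure(list(x = x, covariates = covariates, genes = genes,
                 blocks = blocks, mode = mode, samples = samples),
            class = "starnn_input")
}

#' @exportS3Method base::print
print.starnn_input <- function(x, ...) {
  cat(sprintf(
    "<starnn_input> mode %s: %d samples x %d variant nodes (%d genes%s)\n",
    x$mode, nrow(x$x), ncol(x$x), length(x$genes),
    if (is.null(x$covariates)) ""
    else paste0(" + ", paste(colnames(x$covariates), collapse = ", "))))
  invisible(x)
}
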