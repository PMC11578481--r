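#' Write a cohort to plain-text fixture files
#'
#' Emits a minimal VCF 4.2 (`FORMAT GT:DP:GQ:AD:PL`, missing genotypes as
#' `./.`) containing the rare variants followed by the common variants, an
#' annotation TSV, a phenotype TSV and an effect-size TSV for polygenic
#' scoring. When the cohort carries no QC field matrices, clean
#' placeholder fields (DP 60, GQ 60, AD/PL consistent with the call) are
#' written. The files round-trip losslessly through
#' [read_cohort_fixture()] for genotype and annotation content.
#'
#' @param cohort A [simulate_cohort()] cohort.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the file paths.
#' @export
write_cohort_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(dir), paste0("cannot create directory ", dir))
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             annotations = file.path(dir, "annotations.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             effects = file.path(dir, "pgs_effects.tsv"))

  geno <- cohort$genotypes
  samples <- rownames(geno)
  variants <- cohort$variants

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=starnn-synthetic",
    "##contig=<ID=chr1>", "##contig=<ID=chr2>", "##contig=<ID=chrY>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred likelihoods\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))

  gt_strings <- c("0/0", "0/1", "1/1")
  fmt_variant <- function(j, chrom, pos, id, ref, alt, qc, g_col) {
    gt <- ifelse(is.na(g_col), "./.", gt_strings[g_col + 1L])
    if (is.null(qc)) {
      dp <- rep(60L, length(g_col)); gq <- rep(60L, length(g_col))
      alt_n <- ifelse(is.na(g_col), 0L, c(0L, 30L, 60L)[g_col + 1L])
      ref_n <- dp - alt_n
      pl <- c("0,60,120", "60,0,60", "120,60,0")[ifelse(is.na(g_col), 1L,
                                                        g_col + 1L)]
      pl[is.na(g_col)] <- "0,0,0"
    } else {
      dp <- qc$dp[, j]; gq <- qc$gq[, j]
      alt_n <- qc$ad_alt[, j]; ref_n <- qc$ad_ref[, j]
      pl <- paste(qc$pl_homref[, j], qc$pl_het[, j], qc$pl_homalt[, j],
                  sep = ",")
    }
    calls <- paste(gt, dp, gq, paste(ref_n, alt_n, sep = ","), pl,
                   sep = ":")
    paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT:DP:GQ:AD:PL",
            calls), collapse = "\t")
  }

  lines <- vapply(seq_len(ncol(geno)), function(j) {
    fmt_variant(j, variants$chrom[j], variants$pos[j],
                variants$variant_id[j], variants$ref[j], variants$alt[j],
                cohort$qc, geno[, j])
  }, character(1))
  if (!is.null(cohort$common)) {
    cv <- cohort$common$variants
    dos <- cohort$common$dosages
    lines <- c(lines, vapply(seq_len(ncol(dos)), function(j) {
      fmt_variant(j, cv$chrom[j], cv$pos[j], cv$variant_id[j], cv$ref[j],
                  cv$alt[j], NULL, dos[, j])
    }, character(1)))
  }
  writeLines(c(header, lines), paths[["vcf"]])

  ann <- variants[, c("variant_id", "gene", "consequence", "mpc",
                      "maf_cohort", "maf_external")]
  write.table(ann, paths[["annotations"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$samples, paths[["phenotypes"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  eff <- if (is.null(cohort$common)) {
    tibble(variant_id = character(), effect_allele = character(),
           beta = numeric())
  } else cohort$common$effects
  write.table(eff, paths[["effects"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read cohort fixture files
#'
#' Parses the VCF via `vcfR` into a samples x variants genotype matrix
#' (0/1/2 with `NA` for `./.`), plus per-call DP/GQ/AD/PL matrices, and
#' reads the annotation, phenotype and effect-size tables.
#'
#' @param dir Directory written by [write_cohort_fixture()].
#' @return List with `genotypes`, `qc`, `variants` (CHROM/POS/REF/ALT
#'   tibble), `annotations`, `phenotypes`, `effects`.
#' @export
read_cohort_fixture <- function(dir) {
  vcf_path <- file.path(dir, "cohort.vcf")
  assert_that(file.exists(vcf_path), paste0("no cohort.vcf under ", dir))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ids <- fix$ID

  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  geno <- matrix(NA_integer_, nrow = ncol(gt_chr), ncol = nrow(gt_chr),
                 dimnames = list(colnames(gt_chr), ids))
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  geno[] <- t(matrix(code[gt_chr], nrow = nrow(gt_chr)))

  num_field <- function(el) {
    m <- vcfR::extract.gt(vcf, element = el, as.numeric = TRUE)
    out <- t(m)
    dimnames(out) <- list(colnames(gt_chr), ids)
    out
  }
  split_field <- function(el, part) {
    m <- vcfR::extract.gt(vcf, element = el)
    vals <- vapply(strsplit(as.vector(m), ","),
                   function(x) suppressWarnings(as.numeric(x[part])),
                   numeric(1))
    out <- t(matrix(vals, nrow = nrow(gt_chr)))
    dimnames(out) <- list(colnames(gt_chr), ids)
    out
  }
  qc <- list(dp = num_field("DP"), gq = num_field("GQ"),
             ad_ref = split_field("AD", 1), ad_alt = split_field("AD", 2),
             pl_homref = split_field("PL", 1),
             pl_het = split_field("PL", 2),
             pl_homalt = split_field("PL", 3))

  read_tsv_if <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) return(NULL)
    as_tibble(read.table(p, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE))
  }
  list(genotypes = geno, qc = qc,
       variants = tibble(variant_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT),
       annotations = read_tsv_if("annotations.tsv"),
       phenotypes = read_tsv_if("phenotypes.tsv"),
       effects = read_tsv_if("pgs_effects.tsv"))
}
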