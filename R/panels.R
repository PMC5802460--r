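#' Construct a genotype panel
#'
#' A genotype panel bundles a sample-by-SNP dosage matrix with a per-variant
#' annotation table. Dosages count copies of the effect allele and lie in
#' \[0, 2\]; fractional values are allowed for imputed data. Per-variant minor
#' allele frequency and dosage standard deviation are (re)computed from the
#' non-missing dosages, so they stay consistent under any subsetting.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns. Column
#'   names must match `variants$id`.
#' @param variants data.frame with columns `id`, `chr`, `pos` (1-based bp),
#'   `effect_allele`, `other_allele`, and optionally `imp_r2` (imputation
#'   quality in \[0, 1\]).
#' @param sample_ids character vector of sample identifiers; defaults to the
#'   dosage row names or `S1..Sn`.
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosages`, `variants` (with `maf`, `sd`, `call_rate` filled in) and
#'   `sample_ids`.
#' @export
genotype_panel <- function(dosages, variants, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("id", "chr", "pos", "effect_allele", "other_allele")
  miss <- setdiff(req, names(variants))
  if (length(miss) > 0)
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$id))
    stop("variant ids must be unique")
  if (ncol(dosages) != nrow(variants))
    stop("dosage columns (", ncol(dosages), ") do not match variant rows (",
         nrow(variants), ")")
  if (length(sample_ids) != nrow(dosages))
    stop("sample_ids length does not match dosage rows")
  bad <- which(!is.na(dosages) & (dosages < 0 | dosages > 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("dosage outside [0, 2] at sample %s, SNP %s",
                 sample_ids[bad[1, 1]], variants$id[bad[1, 2]]))
  variants$chr <- as.character(variants$chr)
  variants$pos <- as.integer(variants$pos)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  obj <- structure(
    list(dosages = dosages, variants = variants, sample_ids = sample_ids),
    class = "genotype_panel")
  recompute_variant_stats(obj)
}

## MAF, SD (n-1 denominator) and call rate from non-missing dosages.
recompute_variant_stats <- function(panel) {
  d <- panel$dosages
  n_obs <- colSums(!is.na(d))
  m <- colMeans(d, na.rm = TRUE) / 2
  panel$variants$maf <- pmin(m, 1 - m)
  panel$variants$sd <- apply(d, 2, stats::sd, na.rm = TRUE)
  panel$variants$call_rate <- n_obs / nrow(d)
  if (is.null(panel$variants$imp_r2)) panel$variants$imp_r2 <- NA_real_
  panel
}

#' Subset a genotype panel
#'
#' @param x a `genotype_panel`.
#' @param samples sample ids or indices to keep (default all).
#' @param snps SNP ids or indices to keep (default all).
#' @param ... unused.
#' @return A `genotype_panel` with MAF/SD/call-rate recomputed on the subset.
#' @export
subset.genotype_panel <- function(x, samples = NULL, snps = NULL, ...) {
  i <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  if (is.character(i)) i <- match(i, x$sample_ids)
  j <- if (is.null(snps)) seq_len(nrow(x$variants)) else snps
  if (is.character(j)) j <- match(j, x$variants$id)
  genotype_panel(x$dosages[i, j, drop = FALSE],
                 x$variants[j, setdiff(names(x$variants),
                                       c("maf", "sd", "call_rate")),
                            drop = FALSE],
                 x$sample_ids[i])
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$sample_ids), "samples x",
      nrow(x$variants), "SNPs\n")
  cat("  chromosomes:", paste(unique(x$variants$chr), collapse = ", "), "\n")
  cat("  MAF range:", sprintf("%.3f-%.3f", min(x$variants$maf),
                              max(x$variants$maf)), "\n")
  invisible(x)
}

#' Construct a methylation panel
#'
#' Holds a sample-by-CpG methylation matrix plus CpG coordinates. Values are
#' tagged with their scale: `beta` (fraction in \[0, 1\]), `m` (log2 odds of
#' beta) or `adjusted` (covariate-residualized M-values).
#'
#' @param values numeric matrix, samples in rows, CpGs in columns.
#' @param cpgs data.frame with columns `id`, `chr`, `pos` (1-based bp).
#' @param scale one of `"beta"`, `"m"`, `"adjusted"`.
#' @param sample_ids character vector; defaults to row names or `S1..Sn`.
#' @return An object of class `methylation_panel` with per-CpG `missing_rate`
#'   filled in.
#' @export
methylation_panel <- function(values, cpgs, scale = c("beta", "m", "adjusted"),
                              sample_ids = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  cpgs <- as.data.frame(cpgs, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "chr", "pos"), names(cpgs))
  if (length(miss) > 0)
    stop("CpG table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cpgs$id)) stop("CpG ids must be unique")
  if (ncol(values) != nrow(cpgs))
    stop("value columns do not match CpG rows")
  if (scale == "beta") {
    bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("beta value outside [0, 1] at sample %s, CpG %s",
                   sample_ids[bad[1, 1]], cpgs$id[bad[1, 2]]))
  }
  cpgs$chr <- as.character(cpgs$chr)
  cpgs$pos <- as.integer(cpgs$pos)
  cpgs$missing_rate <- colMeans(is.na(values))
  rownames(values) <- sample_ids
  colnames(values) <- cpgs$id
  structure(list(values = values, cpgs = cpgs, sample_ids = sample_ids,
                 scale = scale),
            class = "methylation_panel")
}

#' @export
print.methylation_panel <- function(x, ...) {
  cat("methylation_panel:", length(x$sample_ids), "samples x",
      nrow(x$cpgs), "CpGs [scale:", x$scale, "]\n")
  invisible(x)
}

#' Construct a GWAS summary-statistics table
#'
#' Per-SNP marginal association statistics. `z` is derived as `beta/se` when
#' absent; when both are given they must agree.
#'
#' @param df data.frame with columns `id`, `effect_allele`, `other_allele`,
#'   and either (`beta`, `se`) or `z`; optional `n` (sample size) and `r2`
#'   (per-SNP fraction of phenotypic variance explained, used only by the
#'   exact statistic).
#' @return A data.frame of class `gwas_summary`.
#' @export
gwas_summary <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("id", "effect_allele", "other_allele")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("GWAS table missing column(s): ", paste(miss, collapse = ", "))
  has_bs <- all(c("beta", "se") %in% names(df))
  has_z <- "z" %in% names(df)
  if (!has_bs && !has_z)
    stop("GWAS table needs either (beta, se) or z")
  if (has_bs) {
    if (any(df$se <= 0, na.rm = TRUE)) stop("se must be positive")
    zc <- df$beta / df$se
    if (has_z) {
      off <- abs(df$z - zc) > 1e-9
      if (any(off, na.rm = TRUE))
        stop("z inconsistent with beta/se at row ", which(off)[1])
    }
    df$z <- zc
  }
  if (!has_bs) {
    df$beta <- NA_real_
    df$se <- NA_real_
  }
  if (is.null(df$n)) df$n <- NA_real_
  if (is.null(df$r2)) df$r2 <- NA_real_
  if (any(!is.na(df$r2) & (df$r2 < 0 | df$r2 >= 1)))
    stop("r2 must lie in [0, 1)")
  class(df) <- c("gwas_summary", "data.frame")
  df
}
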