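#' Predict genetically estimated methylation for one CpG model
#'
#' Computes `intercept + sum_k w_k * dosage_k` over the model SNPs matched
#' in the panel (allele-harmonized; swapped-allele dosages are reflected as
#' `2 - d`). Model SNPs absent from the panel contribute 0. Missing dosages
#' are mean-imputed per SNP. When the matched fraction of model SNPs falls
#' below `coverage_min` the result is flagged as discarded.
#'
#' @param object a `cpg_model`.
#' @param panel a [genotype_panel()].
#' @param coverage_min minimum matched-SNP fraction (default 0.5).
#' @param policy allele-matching policy, see [harmonize_alleles()].
#' @param ... unused.
#' @return Named numeric vector of estimates (one per sample) with
#'   attributes `coverage` and `discarded`.
#' @export
predict.cpg_model <- function(object, panel, coverage_min = 0.5,
                              policy = "allow-swap", ...) {
  h <- harmonize_alleles(object, panel, policy = policy)
  m <- h$matched
  n <- length(panel$sample_ids)
  if (nrow(m) == 0) {
    est <- rep(object$intercept, n)
  } else {
    D <- mean_impute(panel$dosages[, m$ext_index, drop = FALSE])
    D[, m$sign < 0] <- 2 - D[, m$sign < 0, drop = FALSE]
    est <- object$intercept + as.numeric(D %*% m$weight)
  }
  names(est) <- panel$sample_ids
  attr(est, "coverage") <- h$coverage
  attr(est, "discarded") <- is.na(h$coverage) || h$coverage < coverage_min
  est
}

#' Predict genetically estimated methylation for all models
#'
#' @param object a `cis_model_set`.
#' @param panel a [genotype_panel()].
#' @param coverage_min minimum matched-SNP fraction per model (default 0.5).
#' @param policy allele-matching policy.
#' @param ... unused.
#' @return Samples-by-models matrix of estimates with attributes `coverage`
#'   (per-model matched fraction) and `discarded` (logical per model).
#' @export
predict.cis_model_set <- function(object, panel, coverage_min = 0.5,
                                  policy = "allow-swap", ...) {
  ests <- lapply(object$models, predict, panel = panel,
                 coverage_min = coverage_min, policy = policy)
  out <- do.call(cbind, lapply(ests, as.numeric))
  rownames(out) <- panel$sample_ids
  colnames(out) <- names(object$models)
  attr(out, "coverage") <- vapply(ests, attr, 0, "coverage")
  attr(out, "discarded") <- vapply(ests, attr, TRUE, "discarded")
  out
}

#' Individual-level association of an estimate with a trait
#'
#' Pearson correlation test between the genetic methylation estimate and a
#' trait: `T = r * sqrt(n - 2) / sqrt(1 - r^2)`, two-sided p from the t
#' distribution with `n - 2` degrees of freedom (capped below at the
#' smallest positive double).
#'
#' @param estimate numeric vector of genetic methylation estimates.
#' @param trait numeric trait vector, aligned with `estimate`.
#' @return List of class `assoc_result`: `statistic`, `p`, `r`, `n_eff`,
#'   `method = "individual"`.
#' @export
associate_trait <- function(estimate, trait) {
  ok <- !is.na(estimate) & !is.na(trait)
  if (sum(ok) < 4) stop("need >= 4 paired non-missing values")
  e <- estimate[ok]; y <- trait[ok]
  if (stats::sd(e) == 0 || stats::sd(y) == 0)
    stop("constant estimate or trait")
  r <- stats::cor(e, y)
  tp <- cor_test_tp(r, length(e))
  structure(list(statistic = tp$t, p = tp$p, r = r, n_eff = length(e),
                 method = "individual"), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(x$method, "association: statistic =", signif(x$statistic, 4),
      ", p =", format(x$p, digits = 3))
  if (!is.null(x$n_eff)) cat(", n =", x$n_eff)
  if (!is.null(x$coverage)) cat(", coverage =", signif(x$coverage, 3))
  cat("\n")
  invisible(x)
}

#' Build a model's SNP covariance from a genotype panel
#'
#' Sample covariance (n-1 denominator) of the model's allele-harmonized
#' dosage columns, typically from an external reference panel. The
#' shrinkage parameter `lambda_s` is stored but not yet applied: the shrunk
#' denominator `sigma_gref = sqrt(W' (Sigma + lambda_s * diag(Sigma)) W)`
#' is computed on demand by the association statistics. A matched SNP with
#' zero variance keeps its zero row/column (its term contributes nothing).
#'
#' @param model a `cpg_model`.
#' @param panel a [genotype_panel()] with >= 2 samples.
#' @param lambda_s diagonal shrinkage (default 0.1).
#' @param policy allele-matching policy.
#' @return List of class `covariance_panel`: `cpg_id`, `snp_id` (matched
#'   model SNPs), `sigma` (covariance matrix), `sd` (its square-root
#'   diagonal), `lambda_s`, `source` tag, `n` (panel size).
#' @export
build_covariance <- function(model, panel, lambda_s = 0.1,
                             policy = "allow-swap") {
  stopifnot(length(panel$sample_ids) >= 2, lambda_s >= 0)
  h <- harmonize_alleles(model, panel, policy = policy)
  m <- h$matched
  D <- mean_impute(panel$dosages[, m$ext_index, drop = FALSE])
  D[, m$sign < 0] <- 2 - D[, m$sign < 0, drop = FALSE]
  sigma <- stats::cov(D)
  zero_var <- diag(sigma) == 0
  if (any(zero_var))
    warning(sum(zero_var), " matched SNP(s) with zero variance retained")
  dimnames(sigma) <- list(m$snp_id, m$snp_id)
  structure(list(cpg_id = model$cpg_id, snp_id = m$snp_id, sigma = sigma,
                 sd = sqrt(diag(sigma)), lambda_s = lambda_s,
                 source = "reference", n = length(panel$sample_ids)),
            class = "covariance_panel")
}

## sqrt(w' (Sigma + lambda_s diag Sigma) w) over the given SNP subset
sigma_g_shrunk <- function(cov, snp_id, w, lambda_s = cov$lambda_s) {
  i <- match(snp_id, cov$snp_id)
  S <- cov$sigma[i, i, drop = FALSE]
  S <- S + lambda_s * diag(diag(S), nrow = nrow(S))
  val <- as.numeric(t(w) %*% S %*% w)
  sqrt(max(val, 0))
}

#' Summary-statistics association z-score with reference covariance
#'
#' Approximates the individual-level statistic from GWAS summary z-scores:
#' `Z_g = sum_k w_k * (sigma_k / sigma_gref) * z_k`, where `sigma_k` are
#' unshrunk reference-panel dosage SDs and `sigma_gref = sqrt(W' (Sigma +
#' lambda_s * diag(Sigma)) W)` applies the diagonal shrinkage in the
#' denominator only. The statistic is computed over the model SNPs present
#' in both the GWAS table and the covariance panel (the truncated model's
#' own association); coverage is reported relative to the full model.
#'
#' @param model a `cpg_model`.
#' @param gwas a [gwas_summary()].
#' @param cov a [build_covariance()] result for this model.
#' @param policy allele-matching policy for the GWAS side.
#' @return List of class `assoc_result`: `statistic` (Z), two-sided normal
#'   `p`, `coverage`, `n_snps`, `method = "sumstat"`.
#' @export
sumstat_z <- function(model, gwas, cov, policy = "allow-swap") {
  h <- harmonize_alleles(model, gwas, policy = policy)
  m <- h$matched
  m <- m[m$snp_id %in% cov$snp_id, , drop = FALSE]
  n_model <- nrow(model$weights)
  coverage <- if (n_model > 0) nrow(m) / n_model else NA_real_
  if (nrow(m) == 0)
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          coverage = coverage, n_snps = 0L,
                          method = "sumstat"), class = "assoc_result"))
  z <- gwas$z[m$ext_index] * m$sign
  sd_k <- cov$sd[match(m$snp_id, cov$snp_id)]
  s_g <- sigma_g_shrunk(cov, m$snp_id, m$weight)
  if (s_g == 0)
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          coverage = coverage, n_snps = nrow(m),
                          method = "sumstat"), class = "assoc_result"))
  Z <- sum(m$weight * sd_k / s_g * z)
  p <- max(2 * stats::pnorm(abs(Z), lower.tail = FALSE),
           .Machine$double.xmin)
  structure(list(statistic = Z, p = p, coverage = coverage,
                 n_snps = nrow(m), method = "sumstat"),
            class = "assoc_result")
}

#' Exact summary-statistics association statistic
#'
#' The unapproximated statistic, requiring the study sample's own
#' covariance (no shrinkage) and per-SNP/estimator phenotypic variance
#' fractions: `T_g = sum_k w_k * (sigma_k / sigma_g) * z_k *
#' sqrt((1 - R_k^2) / (1 - R_g^2))`. With the marginal statistics, the
#' variance fractions, and the covariance all taken from the same sample as
#' the trait, this equals the individual-level correlation-test statistic.
#'
#' @param model a `cpg_model`.
#' @param gwas a [gwas_summary()] carrying `r2` (per-SNP phenotypic
#'   variance fraction).
#' @param cov a [build_covariance()] result from the study sample with
#'   `lambda_s = 0`.
#' @param r2_g phenotypic variance fraction of the estimator, in \[0, 1).
#' @param policy allele-matching policy.
#' @return List of class `assoc_result` with `method = "exact"` and the
#'   two-sided normal p-value.
#' @export
exact_z <- function(model, gwas, cov, r2_g, policy = "allow-swap") {
  if (r2_g >= 1 || r2_g < 0) stop("r2_g must lie in [0, 1)")
  if (cov$lambda_s != 0)
    warning("exact statistic expects an unshrunk sample covariance")
  h <- harmonize_alleles(model, gwas, policy = policy)
  m <- h$matched
  m <- m[m$snp_id %in% cov$snp_id, , drop = FALSE]
  if (nrow(m) == 0) stop("no matched SNPs")
  z <- gwas$z[m$ext_index] * m$sign
  r2_k <- gwas$r2[m$ext_index]
  if (any(is.na(r2_k))) {
    n_k <- gwas$n[m$ext_index]
    if (any(is.na(n_k)))
      stop("exact statistic needs per-SNP r2 or sample size n")
    r2_k <- z^2 / (z^2 + n_k - 2)
  }
  sd_k <- cov$sd[match(m$snp_id, cov$snp_id)]
  s_g <- sigma_g_shrunk(cov, m$snp_id, m$weight, lambda_s = 0)
  if (s_g == 0) stop("estimator has zero variance in the sample")
  Tg <- sum(m$weight * sd_k / s_g * z * sqrt((1 - r2_k) / (1 - r2_g)))
  p <- max(2 * stats::pnorm(abs(Tg), lower.tail = FALSE),
           .Machine$double.xmin)
  structure(list(statistic = Tg, p = p, coverage = h$coverage,
                 n_snps = nrow(m), method = "exact"),
            class = "assoc_result")
}

#' Genome-wide summary-statistics scan
#'
#' Runs [sumstat_z()] for every model in a set against one GWAS. Models
#' with GWAS SNP coverage below `coverage_min` are excluded and counted.
#' The Bonferroni threshold is `alpha / n_retained`.
#'
#' @param models a `cis_model_set`.
#' @param gwas a [gwas_summary()].
#' @param ref_panel reference [genotype_panel()] supplying covariances.
#' @param coverage_min minimum GWAS SNP coverage (default 0.8).
#' @param alpha family-wise error target (default 0.05).
#' @param lambda_s diagonal shrinkage (default 0.1).
#' @param policy allele-matching policy.
#' @return Data.frame ordered by chromosome and position: `cpg_id`, `chr`,
#'   `pos`, `n_snps`, `coverage`, `statistic`, `p`, `bonferroni_sig`; with
#'   attributes `threshold`, `n_retained`, `n_low_coverage`.
#' @export
scan_gwas <- function(models, gwas, ref_panel, coverage_min = 0.8,
                      alpha = 0.05, lambda_s = 0.1, policy = "allow-swap") {
  rows <- list()
  n_low <- 0L
  for (m in models$models) {
    h <- harmonize_alleles(m, gwas, policy = policy)
    if (is.na(h$coverage) || h$coverage < coverage_min) {
      n_low <- n_low + 1L
      next
    }
    cov <- build_covariance(m, ref_panel, lambda_s = lambda_s,
                            policy = policy)
    res <- sumstat_z(m, gwas, cov, policy = policy)
    rows[[m$cpg_id]] <- data.frame(
      cpg_id = m$cpg_id, chr = m$chr, pos = m$pos,
      n_snps = m$n_selected_snps, coverage = res$coverage,
      statistic = res$statistic, p = res$p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    message("no models retained at coverage >= ", coverage_min)
    out <- data.frame(cpg_id = character(), chr = character(),
                      pos = integer(), n_snps = integer(),
                      coverage = double(), statistic = double(),
                      p = double(), bonferroni_sig = logical())
    attr(out, "threshold") <- NA_real_
    attr(out, "n_retained") <- 0L
    attr(out, "n_low_coverage") <- n_low
    return(out)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- out[order(out$chr, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  thr <- bonferroni_threshold(nrow(out), alpha)
  out$bonferroni_sig <- !is.na(out$p) & out$p < thr
  attr(out, "threshold") <- thr
  attr(out, "n_retained") <- nrow(out)
  attr(out, "n_low_coverage") <- n_low
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' @param n_tests number of tests (>= 1).
#' @param alpha family-wise error target (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with cumulative-minimum enforcement
#' (`stats::p.adjust(method = "BH")`).
#'
#' @param p vector of p-values in \[0, 1\] (`NA` allowed).
#' @return Adjusted p-values, same length.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
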