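#' Quality-control threshold configuration
#'
#' Defaults follow the training-stage convention: MAF > 0.05, HWE p > 1e-4,
#' imputation R2 > 0.8, per-SNP call rate > 0.95 and per-CpG missing rate
#' below 5%. A looser evaluation-stage convention (MAF > 0.01, imputation
#' R2 > 0.5) is available via `preset = "evaluation"`. All "pass" rules are
#' strict inequalities: a value exactly at the threshold fails.
#'
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg equilibrium p-value.
#' @param imp_r2_min minimum imputation quality (skipped when absent).
#' @param call_rate_min minimum per-SNP call rate.
#' @param cpg_missing_max maximum per-CpG missing rate (rule: `>=` fails).
#' @param detection_p_max maximum detection p (mask assumed pre-applied).
#' @param preset `"training"` or `"evaluation"` default set.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(maf_min = NULL, hwe_p_min = 1e-4,
                          imp_r2_min = NULL, call_rate_min = 0.95,
                          cpg_missing_max = 0.05, detection_p_max = 0.05,
                          preset = c("training", "evaluation")) {
  preset <- match.arg(preset)
  if (is.null(maf_min)) maf_min <- if (preset == "training") 0.05 else 0.01
  if (is.null(imp_r2_min)) imp_r2_min <- if (preset == "training") 0.8 else 0.5
  stopifnot(maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1,
            imp_r2_min >= 0, imp_r2_min <= 1, call_rate_min >= 0,
            call_rate_min <= 1, cpg_missing_max >= 0, cpg_missing_max <= 1)
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 imp_r2_min = imp_r2_min, call_rate_min = call_rate_min,
                 cpg_missing_max = cpg_missing_max,
                 detection_p_max = detection_p_max),
            class = "filter_config")
}

#' Convert methylation beta-values to M-values
#'
#' `m = log2(beta / (1 - beta))`, elementwise. Values at exactly 0 or 1 are
#' clamped to `[eps, 1 - eps]` first, with a warning giving the count.
#'
#' @param x numeric vector/matrix of beta-values, or a beta-scale
#'   [methylation_panel()].
#' @param eps clamping bound (default 1e-6).
#' @return The M-values, same shape as the input; for a panel, a panel with
#'   scale `"m"`.
#' @export
beta_to_m <- function(x, eps = 1e-6) {
  if (inherits(x, "methylation_panel")) {
    if (x$scale != "beta") stop("panel is not on the beta scale")
    x$values <- beta_to_m(x$values, eps)
    x$scale <- "m"
    return(x)
  }
  n_clamp <- sum(x <= 0 | x >= 1, na.rm = TRUE)
  if (n_clamp > 0)
    warning(n_clamp, " beta value(s) at or beyond {0, 1} clamped")
  b <- pmin(pmax(x, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (is.matrix(x)) dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Residualize a matrix against covariates
#'
#' Replaces each column by its least-squares residual against an intercept
#' plus the covariates. Categorical covariates are one-hot encoded dropping
#' one level. Missing entries in a column are preserved as missing; the
#' regression for that column uses its complete rows.
#'
#' @param values numeric matrix (samples x features) or a
#'   [methylation_panel()] (scale becomes `"adjusted"`).
#' @param covariates data.frame of covariates aligned with the rows, or
#'   `NULL`/empty for intercept-only (mean centering).
#' @return The residualized matrix (or panel).
#' @export
residualize <- function(values, covariates = NULL) {
  if (inherits(values, "methylation_panel")) {
    values$values <- residualize(values$values, covariates)
    values$scale <- "adjusted"
    return(values)
  }
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    X <- matrix(1, n, 1)
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      stop("covariate rows do not match value rows")
    X <- stats::model.matrix(~ ., data = covariates)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("covariate design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  out <- values
  complete <- !is.na(values)
  all_complete <- all(complete)
  if (all_complete) {
    out[] <- qr.resid(qr_x, values)
  } else {
    for (j in seq_len(ncol(values))) {
      obs <- complete[, j]
      if (all(obs)) {
        out[, j] <- qr.resid(qr_x, values[, j])
      } else {
        fit <- stats::lm.fit(X[obs, , drop = FALSE], values[obs, j])
        out[obs, j] <- fit$residuals
      }
    }
  }
  out
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the genotype counts against the
#' expected proportions (p^2, 2pq, q^2) with the allele frequency estimated
#' from the counts. Monomorphic input returns p = 1 by convention. For
#' imputed dosages, round to hard calls before counting.
#'
#' @param counts integer vector `(n_AA, n_Aa, n_aa)`.
#' @return The p-value.
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("empty genotype counts")
  p <- (2 * counts[1] + counts[2]) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Filter SNPs on MAF, HWE, imputation quality and call rate
#'
#' Retains SNPs passing all of: `maf > maf_min`, HWE p (`hwe_test` on
#' rounded hard calls) `> hwe_p_min`, `imp_r2 > imp_r2_min` (skipped when
#' imputation quality is absent), `call_rate > call_rate_min`. A SNP failing
#' several rules is counted once, under the first failing criterion in the
#' order maf, hwe, imp_r2, call_rate.
#'
#' @param panel a [genotype_panel()].
#' @param cfg a [filter_config()].
#' @return The filtered panel, with an `exclusions` attribute giving
#'   per-criterion counts.
#' @export
filter_snps <- function(panel, cfg = filter_config()) {
  v <- panel$variants
  hard <- round(panel$dosages)
  hwe_p <- vapply(seq_len(ncol(hard)), function(j) {
    g <- hard[, j]
    hwe_test(c(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
               sum(g == 2, na.rm = TRUE)))
  }, 0)
  fail_maf <- !(v$maf > cfg$maf_min)
  fail_hwe <- !(hwe_p > cfg$hwe_p_min)
  fail_imp <- !is.na(v$imp_r2) & !(v$imp_r2 > cfg$imp_r2_min)
  fail_cr <- !(v$call_rate > cfg$call_rate_min)
  first_fail <- rep(NA_character_, nrow(v))
  first_fail[fail_cr] <- "call_rate"
  first_fail[fail_imp] <- "imp_r2"
  first_fail[fail_hwe] <- "hwe"
  first_fail[fail_maf] <- "maf"
  keep <- is.na(first_fail)
  out <- subset(panel, snps = which(keep))
  attr(out, "exclusions") <- c(
    maf = sum(first_fail == "maf", na.rm = TRUE),
    hwe = sum(first_fail == "hwe", na.rm = TRUE),
    imp_r2 = sum(first_fail == "imp_r2", na.rm = TRUE),
    call_rate = sum(first_fail == "call_rate", na.rm = TRUE))
  out
}

#' Filter CpG probes
#'
#' Drops CpGs listed in an exclusion table (e.g. probes in non-CpG context
#' or overlapping a SNP, supplied from array annotation), non-autosomal
#' CpGs, and CpGs with missing rate at or above `cpg_missing_max`.
#'
#' @param panel a [methylation_panel()].
#' @param exclusion_ids character vector of CpG ids to drop (may be empty).
#' @param cfg a [filter_config()].
#' @return The filtered panel.
#' @export
filter_cpgs <- function(panel, exclusion_ids = character(),
                        cfg = filter_config()) {
  cp <- panel$cpgs
  autosomes <- as.character(c(1:22, paste0("chr", 1:22)))
  keep <- !(cp$id %in% exclusion_ids) &
    cp$chr %in% autosomes &
    cp$missing_rate < cfg$cpg_missing_max
  methylation_panel(panel$values[, keep, drop = FALSE],
                    cp[keep, c("id", "chr", "pos"), drop = FALSE],
                    scale = panel$scale, sample_ids = panel$sample_ids)
}

#' k-nearest-neighbour imputation of missing methylation values
#'
#' Each missing entry is replaced by the mean, over that sample, of the `k`
#' CpGs closest to the target CpG in Euclidean distance. Distances are
#' computed over samples observed in both CpGs and rescaled by the shared
#' count; CpG pairs with no shared observations are not neighbours. When a
#' CpG has fewer than `k` usable neighbours with an observed value in the
#' needed sample, the column mean is used with a warning.
#'
#' @param panel a [methylation_panel()] (every CpG needs >= 1 observed value).
#' @param k neighbour count (default 10).
#' @return The panel with all missing values filled; observed values are
#'   untouched.
#' @export
knn_impute_cpg <- function(panel, k = 10) {
  vals <- panel$values
  miss <- is.na(vals)
  if (!any(miss)) return(panel)
  if (any(colSums(!miss) == 0))
    stop("a CpG has no observed values; cannot impute")
  p <- ncol(vals)
  fallback <- 0L
  col_means <- colMeans(vals, na.rm = TRUE)
  for (j in which(colSums(miss) > 0)) {
    ## scaled squared distance to every other CpG over shared observed rows
    d2 <- rep(Inf, p)
    xj <- vals[, j]
    for (l in seq_len(p)) {
      if (l == j) next
      sh <- !miss[, j] & !miss[, l]
      ns <- sum(sh)
      if (ns == 0) next
      d2[l] <- sum((xj[sh] - vals[sh, l])^2) / ns
    }
    ord <- order(d2)
    for (i in which(miss[, j])) {
      neigh <- ord[!miss[i, ord] & is.finite(d2[ord])]
      if (length(neigh) >= k) {
        vals[i, j] <- mean(vals[i, neigh[seq_len(k)]])
      } else {
        fallback <- fallback + 1L
        vals[i, j] <- col_means[j]
      }
    }
  }
  if (fallback > 0)
    warning(fallback, " entr(ies) imputed by column mean: fewer than k ",
            "usable neighbours")
  methylation_panel(vals, panel$cpgs[, c("id", "chr", "pos")],
                    scale = panel$scale, sample_ids = panel$sample_ids)
}
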