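#' Elastic-net fitting configuration
#'
#' The penalized objective is `(1/(2n))||y - b0 - Xb||^2 +
#' lambda * (alpha*||b||_1 + ((1-alpha)/2)*||b||^2)`, with predictors
#' standardized internally and coefficients reported on the original dosage
#' scale. The mixing parameter defaults to 0.5 and the penalty strength is
#' chosen by 10-fold cross-validation.
#'
#' @param alpha elastic-net mixing parameter in \[0, 1\] (default 0.5).
#' @param n_folds cross-validation folds (default 10).
#' @param lambda_rule `"min-cv-error"` (lambda minimizing CV mean squared
#'   error; default) or `"one-se"`.
#' @param seed seed controlling fold assignment.
#' @param standardize standardize predictors internally (default `TRUE`).
#' @param lambda optional fixed penalty; when given, cross-validation is
#'   skipped and CV performance is unavailable.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(alpha = 0.5, n_folds = 10,
                        lambda_rule = c("min-cv-error", "one-se"),
                        seed = 1L, standardize = TRUE, lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(alpha >= 0, alpha <= 1, n_folds >= 2)
  structure(list(alpha = alpha, n_folds = n_folds, lambda_rule = lambda_rule,
                 seed = as.integer(seed), standardize = standardize,
                 lambda = lambda),
            class = "enet_config")
}

## run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## two-sided correlation-test t statistic and p-value
cor_test_tp <- function(r, n) {
  df <- n - 2
  denom <- 1 - r^2
  if (denom <= 0) {
    t <- sign(r) * Inf
    p <- .Machine$double.xmin
  } else {
    t <- r * sqrt(df) / sqrt(denom)
    p <- max(2 * stats::pt(abs(t), df, lower.tail = FALSE),
             .Machine$double.xmin)
  }
  list(t = t, p = p)
}

mean_impute <- function(X) {
  nas <- which(is.na(X))
  if (length(nas) == 0) return(X)
  cm <- colMeans(X, na.rm = TRUE)
  X[nas] <- cm[((nas - 1) %/% nrow(X)) + 1]
  X
}

#' Cis-window SNP lookup
#'
#' SNPs on the CpG's chromosome with position inside the closed interval
#' `[pos - window_bp, pos + window_bp]`, in position order.
#'
#' @param cpg list or one-row data.frame with `chr` and `pos`.
#' @param panel a [genotype_panel()].
#' @param window_bp half-window in bp (default 1e6).
#' @return Integer indices into `panel$variants`.
#' @export
cis_window <- function(cpg, panel, window_bp = 1e6) {
  v <- panel$variants
  idx <- which(v$chr == as.character(cpg$chr) &
                 v$pos >= cpg$pos - window_bp &
                 v$pos <= cpg$pos + window_bp)
  idx[order(v$pos[idx])]
}

#' Fit one CpG's elastic-net genetic model
#'
#' Fits the penalized regression of adjusted methylation on cis-SNP dosages.
#' Missing dosages are mean-imputed per SNP and constant columns dropped
#' before fitting. The penalty is tuned by cross-validation (fold assignment
#' from `cfg$seed`); the cross-validation estimate for each sample comes
#' from the fold model not trained on it (prevalidation), and `cv_r2` is the
#' squared Pearson correlation between that estimate and the observed
#' values. A fit selecting zero SNPs at the chosen penalty is a null model
#' and returns `NULL`.
#'
#' @param X dosage submatrix (samples x cis-SNPs), column-named by SNP id.
#' @param y adjusted methylation vector.
#' @param cfg an [enet_config()].
#' @return `NULL` for a null model, otherwise a list with `intercept`,
#'   `weights` (named vector over selected SNPs), `cv_estimate`, `cv_r2`,
#'   `cv_p`.
#' @export
fit_elastic_net <- function(X, y, cfg = enet_config()) {
  X <- mean_impute(as.matrix(X))
  if (stats::sd(y) == 0) return(NULL)
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 1) return(NULL)
  if (ncol(X) == 1) {
    ## glmnet needs >= 2 columns; pad with a zero column it cannot select
    X <- cbind(X, `..pad..` = 0)
  }
  n <- nrow(X)
  if (!is.null(cfg$lambda)) {
    fit <- glmnet::glmnet(X, y, alpha = cfg$alpha, lambda = cfg$lambda,
                          standardize = cfg$standardize)
    b <- as.numeric(fit$beta)
    names(b) <- colnames(X)
    nz <- b != 0
    if (!any(nz)) return(NULL)
    return(list(intercept = as.numeric(fit$a0), weights = b[nz],
                cv_estimate = NULL, cv_r2 = NA_real_, cv_p = NA_real_))
  }
  foldid <- with_seed(cfg$seed,
                      sample(rep(seq_len(cfg$n_folds), length.out = n)))
  cvfit <- glmnet::cv.glmnet(X, y, alpha = cfg$alpha, foldid = foldid,
                             keep = TRUE, standardize = cfg$standardize)
  s <- if (cfg$lambda_rule == "min-cv-error") cvfit$lambda.min
       else cvfit$lambda.1se
  idx <- which.min(abs(cvfit$lambda - s))
  b <- as.numeric(cvfit$glmnet.fit$beta[, idx])
  names(b) <- colnames(X)
  nz <- b != 0
  if (!any(nz)) return(NULL)
  preval <- cvfit$fit.preval[, idx]
  if (stats::sd(preval) == 0) {
    cv_r2 <- 0
    cv_p <- 1
  } else {
    r <- stats::cor(preval, y)
    tp <- cor_test_tp(r, n)
    cv_r2 <- r^2
    cv_p <- tp$p
  }
  list(intercept = as.numeric(cvfit$glmnet.fit$a0[idx]), weights = b[nz],
       cv_estimate = preval, cv_r2 = cv_r2, cv_p = cv_p)
}

#' Construct a CpG model by hand
#'
#' Normally models come from [fit_cis_models()]; this constructor builds one
#' directly, e.g. for models imported from elsewhere.
#'
#' @param cpg_id,chr,pos CpG identity and coordinates.
#' @param intercept model intercept (M-units).
#' @param weights data.frame with `snp_id`, `chr`, `pos`, `effect_allele`,
#'   `other_allele`, `weight` (M-units per effect-allele count).
#' @param n_candidate_snps candidate cis-SNP count (default: rows of
#'   `weights`).
#' @return An object of class `cpg_model`.
#' @export
cpg_model <- function(cpg_id, chr, pos, intercept, weights,
                      n_candidate_snps = nrow(weights)) {
  weights <- as.data.frame(weights, stringsAsFactors = FALSE)
  req <- c("snp_id", "chr", "pos", "effect_allele", "other_allele", "weight")
  miss <- setdiff(req, names(weights))
  if (length(miss) > 0)
    stop("weights missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(weights) < 1) stop("null models are not stored")
  structure(list(cpg_id = cpg_id, chr = as.character(chr),
                 pos = as.integer(pos), intercept = intercept,
                 weights = weights, n_candidate_snps = n_candidate_snps,
                 n_selected_snps = nrow(weights)),
            class = "cpg_model")
}

new_cis_model_set <- function(models, performance, meta) {
  structure(list(models = models, performance = performance, meta = meta),
            class = "cis_model_set")
}

#' Fit per-CpG elastic-net genetic models across a methylation panel
#'
#' The central fitter: for every CpG with at least `min_cis_snps` cis-SNPs,
#' fits the elastic-net additive model of adjusted methylation on cis-SNP
#' dosages ([fit_elastic_net()]). CpGs yielding a null model (no SNP
#' selected at the tuned penalty) are counted but not stored.
#'
#' @param meth an adjusted-scale [methylation_panel()].
#' @param geno a [genotype_panel()] on the same samples (matched by id).
#' @param cfg an [enet_config()].
#' @param window_bp cis half-window in bp (default 1e6).
#' @param min_cis_snps minimum candidate cis-SNPs for eligibility
#'   (default 2: a CpG must be encompassed by more than one cis-SNP).
#' @param verbose print per-CpG progress.
#' @return A `cis_model_set`: list of `cpg_model`s plus a `performance`
#'   data.frame (`cpg_id`, `chr`, `pos`, `n_snps`, `n_candidate`,
#'   `intercept`, `cv_r2`, `cv_p`, and test columns filled by
#'   [evaluate_models()]) and provenance metadata.
#' @seealso [predict.cis_model_set()], [evaluate_models()],
#'   [select_robust_models()]
#' @export
fit_cis_models <- function(meth, geno, cfg = enet_config(),
                           window_bp = 1e6, min_cis_snps = 2,
                           verbose = FALSE) {
  stopifnot(inherits(meth, "methylation_panel"),
            inherits(geno, "genotype_panel"))
  common <- intersect(meth$sample_ids, geno$sample_ids)
  if (length(common) < cfg$n_folds)
    stop("need at least n_folds overlapping samples")
  mi <- match(common, meth$sample_ids)
  gi <- match(common, geno$sample_ids)
  models <- list()
  rows <- list()
  n_null <- 0L
  for (ci in seq_len(nrow(meth$cpgs))) {
    cpg <- meth$cpgs[ci, ]
    snp_idx <- cis_window(cpg, geno, window_bp)
    if (length(snp_idx) < min_cis_snps) { n_null <- n_null + 1L; next }
    X <- geno$dosages[gi, snp_idx, drop = FALSE]
    y <- meth$values[mi, ci]
    fit <- fit_elastic_net(X, y, cfg)
    if (is.null(fit)) { n_null <- n_null + 1L; next }
    wsel <- match(names(fit$weights), geno$variants$id)
    vv <- geno$variants[wsel, ]
    model <- structure(list(
      cpg_id = cpg$id, chr = cpg$chr, pos = cpg$pos,
      intercept = fit$intercept,
      weights = data.frame(snp_id = vv$id, chr = vv$chr, pos = vv$pos,
                           effect_allele = vv$effect_allele,
                           other_allele = vv$other_allele,
                           weight = unname(fit$weights),
                           stringsAsFactors = FALSE),
      n_candidate_snps = length(snp_idx),
      n_selected_snps = length(fit$weights)), class = "cpg_model")
    models[[cpg$id]] <- model
    rows[[cpg$id]] <- data.frame(
      cpg_id = cpg$id, chr = cpg$chr, pos = cpg$pos,
      n_snps = length(fit$weights), n_candidate = length(snp_idx),
      intercept = fit$intercept, cv_r2 = fit$cv_r2, cv_p = fit$cv_p,
      test_r2 = NA_real_, test_p = NA_real_, test_sign = NA_real_,
      stringsAsFactors = FALSE)
    if (verbose)
      message(cpg$id, ": ", length(fit$weights), "/", length(snp_idx),
              " SNPs, cv_r2 = ", signif(fit$cv_r2, 3))
  }
  perf <- if (length(rows) > 0) do.call(rbind, c(rows, make.row.names = FALSE))
          else data.frame(cpg_id = character(), chr = character(),
                          pos = integer(), n_snps = integer(),
                          n_candidate = integer(), intercept = double(),
                          cv_r2 = double(), cv_p = double(),
                          test_r2 = double(), test_p = double(),
                          test_sign = double())
  meta <- list(window_bp = window_bp, alpha = cfg$alpha,
               n_folds = cfg$n_folds, lambda_rule = cfg$lambda_rule,
               seed = cfg$seed, n_null = n_null,
               package = "cismeth",
               version = as.character(utils::packageVersion("cismeth")))
  new_cis_model_set(models, perf, meta)
}

#' @export
print.cis_model_set <- function(x, ...) {
  cat("cis_model_set:", length(x$models), "CpG models (",
      x$meta$n_null, "null fits not stored)\n")
  cat("  alpha =", x$meta$alpha, "| folds =", x$meta$n_folds,
      "| window =", format(x$meta$window_bp, big.mark = ","), "bp\n")
  if (nrow(x$performance) > 0)
    cat("  mean cv_r2 =", signif(mean(x$performance$cv_r2, na.rm = TRUE), 3),
        "| mean selected SNPs =",
        signif(mean(x$performance$n_snps), 3), "\n")
  invisible(x)
}

#' @export
summary.cis_model_set <- function(object, ...) {
  perf <- object$performance
  out <- list(n_models = length(object$models), n_null = object$meta$n_null,
              cv_r2 = summary(perf$cv_r2),
              test_r2 = if (all(is.na(perf$test_r2))) NULL
                        else summary(perf$test_r2),
              n_snps = summary(perf$n_snps))
  class(out) <- "summary.cis_model_set"
  out
}

#' @export
print.summary.cis_model_set <- function(x, ...) {
  cat("Models stored:", x$n_models, "(null fits:", x$n_null, ")\n")
  cat("Selected SNPs per model:\n"); print(x$n_snps)
  cat("Cross-validation r2:\n"); print(x$cv_r2)
  if (!is.null(x$test_r2)) { cat("Test r2:\n"); print(x$test_r2) }
  invisible(x)
}

#' @export
coef.cpg_model <- function(object, ...) {
  stats::setNames(c(object$intercept, object$weights$weight),
                  c("(Intercept)", object$weights$snp_id))
}

#' @export
print.cpg_model <- function(x, ...) {
  cat("cpg_model", x$cpg_id, "(", x$chr, ":", x$pos, ") —",
      x$n_selected_snps, "of", x$n_candidate_snps, "cis-SNPs selected\n")
  invisible(x)
}

#' @export
coef.cis_model_set <- function(object, ...) {
  do.call(rbind, c(lapply(object$models, function(m)
    data.frame(cpg_id = m$cpg_id, snp_id = m$weights$snp_id,
               weight = m$weights$weight, stringsAsFactors = FALSE)),
    make.row.names = FALSE))
}

#' Evaluate models on an independent test panel
#'
#' Computes the genetic methylation estimate on the test genotypes and
#' correlates it with the observed adjusted methylation: `test_r2` is the
#' squared Pearson correlation, `test_sign` its sign, `test_p` the two-sided
#' correlation-test p-value. Models whose estimate has zero variance on the
#' test panel (e.g. all model SNPs absent) get `NA` performance.
#'
#' @param models a `cis_model_set`.
#' @param geno test [genotype_panel()].
#' @param meth test [methylation_panel()] (adjusted scale).
#' @return The model set with test columns of `performance` filled.
#' @export
evaluate_models <- function(models, geno, meth) {
  common <- intersect(meth$sample_ids, geno$sample_ids)
  if (length(common) < 3) stop("need >= 3 overlapping samples")
  mi <- match(common, meth$sample_ids)
  perf <- models$performance
  est <- predict(models, geno, coverage_min = 0)
  for (i in seq_len(nrow(perf))) {
    cid <- perf$cpg_id[i]
    ci <- match(cid, meth$cpgs$id)
    if (is.na(ci)) next
    e <- est[match(common, rownames(est)), cid]
    y <- meth$values[mi, ci]
    if (stats::sd(e) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(e, y)
    tp <- cor_test_tp(r, length(common))
    perf$test_r2[i] <- r^2
    perf$test_p[i] <- tp$p
    perf$test_sign[i] <- sign(r)
  }
  models$performance <- perf
  models
}

#' Select robust models by double FDR and sign criteria
#'
#' A model is retained when (1) its Benjamini-Hochberg-adjusted
#' cross-validation p-value, adjusted across all stored (non-null) models,
#' is below `fdr_q`; (2) among those survivors, its BH-adjusted test
#' p-value is below `fdr_q`; and (3) the test correlation is positive.
#'
#' @param models a `cis_model_set` with test performance filled, or its
#'   `performance` data.frame.
#' @param fdr_q false-discovery-rate threshold (default 0.05).
#' @return Character vector of retained CpG ids.
#' @export
select_robust_models <- function(models, fdr_q = 0.05) {
  perf <- if (inherits(models, "cis_model_set")) models$performance
          else models
  if (nrow(perf) == 0) return(character())
  q1 <- bh_adjust(perf$cv_p)
  c1 <- !is.na(q1) & q1 < fdr_q
  surv <- perf[c1, , drop = FALSE]
  if (nrow(surv) == 0) return(character())
  q2 <- bh_adjust(surv$test_p)
  keep <- !is.na(q2) & q2 < fdr_q &
    !is.na(surv$test_sign) & surv$test_sign > 0
  surv$cpg_id[keep]
}

#' Best single-mQTL r-squared for one CpG
#'
#' Squared Pearson correlation between each cis-SNP dosage and the adjusted
#' methylation, returning the maximizing SNP. Ties are broken by lowest
#' position, then lexicographic id.
#'
#' @param X cis-dosage matrix, column-named by SNP id.
#' @param y adjusted methylation vector.
#' @param snp_info data.frame aligned with columns of `X`, with `id`, `pos`.
#' @return List with `snp_id` and `r2`.
#' @export
best_univariate_mqtl <- function(X, y, snp_info = NULL) {
  X <- mean_impute(as.matrix(X))
  sds <- apply(X, 2, stats::sd)
  r2 <- rep(0, ncol(X))
  ok <- sds > 0
  r2[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], y))^2
  if (is.null(snp_info))
    snp_info <- data.frame(id = colnames(X), pos = seq_len(ncol(X)))
  best <- max(r2)
  cand <- which(r2 >= best - 1e-12)
  cand <- cand[order(snp_info$pos[cand], snp_info$id[cand])]
  list(snp_id = snp_info$id[cand[1]], r2 = best)
}

#' Test-performance stability under random marker loss
#'
#' Repeatedly zeroes a random fraction of a model's SNP weights and
#' re-evaluates the test r-squared, emulating markers absent from an
#' external dataset.
#'
#' @param model a `cpg_model` with >= 2 SNPs.
#' @param geno test [genotype_panel()].
#' @param meth test [methylation_panel()].
#' @param drop_frac fraction of model SNPs dropped per replicate
#'   (default 0.10; `ceiling(drop_frac * n_snps)` SNPs are removed).
#' @param reps replicates (default 100).
#' @param seed RNG seed.
#' @return List with `r2` (per-rep vector, `NA` when the reduced estimate is
#'   degenerate), `mean`, and `q05`/`q95` quantiles.
#' @export
stability_under_missingness <- function(model, geno, meth, drop_frac = 0.10,
                                        reps = 100, seed = 1L) {
  stopifnot(inherits(model, "cpg_model"))
  common <- intersect(meth$sample_ids, geno$sample_ids)
  mi <- match(common, meth$sample_ids)
  ci <- match(model$cpg_id, meth$cpgs$id)
  y <- meth$values[mi, ci]
  n_snps <- nrow(model$weights)
  n_drop <- ceiling(drop_frac * n_snps)
  r2 <- with_seed(seed, vapply(seq_len(reps), function(rep) {
    m2 <- model
    if (n_drop > 0) {
      drop <- sample.int(n_snps, n_drop)
      m2$weights <- m2$weights[-drop, , drop = FALSE]
      m2$n_selected_snps <- nrow(m2$weights)
    }
    if (nrow(m2$weights) == 0) return(NA_real_)
    e <- predict(m2, geno, coverage_min = 0)
    e <- e[match(common, names(e))]
    if (stats::sd(e) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(e, y)^2
  }, 0))
  if (all(is.na(r2)))
    return(list(r2 = r2, mean = NA_real_, q05 = NA_real_, q95 = NA_real_))
  list(r2 = r2, mean = mean(r2, na.rm = TRUE),
       q05 = unname(stats::quantile(r2, 0.05, na.rm = TRUE)),
       q95 = unname(stats::quantile(r2, 0.95, na.rm = TRUE)))
}
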