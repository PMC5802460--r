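test_that("cis window is a closed +/- 1 Mbp interval on the same chromosome", {
  v <- data.frame(id = c("in_lo", "in_hi", "out_hi", "other_chr"),
                  chr = c("1", "1", "1", "2"),
                  pos = c(1000000L, 3000000L, 3000001L, 2000000L),
                  effect_allele = "A", other_allele = "G")
  panel <- genotype_panel(matrix(1, 3, 4), v)
  idx <- cis_window(list(chr = "1", pos = 2000000L), panel)
  expect_equal(panel$variants$id[idx], c("in_lo", "in_hi"))
})

test_that("fixed-penalty univariate fit matches the soft-threshold closed form", {
  # x and y standardized (sum(x^2)/n = sum(y^2)/n = 1) with sum(x*y)/n = 0.5;
  # objective (1/(2n))RSS + lambda(alpha|b| + (1-alpha)/2 b^2)
  x <- c(1, -1, 1, -1)
  z <- c(1, 1, -1, -1)
  y <- 0.5 * x + sqrt(0.75) * z
  # brute-force oracle over the 1-d objective
  obj <- function(b) mean((y - b * x)^2) / 2 +
    0.2 * (0.5 * abs(b) + 0.25 * b^2)
  oracle <- optimize(obj, c(-2, 2))$minimum
  expect_equal(oracle, 0.4 / 1.1, tolerance = 1e-4)
  fit <- fit_elastic_net(matrix(x, dimnames = list(NULL, "s1")), y,
                         enet_config(alpha = 0.5, lambda = 0.2,
                                     standardize = FALSE))
  expect_equal(unname(fit$weights["s1"]), 0.5 / 1.1 - 0.1 / 1.1,
               tolerance = 1e-6)
})

test_that("a dominating penalty yields a null model", {
  set.seed(10)
  X <- matrix(rbinom(100 * 10, 2, 0.3), 100, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  y <- rnorm(100)
  expect_null(fit_elastic_net(X, y, enet_config(lambda = 1)))
  # under cross-validation on pure noise, the one-SE rule lands at or near
  # the top of the path: null, or at most a near-zero cv r2
  fit <- fit_elastic_net(X, y, enet_config(seed = 1, lambda_rule = "one-se"))
  expect_true(is.null(fit) || fit$cv_r2 < 0.05)
})

test_that("a noiseless single-SNP signal is recovered in the weak-penalty limit", {
  set.seed(11)
  X <- matrix(rbinom(200 * 5, 2, 0.4), 200, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  y <- X[, 2]
  fit <- fit_elastic_net(X, y, enet_config(lambda = 1e-4))
  expect_equal(unname(fit$weights["s2"]), 1, tolerance = 0.02)
  expect_lt(sum(abs(fit$weights[names(fit$weights) != "s2"])), 0.02)
})

test_that("constant outcomes and constant SNPs are handled", {
  X <- matrix(c(rep(1, 20), rbinom(20, 2, 0.4)), 20, 2,
              dimnames = list(NULL, c("const", "ok")))
  expect_null(fit_elastic_net(X, rep(3, 20), enet_config()))
})

test_that("the fitter stores sparse models with cross-validated performance", {
  models <- fx_models()
  expect_s3_class(models, "cis_model_set")
  perf <- models$performance
  expect_true(all(perf$n_snps >= 1))
  expect_true(all(perf$cv_r2 >= 0 & perf$cv_r2 <= 1))
  # weights live inside the CpG's cis window
  for (m in models$models[1:5]) {
    expect_true(all(m$weights$chr == m$chr))
    expect_true(all(abs(m$weights$pos - m$pos) <= 1e6))
  }
  # cv_r2 (out-of-fold) does not beat the in-sample r2 of the final model
  gt <- fx_train(); me <- fx_meth()
  for (id in names(models$models)[1:10]) {
    e <- as.numeric(predict(models$models[[id]], gt, coverage_min = 0))
    ins <- cor(e, me$values[, id])^2
    expect_lte(perf$cv_r2[perf$cpg_id == id], ins + 1e-8)
  }
})

test_that("test-panel evaluation matches the correlation-test closed form", {
  # r = 0.5 at n = 27: t = 2.887, two-sided p ~ 0.0078
  tp <- associate_trait(c(scale(1:27)),
                        0.5 * c(scale(1:27)) +
                          sqrt(0.75) * c(scale(resid(lm(rnorm(27) ~ I(1:27))))))
  expect_equal(tp$statistic, 0.5 * 5 / sqrt(0.75), tolerance = 1e-6)
  expect_equal(tp$p, 2 * pt(2.886751, 25, lower.tail = FALSE),
               tolerance = 1e-4)
})

test_that("evaluation fills test r2, sign and p on an independent panel", {
  models <- fx_models()
  cfg <- fx_cfg()
  gt2 <- simulate_genotypes(cfg, seed = 104)
  me2 <- simulate_methylation(gt2, cfg, seed = 204)
  ev <- evaluate_models(models, gt2, me2)
  perf <- ev$performance
  expect_true(all(!is.na(perf$test_r2)))
  expect_true(all(perf$test_r2 >= 0 & perf$test_r2 <= 1))
  # an exactly reproduced signal gives r2 = 1 with positive sign,
  # a negated one flips only the sign
  me_pos <- me2; me_neg <- me2
  id1 <- perf$cpg_id[1]
  e <- as.numeric(predict(models$models[[id1]], gt2, coverage_min = 0))
  me_pos$values[, id1] <- e
  me_neg$values[, id1] <- -e
  pv <- evaluate_models(models, gt2, me_pos)$performance
  nv <- evaluate_models(models, gt2, me_neg)$performance
  expect_equal(pv$test_r2[pv$cpg_id == id1], 1)
  expect_equal(pv$test_sign[pv$cpg_id == id1], 1)
  expect_equal(nv$test_r2[nv$cpg_id == id1], 1)
  expect_equal(nv$test_sign[nv$cpg_id == id1], -1)
})

test_that("robust-model selection applies FDR twice and requires positive sign", {
  # BH by hand: (0.01, 0.02, 0.03, 0.5) -> (0.04, 0.04, 0.04, 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  perf <- data.frame(cpg_id = paste0("cg", 1:4),
                     cv_p = c(0.01, 0.02, 0.03, 0.5),
                     test_p = c(1e-4, 1e-4, 1e-4, 1e-4),
                     test_sign = c(1, -1, 1, 1))
  kept <- select_robust_models(perf, fdr_q = 0.05)
  # cg4 fails criterion 1; cg2 fails the sign criterion
  expect_setequal(kept, c("cg1", "cg3"))
  # all-null p-values select nothing
  perf$cv_p <- 1
  expect_length(select_robust_models(perf), 0)
})

test_that("the retained set shrinks monotonically as fdr_q tightens", {
  set.seed(12)
  perf <- data.frame(cpg_id = paste0("cg", 1:100),
                     cv_p = runif(100)^2, test_p = runif(100)^2,
                     test_sign = sample(c(1, -1), 100, TRUE, c(0.8, 0.2)))
  qs <- c(0.2, 0.1, 0.05, 0.01)
  sets <- lapply(qs, function(q) select_robust_models(perf, q))
  for (i in 2:length(sets))
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("best univariate mQTL finds the top SNP with deterministic ties", {
  panel <- tiny_panel()
  X <- panel$dosages
  info <- data.frame(id = panel$variants$id, pos = panel$variants$pos)
  got <- best_univariate_mqtl(X, X[, "s3"], info)
  expect_equal(got$snp_id, "s3")
  expect_equal(got$r2, 1)
  # duplicated column: tie broken by lowest position
  X2 <- cbind(X, s0 = X[, "s3"])
  info2 <- rbind(info, data.frame(id = "s0", pos = 50L))
  got2 <- best_univariate_mqtl(X2, X[, "s3"], info2)
  expect_equal(got2$snp_id, "s0")
})

test_that("two equal independent causal SNPs each explain half the signal", {
  set.seed(13)
  n <- 4000
  x1 <- rbinom(n, 2, 0.4); x2 <- rbinom(n, 2, 0.4)
  y <- scale(x1)[, 1] + scale(x2)[, 1]
  info <- data.frame(id = c("a", "b"), pos = c(1L, 2L))
  r2 <- best_univariate_mqtl(cbind(a = x1, b = x2), y, info)$r2
  expect_equal(r2, 0.5, tolerance = 0.05)
  # the joint fit explains essentially everything
  fit <- fit_elastic_net(cbind(a = x1, b = x2, c = rbinom(n, 2, 0.3)),
                         y, enet_config(lambda = 1e-3))
  est <- cbind(x1, x2, 0) %*% c(fit$weights["a"], fit$weights["b"], 0)
  expect_gt(cor(est, y)^2, 0.9)
})

test_that("marker-dropout stability behaves at the declared edge cases", {
  models <- fx_models()
  cfg <- fx_cfg()
  gt2 <- simulate_genotypes(cfg, seed = 104)
  me2 <- simulate_methylation(gt2, cfg, seed = 204)
  m <- models$models[[1]]
  base <- evaluate_models(models, gt2, me2)$performance
  base_r2 <- base$test_r2[base$cpg_id == m$cpg_id]
  # drop_frac 0 reproduces the baseline each replicate
  s0 <- stability_under_missingness(m, gt2, me2, drop_frac = 0, reps = 5)
  expect_equal(s0$r2, rep(base_r2, 5), tolerance = 1e-10)
  # a single-SNP model loses everything: ceiling(0.1) = 1 SNP dropped
  m1 <- one_snp_model()
  s1 <- stability_under_missingness(m1, tiny_panel_meth()$geno,
                                    tiny_panel_meth()$meth,
                                    drop_frac = 0.1, reps = 3)
  expect_true(all(is.na(s1$r2)))
})

test_that("dropping one of two perfectly correlated SNPs leaves r2 unchanged", {
  set.seed(14)
  n <- 100
  x <- rbinom(n, 2, 0.4)
  dos <- cbind(dup1 = x, dup2 = x)
  geno <- genotype_panel(dos, data.frame(
    id = c("dup1", "dup2"), chr = "1", pos = c(100L, 200L),
    effect_allele = "A", other_allele = "G"))
  meth <- methylation_panel(matrix(x + rnorm(n, sd = 0.5), ncol = 1),
                            data.frame(id = "cgDUP", chr = "1", pos = 150L),
                            scale = "adjusted",
                            sample_ids = geno$sample_ids)
  m <- cpg_model("cgDUP", "1", 150L, 0, data.frame(
    snp_id = c("dup1", "dup2"), chr = "1", pos = c(100L, 200L),
    effect_allele = "A", other_allele = "G", weight = c(0.5, 0.5)))
  s <- stability_under_missingness(m, geno, meth, drop_frac = 0.5, reps = 10)
  base <- cor(x, meth$values[, 1])^2
  expect_equal(s$r2, rep(base, 10), tolerance = 1e-10)
})
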