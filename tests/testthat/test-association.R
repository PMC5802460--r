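test_that("prediction is the weighted dosage sum with coverage flags", {
  panel <- tiny_panel()
  m <- one_snp_model(weight = 0.5, intercept = 0)
  e <- predict(m, panel)
  expect_equal(unname(e[1:3]), c(0, 0.5, 1.0))
  expect_equal(attr(e, "coverage"), 1)
  expect_false(attr(e, "discarded"))
})

test_that("swapped-allele SNPs contribute through the reflected dosage", {
  panel <- tiny_panel()
  m <- one_snp_model(weight = 0.5, ea = "G", oa = "A")  # swapped vs panel
  e <- predict(m, panel)
  expect_equal(unname(e[1:3]), 0.5 * (2 - panel$dosages[1:3, "s1"]),
               ignore_attr = TRUE)
})

test_that("models below 50% panel coverage are flagged discarded", {
  set.seed(20)
  # 10-SNP model, panel carries only 4 of them
  ids <- paste0("m", 1:10)
  w <- data.frame(snp_id = ids, chr = "1", pos = 1:10 * 100L,
                  effect_allele = "A", other_allele = "G", weight = 0.1)
  m <- cpg_model("cgC", "1", 500L, 0, w)
  dos <- matrix(rbinom(20 * 4, 2, 0.4), 20, 4)
  panel4 <- genotype_panel(dos, data.frame(
    id = ids[1:4], chr = "1", pos = 1:4 * 100L,
    effect_allele = "A", other_allele = "G"))
  e <- predict(m, panel4)
  expect_equal(attr(e, "coverage"), 0.4)
  expect_true(attr(e, "discarded"))
  # zero matched SNPs is also discarded
  panel0 <- genotype_panel(dos, data.frame(
    id = paste0("x", 1:4), chr = "1", pos = 1:4 * 100L,
    effect_allele = "A", other_allele = "G"))
  expect_true(attr(predict(m, panel0), "discarded"))
})

test_that("trait association follows the exact correlation test", {
  set.seed(21)
  e <- rnorm(50)
  a <- associate_trait(e, e)
  expect_equal(a$r, 1)
  expect_equal(a$p, .Machine$double.xmin)
  # sign flip negates the statistic, p unchanged
  y <- e + rnorm(50)
  a1 <- associate_trait(e, y)
  a2 <- associate_trait(e, -y)
  expect_equal(a2$statistic, -a1$statistic)
  expect_equal(a2$p, a1$p)
  # oracle: cor.test
  ct <- cor.test(e, y)
  expect_equal(a1$statistic, unname(ct$statistic), tolerance = 1e-10)
  expect_equal(a1$p, ct$p.value, tolerance = 1e-10)
})

test_that("single-SNP covariance arithmetic: shrinkage scales the denominator", {
  panel <- tiny_panel()
  m <- one_snp_model(weight = 1)
  g <- gwas_summary(data.frame(id = "s1", effect_allele = "A",
                               other_allele = "G", z = 3))
  cv0 <- build_covariance(m, panel, lambda_s = 0)
  expect_equal(sumstat_z(m, g, cv0)$statistic, 3)
  cv1 <- build_covariance(m, panel, lambda_s = 0.1)
  expect_equal(sumstat_z(m, g, cv1)$statistic, 3 / sqrt(1.1))
})

test_that("two-SNP hand arithmetic: unit SDs and correlation 0.5 give 4/sqrt(3)", {
  # construct dosage columns with exactly equal variances and cor 0.5
  a <- rep(c(0.5, -0.5, 0.5, -0.5), 2)
  b <- rep(c(0.5, 0.5, -0.5, -0.5), 2)
  d1 <- 1 + a
  d2 <- 1 + 0.5 * a + sqrt(3) / 2 * b
  panel <- genotype_panel(cbind(p = d1, q = d2), data.frame(
    id = c("p", "q"), chr = "1", pos = c(100L, 200L),
    effect_allele = "A", other_allele = "G"))
  m <- cpg_model("cg2", "1", 150L, 0, data.frame(
    snp_id = c("p", "q"), chr = "1", pos = c(100L, 200L),
    effect_allele = "A", other_allele = "G", weight = c(1, 1)))
  g <- gwas_summary(data.frame(id = c("p", "q"), effect_allele = "A",
                               other_allele = "G", z = c(2, 2)))
  cv <- build_covariance(m, panel, lambda_s = 0)
  expect_equal(cov(d1, d2) / (sd(d1) * sd(d2)), 0.5, tolerance = 1e-12)
  expect_equal(sumstat_z(m, g, cv)$statistic, 4 / sqrt(3), tolerance = 1e-12)
})

test_that("the statistic is scale-invariant in the weights and odd in their sign", {
  models <- fx_models()
  m <- models$models[[2]]
  tr <- simulate_trait(n = 500, kind = "null", seed = 7)
  g <- marginal_gwas(fx_train(), tr)
  cv <- build_covariance(m, fx_ref(), lambda_s = 0.1)
  z0 <- sumstat_z(m, g, cv)$statistic
  m_scaled <- m; m_scaled$weights$weight <- 3.7 * m$weights$weight
  cv_s <- build_covariance(m_scaled, fx_ref(), lambda_s = 0.1)
  expect_equal(sumstat_z(m_scaled, g, cv_s)$statistic, z0, tolerance = 1e-10)
  m_neg <- m; m_neg$weights$weight <- -m$weights$weight
  cv_n <- build_covariance(m_neg, fx_ref(), lambda_s = 0.1)
  expect_equal(sumstat_z(m_neg, g, cv_n)$statistic, -z0, tolerance = 1e-10)
})

test_that("positive shrinkage strictly deflates the statistic", {
  models <- fx_models()
  tr <- simulate_trait(n = 500, kind = "null", seed = 8)
  g <- marginal_gwas(fx_train(), tr)
  for (m in models$models[1:10]) {
    cv0 <- build_covariance(m, fx_ref(), lambda_s = 0)
    cv1 <- build_covariance(m, fx_ref(), lambda_s = 0.1)
    z0 <- sumstat_z(m, g, cv0)$statistic
    z1 <- sumstat_z(m, g, cv1)$statistic
    expect_lt(abs(z1), abs(z0))
    expect_equal(sign(z1), sign(z0))
  }
})

test_that("exact statistic with zero R2 terms reduces to the approximation", {
  models <- fx_models()
  m <- models$models[[3]]
  tr <- simulate_trait(n = 500, kind = "null", seed = 9)
  g <- marginal_gwas(fx_train(), tr)
  g$r2 <- 0
  cv <- build_covariance(m, fx_train(), lambda_s = 0)
  expect_equal(exact_z(m, g, cv, r2_g = 0)$statistic,
               sumstat_z(m, g, cv)$statistic, tolerance = 1e-12)
})

test_that("exact statistic equals the individual-level statistic on the same sample", {
  models <- fx_models()
  gt <- fx_train()
  for (m in models$models[1:10]) {
    e <- as.numeric(predict(m, gt, coverage_min = 0))
    tr <- simulate_trait(e, "correlated", target_r = 0.3,
                         seed = 100 + match(m$cpg_id, names(models$models)))
    a <- associate_trait(e, tr)
    g <- marginal_gwas(gt, tr)
    cv <- build_covariance(m, gt, lambda_s = 0)
    x <- exact_z(m, g, cv, r2_g = cor(e, tr)^2)
    expect_equal(x$statistic, a$statistic, tolerance = 1e-6)
  }
})

test_that("a single-SNP estimator reproduces that SNP's own statistic", {
  gt <- fx_train()
  m <- one_snp_model(weight = 2.5, snp_id = gt$variants$id[1])
  m$weights$chr <- gt$variants$chr[1]
  m$weights$pos <- gt$variants$pos[1]
  tr <- simulate_trait(n = 500, kind = "null", seed = 31)
  g <- marginal_gwas(gt, tr)
  cv <- build_covariance(m, gt, lambda_s = 0)
  snp_t <- g$z[g$id == m$weights$snp_id]
  expect_equal(exact_z(m, g, cv, r2_g = g$r2[g$id == m$weights$snp_id])$statistic,
               snp_t, tolerance = 1e-9)
})

test_that("dropping the R2 ratio deflates large-effect statistics", {
  models <- fx_models()
  gt <- fx_train()
  for (m in models$models[1:8]) {
    e <- as.numeric(predict(m, gt, coverage_min = 0))
    tr <- simulate_trait(e, "correlated", target_r = 0.6,
                         seed = 400 + match(m$cpg_id, names(models$models)))
    a <- associate_trait(e, tr)
    g <- marginal_gwas(gt, tr)
    cv <- build_covariance(m, gt, lambda_s = 0)
    z_approx <- sumstat_z(m, g, cv)$statistic
    # R_g^2 exceeds every per-SNP R_k^2, so the approximation shrinks |T|
    expect_lte(abs(z_approx), abs(a$statistic) + 1e-9)
  }
})

test_that("the scan applies the 80% coverage rule and Bonferroni threshold", {
  models <- fx_models()
  tr <- simulate_trait(n = 500, kind = "null", seed = 10)
  g_full <- marginal_gwas(fx_train(), tr)
  # drop 30% of SNPs from one model's region to push it below coverage
  m1 <- models$models[[1]]
  drop_ids <- m1$weights$snp_id[seq_len(ceiling(0.3 * nrow(m1$weights)))]
  g_cut <- gwas_summary(g_full[!(g_full$id %in% drop_ids), ])
  scan <- scan_gwas(models, g_cut, fx_ref(), coverage_min = 0.8)
  expect_false(m1$cpg_id %in% scan$cpg_id)
  expect_gte(attr(scan, "n_low_coverage"), 1)
  expect_true(all(scan$coverage >= 0.8))
  expect_equal(attr(scan, "threshold"), 0.05 / attr(scan, "n_retained"))
  # genomic order
  expect_false(is.unsorted(order(scan$chr, scan$pos)))
})

test_that("a 10-SNP model needs 8 matched GWAS SNPs to stay in the scan", {
  ids <- paste0("m", 1:10)
  w <- data.frame(snp_id = ids, chr = "1", pos = 1:10 * 100L,
                  effect_allele = "A", other_allele = "G", weight = 0.1)
  m <- cpg_model("cgC", "1", 500L, 0, w)
  g8 <- gwas_summary(data.frame(id = ids[1:8], effect_allele = "A",
                                other_allele = "G", z = 0.5))
  g7 <- gwas_summary(data.frame(id = ids[1:7], effect_allele = "A",
                                other_allele = "G", z = 0.5))
  expect_equal(harmonize_alleles(m, g8)$coverage, 0.8)
  expect_lt(harmonize_alleles(m, g7)$coverage, 0.8)
})

test_that("Bonferroni thresholds reproduce the genome-wide values", {
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(signif(bonferroni_threshold(86518, 0.05), 2), 5.8e-7)
  expect_equal(bonferroni_threshold(86710, 0.05), 0.05 / 86710)
})

test_that("BH adjustment matches the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(22)
  p <- runif(50)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
})
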