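#' Synthetic-data generation configuration
#'
#' Describes a generative population: LD-structured diploid dosages in
#' regions, CpG methylation with a target cis-heritability, and a cohort
#' size for summary-statistic generation. The population itself (per-SNP
#' allele frequencies and the per-CpG causal architecture) is a
#' deterministic function of `seed`, so panels drawn with different draw
#' seeds come from the same population.
#'
#' @param n_samples samples per drawn panel (default 500).
#' @param n_regions independent genomic regions (default 20); each region
#'   is placed on its own chromosome with one CpG at its centre.
#' @param n_snps SNPs per region (default 200), spaced `spacing_bp` apart.
#' @param spacing_bp inter-SNP spacing in bp (default 1000).
#' @param maf_range range the per-SNP minor allele frequencies are drawn
#'   from (default 0.05-0.5).
#' @param ld_rho autoregressive latent correlation between adjacent SNPs
#'   (default 0.7); dosage LD decays as roughly `ld_rho^|i-j|` on the
#'   latent scale.
#' @param n_causal causal cis-SNPs per CpG (default 3).
#' @param h2 target cis-heritability of methylation, scalar or per-CpG
#'   vector (default 0.09, the average at modeled CpGs; 0.04 emulates
#'   CpGs too weakly heritable to model).
#' @param gwas_n cohort size for summary-statistic generation
#'   (default 10000).
#' @param seed population seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500, n_regions = 20, n_snps = 200,
                       spacing_bp = 1000, maf_range = c(0.05, 0.5),
                       ld_rho = 0.7, n_causal = 3, h2 = 0.09,
                       gwas_n = 10000, seed = 1L) {
  stopifnot(ld_rho > -1, ld_rho < 1, all(h2 >= 0), all(h2 <= 1),
            maf_range[1] > 0, maf_range[2] <= 0.5, n_causal <= n_snps)
  structure(list(n_samples = n_samples, n_regions = n_regions,
                 n_snps = n_snps, spacing_bp = spacing_bp,
                 maf_range = maf_range, ld_rho = ld_rho,
                 n_causal = n_causal, h2 = h2, gwas_n = gwas_n,
                 seed = as.integer(seed)),
            class = "sim_config")
}

## population layout: allele frequencies, positions, chromosomes, causal
## architecture — all deterministic from cfg$seed
sim_population <- function(cfg) {
  with_seed(cfg$seed, {
    p <- cfg$n_regions * cfg$n_snps
    maf <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
    region <- rep(seq_len(cfg$n_regions), each = cfg$n_snps)
    pos <- rep(seq_len(cfg$n_snps) * cfg$spacing_bp, cfg$n_regions)
    variants <- data.frame(
      id = sprintf("rs%d_%d", region, rep(seq_len(cfg$n_snps),
                                          cfg$n_regions)),
      chr = as.character(region), pos = as.integer(pos),
      effect_allele = "A", other_allele = "G",
      stringsAsFactors = FALSE)
    h2 <- rep_len(cfg$h2, cfg$n_regions)
    arch <- lapply(seq_len(cfg$n_regions), function(r) {
      idx <- which(region == r)
      causal <- sort(sample(idx, cfg$n_causal))
      list(cpg_id = sprintf("cg%08d", r),
           chr = as.character(r),
           pos = as.integer(round(stats::median(pos[idx]))),
           causal_ids = variants$id[causal],
           effects = stats::rnorm(cfg$n_causal),
           h2 = h2[r])
    })
    list(variants = variants, maf = maf, region = region, arch = arch)
  })
}

#' Simulate an LD-structured genotype panel
#'
#' Diploid dosages via a Gaussian copula: per haplotype, a latent AR(1)
#' Gaussian vector with adjacent correlation `ld_rho` is thresholded at the
#' MAF-matched quantile, and the two haplotypes are summed to a dosage in
#' \{0, 1, 2\}. Allele frequencies and coordinates are fixed by the
#' population (`cfg$seed`); the panel draw is controlled by `seed`, so
#' several panels from the same population can be drawn.
#'
#' @param cfg a [sim_config()].
#' @param n samples (default `cfg$n_samples`).
#' @param seed draw seed (default `cfg$seed`).
#' @return A [genotype_panel()] with a `truth` attribute holding the
#'   population description.
#' @export
simulate_genotypes <- function(cfg, n = cfg$n_samples, seed = cfg$seed) {
  pop <- sim_population(cfg)
  p <- nrow(pop$variants)
  thr <- stats::qnorm(pop$maf)
  rho <- cfg$ld_rho
  dos <- with_seed(seed, {
    acc <- matrix(0L, n, p)
    for (h in 1:2) {
      z <- matrix(stats::rnorm(n * p), n, p)
      for (r in seq_len(cfg$n_regions)) {
        idx <- which(pop$region == r)
        for (j in idx[-1])
          z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
      acc <- acc + (z < rep(thr, each = n))
    }
    acc
  })
  panel <- genotype_panel(dos, pop$variants,
                          sample_ids = sprintf("sim%d_%d", seed, seq_len(n)))
  attr(panel, "truth") <- pop
  panel
}

#' Simulate CpG methylation with a target cis-heritability
#'
#' One CpG per region, at the region centre. The adjusted-scale signal is
#' `y = X_causal b + e`, with the noise standard deviation set from the
#' realized genetic variance on the panel so that
#' `Var(genetic) / Var(total)` targets `h2`. The causal SNPs and effects
#' are population-level (deterministic from `cfg$seed`), so independent
#' panels share the same architecture.
#'
#' @param panel a [simulate_genotypes()] panel.
#' @param cfg the same [sim_config()].
#' @param seed noise seed (default: draw-seed-linked, `cfg$seed + 1`).
#' @return An adjusted-scale [methylation_panel()] with a `truth` attribute
#'   (per CpG: causal ids, effects, realized h2).
#' @export
simulate_methylation <- function(panel, cfg, seed = cfg$seed + 1L) {
  pop <- attr(panel, "truth")
  if (is.null(pop)) pop <- sim_population(cfg)
  n <- length(panel$sample_ids)
  vals <- matrix(NA_real_, n, cfg$n_regions)
  truth <- list()
  noise <- with_seed(seed, matrix(stats::rnorm(n * cfg$n_regions), n))
  h2_vec <- rep_len(cfg$h2, cfg$n_regions)
  for (r in seq_len(cfg$n_regions)) {
    a <- pop$arch[[r]]
    a$h2 <- h2_vec[r]
    Xc <- panel$dosages[, a$causal_ids, drop = FALSE]
    g <- as.numeric(Xc %*% a$effects)
    vg <- stats::var(g)
    if (a$h2 >= 1 && vg == 0)
      stop("h2 = 1 with zero-variance genetic component")
    y <- if (a$h2 <= 0 || vg == 0) {
      noise[, r]
    } else {
      sd_e <- sqrt(vg * (1 - a$h2) / a$h2)
      g + sd_e * noise[, r]
    }
    vals[, r] <- y
    truth[[a$cpg_id]] <- list(causal_ids = a$causal_ids,
                              effects = a$effects, target_h2 = a$h2,
                              realized_h2 = if (stats::var(y) > 0)
                                vg / stats::var(y) else 0)
  }
  cpgs <- data.frame(
    id = vapply(pop$arch, `[[`, "", "cpg_id"),
    chr = vapply(pop$arch, `[[`, "", "chr"),
    pos = vapply(pop$arch, `[[`, 0L, "pos"),
    stringsAsFactors = FALSE)
  out <- methylation_panel(vals, cpgs, scale = "adjusted",
                           sample_ids = panel$sample_ids)
  attr(out, "truth") <- truth
  out
}

#' Simulate a trait, null or correlated with an estimate
#'
#' `null`: independent standard normal draws. `correlated`: `trait =
#' target_r * standardize(estimates) + sqrt(1 - target_r^2) * noise`, so the
#' population correlation with the estimate equals `target_r`.
#'
#' @param estimates genetic methylation estimate vector (required for
#'   `correlated`), or `NULL` with `n` given for `null`.
#' @param kind `"null"` or `"correlated"`.
#' @param target_r target correlation (default 0.27).
#' @param n length for a null trait when `estimates` is absent.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return Numeric trait vector.
#' @export
simulate_trait <- function(estimates = NULL, kind = c("null", "correlated"),
                           target_r = 0.27, n = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (abs(target_r) > 1) stop("|target_r| must be <= 1")
  draw <- function() {
    if (kind == "null") {
      if (is.null(n)) n <- length(estimates)
      stats::rnorm(n)
    } else {
      if (is.null(estimates) || stats::sd(estimates) == 0)
        stop("correlated trait requires a non-constant estimate")
      e <- as.numeric(scale(estimates))
      target_r * e + sqrt(1 - target_r^2) * stats::rnorm(length(e))
    }
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Per-SNP marginal association statistics on a panel
#'
#' Ordinary least squares of the trait on each SNP dosage separately
#' (intercept + dosage): effect, standard error, z, per-SNP phenotypic
#' variance fraction and sample size — the inputs the summary-statistics
#' association consumes.
#'
#' @param panel a [genotype_panel()].
#' @param trait numeric trait vector aligned with the panel samples.
#' @return A [gwas_summary()].
#' @export
marginal_gwas <- function(panel, trait) {
  X <- mean_impute(panel$dosages)
  n <- nrow(X)
  xc <- sweep(X, 2, colMeans(X))
  yc <- trait - mean(trait)
  sxx <- colSums(xc^2)
  syy <- sum(yc^2)
  sxy <- as.numeric(crossprod(xc, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- syy - beta^2 * sxx
  se <- ifelse(sxx > 0, sqrt(pmax(rss, 0) / (n - 2) / sxx), NA_real_)
  r2 <- ifelse(sxx > 0 & syy > 0, beta^2 * sxx / syy, 0)
  v <- panel$variants
  gwas_summary(data.frame(
    id = v$id, effect_allele = v$effect_allele,
    other_allele = v$other_allele, beta = beta, se = se,
    n = n, r2 = pmin(r2, 1 - 1e-12), stringsAsFactors = FALSE))
}

#' Simulate GWAS summary statistics from a fresh cohort
#'
#' Draws a cohort of `gwas_n` individuals from the configured population,
#' generates a trait (null, or correlated with a CpG model's genetic
#' estimate), and computes per-SNP marginal statistics.
#'
#' @param cfg a [sim_config()].
#' @param kind trait recipe: `"null"` or `"correlated"`.
#' @param model a `cpg_model` supplying the estimate for a correlated trait.
#' @param target_r target estimate-trait correlation (default 0.27).
#' @param gwas_n cohort size (default `cfg$gwas_n`).
#' @param seed draw seed.
#' @return A [gwas_summary()] with the cohort panel attached as attribute
#'   `panel` and the trait as attribute `trait`.
#' @export
simulate_gwas_summary <- function(cfg, kind = c("null", "correlated"),
                                  model = NULL, target_r = 0.27,
                                  gwas_n = cfg$gwas_n, seed = cfg$seed + 2L) {
  kind <- match.arg(kind)
  panel <- simulate_genotypes(cfg, n = gwas_n, seed = seed)
  trait <- if (kind == "null") {
    simulate_trait(kind = "null", n = gwas_n, seed = seed + 1L)
  } else {
    est <- predict(model, panel, coverage_min = 0)
    simulate_trait(as.numeric(est), kind = "correlated",
                   target_r = target_r, seed = seed + 1L)
  }
  g <- marginal_gwas(panel, trait)
  attr(g, "panel") <- panel
  attr(g, "trait") <- trait
  g
}

## per-model harmonized pieces for fast repeated null/power scans:
## standardized study dosage columns and the coefficient vector
## c_k = sign_k * w_k * sigma_k(ref) / sigma_gref(shrunk)
scan_precompute <- function(models, study_panel, ref_panel, lambda_s) {
  pieces <- list()
  for (m in models$models) {
    hs <- harmonize_alleles(m, study_panel)
    cov <- build_covariance(m, ref_panel, lambda_s = lambda_s)
    keep <- hs$matched$snp_id %in% cov$snp_id
    ms <- hs$matched[keep, , drop = FALSE]
    if (nrow(ms) == 0) next
    s_g <- sigma_g_shrunk(cov, ms$snp_id, ms$weight)
    if (s_g == 0) next
    sd_k <- cov$sd[match(ms$snp_id, cov$snp_id)]
    X <- mean_impute(study_panel$dosages[, ms$ext_index, drop = FALSE])
    ok <- apply(X, 2, stats::sd) > 0
    pieces[[m$cpg_id]] <- list(
      Xs = scale(X[, ok, drop = FALSE]),
      coefs = (ms$sign * ms$weight * sd_k / s_g)[ok])
  }
  pieces
}

#' Type-I error study: repeated null summary-statistics scans
#'
#' For each run, a null standard-normal trait is drawn on the study panel,
#' per-SNP marginal statistics are computed on that same panel, a full
#' summary-statistics scan (reference covariance, shrinkage `lambda_s`) is
#' executed, and the minimum p-value across models is recorded. The 5%
#' quantile of the minimum p should sit at or above the Bonferroni
#' threshold when the shrinkage makes the scan conservative.
#'
#' @param models a `cis_model_set`.
#' @param ref_panel reference [genotype_panel()] for covariances.
#' @param study_panel study [genotype_panel()] the null traits are drawn on.
#' @param n_runs scan repetitions (default 1000).
#' @param lambda_s diagonal shrinkage (default 0.1).
#' @param alpha family-wise error target (default 0.05).
#' @param seed RNG seed.
#' @return List: `min_p` (per-run), `q05` (its 5% quantile), `threshold`
#'   (Bonferroni `alpha`/n models), `fwer` (fraction of runs with any
#'   `p < threshold`), `n_models`.
#' @export
type1_study <- function(models, ref_panel, study_panel, n_runs = 1000,
                        lambda_s = 0.1, alpha = 0.05, seed = 1L) {
  pieces <- scan_precompute(models, study_panel, ref_panel, lambda_s)
  if (length(pieces) == 0) stop("no usable models")
  n <- length(study_panel$sample_ids)
  min_p <- with_seed(seed, vapply(seq_len(n_runs), function(run) {
    y <- stats::rnorm(n)
    ys <- (y - mean(y)) / stats::sd(y)
    pmin <- 1
    for (pc in pieces) {
      r <- as.numeric(crossprod(pc$Xs, ys)) / (n - 1)
      t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-12))
      Z <- sum(pc$coefs * t)
      p <- 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
      if (p < pmin) pmin <- p
    }
    pmin
  }, 0))
  thr <- bonferroni_threshold(length(pieces), alpha)
  list(min_p = min_p,
       q05 = unname(stats::quantile(min_p, 0.05)),
       threshold = thr, fwer = mean(min_p < thr),
       n_models = length(pieces))
}

#' Power study at a designed effect size
#'
#' For each CpG model and replicate, a trait correlated with the model's
#' genetic methylation estimate at `r = sqrt(effect_r2)` is generated on
#' the study panel and tested: individual-level via the correlation test,
#' and optionally summary-statistics-level using marginal statistics
#' computed on the same panel with a reference-panel covariance. Power is
#' the rejection fraction at `alpha` with the declared sidedness.
#'
#' @param models a `cis_model_set`.
#' @param study_panel study [genotype_panel()].
#' @param effect_r2 squared estimate-trait correlation (default 0.071).
#' @param reps_per_cpg replicates per CpG (default 300).
#' @param alpha rejection threshold (default `0.05 / 86518`, a genome-wide
#'   scan's Bonferroni level).
#' @param sided `"one"` (default) or `"two"`.
#' @param ref_panel optional reference [genotype_panel()]; when given,
#'   summary-statistics power is also computed.
#' @param lambda_s diagonal shrinkage for the summary path (default 0.1).
#' @param seed RNG seed.
#' @return List: `per_cpg` data.frame (`cpg_id`, `power_individual`,
#'   `power_sumstat`), `average_individual`, `average_sumstat`, `alpha`,
#'   `sided`, `n_reps_total`.
#' @export
power_study <- function(models, study_panel, effect_r2 = 0.071,
                        reps_per_cpg = 300, alpha = 0.05 / 86518,
                        sided = c("one", "two"), ref_panel = NULL,
                        lambda_s = 0.1, seed = 1L) {
  sided <- match.arg(sided)
  stopifnot(effect_r2 >= 0, effect_r2 <= 1)
  r_target <- sqrt(effect_r2)
  n <- length(study_panel$sample_ids)
  df <- n - 2
  do_sumstat <- !is.null(ref_panel)
  pieces <- if (do_sumstat)
    scan_precompute(models, study_panel, ref_panel, lambda_s) else NULL
  rows <- list()
  with_seed(seed, {
    for (m in models$models) {
      e <- as.numeric(predict(m, study_panel, coverage_min = 0))
      if (stats::sd(e) == 0) next
      es <- as.numeric(scale(e))
      noise <- matrix(stats::rnorm(n * reps_per_cpg), n)
      Y <- r_target * es + sqrt(1 - effect_r2) * noise
      Ys <- scale(Y)
      r <- as.numeric(crossprod(es, Ys)) / (n - 1)
      t <- r * sqrt(df) / sqrt(pmax(1 - r^2, 1e-12))
      p_ind <- if (sided == "one")
        stats::pt(t, df, lower.tail = FALSE)
      else 2 * stats::pt(abs(t), df, lower.tail = FALSE)
      row <- data.frame(cpg_id = m$cpg_id,
                        power_individual = mean(p_ind < alpha),
                        power_sumstat = NA_real_,
                        stringsAsFactors = FALSE)
      if (do_sumstat && !is.null(pieces[[m$cpg_id]])) {
        pc <- pieces[[m$cpg_id]]
        rz <- crossprod(pc$Xs, Ys) / (n - 1)
        tz <- rz * sqrt(df) / sqrt(pmax(1 - rz^2, 1e-12))
        Z <- as.numeric(crossprod(pc$coefs, tz))
        p_ss <- if (sided == "one")
          stats::pnorm(Z, lower.tail = FALSE)
        else 2 * stats::pnorm(abs(Z), lower.tail = FALSE)
        row$power_sumstat <- mean(p_ss < alpha)
      }
      rows[[m$cpg_id]] <- row
    }
  })
  per_cpg <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(per_cpg = per_cpg,
       average_individual = mean(per_cpg$power_individual),
       average_sumstat = if (do_sumstat)
         mean(per_cpg$power_sumstat, na.rm = TRUE) else NA_real_,
       alpha = alpha, sided = sided,
       n_reps_total = nrow(per_cpg) * reps_per_cpg)
}

#' Analytic one-sided power of the correlation test (Fisher z)
#'
#' `power = Phi(atanh(r) * sqrt(n - 3) - qnorm(1 - alpha))`. Setting the
#' left side to the target power and solving for `r` recovers the designed
#' effect size of a scan: `r = tanh((qnorm(power) + qnorm(1 - alpha)) /
#' sqrt(n - 3))`.
#'
#' @param r true correlation (for `fisher_power`).
#' @param n sample size.
#' @param alpha one-sided rejection level.
#' @return `fisher_power`: the power; `fisher_design_r2`: the squared
#'   correlation detectable at `power`.
#' @export
fisher_power <- function(r, n, alpha) {
  stats::pnorm(atanh(r) * sqrt(n - 3) - stats::qnorm(1 - alpha))
}

#' @rdname fisher_power
#' @param power target power (for `fisher_design_r2`).
#' @export
fisher_design_r2 <- function(power, n, alpha) {
  tanh((stats::qnorm(power) + stats::qnorm(1 - alpha)) / sqrt(n - 3))^2
}
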