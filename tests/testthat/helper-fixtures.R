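# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) assign(name, builder(), .fx_cache)
  get(name, .fx_cache)
}

# main simulated study: 50 regions x 40 SNPs, 3 causal SNPs per CpG,
# cis-h2 0.25, LD rho 0.7
fx_cfg <- function() sim_config(n_samples = 500, n_regions = 50,
                                n_snps = 40, n_causal = 3, h2 = 0.25,
                                seed = 101)

fx_train <- function() fx("train", function()
  simulate_genotypes(fx_cfg(), seed = 101))

fx_meth <- function() fx("meth", function()
  simulate_methylation(fx_train(), fx_cfg()))

fx_models <- function() fx("models", function()
  fit_cis_models(fx_meth(), fx_train(), enet_config(seed = 3)))

# independent draws from the same population
fx_ref <- function() fx("ref", function()
  simulate_genotypes(fx_cfg(), n = 500, seed = 102))

fx_study319 <- function() fx("study319", function()
  simulate_genotypes(fx_cfg(), n = 319, seed = 103))

# a small hand-made genotype panel: 6 samples x 3 SNPs on one chromosome
tiny_panel <- function() {
  dos <- cbind(s1 = c(0, 1, 2, 1, 0, 2),
               s2 = c(2, 1, 0, 1, 2, 0),
               s3 = c(0, 0, 1, 1, 2, 2))
  genotype_panel(dos, data.frame(
    id = c("s1", "s2", "s3"), chr = "1", pos = c(100L, 200L, 300L),
    effect_allele = c("A", "G", "C"), other_allele = c("G", "A", "T"),
    stringsAsFactors = FALSE))
}

# aligned tiny genotype + methylation pair for single-CpG checks
tiny_panel_meth <- function() {
  geno <- tiny_panel()
  set.seed(99)
  vals <- matrix(geno$dosages[, "s1"] * 0.5 + rnorm(6, sd = 0.3), ncol = 1)
  meth <- methylation_panel(vals,
                            data.frame(id = "cgTEST", chr = "1", pos = 150L),
                            scale = "adjusted",
                            sample_ids = geno$sample_ids)
  list(geno = geno, meth = meth)
}

# single-SNP model helper
one_snp_model <- function(weight = 0.5, intercept = 0, snp_id = "s1",
                          ea = "A", oa = "G") {
  cpg_model("cgTEST", "1", 150L, intercept,
            data.frame(snp_id = snp_id, chr = "1", pos = 100L,
                       effect_allele = ea, other_allele = oa,
                       weight = weight, stringsAsFactors = FALSE))
}
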