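#' Harmonize alleles between a CpG model and external SNP data
#'
#' Matches a model's weighted SNPs against a GWAS summary table or a
#' genotype panel by SNP id and allele pair. Under `strict` only exact
#' (effect, other) allele matches are kept, with sign +1. Under `allow-swap`
#' a swapped pair (model effect allele = external other allele and vice
#' versa) is also kept, with sign -1: downstream code negates the external z
#' or reflects the dosage as `2 - d`. Any other allele pair is an allelic
#' mismatch and is discarded. Strand-ambiguous SNPs (A/T, C/G) are matched by
#' id and alleles like any other pair; set `drop_ambiguous = TRUE` to exclude
#' them instead.
#'
#' @param model a `cpg_model`.
#' @param external a [gwas_summary()] or [genotype_panel()].
#' @param policy `"allow-swap"` (default) or `"strict"`.
#' @param drop_ambiguous drop A/T and C/G SNPs entirely (default `FALSE`).
#' @return A list with `matched` (data.frame: `snp_id`, `weight`, `sign`,
#'   `ext_index`), `coverage` (matched / model size) and `n_discarded`.
#' @export
harmonize_alleles <- function(model, external,
                              policy = c("allow-swap", "strict"),
                              drop_ambiguous = FALSE) {
  policy <- match.arg(policy)
  stopifnot(inherits(model, "cpg_model"))
  w <- model$weights
  if (inherits(external, "genotype_panel")) {
    ext <- external$variants[, c("id", "effect_allele", "other_allele")]
  } else if (inherits(external, "gwas_summary")) {
    ext <- external[, c("id", "effect_allele", "other_allele")]
  } else stop("external must be a gwas_summary or genotype_panel")
  idx <- match(w$snp_id, ext$id)
  ea <- toupper(ext$effect_allele[idx])
  oa <- toupper(ext$other_allele[idx])
  mea <- toupper(w$effect_allele)
  moa <- toupper(w$other_allele)
  exact <- !is.na(idx) & ea == mea & oa == moa
  swapped <- !is.na(idx) & ea == moa & oa == mea & !exact
  keep <- exact
  sign <- rep(1, nrow(w))
  if (policy == "allow-swap") {
    keep <- keep | swapped
    sign[swapped] <- -1
  }
  if (drop_ambiguous) {
    ambig <- (mea == "A" & moa == "T") | (mea == "T" & moa == "A") |
      (mea == "C" & moa == "G") | (mea == "G" & moa == "C")
    keep <- keep & !ambig
  }
  matched <- data.frame(snp_id = w$snp_id[keep], weight = w$weight[keep],
                        sign = sign[keep], ext_index = idx[keep],
                        stringsAsFactors = FALSE)
  list(matched = matched,
       coverage = if (nrow(w) > 0) nrow(matched) / nrow(w) else NA_real_,
       n_discarded = nrow(w) - nrow(matched))
}
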