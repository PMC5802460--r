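#' Read a genotype panel from VCF or a dosage matrix
#'
#' For VCF input the dosage field (default `DS`) is used when present,
#' falling back to hard-call counts of the ALT allele from `GT`. The ALT
#' allele becomes the effect allele. Multi-allelic records are skipped with a
#' warning. For `dosage-tsv` input the file is a tab-delimited matrix with a
#' header row of SNP ids and a first column of sample ids, accompanied by a
#' variant table (columns `id`, `chr`, `pos`, `effect_allele`,
#' `other_allele`\[, `imp_r2`\]).
#'
#' @param path path to the VCF or dosage matrix file.
#' @param format `"vcf"` or `"dosage-tsv"`.
#' @param variant_table path to the companion variant table (dosage-tsv only).
#' @param dosage_field VCF FORMAT field holding dosages (default `"DS"`).
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage-tsv"),
                           variant_table = NULL, dosage_field = "DS") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT, fixed = TRUE)
    if (any(multi)) {
      warning(sum(multi), " multi-allelic VCF record(s) skipped")
      vcf <- vcf[!multi, ]
      fix <- fix[!multi, , drop = FALSE]
    }
    fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
    if (dosage_field %in% fmt_keys) {
      d <- vcfR::extract.gt(vcf, element = dosage_field, as.numeric = TRUE)
    } else if ("GT" %in% fmt_keys) {
      gt <- vcfR::extract.gt(vcf, element = "GT")
      d <- apply(gt, c(1, 2), function(g) {
        if (is.na(g)) return(NA_real_)
        sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
      })
    } else {
      stop("VCF has neither a '", dosage_field, "' nor a 'GT' FORMAT field")
    }
    ids <- fix$ID
    noid <- is.na(ids) | ids == "."
    ids[noid] <- paste0(fix$CHROM[noid], ":", fix$POS[noid])
    variants <- data.frame(id = ids, chr = fix$CHROM,
                           pos = as.integer(fix$POS),
                           effect_allele = fix$ALT, other_allele = fix$REF,
                           stringsAsFactors = FALSE)
    genotype_panel(t(d), variants, sample_ids = colnames(d))
  } else {
    if (is.null(variant_table))
      stop("dosage-tsv format requires a variant_table")
    mat <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(mat) < 2) stop("malformed dosage matrix header")
    sample_ids <- as.character(mat[[1]])
    d <- as.matrix(mat[, -1, drop = FALSE])
    variants <- utils::read.delim(variant_table, stringsAsFactors = FALSE)
    if (!identical(colnames(d), as.character(variants$id)))
      stop("dosage matrix SNP ids do not match the variant table")
    genotype_panel(d, variants, sample_ids = sample_ids)
  }
}

#' Write a genotype panel as a dosage matrix plus variant table
#'
#' @param panel a [genotype_panel()].
#' @param path output path for the dosage matrix.
#' @param variant_table output path for the variant table.
#' @return Invisibly, `path`.
#' @export
write_genotypes <- function(panel, path, variant_table) {
  mat <- data.frame(sample_id = panel$sample_ids,
                    panel$dosages, check.names = FALSE)
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cols <- c("id", "chr", "pos", "effect_allele", "other_allele", "imp_r2")
  utils::write.table(panel$variants[, cols], variant_table, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a methylation panel
#'
#' @param path tab-delimited matrix: header row of CpG ids, first column of
#'   sample ids.
#' @param cpg_table tab-delimited CpG coordinate table (`id`, `chr`, `pos`).
#' @param scale value scale: `"beta"`, `"m"` or `"adjusted"`.
#' @return A [methylation_panel()].
#' @export
read_methylation <- function(path, cpg_table,
                             scale = c("beta", "m", "adjusted")) {
  scale <- match.arg(scale)
  mat <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sample_ids <- as.character(mat[[1]])
  vals <- as.matrix(mat[, -1, drop = FALSE])
  cpgs <- utils::read.delim(cpg_table, stringsAsFactors = FALSE)
  if (!identical(colnames(vals), as.character(cpgs$id)))
    stop("methylation matrix CpG ids do not match the CpG table")
  methylation_panel(vals, cpgs, scale = scale, sample_ids = sample_ids)
}

#' Write a methylation panel
#'
#' @param panel a [methylation_panel()].
#' @param path output path for the value matrix.
#' @param cpg_table output path for the CpG coordinate table.
#' @return Invisibly, `path`.
#' @export
write_methylation <- function(panel, path, cpg_table) {
  mat <- data.frame(sample_id = panel$sample_ids, panel$values,
                    check.names = FALSE)
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$cpgs[, c("id", "chr", "pos")], cpg_table,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics with an explicit column map
#'
#' Consortium files differ in column naming; rather than sniffing, the caller
#' declares which file column supplies each required field. Rows whose
#' alleles are not single A/C/G/T bases (indel codes, multi-base alleles)
#' are dropped with a message.
#'
#' @param path tab-delimited summary-statistics file with a header.
#' @param column_map named list/vector mapping the canonical names `id`,
#'   `effect_allele`, `other_allele` and either (`beta`, `se`) or `z`
#'   (optionally `n`, `r2`) to column names in the file.
#' @return A [gwas_summary()] data.frame.
#' @export
read_gwas_summary <- function(path, column_map) {
  column_map <- as.list(column_map)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  req <- c("id", "effect_allele", "other_allele")
  miss <- setdiff(req, names(column_map))
  if (length(miss) > 0)
    stop("column_map missing: ", paste(miss, collapse = ", "))
  if (!(all(c("beta", "se") %in% names(column_map)) ||
        "z" %in% names(column_map)))
    stop("column_map must provide either (beta, se) or z")
  absent <- setdiff(unlist(column_map), names(raw))
  if (length(absent) > 0)
    stop("file lacks mapped column(s): ", paste(absent, collapse = ", "))
  out <- lapply(column_map, function(cl) raw[[cl]])
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  ok <- df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T")
  if (any(!ok))
    message(sum(!ok), " row(s) with non-ACGT alleles dropped")
  gwas_summary(df[ok, , drop = FALSE])
}

## sentinel for not-yet-evaluated performance fields in the model store
.store_na <- function(x) ifelse(is.na(x), "NA", format(x, digits = 15))

#' Write a model set to a plain-text store
#'
#' The store is a directory holding two tab-delimited files: `weights.tsv`
#' (one row per nonzero SNP weight) and `summary.tsv` (one row per CpG
#' model), each preceded by a `#`-prefixed `key=value` metadata block.
#' Weights are serialized with 15 significant digits so the round trip is
#' lossless at double precision.
#'
#' @param models a `cis_model_set` (see [fit_cis_models()]).
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_model_store <- function(models, dir) {
  stopifnot(inherits(models, "cis_model_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- models$meta
  hdr <- sprintf("#%s=%s", names(meta), unlist(meta))
  wt <- do.call(rbind, lapply(models$models, function(m) {
    data.frame(cpg_id = m$cpg_id, snp_id = m$weights$snp_id,
               chr = m$weights$chr, pos = m$weights$pos,
               effect_allele = m$weights$effect_allele,
               other_allele = m$weights$other_allele,
               weight = m$weights$weight, stringsAsFactors = FALSE)
  }))
  if (is.null(wt))
    wt <- data.frame(cpg_id = character(), snp_id = character(),
                     chr = character(), pos = integer(),
                     effect_allele = character(), other_allele = character(),
                     weight = double())
  wt$weight <- format(wt$weight, digits = 15, trim = TRUE)
  wpath <- file.path(dir, "weights.tsv")
  writeLines(c(hdr, paste(names(wt), collapse = "\t")), wpath)
  if (nrow(wt) > 0)
    utils::write.table(wt, wpath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE)
  perf <- models$performance
  sm <- data.frame(cpg_id = perf$cpg_id, chr = perf$chr, pos = perf$pos,
                   n_snps = perf$n_snps, n_candidate = perf$n_candidate,
                   intercept = format(perf$intercept, digits = 15,
                                      trim = TRUE),
                   cv_r2 = .store_na(perf$cv_r2),
                   test_r2 = .store_na(perf$test_r2),
                   train_p = .store_na(perf$cv_p),
                   test_p = .store_na(perf$test_p),
                   test_sign = .store_na(perf$test_sign),
                   stringsAsFactors = FALSE)
  spath <- file.path(dir, "summary.tsv")
  writeLines(c(hdr, paste(names(sm), collapse = "\t")), spath)
  if (nrow(sm) > 0)
    utils::write.table(sm, spath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(dir)
}

#' Read a model set back from a plain-text store
#'
#' @param dir directory written by [write_model_store()].
#' @return A `cis_model_set`.
#' @export
read_model_store <- function(dir) {
  wpath <- file.path(dir, "weights.tsv")
  spath <- file.path(dir, "summary.tsv")
  if (!file.exists(wpath) || !file.exists(spath))
    stop("model store at ", dir, " is incomplete")
  meta_lines <- grep("^#", readLines(spath), value = TRUE)
  kv <- strsplit(sub("^#", "", meta_lines), "=", fixed = TRUE)
  meta <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
                          vapply(kv, `[`, "", 1))
  wt <- utils::read.delim(wpath, comment.char = "#",
                          stringsAsFactors = FALSE)
  sm <- utils::read.delim(spath, comment.char = "#",
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (anyDuplicated(sm$cpg_id))
    stop("duplicate CpG id in model store summary")
  sm$chr <- as.character(sm$chr)
  wt$chr <- as.character(wt$chr)
  models <- lapply(seq_len(nrow(sm)), function(i) {
    w <- wt[wt$cpg_id == sm$cpg_id[i], , drop = FALSE]
    structure(list(
      cpg_id = sm$cpg_id[i], chr = sm$chr[i], pos = sm$pos[i],
      intercept = sm$intercept[i],
      weights = data.frame(snp_id = w$snp_id, chr = w$chr, pos = w$pos,
                           effect_allele = w$effect_allele,
                           other_allele = w$other_allele,
                           weight = w$weight, stringsAsFactors = FALSE),
      n_candidate_snps = sm$n_candidate[i],
      n_selected_snps = sm$n_snps[i]), class = "cpg_model")
  })
  names(models) <- sm$cpg_id
  perf <- data.frame(cpg_id = sm$cpg_id, chr = sm$chr, pos = sm$pos,
                     n_snps = sm$n_snps, n_candidate = sm$n_candidate,
                     intercept = sm$intercept,
                     cv_r2 = sm$cv_r2, cv_p = sm$train_p,
                     test_r2 = sm$test_r2, test_p = sm$test_p,
                     test_sign = sm$test_sign, stringsAsFactors = FALSE)
  new_cis_model_set(models, perf, meta)
}
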