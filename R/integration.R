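#' Construct an expression panel
#'
#' @param values adjusted expression matrix, samples in rows, genes in
#'   columns.
#' @param genes data.frame with `id`, `chr`, `start`, `end`.
#' @param sample_ids sample identifiers (default row names or `S1..Sn`).
#' @return A list of class `expression_panel`.
#' @export
expression_panel <- function(values, genes, sample_ids = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "chr", "start", "end"), names(genes))
  if (length(miss) > 0)
    stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(genes$id)) stop("gene ids must be unique")
  if (any(genes$start > genes$end)) stop("gene start must be <= end")
  genes$chr <- as.character(genes$chr)
  rownames(values) <- sample_ids
  colnames(values) <- genes$id
  structure(list(values = values, genes = genes, sample_ids = sample_ids),
            class = "expression_panel")
}

#' Cis CpG-expression association scan
#'
#' Tests every (CpG, gene) pair with the CpG inside
#' `[gene start - window_bp, gene end + window_bp]` on the same chromosome:
#' Pearson correlation, two-sided p, and BH-adjusted q across all tested
#' pairs.
#'
#' @param meth a [methylation_panel()] (adjusted scale).
#' @param expr an [expression_panel()].
#' @param window_bp cis window from the gene boundaries (default 1e6).
#' @param fdr_q significance threshold on the adjusted p (default 0.05).
#' @return Data.frame: `cpg_id`, `gene_id`, `r`, `p`, `q`, `significant`,
#'   ordered by p.
#' @export
cis_expression_scan <- function(meth, expr, window_bp = 1e6, fdr_q = 0.05) {
  common <- intersect(meth$sample_ids, expr$sample_ids)
  if (length(common) < 4) stop("need >= 4 overlapping samples")
  mi <- match(common, meth$sample_ids)
  ei <- match(common, expr$sample_ids)
  rows <- list()
  for (g in seq_len(nrow(expr$genes))) {
    gene <- expr$genes[g, ]
    hits <- which(meth$cpgs$chr == gene$chr &
                    meth$cpgs$pos >= gene$start - window_bp &
                    meth$cpgs$pos <= gene$end + window_bp)
    if (length(hits) == 0) next
    ev <- expr$values[ei, g]
    for (ci in hits) {
      mv <- meth$values[mi, ci]
      ok <- !is.na(mv) & !is.na(ev)
      if (sum(ok) < 4 || stats::sd(mv[ok]) == 0 || stats::sd(ev[ok]) == 0)
        next
      r <- stats::cor(mv[ok], ev[ok])
      tp <- cor_test_tp(r, sum(ok))
      rows[[length(rows) + 1L]] <- data.frame(
        cpg_id = meth$cpgs$id[ci], gene_id = gene$id, r = r, p = tp$p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(cpg_id = character(), gene_id = character(),
                      r = double(), p = double(), q = double(),
                      significant = logical()))
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < fdr_q
  out[order(out$p), , drop = FALSE]
}

#' CpG-expression association before and after genetic adjustment
#'
#' Quantifies how much of a CpG-gene association is carried by the CpG's
#' genetic component: `r2_before` is the squared correlation of methylation
#' with expression; `r2_after` the same after residualizing methylation on
#' its genetic estimate.
#'
#' @param dnam observed adjusted methylation vector.
#' @param expr expression vector.
#' @param estimate genetic methylation estimate vector.
#' @return List with `r2_before` and `r2_after` (`NA` when the residual is
#'   constant).
#' @export
adjusted_association <- function(dnam, expr, estimate) {
  stopifnot(length(dnam) == length(expr), length(dnam) == length(estimate))
  if (stats::sd(dnam) == 0 || stats::sd(expr) == 0)
    stop("constant dnam or expr")
  r2_before <- stats::cor(dnam, expr)^2
  resid <- residualize(matrix(dnam, ncol = 1),
                       data.frame(estimate = estimate))[, 1]
  r2_after <- if (stats::sd(resid) == 0) NA_real_
              else stats::cor(resid, expr)^2
  list(r2_before = r2_before, r2_after = r2_after)
}

#' Permutation enrichment of a CpG set in an annotation
#'
#' Counts the overlap of a target CpG set with an annotated set, then draws
#' `n_perm` random sets of the same size from the universe and recomputes
#' the overlap. The p-value uses the add-one estimator
#' `(1 + #\{perm >= observed\}) / (n_perm + 1)`, so its floor is
#' `1/(n_perm + 1)`.
#'
#' @param target_set CpG ids of interest (subset of `universe`).
#' @param annotated_set annotated CpG ids (subset of `universe`).
#' @param universe all eligible CpG ids.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return List of class `enrichment_result`: `observed`,
#'   `permutation_counts`, `p`.
#' @export
permutation_enrichment <- function(target_set, annotated_set, universe,
                                   n_perm = 10000, seed = 1L) {
  if (!all(target_set %in% universe) || !all(annotated_set %in% universe))
    stop("target and annotated sets must be subsets of the universe")
  observed <- length(intersect(target_set, annotated_set))
  k <- length(target_set)
  in_ann <- universe %in% annotated_set
  counts <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    sum(in_ann[sample.int(length(universe), k)]), 0L))
  p <- (1 + sum(counts >= observed)) / (n_perm + 1)
  structure(list(observed = observed, permutation_counts = counts, p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("permutation enrichment: observed =", x$observed,
      "| permutation mean =", signif(mean(x$permutation_counts), 3),
      "| p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Select informative CpGs by blood variability and blood-brain concordance
#'
#' A CpG is informative when its whole-blood coefficient of variation
#' exceeds `cv_min` and its absolute blood-brain Spearman correlation
#' exceeds the region-specific threshold in at least one brain region.
#'
#' @param metrics data.frame with `cpg_id`, `cv`, and one column per brain
#'   region named as in `cor_min` (e.g. `r_ba7`, `r_ba10`, `r_ba20`).
#' @param cv_min coefficient-of-variation threshold (default 0.1).
#' @param cor_min named vector of per-region absolute-correlation
#'   thresholds (default `c(r_ba7 = 0.36, r_ba10 = 0.40, r_ba20 = 0.33)`).
#' @return Character vector of informative CpG ids.
#' @export
informative_cpgs <- function(metrics, cv_min = 0.1,
                             cor_min = c(r_ba7 = 0.36, r_ba10 = 0.40,
                                         r_ba20 = 0.33)) {
  miss <- setdiff(c("cpg_id", "cv", names(cor_min)), names(metrics))
  if (length(miss) > 0)
    stop("metrics missing column(s): ", paste(miss, collapse = ", "))
  conc <- Reduce(`|`, lapply(names(cor_min), function(rg)
    !is.na(metrics[[rg]]) & abs(metrics[[rg]]) > cor_min[[rg]]))
  keep <- !is.na(metrics$cv) & metrics$cv > cv_min & conc
  metrics$cpg_id[keep]
}

#' Choose the expression-PC adjustment by eQTL yield
#'
#' Residualizes expression on its top-k principal components for
#' k = 0, 1, ..., counts significant cis-eQTLs at each k (per-gene best
#' SNP, BH-adjusted across genes at q < 0.05), and stops at the first k
#' whose count does not exceed the running maximum.
#'
#' @param expr an [expression_panel()] (unadjusted for hidden factors).
#' @param panel a filtered [genotype_panel()].
#' @param max_pcs largest k to consider (default 10).
#' @param window_bp cis window from gene boundaries (default 1e6).
#' @param fdr_q eQTL significance threshold (default 0.05).
#' @return List: `k` (chosen PC count), `trace` (eQTL count per k tried).
#' @export
select_pc_adjustment <- function(expr, panel, max_pcs = 10,
                                 window_bp = 1e6, fdr_q = 0.05) {
  common <- intersect(expr$sample_ids, panel$sample_ids)
  if (length(common) < 4) stop("need >= 4 overlapping samples")
  ei <- match(common, expr$sample_ids)
  gi <- match(common, panel$sample_ids)
  E0 <- expr$values[ei, , drop = FALSE]
  D <- mean_impute(panel$dosages[gi, , drop = FALSE])
  pcs <- stats::prcomp(E0, center = TRUE, scale. = FALSE)$x
  n <- length(common)
  count_eqtls <- function(E) {
    best_p <- rep(NA_real_, ncol(E))
    for (g in seq_len(ncol(E))) {
      gene <- expr$genes[g, ]
      hits <- which(panel$variants$chr == gene$chr &
                      panel$variants$pos >= gene$start - window_bp &
                      panel$variants$pos <= gene$end + window_bp)
      if (length(hits) == 0) next
      X <- D[, hits, drop = FALSE]
      sds <- apply(X, 2, stats::sd)
      if (all(sds == 0)) next
      r <- suppressWarnings(as.numeric(stats::cor(X, E[, g])))
      r[sds == 0] <- 0
      rb <- max(abs(r))
      best_p[g] <- cor_test_tp(rb, n)$p
    }
    sum(bh_adjust(best_p) < fdr_q, na.rm = TRUE)
  }
  trace <- integer(0)
  best <- -1L
  chosen <- 0L
  for (k in 0:max_pcs) {
    E <- if (k == 0) residualize(E0, NULL)
         else residualize(E0, as.data.frame(pcs[, seq_len(k), drop = FALSE]))
    cnt <- count_eqtls(E)
    trace <- c(trace, cnt)
    if (cnt > best) {
      best <- cnt
      chosen <- k
    } else {
      return(list(k = chosen, trace = trace))
    }
  }
  warning("eQTL count still increasing at max_pcs = ", max_pcs)
  list(k = chosen, trace = trace)
}
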