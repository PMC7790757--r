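#' Full splice-pattern similarity protocol for two alteration groups
#'
#' Runs, for one aberration category, the complete comparison of two
#' alteration groups against controls: (1) per-junction Wilcoxon scans
#' (A vs control, B vs control, and A vs B for the enrichment histogram);
#' (2) low-p enrichment per comparison; (3) supervised PCA selection of
#' group-associated junctions independently for each group; (4) an
#' overlap test of the two selected sets against the resampling null over
#' the tested-junction universe; (5) SI_max classification of the union
#' into shared / group-specific / not-determined junctions.
#'
#' @param x An `si_matrix` with group labels in `x$samples$group`.
#' @param group_a,group_b,control Group labels.
#' @param category Aberration category to analyse (default `"proximal3"`);
#'   junctions are restricted to pairs of this category.
#' @param alpha Wilcoxon candidate threshold (uncorrected, default 0.05).
#' @param var_min,auc_min,cor_min,loading_min Supervised-PCA parameters,
#'   see [supervised_pca()].
#' @param n_resamples Resamples for the overlap test.
#' @param seed Seed for the overlap resampling.
#' @return A list of class `similarity_report`: per-comparison p-value
#'   vectors and enrichment p-values, the two `supervised_pca` results,
#'   the `overlap_test`, the shared classification of the union, and the
#'   junction universe used.
#' @export
splice_pattern_similarity <- function(x, group_a, group_b,
                                      control = "control",
                                      category = "proximal3",
                                      alpha = 0.05, var_min = 0.05,
                                      auc_min = 1, cor_min = 0.2,
                                      loading_min = 0.05,
                                      n_resamples = 10000L, seed = NULL) {
  stopifnot(inherits(x, "si_matrix"))
  ids <- x$pairs$id[x$pairs$category == category]
  if (length(ids) == 0L) {
    stop("no junction pairs of category '", category, "'", call. = FALSE)
  }
  si <- si_values(x, ids)
  labels <- x$samples$group

  p_a <- wilcoxon_scan(si, labels, group_a, control)
  p_b <- wilcoxon_scan(si, labels, group_b, control)
  p_ab <- wilcoxon_scan(si, labels, group_a, group_b)

  enrich <- c(a_vs_control = lowp_enrichment(p_a, alpha),
              b_vs_control = lowp_enrichment(p_b, alpha),
              a_vs_b = lowp_enrichment(p_ab, alpha))

  spca_a <- supervised_pca(si, labels, group_a, control, p = p_a,
                           alpha = alpha, var_min = var_min,
                           auc_min = auc_min, cor_min = cor_min,
                           loading_min = loading_min)
  spca_b <- supervised_pca(si, labels, group_b, control, p = p_b,
                           alpha = alpha, var_min = var_min,
                           auc_min = auc_min, cor_min = cor_min,
                           loading_min = loading_min)
  sel_a <- spca_a$selected$junction
  sel_b <- spca_b$selected$junction

  overlap <- overlap_test(sel_a, sel_b, universe_size = length(ids),
                          n_resamples = n_resamples, seed = seed)

  union_sel <- union(sel_a, sel_b)
  shared <- if (length(union_sel) > 0L) {
    classify_shared(si, labels, group_a, group_b, control,
                    junctions = union_sel)
  } else {
    classify_shared(si, labels, group_a, group_b, control,
                    junctions = character(0))
  }

  structure(list(category = category,
                 universe = ids,
                 p_values = list(a_vs_control = p_a, b_vs_control = p_b,
                                 a_vs_b = p_ab),
                 enrichment_p = enrich,
                 spca_a = spca_a, spca_b = spca_b,
                 selected_a = sel_a, selected_b = sel_b,
                 overlap = overlap,
                 shared = shared),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("similarity_report (%s): %d junctions tested\n",
              x$category, length(x$universe)))
  cat(sprintf("  low-p enrichment: A vs ctl %.3g, B vs ctl %.3g, A vs B %.3g\n",
              x$enrichment_p[["a_vs_control"]],
              x$enrichment_p[["b_vs_control"]],
              x$enrichment_p[["a_vs_b"]]))
  cat(sprintf("  selected: |A| = %d, |B| = %d, overlap %d (hypergeom p %.3g)\n",
              length(x$selected_a), length(x$selected_b),
              x$overlap$observed, x$overlap$hypergeom_p))
  if (nrow(x$shared) > 0L) {
    tab <- table(x$shared$label)
    cat("  shared classification:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
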