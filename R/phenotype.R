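#' Call the SF3B1-like splicing phenotype by PCA with a robust cutoff
#'
#' Runs a principal component analysis on the samples x junctions SI
#' matrix (missing SI imputed as 0, columns mean-centred, no variance
#' scaling: SI values already share the `[0, 1]` scale). The sign of PC1
#' is oriented so that it correlates positively with the per-sample mean
#' SI, making high PC1 mean "more cryptic 3'ss usage". A sample is called
#' phenotype-positive when its PC1 score exceeds
#' `median + mad_k * MAD` of the cohort PC1 scores. The MAD carries the
#' usual 1.4826 normal-consistency factor by default (the [stats::mad()]
#' convention, making `mad_k = 3` a robust three-sigma rule); set
#' `mad_constant = 1` for the raw median absolute deviation.
#'
#' @param si Numeric samples x junctions SI matrix, or an `si_matrix`
#'   (optionally restricted via `junctions`).
#' @param junctions Optional junction ids when `si` is an `si_matrix`.
#' @param mad_k Multiplier on the MAD (default 3).
#' @param mad_constant Consistency factor passed to [stats::mad()]
#'   (default 1.4826).
#' @param n_pc Number of PC scores to keep in the output (default 2).
#' @return A data.frame of class `phenotype_calls`: `sample_id`, PC score
#'   columns, `pc1_score`, and logical `sf3b1_like`; attributes `cutoff`,
#'   `var_explained` and `pca` (the `prcomp` fit). A constant matrix is
#'   degenerate: a warning is raised and no sample is called.
#' @export
pca_phenotype <- function(si, junctions = NULL, mad_k = 3,
                          mad_constant = 1.4826, n_pc = 2L) {
  if (inherits(si, "si_matrix")) si <- si_values(si, junctions)
  stopifnot(is.matrix(si))
  if (nrow(si) < 3L || ncol(si) < 2L) {
    stop("need at least 3 samples and 2 junctions for the phenotype PCA",
         call. = FALSE)
  }
  si[is.na(si)] <- 0
  ids <- rownames(si)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(nrow(si)))

  if (all(apply(si, 2L, function(col) max(col) == min(col)))) {
    warning("constant SI matrix: PCA is degenerate, no phenotype called",
            call. = FALSE)
    out <- data.frame(sample_id = ids, pc1_score = 0,
                      sf3b1_like = FALSE, stringsAsFactors = FALSE)
    attr(out, "cutoff") <- NA_real_
    class(out) <- c("phenotype_calls", "data.frame")
    return(out)
  }

  pca <- prcomp(si, center = TRUE, scale. = FALSE)
  scores <- pca$x
  # PCA signs are arbitrary; anchor PC1 to overall cryptic 3'ss usage
  orient <- cor(scores[, 1L], rowMeans(si))
  if (!is.na(orient) && orient < 0) {
    pca$x[, 1L] <- -pca$x[, 1L]
    pca$rotation[, 1L] <- -pca$rotation[, 1L]
    scores <- pca$x
  }
  pc1 <- scores[, 1L]
  cutoff <- median(pc1) + mad_k * mad(pc1, constant = mad_constant)

  n_pc <- min(n_pc, ncol(scores))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (k in seq_len(n_pc)) out[[paste0("PC", k)]] <- unname(scores[, k])
  out$pc1_score <- unname(pc1)
  out$sf3b1_like <- if (mad(pc1, constant = mad_constant) > 0) pc1 > cutoff else {
    warning("MAD of PC1 scores is 0: cutoff degenerate, no sample called",
            call. = FALSE)
    rep(FALSE, length(pc1))
  }
  attr(out, "cutoff") <- cutoff
  attr(out, "var_explained") <- pca$sdev^2 / sum(pca$sdev^2)
  attr(out, "pca") <- pca
  class(out) <- c("phenotype_calls", "data.frame")
  out
}

#' @export
print.phenotype_calls <- function(x, ...) {
  cat(sprintf("phenotype_calls: %d/%d samples above PC1 cutoff %.4g\n",
              sum(x$sf3b1_like), nrow(x), attr(x, "cutoff")))
  invisible(as.data.frame(x))
}

#' Genotype-phenotype enrichment by one-sided Fisher's exact test
#'
#' Tests whether a genetic alteration is over-represented among
#' phenotype-positive samples using the hypergeometric (one-sided,
#' enrichment direction) Fisher's exact test on the 2x2 table, with a
#' Bonferroni adjustment for the number of genes screened.
#'
#' @param n11 Phenotype-positive and altered.
#' @param n12 Phenotype-positive, not altered.
#' @param n21 Altered, phenotype-negative.
#' @param n22 Neither.
#' @param n_tests Bonferroni multiple-testing factor (>= 1), typically the
#'   size of the gene set screened.
#' @return A list of class `enrichment_result`: `table`, `raw_p`,
#'   `adjusted_p` (= `min(1, raw_p * n_tests)`), `n_tests`, `odds_ratio`.
#' @examples
#' fisher_enrichment(5, 4, 3, 11338, n_tests = 500)
#' @export
fisher_enrichment <- function(n11, n12, n21, n22, n_tests = 1L) {
  counts <- c(n11, n12, n21, n22)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be non-negative integers", call. = FALSE)
  }
  if (n_tests < 1) stop("'n_tests' must be >= 1", call. = FALSE)
  # with this layout 'greater' is the enrichment direction
  ft <- fisher.test(matrix(c(n11, n12, n21, n22), nrow = 2L, byrow = TRUE),
                    alternative = "greater")
  raw_p <- ft$p.value
  structure(list(table = matrix(counts, nrow = 2L, byrow = TRUE,
                                dimnames = list(c("phenotype_pos",
                                                  "phenotype_neg"),
                                                c("altered", "wild_type"))),
                 raw_p = raw_p,
                 adjusted_p = min(1, raw_p * n_tests),
                 n_tests = n_tests,
                 odds_ratio = unname(ft$estimate)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("one-sided Fisher p = %.3g; Bonferroni x%d -> %.3g\n",
              x$raw_p, x$n_tests, x$adjusted_p))
  invisible(x)
}
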