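#' Splicing index
#'
#' SI = a / (a + c), the fraction of split reads supporting the aberrant
#' junction among all split reads at the paired aberrant/canonical site.
#' Undefined (NA) when neither junction has any split read.
#'
#' @param a_count,c_count Non-negative integer vectors of aberrant and
#'   canonical split-read counts (recycled to a common length).
#' @return Numeric vector of SI values in `[0, 1]`, NA where
#'   `a_count + c_count == 0`.
#' @examples
#' compute_si(10, 90)            # 0.1
#' compute_si(c(0, 0), c(50, 0)) # 0 and NA
#' @export
compute_si <- function(a_count, c_count) {
  if (any(a_count < 0, na.rm = TRUE) || any(c_count < 0, na.rm = TRUE)) {
    stop("split-read counts must be non-negative", call. = FALSE)
  }
  tot <- a_count + c_count
  ifelse(tot > 0, a_count / tot, NA_real_)
}

#' Expression quantiles against a sample's canonical junction counts
#'
#' The per-sample expression quantile of a count `x` is the fraction of
#' that sample's observed canonical-junction split-read counts that are
#' `<= x` (right-continuous empirical CDF, ties included). Applied to
#' canonical counts this gives CQ, to aberrant counts AQ; both are then
#' comparable across samples of different sequencing depth.
#'
#' @param counts Counts to convert to quantiles.
#' @param canonical_counts The sample's canonical-junction counts; at least
#'   one must be positive.
#' @return Numeric vector of quantiles in `[0, 1]`.
#' @examples
#' compute_quantiles(3, c(1, 2, 3, 4))  # 0.75
#' @export
compute_quantiles <- function(counts, canonical_counts) {
  canonical_counts <- canonical_counts[!is.na(canonical_counts)]
  if (length(canonical_counts) == 0L || all(canonical_counts <= 0)) {
    stop("no expressed canonical junction in sample: quantiles undefined",
         call. = FALSE)
  }
  sorted <- sort(canonical_counts)
  findInterval(counts, sorted) / length(sorted)
}

#' Build the samples x junction-pairs SI/AQ/CQ matrix
#'
#' For every retained aberrant junction (paired with its canonical
#' partner) and every sample, computes the splicing index SI and the
#' expression quantiles AQ (of the aberrant count) and CQ (of the
#' canonical count) within that sample's canonical-count distribution.
#' Junctions absent from a sample's table count as zero split reads.
#'
#' @param sj_list Named list of per-sample junction tables.
#' @param classification A [classify_junctions()] result for the cohort
#'   catalog.
#' @param samples Metadata data.frame with `sample_id` and `group`
#'   (order defines the matrix rows); defaults to the `sj_list` names with
#'   no groups.
#' @return An object of class `si_matrix`: list with numeric matrices
#'   `SI`, `AQ`, `CQ` (samples x pairs), the `samples` metadata and the
#'   `pairs` catalog.
#' @export
build_si_matrix <- function(sj_list, classification, samples = NULL) {
  stopifnot(inherits(classification, "junction_classification"))
  if (is.null(samples)) {
    samples <- data.frame(sample_id = names(sj_list),
                          group = NA_character_, stringsAsFactors = FALSE)
  }
  if (!all(samples$sample_id %in% names(sj_list))) {
    stop("samples metadata lists samples missing from 'sj_list'",
         call. = FALSE)
  }
  pairs <- classification$pairs
  canon_ids <- classification$canonical$id
  n_s <- nrow(samples); n_j <- nrow(pairs)
  SI <- AQ <- CQ <- matrix(NA_real_, n_s, n_j,
                           dimnames = list(samples$sample_id, pairs$id))
  for (s in seq_len(n_s)) {
    tab <- sj_list[[samples$sample_id[s]]]
    counts <- setNames(tab$unique_count,
                       junction_id(tab$chrom, tab$start, tab$end))
    canon_obs <- counts[names(counts) %in% canon_ids]
    canon_obs <- canon_obs[canon_obs > 0]
    a <- unname(counts[pairs$id]); a[is.na(a)] <- 0
    cc <- unname(counts[pairs$canonical_id]); cc[is.na(cc)] <- 0
    SI[s, ] <- compute_si(a, cc)
    AQ[s, ] <- compute_quantiles(a, canon_obs)
    CQ[s, ] <- compute_quantiles(cc, canon_obs)
  }
  structure(list(SI = SI, AQ = AQ, CQ = CQ, samples = samples,
                 pairs = pairs),
            class = "si_matrix")
}

#' @export
print.si_matrix <- function(x, ...) {
  cat(sprintf("si_matrix: %d samples x %d junction pairs\n",
              nrow(x$SI), ncol(x$SI)))
  if (!all(is.na(x$samples$group))) {
    cat("  groups:", paste(names(table(x$samples$group)),
                           table(x$samples$group), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the SI value matrix, optionally restricted and zero-imputed
#'
#' @param x An `si_matrix`.
#' @param junctions Optional junction-pair ids to keep (in this order).
#' @param impute If TRUE (default), missing SI (no split read at either
#'   junction) is treated as 0, i.e. the aberrant form is unexpressed.
#' @return Numeric samples x junctions matrix.
#' @export
si_values <- function(x, junctions = NULL, impute = TRUE) {
  stopifnot(inherits(x, "si_matrix"))
  m <- x$SI
  if (!is.null(junctions)) {
    missing <- setdiff(junctions, colnames(m))
    if (length(missing) > 0L) {
      stop("unknown junction id(s): ", paste(utils::head(missing, 3),
                                             collapse = ", "), call. = FALSE)
    }
    m <- m[, junctions, drop = FALSE]
  }
  if (impute) m[is.na(m)] <- 0
  m
}

#' Unsupervised junction selection by SI and expression gating
#'
#' A junction pair is kept when at least one sample satisfies all of
#' SI >= `si_min`, AQ >= `aq_min` and CQ >= `cq_min`. Two optional rules
#' refine the set: a *ubiquity* rule requiring the canonical partner to
#' show at least marginal expression (CQ >= `ubiquity_cq`) in a fraction
#' `ubiquity_frac` of all samples (guards against tissue-restricted
#' genes in heterogeneous cohorts), and a *control exclusion* rule
#' removing junctions whose canonical partner is unexpressed
#' (CQ < `control_cq_min`) or whose aberrant junction is already well
#' expressed (AQ > `control_aq_max`) in any control-group sample.
#'
#' @param x An `si_matrix`.
#' @param si_min,aq_min,cq_min Per-sample thresholds in `[0, 1]`.
#' @param ubiquity_cq,ubiquity_frac Optional ubiquity rule (both in
#'   `[0, 1]`); disabled when `ubiquity_cq` is NULL.
#' @param control_cq_min,control_aq_max Optional control-exclusion
#'   thresholds; require a `group` column with `control_group` entries.
#' @param control_group Group label treated as control.
#' @return Character vector of selected junction-pair ids.
#' @examples
#' # see the package vignette for an end-to-end example
#' @export
select_junctions <- function(x, si_min = 0.15, aq_min = 0.4, cq_min = 0.5,
                             ubiquity_cq = NULL, ubiquity_frac = 0.95,
                             control_cq_min = NULL, control_aq_max = NULL,
                             control_group = "control") {
  stopifnot(inherits(x, "si_matrix"))
  thr <- c(si_min, aq_min, cq_min, ubiquity_cq, ubiquity_frac,
           control_cq_min, control_aq_max)
  if (any(thr < 0 | thr > 1)) {
    stop("selection thresholds must lie in [0, 1]", call. = FALSE)
  }
  si <- x$SI; si[is.na(si)] <- 0
  pass <- si >= si_min & x$AQ >= aq_min & x$CQ >= cq_min
  keep <- colSums(pass) > 0L

  if (!is.null(ubiquity_cq)) {
    keep <- keep & colMeans(x$CQ >= ubiquity_cq) >= ubiquity_frac
  }
  if (!is.null(control_cq_min) || !is.null(control_aq_max)) {
    ctl <- which(x$samples$group == control_group)
    if (length(ctl) == 0L) {
      stop("control exclusion requested but no '", control_group,
           "' samples present", call. = FALSE)
    }
    if (!is.null(control_cq_min)) {
      keep <- keep & colSums(x$CQ[ctl, , drop = FALSE] < control_cq_min) == 0L
    }
    if (!is.null(control_aq_max)) {
      keep <- keep & colSums(x$AQ[ctl, , drop = FALSE] > control_aq_max) == 0L
    }
  }
  colnames(x$SI)[keep]
}
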