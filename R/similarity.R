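#' Per-junction Wilcoxon rank-sum comparison of SI between two groups
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test on the splicing index
#' of one junction, group versus control. Missing SI is treated as 0
#' (aberrant form unexpressed). The exact null distribution is used when
#' the smaller group has at most 10 samples and the data are tie-free;
#' otherwise the normal approximation with tie correction applies.
#'
#' @param group_si,control_si Numeric SI vectors (NA allowed, read as 0).
#' @return Two-sided p-value.
#' @export
wilcoxon_si <- function(group_si, control_si) {
  if (length(group_si) == 0L || length(control_si) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  group_si[is.na(group_si)] <- 0
  control_si[is.na(control_si)] <- 0
  if (length(group_si) < 2L || length(control_si) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  exact_ok <- min(length(group_si), length(control_si)) <= 10L &&
    !any(duplicated(c(group_si, control_si)))
  suppressWarnings(
    wilcox.test(group_si, control_si, exact = exact_ok,
                correct = TRUE)$p.value
  )
}

#' Wilcoxon scan over all junctions of an SI matrix
#'
#' @param si Samples x junctions SI matrix (or `si_matrix`).
#' @param labels Character vector of group labels per sample (row order).
#' @param group,control Labels of the two compared groups.
#' @return Named vector of two-sided p-values, one per junction.
#' @export
wilcoxon_scan <- function(si, labels, group, control = "control") {
  if (inherits(si, "si_matrix")) {
    labels <- si$samples$group
    si <- si_values(si)
  }
  gi <- which(labels == group); ci <- which(labels == control)
  if (length(gi) == 0L || length(ci) == 0L) {
    stop("empty group in comparison ", group, " vs ", control,
         call. = FALSE)
  }
  apply(si, 2L, function(col) wilcoxon_si(col[gi], col[ci]))
}

#' Enrichment of low p-values against the uniform null
#'
#' Compares the observed split of p-values below/above `alpha` with the
#' split expected under uniformity (`round(alpha * N)` low p-values) by a
#' one-sided Fisher's exact test toward enrichment. Used to decide whether
#' an aberration category reacts at all to a splicing-factor alteration.
#'
#' @param p Vector of p-values.
#' @param alpha Low-p threshold in (0, 1), default 0.05.
#' @return One-sided enrichment p-value.
#' @export
lowp_enrichment <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop("no p-values supplied", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)",
                                     call. = FALSE)
  n <- length(p)
  k <- sum(p < alpha)
  e <- round(alpha * n)
  fisher.test(matrix(c(k, n - k, e, n - e), nrow = 2L, byrow = TRUE),
              alternative = "greater")$p.value
}

#' Supervised PCA selection of group-associated aberrant junctions
#'
#' Implements the three-step protocol for small alteration groups in a
#' heterogeneous cohort: (i) candidate junctions are those with Wilcoxon
#' p < `alpha` (uncorrected) versus controls; (ii) PCA on the centred SI
#' of group + control samples retains major components (explained-variance
#' fraction > `var_min`) and keeps those whose scores separate the group
#' from controls (rank separation measured by AUC, complete separation
#' `auc_min = 1` by default); (iii) junctions correlated with an
#' associated PC (|Pearson r| > `cor_min` or |loading| > `loading_min`)
#' are selected as specific to the alteration.
#'
#' @param si Samples x junctions SI matrix (or `si_matrix`); columns
#'   should already be restricted to the candidate junctions, or supply
#'   `p` to restrict here.
#' @param labels Group label per sample.
#' @param group Label of the alteration group.
#' @param control Label of the control group.
#' @param p Optional named per-junction p-values; when given, candidates
#'   are `names(p)[p < alpha]`.
#' @param alpha Candidate threshold on `p` (default 0.05, uncorrected).
#' @param var_min Minimum explained-variance fraction for a major PC.
#' @param auc_min Minimum separation AUC (in either direction) for a PC to
#'   count as group-associated; 1 demands complete rank separation.
#' @param cor_min,loading_min Junction selection thresholds.
#' @return A list of class `supervised_pca`: `candidates`, `var_explained`,
#'   `major_pcs`, `associated_pcs`, `selected` (data.frame with junction,
#'   PC, correlation, loading, reason), `scores`, `loadings`.
#' @export
supervised_pca <- function(si, labels, group, control = "control",
                           p = NULL, alpha = 0.05, var_min = 0.05,
                           auc_min = 1, cor_min = 0.2,
                           loading_min = 0.05) {
  if (inherits(si, "si_matrix")) {
    labels <- si$samples$group
    si <- si_values(si)
  }
  si[is.na(si)] <- 0
  if (!is.null(p)) {
    cand <- names(p)[!is.na(p) & p < alpha]
    si <- si[, intersect(colnames(si), cand), drop = FALSE]
  }
  cand <- colnames(si)
  empty <- structure(list(candidates = cand,
                          var_explained = numeric(0),
                          major_pcs = integer(0),
                          associated_pcs = integer(0),
                          selected = data.frame(junction = character(0),
                                                pc = integer(0),
                                                correlation = numeric(0),
                                                loading = numeric(0),
                                                reason = character(0),
                                                stringsAsFactors = FALSE),
                          scores = NULL, loadings = NULL),
                     class = "supervised_pca")
  if (length(cand) == 0L) return(empty)

  keep <- labels %in% c(group, control)
  if (sum(labels == group) < 2L) {
    stop("need at least 2 '", group, "' samples", call. = FALSE)
  }
  si <- si[keep, , drop = FALSE]
  labels <- labels[keep]

  # drop zero-variance columns (constant junctions carry no signal)
  v <- apply(si, 2L, function(col) max(col) - min(col))
  si_v <- si[, v > 0, drop = FALSE]
  if (ncol(si_v) == 0L) return(empty)

  pca <- prcomp(si_v, center = TRUE, scale. = FALSE)
  varfrac <- pca$sdev^2 / sum(pca$sdev^2)
  major <- which(varfrac > var_min)
  empty$var_explained <- varfrac
  empty$scores <- pca$x
  empty$loadings <- pca$rotation
  if (length(major) == 0L) return(empty)

  gmask <- labels == group
  auc_of <- function(scores) {
    # Mann-Whitney AUC of group vs control scores
    r <- rank(scores)
    n1 <- sum(gmask); n0 <- sum(!gmask)
    (sum(r[gmask]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  aucs <- vapply(major, function(k) auc_of(pca$x[, k]), numeric(1))
  associated <- major[pmax(aucs, 1 - aucs) >= auc_min]
  empty$major_pcs <- major
  empty$associated_pcs <- associated
  if (length(associated) == 0L) return(empty)

  sel <- list()
  for (k in associated) {
    cors <- suppressWarnings(
      apply(si_v, 2L, function(col) cor(col, pca$x[, k])))
    loads <- pca$rotation[, k]
    hit <- which(abs(cors) > cor_min | abs(loads) > loading_min)
    if (length(hit) > 0L) {
      sel[[length(sel) + 1L]] <- data.frame(
        junction = colnames(si_v)[hit], pc = k,
        correlation = unname(cors[hit]), loading = unname(loads[hit]),
        reason = ifelse(abs(cors[hit]) > cor_min, "correlation", "loading"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(sel) > 0L) {
    sel <- do.call(rbind, sel)
    sel <- sel[!duplicated(sel$junction), , drop = FALSE]
    rownames(sel) <- NULL
    empty$selected <- sel
  }
  empty
}

#' @export
print.supervised_pca <- function(x, ...) {
  cat(sprintf(paste0("supervised_pca: %d candidates; major PCs [%s]; ",
                     "associated PCs [%s]; %d junctions selected\n"),
              length(x$candidates),
              paste(x$major_pcs, collapse = ","),
              paste(x$associated_pcs, collapse = ","),
              nrow(x$selected)))
  invisible(x)
}

#' Significance of the overlap between two selected junction sets
#'
#' Compares the observed overlap of two junction sets with the null in
#' which both are uniform random draws from a common universe. Under that
#' null the overlap count is exactly hypergeometric, so the Monte-Carlo
#' resamples draw overlap counts directly from the hypergeometric law;
#' the closed-form upper-tail probability is reported alongside.
#'
#' @param set_a,set_b Character vectors of junction ids (or their sizes as
#'   single integers together with `observed`).
#' @param universe_size Size of the common candidate pool.
#' @param n_resamples Number of Monte-Carlo resamples (default 10000).
#' @param seed Optional seed for the resampling stream.
#' @param observed Overlap count, only needed when `set_a`/`set_b` are
#'   given as sizes.
#' @return A list of class `overlap_test`: `observed`, `expected`
#'   (`|A||B|/U`), `empirical_p` (add-one estimator), `hypergeom_p`,
#'   `n_resamples`.
#' @examples
#' overlap_test(211, 179, 5357, observed = 110, seed = 1)
#' @export
overlap_test <- function(set_a, set_b, universe_size, n_resamples = 10000L,
                         seed = NULL, observed = NULL) {
  if (length(set_a) == 1L && is.numeric(set_a)) {
    n_a <- as.integer(set_a); n_b <- as.integer(set_b)
    if (is.null(observed)) {
      stop("supply 'observed' when passing set sizes", call. = FALSE)
    }
  } else {
    n_a <- length(unique(set_a)); n_b <- length(unique(set_b))
    observed <- length(intersect(set_a, set_b))
  }
  if (n_a > universe_size || n_b > universe_size) {
    stop("universe smaller than one of the sets", call. = FALSE)
  }
  expected <- n_a * n_b / universe_size
  hyper_p <- phyper(observed - 1L, n_a, universe_size - n_a, n_b,
                    lower.tail = FALSE)
  draws <- with_seed(seed,
                     rhyper(n_resamples, n_a, universe_size - n_a, n_b))
  empirical_p <- (1 + sum(draws >= observed)) / (n_resamples + 1)
  structure(list(observed = observed, expected = expected,
                 empirical_p = empirical_p, hypergeom_p = hyper_p,
                 n_resamples = n_resamples, n_a = n_a, n_b = n_b,
                 universe_size = universe_size),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(paste0("overlap: %d observed vs %.2f expected (|A|=%d, ",
                     "|B|=%d, U=%d)\n  empirical p = %.3g (%d resamples), ",
                     "hypergeometric p = %.3g\n"),
              x$observed, x$expected, x$n_a, x$n_b, x$universe_size,
              x$empirical_p, x$n_resamples, x$hypergeom_p))
  invisible(x)
}

#' Classify selected junctions as shared or group-specific
#'
#' Re-evaluates aberrant expression in the union of the two groups'
#' selected junctions using the maximal SI per group: a junction is
#' `shared` when SI_max exceeds the control 95% quantile in BOTH groups;
#' `A_specific`/`B_specific` (definitively not shared) when one group's
#' SI_max exceeds the control 95% quantile while the other's falls below
#' the control 75% quantile; `not_determined` otherwise (and excluded
#' from shared-fraction summaries downstream).
#'
#' @param si Samples x junctions SI matrix (or `si_matrix`).
#' @param labels Group label per sample.
#' @param group_a,group_b,control Group labels.
#' @param junctions Junction ids to classify (default: all columns).
#' @param q_hi,q_lo Control quantile levels (defaults 0.95 and 0.75,
#'   linear-interpolation sample quantiles).
#' @param min_controls Minimum control group size for the quantiles to be
#'   meaningful (default 20).
#' @return data.frame: `junction`, `si_max_a`, `si_max_b`, `q95`, `q75`,
#'   `label`.
#' @export
classify_shared <- function(si, labels, group_a, group_b,
                            control = "control", junctions = NULL,
                            q_hi = 0.95, q_lo = 0.75, min_controls = 20L) {
  if (inherits(si, "si_matrix")) {
    labels <- si$samples$group
    si <- si_values(si)
  }
  si[is.na(si)] <- 0
  if (!is.null(junctions)) si <- si[, junctions, drop = FALSE]
  ci <- which(labels == control)
  if (length(ci) == 0L) stop("empty control group", call. = FALSE)
  if (length(ci) < min_controls) {
    stop("need at least ", min_controls, " control samples for stable ",
         "quantiles (got ", length(ci), ")", call. = FALSE)
  }
  ai <- which(labels == group_a); bi <- which(labels == group_b)
  if (length(ai) == 0L || length(bi) == 0L) {
    stop("empty alteration group", call. = FALSE)
  }
  if (ncol(si) == 0L) {
    return(data.frame(junction = character(0), si_max_a = numeric(0),
                      si_max_b = numeric(0), q95 = numeric(0),
                      q75 = numeric(0), label = character(0),
                      stringsAsFactors = FALSE))
  }
  simax_a <- apply(si[ai, , drop = FALSE], 2L, max)
  simax_b <- apply(si[bi, , drop = FALSE], 2L, max)
  q95 <- apply(si[ci, , drop = FALSE], 2L, quantile, probs = q_hi,
               names = FALSE)
  q75 <- apply(si[ci, , drop = FALSE], 2L, quantile, probs = q_lo,
               names = FALSE)
  label <- rep("not_determined", ncol(si))
  label[simax_a > q95 & simax_b > q95] <- "shared"
  label[simax_a > q95 & simax_b < q75] <- "A_specific"
  label[simax_b > q95 & simax_a < q75] <- "B_specific"
  data.frame(junction = colnames(si), si_max_a = unname(simax_a),
             si_max_b = unname(simax_b), q95 = unname(q95),
             q75 = unname(q75), label = label, stringsAsFactors = FALSE)
}

#' Relative shift in maximal splicing index versus controls
#'
#' For each junction and experimental group, computes
#' `delta_si_max = (max(SI_exp) - max(SI_ctl)) / max(SI_ctl)`: the
#' relative change of the best-reacting replicate, an exploratory
#' statistic suited to very small experimental groups. Undefined (NA)
#' when the control maximum is 0; such junctions are excluded from
#' delta-SI rankings.
#'
#' @param si Samples x junctions SI matrix (or `si_matrix`).
#' @param labels Group label per sample.
#' @param exp_groups Character vector of experimental group labels.
#' @param control Control group label.
#' @return data.frame: `junction`, one `delta_<group>` column per
#'   experimental group, plus `si_max_control`.
#' @export
delta_si_max <- function(si, labels, exp_groups, control = "control") {
  if (inherits(si, "si_matrix")) {
    labels <- si$samples$group
    si <- si_values(si)
  }
  si[is.na(si)] <- 0
  unknown <- setdiff(c(exp_groups, control), labels)
  if (length(unknown) > 0L) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ci <- which(labels == control)
  max_ctl <- apply(si[ci, , drop = FALSE], 2L, max)
  out <- data.frame(junction = colnames(si),
                    si_max_control = unname(max_ctl),
                    stringsAsFactors = FALSE)
  for (g in exp_groups) {
    gi <- which(labels == g)
    max_g <- apply(si[gi, , drop = FALSE], 2L, max)
    delta <- ifelse(max_ctl > 0, (max_g - max_ctl) / max_ctl, NA_real_)
    out[[paste0("delta_", g)]] <- unname(delta)
  }
  out
}
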