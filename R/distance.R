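#' Distance profile of cryptic 3' acceptors around the canonical acceptor
#'
#' Histogram of signed aberrant-acceptor distances (transcript
#' orientation, 0 = canonical acceptor, negative = upstream) for
#' proximal-3' junction pairs within a +/- `window` nt window, plus the
#' fraction of pairs falling in the characteristic 10-30 nt upstream band.
#'
#' @param pairs Junction-pair table (from [classify_junctions()]);
#'   only rows with `category == "proximal3"` are profiled.
#' @param window Half-width of the histogram window in nt (default 50).
#' @return A list of class `distance_profile`: `histogram` (data.frame
#'   `distance`, `n` covering `-window..window`), `frac_upstream_10_30`
#'   (fraction of proximal-3' pairs with distance in `[-30, -10]`),
#'   `n_overflow` (pairs outside the window), `n_total`.
#' @export
distance_profile <- function(pairs, window = 50L) {
  window <- as.integer(window)
  d <- pairs$distance[pairs$category == "proximal3"]
  d <- d[!is.na(d)]
  inside <- d[abs(d) <= window]
  hist <- data.frame(distance = seq(-window, window),
                     n = as.integer(table(factor(inside,
                                                 levels = seq(-window,
                                                              window)))))
  structure(list(histogram = hist,
                 frac_upstream_10_30 = if (length(d) > 0) {
                   mean(d >= -30L & d <= -10L)
                 } else NA_real_,
                 n_overflow = length(d) - length(inside),
                 n_total = length(d)),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf(paste0("distance_profile: %d proximal-3' pairs (%d outside ",
                     "window); %.1f%% at 10-30 nt upstream\n"),
              x$n_total, x$n_overflow, 100 * x$frac_upstream_10_30))
  invisible(x)
}

#' Reading-frame consequence of proximal-3' aberrant junctions
#'
#' A cryptic acceptor shifted by `distance` nt changes the transcript
#' length by |distance|; the junction is out-of-frame when |distance| is
#' not a multiple of 3. Under uniformly distributed offsets 2/3 of
#' junctions are expected out-of-frame; observing fewer suggests
#' nonsense-mediated decay removes out-of-frame products before they are
#' sequenced.
#'
#' @param pairs Junction-pair table; only `proximal3` rows with a defined
#'   distance are counted.
#' @return A list: `n_out_of_frame`, `n_total`, `fraction`.
#' @export
frame_fraction <- function(pairs) {
  d <- pairs$distance[pairs$category == "proximal3"]
  d <- d[!is.na(d)]
  oof <- abs(d) %% 3L != 0L
  list(n_out_of_frame = sum(oof), n_total = length(d),
       fraction = if (length(d) > 0) mean(oof) else NA_real_)
}

#' Differentially spliced junctions between replicate groups
#'
#' Per-junction two-sided Welch t-test on SI across biological replicates
#' combined with an effect-size threshold on
#' `|log2(mean SI group1 / mean SI group2)|`. Selection can use raw
#' p-values or Benjamini-Hochberg FDR.
#'
#' @param si Samples x junctions SI matrix (or `si_matrix`).
#' @param labels Group label per sample.
#' @param group1,group2 Labels of the two replicate groups (>= 2 each).
#' @param p_max Significance threshold (default 0.05 on raw p; use
#'   `adjust = "BH"` with e.g. `p_max = 0.01` for an FDR criterion).
#' @param log2fc_min Minimum |log2 fold change| of mean SI (default 1).
#' @param adjust `"none"` (raw p) or `"BH"`.
#' @return data.frame: `junction`, `mean_si_1`, `mean_si_2`, `log2fc`,
#'   `p`, `p_adj`, logical `selected`. Junctions with zero mean SI in
#'   both groups are skipped (NA statistics, never selected).
#' @export
differential_junctions <- function(si, labels, group1, group2,
                                   p_max = 0.05, log2fc_min = 1,
                                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (inherits(si, "si_matrix")) {
    labels <- si$samples$group
    si <- si_values(si)
  }
  si[is.na(si)] <- 0
  i1 <- which(labels == group1); i2 <- which(labels == group2)
  if (length(i1) < 2L || length(i2) < 2L) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  m1 <- colMeans(si[i1, , drop = FALSE])
  m2 <- colMeans(si[i2, , drop = FALSE])
  log2fc <- ifelse(m1 > 0 & m2 > 0, log2(m1 / m2),
                   ifelse(m1 == 0 & m2 == 0, NA_real_,
                          ifelse(m1 > 0, Inf, -Inf)))
  p <- vapply(seq_len(ncol(si)), function(j) {
    x <- si[i1, j]; y <- si[i2, j]
    if (m1[j] == 0 && m2[j] == 0) return(NA_real_)
    if (max(x) == min(x) && max(y) == min(y)) {
      # no within-group variance: identical groups are unremarkable,
      # different constant groups are maximally separated
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    }
    t.test(x, y)$p.value
  }, numeric(1))
  p_adj <- if (adjust == "BH") p.adjust(p, method = "BH") else p
  selected <- !is.na(p_adj) & p_adj <= p_max &
    !is.na(log2fc) & abs(log2fc) >= log2fc_min
  data.frame(junction = colnames(si), mean_si_1 = unname(m1),
             mean_si_2 = unname(m2), log2fc = unname(log2fc),
             p = p, p_adj = p_adj, selected = selected,
             stringsAsFactors = FALSE)
}
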