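#' Configuration for the synthetic splice-junction cohort generator
#'
#' Bundles all tunable parameters of the simulator and validates them.
#' The defaults reproduce the study-sized cohort used throughout the
#' package's own validation: 400 control samples, a 6-sample and a 5-sample
#' alteration group, 90 sensitive junctions (50 elevated in both groups,
#' 20 specific to each), a mean splicing index of 0.3 at sensitive junctions
#' in the elevated group(s) and 0.01 elsewhere, and cryptic acceptors
#' planted 10 to 30 nt upstream of canonical acceptors.
#'
#' @param n_genes Number of multi-exon genes to simulate.
#' @param exons_per_gene Integer range `c(min, max)`: exons per gene.
#' @param exon_len Integer range: exon length in nt.
#' @param intron_len Integer range: intron length in nt. Must leave room for
#'   the largest cryptic offset plus a 20 nt donor-side margin.
#' @param n_controls,n_groupA,n_groupB Cohort group sizes. At least one must
#'   be positive.
#' @param n_sensitive Number of canonical junctions given an elevated
#'   cryptic acceptor in one or both alteration groups.
#' @param frac_shared Fraction of sensitive junctions elevated in BOTH
#'   groups; the remainder is split evenly between A-specific and
#'   B-specific.
#' @param si_effect Mean splicing index at a sensitive junction in its
#'   elevated group(s).
#' @param si_background Mean splicing index everywhere else (must be
#'   strictly below `si_effect`).
#' @param nb_dispersion Negative-binomial dispersion of per-junction total
#'   split-read counts (`size = 1/nb_dispersion`).
#' @param base_expr_meanlog,base_expr_sdlog Log-normal parameters for the
#'   per-junction baseline expected split-read count.
#' @param coverage_range Range of per-sample library-size multipliers.
#' @param cryptic_offset_range Integer range (nt) of planted cryptic
#'   acceptor offsets upstream of the canonical acceptor; must lie within
#'   5-100 nt.
#' @param seed Integer seed; identical seeds give bit-identical genomes,
#'   junction tables and reads.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 4, n_controls = 5, n_groupA = 2,
#'                   n_groupB = 2, n_sensitive = 2, seed = 7)
#' @export
sim_config <- function(n_genes = 40,
                       exons_per_gene = c(3L, 6L),
                       exon_len = c(120L, 300L),
                       intron_len = c(150L, 400L),
                       n_controls = 400L,
                       n_groupA = 6L,
                       n_groupB = 5L,
                       n_sensitive = 90L,
                       frac_shared = 50 / 90,
                       si_effect = 0.3,
                       si_background = 0.01,
                       nb_dispersion = 0.15,
                       base_expr_meanlog = log(80),
                       base_expr_sdlog = 0.6,
                       coverage_range = c(0.5, 2),
                       cryptic_offset_range = c(10L, 30L),
                       seed = 1L) {
  rng2 <- function(x, nm) {
    if (length(x) == 1L) x <- c(x, x)
    if (length(x) != 2L || any(is.na(x)) || x[1] > x[2]) {
      stop("'", nm, "' must be a c(min, max) range", call. = FALSE)
    }
    x
  }
  exons_per_gene <- rng2(as.integer(exons_per_gene), "exons_per_gene")
  exon_len <- rng2(as.integer(exon_len), "exon_len")
  intron_len <- rng2(as.integer(intron_len), "intron_len")
  coverage_range <- rng2(as.numeric(coverage_range), "coverage_range")
  cryptic_offset_range <- rng2(as.integer(cryptic_offset_range),
                               "cryptic_offset_range")

  n_genes <- as.integer(n_genes)
  if (n_genes < 1L) stop("'n_genes' must be >= 1", call. = FALSE)
  if (exons_per_gene[1] < 2L) {
    stop("genes need at least 2 exons to carry a junction", call. = FALSE)
  }
  groups <- c(n_controls = as.integer(n_controls),
              n_groupA = as.integer(n_groupA),
              n_groupB = as.integer(n_groupB))
  if (any(groups < 0L)) stop("group sizes must be >= 0", call. = FALSE)
  if (sum(groups) == 0L) {
    stop("at least one cohort group must be non-empty", call. = FALSE)
  }
  n_sensitive <- as.integer(n_sensitive)
  if (n_sensitive < 0L) stop("'n_sensitive' must be >= 0", call. = FALSE)
  if (frac_shared < 0 || frac_shared > 1) {
    stop("'frac_shared' must be in [0, 1]", call. = FALSE)
  }
  if (!(si_background >= 0 && si_background < si_effect && si_effect <= 1)) {
    stop("need 0 <= si_background < si_effect <= 1", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("'nb_dispersion' must be > 0", call. = FALSE)
  if (any(coverage_range <= 0)) {
    stop("'coverage_range' must be positive", call. = FALSE)
  }
  if (cryptic_offset_range[1] < 5L || cryptic_offset_range[2] > 100L) {
    stop("'cryptic_offset_range' must lie within 5-100 nt", call. = FALSE)
  }
  # the cryptic AG must fall inside the intron, clear of the donor site
  if (intron_len[1] < cryptic_offset_range[2] + 20L) {
    stop("intron shorter than cryptic offset: min intron length must be ",
         "at least max offset + 20 nt", call. = FALSE)
  }

  structure(
    list(n_genes = n_genes,
         exons_per_gene = exons_per_gene,
         exon_len = exon_len,
         intron_len = intron_len,
         n_controls = groups[["n_controls"]],
         n_groupA = groups[["n_groupA"]],
         n_groupB = groups[["n_groupB"]],
         n_sensitive = n_sensitive,
         frac_shared = frac_shared,
         si_effect = si_effect,
         si_background = si_background,
         nb_dispersion = nb_dispersion,
         base_expr_meanlog = base_expr_meanlog,
         base_expr_sdlog = base_expr_sdlog,
         coverage_range = coverage_range,
         cryptic_offset_range = cryptic_offset_range,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  genes: %d (%d-%d exons, exon %d-%d nt, intron %d-%d nt)\n",
              x$n_genes, x$exons_per_gene[1], x$exons_per_gene[2],
              x$exon_len[1], x$exon_len[2],
              x$intron_len[1], x$intron_len[2]))
  cat(sprintf("  samples: %d control / %d group A / %d group B\n",
              x$n_controls, x$n_groupA, x$n_groupB))
  cat(sprintf("  sensitive junctions: %d (frac shared %.2f), SI %.3g vs %.3g\n",
              x$n_sensitive, x$frac_shared, x$si_effect, x$si_background))
  cat(sprintf("  cryptic offsets: %d-%d nt upstream; seed %d\n",
              x$cryptic_offset_range[1], x$cryptic_offset_range[2], x$seed))
  invisible(x)
}
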