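#' Simulate a cohort of per-sample splice-junction count tables
#'
#' Draws, for every canonical junction and sample, a total split-read count
#' from a negative binomial (junction-specific baseline expression times a
#' per-sample coverage multiplier, shared dispersion) and splits it between
#' the canonical and the paired cryptic junction by binomial thinning, so
#' that the expected splicing index SI = a/(a+c) equals `si_effect` at a
#' sensitive junction in its elevated group(s) and `si_background`
#' everywhere else. Sensitive junctions are drawn once and partitioned into
#' shared / A-specific / B-specific classes according to `frac_shared`.
#'
#' @param config A [sim_config()].
#' @param model A [make_gene_model()] gene model (normally built from the
#'   same config).
#' @return An object of class `sim_cohort`: a list with
#'   \describe{
#'     \item{sj}{named list of per-sample junction tables in STAR
#'       `SJ.out.tab` column order (see [read_sj_table()]); only junctions
#'       with at least one split read are emitted.}
#'     \item{samples}{data.frame `sample_id`, `group`
#'       (control/groupA/groupB), `coverage` (library-size multiplier).}
#'     \item{truth}{ground truth: data.frame `sensitive` (canonical and
#'       cryptic junction ids, class shared/A_specific/B_specific, planted
#'       offset), plus the planted SI means.}
#'   }
#' @examples
#' cfg <- sim_config(n_genes = 4, n_controls = 4, n_groupA = 2,
#'                   n_groupB = 2, n_sensitive = 3, seed = 11)
#' gm <- make_gene_model(cfg)
#' coh <- simulate_cohort(cfg, gm)
#' head(coh$sj[[1]])
#' @export
simulate_cohort <- function(config, model) {
  stopifnot(inherits(config, "sim_config"), inherits(model, "gene_model"))
  jx <- model$junctions
  if (config$n_sensitive > nrow(jx)) {
    stop("n_sensitive exceeds the number of canonical junctions (",
         nrow(jx), ")", call. = FALSE)
  }
  # offset the stream so the cohort draw is independent of the genome draw
  with_seed(config$seed + 1000L, simulate_cohort_impl(config, jx))
}

simulate_cohort_impl <- function(config, jx) {
  n_jx <- nrow(jx)

  sens_idx <- sort(sample(n_jx, config$n_sensitive))
  n_shared <- round(config$frac_shared * config$n_sensitive)
  n_rest <- config$n_sensitive - n_shared
  n_a <- ceiling(n_rest / 2)
  cls <- rep(c("shared", "A_specific", "B_specific"),
             c(n_shared, n_a, n_rest - n_a))
  cls <- sample(cls)  # random interleaving over the sensitive set

  groups <- rep(c("control", "groupA", "groupB"),
                c(config$n_controls, config$n_groupA, config$n_groupB))
  ids <- sprintf("%s%03d", c("C", "A", "B")[match(groups,
                 c("control", "groupA", "groupB"))],
                 unlist(lapply(c(config$n_controls, config$n_groupA,
                                 config$n_groupB), seq_len)))
  coverage <- runif(length(ids), config$coverage_range[1],
                    config$coverage_range[2])

  base_expr <- rlnorm(n_jx, config$base_expr_meanlog, config$base_expr_sdlog)

  # planted SI per junction x group
  si_for <- function(group) {
    si <- rep(config$si_background, n_jx)
    elev <- switch(group,
                   control = character(0),
                   groupA = c("shared", "A_specific"),
                   groupB = c("shared", "B_specific"))
    si[sens_idx[cls %in% elev]] <- config$si_effect
    si
  }
  si_by_group <- list(control = si_for("control"),
                      groupA = si_for("groupA"),
                      groupB = si_for("groupB"))

  size <- 1 / config$nb_dispersion
  strand_code <- ifelse(jx$strand == "+", 1L, 2L)
  motif_code <- ifelse(jx$strand == "+", 1L, 2L)  # GT/AG vs CT/AC

  sj <- vector("list", length(ids))
  names(sj) <- ids
  for (s in seq_along(ids)) {
    total <- as.integer(rnbinom(n_jx, size = size,
                                mu = base_expr * coverage[s]))
    ab <- as.integer(rbinom(n_jx, total, si_by_group[[groups[s]]]))
    can <- total - ab
    tab <- rbind(
      data.frame(chrom = jx$chrom, start = jx$start, end = jx$end,
                 strand_code = strand_code, motif = motif_code,
                 annotated = 1L, unique_count = can, multi_count = 0L,
                 overhang = 50L, stringsAsFactors = FALSE),
      data.frame(chrom = jx$chrom, start = jx$cryptic_start,
                 end = jx$cryptic_end, strand_code = strand_code,
                 motif = motif_code, annotated = 0L, unique_count = ab,
                 multi_count = 0L, overhang = 50L, stringsAsFactors = FALSE)
    )
    tab <- tab[tab$unique_count > 0L, , drop = FALSE]
    tab <- tab[order(tab$chrom, tab$start, tab$end), , drop = FALSE]
    rownames(tab) <- NULL
    sj[[s]] <- tab
  }

  sensitive <- data.frame(
    canonical_id = jx$canonical_id[sens_idx],
    cryptic_id = jx$cryptic_id[sens_idx],
    class = cls,
    offset = jx$offset[sens_idx],
    stringsAsFactors = FALSE
  )

  structure(
    list(sj = sj,
         samples = data.frame(sample_id = ids, group = groups,
                              coverage = coverage, stringsAsFactors = FALSE),
         truth = list(sensitive = sensitive,
                      si_effect = config$si_effect,
                      si_background = config$si_background)),
    class = "sim_cohort"
  )
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d samples (%s), %d sensitive junctions\n",
              nrow(x$samples),
              paste(table(x$samples$group), collapse = "/"),
              nrow(x$truth$sensitive)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes one `SJ.out.tab`-dialect file per sample plus a metadata TSV
#' (`sample_id`, `group`, `coverage`) into `dir`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (id in names(cohort$sj)) {
    p <- file.path(dir, paste0(id, ".SJ.out.tab"))
    write.table(cohort$sj[[id]], p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, "samples.tsv")
  write.table(cohort$samples, mp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paths, mp))
}
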