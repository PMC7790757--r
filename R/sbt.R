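#' Build a 40-nt probe set spanning aberrant junctions
#'
#' For each aberrant junction, extracts the 40-nt sequence centred on the
#' aberrant splice joint in the mature mRNA: the 20 genomic nt ending at
#' the last base before the intron start, concatenated with the 20 nt
#' starting right after the intron end, reverse-complemented to mRNA sense
#' for minus-strand junctions. Duplicate probe sequences arising from
#' distinct junctions are collapsed to a single probe; all source junction
#' ids are retained in the map.
#'
#' @param pairs Aberrant-junction table (the `pairs` element of a
#'   [classify_junctions()] result, or any data.frame with `chrom`,
#'   `start`, `end`, `strand` and `id`).
#' @param genome A named [Biostrings::DNAStringSet] covering the junction
#'   coordinates (e.g. `model$genome`).
#' @param flank Half-width of the probe (default 20 nt per side).
#' @return An object of class `probe_set`: list with `probes` (a named
#'   `DNAStringSet` of unique probe sequences) and `map` (data.frame
#'   `probe_id`, `junction_id`, `sequence`). Junctions too close to a
#'   contig end are skipped with a warning.
#' @export
build_probe_set <- function(pairs, genome, flank = 20L) {
  stopifnot(inherits(genome, "DNAStringSet"))
  flank <- as.integer(flank)
  if (is.null(pairs$id)) {
    pairs$id <- junction_id(pairs$chrom, pairs$start, pairs$end)
  }
  widths <- setNames(Biostrings::width(genome), names(genome))
  seqs <- character(nrow(pairs))
  ok <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    w <- widths[[pairs$chrom[i]]]
    if (is.null(w) || pairs$start[i] - flank < 1L ||
        pairs$end[i] + flank > w) {
      warning("junction ", pairs$id[i],
              " too close to contig end; skipped", call. = FALSE)
      next
    }
    chrom_seq <- genome[[pairs$chrom[i]]]
    probe <- paste0(
      as.character(Biostrings::subseq(chrom_seq, pairs$start[i] - flank,
                                      pairs$start[i] - 1L)),
      as.character(Biostrings::subseq(chrom_seq, pairs$end[i] + 1L,
                                      pairs$end[i] + flank))
    )
    if (identical(pairs$strand[i], "-")) {
      probe <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(probe)))
    }
    seqs[i] <- probe
    ok[i] <- TRUE
  }
  map <- data.frame(junction_id = pairs$id[ok], sequence = seqs[ok],
                    stringsAsFactors = FALSE)
  uniq <- unique(map$sequence)
  probe_ids <- setNames(sprintf("probe%04d", seq_along(uniq)), uniq)
  map$probe_id <- unname(probe_ids[map$sequence])
  probes <- Biostrings::DNAStringSet(setNames(uniq, unname(probe_ids[uniq])))
  structure(list(probes = probes,
                 map = map[, c("probe_id", "junction_id", "sequence")]),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe_set: %d unique %d-nt probes from %d junctions\n",
              length(x$probes), Biostrings::width(x$probes)[1],
              nrow(x$map)))
  invisible(x)
}

#' Write / read a probe set as FASTA
#'
#' @param probes A `probe_set`.
#' @param path FASTA file path.
#' @return `read_probe_fasta()` returns a `probe_set` (map reduced to one
#'   row per probe); writers return `path` invisibly.
#' @export
write_probe_fasta <- function(probes, path) {
  stopifnot(inherits(probes, "probe_set"))
  Biostrings::writeXStringSet(probes$probes, path)
  invisible(path)
}

#' @rdname write_probe_fasta
#' @export
read_probe_fasta <- function(path) {
  probes <- Biostrings::readDNAStringSet(path)
  structure(list(probes = probes,
                 map = data.frame(probe_id = names(probes),
                                  junction_id = names(probes),
                                  sequence = as.character(probes),
                                  stringsAsFactors = FALSE)),
            class = "probe_set")
}

#' Score the probe burden of one sample's reads
#'
#' A probe scores 1 when at least one read contains it (or its reverse
#' complement: libraries may be unstranded) within `max_mismatch`
#' substitutions, 0 otherwise; the sample's burden score is the number of
#' probes found. Matching is substitution-only (Hamming distance, no
#' indels) and exhaustive over all read positions, so a probe truly
#' present at `<= max_mismatch` is never missed.
#'
#' @param reads A [Biostrings::DNAStringSet], or one or more FASTQ paths.
#' @param probes A `probe_set`.
#' @param max_mismatch Maximum substitutions tolerated (default 2).
#' @return Integer burden score with attribute `found`: a named logical
#'   vector, one entry per probe.
#' @export
score_sample <- function(reads, probes, max_mismatch = 2L) {
  stopifnot(inherits(probes, "probe_set"))
  if (is.character(reads)) {
    if (!all(file.exists(reads))) {
      stop("FASTQ file not found: ",
           paste(reads[!file.exists(reads)], collapse = ", "),
           call. = FALSE)
    }
    sets <- lapply(reads, read_fastq)
    reads <- do.call(c, sets)
  }
  stopifnot(inherits(reads, "DNAStringSet"))
  found <- setNames(logical(length(probes$probes)), names(probes$probes))
  if (length(reads) > 0L) {
    for (p in seq_along(probes$probes)) {
      probe <- probes$probes[[p]]
      n <- sum(Biostrings::vcountPattern(probe, reads,
                                         max.mismatch = max_mismatch,
                                         fixed = TRUE))
      if (n == 0L) {
        n <- sum(Biostrings::vcountPattern(
          Biostrings::reverseComplement(probe), reads,
          max.mismatch = max_mismatch, fixed = TRUE))
      }
      found[p] <- n > 0L
    }
  }
  structure(sum(found), found = found)
}

#' Coverage-adjust burden scores with a linear model
#'
#' Fits ordinary least squares `sbt_score ~ coverage` on the samples below
#' the 99th percentile of raw scores (high-burden candidates must not pull
#' the trend), then computes fitted values and residuals for all samples.
#' The residual is the coverage-adjusted burden score.
#'
#' @param results data.frame with columns `sample_id`, `sbt_score`, and
#'   `coverage` (a monotone coverage proxy: read count or file size).
#' @param trim Quantile of raw scores above which samples are excluded
#'   from the fit (default 0.99; ties at the boundary are excluded).
#' @return The input data.frame with `fitted`, `residual` columns and
#'   attribute `model` (the `lm` fit).
#' @export
adjust_scores <- function(results, trim = 0.99) {
  need <- c("sample_id", "sbt_score", "coverage")
  if (!all(need %in% names(results))) {
    stop("'results' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(results) < 3L) {
    stop("need at least 3 samples to fit the coverage model", call. = FALSE)
  }
  if (length(unique(results$coverage)) == 1L) {
    stop("coverage has zero variance; cannot adjust scores", call. = FALSE)
  }
  cutoff <- quantile(results$sbt_score, trim, names = FALSE)
  fit_set <- results$sbt_score < cutoff
  if (sum(fit_set) < 3L) fit_set <- rep(TRUE, nrow(results))
  fit <- lm(sbt_score ~ coverage, data = results[fit_set, , drop = FALSE])
  results$fitted <- unname(predict(fit, newdata = results))
  results$residual <- results$sbt_score - results$fitted
  attr(results, "model") <- fit
  results
}

#' Flag high-burden samples
#'
#' @param results Output of [adjust_scores()].
#' @param cutoff Residual threshold; samples with `residual >= cutoff` are
#'   flagged (boundary inclusive).
#' @param anchor Alternatively, a sample id whose residual defines the
#'   cutoff (e.g. the weakest validated positive case).
#' @return The data.frame with a logical `flagged` column; the cutoff used
#'   is stored as attribute `cutoff`.
#' @export
flag_high <- function(results, cutoff = NULL, anchor = NULL) {
  if (is.null(results$residual)) {
    stop("run adjust_scores() first", call. = FALSE)
  }
  if (is.null(cutoff)) {
    if (is.null(anchor)) stop("supply 'cutoff' or 'anchor'", call. = FALSE)
    hit <- match(anchor, results$sample_id)
    if (is.na(hit)) stop("anchor sample '", anchor, "' not found",
                         call. = FALSE)
    cutoff <- results$residual[hit]
  }
  results$flagged <- results$residual >= cutoff
  attr(results, "cutoff") <- cutoff
  results
}
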