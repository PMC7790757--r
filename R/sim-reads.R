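#' Simulate junction-spanning reads for one sample
#'
#' Every junction row with `unique_count = k` contributes exactly `k`
#' junction-spanning reads: the read concatenates the genomic flank ending
#' at the last exonic base before the intron with the flank starting at the
#' first base after it, split as evenly as `read_len` allows, and is
#' reverse-complemented to mRNA sense for minus-strand junctions. Optional
#' background reads are drawn uniformly from the genome, and a per-base
#' substitution error rate can be applied to all reads.
#'
#' @param sj A per-sample junction table (as produced by
#'   [simulate_cohort()] or [read_sj_table()]); needs columns `chrom`,
#'   `start`, `end`, `strand_code` (or `strand`), `unique_count`.
#' @param model A `gene_model` (supplies the genome sequence).
#' @param read_len Read length in nt; must be at least 40 (the probe
#'   length used by the burden screen).
#' @param n_background Number of background genomic reads.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed for base errors / background placement.
#' @return A named [Biostrings::DNAStringSet] of reads. Junction reads are
#'   named `<junction id>/<i>`, background reads `bg/<i>`.
#' @examples
#' cfg <- sim_config(n_genes = 2, n_controls = 1, n_groupA = 0,
#'                   n_groupB = 0, n_sensitive = 1, seed = 5)
#' gm <- make_gene_model(cfg)
#' coh <- simulate_cohort(cfg, gm)
#' reads <- simulate_reads(coh$sj[[1]], gm, read_len = 60, seed = 5)
#' @export
simulate_reads <- function(sj, model, read_len = 100L, n_background = 0L,
                           error_rate = 0, seed = 1L) {
  stopifnot(inherits(model, "gene_model"))
  read_len <- as.integer(read_len)
  if (read_len < 40L) {
    stop("'read_len' must be >= 40 nt (the probe length)", call. = FALSE)
  }
  if (error_rate < 0 || error_rate >= 1) {
    stop("'error_rate' must be in [0, 1)", call. = FALSE)
  }
  with_seed(seed, simulate_reads_impl(sj, model, read_len,
                                      as.integer(n_background), error_rate))
}

simulate_reads_impl <- function(sj, model, read_len, n_background,
                                error_rate) {
  genome <- model$genome
  strand <- sj_strand(sj)
  l_up <- read_len %/% 2L
  l_dn <- read_len - l_up

  seqs <- character(0)
  nms <- character(0)
  keep <- sj$unique_count > 0L
  for (i in which(keep)) {
    chrom_seq <- genome[[sj$chrom[i]]]
    up <- as.character(Biostrings::subseq(chrom_seq,
                                          sj$start[i] - l_up, sj$start[i] - 1L))
    dn <- as.character(Biostrings::subseq(chrom_seq,
                                          sj$end[i] + 1L, sj$end[i] + l_dn))
    read <- paste0(up, dn)
    if (identical(strand[i], "-")) {
      read <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(read)))
    }
    k <- sj$unique_count[i]
    seqs <- c(seqs, rep(read, k))
    nms <- c(nms, sprintf("%s/%d", junction_id(sj$chrom[i], sj$start[i],
                                               sj$end[i]), seq_len(k)))
  }

  if (n_background > 0L) {
    chrom <- names(genome)[1]
    maxpos <- Biostrings::width(genome)[1] - read_len + 1L
    starts <- sample(maxpos, n_background, replace = TRUE)
    bg <- substring(as.character(genome[[chrom]]), starts,
                    starts + read_len - 1L)
    flip <- runif(n_background) < 0.5
    if (any(flip)) {
      bg[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(bg[flip])))
    }
    seqs <- c(seqs, bg)
    nms <- c(nms, sprintf("bg/%d", seq_len(n_background)))
  }

  if (error_rate > 0 && length(seqs) > 0) {
    seqs <- add_base_errors(seqs, error_rate)
  }
  Biostrings::DNAStringSet(setNames(seqs, nms))
}

# substitution errors: each position independently replaced by one of the
# three other bases with probability `rate`
add_base_errors <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (p in hit) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# strand labels from either a strand column or the SJ.out.tab strand code
# (exact name lookup: `$` would partially match strand -> strand_code)
sj_strand <- function(sj) {
  if ("strand" %in% names(sj)) {
    as.character(sj[["strand"]])
  } else if ("strand_code" %in% names(sj)) {
    c("*", "+", "-")[sj[["strand_code"]] + 1L]
  } else {
    rep("*", nrow(sj))
  }
}

#' Write reads as FASTQ
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a DNAStringSet
#'
#' @param path FASTQ file path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fastq <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
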