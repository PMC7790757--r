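#' Generate a toy genome and exon annotation with planted cryptic acceptors
#'
#' Lays out multi-exon genes on both strands of a single synthetic
#' chromosome. Every canonical junction receives proper splice-site
#' dinucleotides (GT donor, AG acceptor, in transcript orientation) and a
#' planted cryptic AG acceptor at a configured offset upstream (in
#' transcript orientation) of the canonical acceptor, inside the intron.
#' Usage of the cryptic acceptor retains the last `offset` intronic
#' nucleotides in the mRNA, the hallmark of branchpoint-corrupted 3'
#' splice-site selection.
#'
#' @param config A [sim_config()].
#' @return An object of class `gene_model`: a list with
#'   \describe{
#'     \item{genome}{named [Biostrings::DNAStringSet] (one chromosome).}
#'     \item{exons}{data.frame of exon boundaries: `gene_id`, `chrom`,
#'       `strand`, `exon` (transcript order), `start`, `end` (genomic).}
#'     \item{junctions}{data.frame with one row per canonical junction:
#'       intron coordinates (`start`, `end`, first/last intronic base),
#'       the paired cryptic-junction coordinates, the planted `offset`
#'       (nt upstream of the canonical acceptor), and id strings.}
#'   }
#' @examples
#' gm <- make_gene_model(sim_config(n_genes = 2, n_controls = 1,
#'                                  n_sensitive = 1, seed = 3))
#' gm$junctions
#' @export
make_gene_model <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, make_gene_model_impl(config))
}

make_gene_model_impl <- function(config) {
  gap <- 500L
  chrom <- "chrS"
  exon_rows <- list()
  jx_rows <- list()
  cursor <- gap
  plant <- list()  # list of (pos, "XY") dinucleotide plantings

  for (g in seq_len(config$n_genes)) {
    gene_id <- sprintf("gene%03d", g)
    strand <- if (g %% 2L == 0L) "-" else "+"
    n_ex <- sample_range(config$exons_per_gene[1], config$exons_per_gene[2])
    ex_len <- sample_range(config$exon_len[1], config$exon_len[2], n_ex)
    in_len <- sample_range(config$intron_len[1], config$intron_len[2],
                           n_ex - 1L)

    starts <- integer(n_ex)
    ends <- integer(n_ex)
    pos <- cursor + 1L
    for (i in seq_len(n_ex)) {
      starts[i] <- pos
      ends[i] <- pos + ex_len[i] - 1L
      pos <- ends[i] + 1L
      if (i < n_ex) pos <- pos + in_len[i]
    }
    cursor <- ends[n_ex] + gap

    # exon numbers follow transcript order (reversed on the minus strand)
    exon_no <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
    exon_rows[[g]] <- data.frame(
      gene_id = gene_id, chrom = chrom, strand = strand,
      exon = exon_no, start = starts, end = ends,
      stringsAsFactors = FALSE
    )

    for (i in seq_len(n_ex - 1L)) {
      istart <- ends[i] + 1L
      iend <- starts[i + 1L] - 1L
      ilen <- iend - istart + 1L
      off <- sample_range(config$cryptic_offset_range[1],
                          min(config$cryptic_offset_range[2], ilen - 20L))
      if (strand == "+") {
        plant[[length(plant) + 1L]] <- list(istart, "GT")          # donor
        plant[[length(plant) + 1L]] <- list(iend - 1L, "AG")       # acceptor
        plant[[length(plant) + 1L]] <- list(iend - off - 1L, "AG") # cryptic
        cs <- istart; ce <- iend - off
      } else {
        plant[[length(plant) + 1L]] <- list(iend - 1L, "AC")       # donor (rc GT)
        plant[[length(plant) + 1L]] <- list(istart, "CT")          # acceptor (rc AG)
        plant[[length(plant) + 1L]] <- list(istart + off, "CT")    # cryptic
        cs <- istart + off; ce <- iend
      }
      jx_rows[[length(jx_rows) + 1L]] <- data.frame(
        gene_id = gene_id, chrom = chrom, strand = strand,
        start = istart, end = iend,
        cryptic_start = cs, cryptic_end = ce, offset = off,
        canonical_id = junction_id(chrom, istart, iend),
        cryptic_id = junction_id(chrom, cs, ce),
        stringsAsFactors = FALSE
      )
    }
  }

  len <- cursor + gap
  seq_chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (p in plant) {
    seq_chars[p[[1]] + 0:1] <- strsplit(p[[2]], "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(
    setNames(paste(seq_chars, collapse = ""), chrom)
  )

  structure(
    list(genome = genome,
         exons = do.call(rbind, exon_rows),
         junctions = do.call(rbind, jx_rows)),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d genes, %d canonical junctions, genome %s (%d nt)\n",
              length(unique(x$exons$gene_id)), nrow(x$junctions),
              names(x$genome)[1], Biostrings::width(x$genome)[1]))
  invisible(x)
}

#' Write and read gene-model components as plain-text files
#'
#' `write_genome_fasta()` writes the synthetic chromosome(s) as FASTA;
#' `write_exon_table()` / `read_exon_table()` exchange the exon annotation
#' as a tab-separated table with columns `gene_id`, `chrom`, `strand`,
#' `exon`, `start`, `end`.
#'
#' @param model A `gene_model`.
#' @param path Output (or input) file path.
#' @return `read_exon_table()` returns the exon data.frame; the writers
#'   return `path` invisibly.
#' @export
write_genome_fasta <- function(model, path) {
  Biostrings::writeXStringSet(model$genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
write_exon_table <- function(model, path) {
  write.table(model$exons, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_exon_table <- function(path) {
  exons <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "exon", "start", "end")
  if (!all(need %in% names(exons))) {
    stop("exon table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  exons
}
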