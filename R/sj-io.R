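#' Read a STAR SJ.out.tab splice-junction table
#'
#' Parses the 9-column tab-separated dialect written by STAR: chromosome,
#' first intronic base (1-based), last intronic base (1-based), strand code
#' (0 undetermined / 1 plus / 2 minus), intron motif code, annotated flag,
#' unique-mapping read count, multi-mapping read count, maximum overhang.
#' Only unique-mapping reads are used as split-read counts downstream
#' (multi-mappers are conservative noise).
#'
#' @param path Path to an SJ.out.tab-style file.
#' @return A data.frame with the 9 SJ columns plus a derived `strand`
#'   factor-free column (`"+"`, `"-"`, or `"*"` for undetermined). An empty
#'   file yields a zero-row table.
#' @examples
#' tf <- tempfile()
#' writeLines("chr1\t1001\t2000\t1\t1\t1\t42\t3\t50", tf)
#' read_sj_table(tf)
#' @export
read_sj_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- c("chrom", "start", "end", "strand_code", "motif", "annotated",
            "unique_count", "multi_count", "overhang")
  if (file.size(path) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand_code = integer(0),
                      motif = integer(0), annotated = integer(0),
                      unique_count = integer(0), multi_count = integer(0),
                      overhang = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  nf <- count.fields(path, sep = "\t", quote = "")
  bad <- which(nf != 9L)
  if (length(bad) > 0L) {
    stop("malformed SJ row (expected 9 tab-separated columns, got ",
         nf[bad[1]], ") at line ", bad[1], " of ", path, call. = FALSE)
  }
  tab <- read.delim(path, header = FALSE, col.names = cols,
                    colClasses = c("character", rep("integer", 8L)),
                    quote = "", stringsAsFactors = FALSE)
  if (any(tab$start >= tab$end)) {
    stop("malformed SJ row (intron start must precede intron end) at line ",
         which(tab$start >= tab$end)[1], " of ", path, call. = FALSE)
  }
  if (any(tab$unique_count < 0L)) {
    stop("negative split-read count at line ",
         which(tab$unique_count < 0L)[1], " of ", path, call. = FALSE)
  }
  tab$strand <- c("*", "+", "-")[tab$strand_code + 1L]
  tab
}

#' Read a cohort directory of SJ tables plus metadata
#'
#' Companion to [write_cohort()]: reads `samples.tsv` and one
#' `<sample_id>.SJ.out.tab` per sample.
#'
#' @param dir Directory written by [write_cohort()].
#' @return A list with `sj` (named list of junction tables) and `samples`
#'   (metadata data.frame).
#' @export
read_cohort <- function(dir) {
  mp <- file.path(dir, "samples.tsv")
  if (!file.exists(mp)) stop("no samples.tsv in ", dir, call. = FALSE)
  samples <- read.delim(mp, stringsAsFactors = FALSE)
  sj <- lapply(samples$sample_id, function(id) {
    read_sj_table(file.path(dir, paste0(id, ".SJ.out.tab")))
  })
  names(sj) <- samples$sample_id
  list(sj = sj, samples = samples)
}
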