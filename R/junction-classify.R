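#' Collapse per-sample junction tables into a cohort junction catalog
#'
#' @param sj_list A (named) list of per-sample junction tables.
#' @return A data.frame of unique junctions (`chrom`, `start`, `end`,
#'   `strand`, `id`); where samples disagree on strand, the first
#'   determined value wins.
#' @export
junction_catalog <- function(sj_list) {
  all <- do.call(rbind, lapply(sj_list, function(tab) {
    data.frame(chrom = tab$chrom, start = tab$start, end = tab$end,
               strand = sj_strand(tab), stringsAsFactors = FALSE)
  }))
  all$id <- junction_id(all$chrom, all$start, all$end)
  # prefer determined strands when deduplicating
  all <- all[order(all$id, all$strand == "*"), , drop = FALSE]
  out <- all[!duplicated(all$id), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# annotated introns derived from an exon table: one row per gap between
# genomically adjacent exons of a gene
annotated_introns <- function(exons) {
  if (is.null(exons) || nrow(exons) == 0L) {
    stop("annotation without exons", call. = FALSE)
  }
  need <- c("gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons))) {
    stop("exon annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  parts <- split(exons, exons$gene_id)
  rows <- lapply(parts, function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    n <- nrow(ex)
    if (n < 2L) return(NULL)
    data.frame(gene_id = ex$gene_id[1], chrom = ex$chrom[1],
               strand = ex$strand[1],
               start = ex$end[-n] + 1L, end = ex$start[-1L] - 1L,
               stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, rows)
  if (is.null(introns) || nrow(introns) == 0L) {
    stop("annotation has no multi-exon gene, no junction can be annotated",
         call. = FALSE)
  }
  introns$id <- junction_id(introns$chrom, introns$start, introns$end)
  rownames(introns) <- NULL
  introns
}

#' Classify cohort junctions against an exon annotation
#'
#' Reproduces the junction taxonomy used for cryptic 3'ss analysis. A
#' junction is **canonical** when both ends coincide with an annotated
#' intron of one gene. Junctions sharing exactly one end with an annotated
#' intron are **half-canonical** and are paired with the nearest annotated
#' partner sharing that end: category `proximal3` / `proximal5` when the
#' free acceptor / donor lies within 100 nt of the canonical one, `distant`
#' beyond 100 nt. Junctions joining exon boundaries of the same gene
#' without being annotated are `aberrant_exon` (e.g. exon skipping).
#' Junctions with two non-annotated ends, or connecting two different
#' genes (chimeric), are discarded with a reason.
#'
#' Distances are reported in transcript orientation: negative means the
#' aberrant splice site lies upstream (for a cryptic 3' acceptor 15 nt
#' into the intron, `distance = -15` on either strand). A junction with
#' undetermined strand is retained and inherits the strand of the matched
#' gene.
#'
#' @param junctions A junction catalog ([junction_catalog()]) or any
#'   data.frame with `chrom`, `start`, `end` and `strand` (or
#'   `strand_code`).
#' @param exons Exon annotation data.frame (`gene_id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @return A list of class `junction_classification`:
#'   \describe{
#'     \item{canonical}{annotated junctions observed in the cohort.}
#'     \item{pairs}{one row per retained aberrant junction: coordinates,
#'       `gene_id`, `strand`, `category`, signed `distance`, and its
#'       canonical partner's id and coordinates.}
#'     \item{discarded}{junctions removed, with a `reason`
#'       (`both_noncanonical` or `chimeric`).}
#'   }
#' @export
classify_junctions <- function(junctions, exons) {
  introns <- annotated_introns(exons)
  if (!"strand" %in% names(junctions)) junctions$strand <- sj_strand(junctions)
  if (!"id" %in% names(junctions)) {
    junctions$id <- junction_id(junctions$chrom, junctions$start,
                                junctions$end)
  }

  intron_ids <- introns$id
  start_key <- paste(introns$chrom, introns$start)
  end_key <- paste(introns$chrom, introns$end)

  canonical <- list(); pairs <- list(); discarded <- list()

  for (i in seq_len(nrow(junctions))) {
    jx <- junctions[i, ]
    if (jx$id %in% intron_ids) {
      hit <- introns[match(jx$id, intron_ids), ]
      canonical[[length(canonical) + 1L]] <- data.frame(
        id = jx$id, chrom = jx$chrom, start = jx$start, end = jx$end,
        strand = hit$strand, gene_id = hit$gene_id,
        stringsAsFactors = FALSE)
      next
    }
    # ends matching annotated splice sites (strand-compatible genes only)
    ok_strand <- function(idx) {
      idx[jx$strand == "*" | introns$strand[idx] == jx$strand]
    }
    m_start <- ok_strand(which(start_key == paste(jx$chrom, jx$start)))
    m_end <- ok_strand(which(end_key == paste(jx$chrom, jx$end)))
    g_start <- unique(introns$gene_id[m_start])
    g_end <- unique(introns$gene_id[m_end])

    if (length(m_start) > 0L && length(m_end) > 0L) {
      common <- intersect(g_start, g_end)
      if (length(common) == 0L) {
        discarded[[length(discarded) + 1L]] <- data.frame(
          id = jx$id, reason = "chimeric", stringsAsFactors = FALSE)
        next
      }
      gene <- sort(common)[1]
      strand <- introns$strand[introns$gene_id == gene][1]
      # both ends are annotated boundaries but the junction itself is not:
      # aberrant exon usage; pair with the annotated intron sharing the
      # transcript donor for bookkeeping (distance is undefined)
      donor_pool <- if (strand == "+") m_start else m_end
      donor_pool <- donor_pool[introns$gene_id[donor_pool] == gene]
      partner <- introns[donor_pool[1], ]
      pairs[[length(pairs) + 1L]] <- data.frame(
        id = jx$id, chrom = jx$chrom, start = jx$start, end = jx$end,
        strand = strand, gene_id = gene, category = "aberrant_exon",
        distance = NA_integer_, canonical_id = partner$id,
        canonical_start = partner$start, canonical_end = partner$end,
        stringsAsFactors = FALSE)
      next
    }
    if (length(m_start) == 0L && length(m_end) == 0L) {
      discarded[[length(discarded) + 1L]] <- data.frame(
        id = jx$id, reason = "both_noncanonical", stringsAsFactors = FALSE)
      next
    }

    if (length(m_start) > 0L) {
      # shared end at the intron start: donor on '+', acceptor on '-'
      cand <- introns[m_start, , drop = FALSE]
      cand <- cand[cand$gene_id == cand$gene_id[1], , drop = FALSE]
      strand <- cand$strand[1]
      dvec <- jx$end - cand$end
      side <- if (strand == "+") "3" else "5"
    } else {
      cand <- introns[m_end, , drop = FALSE]
      cand <- cand[cand$gene_id == cand$gene_id[1], , drop = FALSE]
      strand <- cand$strand[1]
      dvec <- jx$start - cand$start
      side <- if (strand == "+") "5" else "3"
    }
    sign <- if (strand == "+") 1L else -1L
    tdist <- sign * dvec
    # nearest annotated partner; exact ties break to the lower coordinate
    ord <- order(abs(tdist), cand$start, cand$end)
    best <- ord[1]
    distance <- as.integer(tdist[best])
    category <- if (abs(distance) <= 100L) paste0("proximal", side) else "distant"
    pairs[[length(pairs) + 1L]] <- data.frame(
      id = jx$id, chrom = jx$chrom, start = jx$start, end = jx$end,
      strand = strand, gene_id = cand$gene_id[1], category = category,
      distance = distance, canonical_id = cand$id[best],
      canonical_start = cand$start[best], canonical_end = cand$end[best],
      stringsAsFactors = FALSE)
  }

  bind <- function(lst, proto) {
    if (length(lst) == 0L) proto else {
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    }
  }
  structure(
    list(
      canonical = bind(canonical, data.frame(
        id = character(0), chrom = character(0), start = integer(0),
        end = integer(0), strand = character(0), gene_id = character(0),
        stringsAsFactors = FALSE)),
      pairs = bind(pairs, data.frame(
        id = character(0), chrom = character(0), start = integer(0),
        end = integer(0), strand = character(0), gene_id = character(0),
        category = character(0), distance = integer(0),
        canonical_id = character(0), canonical_start = integer(0),
        canonical_end = integer(0), stringsAsFactors = FALSE)),
      discarded = bind(discarded, data.frame(
        id = character(0), reason = character(0), stringsAsFactors = FALSE)),
      introns = introns
    ),
    class = "junction_classification"
  )
}

#' @export
print.junction_classification <- function(x, ...) {
  cat(sprintf(paste0("junction_classification: %d canonical, %d aberrant",
                     " (%s), %d discarded\n"),
              nrow(x$canonical), nrow(x$pairs),
              paste(names(table(x$pairs$category)),
                    table(x$pairs$category), sep = "=", collapse = ", "),
              nrow(x$discarded)))
  invisible(x)
}
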