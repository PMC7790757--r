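# Shared fixtures and independent oracles. Everything here is generated in
# code at test time; the oracles deliberately avoid the code paths they
# check (plain-R loops, closed forms, exhaustive enumeration).

.fx <- new.env()

# a small cohort world reused across test files: 10 genes, 30 controls,
# 4 + 4 alteration samples, 10 sensitive junctions
small_world <- function() {
  if (is.null(.fx$world)) {
    cfg <- sim_config(n_genes = 10, n_controls = 30, n_groupA = 4,
                      n_groupB = 4, n_sensitive = 10, seed = 42)
    gm <- make_gene_model(cfg)
    coh <- simulate_cohort(cfg, gm)
    cl <- classify_junctions(junction_catalog(coh$sj), gm$exons)
    sim <- build_si_matrix(coh$sj, cl, coh$samples)
    .fx$world <- list(cfg = cfg, gm = gm, coh = coh, cl = cl, sim = sim)
  }
  .fx$world
}

# a hand-built two-gene exon annotation (one gene per strand) for the
# classifier unit tests; coordinates chosen so arithmetic is easy to check
toy_exons <- function() {
  rbind(
    data.frame(gene_id = "gplus", chrom = "chr1", strand = "+",
               exon = 1:3, start = c(100L, 1001L, 2001L),
               end = c(500L, 1500L, 2500L)),
    data.frame(gene_id = "gminus", chrom = "chr1", strand = "-",
               exon = 3:1, start = c(5000L, 6001L, 7001L),
               end = c(5500L, 6500L, 7500L)),
    data.frame(gene_id = "gother", chrom = "chr2", strand = "+",
               exon = 1:2, start = c(100L, 1001L),
               end = c(500L, 1500L))
  )
}

toy_junction <- function(chrom, start, end, strand = "*") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand,
             stringsAsFactors = FALSE)
}

# brute-force Hamming sliding-window probe scoring: the oracle for
# score_sample(); substitution-only distance on both strands
revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

hamming_found <- function(probe, reads, max_mm) {
  pl <- nchar(probe)
  pc <- strsplit(probe, "")[[1]]
  rc <- strsplit(revcomp_chr(probe), "")[[1]]
  for (r in reads) {
    n <- nchar(r)
    if (n < pl) next
    rchars <- strsplit(r, "")[[1]]
    for (off in 0:(n - pl)) {
      win <- rchars[(off + 1):(off + pl)]
      if (sum(win != pc) <= max_mm || sum(win != rc) <= max_mm) {
        return(TRUE)
      }
    }
  }
  FALSE
}

hamming_score <- function(probes, reads, max_mm) {
  sum(vapply(probes, hamming_found, logical(1), reads = reads,
             max_mm = max_mm))
}

# exhaustive enumeration of the one-sided Fisher p for fixed margins,
# using only factorial arithmetic (independent of phyper/fisher.test)
fisher_enum_p <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12; c1 <- n11 + n21; n <- n11 + n12 + n21 + n22
  a_min <- max(0L, r1 + c1 - n); a_max <- min(r1, c1)
  prob_a <- function(a) {
    exp(lchoose(c1, a) + lchoose(n - c1, r1 - a) - lchoose(n, r1))
  }
  sum(vapply(n11:a_max, prob_a, numeric(1)))
}

# exact two-sided rank-sum p by enumerating all group assignments
# (tie-free data, small n); mirrors the R convention 2*min(tails)
ranksum_enum_p <- function(x, y) {
  vals <- c(x, y)
  stopifnot(!any(duplicated(vals)))
  m <- length(x)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(length(vals), m)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# continuous null SI (tie-free almost surely) for calibration checks
null_si_groups <- function(n_group, n_control) {
  list(group = stats::rbeta(n_group, 1, 30),
       control = stats::rbeta(n_control, 1, 30))
}
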