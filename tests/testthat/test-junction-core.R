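test_that("SJ.out.tab rows parse by the format contract", {
  tf <- withr::local_tempfile()
  writeLines(c("chr1\t1001\t2000\t1\t1\t1\t42\t3\t50",
               "chr1\t3001\t4000\t0\t0\t0\t7\t0\t31"), tf)
  tab <- read_sj_table(tf)
  expect_identical(tab$chrom, c("chr1", "chr1"))
  expect_identical(tab$start, c(1001L, 3001L))
  expect_identical(tab$end, c(2000L, 4000L))
  expect_identical(tab$strand, c("+", "*"))   # code 0 retained, undetermined
  expect_identical(tab$unique_count, c(42L, 7L))

  bad <- withr::local_tempfile()
  writeLines(c("chr1\t1001\t2000\t1\t1\t1\t42\t3\t50",
               "chr1\t1001\t2000\t1\t1\t1\t42\t3"), bad)
  expect_error(read_sj_table(bad), "line 2")

  empty <- withr::local_tempfile()
  file.create(empty)
  expect_identical(nrow(read_sj_table(empty)), 0L)
})

test_that("junction taxonomy follows the category definitions", {
  ex <- toy_exons()
  # gplus introns: 501-1000 and 1501-2000; gminus: 5501-6000, 6501-7000
  cases <- rbind(
    cbind(toy_junction("chr1", 501, 1000, "+"), want = "canonical"),
    cbind(toy_junction("chr1", 501, 985, "+"), want = "proximal3"),
    cbind(toy_junction("chr1", 501, 1850, "+"), want = "distant"),
    cbind(toy_junction("chr1", 530, 1000, "+"), want = "proximal5"),
    cbind(toy_junction("chr1", 501, 2000, "+"), want = "aberrant_exon"),
    cbind(toy_junction("chr1", 333, 777, "+"), want = "both_noncanonical"),
    cbind(toy_junction("chr1", 6516, 7000, "-"), want = "proximal3"),
    cbind(toy_junction("chr1", 6501, 6960, "-"), want = "proximal5")
  )
  cl <- classify_junctions(cases, ex)
  expect_identical(cl$canonical$id, "chr1:501:1000")
  expect_identical(cl$discarded$reason, "both_noncanonical")
  got <- setNames(cl$pairs$category, cl$pairs$id)
  expect_identical(unname(got["chr1:501:985"]), "proximal3")
  expect_identical(unname(got["chr1:501:1850"]), "distant")
  expect_identical(unname(got["chr1:530:1000"]), "proximal5")
  expect_identical(unname(got["chr1:501:2000"]), "aberrant_exon")

  d <- setNames(cl$pairs$distance, cl$pairs$id)
  expect_identical(unname(d["chr1:501:985"]), -15L)   # acceptor 15 nt upstream
  expect_identical(unname(d["chr1:530:1000"]), 29L)   # donor 29 nt into intron
  # minus strand: upstream is the higher genomic coordinate
  expect_identical(unname(d["chr1:6516:7000"]), -15L)
  expect_identical(unname(d["chr1:6501:6960"]), 40L)
})

test_that("chimeric junctions are excluded and undetermined strand is rescued", {
  ex <- toy_exons()
  # donor of gplus joined to an acceptor coordinate of gother (chr2): the
  # two ends match different genes only when on the same chromosome, so
  # emulate a chimera within chr1 by joining gplus donor to gminus acceptor
  chim <- toy_junction("chr1", 501, 6000, "*")
  cl <- classify_junctions(chim, ex)
  expect_identical(cl$discarded$reason, "chimeric")

  undet <- toy_junction("chr1", 501, 985, "*")
  cl2 <- classify_junctions(undet, ex)
  expect_identical(cl2$pairs$strand, "+")
  expect_identical(cl2$pairs$category, "proximal3")

  expect_error(classify_junctions(undet, ex[0, ]), "exons")
})

test_that("every retained aberrant junction receives exactly one category", {
  w <- small_world()
  cl <- w$cl
  expect_true(all(cl$pairs$category %in%
                  c("proximal3", "proximal5", "distant", "aberrant_exon")))
  expect_identical(anyDuplicated(cl$pairs$id), 0L)
  # catalog partition: canonical + pairs + discarded covers the catalog
  catalog <- junction_catalog(w$coh$sj)
  expect_setequal(catalog$id,
                  c(cl$canonical$id, cl$pairs$id, cl$discarded$id))
})

test_that("the splicing index follows its defining formula", {
  expect_identical(compute_si(10, 90), 0.1)
  expect_identical(compute_si(0, 50), 0)
  expect_true(is.na(compute_si(0, 0)))
  expect_error(compute_si(-1, 5), "non-negative")
  # complementarity: SI(a, c) + SI(c, a) = 1 whenever a + c > 0
  a <- c(0L, 1L, 7L, 120L); b <- c(5L, 0L, 3L, 80L)
  expect_equal(compute_si(a, b) + compute_si(b, a), rep(1, 4))
})

test_that("expression quantiles are the canonical-count eCDF", {
  expect_identical(compute_quantiles(3, c(1, 2, 3, 4)), 0.75)
  expect_identical(compute_quantiles(10, c(1, 2, 3, 4)), 1)
  expect_identical(compute_quantiles(0, c(1, 2, 3, 4)), 0)
  expect_error(compute_quantiles(3, numeric(0)), "quantiles undefined")
  expect_error(compute_quantiles(3, c(0, 0)), "quantiles undefined")
  # monotone non-decreasing in the count, ties counted <= x
  canon <- c(4, 4, 9, 1, 30, 2, 2)
  q <- compute_quantiles(0:31, canon)
  expect_true(all(diff(q) >= 0))
  expect_identical(compute_quantiles(4, canon), 5 / 7)  # {1,2,2,4,4} <= 4
})

test_that("the SI matrix reproduces hand-computed cells", {
  ex <- data.frame(gene_id = "g", chrom = "c", strand = "+",
                   exon = 1:2, start = c(1L, 201L), end = c(100L, 300L))
  mk <- function(counts) {
    # rows: canonical 101-200, cryptic 101-185, extra canonical-free noise
    data.frame(chrom = "c", start = c(101L, 101L), end = c(200L, 185L),
               strand_code = 1L, motif = 1L, annotated = c(1L, 0L),
               unique_count = counts, multi_count = 0L, overhang = 50L)
  }
  sj <- list(s1 = mk(c(90L, 10L)), s2 = mk(c(50L, 0L)))
  cl <- classify_junctions(junction_catalog(sj), ex)
  sim <- build_si_matrix(sj, cl)
  expect_identical(dim(sim$SI), c(2L, 1L))
  expect_equal(sim$SI["s1", "c:101:185"], 0.1)
  expect_equal(sim$SI["s2", "c:101:185"], 0)
  # one expressed canonical junction per sample: CQ = 1, AQ = eCDF(a)
  expect_equal(sim$CQ["s1", 1], 1)
  expect_equal(sim$AQ["s1", 1], 0)   # 10 < 90, no canonical count <= 10
  expect_equal(sim$AQ["s2", 1], 0)
})

test_that("junction selection applies the threshold rules per sample", {
  # hand-built matrix: one junction passes all three gates in one sample,
  # one fails the SI gate everywhere, one ubiquitously weak canonical
  mk <- function(...) matrix(c(...), nrow = 2, byrow = TRUE,
                             dimnames = list(c("s1", "s2"),
                                             c("j_keep", "j_lowsi", "j_weak")))
  sim <- structure(list(
    SI = mk(0.20, 0.10, 0.30,
            0.05, 0.10, 0.30),
    AQ = mk(0.50, 0.50, 0.50,
            0.10, 0.50, 0.50),
    CQ = mk(0.60, 0.60, 0.25,
            0.60, 0.60, 0.25),
    samples = data.frame(sample_id = c("s1", "s2"),
                         group = c("control", "control")),
    pairs = data.frame(id = c("j_keep", "j_lowsi", "j_weak"))),
    class = "si_matrix")
  expect_identical(select_junctions(sim, 0.15, 0.4, 0.5), "j_keep")
  # j_weak passes its gates (SI 0.3, AQ 0.5) only while CQ >= 0.25 allowed
  expect_setequal(select_junctions(sim, 0.15, 0.4, 0.2),
                  c("j_keep", "j_weak"))
  # ubiquity at CQ >= 0.3 in 95% of samples removes j_weak again
  expect_identical(select_junctions(sim, 0.15, 0.4, 0.2,
                                    ubiquity_cq = 0.3,
                                    ubiquity_frac = 0.95), "j_keep")
  expect_error(select_junctions(sim, si_min = 1.5), "\\[0, 1\\]")
})

test_that("junction selection is monotone and recovers expressed sensitive junctions", {
  w <- small_world()
  sim <- w$sim
  sel <- select_junctions(sim, si_min = 0.15, aq_min = 0.1, cq_min = 0.3)
  truth <- w$coh$truth$sensitive$cryptic_id
  # expression gating keeps the well-expressed sensitive junctions (some
  # planted junctions sit in weakly expressed genes and fail AQ/CQ, which
  # is the gates' purpose) and admits no background junction
  expect_gte(mean(truth %in% sel), 0.5)
  expect_true(all(sel %in% truth))

  # monotonicity: raising any threshold never adds junctions
  sel_base <- select_junctions(sim, 0.1, 0.1, 0.1)
  for (args in list(c(0.3, 0.1, 0.1), c(0.1, 0.5, 0.1), c(0.1, 0.1, 0.6))) {
    tighter <- select_junctions(sim, args[1], args[2], args[3])
    expect_true(all(tighter %in% sel_base))
  }

  # ubiquity: junctions whose canonical partner drops below CQ 0.3 in more
  # than 5% of samples are removed
  sel_ubiq <- select_junctions(sim, 0.1, 0.1, 0.1, ubiquity_cq = 0.3,
                               ubiquity_frac = 0.95)
  expect_true(all(sel_ubiq %in% sel_base))
  frac_ok <- colMeans(sim$CQ >= 0.3)
  expect_true(all(frac_ok[sel_ubiq] >= 0.95))
  expect_true(all(frac_ok[setdiff(sel_base, sel_ubiq)] < 0.95))
})

test_that("control-group exclusion removes junctions aberrantly expressed in controls", {
  w <- small_world()
  sim <- w$sim
  sel <- select_junctions(sim, 0.1, 0.1, 0.1,
                          control_cq_min = 0.2, control_aq_max = 0.6)
  ctl <- which(sim$samples$group == "control")
  for (j in sel) {
    expect_true(all(sim$CQ[ctl, j] >= 0.2))
    expect_true(all(sim$AQ[ctl, j] <= 0.6))
  }
  expect_error(select_junctions(sim, 0.1, 0.1, 0.1, control_cq_min = 0.2,
                                control_group = "nope"), "no 'nope'")
})
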