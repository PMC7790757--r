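test_that("the Wilcoxon SI comparison is exact for small tie-free groups", {
  set.seed(23)
  for (rep in 1:10) {
    x <- round(rbeta(4, 2, 5), 6)
    y <- round(rbeta(7, 2, 5), 6)
    if (any(duplicated(c(x, y)))) next
    expect_equal(wilcoxon_si(x, y), ranksum_enum_p(x, y),
                 tolerance = 1e-12)
  }
  # complete separation of a 5-sample group from many controls is a very
  # small but finite tail
  p_sep <- wilcoxon_si(rep(0.3, 5), rep(0, 100))
  expect_lt(p_sep, 1e-4)
  # a group drawn as a permutation of control values sits at the centre
  vals <- rbeta(20, 2, 5)
  expect_gt(wilcoxon_si(vals[1:10], vals[11:20] * 0 + vals[1:10]), 0.9)
  expect_error(wilcoxon_si(numeric(0), 1:3), "non-empty")
  expect_error(wilcoxon_si(0.5, c(0.1, 0.2)), "2 values")
})

test_that("null p-values are approximately uniform across junctions", {
  set.seed(67)
  p <- replicate(400, {
    g <- null_si_groups(5, 60)
    wilcoxon_si(g$group, g$control)
  })
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("low-p enrichment detects excesses and stays calm at zero", {
  # 500 of 1000 below alpha: astronomically enriched
  p_enriched <- c(runif(500, 0, 0.049), runif(500, 0.06, 1))
  expect_lt(lowp_enrichment(p_enriched), 1e-10)
  # closed-form check at the same counts (one-sided hypergeometric tail)
  k <- 500; n <- 1000; e <- round(0.05 * n)
  expect_equal(lowp_enrichment(p_enriched),
               fisher_enum_p(k, n - k, e, n - e), tolerance = 1e-10)
  # no low p-values at all: p = 1
  expect_equal(lowp_enrichment(runif(100, 0.2, 1)), 1)
  expect_error(lowp_enrichment(numeric(0)), "no p-values")
  expect_error(lowp_enrichment(0.5, alpha = 1), "alpha")
})

test_that("supervised PCA selects planted junctions and resists label shuffles", {
  w <- small_world()
  sim <- w$sim
  truth <- w$coh$truth$sensitive
  planted_a <- truth$cryptic_id[truth$class %in% c("shared", "A_specific")]
  si <- si_values(sim)
  labels <- sim$samples$group
  p_a <- wilcoxon_scan(si, labels, "groupA")
  res <- supervised_pca(si, labels, "groupA", p = p_a)
  expect_true(length(res$associated_pcs) >= 1)
  sel <- res$selected$junction
  expect_gte(mean(planted_a %in% sel), 0.8)
  # few unplanted junctions sneak in
  expect_lte(mean(!(sel %in% truth$cryptic_id)), 0.2)
  # retained PCs all explain > 5% variance
  expect_true(all(res$var_explained[res$major_pcs] > 0.05))

  # shuffled labels: no group-associated PC in >= 95% of permutations
  set.seed(91)
  hits <- replicate(40, {
    lab_perm <- sample(labels)
    r <- supervised_pca(si, lab_perm, "groupA",
                        p = wilcoxon_scan(si, lab_perm, "groupA"))
    length(r$associated_pcs) > 0
  })
  expect_lte(mean(hits), 0.05)
})

test_that("a single perfectly separating junction is selected via PC1", {
  si <- cbind(jx = c(rep(0.4, 3), rep(0.01, 20)) +
                seq(0, 0.001, length.out = 23))
  rownames(si) <- paste0("s", 1:23)
  labels <- c(rep("groupA", 3), rep("control", 20))
  res <- supervised_pca(si, labels, "groupA")
  expect_identical(res$associated_pcs, 1L)
  expect_identical(res$selected$junction, "jx")
})

test_that("overlap significance agrees with enumeration and behaves at the edges", {
  # tiny universe: empirical within Monte-Carlo error of the closed form
  ot <- overlap_test(3, 3, 10, n_resamples = 20000, seed = 2,
                     observed = 2)
  exact <- sum(vapply(2:3, function(k) {
    choose(3, k) * choose(7, 3 - k) / choose(10, 3)
  }, numeric(1)))
  expect_equal(ot$hypergeom_p, exact, tolerance = 1e-12)
  mc_se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(ot$empirical_p - exact), 3 * mc_se + 1e-4)

  # id-based call
  ot2 <- overlap_test(letters[1:5], letters[4:8], 26, n_resamples = 1000,
                      seed = 1)
  expect_identical(ot2$observed, 2L)
  expect_equal(ot2$expected, 25 / 26)

  # empty overlap of tiny sets in a huge universe is unremarkable
  ot3 <- overlap_test(paste0("a", 1:3), paste0("b", 1:3), 1e4,
                      n_resamples = 1000, seed = 3)
  expect_gt(ot3$empirical_p, 0.95)
  expect_equal(ot3$hypergeom_p, 1, tolerance = 1e-6)

  expect_error(overlap_test(5, 3, 4, observed = 1), "universe smaller")
})

test_that("the SI_max rule classifies shared and specific junctions", {
  # 30 controls at 0 with a known spread; groups engineered around the
  # control quantiles
  set.seed(6)
  ctl <- matrix(runif(30 * 3, 0, 0.2), 30, 3)
  q95 <- apply(ctl, 2, quantile, 0.95)
  q75 <- apply(ctl, 2, quantile, 0.75)
  si <- rbind(ctl,
              a1 = c(0.4, 0.4, 0.4),
              b1 = c(0.35, q75[2] * 0.5, (q75[3] + q95[3]) / 2))
  colnames(si) <- c("shared_jx", "a_only_jx", "grey_jx")
  labels <- c(rep("control", 30), "groupA", "groupB")
  got <- classify_shared(si, labels, "groupA", "groupB",
                         min_controls = 20)
  expect_identical(got$label,
                   c("shared", "A_specific", "not_determined"))
  expect_error(classify_shared(si, labels, "groupA", "groupB",
                               control = "none"), "control")
  expect_error(classify_shared(si[1:10, , drop = FALSE],
                               labels[1:10], "groupA", "groupB"),
               "at least 20")
})

test_that("delta SI max follows its formula with a guarded denominator", {
  si <- rbind(c1 = c(0.1, 0, 0.2), c2 = c(0.05, 0, 0.1),
              e1 = c(0.3, 0.5, 0.1), e2 = c(0.25, 0.1, 0.2))
  colnames(si) <- c("j1", "j2", "j3")
  labels <- c("control", "control", "exp", "exp")
  d <- delta_si_max(si, labels, "exp")
  expect_equal(d$delta_exp[1], (0.3 - 0.1) / 0.1)   # = 2
  expect_true(is.na(d$delta_exp[2]))                # control max 0
  expect_equal(d$delta_exp[3], 0)                   # equal maxima
  expect_error(delta_si_max(si, labels, "nope"), "unknown group")
})

test_that("distance profiling and frame accounting follow the definitions", {
  pairs <- data.frame(id = paste0("j", 1:5), category = "proximal3",
                      distance = c(-15L, -16L, -24L, -99L, 60L))
  # 60 is outside the +/-50 window; -99 in window? no: |distance|>50
  dp <- distance_profile(pairs, window = 50)
  expect_identical(dp$n_total, 5L)
  expect_identical(dp$n_overflow, 2L)
  expect_identical(dp$histogram$n[dp$histogram$distance == -15], 1L)
  expect_identical(sum(dp$histogram$n), 3L)
  expect_equal(dp$frac_upstream_10_30, 3 / 5)

  ff <- frame_fraction(pairs)
  # out of frame: -16, -99? 99 %% 3 == 0 -> in frame; 60 %% 3 == 0
  expect_identical(ff$n_out_of_frame, 1L)
  expect_equal(ff$fraction, 1 / 5)
  # distances uniform over an interval of length divisible by 3: exactly
  # 2/3 out of frame
  unif <- data.frame(id = paste0("u", 1:99), category = "proximal3",
                     distance = -(1:99))
  expect_equal(frame_fraction(unif)$fraction, 2 / 3)
  # single junction at -15 is in frame and fully in the 10-30 band
  single <- data.frame(id = "s", category = "proximal3", distance = -15L)
  expect_equal(distance_profile(single)$frac_upstream_10_30, 1)
  expect_identical(frame_fraction(single)$n_out_of_frame, 0L)
})

test_that("differential junctions need both significance and fold change", {
  si <- rbind(m1 = c(0.30, 0.10, 0.18, 0), m2 = c(0.28, 0.11, 0.19, 0),
              m3 = c(0.32, 0.09, 0.20, 0),
              w1 = c(0.05, 0.10, 0.10, 0), w2 = c(0.06, 0.11, 0.11, 0),
              w3 = c(0.04, 0.09, 0.09, 0))
  colnames(si) <- c("strong", "flat", "small_fc", "silent")
  labels <- rep(c("mut", "wt"), each = 3)
  res <- differential_junctions(si, labels, "mut", "wt")
  expect_true(res$selected[res$junction == "strong"])
  # hand-computed Welch t for the strong junction
  tt <- t.test(c(0.30, 0.28, 0.32), c(0.05, 0.06, 0.04))
  expect_equal(res$p[res$junction == "strong"], tt$p.value)
  expect_gt(res$log2fc[res$junction == "strong"], 1)
  # identical distributions: not selected
  expect_false(res$selected[res$junction == "flat"])
  # significant but |log2FC| < 1: not selected
  expect_lt(res$p[res$junction == "small_fc"], 0.05)
  expect_lt(abs(res$log2fc[res$junction == "small_fc"]), 1)
  expect_false(res$selected[res$junction == "small_fc"])
  # zero SI in both groups: skipped
  expect_true(is.na(res$p[res$junction == "silent"]))
  expect_false(res$selected[res$junction == "silent"])
  # BH mode never selects more than raw mode at the same threshold
  res_bh <- differential_junctions(si, labels, "mut", "wt", adjust = "BH")
  expect_true(all(res_bh$selected <= res$selected))
  expect_error(differential_junctions(si[1:2, ], labels[1:2], "mut", "wt"),
               "2 replicates")
})

test_that("the full similarity protocol reports coherent structure", {
  w <- small_world()
  rep <- splice_pattern_similarity(w$sim, "groupA", "groupB",
                                   n_resamples = 2000, seed = 14)
  truth <- w$coh$truth$sensitive
  # only proximal3 junctions are tested (that is where effects live)
  expect_identical(rep$category, "proximal3")
  # both group comparisons light up, A vs B does not
  expect_lt(rep$enrichment_p[["a_vs_control"]], 0.05)
  expect_lt(rep$enrichment_p[["b_vs_control"]], 0.05)
  expect_gt(rep$enrichment_p[["a_vs_b"]], 0.05)
  # selected sets overlap far beyond chance
  expect_lt(rep$overlap$hypergeom_p, 0.01)
  expect_equal(rep$overlap$empirical_p, rep$overlap$hypergeom_p,
               tolerance = 0.02)
  # shared junctions found among the planted shared set
  shared_called <- rep$shared$junction[rep$shared$label == "shared"]
  expect_gt(length(shared_called), 0)
  expect_true(all(shared_called %in% truth$cryptic_id))
})
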