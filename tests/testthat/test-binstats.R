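test_that("one-way ANOVA reproduces hand sums of squares", {
  # {A:(2,3,7), B:(6,8,10)}: SSB = 24, SSW = 22, F = 24/(22/4)
  r <- one_way_anova(list(A = c(2, 3, 7), B = c(6, 8, 10)))
  expect_equal(r$F, 24 / (22 / 4), tolerance = 1e-12)
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 4L)
  # equal group contents: F = 0, p = 1
  r0 <- one_way_anova(list(A = c(1, 2, 3), B = c(1, 2, 3)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # zero within-group variance with unequal means: p = 0
  rz <- one_way_anova(list(A = c(0, 0), B = c(1, 1)))
  expect_equal(rz$p, 0)
  expect_error(one_way_anova(list(A = 1:3)), "2 groups")
})

test_that("one-way ANOVA matches the linear-model oracle on random data", {
  set.seed(101)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    samples <- lapply(seq_len(k), function(i)
      rnorm(sample(2:8, 1), mean = runif(1, 0, 3)))
    mine <- one_way_anova(samples)
    orc <- oracle_anova(samples)
    expect_equal(mine$F, orc$F, tolerance = 1e-9)
    expect_equal(mine$p, orc$p, tolerance = 1e-9)
    expect_equal(mine$df1, orc$df1)
    expect_equal(mine$df2, orc$df2)
  }
})

test_that("F is invariant under relabeling of groups", {
  set.seed(7)
  samples <- lapply(1:4, function(i) rnorm(6, i / 2))
  f1 <- one_way_anova(samples)$F
  f2 <- one_way_anova(samples[c(3, 1, 4, 2)])$F
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("BH step-up matches hand computations and rejects bad input", {
  r <- bh_fdr(c(0.01, 0.04, 0.03, 0.02))
  expect_equal(r$q, rep(0.04, 4))
  r2 <- bh_fdr(c(0.001, 0.9))
  expect_equal(r2$q, c(0.002, 0.9))
  r3 <- bh_fdr(rep(1, 5))
  expect_equal(r3$q, rep(1, 5))
  expect_false(any(r3$reject))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("BH q-values match the literal step-up and stats::p.adjust", {
  set.seed(202)
  for (rep in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)$q
    expect_equal(q, oracle_bh(p))
    # p.adjust orders its multiplications differently; agree to 1e-12
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p))
    # monotone in the sorted order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

make_cm <- function(counts, id, group) structure(
  list(animal_id = id, group = group, counts = counts,
       n_in_roi = sum(counts), n_outside = 0L, n_in_masked_bins = 0L),
  class = "count_matrix")

test_that("mass-univariate statistics: identical groups, F = t^2, family rules", {
  roi <- rect_roi(90, 70)
  grid <- build_bin_grid(roi, 7, 9)
  base <- matrix(rpois(63, 5), 7, 9)
  cms <- c(lapply(1:3, function(i) make_cm(base, paste0("a", i), "g1")),
           lapply(1:3, function(i) make_cm(base, paste0("b", i), "g2")))
  bs <- mass_univariate(cms, grid)
  expect_true(all(bs$F[bs$family] == 0))
  expect_false(any(bs$significant))
  # two groups: per-bin F equals the squared pooled t statistic
  set.seed(5)
  cms2 <- c(lapply(1:4, function(i)
    make_cm(matrix(rpois(63, 5), 7, 9), paste0("a", i), "g1")),
    lapply(1:4, function(i)
      make_cm(matrix(rpois(63, 8), 7, 9), paste0("b", i), "g2")))
  bs2 <- mass_univariate(cms2, grid)
  x <- sapply(cms2, function(m) as.vector(m$counts))
  g <- rep(c("g1", "g2"), each = 4)
  for (bin in c(1, 17, 40)) {
    tt <- t.test(x[bin, g == "g1"], x[bin, g == "g2"], var.equal = TRUE)
    expect_equal(bs2$F[bin], unname(tt$statistic^2), tolerance = 1e-9)
  }
  # all-zero bins never enter the FDR family
  zero_bin <- lapply(cms2, function(m) { m$counts[3, 3] <- 0L; m })
  bs3 <- mass_univariate(zero_bin, grid)
  expect_false(bs3$family[3, 3])
  expect_true(is.na(bs3$q[3, 3]))
  expect_equal(bs3$m, 62L)
})

test_that("grid mismatch and single-condition inputs error", {
  roi <- rect_roi(90, 70)
  grid <- build_bin_grid(roi, 7, 9)
  cms <- list(make_cm(matrix(1L, 7, 9), "a", "g1"),
              make_cm(matrix(1L, 5, 5), "b", "g2"))
  expect_error(mass_univariate(cms, grid), "differing grids")
  one <- lapply(1:4, function(i) make_cm(matrix(1L, 7, 9), paste0("a", i), "g1"))
  expect_error(mass_univariate(one, grid), "2 conditions")
})

test_that("a seeded hotspot bin attains the family's minimum p", {
  roi <- rect_roi()
  grid <- build_bin_grid(roi, 7, 9)
  cfg <- sim_config(
    roi, hotspots = list(hotspot(c(450, 350), 15, 60)),
    spatial = list(group_spatial_spec("on", 150, 1),
                   group_spatial_spec("off", 150, 0)),
    n_per_group = 6L, seed = 77L)
  cms <- assign_counts_cohort(simulate_neuron_maps(cfg), grid, roi)
  bs <- mass_univariate(cms, grid)
  hot_lin <- which(bs$p == bs$p[4, 5]) # (row 4, col 5) holds (450, 350)
  expect_equal(which.min(bs$p), (5 - 1) * 7 + 4) # column-major index
  # and the per-bin value matches the scalar ANOVA on the same data
  y <- sapply(cms, function(m) m$counts[4, 5])
  grp <- sapply(cms, `[[`, "group")
  orc <- one_way_anova(split(y, grp))
  expect_equal(bs$F[4, 5], orc$F, tolerance = 1e-9)
  expect_equal(bs$p[4, 5], orc$p, tolerance = 1e-9)
})

test_that("bin classification distinguishes shared and specific reductions", {
  roi <- rect_roi(90, 70)
  grid <- build_bin_grid(roi, 3, 3)
  # bin 1: both drugs clearly below vehicle, equal to each other (red)
  # bin 2 (row 1, col 2): only drugA reduced, below vehicle AND drugB (blue)
  # bin 3 (row 1, col 3): no group difference
  veh <- c(20, 10, 8); dA <- c(5, 2, 8); dB <- c(5, 10, 8)
  mk_group <- function(means, lab) lapply(1:4, function(i) {
    counts <- matrix(5L, 3, 3)
    counts[1, 1:3] <- as.integer(means + c(0, 1, -1, 0)[i])
    make_cm(counts, sprintf("%s%d", lab, i), lab)
  })
  cms <- c(mk_group(veh, "vehicle"), mk_group(dA, "drugA"),
           mk_group(dB, "drugB"))
  bs <- mass_univariate(cms, grid, q_threshold = 0.1)
  expect_true(bs$significant[1, 1])
  expect_true(bs$significant[1, 2])
  expect_false(bs$significant[1, 3])
  cls <- classify_bins(bs, cms, reference_group = "vehicle", alpha = 0.05)
  expect_equal(cls[1, 1], "all-drugs-lower")
  expect_equal(cls[1, 2], "drugA-specific")
  expect_equal(cls[1, 3], "none")
  expect_true(all(cls[2:3, ] == "none"))
  expect_error(classify_bins(bs, cms, reference_group = "ghost"), "ghost")
})

test_that("total-count comparison follows the scalar ANOVA", {
  roi <- rect_roi(90, 70)
  grid <- build_bin_grid(roi, 3, 3)
  empty <- c(lapply(1:3, function(i) make_cm(matrix(0L, 3, 3), paste0("a", i), "g1")),
             lapply(1:3, function(i) make_cm(matrix(0L, 3, 3), paste0("b", i), "g2")))
  te <- total_count_anova(empty, grid)
  expect_true(all(te$totals$total == 0))
  expect_equal(te$anova$F, 0)
  # seeded hotspot simulation: multiplier 1 vs 0.2 orders the group totals
  roi2 <- rect_roi()
  grid2 <- build_bin_grid(roi2, 7, 9)
  cfg <- sim_config(
    roi2, hotspots = list(hotspot(c(450, 350), 20, 50)),
    spatial = list(group_spatial_spec("hi", 100, 1),
                   group_spatial_spec("lo", 100, 0.2)),
    n_per_group = 6L, seed = 7L)
  cms <- assign_counts_cohort(simulate_neuron_maps(cfg), grid2, roi2)
  tc <- total_count_anova(cms, grid2)
  m_hi <- mean(tc$totals$total[tc$totals$group == "hi"])
  m_lo <- mean(tc$totals$total[tc$totals$group == "lo"])
  expect_gt(m_hi, m_lo)
  orc <- oracle_anova(split(tc$totals$total, tc$totals$group))
  expect_equal(tc$anova$F, orc$F, tolerance = 1e-9)
})
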