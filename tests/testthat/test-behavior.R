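test_that("inclusion criterion is strictly greater than the threshold", {
  rec <- data.frame(
    animal_id = rep(c("m1", "m2", "m3"), each = 3),
    group = "g",
    phase = rep(c("training-post", "reactivation", "test"), 3),
    percent_freezing = c(40, 37.0, 50, 40, 37.1, 50, 40, 80, 50))
  fl <- exclusion_filter(rec, threshold = 37)
  expect_equal(fl$excluded, "m1")     # exactly 37.0 is excluded
  expect_equal(sort(fl$retained), c("m2", "m3"))
  expect_equal(nrow(fl$records), 6L)
  # empty cohort
  fe <- exclusion_filter(rec[0, ], threshold = 37)
  expect_equal(fe$n_retained, 0L)
  expect_equal(fe$n_excluded, 0L)
  # missing reactivation record names the animal
  expect_error(exclusion_filter(rec[rec$animal_id != "m2" |
                                      rec$phase != "reactivation", ]),
               "m2")
})

test_that("mixed ANOVA reproduces a hand-computed toy table", {
  # 2 groups x 2 subjects x 2 days, pure group effect: G1 all 10, G2 all 20
  vals <- rbind(c(10, 10), c(10, 10), c(20, 20), c(20, 20))
  rec <- freezing_table(vals, groups = c("G1", "G1", "G2", "G2"))
  r <- rm_anova(rec)
  ss <- setNames(r$ss$SS, r$ss$source)
  expect_equal(unname(ss["group"]), 200)
  expect_equal(unname(ss["phase"]), 0)
  expect_equal(unname(ss["group:phase"]), 0)
  expect_equal(unname(ss["subjects-within-groups"]), 0)
  # zero error with positive effect: the stated convention
  eff <- r$effects
  expect_equal(eff$p[eff$effect == "group"], 0)
  expect_equal(eff$F[eff$effect == "phase"], 0)
  expect_equal(eff$p[eff$effect == "phase"], 1)
})

test_that("all-equal observations give F = 0, p = 1 for every effect", {
  vals <- matrix(33, 6, 3)
  rec <- freezing_table(vals, groups = rep(c("A", "B"), each = 3))
  r <- rm_anova(rec)
  expect_true(all(r$effects$F == 0))
  expect_true(all(r$effects$p == 1))
})

test_that("mixed ANOVA is location invariant and matches the aov oracle", {
  set.seed(404)
  for (rep in 1:10) {
    k <- sample(2:4, 1); n <- sample(3:6, 1); m <- sample(2:4, 1)
    vals <- matrix(rnorm(k * n * m, 50, 10), k * n, m)
    rec <- freezing_table(vals, groups = rep(paste0("G", 1:k), each = n))
    r <- rm_anova(rec)
    orc <- oracle_rm_anova(rec)
    eff <- r$effects
    expect_equal(eff$F[eff$effect == "group"], orc$F_group, tolerance = 1e-9)
    expect_equal(eff$p[eff$effect == "group"], orc$p_group, tolerance = 1e-9)
    expect_equal(eff$F[eff$effect == "phase"], orc$F_phase, tolerance = 1e-9)
    expect_equal(eff$F[eff$effect == "group:phase"], orc$F_int,
                 tolerance = 1e-9)
    # adding a constant leaves every F unchanged
    rec2 <- rec
    rec2$percent_freezing <- rec2$percent_freezing + 13.7
    expect_equal(rm_anova(rec2)$effects$F, eff$F, tolerance = 1e-9)
    # SS decomposition closes
    ss <- setNames(r$ss$SS, r$ss$source)
    expect_equal(
      unname(ss["total"]),
      unname(ss["group"] + ss["subjects-within-groups"] + ss["phase"] +
               ss["group:phase"] + ss["residual-within"]),
      tolerance = 1e-9)
  }
})

test_that("unbalanced phases are rejected with the offending animal", {
  vals <- matrix(rnorm(12, 50, 5), 4, 3)
  rec <- freezing_table(vals, groups = rep(c("A", "B"), each = 2))
  rec <- rec[!(rec$animal_id == "a03" & rec$phase == "p2"), ]
  expect_error(rm_anova(rec), "a03")
})

test_that("group F from the mixed ANOVA equals a one-way ANOVA on subject means", {
  set.seed(505)
  vals <- matrix(rnorm(36 * 3, 50, 10), 36, 3)
  vals[25:36, ] <- vals[25:36, ] + 8
  rec <- freezing_table(vals, groups = rep(c("A", "B", "C"), each = 12))
  r <- rm_anova(rec)
  sm <- r$subject_means
  ow <- one_way_anova(split(sm$mean, sm$group))
  expect_equal(r$effects$F[r$effects$effect == "group"], ow$F,
               tolerance = 1e-9)
})

test_that("Tukey HSD: identities, conventions and a Monte-Carlo range oracle", {
  # all group means identical: every adjusted p = 1
  g0 <- list(A = c(5, 6, 4), B = c(5, 4, 6), C = c(6, 5, 4))
  tk0 <- tukey_hsd(g0)
  expect_true(all(tk0$p_adj == 1))
  # two groups: Tukey p equals the pooled two-sided t-test p
  gA <- c(2, 3, 7); gB <- c(6, 8, 10)
  tk <- tukey_hsd(list(A = gA, B = gB))
  tt <- t.test(gA, gB, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-5) # ptukey quadrature
  # zero error MS with unequal means: adjusted p = 0
  tkz <- tukey_hsd(list(A = c(1, 1), B = c(2, 2)))
  expect_equal(tkz$p_adj, 0)
  # 3-group toy data against a simulated studentized-range distribution
  g3 <- list(A = c(10, 12, 11, 13), B = c(14, 15, 13, 16), C = c(11, 10, 12, 12))
  tk3 <- tukey_hsd(g3)
  k <- 3; n <- 4; df <- 9
  ssw <- sum(vapply(g3, function(v) sum((v - mean(v))^2), numeric(1)))
  ms <- ssw / df
  set.seed(606)
  nrep <- 1e5
  zz <- matrix(rnorm(nrep * k), nrep, k)
  qsim <- (apply(zz, 1, max) - apply(zz, 1, min)) /
    sqrt(rchisq(nrep, df) / df)
  for (i in seq_len(nrow(tk3))) {
    p_mc <- mean(qsim > tk3$q[i])
    expect_lt(abs(tk3$p_adj[i] - p_mc), 0.01)
  }
  # agreement with R's TukeyHSD on the same one-way layout
  y <- unlist(g3); grp <- factor(rep(names(g3), each = 4))
  thsd <- TukeyHSD(aov(y ~ grp))$grp[, "p adj"]
  expect_equal(sort(tk3$p_adj), sort(unname(thsd)), tolerance = 1e-6)
})

test_that("power function: limits, monotonicity and the df floor", {
  spec <- power_spec(f = 1e-8, alpha = 0.05, power = 0.8, k = 6, m = 3,
                     rho = 0.5)
  expect_equal(rm_anova_power(spec, 36), 0.05, tolerance = 1e-4)
  spec2 <- power_spec(f = 0.58, alpha = 0.05, power = 0.8, k = 6, m = 3,
                      rho = 0.5)
  pw <- vapply(seq(12, 60, 6), function(N) rm_anova_power(spec2, N),
               numeric(1))
  expect_true(all(diff(pw) > 0))
  fs <- c(0.2, 0.4, 0.6, 0.8)
  pf_ <- vapply(fs, function(f)
    rm_anova_power(power_spec(f, 0.05, 0.8, 6, 3, 0.5), 36), numeric(1))
  expect_true(all(diff(pf_) > 0))
  # required N is non-increasing in f
  Ns <- vapply(fs, function(f)
    rm_anova_sample_size(power_spec(f, 0.05, 0.8, 6, 3, 0.5)), integer(1))
  expect_true(all(diff(Ns) <= 0))
  # absurdly large effect: N hits the floor imposed by degrees of freedom
  spec_huge <- power_spec(f = 10, alpha = 0.05, power = 0.8, k = 6, m = 3,
                          rho = 0.5)
  N_floor <- rm_anova_sample_size(spec_huge)
  expect_equal(N_floor, 12L) # smallest multiple of 6 exceeding k = 6
  expect_gte(rm_anova_power(spec_huge, N_floor), 0.8)
  # the returned N always achieves the target by construction
  N <- rm_anova_sample_size(spec2)
  expect_gte(rm_anova_power(spec2, N), 0.8)
  expect_lt(rm_anova_power(spec2, N - 6L), 0.8)
  # invariant violations are rejected
  expect_error(power_spec(f = 0, alpha = 0.05, power = 0.8), "`f`")
  expect_error(power_spec(f = 0.5, alpha = 0, power = 0.8), "alpha")
  expect_error(power_spec(f = 0.5, rho = 1), "rho")
})

test_that("endpoint ANOVA delegates to the one-way engine and is calibrated", {
  expect_equal(endpoint_anova(list(A = c(2, 3, 7), B = c(6, 8, 10)))$F,
               24 / (22 / 4), tolerance = 1e-12)
  expect_equal(endpoint_anova(list(A = 1:4, B = 1:4))$F, 0)
  # type-I calibration: three null groups, 500 seeded cohorts
  set.seed(707)
  rej <- vapply(1:500, function(i) {
    s <- lapply(1:3, function(j) rnorm(8, 50, 10))
    endpoint_anova(s)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})
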