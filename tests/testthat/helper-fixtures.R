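# Shared fixtures and independent oracles.

rect_roi <- function(w = 900, h = 700) {
  roi_contour(c(0, w, w, 0), c(0, 0, h, h))
}

tri_roi <- function(s = 100) {
  # right triangle occupying the lower-left half of its bounding box
  roi_contour(c(0, s, 0), c(0, 0, s))
}

# random convex polygon: sorted angles on a noisy circle
random_convex_roi <- function(n = 8, r = 100) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  rad <- r * (0.6 + 0.4 * stats::runif(n))
  roi_contour(rad * cos(th) + 2 * r, rad * sin(th) + 2 * r)
}

# literal Benjamini-Hochberg step-up, written from the definition with
# explicit loops (independent of the package's vectorized path)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q_sorted[i] <- max(min(best, 1), ps[i]) # q >= p by definition
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# one-way ANOVA oracle via R's linear-model machinery
oracle_anova <- function(samples) {
  y <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), lengths(samples)))
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a$`F value`[1L], p = a$`Pr(>F)`[1L], df1 = a$Df[1L], df2 = a$Df[2L])
}

# mixed-ANOVA oracle via aov with an Error() stratum
oracle_rm_anova <- function(records) {
  d <- data.frame(
    y = records$percent_freezing,
    g = factor(records$group),
    ph = factor(records$phase),
    a = factor(records$animal_id)
  )
  fit <- stats::aov(y ~ g * ph + Error(a), data = d)
  s <- summary(fit)
  between <- s[["Error: a"]][[1L]]
  within <- s[["Error: Within"]][[1L]]
  list(
    F_group = between["g", "F value"],
    p_group = between["g", "Pr(>F)"],
    F_phase = within["ph", "F value"],
    F_int = within["g:ph", "F value"],
    p_int = within["g:ph", "Pr(>F)"]
  )
}

# small synthetic cohort for pipeline-level tests
small_sim_config <- function(seed = 1L, n_per_group = 4L,
                             multipliers = c(vehicle = 1, drugA = 0.2,
                                             drugB = 1)) {
  roi <- rect_roi()
  hs <- hotspot(center = c(450, 350), radius = 20, amplitude = 30)
  spatial <- mapply(function(lab, mult)
    group_spatial_spec(lab, baseline_count = 100, hotspot_multiplier = mult),
    names(multipliers), multipliers, SIMPLIFY = FALSE)
  freezing <- lapply(names(multipliers), function(lab)
    group_freezing_spec(
      lab,
      means = c(`training-post` = 45, reactivation = 65, test = 50),
      sds = c(`training-post` = 10, reactivation = 10, test = 10)))
  sim_config(roi, hotspots = list(hs), spatial = spatial,
             freezing = freezing, n_per_group = n_per_group, seed = seed)
}

# long-format freezing table from a matrix of subject x phase values
freezing_table <- function(values, groups,
                           phases = paste0("p", seq_len(ncol(values)))) {
  n <- nrow(values)
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(animal_id = sprintf("a%02d", i), group = groups[i],
               phase = phases, percent_freezing = values[i, ])))
}
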