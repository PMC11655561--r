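#' Conditioned-freezing inclusion filter
#'
#' Animals whose reactivation-day freezing is not strictly greater than the
#' threshold failed to acquire the conditioned memory and are removed from
#' further analysis. The criterion is strict: an animal at exactly the
#' threshold is excluded.
#'
#' @param records long-format freezing data.frame (`animal_id`, `group`,
#'   `phase`, `percent_freezing`).
#' @param threshold percent-freezing cutoff (default 37).
#' @param phase the phase the criterion applies to (default
#'   `"reactivation"`).
#' @return List with `retained` and `excluded` id vectors, counts, and the
#'   filtered `records` (all phases, retained animals only).
#' @export
exclusion_filter <- function(records, threshold = 37, phase = "reactivation") {
  if (threshold < 0 || threshold > 100) {
    stop("`threshold` must lie in [0, 100]", call. = FALSE)
  }
  ids <- unique(as.character(records$animal_id))
  re <- records[records$phase == phase, , drop = FALSE]
  missing <- setdiff(ids, as.character(re$animal_id))
  if (length(missing)) {
    stop(sprintf("animal '%s' has no %s record", missing[1L], phase),
         call. = FALSE)
  }
  if (anyDuplicated(re$animal_id)) {
    stop("an animal has more than one record for the criterion phase",
         call. = FALSE)
  }
  keep <- as.character(re$animal_id[re$percent_freezing > threshold])
  excl <- setdiff(ids, keep)
  list(
    retained = keep, excluded = excl,
    n_retained = length(keep), n_excluded = length(excl),
    records = records[as.character(records$animal_id) %in% keep, ,
                      drop = FALSE]
  )
}

#' Two-way mixed (repeated-measures) ANOVA
#'
#' Standard sums-of-squares partition for a design with one between-subject
#' factor (group) and one within-subject factor (phase/day), balanced
#' within animal: every retained animal contributes one observation per
#' phase. The group effect is tested against the between-subject error
#' (subjects within groups, df `N - k`); the phase and group x phase
#' effects are tested against the within-subject residual
#' (df `(N - k)(m - 1)`).
#'
#' Degenerate data follow the package-wide conventions: a zero error mean
#' square gives `F = 0, p = 1` when the effect SS is also zero, and
#' `F = Inf, p = 0` otherwise.
#'
#' @param records long-format freezing data.frame (`animal_id`, `group`,
#'   `phase`, `percent_freezing`).
#' @return An `rm_anova_result`: `effects` data.frame (effect, df1, df2,
#'   SS, MS, F, p), full `ss` table, `n_subjects`, `k`, `m`,
#'   `subject_means`.
#' @export
rm_anova <- function(records) {
  a <- factor(as.character(records$animal_id))
  g <- factor(as.character(records$group))
  ph <- factor(as.character(records$phase))
  y <- records$percent_freezing
  if (nlevels(g) < 2L || nlevels(ph) < 2L) {
    stop("need >= 2 groups and >= 2 phases", call. = FALSE)
  }
  tab <- table(a, ph)
  bad <- rownames(tab)[rowSums(tab != 1L) > 0L]
  if (length(bad)) {
    stop("unbalanced phases for animal(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  # one group per animal
  ag <- tapply(as.integer(g), a, function(v) length(unique(v)))
  if (any(ag != 1L)) stop("an animal appears in more than one group",
                          call. = FALSE)
  N <- nlevels(a)
  k <- nlevels(g)
  m <- nlevels(ph)
  grand <- mean(y)
  subj_mean <- tapply(y, a, mean)
  subj_group <- tapply(as.character(g), a, `[`, 1L)
  group_mean <- tapply(y, g, mean)
  phase_mean <- tapply(y, ph, mean)
  cell_mean <- tapply(y, list(g, ph), mean)
  n_g <- table(factor(subj_group, levels = levels(g)))

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- m * sum((subj_mean - grand)^2)
  ss_group <- m * sum(n_g * (group_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_within_subj <- ss_total - ss_between_subj
  ss_phase <- N * sum((phase_mean - grand)^2)
  # interaction from cell means
  ss_cells <- sum(rep(n_g, times = m) *
                    (as.vector(cell_mean) - grand)^2)
  ss_interaction <- ss_cells - ss_group - ss_phase
  ss_resid <- ss_within_subj - ss_phase - ss_interaction
  # guard tiny negatives from floating point
  clamp0 <- function(v) if (v < 0 && v > -1e-8 * max(ss_total, 1)) 0 else v
  ss_subj_within <- clamp0(ss_subj_within)
  ss_interaction <- clamp0(ss_interaction)
  ss_resid <- clamp0(ss_resid)

  df_group <- k - 1L
  df_subj <- N - k
  df_phase <- m - 1L
  df_int <- (k - 1L) * (m - 1L)
  df_resid <- (N - k) * (m - 1L)
  if (df_subj < 1L) stop("no between-subject error degrees of freedom",
                         call. = FALSE)

  ftest <- function(ss_eff, df_eff, ss_err, df_err) {
    ms_eff <- ss_eff / df_eff
    ms_err <- ss_err / df_err
    if (ms_err <= 0) {
      if (ms_eff <= 0) list(F = 0, p = 1) else list(F = Inf, p = 0)
    } else {
      Fst <- ms_eff / ms_err
      list(F = Fst, p = stats::pf(Fst, df_eff, df_err, lower.tail = FALSE))
    }
  }
  tg <- ftest(ss_group, df_group, ss_subj_within, df_subj)
  tp <- ftest(ss_phase, df_phase, ss_resid, df_resid)
  ti <- ftest(ss_interaction, df_int, ss_resid, df_resid)

  effects <- data.frame(
    effect = c("group", "phase", "group:phase"),
    df1 = c(df_group, df_phase, df_int),
    df2 = c(df_subj, df_resid, df_resid),
    SS = c(ss_group, ss_phase, ss_interaction),
    MS = c(ss_group / df_group, ss_phase / df_phase, ss_interaction / df_int),
    F = c(tg$F, tp$F, ti$F),
    p = c(tg$p, tp$p, ti$p)
  )
  ss <- data.frame(
    source = c("group", "subjects-within-groups", "phase", "group:phase",
               "residual-within", "total"),
    df = c(df_group, df_subj, df_phase, df_int, df_resid, N * m - 1L),
    SS = c(ss_group, ss_subj_within, ss_phase, ss_interaction, ss_resid,
           ss_total)
  )
  structure(
    list(effects = effects, ss = ss, n_subjects = N, k = k, m = m,
         subject_means = data.frame(
           animal_id = names(subj_mean),
           group = as.character(subj_group),
           mean = as.numeric(subj_mean)),
         error_between = list(ms = ss_subj_within / df_subj, df = df_subj)),
    class = "rm_anova_result"
  )
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("two-way mixed ANOVA: %d subjects, %d groups x %d phases\n",
              x$n_subjects, x$k, x$m))
  e <- x$effects
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  %-12s F(%d, %d) = %.3f, p = %.4g\n",
                e$effect[i], e$df1[i], e$df2[i], e$F[i], e$p[i]))
  }
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range based pairwise group comparisons (Tukey-Kramer for
#' unequal n) against a supplied error term. For between-group comparisons
#' after [rm_anova()], pass the subject means per group with the
#' between-subject error mean square and df.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param error_ms error mean square; if `NULL`, the pooled within-group
#'   mean square of `groups` is used.
#' @param error_df its degrees of freedom (required with `error_ms`).
#' @return data.frame of all pairs: `group1`, `group2`, `diff`, `se`,
#'   `q` statistic, `p_adj`.
#' @export
tukey_hsd <- function(groups, error_ms = NULL, error_df = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  n <- lengths(groups)
  if (is.null(error_ms)) {
    ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1L)))
    error_df <- sum(n) - length(groups)
    if (error_df < 1L) stop("error df must be >= 1", call. = FALSE)
    error_ms <- ssw / error_df
  } else if (is.null(error_df) || error_df < 1L) {
    stop("`error_df` >= 1 required with a supplied `error_ms`", call. = FALSE)
  }
  means <- vapply(groups, mean, numeric(1L))
  k <- length(groups)
  pairs <- utils::combn(k, 2L)
  out <- data.frame(
    group1 = names(groups)[pairs[1L, ]],
    group2 = names(groups)[pairs[2L, ]],
    diff = means[pairs[1L, ]] - means[pairs[2L, ]],
    se = sqrt(error_ms / 2 * (1 / n[pairs[1L, ]] + 1 / n[pairs[2L, ]]))
  )
  out$q <- ifelse(out$se > 0, abs(out$diff) / out$se, Inf)
  out$p_adj <- ifelse(
    out$se > 0,
    stats::ptukey(out$q, nmeans = k, df = error_df, lower.tail = FALSE),
    ifelse(out$diff == 0, 1, 0)
  )
  out$q[out$se == 0 & out$diff == 0] <- 0
  rownames(out) <- NULL
  out
}

#' Power-analysis specification for repeated-measures ANOVA
#'
#' @param f Cohen's effect size f (> 0): between-group SD of means divided
#'   by the within-group SD.
#' @param alpha type-I level in (0, 1).
#' @param power target power in (0, 1).
#' @param k number of groups (>= 2).
#' @param m number of repeated measures (>= 2).
#' @param rho correlation among repeated measures, in [0, 1).
#' @param eps nonsphericity correction in (0, 1] (default 1, sphericity).
#' @return A `power_spec` object.
#' @export
power_spec <- function(f, alpha = 0.05, power = 0.8, k = 6L, m = 3L,
                       rho = 0.5, eps = 1) {
  if (!is.finite(f) || f <= 0) stop("`f` must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("`power` must be in (0, 1)", call. = FALSE)
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (m < 2L) stop("`m` must be >= 2", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("`rho` must be in [0, 1)", call. = FALSE)
  if (eps <= 0 || eps > 1) stop("`eps` must be in (0, 1]", call. = FALSE)
  structure(list(f = f, alpha = alpha, power = power, k = as.integer(k),
                 m = as.integer(m), rho = rho, eps = eps),
            class = "power_spec")
}

#' Noncentral-F power for repeated-measures ANOVA
#'
#' Analytic power for the three standard repeated-measures effects, in the
#' convention popularized by G*Power (effect size `f` on the total-variance
#' scale, repeated measures with compound-symmetric correlation `rho`):
#' \describe{
#'   \item{between}{group main effect, tested on subject means;
#'     `lambda = f^2 N m / (1 + (m - 1) rho)`, df `(k - 1, N - k)`. This is
#'     the test an a priori sample-size computation for a drug (between-
#'     group) effect uses, and the default.}
#'   \item{within}{time main effect;
#'     `lambda = f^2 N m eps / (1 - rho)`, df
#'     `((m - 1) eps, (N - k)(m - 1) eps)`.}
#'   \item{interaction}{group x time;
#'     `lambda = f^2 N m eps / (1 - rho)`, df
#'     `((k - 1)(m - 1) eps, (N - k)(m - 1) eps)`.}
#' }
#'
#' @param spec a [power_spec()].
#' @param N total sample size (all groups); must exceed `k`.
#' @param effect which effect the power refers to.
#' @return Achieved power (scalar).
#' @export
rm_anova_power <- function(spec, N,
                           effect = c("between", "within", "interaction")) {
  stopifnot(inherits(spec, "power_spec"))
  effect <- match.arg(effect)
  if (N <= spec$k) stop("`N` must exceed the number of groups", call. = FALSE)
  k <- spec$k; m <- spec$m; rho <- spec$rho; eps <- spec$eps
  if (effect == "between") {
    lambda <- spec$f^2 * N * m / (1 + (m - 1) * rho)
    df1 <- k - 1
    df2 <- N - k
  } else {
    lambda <- spec$f^2 * N * m * eps / (1 - rho)
    df1 <- (if (effect == "within") 1 else k - 1) * (m - 1) * eps
    df2 <- (N - k) * (m - 1) * eps
  }
  if (df2 < 1) stop("no error degrees of freedom at this N", call. = FALSE)
  crit <- stats::qf(1 - spec$alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' A priori total sample size for repeated-measures ANOVA
#'
#' Smallest total N, constrained to equal group sizes (a multiple of
#' `group_multiple`), whose [rm_anova_power()] reaches the target power.
#'
#' @param spec a [power_spec()].
#' @param group_multiple N must be a multiple of this (normally `spec$k`).
#' @param effect forwarded to [rm_anova_power()].
#' @param max_N search cap (error if the target power is unreachable below
#'   it).
#' @return Total sample size N (integer).
#' @examples
#' \donttest{
#' rm_anova_sample_size(power_spec(f = 0.58, alpha = 0.05, power = 0.8,
#'                                 k = 6, m = 3, rho = 0.5))  # 36
#' }
#' @export
rm_anova_sample_size <- function(spec, group_multiple = spec$k,
                                 effect = "between", max_N = 1e6) {
  stopifnot(inherits(spec, "power_spec"))
  group_multiple <- as.integer(group_multiple)
  if (group_multiple < 1L) stop("`group_multiple` must be >= 1", call. = FALSE)
  N <- group_multiple * max(1L, ceiling((spec$k + 1L) / group_multiple))
  while (N <= max_N) {
    if (N > spec$k && (N - spec$k) * (spec$m - 1) * spec$eps >= 1 &&
        rm_anova_power(spec, N, effect) >= spec$power) {
      return(as.integer(N))
    }
    N <- N + group_multiple
  }
  stop("target power unreachable within the search cap", call. = FALSE)
}

#' One-way ANOVA for behavioral endpoints
#'
#' Entry point for single-measurement endpoints (e.g. Barnes-maze primary
#' latency, primary errors, time in target quadrant, open-field line
#' crossings); delegates to [one_way_anova()].
#'
#' @param samples named list of per-group numeric vectors.
#' @return See [one_way_anova()].
#' @export
endpoint_anova <- function(samples) {
  one_way_anova(samples)
}
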