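#' One-way fixed-effects ANOVA
#'
#' Classical between/within sums-of-squares F test, with explicit
#' conventions for the degenerate inputs that per-bin count data at small n
#' regularly produce: if all values are equal across all groups, `F = 0`
#' and `p = 1`; if the within-group sum of squares is zero while group
#' means differ, `F = Inf` and `p = 0`.
#'
#' @param samples list of numeric vectors, one per group (>= 2 groups, each
#'   with >= 1 value).
#' @return List with `F`, `df1`, `df2`, `p`, `ss_between`, `ss_within`,
#'   `group_means`, `n`.
#' @examples
#' one_way_anova(list(A = c(2, 3, 7), B = c(6, 8, 10)))$F  # 4.3636...
#' @export
one_way_anova <- function(samples) {
  if (!is.list(samples) || length(samples) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  n <- lengths(samples)
  if (any(n < 1L)) stop("every group needs at least 1 value", call. = FALSE)
  vals <- unlist(samples, use.names = FALSE)
  if (!all(is.finite(vals))) stop("values must be finite", call. = FALSE)
  k <- length(samples)
  N <- sum(n)
  gm <- vapply(samples, mean, numeric(1L))
  grand <- mean(vals)
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(vapply(samples, function(v) sum((v - mean(v))^2), numeric(1L)))
  df1 <- k - 1L
  df2 <- N - k
  if (ssb + ssw <= 0 || (ssb == 0)) {
    # all equal, or no between-group signal at all
    Fst <- 0
    p <- 1
  } else if (ssw == 0) {
    Fst <- Inf
    p <- 0
  } else {
    if (df2 < 1L) stop("no residual degrees of freedom", call. = FALSE)
    Fst <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  }
  list(F = Fst, df1 = df1, df2 = df2, p = p,
       ss_between = ssb, ss_within = ssw, group_means = gm, n = n)
}

#' Benjamini-Hochberg step-up false discovery rate
#'
#' Computes q-values by the step-up rule: with the p-values sorted
#' ascending, `q_(i) = min over j >= i of p_(j) * m / j`, capped at 1 and
#' mapped back to the original order. The rejection set is
#' `{i : q_i < q_threshold}` (strict, matching a tolerable limit stated as
#' `q < threshold`).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param q_threshold tolerable FDR limit (default 0.1).
#' @return List with `q` (same order as `p`) and logical `reject`.
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03, 0.02))$q  # all 0.04
#' @export
bh_fdr <- function(p, q_threshold = 0.1) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  # q >= p holds by definition (the j = i term is p * m / i); clamp the
  # floating-point rounding of the division so the invariant is exact
  q <- pmax(q, p)
  list(q = q, reject = q < q_threshold, m = m, q_threshold = q_threshold)
}

# Stack a list of count_matrix objects into a bins x animals matrix plus a
# group factor, checking the grid is shared.
counts_by_group <- function(matrices, grid) {
  check_same_grid(matrices)
  if (!is.null(grid)) {
    if (nrow(matrices[[1L]]$counts) != grid$rows ||
        ncol(matrices[[1L]]$counts) != grid$cols) {
      stop("count matrices do not match the grid", call. = FALSE)
    }
  }
  x <- stack_counts(matrices) # (rows*cols, column-major) x animals
  g <- factor(vapply(matrices, `[[`, character(1L), "group"))
  list(x = x, g = g)
}

#' Mass-univariate per-bin ANOVA with FDR control
#'
#' Applies [one_way_anova()] to every bin of the analysis family, with
#' animals as replicates, and corrects the family of p-values with
#' [bh_fdr()]. The family comprises the unmasked bins (centre inside the
#' contour) in which at least one animal has a nonzero count; structurally
#' empty bins carry no statistic and never inflate the family size. The
#' full q-matrix is reported, including bins above the threshold.
#'
#' @param matrices list of `count_matrix` objects covering >= 2 groups.
#' @param grid the shared [build_bin_grid()].
#' @param q_threshold tolerable FDR limit (default 0.1).
#' @return A `bin_stat_result`: matrices `F`, `p`, `q` (NA outside the
#'   family), logical `family` and `significant` matrices, family size `m`,
#'   `q_threshold`, group labels.
#' @export
mass_univariate <- function(matrices, grid, q_threshold = 0.1) {
  stopifnot(inherits(grid, "bin_grid"))
  cg <- counts_by_group(matrices, grid)
  if (nlevels(cg$g) < 2L) stop("need at least 2 conditions", call. = FALSE)
  fam_vec <- as.vector(grid$inside) & rowSums(cg$x) > 0
  Fm <- pm <- qm <- matrix(NA_real_, grid$rows, grid$cols)
  sig <- fam <- matrix(FALSE, grid$rows, grid$cols)
  fam[] <- fam_vec
  if (any(fam_vec)) {
    st <- anova_rows(cg$x[fam_vec, , drop = FALSE], cg$g)
    Fm[fam_vec] <- st$F
    pm[fam_vec] <- st$p
    bh <- bh_fdr(st$p, q_threshold)
    qm[fam_vec] <- bh$q
    sig[fam_vec] <- bh$reject
  }
  structure(
    list(F = Fm, p = pm, q = qm, family = fam, significant = sig,
         m = sum(fam_vec), q_threshold = q_threshold,
         df1 = nlevels(cg$g) - 1L, df2 = length(cg$g) - nlevels(cg$g),
         groups = levels(cg$g)),
    class = "bin_stat_result"
  )
}

# Vectorized one-way ANOVA across the rows of x (bins x animals), sharing
# the degenerate conventions of one_way_anova().
anova_rows <- function(x, g) {
  k <- nlevels(g)
  N <- length(g)
  ng <- as.vector(table(g))
  gsum <- t(rowsum(t(x), g)) # bins x k group sums
  gmean <- sweep(gsum, 2L, ng, "/")
  grand <- rowMeans(x)
  ssb <- rowSums(sweep((gmean - grand)^2, 2L, ng, "*"))
  ssw <- rowSums((x - gmean[, as.integer(g), drop = FALSE])^2)
  df1 <- k - 1L
  df2 <- N - k
  Fst <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fst, df1, df2, lower.tail = FALSE)
  # degenerate conventions
  eq <- ssb <= 0
  Fst[eq] <- 0; p[eq] <- 1
  zw <- ssw == 0 & ssb > 0
  Fst[zw] <- Inf; p[zw] <- 0
  list(F = Fst, p = p, df1 = df1, df2 = df2)
}

#' @export
print.bin_stat_result <- function(x, ...) {
  cat(sprintf(
    "mass-univariate ANOVA: %d-bin family, df (%d, %d), %d bins with q < %.3g\n",
    x$m, x$df1, x$df2, sum(x$significant), x$q_threshold))
  invisible(x)
}

# Pooled-variance (or Welch) two-sample two-sided t-test p-value, with the
# zero-variance conventions shared across the package.
two_sample_t <- function(a, b, welch = FALSE) {
  na <- length(a); nb <- length(b)
  d <- mean(a) - mean(b)
  if (welch) {
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    se <- sqrt(va + vb)
    df <- if (se > 0) (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1)) else NA
  } else {
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2L)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2L
  }
  if (se == 0) {
    p <- if (d == 0) 1 else 0
  } else {
    p <- 2 * stats::pt(abs(d) / se, df, lower.tail = FALSE)
  }
  list(diff = d, p = p)
}

#' Classify FDR-significant bins by planned comparisons
#'
#' Within every FDR-significant bin, runs uncorrected ("planned")
#' two-sample t-tests of each treatment group against the reference and
#' between treatment pairs, at level `alpha`. Codes:
#' \describe{
#'   \item{`all-drugs-lower`}{every treatment significantly below the
#'     reference, and no two treatments significantly different.}
#'   \item{`<group>-specific`}{that treatment significantly below the
#'     reference and below every other treatment.}
#'   \item{`other`}{significant bin matching neither pattern.}
#'   \item{`none`}{bin not FDR-significant (or outside the family).}
#' }
#'
#' @param result a [mass_univariate()] result on the same grouping.
#' @param matrices the same list of `count_matrix` objects.
#' @param reference_group label of the control group.
#' @param alpha planned-comparison level (default 0.05).
#' @param welch use Welch instead of pooled-variance t-tests.
#' @return Character matrix (rows x cols) of classification codes, `NA`
#'   outside the family.
#' @export
classify_bins <- function(result, matrices, reference_group, alpha = 0.05,
                          welch = FALSE) {
  stopifnot(inherits(result, "bin_stat_result"))
  cg <- counts_by_group(matrices, NULL)
  if (!reference_group %in% levels(cg$g)) {
    stop(sprintf("reference group '%s' not present", reference_group),
         call. = FALSE)
  }
  treatments <- setdiff(levels(cg$g), reference_group)
  codes <- matrix(NA_character_, nrow(result$F), ncol(result$F))
  codes[result$family] <- "none"
  for (bin in which(result$significant)) {
    y <- cg$x[bin, ]
    ref <- y[cg$g == reference_group]
    lower_than_ref <- logical(length(treatments))
    names(lower_than_ref) <- treatments
    for (tr in treatments) {
      tt <- two_sample_t(y[cg$g == tr], ref, welch)
      lower_than_ref[tr] <- tt$p < alpha && tt$diff < 0
    }
    # pairwise treatment differences
    pair_diff <- matrix(FALSE, length(treatments), length(treatments),
                        dimnames = list(treatments, treatments))
    pair_lower <- pair_diff
    if (length(treatments) > 1L) {
      for (i in seq_along(treatments)[-length(treatments)]) {
        for (j in seq.int(i + 1L, length(treatments))) {
          tt <- two_sample_t(y[cg$g == treatments[i]],
                             y[cg$g == treatments[j]], welch)
          sig <- tt$p < alpha
          pair_diff[i, j] <- pair_diff[j, i] <- sig
          pair_lower[i, j] <- sig && tt$diff < 0
          pair_lower[j, i] <- sig && tt$diff > 0
        }
      }
    }
    code <- "other"
    if (all(lower_than_ref) && !any(pair_diff)) {
      code <- "all-drugs-lower"
    } else {
      for (tr in treatments) {
        others <- setdiff(treatments, tr)
        if (lower_than_ref[tr] &&
            (length(others) == 0L || all(pair_lower[tr, others]))) {
          code <- paste0(tr, "-specific")
          break
        }
      }
    }
    codes[bin] <- code
  }
  codes
}

#' Whole-ROI total-count comparison
#'
#' Per-animal total neuron counts over the unmasked bins, compared across
#' groups with a one-way ANOVA.
#'
#' @param matrices list of `count_matrix` objects.
#' @param grid the shared [build_bin_grid()].
#' @return List with `totals` (data.frame: animal_id, group, total) and the
#'   [one_way_anova()] result under `anova`.
#' @export
total_count_anova <- function(matrices, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  check_same_grid(matrices)
  totals <- data.frame(
    animal_id = vapply(matrices, `[[`, character(1L), "animal_id"),
    group = vapply(matrices, `[[`, character(1L), "group"),
    total = vapply(matrices, function(m) sum(m$counts[grid$inside]),
                   numeric(1L))
  )
  samples <- split(totals$total, totals$group)
  list(totals = totals, anova = one_way_anova(samples))
}
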