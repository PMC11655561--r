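#' Hotspot specification
#'
#' A localized region of elevated neuronal activation, modelled as a
#' two-dimensional Gaussian component of an inhomogeneous Poisson point
#' process, truncated to the ROI.
#'
#' @param center numeric length-2, (x, y) position of the hotspot centre in µm.
#' @param radius Gaussian kernel scale (SD) in µm; must be > 0.
#' @param amplitude expected number of extra neurons the hotspot contributes
#'   per animal (before any group multiplier); must be >= 0.
#' @return A `hotspot` object.
#' @export
hotspot <- function(center, radius, amplitude) {
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center))) {
    stop("`center` must be a finite (x, y) pair", call. = FALSE)
  }
  if (!is.finite(radius) || radius <= 0) {
    stop("`radius` must be > 0", call. = FALSE)
  }
  if (!is.finite(amplitude) || amplitude < 0) {
    stop("`amplitude` must be >= 0", call. = FALSE)
  }
  structure(list(center = center, radius = radius, amplitude = amplitude),
            class = "hotspot")
}

#' Per-group spatial intensity specification
#'
#' @param label group label (e.g. `"vehicle"`, `"mirdametinib_25"`).
#' @param baseline_count expected number of baseline (spatially uniform)
#'   neurons per animal inside the ROI; >= 0.
#' @param hotspot_multiplier nonnegative scale applied to every hotspot
#'   amplitude for this group. A treatment that erases the localized
#'   activation has multiplier < 1; the reference group has 1.
#' @return A `group_spatial_spec` object.
#' @export
group_spatial_spec <- function(label, baseline_count, hotspot_multiplier = 1) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("`label` must be a non-empty string", call. = FALSE)
  }
  if (!is.finite(baseline_count) || baseline_count < 0) {
    stop("`baseline_count` must be >= 0", call. = FALSE)
  }
  if (!is.finite(hotspot_multiplier) || hotspot_multiplier < 0) {
    stop("`hotspot_multiplier` must be >= 0", call. = FALSE)
  }
  structure(list(label = label, baseline_count = baseline_count,
                 hotspot_multiplier = hotspot_multiplier),
            class = "group_spatial_spec")
}

#' Per-group freezing specification
#'
#' Mean and SD of percent freezing for each behavioral phase. Values are
#' drawn Normal(mean, SD) and clamped to [0, 100].
#'
#' @param label group label.
#' @param means named numeric vector of per-phase mean percent freezing,
#'   names among the phase labels (default phases: `training-post`,
#'   `reactivation`, `test`); all in [0, 100].
#' @param sds named numeric vector of per-phase SDs (same names); all >= 0.
#' @return A `group_freezing_spec` object.
#' @export
group_freezing_spec <- function(label, means, sds) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("`label` must be a non-empty string", call. = FALSE)
  }
  if (is.null(names(means)) || is.null(names(sds)) ||
      !setequal(names(means), names(sds))) {
    stop("`means` and `sds` must be named by phase and share names",
         call. = FALSE)
  }
  if (any(!is.finite(means)) || any(means < 0) || any(means > 100)) {
    stop("freezing means must lie in [0, 100]", call. = FALSE)
  }
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("freezing SDs must be >= 0", call. = FALSE)
  }
  structure(list(label = label, means = means, sds = sds[names(means)]),
            class = "group_freezing_spec")
}

#' Simulation configuration
#'
#' Full description of a synthetic cohort: the ROI, the shared hotspot
#' layout, per-group spatial and freezing specifications, the number of
#' animals per group and the random seed.
#'
#' @param roi an [roi_contour()].
#' @param hotspots list of [hotspot()] objects (possibly empty).
#' @param spatial list of [group_spatial_spec()] objects, unique labels.
#' @param freezing list of [group_freezing_spec()] objects (may be empty if
#'   only neuron maps are simulated); labels must match `spatial` when used.
#' @param n_per_group integer >= 1, animals per group.
#' @param seed integer random seed; identical configs give bit-identical
#'   output.
#' @param phases character vector of phase labels, in within-animal order.
#' @return A `sim_config` object.
#' @export
sim_config <- function(roi, hotspots = list(), spatial, freezing = list(),
                       n_per_group = 6L, seed = 1L,
                       phases = c("training-post", "reactivation", "test")) {
  stopifnot(inherits(roi, "roi_contour"))
  if (inherits(hotspots, "hotspot")) hotspots <- list(hotspots)
  if (inherits(spatial, "group_spatial_spec")) spatial <- list(spatial)
  if (inherits(freezing, "group_freezing_spec")) freezing <- list(freezing)
  lapply(hotspots, function(h) stopifnot(inherits(h, "hotspot")))
  lapply(spatial, function(s) stopifnot(inherits(s, "group_spatial_spec")))
  lapply(freezing, function(s) stopifnot(inherits(s, "group_freezing_spec")))
  labels <- vapply(spatial, `[[`, character(1L), "label")
  if (anyDuplicated(labels)) {
    stop("group labels must be unique", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group)
  if (is.na(n_per_group) || n_per_group < 1L) {
    stop("`n_per_group` must be >= 1", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  structure(
    list(roi = roi, hotspots = hotspots, spatial = spatial,
         freezing = freezing, n_per_group = n_per_group, seed = seed,
         phases = phases),
    class = "sim_config"
  )
}

# Deterministic per-animal sub-seed: a fixed-stride counter scheme so that
# regenerating animal i alone reproduces its data regardless of cohort size.
# offset separates the neuron-map stream (0) from the freezing stream (1).
animal_seed <- function(seed, i, offset = 0L) {
  as.integer((as.double(seed) + 97003 * i + 500009 * offset) %% 2147483647)
}

# Rejection-sample n points uniformly over the ROI from its bounding box.
# Hard cap on proposals so a pathological polygon fails loudly instead of
# spinning.
sample_uniform_roi <- function(n, roi, max_iter = 1e6) {
  out <- matrix(numeric(0), ncol = 2L)
  tried <- 0
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    if (tried + m > max_iter) {
      stop("rejection sampling exceeded the proposal cap; ",
           "is the ROI polygon degenerate?", call. = FALSE)
    }
    px <- stats::runif(m, roi$xlim[1], roi$xlim[2])
    py <- stats::runif(m, roi$ylim[1], roi$ylim[2])
    keep <- point_in_roi(px, py, roi)
    out <- rbind(out, cbind(px[keep], py[keep]))
    tried <- tried + m
  }
  out[seq_len(n), , drop = FALSE]
}

# Sample n points from an isotropic Gaussian at the hotspot centre,
# truncated to the ROI by rejection.
sample_hotspot <- function(n, hs, roi, max_iter = 1e6) {
  out <- matrix(numeric(0), ncol = 2L)
  tried <- 0
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    if (tried + m > max_iter) {
      stop("hotspot truncation exceeded the proposal cap; ",
           "does the hotspot overlap the ROI at all?", call. = FALSE)
    }
    px <- stats::rnorm(m, hs$center[1], hs$radius)
    py <- stats::rnorm(m, hs$center[2], hs$radius)
    keep <- point_in_roi(px, py, roi)
    out <- rbind(out, cbind(px[keep], py[keep]))
    tried <- tried + m
  }
  out[seq_len(n), , drop = FALSE]
}

#' Simulate per-animal neuron coordinate maps
#'
#' Draws each animal's set of activated-neuron (x, y) coordinates from an
#' inhomogeneous Poisson process: a spatially uniform baseline over the ROI
#' plus Gaussian hotspot components truncated to the ROI. The total count is
#' Poisson with mean `baseline_count + hotspot_multiplier * sum(amplitudes)`;
#' each point is assigned to a component with probability proportional to
#' that component's intensity mass.
#'
#' @param config a [sim_config()].
#' @return A data.frame with columns `animal_id`, `group`, `x_um`, `y_um`
#'   (one row per neuron; animals with zero neurons still appear in the
#'   `animals` attribute). Class `neuron_maps`.
#' @export
simulate_neuron_maps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  roi <- config$roi
  for (hs in config$hotspots) {
    if (!point_in_roi(hs$center[1], hs$center[2], roi)) {
      warning(sprintf(
        "hotspot centre (%.1f, %.1f) lies outside the ROI; points are still truncated to the ROI",
        hs$center[1], hs$center[2]), call. = FALSE)
    }
  }
  amps <- vapply(config$hotspots, `[[`, numeric(1L), "amplitude")
  rows <- list()
  animals <- character(0)
  groups <- character(0)
  idx <- 0L
  for (sp in config$spatial) {
    for (a in seq_len(config$n_per_group)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", sp$label, a)
      animals <- c(animals, id)
      groups <- c(groups, sp$label)
      intens <- c(sp$baseline_count, sp$hotspot_multiplier * amps)
      total <- sum(intens)
      pts <- withr::with_seed(animal_seed(config$seed, idx, 0L), {
        n <- stats::rpois(1L, total)
        if (n == 0L) {
          matrix(numeric(0), ncol = 2L)
        } else {
          comp <- sample.int(length(intens), n, replace = TRUE,
                             prob = intens / total)
          out <- matrix(NA_real_, n, 2L)
          if (any(comp == 1L)) {
            out[comp == 1L, ] <- sample_uniform_roi(sum(comp == 1L), roi)
          }
          for (h in seq_along(config$hotspots)) {
            sel <- comp == h + 1L
            if (any(sel)) {
              out[sel, ] <- sample_hotspot(sum(sel), config$hotspots[[h]], roi)
            }
          }
          out
        }
      })
      if (nrow(pts) > 0L) {
        rows[[idx]] <- data.frame(animal_id = id, group = sp$label,
                                  x_um = pts[, 1L], y_um = pts[, 2L])
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(animal_id = character(0), group = character(0),
               x_um = numeric(0), y_um = numeric(0))
  rownames(out) <- NULL
  attr(out, "animals") <- data.frame(animal_id = animals, group = groups)
  class(out) <- c("neuron_maps", "data.frame")
  out
}

#' Simulate a freezing cohort
#'
#' One record per animal and phase; percent freezing is drawn
#' Normal(mean, SD) from the group's phase specification and clamped to
#' [0, 100] (truncation applied after sampling, since freezing is a bounded
#' percentage).
#'
#' @param config a [sim_config()] with a freezing spec for every group.
#' @return A long-format data.frame: `animal_id`, `group`, `phase`,
#'   `percent_freezing`.
#' @export
simulate_freezing <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fz <- config$freezing
  fz_labels <- vapply(fz, `[[`, character(1L), "label")
  rows <- list()
  idx <- 0L
  for (sp in config$spatial) {
    k <- match(sp$label, fz_labels)
    if (is.na(k)) {
      stop(sprintf("no freezing specification for group '%s'", sp$label),
           call. = FALSE)
    }
    spec <- fz[[k]]
    for (ph in config$phases) {
      if (!ph %in% names(spec$means)) {
        stop(sprintf("group '%s' is missing a freezing spec for phase '%s'",
                     sp$label, ph), call. = FALSE)
      }
    }
    for (a in seq_len(config$n_per_group)) {
      idx <- idx + 1L
      id <- sprintf("%s_%02d", sp$label, a)
      vals <- withr::with_seed(animal_seed(config$seed, idx, 1L), {
        v <- stats::rnorm(length(config$phases),
                          mean = spec$means[config$phases],
                          sd = spec$sds[config$phases])
        pmin(pmax(v, 0), 100)
      })
      rows[[idx]] <- data.frame(animal_id = id, group = sp$label,
                                phase = config$phases,
                                percent_freezing = as.numeric(vals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled demonstration configuration
#'
#' A six-arm cohort mirroring a typical reconsolidation design (vehicle,
#' three doses of a reconsolidation-blocking MEK inhibitor, a brain-
#' penetrant positive control, and a non-penetrant negative control), six
#' animals per arm. Effective treatments carry `hotspot_multiplier` < 1;
#' the negative control matches vehicle. Freezing means are qualitative:
#' moderate post-training freezing, high freezing at reactivation, and a
#' treatment-dependent test-day level. These defaults are illustrative, not
#' fitted to any particular dataset.
#'
#' @param seed integer seed.
#' @param n_per_group animals per arm (default 6).
#' @return A [sim_config()].
#' @export
demo_sim_config <- function(seed = 1L, n_per_group = 6L) {
  # stylized almond-shaped contour, roughly lateral-amygdala proportions
  theta <- seq(0, 2 * pi, length.out = 25L)[-25L]
  roi <- roi_contour(450 * cos(theta) + 450,
                     330 * sin(theta) * (1 + 0.25 * cos(theta)) + 350)
  hs <- list(
    hotspot(center = c(320, 480), radius = 55, amplitude = 40),
    hotspot(center = c(620, 300), radius = 60, amplitude = 35),
    hotspot(center = c(450, 200), radius = 45, amplitude = 25)
  )
  arms <- c(vehicle = 1, mirdametinib_5 = 0.35, mirdametinib_10 = 0.3,
            mirdametinib_25 = 0.25, sl327_50 = 0.25, trametinib_5 = 1)
  spatial <- mapply(function(lab, mult)
    group_spatial_spec(lab, baseline_count = 250, hotspot_multiplier = mult),
    names(arms), arms, SIMPLIFY = FALSE)
  test_means <- c(vehicle = 60, mirdametinib_5 = 35, mirdametinib_10 = 32,
                  mirdametinib_25 = 30, sl327_50 = 30, trametinib_5 = 58)
  freezing <- lapply(names(arms), function(lab)
    group_freezing_spec(
      lab,
      means = c(`training-post` = 45, reactivation = 65, test = test_means[[lab]]),
      sds = c(`training-post` = 12, reactivation = 12, test = 12)
    ))
  sim_config(roi, hotspots = hs, spatial = spatial, freezing = freezing,
             n_per_group = n_per_group, seed = seed)
}

#' Read / write neuron coordinate and freezing CSV files
#'
#' Coordinates: columns `animal_id,group,x_um,y_um`. Freezing: columns
#' `animal_id,group,phase,percent_freezing`.
#'
#' @param path file path.
#' @param maps,freezing data.frames in the formats above.
#' @return The read functions return data.frames.
#' @export
read_coords_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("animal_id", "group", "x_um", "y_um")
  if (!all(need %in% names(d))) {
    stop("coordinate CSV must have columns animal_id,group,x_um,y_um",
         call. = FALSE)
  }
  d
}

#' @rdname read_coords_csv
#' @export
write_coords_csv <- function(maps, path) {
  utils::write.csv(
    maps[, c("animal_id", "group", "x_um", "y_um")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_coords_csv
#' @export
read_freezing_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("animal_id", "group", "phase", "percent_freezing")
  if (!all(need %in% names(d))) {
    stop("freezing CSV must have columns animal_id,group,phase,percent_freezing",
         call. = FALSE)
  }
  d
}

#' @rdname read_coords_csv
#' @export
write_freezing_csv <- function(freezing, path) {
  utils::write.csv(
    freezing[, c("animal_id", "group", "phase", "percent_freezing")],
    path, row.names = FALSE)
  invisible(path)
}
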