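#' Pipeline configuration
#'
#' A single structure driving the full analysis. Either `simulate = TRUE`
#' (inputs generated by the synthetic module from `sim`) or explicit file
#' paths for coordinates, ROI and freezing tables.
#'
#' @param out_dir output directory (created if absent).
#' @param simulate generate inputs with the synthetic module.
#' @param sim a [sim_config()] (required when `simulate`); its seed is
#'   overridden by `seed`.
#' @param coords_path,roi_path,freezing_path input CSVs (required when
#'   `simulate = FALSE`).
#' @param rows,cols bin-grid dimensions (default 7 x 9).
#' @param q_threshold FDR tolerable limit (default 0.1).
#' @param freezing_threshold inclusion cutoff, percent (default 37).
#' @param alpha planned-comparison / post-hoc level (default 0.05).
#' @param reference_group control group label.
#' @param seed integer seed for every stochastic stage.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, sim = NULL,
                            coords_path = NULL, roi_path = NULL,
                            freezing_path = NULL, rows = 7L, cols = 9L,
                            q_threshold = 0.1, freezing_threshold = 37,
                            alpha = 0.05, reference_group = "vehicle",
                            seed = 1L) {
  if (q_threshold <= 0 || q_threshold >= 1) {
    stop("`q_threshold` must lie in (0, 1)", call. = FALSE)
  }
  if (freezing_threshold < 0 || freezing_threshold > 100) {
    stop("`freezing_threshold` must lie in [0, 100]", call. = FALSE)
  }
  if (simulate) {
    if (is.null(sim)) sim <- demo_sim_config(seed = seed)
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
  } else {
    for (p in c(coords_path, roi_path, freezing_path)) {
      if (!is.null(p) && !file.exists(p)) {
        stop(sprintf("input file not found: %s", p), call. = FALSE)
      }
    }
    if (is.null(coords_path) || is.null(roi_path)) {
      stop("`coords_path` and `roi_path` are required when not simulating",
           call. = FALSE)
    }
  }
  structure(
    list(out_dir = out_dir, simulate = simulate, sim = sim,
         coords_path = coords_path, roi_path = roi_path,
         freezing_path = freezing_path, rows = as.integer(rows),
         cols = as.integer(cols), q_threshold = q_threshold,
         freezing_threshold = freezing_threshold, alpha = alpha,
         reference_group = reference_group, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Recognized fields mirror the arguments of [pipeline_config()]; a
#' `sim` block, when present, holds `roi` (list of `x_um`/`y_um` vertex
#' arrays or a path), `hotspots` (list of `center`, `radius`, `amplitude`),
#' `groups` (list of `label`, `baseline_count`, `hotspot_multiplier`, and
#' optional `freezing` means/sds by phase) and `n_per_group`.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @param out_dir,seed overrides for the file's values (optional).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  sim <- NULL
  simulate <- isTRUE(cfg$simulate) || !is.null(cfg$sim)
  if (simulate && !is.null(cfg$sim)) {
    s <- cfg$sim
    roi <- if (is.character(s$roi)) read_roi_csv(s$roi) else
      roi_contour(s$roi$x_um, s$roi$y_um)
    hs <- lapply(seq_len(NROW(s$hotspots)), function(i) {
      h <- if (is.data.frame(s$hotspots)) as.list(s$hotspots[i, ]) else
        s$hotspots[[i]]
      hotspot(unlist(h$center), h$radius, h$amplitude)
    })
    grp <- lapply(seq_len(NROW(s$groups)), function(i) {
      if (is.data.frame(s$groups)) as.list(s$groups[i, ]) else s$groups[[i]]
    })
    spatial <- lapply(grp, function(g)
      group_spatial_spec(g$label, g$baseline_count,
                         if (is.null(g$hotspot_multiplier)) 1 else
                           g$hotspot_multiplier))
    freezing <- Filter(Negate(is.null), lapply(grp, function(g) {
      if (is.null(g$freezing)) return(NULL)
      group_freezing_spec(g$label, unlist(g$freezing$means),
                          unlist(g$freezing$sds))
    }))
    sim <- sim_config(roi, hotspots = hs, spatial = spatial,
                      freezing = freezing,
                      n_per_group = if (is.null(s$n_per_group)) 6L else
                        s$n_per_group,
                      seed = cfg$seed)
  }
  pipeline_config(
    out_dir = cfg$out_dir, simulate = simulate, sim = sim,
    coords_path = cfg$coords_path, roi_path = cfg$roi_path,
    freezing_path = cfg$freezing_path,
    rows = if (is.null(cfg$rows)) 7L else cfg$rows,
    cols = if (is.null(cfg$cols)) 9L else cfg$cols,
    q_threshold = if (is.null(cfg$q_threshold)) 0.1 else cfg$q_threshold,
    freezing_threshold = if (is.null(cfg$freezing_threshold)) 37 else
      cfg$freezing_threshold,
    alpha = if (is.null(cfg$alpha)) 0.05 else cfg$alpha,
    reference_group = if (is.null(cfg$reference_group)) "vehicle" else
      cfg$reference_group,
    seed = cfg$seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> bin -> density/CV maps -> mass-univariate
#' FDR statistics and bin classification -> total-count ANOVA -> freezing
#' inclusion filter -> mixed ANOVA with Tukey post-hoc, writing every stage
#' output under `config$out_dir` plus a JSON manifest. Reruns with the same
#' config and seed reproduce byte-identical CSV outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return The manifest (invisibly), a list recording inputs, seed, stage
#'   summaries and every file written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  say <- function(...) if (!quiet) message(sprintf(...))
  emit <- function(writer, obj, name) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    files <<- c(files, name)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  manifest <- list(seed = config$seed,
                   parameters = list(
                     rows = config$rows, cols = config$cols,
                     q_threshold = config$q_threshold,
                     freezing_threshold = config$freezing_threshold,
                     alpha = config$alpha,
                     reference_group = config$reference_group),
                   stages = list())

  # --- inputs -------------------------------------------------------------
  if (config$simulate) {
    stage("simulate", {
      maps <- simulate_neuron_maps(config$sim)
      freezing <- if (length(config$sim$freezing))
        simulate_freezing(config$sim) else NULL
      roi <- config$sim$roi
      emit(write_coords_csv, maps, "coords.csv")
      emit(write_roi_csv, roi, "roi.csv")
      if (!is.null(freezing)) emit(write_freezing_csv, freezing, "freezing.csv")
    })
    say("simulated %d neurons across %d animals", nrow(maps),
        nrow(attr(maps, "animals")))
  } else {
    maps <- stage("load", read_coords_csv(config$coords_path))
    roi <- stage("load", read_roi_csv(config$roi_path))
    freezing <- if (!is.null(config$freezing_path))
      stage("load", read_freezing_csv(config$freezing_path)) else NULL
  }
  manifest$stages$input <- list(
    n_neurons = nrow(maps),
    n_animals = length(unique(maps$animal_id)),
    simulated = config$simulate)

  # --- topography ----------------------------------------------------------
  grid <- stage("topomap", build_bin_grid(roi, config$rows, config$cols))
  cms <- stage("topomap", assign_counts_cohort(maps, grid, roi))
  n_outside <- sum(vapply(cms, `[[`, integer(1L), "n_outside"))
  say("binned into %d x %d grid (%d-bin family), %d neurons outside ROI",
      config$rows, config$cols, sum(grid$inside), n_outside)
  groups <- unique(vapply(cms, `[[`, character(1L), "group"))
  for (gname in groups) {
    gm <- Filter(function(m) identical(m$group, gname), cms)
    if (length(gm) >= 2L) {
      dm <- density_cv_maps(gm)
      emit(write_map_csv, dm$density, sprintf("density_%s.csv", gname))
      emit(write_map_csv, dm$cv, sprintf("cv_%s.csv", gname))
      emit(function(o, p) plot_map_png(o, p, main = sprintf("density: %s", gname)),
           dm$density, sprintf("density_%s.png", gname))
    }
  }
  counts_tab <- do.call(rbind, lapply(cms, function(m)
    data.frame(animal_id = m$animal_id, group = m$group,
               bin = seq_along(m$counts), # row-major numbering
               count = as.vector(t(m$counts)))))
  emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
       counts_tab, "bin_counts.csv")
  manifest$stages$topography <- list(
    rows = config$rows, cols = config$cols, family_size = sum(grid$inside),
    n_outside_roi = n_outside,
    n_in_masked_bins = sum(vapply(cms, `[[`, integer(1L), "n_in_masked_bins")))

  # --- bin statistics ------------------------------------------------------
  bs <- cls <- NULL
  if (length(groups) >= 2L) {
    bs <- stage("binstats", mass_univariate(cms, grid, config$q_threshold))
    cls <- stage("binstats", classify_bins(
      bs, cms, reference_group = config$reference_group,
      alpha = config$alpha))
    tot <- stage("binstats", total_count_anova(cms, grid))
    emit(write_map_csv, bs$q, "q_matrix.csv")
    emit(write_map_csv, bs$F, "f_matrix.csv")
    emit(function(o, p) plot_map_png(o, p, main = "q-value matrix",
                                     palette = "Blue-Red"),
         bs$q, "q_matrix.png")
    emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
         data.frame(bin = which(t(bs$family)),
                    code = as.vector(t(cls))[which(t(bs$family))]),
         "bin_classification.csv")
    emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
         tot$totals, "total_counts.csv")
    summary_js <- list(
      family_size = bs$m,
      rejected_bins = which(t(bs$significant)), # row-major bin numbers
      q_threshold = bs$q_threshold,
      classification = as.list(table(as.vector(cls[bs$significant]))),
      total_count_anova = tot$anova[c("F", "df1", "df2", "p")])
    emit(function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                             pretty = TRUE, digits = NA),
         summary_js, "binstats_summary.json")
    say("%d of %d bins significant at q < %.2g", sum(bs$significant), bs$m,
        config$q_threshold)
    manifest$stages$binstats <- list(
      family_size = bs$m, n_significant = sum(bs$significant),
      total_anova_p = tot$anova$p)
  }

  # --- behavior ------------------------------------------------------------
  if (!is.null(freezing)) {
    fl <- stage("behavior", exclusion_filter(
      freezing, threshold = config$freezing_threshold))
    say("inclusion filter: %d retained, %d excluded",
        fl$n_retained, fl$n_excluded)
    rm_res <- tk <- NULL
    if (fl$n_retained >= 4L &&
        length(unique(fl$records$group)) >= 2L) {
      rm_res <- stage("behavior", rm_anova(fl$records))
      sm <- rm_res$subject_means
      tk <- stage("behavior", tukey_hsd(
        split(sm$mean, sm$group),
        error_ms = rm_res$error_between$ms / rm_res$m,
        error_df = rm_res$error_between$df))
      emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
           tk, "tukey.csv")
      emit(function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                               pretty = TRUE, digits = NA),
           list(effects = rm_res$effects,
                excluded = fl$excluded,
                n_retained = fl$n_retained),
           "behavior_anova.json")
    }
    manifest$stages$behavior <- list(
      n_retained = fl$n_retained, n_excluded = fl$n_excluded,
      excluded = fl$excluded,
      group_p = if (!is.null(rm_res))
        rm_res$effects$p[rm_res$effects$effect == "group"] else NULL)
  }

  manifest$files <- files
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("wrote %d files to %s", length(files) + 1L, config$out_dir)
  invisible(manifest)
}
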