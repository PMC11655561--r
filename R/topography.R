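#' Build a bin grid over an ROI
#'
#' Tessellates the ROI's axis-aligned bounding box into `rows` x `cols`
#' equal rectangular bins. Bin `(r, c)` covers the half-open rectangle
#' `[x0 + (c-1) w, x0 + c w) x [y0 + (r-1) h, y0 + r h)`, with the last row
#' and column closed on the far edge so every bounding-box point maps to
#' exactly one bin. A bin belongs to the analysis family ("unmasked") iff
#' its centre lies inside the contour.
#'
#' Bins are numbered row-major from the origin corner: bin
#' `(r-1) * cols + c`. Matrix row 1 is the row adjacent to the bounding-box
#' minimum y; y increases with the stored coordinate value (no image-axis
#' flip is assumed).
#'
#' @param roi an [roi_contour()].
#' @param rows,cols number of bin rows and columns (default 7 x 9 = 63 bins).
#' @return A `bin_grid` object: `rows`, `cols`, `origin`, `bin_w`, `bin_h`
#'   (µm), `inside` (rows x cols logical, `TRUE` = bin in the family) and
#'   `roi_area`.
#' @examples
#' roi <- roi_contour(c(0, 90, 90, 0), c(0, 0, 70, 70))
#' g <- build_bin_grid(roi, rows = 7, cols = 9)
#' sum(g$inside)  # 63: a rectangular ROI leaves every bin unmasked
#' @export
build_bin_grid <- function(roi, rows = 7L, cols = 9L) {
  stopifnot(inherits(roi, "roi_contour"))
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L) {
    stop("`rows` and `cols` must be >= 1", call. = FALSE)
  }
  x0 <- roi$xlim[1]; y0 <- roi$ylim[1]
  w <- diff(roi$xlim) / cols
  h <- diff(roi$ylim) / rows
  if (w <= 0 || h <= 0) {
    stop("degenerate ROI bounding box", call. = FALSE)
  }
  cx <- x0 + (seq_len(cols) - 0.5) * w
  cy <- y0 + (seq_len(rows) - 0.5) * h
  centers <- expand.grid(y = cy, x = cx) # column-major fill of rows x cols
  inside <- matrix(point_in_roi(centers$x, centers$y, roi), rows, cols)
  if (!any(inside)) {
    stop("empty bin family: no bin centre falls inside the ROI; ",
         "use a coarser grid", call. = FALSE)
  }
  structure(
    list(rows = rows, cols = cols, origin = c(x = x0, y = y0),
         bin_w = w, bin_h = h, inside = inside, roi_area = roi$area),
    class = "bin_grid"
  )
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("bin grid: %d x %d = %d bins (%d in family), bin %.1f x %.1f um\n",
              x$rows, x$cols, x$rows * x$cols, sum(x$inside), x$bin_w, x$bin_h))
  invisible(x)
}

#' Suggest bin-grid dimensions
#'
#' Helper choosing `rows` x `cols` so the expected neuron count per
#' in-family bin is at least `min_per_bin`, keeping the bins close to
#' square and the total near a requested family size.
#'
#' @param roi an [roi_contour()].
#' @param expected_total expected in-ROI neurons per animal.
#' @param min_per_bin minimum expected neurons per bin (default 1).
#' @return Named integer vector `c(rows, cols)`.
#' @export
suggest_bin_dims <- function(roi, expected_total, min_per_bin = 1) {
  stopifnot(inherits(roi, "roi_contour"))
  if (expected_total <= 0) return(c(rows = 1L, cols = 1L))
  max_bins <- max(1, floor(expected_total / min_per_bin))
  aspect <- diff(roi$xlim) / diff(roi$ylim)
  rows <- max(1L, floor(sqrt(max_bins / aspect)))
  cols <- max(1L, floor(max_bins / rows))
  c(rows = rows, cols = cols)
}

# Map coordinates (already inside the bounding box) to (row, col); far
# edges fold into the last row/column.
bin_of <- function(x, y, grid) {
  cc <- pmin(floor((x - grid$origin[["x"]]) / grid$bin_w), grid$cols - 1L) + 1L
  rr <- pmin(floor((y - grid$origin[["y"]]) / grid$bin_h), grid$rows - 1L) + 1L
  cbind(row = pmax(rr, 1L), col = pmax(cc, 1L))
}

#' Bin one animal's neuron coordinates
#'
#' Every coordinate inside (or on) the ROI contour increments exactly one
#' bin; coordinates outside the ROI are excluded and counted. A point inside
#' the ROI whose bin centre lies outside the contour still increments its
#' geometric bin; such bins are masked out of downstream statistics, and the
#' number of points they captured is reported as `n_in_masked_bins`.
#'
#' @param map data.frame with columns `x_um`, `y_um` (optionally
#'   `animal_id`, `group`) for one animal.
#' @param grid a [build_bin_grid()] result built from `roi`.
#' @param roi the [roi_contour()] the grid was built from.
#' @param animal_id,group identifiers; taken from `map` when present.
#' @return A `count_matrix` object: `animal_id`, `group`, `counts`
#'   (rows x cols integer matrix), `n_in_roi`, `n_outside`,
#'   `n_in_masked_bins`.
#' @export
assign_counts <- function(map, grid, roi, animal_id = NULL, group = NULL) {
  stopifnot(inherits(grid, "bin_grid"), inherits(roi, "roi_contour"))
  x <- map$x_um
  y <- map$y_um
  bad <- which(!is.finite(x) | !is.finite(y))
  if (length(bad)) {
    stop(sprintf("non-finite coordinate in row %d", bad[1L]), call. = FALSE)
  }
  if (is.null(animal_id)) {
    animal_id <- if (!is.null(map$animal_id) && nrow(map) > 0)
      as.character(map$animal_id[1L]) else NA_character_
  }
  if (is.null(group)) {
    group <- if (!is.null(map$group) && nrow(map) > 0)
      as.character(map$group[1L]) else NA_character_
  }
  counts <- matrix(0L, grid$rows, grid$cols)
  n_out <- 0L
  if (length(x)) {
    inroi <- point_in_roi(x, y, roi)
    n_out <- sum(!inroi)
    if (any(inroi)) {
      rc <- bin_of(x[inroi], y[inroi], grid)
      tab <- table(factor((rc[, "row"] - 1L) * grid$cols + rc[, "col"],
                          levels = seq_len(grid$rows * grid$cols)))
      counts <- matrix(as.integer(tab), grid$rows, grid$cols, byrow = TRUE)
    }
  }
  structure(
    list(animal_id = animal_id, group = group, counts = counts,
         n_in_roi = sum(counts), n_outside = n_out,
         n_in_masked_bins = sum(counts[!grid$inside])),
    class = "count_matrix"
  )
}

#' Bin a whole cohort of neuron maps
#'
#' Splits a long coordinate table by animal and applies [assign_counts()]
#' to each. Animals listed in the table's `animals` attribute (as produced
#' by [simulate_neuron_maps()]) but absent from the rows (zero neurons)
#' receive all-zero matrices.
#'
#' @param maps data.frame with `animal_id`, `group`, `x_um`, `y_um`.
#' @inheritParams assign_counts
#' @return List of `count_matrix` objects, one per animal.
#' @export
assign_counts_cohort <- function(maps, grid, roi) {
  roster <- attr(maps, "animals")
  if (is.null(roster)) {
    roster <- unique(maps[, c("animal_id", "group")])
  }
  lapply(seq_len(nrow(roster)), function(i) {
    id <- as.character(roster$animal_id[i])
    sub <- maps[maps$animal_id == id, , drop = FALSE]
    assign_counts(sub, grid, roi, animal_id = id,
                  group = as.character(roster$group[i]))
  })
}

check_same_grid <- function(matrices) {
  dims <- vapply(matrices, function(m) dim(m$counts), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("count matrices were built on differing grids", call. = FALSE)
  }
  invisible(TRUE)
}

stack_counts <- function(matrices) {
  check_same_grid(matrices)
  nb <- length(matrices[[1L]]$counts)
  x <- vapply(matrices, function(m) as.vector(m$counts), numeric(nb))
  if (is.null(dim(x))) x <- matrix(x, nrow = nb) # single-bin grids
  x
}

#' Group density map (per-bin mean count)
#'
#' @param matrices list of `count_matrix` objects (>= 1 animal), typically
#'   one group.
#' @return Numeric rows x cols matrix of per-bin mean counts.
#' @export
density_map <- function(matrices) {
  if (length(matrices) < 1L) stop("need at least one animal", call. = FALSE)
  x <- stack_counts(matrices)
  matrix(rowMeans(x), nrow(matrices[[1L]]$counts))
}

#' Coefficient-of-variance map
#'
#' Per-bin sample SD (n - 1 denominator) divided by the per-bin mean.
#' Undefined (NA) where the mean is zero; requires at least two animals.
#'
#' @inheritParams density_map
#' @return Numeric rows x cols matrix; `NA` flags undefined bins.
#' @export
cv_map <- function(matrices) {
  if (length(matrices) < 2L) {
    stop("a CV map needs at least 2 animals", call. = FALSE)
  }
  x <- stack_counts(matrices)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1L))
  cv <- ifelse(m > 0, s / m, NA_real_)
  matrix(cv, nrow(matrices[[1L]]$counts))
}

#' Density and CV maps for one group
#'
#' @param matrices list of `count_matrix` objects.
#' @param group optional group label to subset on.
#' @return List with `density` and `cv` matrices (see [density_map()],
#'   [cv_map()]) and `n` animals used.
#' @export
density_cv_maps <- function(matrices, group = NULL) {
  if (!is.null(group)) {
    matrices <- Filter(function(m) identical(m$group, group), matrices)
  }
  if (length(matrices) < 2L) {
    stop("density/CV maps need at least 2 animals in the group", call. = FALSE)
  }
  list(density = density_map(matrices), cv = cv_map(matrices),
       n = length(matrices))
}

#' Write a map matrix as row-major CSV
#'
#' @param m numeric matrix.
#' @param path output path.
#' @export
write_map_csv <- function(m, path) {
  d <- as.data.frame(m)
  names(d) <- sprintf("c%02d", seq_len(ncol(m)))
  utils::write.csv(cbind(row = seq_len(nrow(m)), d), path, row.names = FALSE)
  invisible(path)
}

#' Render a map matrix as a PNG heat map
#'
#' @param m numeric matrix (bins); `NA` cells are drawn blank.
#' @param path output PNG path.
#' @param main plot title.
#' @param palette an `hcl.colors` palette name.
#' @export
plot_map_png <- function(m, path, main = "", palette = "YlOrRd") {
  grDevices::png(path, width = 640, height = 520)
  on.exit(grDevices::dev.off())
  graphics::image(
    x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
    col = grDevices::hcl.colors(64, palette, rev = TRUE),
    xlab = "bin column", ylab = "bin row", main = main, useRaster = FALSE
  )
  invisible(path)
}
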