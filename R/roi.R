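#' Region-of-interest contour
#'
#' Construct a traced region-of-interest (ROI) contour from an ordered list
#' of polygon vertices in micrometres, as exported after outlining a brain
#' structure (e.g. the lateral amygdala) on a calibrated section image. The
#' polygon is closed implicitly (the last vertex connects back to the first).
#'
#' @param x,y numeric vectors of vertex coordinates in µm (same length,
#'   at least 3 vertices, finite values).
#' @return An object of class `roi_contour`: a list with `vertices`
#'   (two-column matrix), `area` (µm², shoelace formula) and the bounding
#'   box `xlim`/`ylim`.
#' @examples
#' roi <- roi_contour(c(0, 100, 100, 0), c(0, 0, 50, 50))
#' roi$area
#' @export
roi_contour <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("an ROI contour needs at least 3 vertices", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("ROI vertices must be finite", call. = FALSE)
  }
  # drop an explicitly repeated closing vertex
  n <- length(x)
  if (x[1L] == x[n] && y[1L] == y[n]) {
    x <- x[-n]
    y <- y[-n]
    if (length(x) < 3L) {
      stop("an ROI contour needs at least 3 distinct vertices", call. = FALSE)
    }
  }
  if (!polygon_is_simple(x, y)) {
    stop("ROI polygon is self-intersecting; contours must be simple",
         call. = FALSE)
  }
  area <- polygon_area(x, y)
  if (area <= 0) {
    stop("degenerate ROI: polygon area is zero", call. = FALSE)
  }
  structure(
    list(
      vertices = cbind(x = x, y = y),
      area = area,
      xlim = range(x),
      ylim = range(y)
    ),
    class = "roi_contour"
  )
}

#' @export
print.roi_contour <- function(x, ...) {
  cat(sprintf(
    "ROI contour: %d vertices, area %.1f um^2, bbox [%.1f, %.1f] x [%.1f, %.1f]\n",
    nrow(x$vertices), x$area, x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2]
  ))
  invisible(x)
}

#' Unsigned polygon area (shoelace formula)
#'
#' @param x,y vertex coordinates of a closed polygon (closing edge implicit).
#' @return Area in squared input units.
#' @export
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Proper-crossing test for two closed segments p1-p2 and p3-p4, used by the
# simplicity check. Shared endpoints between adjacent edges are handled by
# the caller.
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# O(n^2) simplicity test; contours traced by hand have few vertices so the
# quadratic cost is irrelevant.
polygon_is_simple <- function(x, y) {
  n <- length(x)
  v <- cbind(x, y)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # skip edges sharing a vertex (adjacent, incl. the closing edge)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Point-in-polygon test (boundary inclusive)
#'
#' Even-odd ray-casting test with an explicit on-boundary check: points
#' lying exactly on a polygon edge or vertex are counted as inside. The
#' inclusive convention matters for binning — a neuron recorded exactly on
#' the traced contour (or at the grid origin of a rectangular ROI) must be
#' counted, not dropped.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param roi an [roi_contour()] object.
#' @return Logical vector, `TRUE` where the point is inside or on the
#'   contour.
#' @export
point_in_roi <- function(px, py, roi) {
  stopifnot(inherits(roi, "roi_contour"))
  vx <- roi$vertices[, 1L]
  vy <- roi$vertices[, 2L]
  n <- length(vx)
  npt <- length(px)
  inside <- logical(npt)
  on_edge <- logical(npt)
  scale <- max(abs(c(vx, vy)), 1)
  eps <- 1e-12 * scale * scale
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # boundary: |cross| ~ 0 and point within the edge's bounding box
    cross <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
    on_this <- abs(cross) <= eps &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | on_this
    # even-odd crossing of the horizontal ray to +infinity
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Read / write an ROI contour as CSV
#'
#' The CSV has two columns, `x_um` and `y_um`, one row per vertex in order;
#' the polygon is closed implicitly.
#'
#' @param path file path.
#' @return `read_roi_csv` returns an [roi_contour()].
#' @export
read_roi_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(d))) {
    stop("ROI CSV must have columns x_um,y_um", call. = FALSE)
  }
  roi_contour(d$x_um, d$y_um)
}

#' @rdname read_roi_csv
#' @param roi an [roi_contour()] object.
#' @export
write_roi_csv <- function(roi, path) {
  stopifnot(inherits(roi, "roi_contour"))
  utils::write.csv(
    data.frame(x_um = roi$vertices[, 1L], y_um = roi$vertices[, 2L]),
    path, row.names = FALSE
  )
  invisible(path)
}
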