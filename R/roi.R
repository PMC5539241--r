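# Polygonal regions of interest and their rasterization.
#
# Coordinate convention (documented, deterministic): images are indexed
# 0-based row-major in the continuous plane; the pixel at 0-based (row i,
# col j) covers [j, j+1) x [i, i+1) and is tested for polygon membership at
# its center (x, y) = (j + 0.5, i + 0.5). In R the same pixel is matrix
# element [i + 1, j + 1]. Membership uses the even-odd crossing rule with
# the half-open edge convention (an upward-crossing edge includes its lower
# endpoint and excludes its upper one), so points exactly on an edge are
# resolved deterministically and adjacent polygons tile without overlap.

ROI_LABELS <- c("lumen", "adventitia", "plaque", "background")

#' Polygonal region of interest
#'
#' A labelled simple polygon in continuous image coordinates, defining where
#' video intensity is read from a cine loop.
#'
#' @param label One of `"lumen"`, `"adventitia"`, `"plaque"`,
#'   `"background"`.
#' @param vertices Numeric matrix (or coercible two-column structure) of
#'   ordered (x, y) vertices; at least 3; the polygon must be simple
#'   (non-self-intersecting).
#' @return An object of class `roi_polygon`.
#' @export
#' @examples
#' roi <- roi_polygon("lumen", rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)))
#' sum(rasterize_roi(roi, c(10, 10)))  # 16 pixel centers inside
roi_polygon <- function(label, vertices) {
  label <- match.arg(label, ROI_LABELS)
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 3L || any(!is.finite(v)))
    ceus_stop("vertices must be a finite numeric n x 2 matrix with n >= 3",
              "invalid_parameter")
  dimnames(v) <- list(NULL, c("x", "y"))
  if (!polygon_is_simple(v))
    ceus_stop(sprintf("ROI '%s' polygon is self-intersecting", label),
              "invalid_parameter")
  structure(list(label = label, vertices = v), class = "roi_polygon")
}

#' @export
print.roi_polygon <- function(x, ...) {
  cat(sprintf("ROI '%s': %d vertices, bbox x [%.3g, %.3g], y [%.3g, %.3g]\n",
              x$label, nrow(x$vertices),
              min(x$vertices[, 1]), max(x$vertices[, 1]),
              min(x$vertices[, 2]), max(x$vertices[, 2])))
  invisible(x)
}

# Proper-crossing test between non-adjacent edges; collinear-overlap cases
# of degenerate polygons are not flagged (they never arise from rectangular
# or hand-drawn ROIs).
polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE]) # x1 y1 x2 y2 per edge
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  adjacent <- function(i, j) abs(i - j) == 1L || (i == 1L && j == n) || (j == 1L && i == n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (adjacent(i, j)) next
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}

# Even-odd crossing count for a grid of pixel centers, vectorized over the
# whole image; one pass per polygon edge.
even_odd_inside <- function(vertices, height, width) {
  px <- matrix(rep(seq_len(width) - 0.5, each = height), nrow = height)
  py <- matrix(rep(seq_len(height) - 0.5, times = width), nrow = height)
  n <- nrow(vertices)
  crossings <- matrix(0L, height, width)
  xi <- vertices[, 1]; yi <- vertices[, 2]
  xj <- vertices[c(n, seq_len(n - 1L)), 1]
  yj <- vertices[c(n, seq_len(n - 1L)), 2]
  for (e in seq_len(n)) {
    if (yi[e] == yj[e]) next # horizontal edges never cross a rightward ray
    straddles <- (yi[e] > py) != (yj[e] > py) # half-open in y
    xint <- (xj[e] - xi[e]) * (py - yi[e]) / (yj[e] - yi[e]) + xi[e]
    crossings <- crossings + (straddles & (px < xint))
  }
  crossings %% 2L == 1L
}

#' Rasterize an ROI polygon to a pixel mask
#'
#' A pixel belongs to the mask iff its center lies inside the polygon under
#' the even-odd rule (see the coordinate convention in the package
#' vignette). Raises an `empty_roi` error, naming the ROI label, when no
#' pixel center falls inside.
#'
#' @param roi An [roi_polygon()].
#' @param image_shape Integer vector `c(height, width)` in pixels.
#' @return Logical `height x width` matrix.
#' @export
rasterize_roi <- function(roi, image_shape) {
  stopifnot(inherits(roi, "roi_polygon"))
  if (length(image_shape) != 2L || !all(image_shape >= 1) ||
      any(image_shape != floor(image_shape)))
    ceus_stop("image_shape must be positive integers c(height, width)",
              "invalid_parameter")
  mask <- even_odd_inside(roi$vertices, as.integer(image_shape[1]),
                          as.integer(image_shape[2]))
  if (!any(mask))
    ceus_stop(sprintf("ROI '%s' rasterizes to an empty mask on a %d x %d image",
                      roi$label, image_shape[1], image_shape[2]),
              "empty_roi")
  mask
}

# Axis-aligned rectangular ROI from 1-based inclusive row/col ranges; the
# rasterized mask is exactly rows[1]:rows[2] x cols[1]:cols[2].
rect_roi <- function(label, rows, cols) {
  roi_polygon(label, rbind(
    c(cols[1] - 1, rows[1] - 1),
    c(cols[2],     rows[1] - 1),
    c(cols[2],     rows[2]),
    c(cols[1] - 1, rows[2])
  ))
}

#' Read and write labelled ROI sets as JSON
#'
#' The on-disk format is a JSON array of objects
#' `{"label": "...", "vertices": [[x, y], ...]}`; one file may hold several
#' labelled ROIs.
#'
#' @param path File path.
#' @param rois A list of [roi_polygon()] objects.
#' @return `read_rois_json()` returns a named list of `roi_polygon`s (named
#'   by label); `write_rois_json()` returns `path` invisibly.
#' @export
read_rois_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  rois <- lapply(raw, function(r) {
    roi_polygon(r$label, do.call(rbind, lapply(r$vertices, unlist)))
  })
  names(rois) <- vapply(rois, function(r) r$label, character(1))
  rois
}

#' @rdname read_rois_json
#' @export
write_rois_json <- function(rois, path) {
  stopifnot(all(vapply(rois, inherits, logical(1), "roi_polygon")))
  payload <- lapply(rois, function(r) {
    list(label = r$label,
         vertices = lapply(seq_len(nrow(r$vertices)),
                           function(i) as.numeric(r$vertices[i, ])))
  })
  jsonlite::write_json(unname(payload), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
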