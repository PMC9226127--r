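#' Define a raster grid frame
#'
#' A `grid_frame` fixes the geometry every raster in a run must share:
#' grid shape, cell size in metres, and the map coordinates of the outer
#' corner of the top-left cell. Row 1 is the northernmost row; the centre
#' of cell (r, c) is at `(origin_x + (c - 0.5) * cell_size,
#' origin_y - (r - 0.5) * cell_size)`.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin_x,origin_y Map coordinates of the outer corner of the
#'   top-left cell. Defaults place the lower-left corner at (0, 0).
#' @param crs_label Free-text coordinate reference system label.
#' @return An object of class `grid_frame`.
#' @examples
#' grid_frame(10, 10, 30)
#' @export
grid_frame <- function(n_rows, n_cols, cell_size = 30,
                       origin_x = 0, origin_y = n_rows * cell_size,
                       crs_label = "") {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || n_rows < 1L) stop("n_rows must be >= 1")
  if (is.na(n_cols) || n_cols < 1L) stop("n_cols must be >= 1")
  if (!is.finite(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         crs_label = as.character(crs_label)),
    class = "grid_frame"
  )
}

#' @export
print.grid_frame <- function(x, ...) {
  cat(sprintf("<grid_frame> %d x %d cells, %.6g m cells, origin (%.6g, %.6g)%s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              if (nzchar(x$crs_label)) paste0(" [", x$crs_label, "]") else ""))
  invisible(x)
}

frames_equal <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size)) &&
    isTRUE(all.equal(a$origin_x, b$origin_x)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y))
}

#' Assert that rasters share one spatial frame
#'
#' All pipeline stages require their inputs on the same grid. This checks
#' every pairwise field of the frames and returns the shared frame, or
#' stops naming the first field that differs.
#'
#' @param ... Rasters (any of the package raster classes) or `grid_frame`
#'   objects; at least one.
#' @return The shared `grid_frame`.
#' @export
check_frames <- function(...) {
  objs <- list(...)
  if (length(objs) == 0L) stop("at least one raster required")
  frames <- lapply(objs, function(o) if (inherits(o, "grid_frame")) o else o$frame)
  ref <- frames[[1L]]
  for (i in seq_along(frames)[-1L]) {
    f <- frames[[i]]
    for (field in c("n_rows", "n_cols", "cell_size", "origin_x", "origin_y")) {
      if (!isTRUE(all.equal(ref[[field]], f[[field]]))) {
        stop(sprintf("frame mismatch in '%s': %s vs %s (raster %d)",
                     field, format(ref[[field]]), format(f[[field]]), i))
      }
    }
  }
  ref
}

#' Cell area of a frame in square kilometres
#'
#' The single place where cell counts become areas: every area the package
#' reports is `count * cell_area_km2(frame)`.
#'
#' @param frame A `grid_frame`.
#' @return Scalar area of one cell in km^2.
#' @export
cell_area_km2 <- function(frame) {
  (frame$cell_size / 1000)^2
}

# Map centre coordinates of cells given row/col indices (1-based).
cell_centres <- function(frame, rows, cols) {
  cbind(x = frame$origin_x + (cols - 0.5) * frame$cell_size,
        y = frame$origin_y - (rows - 0.5) * frame$cell_size)
}
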