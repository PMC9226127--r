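#' Categorical land-cover raster
#'
#' The pipeline's universal currency: an integer class-code grid with a
#' spatial frame, a legend mapping codes to class names, and a nodata code.
#' Nodata cells are excluded from every area, transition and agreement
#' computation in the package.
#'
#' @param codes Integer matrix (`frame$n_rows` x `frame$n_cols`).
#' @param frame A [grid_frame()].
#' @param legend Named integer vector or list mapping class *names* to
#'   codes (e.g. `c(forest = 2, water = 5)`), or a named character vector
#'   keyed by code. Internally stored as a named integer vector
#'   (names = class names).
#' @param nodata_code Integer code marking invalid cells.
#' @return An object of class `land_raster`.
#' @seealso [read_landcover()], [write_landcover()], [class_areas()]
#' @export
land_raster <- function(codes, frame, legend, nodata_code = -9999L) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != frame$n_rows || ncol(codes) != frame$n_cols)
    stop("codes matrix does not match frame dimensions")
  legend <- normalize_legend(legend)
  if (anyDuplicated(legend)) stop("legend codes must be unique")
  nodata_code <- as.integer(nodata_code)
  present <- unique(codes[!is.na(codes) & codes != nodata_code])
  unknown <- setdiff(present, unname(legend))
  if (length(unknown))
    stop("codes not in legend: ", paste(sort(unknown), collapse = ", "))
  structure(list(frame = frame, codes = codes, legend = legend,
                 nodata_code = nodata_code),
            class = "land_raster")
}

# Accepts name->code (named numeric) or code->name (named character);
# returns named integer vector name -> code.
normalize_legend <- function(legend) {
  if (is.list(legend)) legend <- unlist(legend)
  if (is.null(names(legend)) || any(!nzchar(names(legend))))
    stop("legend must be named")
  if (is.character(legend)) {
    # keyed by code: names are codes, values are class names
    out <- as.integer(names(legend))
    names(out) <- as.character(legend)
    if (anyNA(out)) stop("legend keyed by code must have integer keys")
    return(out)
  }
  out <- as.integer(legend)
  names(out) <- names(legend)
  out
}

#' The six-class land-cover legend used throughout
#'
#' Cultivated land, forest land, grassland, construction land, water area
#' and unused land, coded 1-6. Any custom legend can be supplied instead.
#'
#' @return Named integer vector (class name -> code).
#' @export
default_legend <- function() {
  c(cultivated = 1L, forest = 2L, grass = 3L,
    construction = 4L, water = 5L, unused = 6L)
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("<land_raster> %d x %d, cell %.6g m, %d classes, nodata=%d\n",
              x$frame$n_rows, x$frame$n_cols, x$frame$cell_size,
              length(x$legend), x$nodata_code))
  tab <- class_areas(x)
  print(tab)
  invisible(x)
}

#' Per-class areas of a land-cover raster
#'
#' @param raster A `land_raster`.
#' @return Data frame with columns `class`, `code`, `cells`, `area_km2`;
#'   one row per legend class (zero rows counted too). Nodata excluded.
#' @export
class_areas <- function(raster) {
  a <- cell_area_km2(raster$frame)
  v <- raster$codes[raster$codes != raster$nodata_code & !is.na(raster$codes)]
  counts <- vapply(unname(raster$legend), function(code) sum(v == code), 0L)
  data.frame(class = names(raster$legend), code = unname(raster$legend),
             cells = counts, area_km2 = counts * a,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Continuous-valued raster (DEM, suitability, current density)
#'
#' @param values Numeric matrix matching the frame.
#' @param frame A [grid_frame()].
#' @param nodata Value marking invalid cells (may be `NA`).
#' @return An object of class `cont_raster`.
#' @export
cont_raster <- function(values, frame, nodata = NA_real_) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != frame$n_rows || ncol(values) != frame$n_cols)
    stop("values matrix does not match frame dimensions")
  structure(list(frame = frame, values = values, nodata = nodata),
            class = "cont_raster")
}

#' @export
print.cont_raster <- function(x, ...) {
  v <- x$values
  if (!is.na(x$nodata)) v <- v[v != x$nodata]
  cat(sprintf("<cont_raster> %d x %d, range [%.4g, %.4g]\n",
              x$frame$n_rows, x$frame$n_cols,
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Binary mask raster (e.g. an ecological red-line region)
#'
#' @param bits Matrix of 0/1 (or logical) values.
#' @param frame A [grid_frame()].
#' @return An object of class `mask_raster`.
#' @export
mask_raster <- function(bits, frame) {
  if (!is.matrix(bits)) bits <- as.matrix(bits)
  if (is.logical(bits)) bits <- bits + 0L
  storage.mode(bits) <- "integer"
  if (!all(bits %in% c(0L, 1L))) stop("mask values must be 0 or 1")
  if (nrow(bits) != frame$n_rows || ncol(bits) != frame$n_cols)
    stop("bits matrix does not match frame dimensions")
  structure(list(frame = frame, bits = bits), class = "mask_raster")
}

#' @export
print.mask_raster <- function(x, ...) {
  cat(sprintf("<mask_raster> %d x %d, coverage %.1f%%\n",
              x$frame$n_rows, x$frame$n_cols, 100 * mean(x$bits)))
  invisible(x)
}
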