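#' Read a categorical land-cover raster from an ESRI ASCII grid
#'
#' Parses the standard NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/NODATA_VALUE
#' header and the row-major (north to south) cell block. All values must be
#' representable as integers.
#'
#' @param path Path to an `.asc` file.
#' @param legend Class legend as for [land_raster()].
#' @param strict If `TRUE` (default) a code absent from the legend is an
#'   error naming the code; if `FALSE` such cells are mapped to nodata.
#' @param crs_label Optional CRS label to attach to the frame.
#' @return A `land_raster`.
#' @export
read_landcover <- function(path, legend, strict = TRUE, crs_label = "") {
  g <- read_ascii_grid(path, crs_label = crs_label)
  codes <- g$values
  if (any(is.finite(codes) & codes != round(codes)))
    stop("non-integer cell values in ", path)
  storage.mode(codes) <- "integer"
  nodata <- as.integer(g$nodata)
  legend <- normalize_legend(legend)
  present <- unique(codes[codes != nodata])
  unknown <- setdiff(present, unname(legend))
  if (length(unknown)) {
    if (strict)
      stop("codes not in legend: ", paste(sort(unknown), collapse = ", "))
    codes[codes %in% unknown] <- nodata
  }
  land_raster(codes, g$frame, legend, nodata_code = nodata)
}

#' Write a categorical land-cover raster as an ESRI ASCII grid
#'
#' The file round-trips through [read_landcover()] with bit-identical
#' codes, nodata placement and frame.
#'
#' @param raster A `land_raster`.
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_landcover <- function(raster, path) {
  write_ascii_grid(raster$codes, raster$frame, path,
                   nodata = raster$nodata_code, integer = TRUE)
  invisible(path)
}

#' Read / write continuous rasters (DEM, suitability, current)
#'
#' Same ESRI ASCII grid format as the categorical readers, without the
#' integer restriction.
#'
#' @param path File path.
#' @param crs_label Optional CRS label.
#' @return `read_continuous()` returns a `cont_raster`.
#' @export
read_continuous <- function(path, crs_label = "") {
  g <- read_ascii_grid(path, crs_label = crs_label)
  vals <- g$values
  vals[vals == g$nodata] <- NA_real_
  cont_raster(vals, g$frame, nodata = NA_real_)
}

#' @rdname read_continuous
#' @param raster A `cont_raster`.
#' @param nodata Nodata marker written for `NA` cells.
#' @export
write_continuous <- function(raster, path, nodata = -9999) {
  vals <- raster$values
  vals[is.na(vals)] <- nodata
  write_ascii_grid(vals, raster$frame, path, nodata = nodata, integer = FALSE)
  invisible(path)
}

#' @rdname read_continuous
#' @export
read_mask <- function(path, crs_label = "") {
  g <- read_ascii_grid(path, crs_label = crs_label)
  mask_raster(g$values, g$frame)
}

#' @rdname read_continuous
#' @param mask A `mask_raster`.
#' @export
write_mask <- function(mask, path) {
  write_ascii_grid(mask$bits, mask$frame, path, nodata = -9999, integer = TRUE)
  invisible(path)
}

# -- low-level ESRI ASCII grid codec ----------------------------------------

read_ascii_grid <- function(path, crs_label = "") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  hdr_keys <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]]
    key <- tolower(parts[1L])
    if (!(key %in% hdr_keys)) break
    hdr[[key]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("ASCII grid header missing ", toupper(k),
                                " in ", path)
  if (is.null(hdr$nodata_value)) hdr$nodata_value <- -9999
  body <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(body) != nr * nc)
    stop(sprintf("expected %d cells, found %d in %s", nr * nc, length(body),
                 path))
  values <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  frame <- grid_frame(nr, nc, hdr$cellsize,
                      origin_x = hdr$xllcorner,
                      origin_y = hdr$yllcorner + nr * hdr$cellsize,
                      crs_label = crs_label)
  list(values = values, frame = frame, nodata = hdr$nodata_value)
}

write_ascii_grid <- function(values, frame, path, nodata, integer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  fmt <- function(x) if (integer) format(as.integer(x), scientific = FALSE)
                     else format(x, digits = 17, scientific = FALSE)
  hdr <- c(
    paste("NCOLS", frame$n_cols),
    paste("NROWS", frame$n_rows),
    paste("XLLCORNER", format(frame$origin_x, digits = 17)),
    paste("YLLCORNER",
          format(frame$origin_y - frame$n_rows * frame$cell_size,
                 digits = 17)),
    paste("CELLSIZE", format(frame$cell_size, digits = 17)),
    paste("NODATA_VALUE", format(nodata))
  )
  rows <- apply(values, 1L, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
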