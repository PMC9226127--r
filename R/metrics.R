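#' Cross-tabulate two categorical maps
#'
#' Counts, over cells valid in both maps, how many cells of each start
#' class end in each end class. The diagonal is unchanged area; row sums
#' are start-class totals. Works for land-cover rasters and MSPA maps.
#'
#' @param map_start,map_end Frame-compatible `land_raster` or `mspa_map`
#'   objects.
#' @param interval_years Calendar years between the maps (> 0).
#' @return An object of class `transfer_table`: `counts` (matrix, classes
#'   x classes), `classes`, `interval_years`, `cell_area_km2`.
#' @export
cross_tabulate <- function(map_start, map_end, interval_years) {
  frame <- check_frames(map_start, map_end)
  if (interval_years <= 0) stop("interval_years must be > 0")
  g <- function(m) {
    if (inherits(m, "mspa_map"))
      list(v = m$classes, valid = m$valid,
           lv = unname(mspa_codes()), nm = names(mspa_codes()))
    else
      list(v = m$codes, valid = m$codes != m$nodata_code,
           lv = unname(m$legend), nm = names(m$legend))
  }
  a <- g(map_start); b <- g(map_end)
  both <- a$valid & b$valid
  fa <- factor(a$v[both], levels = a$lv, labels = a$nm)
  fb <- factor(b$v[both], levels = a$lv, labels = a$nm)
  counts <- unclass(table(start = fa, end = fb))
  structure(list(counts = counts, classes = a$nm,
                 interval_years = interval_years,
                 cell_area_km2 = cell_area_km2(frame)),
            class = "transfer_table")
}

#' @export
print.transfer_table <- function(x, ...) {
  cat(sprintf("<transfer_table> T = %g yr, cell %.4g km^2\n",
              x$interval_years, x$cell_area_km2))
  print(x$counts)
  invisible(x)
}

#' Single change rate index (annualized per-class area change)
#'
#' `P_s = (U_b - U_a) / U_a * (1 / T) * 100`, in percent per year.
#' Decline is negative.
#'
#' @param U_a,U_b Class area (km^2) at the start and end of the period;
#'   `U_a` must be positive.
#' @param T_years Period length in years (> 0); fractional years allowed.
#' @return Percent per year.
#' @export
single_change_rate <- function(U_a, U_b, T_years) {
  if (any(T_years <= 0)) stop("T_years must be > 0")
  if (any(U_a <= 0)) stop("single change rate undefined for U_a = 0")
  (U_b - U_a) / U_a / T_years * 100
}

#' Comprehensive change rate index (annualized landscape-wide change)
#'
#' `P_c = sum_i dU_i / (2 * sum_i U_i) * (1 / T) * 100` where `dU_i` is
#' the area of class i at the start that is no longer class i at the end
#' (transfer out: row sum minus diagonal) and `U_i` the start-of-period
#' class areas. The factor 2 compensates the double count of each moved
#' cell (out of one class, into another), bounding `P_c` to
#' `[0, 100 / T]`. The transfer-in interpretation gives the same total,
#' so the two readings coincide.
#'
#' @param transfer A [cross_tabulate()] result.
#' @return Percent per year.
#' @export
comprehensive_change_rate <- function(transfer) {
  cts <- transfer$counts
  U <- rowSums(cts) * transfer$cell_area_km2
  if (sum(U) == 0) stop("no valid start area")
  dU <- (rowSums(cts) - diag(cts)) * transfer$cell_area_km2
  sum(dU) / (2 * sum(U)) / transfer$interval_years * 100
}

#' Per-period change-rate summary of two MSPA maps
#'
#' Convenience wrapper: single rates per MSPA class (where the start area
#' is positive) plus the comprehensive rate.
#'
#' @param mspa_start,mspa_end Frame-compatible `mspa_map`s.
#' @param interval_years Period length in years.
#' @return Data frame with one row per class (`rate_pct_yr` is `NA` where
#'   the class is absent at the start) and attribute `comprehensive`.
#' @export
change_rates <- function(mspa_start, mspa_end, interval_years) {
  ta <- mspa_areas(mspa_start)
  tb <- mspa_areas(mspa_end)
  rate <- ifelse(ta$area_km2 > 0,
                 (tb$area_km2 - ta$area_km2) / ta$area_km2 /
                   interval_years * 100, NA_real_)
  out <- data.frame(class = ta$class, start_km2 = ta$area_km2,
                    end_km2 = tb$area_km2, rate_pct_yr = rate,
                    stringsAsFactors = FALSE)
  tr <- cross_tabulate(mspa_start, mspa_end, interval_years)
  attr(out, "comprehensive") <- comprehensive_change_rate(tr)
  out
}

#' Area-weighted barycenter of a patch set
#'
#' `X_t = sum(C_i * X_i) / sum(C_i)` (and the Y analogue): the mean of
#' patch geometric centroids weighted by patch area. Coordinates are in
#' the projected map frame (metres), not degrees.
#'
#' @param patches Data frame with columns `area_km2` (or `area`),
#'   `centroid_x`, `centroid_y`; e.g. from [major_cores()].
#' @return Named numeric `c(x = , y = )`.
#' @export
barycenter <- function(patches) {
  if (NROW(patches) == 0L) stop("empty patch set")
  w <- if ("area_km2" %in% names(patches)) patches$area_km2 else patches$area
  if (is.null(w) || any(w <= 0)) stop("all patch areas must be > 0")
  c(x = sum(w * patches$centroid_x) / sum(w),
    y = sum(w * patches$centroid_y) / sum(w))
}

#' Barycenter migration track of an MSPA class across dates
#'
#' For each date, the area-weighted barycenter of the chosen structural
#' class's 8-connected patches; plus displacement vectors between
#' consecutive dates. On a uniform grid the patch-weighted and cell-mean
#' definitions coincide.
#'
#' @param mspa_maps List of frame-compatible `mspa_map`s in date order
#'   (>= 2).
#' @param class MSPA class name (default `"core"`; `"island"` accepted
#'   for `"islet"`).
#' @param date_labels Optional character labels, one per map.
#' @return An object of class `barycenter_track`: data frame `track`
#'   (`date`, `x`, `y`, `dx`, `dy`, `step_m`).
#' @export
migration_track <- function(mspa_maps, class = "core", date_labels = NULL) {
  if (length(mspa_maps) < 2L) stop("need >= 2 dates")
  do.call(check_frames, mspa_maps)
  code <- resolve_mspa_class(class)
  if (is.null(date_labels)) date_labels <- as.character(seq_along(mspa_maps))
  pts <- lapply(mspa_maps, function(m) {
    idx <- which(m$classes == code & m$valid)
    if (!length(idx)) stop("no '", class, "' cells at one of the dates")
    rc <- arrayInd(idx, dim(m$classes))
    ctr <- cell_centres(m$frame, rc[, 1], rc[, 2])
    c(x = mean(ctr[, "x"]), y = mean(ctr[, "y"]))
  })
  xy <- do.call(rbind, pts)
  dx <- c(NA, diff(xy[, "x"])); dy <- c(NA, diff(xy[, "y"]))
  track <- data.frame(date = date_labels, x = xy[, "x"], y = xy[, "y"],
                      dx = dx, dy = dy, step_m = sqrt(dx^2 + dy^2),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(track = track, class = class), class = "barycenter_track")
}

#' @export
print.barycenter_track <- function(x, ...) {
  cat(sprintf("<barycenter_track> class '%s', %d dates\n",
              x$class, nrow(x$track)))
  print(x$track)
  invisible(x)
}

#' @export
plot.barycenter_track <- function(x, ...) {
  t <- x$track
  graphics::plot(t$x, t$y, type = "o", pch = 16, xlab = "x (m)",
                 ylab = "y (m)",
                 main = paste("Barycenter migration:", x$class), ...)
  graphics::text(t$x, t$y, t$date, pos = 3, cex = 0.8)
  invisible(x)
}

#' Cohen's kappa agreement between two categorical maps
#'
#' Chance-corrected cell-wise agreement over jointly valid cells:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with `p_o` the observed agreement
#' fraction and `p_e` the expected agreement from the two maps' marginal
#' class frequencies.
#'
#' @param map_a,map_b Frame-compatible `land_raster` or `mspa_map`
#'   objects, or a single confusion-count matrix passed as `map_a`.
#' @return Scalar in \[-1, 1\]. When both maps are constant and equal
#'   (`p_e = 1`) returns 1 with a warning, by convention.
#' @export
cohens_kappa <- function(map_a, map_b = NULL) {
  counts <- if (is.matrix(map_a) && is.null(map_b)) map_a
            else cross_tabulate(map_a, map_b, interval_years = 1)$counts
  n <- sum(counts)
  if (n == 0) stop("no jointly valid cells")
  p_o <- sum(diag(counts)) / n
  p_e <- sum(rowSums(counts) * colSums(counts)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps * 8) {
    warning("both maps constant and equal; kappa = 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}
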