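#' MSPA class codes
#'
#' Fixed code table used in every `mspa_map`: 0 background, 1 core,
#' 2 islet, 3 edge, 4 perforation, 5 bridge, 6 loop, 7 branch.
#' "island" is accepted as an alias for "islet".
#'
#' @return Named integer vector.
#' @export
mspa_codes <- function() {
  c(background = 0L, core = 1L, islet = 2L, edge = 3L, perforation = 4L,
    bridge = 5L, loop = 6L, branch = 7L)
}

mspa_class_names <- function() names(mspa_codes())[-1L]

resolve_mspa_class <- function(class) {
  if (identical(class, "island")) class <- "islet"
  codes <- mspa_codes()
  if (!class %in% names(codes)) stop("unknown MSPA class: ", class)
  codes[[class]]
}

#' Reclassify a land-cover raster into MSPA foreground/background
#'
#' Green-infrastructure analysis treats forest, cultivated, grass and
#' water as foreground habitat and everything else (construction, unused)
#' as background. Nodata cells belong to neither set.
#'
#' @param landcover A `land_raster`.
#' @param foreground_codes Integer codes, or class names resolved through
#'   the raster legend, forming the foreground. Default: the four green
#'   classes of [default_legend()].
#' @return An object of class `binary_landscape` with fields `frame`,
#'   `foreground` (logical matrix), `valid` (logical matrix of non-nodata
#'   cells) and `provenance` (the codes used).
#' @export
to_foreground <- function(landcover,
                          foreground_codes = c("cultivated", "forest",
                                               "grass", "water")) {
  if (is.character(foreground_codes)) {
    bad <- setdiff(foreground_codes, names(landcover$legend))
    if (length(bad)) stop("unknown class name(s): ",
                          paste(bad, collapse = ", "))
    foreground_codes <- unname(landcover$legend[foreground_codes])
  }
  foreground_codes <- as.integer(foreground_codes)
  bad <- setdiff(foreground_codes, unname(landcover$legend))
  if (length(bad)) stop("codes not in legend: ", paste(bad, collapse = ", "))
  valid <- landcover$codes != landcover$nodata_code
  fg <- valid & matrix(landcover$codes %in% foreground_codes,
                       nrow(landcover$codes), ncol(landcover$codes))
  structure(list(frame = landcover$frame, foreground = fg, valid = valid,
                 provenance = foreground_codes),
            class = "binary_landscape")
}

#' Segment a binary landscape into the seven MSPA structural classes
#'
#' Morphological spatial pattern analysis on the 8-neighbour lattice.
#' With edge width `s` (cells):
#'
#' 1. *Core*: foreground cells whose Chebyshev distance to the nearest
#'    background (or nodata, or the raster border) exceeds `s`.
#' 2. *Islet*: every cell of an 8-connected foreground component that
#'    contains no core.
#' 3. *Edge / perforation*: non-core, non-islet foreground within `s`
#'    (Chebyshev) of core of its own component; perforation where the
#'    nearest background is a hole (a 4-connected background component not
#'    touching the raster border), edge otherwise (ties to edge).
#' 4. Remaining foreground cells form 8-connected connector components:
#'    *bridge* if the component contacts >= 2 distinct core components,
#'    *loop* if it contacts one core component through >= 2 disjoint
#'    contact zones, *branch* otherwise. A contact zone is an 8-connected
#'    run of the component's cells lying within Chebyshev distance
#'    `s + 1` of core.
#'
#' The raster border is treated as background (configurable), matching
#' the usual convention that the world outside the study area is not
#' habitat. Nodata cells act as background geometrically but are excluded
#' from all areas.
#'
#' @param binary A `binary_landscape` from [to_foreground()].
#' @param edge_width_s Edge width in cells (>= 1); 1 means a single 3x3
#'   erosion defines core.
#' @param border_is_background Treat cells beyond the raster edge as
#'   background (default `TRUE`).
#' @return An object of class `mspa_map`: fields `frame`, `classes`
#'   (integer matrix coded per [mspa_codes()]), `valid`, `edge_width_s`,
#'   `connectivity` (8).
#' @export
classify_mspa <- function(binary, edge_width_s = 1L,
                          border_is_background = TRUE) {
  s <- as.integer(edge_width_s)
  if (is.na(s) || s < 1L) stop("edge_width_s must be >= 1")
  fg <- binary$foreground
  if (length(fg) == 0L) stop("empty raster")
  nr <- nrow(fg); nc <- ncol(fg)
  codes <- mspa_codes()
  cls <- matrix(codes[["background"]], nr, nc)

  bg <- !fg  # includes nodata cells: background geometry
  # (1) core via capped distance to background
  dist_bg <- chebyshev_dist_capped(bg, cap = s,
                                   border_true = border_is_background)
  core <- fg & dist_bg > s

  # (2) foreground components; islet components have no core
  comp <- label_components(fg, connectivity = 8)
  core_comps <- unique(comp[core])
  islet <- fg & !(comp %in% core_comps)
  dim(islet) <- dim(fg)
  cls[core] <- codes[["core"]]
  cls[islet] <- codes[["islet"]]

  # background holes: 4-connected bg components not touching the border
  bgcomp <- label_components(bg, connectivity = 4)
  border_labels <- unique(c(bgcomp[1, ], bgcomp[nr, ], bgcomp[, 1],
                            bgcomp[, nc]))
  border_labels <- setdiff(border_labels, 0L)
  hole <- bgcomp > 0L & !(bgcomp %in% border_labels)
  dim(hole) <- dim(fg)
  open_bg <- bg & !hole

  # distances to hole vs open background (open includes the outside world)
  dist_hole <- chebyshev_dist_capped(hole, cap = s, border_true = FALSE)
  dist_open <- chebyshev_dist_capped(open_bg, cap = s,
                                     border_true = border_is_background)

  # (3) boundary: within s of core of the same component
  dist_core <- chebyshev_dist_capped(core, cap = s, border_true = FALSE)
  boundary <- fg & !core & !islet & dist_core <= s
  if (any(boundary)) {
    # same-component requirement: distance computed per core component
    # only matters when a cell sits within s of a *different* component's
    # core; redo restricted to its own component where ambiguous
    amb <- boundary
    rc <- which(amb)
    if (length(rc)) {
      own <- comp[rc]
      # distance to core of own component, capped
      ok <- logical(length(rc))
      for (cc in unique(own)) {
        sel <- own == cc
        core_cc <- core & comp == cc
        d_cc <- chebyshev_dist_capped(core_cc, cap = s, border_true = FALSE)
        ok[sel] <- d_cc[rc[sel]] <= s
      }
      boundary[rc] <- ok
    }
  }
  perf <- boundary & dist_hole < dist_open
  edge <- boundary & !perf
  cls[perf] <- codes[["perforation"]]
  cls[edge] <- codes[["edge"]]

  # (4) connectors
  conn <- fg & !core & !islet & !boundary
  if (any(conn)) {
    core_lab <- label_components(core, connectivity = 8)
    conn_lab <- label_components(conn, connectivity = 8)
    near_core <- chebyshev_dist_capped(core, cap = s + 1L,
                                       border_true = FALSE) <= s + 1L
    contact <- conn & near_core
    zone_lab <- label_components(contact, connectivity = 8)
    # core components within s+1 of each contact cell
    reach <- core_reach(core_lab, s + 1L)
    for (k in seq_len(max(conn_lab))) {
      cells <- which(conn_lab == k)
      zones <- setdiff(unique(zone_lab[cells]), 0L)
      cores_touched <- integer(0)
      zone_core_sets <- lapply(zones, function(z) {
        zc <- which(zone_lab == z)
        sort(unique(unlist(reach[zc])))
      })
      cores_touched <- sort(unique(unlist(zone_core_sets)))
      lab <- if (length(cores_touched) >= 2L) "bridge"
             else if (length(cores_touched) == 1L && length(zones) >= 2L) "loop"
             else "branch"
      cls[cells] <- codes[[lab]]
    }
  }

  # nodata cells stay background
  cls[!binary$valid] <- codes[["background"]]
  structure(list(frame = binary$frame, classes = cls, valid = binary$valid,
                 edge_width_s = s, connectivity = 8L,
                 note = paste("component-level connector labeling;",
                              "contact zones = 8-connected runs of",
                              "core-adjacent connector cells")),
            class = "mspa_map")
}

# For every cell, the set of core component labels within Chebyshev
# distance `d`; returned as a list indexed by cell (only cells with a
# nonempty set are populated). Done by dilating each core component.
core_reach <- function(core_lab, d) {
  n <- length(core_lab)
  reach <- vector("list", n)
  for (lab in setdiff(unique(as.vector(core_lab)), 0L)) {
    m <- core_lab == lab
    for (i in seq_len(d)) m <- dilate8(m, border = FALSE)
    idx <- which(m)
    for (i in idx) reach[[i]] <- c(reach[[i]], lab)
  }
  reach
}

#' @export
print.mspa_map <- function(x, ...) {
  cat(sprintf("<mspa_map> %d x %d, edge width %d, 8-neighbour\n",
              x$frame$n_rows, x$frame$n_cols, x$edge_width_s))
  print(mspa_areas(x))
  invisible(x)
}

#' @export
plot.mspa_map <- function(x, ...) {
  pal <- c(background = "grey90", core = "darkgreen", islet = "orange",
           edge = "black", perforation = "brown", bridge = "red",
           loop = "gold", branch = "purple")
  m <- x$classes
  graphics::image(t(m)[, nrow(m):1, drop = FALSE],
                  col = pal, zlim = c(-0.5, 7.5), axes = FALSE,
                  breaks = seq(-0.5, 7.5, by = 1), ...)
  invisible(x)
}

#' Per-class area table of an MSPA map
#'
#' @param mspa_map An `mspa_map`.
#' @param date_label Optional label attached to the table.
#' @return Data frame with one row per MSPA foreground class: `class`,
#'   `cells`, `area_km2`, `share` (fraction of total UGI area; all zero
#'   shares when the map has no foreground), plus attribute `total_km2`.
#' @export
mspa_areas <- function(mspa_map, date_label = NULL) {
  a <- cell_area_km2(mspa_map$frame)
  codes <- mspa_codes()
  v <- mspa_map$classes[mspa_map$valid]
  counts <- vapply(mspa_class_names(),
                   function(nm) sum(v == codes[[nm]]), 0L)
  area <- counts * a
  total <- sum(area)
  share <- if (total > 0) area / total else rep(0, length(area))
  out <- data.frame(class = mspa_class_names(), cells = unname(counts),
                    area_km2 = unname(area), share = unname(share),
                    stringsAsFactors = FALSE)
  attr(out, "total_km2") <- total
  attr(out, "date_label") <- date_label
  out
}

#' Extract major core patches
#'
#' Labels 8-connected core components and keeps those whose area exceeds
#' a threshold — by default 10 km^2, the conventional cut for habitat
#' patches large enough to act as stable ecological sources.
#'
#' @param mspa_map An `mspa_map`.
#' @param min_area_km2 Area threshold (> 0), strict inequality.
#' @return Data frame sorted by descending area: `id` (component label),
#'   `cells`, `area_km2`, `centroid_x`, `centroid_y`; plus attribute
#'   `labels`, the full core component label matrix for spatial use.
#' @export
major_cores <- function(mspa_map, min_area_km2 = 10) {
  if (min_area_km2 <= 0) stop("min_area_km2 must be > 0")
  a <- cell_area_km2(mspa_map$frame)
  core <- mspa_map$classes == mspa_codes()[["core"]]
  lab <- label_components(core, connectivity = 8)
  out <- data.frame(id = integer(0), cells = integer(0),
                    area_km2 = numeric(0), centroid_x = numeric(0),
                    centroid_y = numeric(0))
  if (any(core)) {
    ids <- seq_len(max(lab))
    rows <- lapply(ids, function(k) {
      idx <- which(lab == k)
      n <- length(idx)
      if (n * a <= min_area_km2) return(NULL)
      rc <- arrayInd(idx, dim(lab))
      ctr <- cell_centres(mspa_map$frame, rc[, 1], rc[, 2])
      data.frame(id = k, cells = n, area_km2 = n * a,
                 centroid_x = mean(ctr[, "x"]), centroid_y = mean(ctr[, "y"]))
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) out <- do.call(rbind, rows)
  }
  out <- out[order(-out$area_km2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "labels") <- lab
  out
}

#' Write an MSPA map as an ESRI ASCII grid
#'
#' Uses the fixed code table of [mspa_codes()].
#' @param mspa_map An `mspa_map`.
#' @param path Output path.
#' @export
write_mspa <- function(mspa_map, path) {
  write_ascii_grid(mspa_map$classes, mspa_map$frame, path,
                   nodata = -9999, integer = TRUE)
  invisible(path)
}
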