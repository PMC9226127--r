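#' Recipe for a synthetic multi-date landscape
#'
#' Bundles everything needed to generate a seeded, fully reproducible
#' multi-date land-cover series: the spatial frame, target class
#' proportions, a patch-size (contagion) control, the true class-transition
#' matrix applied between consecutive dates, and the calendar interval.
#' Stands in for a classified satellite time series when exercising the
#' pipeline.
#'
#' @param frame A [grid_frame()].
#' @param class_proportions Named numeric vector (class name -> fraction),
#'   names drawn from `legend`; must sum to 1.
#' @param contagion Patch-size control > 0: the standard deviation (in
#'   cells) of the Gaussian smoothing applied to the per-class random
#'   fields. Larger values give larger, smoother patches.
#' @param seed Integer; fully determines all generator output.
#' @param n_dates Number of dates in the series (>= 1).
#' @param true_transition Row-stochastic matrix (classes in legend order)
#'   applied between consecutive dates; default identity (no change).
#' @param interval_years Calendar years between consecutive dates.
#' @param legend Class legend, default [default_legend()].
#' @return An object of class `landscape_recipe`.
#' @export
landscape_recipe <- function(frame, class_proportions, contagion = 6,
                             seed = 1L, n_dates = 2L,
                             true_transition = NULL, interval_years = 10,
                             legend = default_legend()) {
  legend <- normalize_legend(legend)
  if (is.null(names(class_proportions)))
    stop("class_proportions must be named by class")
  bad <- setdiff(names(class_proportions), names(legend))
  if (length(bad)) stop("unknown classes in proportions: ",
                        paste(bad, collapse = ", "))
  if (any(class_proportions < 0)) stop("proportions must be >= 0")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (!is.finite(contagion) || contagion <= 0) stop("contagion must be > 0")
  k <- length(class_proportions)
  if (is.null(true_transition)) true_transition <- diag(k)
  true_transition <- as.matrix(true_transition)
  if (nrow(true_transition) != k || ncol(true_transition) != k)
    stop("true_transition must be ", k, " x ", k)
  if (any(true_transition < 0) ||
      any(abs(rowSums(true_transition) - 1) > 1e-9))
    stop("true_transition rows must be stochastic")
  dimnames(true_transition) <- list(names(class_proportions),
                                    names(class_proportions))
  structure(list(frame = frame, class_proportions = class_proportions,
                 contagion = contagion, seed = as.integer(seed),
                 n_dates = as.integer(n_dates),
                 true_transition = true_transition,
                 interval_years = interval_years,
                 legend = legend),
            class = "landscape_recipe")
}

#' Generate a spatially contagious base land-cover map
#'
#' Each class gets an independent Gaussian-smoothed noise field; a cell is
#' assigned the class whose (field + offset) is largest, with per-class
#' offsets calibrated iteratively so realized proportions track the
#' requested ones. Deterministic given the recipe seed.
#'
#' @param recipe A [landscape_recipe()].
#' @return A `land_raster` on the recipe frame.
#' @export
generate_base_map <- function(recipe) {
  fr <- recipe$frame
  if (fr$n_rows < 4 || fr$n_cols < 4) stop("frame too small (< 4x4)")
  p <- recipe$class_proportions
  if (any(p < 0)) stop("degenerate proportions")
  classes <- names(p)
  k <- length(classes)
  nr <- fr$n_rows; nc <- fr$n_cols
  set.seed(op_seed(recipe$seed, "generate_base_map"))
  fields <- lapply(seq_len(k), function(i) {
    f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                         recipe$contagion)
    (f - mean(f)) / stats::sd(f)
  })
  # calibrate additive offsets so realized argmax shares match p
  offs <- rep(0, k)
  active <- p > 0
  offs[!active] <- -Inf
  for (iter in 1:60) {
    assigned <- assign_argmax(fields, offs)
    real <- tabulate(assigned, nbins = k) / (nr * nc)
    err <- p - real
    if (max(abs(err[active])) < 0.005) break
    offs[active] <- offs[active] + 1.5 * err[active]
  }
  codes <- matrix(unname(recipe$legend[classes])[assigned], nr, nc)
  land_raster(codes, fr, recipe$legend)
}

assign_argmax <- function(fields, offs) {
  k <- length(fields)
  best <- fields[[1]] + offs[1]
  who <- matrix(1L, nrow(best), ncol(best))
  if (k > 1) for (i in 2:k) {
    fi <- fields[[i]] + offs[i]
    upd <- fi > best
    best[upd] <- fi[upd]
    who[upd] <- i
  }
  who
}

#' Evolve a base map through the recipe's transition matrix
#'
#' Produces `n_dates` rasters. Between consecutive dates each source
#' class's cells are reassigned so that the number moving to each target
#' class matches `true_transition` (largest-remainder quotas), and the
#' specific cells chosen for a target are those with the highest local
#' density of that target class (contagious growth), with a seeded jitter
#' breaking ties. Marginal transition rates therefore converge to the true
#' matrix as the grid grows while change stays spatially clustered.
#'
#' @param base `land_raster` on the recipe frame (typically from
#'   [generate_base_map()]).
#' @param recipe A [landscape_recipe()].
#' @return List of `n_dates` `land_raster`s; the first is `base`.
#' @export
evolve_series <- function(base, recipe) {
  check_frames(base, recipe$frame)
  P <- recipe$true_transition
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop("non-stochastic transition matrix")
  classes <- rownames(P)
  code_of <- unname(recipe$legend[classes])
  out <- vector("list", recipe$n_dates)
  out[[1]] <- base
  if (recipe$n_dates == 1L) return(out)
  set.seed(op_seed(recipe$seed, "evolve_series"))
  cur <- base$codes
  nr <- nrow(cur); nc <- ncol(cur)
  for (t in 2:recipe$n_dates) {
    nxt <- cur
    # local density of each class (5x5 window) for contagion scoring
    dens <- lapply(seq_along(classes), function(j)
      box_mean((cur == code_of[j]) + 0, 2L))
    for (i in seq_along(classes)) {
      cells <- which(cur == code_of[i])
      n_i <- length(cells)
      if (n_i == 0L) next
      quota <- largest_remainder(n_i * P[i, ])
      targets <- which(quota > 0 & seq_along(classes) != i)
      if (!length(targets)) next
      taken <- logical(n_i)
      for (j in targets[order(-quota[targets])]) {
        score <- dens[[j]][cells] + stats::runif(n_i) * 1e-6
        score[taken] <- -Inf
        pick <- order(score, decreasing = TRUE)[seq_len(min(quota[j],
                 sum(!taken)))]
        nxt[cells[pick]] <- code_of[j]
        taken[pick] <- TRUE
      }
    }
    out[[t]] <- land_raster(nxt, base$frame, recipe$legend,
                            nodata_code = base$nodata_code)
    cur <- nxt
  }
  out
}

# Integer apportionment of real-valued quotas preserving the total.
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  short <- round(sum(x)) - sum(fl)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

#' Generate a smooth synthetic elevation model
#'
#' Sum of an optional planar trend (high in the northwest, low in the
#' southeast by default, emulating mountain-ringed basins) and a low-pass
#' random field scaled by `relief`.
#'
#' @param frame A [grid_frame()].
#' @param relief Standard deviation (metres) of the random relief; 0 gives
#'   a constant (plus trend) surface.
#' @param seed Integer seed.
#' @param trend Length-2 numeric: elevation drop per cell along (row, col)
#'   — e.g. `c(2, 2)` falls toward the southeast. Default no trend.
#' @param sigma Smoothing bandwidth of the relief field in cells.
#' @return A `cont_raster`.
#' @export
generate_dem <- function(frame, relief = 100, seed = 1L,
                         trend = c(0, 0), sigma = 8) {
  if (relief < 0) stop("relief must be >= 0")
  nr <- frame$n_rows; nc <- frame$n_cols
  base <- outer(seq_len(nr), seq_len(nc),
                function(r, c) -trend[1] * r - trend[2] * c)
  if (relief > 0) {
    set.seed(op_seed(seed, "generate_dem"))
    f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
    f <- (f - mean(f)) / stats::sd(f) * relief
    base <- base + f
  }
  cont_raster(base - min(base), frame)
}

#' Generate a contiguous-blob binary policy mask
#'
#' Thresholds a smoothed random field at the quantile giving the requested
#' coverage, producing a few compact blobs (e.g. a synthetic ecological
#' red-line region).
#'
#' @param frame A [grid_frame()].
#' @param coverage_fraction Target fraction of cells set to 1, in \[0, 1\].
#' @param seed Integer seed.
#' @param sigma Smoothing bandwidth in cells.
#' @return A `mask_raster`.
#' @export
generate_mask <- function(frame, coverage_fraction, seed = 1L, sigma = 8) {
  if (coverage_fraction < 0 || coverage_fraction > 1)
    stop("coverage_fraction must be in [0, 1]")
  nr <- frame$n_rows; nc <- frame$n_cols
  if (coverage_fraction == 0)
    return(mask_raster(matrix(0L, nr, nc), frame))
  if (coverage_fraction == 1)
    return(mask_raster(matrix(1L, nr, nc), frame))
  set.seed(op_seed(seed, "generate_mask"))
  f <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr, nc), sigma)
  thr <- stats::quantile(f, 1 - coverage_fraction, names = FALSE)
  mask_raster(f > thr, frame)
}
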