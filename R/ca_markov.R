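#' Fit a Markov land-cover transition model from two dated maps
#'
#' Estimates the row-stochastic class-transition matrix from the
#' cross-tabulation of two observed land-cover rasters:
#' `P_ij = n_ij / sum_j n_ij`. A class absent at the first date gets an
#' identity row (flagged in `empty_rows`). The returned object is the
#' entry point to scenario prediction via [predict.ca_markov()].
#'
#' @param map_t1,map_t2 Frame-compatible `land_raster`s at the start and
#'   end of the calibration interval.
#' @param interval_years Calibration interval in calendar years.
#' @return An object of class `ca_markov` with components `transition`
#'   (the matrix), `transfer` (the [cross_tabulate()] source),
#'   `interval_years`, `legend`, `empty_rows`.
#' @examples
#' fr <- grid_frame(40, 40, 30)
#' rec <- landscape_recipe(fr, c(forest = 0.6, construction = 0.4),
#'                         contagion = 3, seed = 7,
#'                         legend = c(forest = 2, construction = 4))
#' maps <- evolve_series(generate_base_map(rec), rec)
#' fit <- ca_markov(maps[[1]], maps[[2]], interval_years = 10)
#' coef(fit)
#' @export
ca_markov <- function(map_t1, map_t2, interval_years) {
  tr <- cross_tabulate(map_t1, map_t2, interval_years)
  P <- estimate_transition(tr)
  structure(list(transition = P, transfer = tr,
                 interval_years = interval_years,
                 legend = map_t1$legend,
                 empty_rows = rownames(P)[rowSums(tr$counts) == 0]),
            class = "ca_markov")
}

#' Row-normalize a transfer table into a transition matrix
#'
#' @param transfer A `transfer_table` from [cross_tabulate()].
#' @return Row-stochastic matrix; empty rows become identity rows.
#' @export
estimate_transition <- function(transfer) {
  cts <- transfer$counts
  rs <- rowSums(cts)
  P <- cts / ifelse(rs == 0, 1, rs)
  for (i in which(rs == 0)) P[i, ] <- as.numeric(seq_len(ncol(P)) == i)
  P
}

#' @export
coef.ca_markov <- function(object, ...) object$transition

#' @export
print.ca_markov <- function(x, ...) {
  cat(sprintf("CA-Markov transition model (calibration interval %g yr)\n",
              x$interval_years))
  print(round(x$transition, 4))
  if (length(x$empty_rows))
    cat("identity rows (class absent at start):",
        paste(x$empty_rows, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ca_markov <- function(object, ...) {
  P <- object$transition
  persistence <- diag(P)
  cat(sprintf("CA-Markov transition model: %d classes, %g yr interval\n",
              nrow(P), object$interval_years))
  cat("Class persistence (diagonal):\n")
  print(round(persistence, 4))
  cat("Largest off-diagonal flows:\n")
  off <- P; diag(off) <- 0
  top <- order(off, decreasing = TRUE)[seq_len(min(5, sum(off > 0)))]
  if (length(top)) {
    rc <- arrayInd(top, dim(P))
    for (i in seq_along(top))
      cat(sprintf("  %s -> %s: %.4f\n", rownames(P)[rc[i, 1]],
                  colnames(P)[rc[i, 2]], off[top[i]]))
  }
  invisible(object)
}

#' Project class-area demand forward with the Markov chain
#'
#' Multiplies the current area row-vector by the n-step transition matrix
#' `P^n`. Total area is conserved exactly.
#'
#' @param areas_now Named numeric vector of current class areas (km^2),
#'   names matching the transition matrix classes.
#' @param transition Row-stochastic matrix.
#' @param n_periods Integer >= 1: number of calibration intervals to step.
#' @return Named numeric vector of target areas (km^2).
#' @export
project_demand <- function(areas_now, transition, n_periods = 1L) {
  n_periods <- as.integer(n_periods)
  if (is.na(n_periods) || n_periods < 1L) stop("n_periods must be >= 1")
  Pn <- diag(nrow(transition))
  for (i in seq_len(n_periods)) Pn <- Pn %*% transition
  v <- as.numeric(areas_now[rownames(transition)] %*% Pn)
  names(v) <- colnames(transition)
  v
}

#' Declare a prediction scenario
#'
#' A scenario bundles the policy constraints under which the allocator
#' runs: classes whose cells never change (`frozen_classes`, e.g.
#' construction land under economic-priority development), a protected
#' mask inside which listed classes are frozen (e.g. forest, water and
#' cultivated land inside an ecological red line), multipliers on a
#' class's outflow probabilities (e.g. boosting transfer out of unused
#' land), and terrain suitability rules as step functions over slope or
#' elevation bands.
#'
#' @param name One of `"natural"`, `"ecological_priority"`,
#'   `"economic_priority"`, `"custom"`.
#' @param frozen_classes Character vector of class names frozen globally.
#' @param protected_mask A `mask_raster` or `NULL`.
#' @param protected_classes Classes frozen inside the mask.
#' @param row_multipliers Named numeric (> 0): factor applied to the
#'   class's off-diagonal outflow before renormalization.
#' @param terrain_rules List of rules, each a list with fields
#'   `variable` (`"slope"` or `"elevation"`), `min`, `max` (band, in
#'   degrees or metres), `classes` (character) and `factor` (in \[0, 1\])
#'   multiplying suitability of those classes inside the band.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("natural", "ecological_priority",
                                   "economic_priority", "custom"),
                          frozen_classes = character(0),
                          protected_mask = NULL,
                          protected_classes = character(0),
                          row_multipliers = numeric(0),
                          terrain_rules = list()) {
  name <- match.arg(name)
  if (length(row_multipliers) && (is.null(names(row_multipliers)) ||
                                  any(row_multipliers <= 0)))
    stop("row_multipliers must be named and > 0")
  for (r in terrain_rules) {
    if (!all(c("variable", "min", "max", "classes", "factor") %in% names(r)))
      stop("terrain rule missing fields")
    if (r$factor < 0 || r$factor > 1) stop("terrain factors must be in [0,1]")
  }
  structure(list(name = name, frozen_classes = frozen_classes,
                 protected_mask = protected_mask,
                 protected_classes = protected_classes,
                 row_multipliers = row_multipliers,
                 terrain_rules = terrain_rules),
            class = "scenario_spec")
}

#' The three standard development scenarios
#'
#' Convenience constructors: under ecological priority the green classes
#' (forest, water, cultivated by default) are frozen inside the red-line
#' mask; under economic priority construction land is frozen globally and
#' outflow from unused land is boosted; natural development applies no
#' constraint.
#'
#' @param redline_mask `mask_raster` for the ecological scenario.
#' @param protected_classes Classes protected inside the red line.
#' @param unused_multiplier Outflow boost for unused land under the
#'   economic scenario.
#' @return A `scenario_spec`.
#' @export
scenario_natural <- function() scenario_spec("natural")

#' @rdname scenario_natural
#' @export
scenario_ecological <- function(redline_mask,
                                protected_classes = c("forest", "water",
                                                      "cultivated")) {
  scenario_spec("ecological_priority", protected_mask = redline_mask,
                protected_classes = protected_classes)
}

#' @rdname scenario_natural
#' @export
scenario_economic <- function(unused_multiplier = 1.5) {
  scenario_spec("economic_priority", frozen_classes = "construction",
                row_multipliers = c(unused = unused_multiplier))
}

#' Apply scenario constraints to a transition matrix
#'
#' Frozen classes get identity rows; row multipliers scale the class's
#' off-diagonal entries before the row is renormalized.
#'
#' @param transition Row-stochastic matrix with class dimnames.
#' @param scenario A [scenario_spec()].
#' @return Adjusted row-stochastic matrix.
#' @export
apply_scenario <- function(transition, scenario) {
  P <- transition
  for (cl in names(scenario$row_multipliers)) {
    if (!cl %in% rownames(P)) stop("unknown class in row_multipliers: ", cl)
    i <- which(rownames(P) == cl)
    row <- P[i, ]
    d <- row[i]
    row[-i] <- row[-i] * scenario$row_multipliers[[cl]]
    s <- d + sum(row[-i])
    if (s == 0) stop("row multiplier produced an all-zero row for ", cl)
    P[i, ] <- row / s
  }
  for (cl in scenario$frozen_classes) {
    if (!cl %in% rownames(P)) stop("unknown frozen class: ", cl)
    P[which(rownames(P) == cl), ] <-
      as.numeric(rownames(P) == cl)
  }
  P
}

#' Build the per-class suitability atlas
#'
#' Suitability of converting a cell to each class =
#' neighborhood density of the class (fraction in a `window` x `window`
#' box) x terrain factor (step functions over slope/elevation bands) x
#' protection factor (0 where the scenario forbids the class to appear),
#' clipped to \[0, 1\]. Slope is computed from the DEM by central
#' differences, in degrees.
#'
#' @param landcover A `land_raster`.
#' @param dem Optional `cont_raster`; absent means terrain factor 1.
#' @param scenario A [scenario_spec()].
#' @param window Odd window size for the neighborhood density (default 5).
#' @return Named list of `cont_raster` suitability layers, one per class,
#'   class `suitability_atlas`.
#' @export
build_suitability <- function(landcover, dem = NULL,
                              scenario = scenario_natural(), window = 5L) {
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  if (!is.null(dem)) check_frames(landcover, dem)
  if (!is.null(scenario$protected_mask))
    check_frames(landcover, scenario$protected_mask)
  for (cl in c(scenario$frozen_classes, scenario$protected_classes))
    if (!cl %in% names(landcover$legend))
      stop("scenario references class absent from legend: ", cl)
  k <- (window - 1L) %/% 2L
  slope <- if (!is.null(dem)) slope_deg(dem) else NULL
  elev <- if (!is.null(dem)) dem$values else NULL
  atlas <- lapply(names(landcover$legend), function(cl) {
    code <- landcover$legend[[cl]]
    suit <- box_mean((landcover$codes == code) + 0, k)
    for (r in scenario$terrain_rules) {
      if (!cl %in% r$classes) next
      v <- if (identical(r$variable, "slope")) slope else elev
      if (is.null(v)) next
      band <- v >= r$min & v < r$max
      suit[band] <- suit[band] * r$factor
    }
    suit[suit < 0] <- 0; suit[suit > 1] <- 1
    cont_raster(suit, landcover$frame)
  })
  names(atlas) <- names(landcover$legend)
  structure(atlas, class = "suitability_atlas")
}

# Slope in degrees from central differences on a DEM.
slope_deg <- function(dem) {
  z <- dem$values
  h <- dem$frame$cell_size
  nr <- nrow(z); nc <- ncol(z)
  dzdx <- (shift_mat(z, 0, -1, fill = NA) - shift_mat(z, 0, 1, fill = NA)) /
    (2 * h)
  dzdy <- (shift_mat(z, -1, 0, fill = NA) - shift_mat(z, 1, 0, fill = NA)) /
    (2 * h)
  # one-sided differences at borders
  dzdx[, 1] <- (z[, 2] - z[, 1]) / h
  dzdx[, nc] <- (z[, nc] - z[, nc - 1]) / h
  dzdy[1, ] <- (z[1, ] - z[2, ]) / h
  dzdy[nr, ] <- (z[nr - 1, ] - z[nr, ]) / h
  atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
}

#' Allocate projected demand spatially with the cellular automaton
#'
#' The Markov demand (class-area targets from [project_demand()]) is
#' split evenly across iterations (largest-remainder rounding). Each
#' iteration, every class with positive remaining demand claims its
#' quota: eligible donor cells (not frozen, not protected, with positive
#' transition probability from their current class, and whose current
#' class itself has surplus area) are ranked by
#' `suitability x P(current -> target)` and the top-ranked convert.
#' Deterministic given the seed, which only feeds the tie-breaking
#' jitter. Infeasible demand yields a logged shortfall, not an error.
#'
#' @param map_now Current `land_raster`.
#' @param transition Scenario-adjusted transition matrix.
#' @param suitability A `suitability_atlas` from [build_suitability()].
#' @param scenario A [scenario_spec()].
#' @param n_periods Markov steps for the demand projection.
#' @param n_iterations CA iterations (default 10).
#' @param seed Integer seed for tie-breaking.
#' @return An object of class `ca_result`: `predicted` (`land_raster`),
#'   `demand_km2`, `achieved_km2`, `shortfall_km2`, `log` (per-iteration
#'   data frame), `seed`.
#' @export
allocate_ca <- function(map_now, transition, suitability,
                        scenario = scenario_natural(), n_periods = 1L,
                        n_iterations = 10L, seed = 1L) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  classes <- rownames(transition)
  codes <- unname(map_now$legend[classes])
  a_km2 <- cell_area_km2(map_now$frame)
  valid <- map_now$codes != map_now$nodata_code
  cur <- map_now$codes

  now_cells <- vapply(codes, function(cd) sum(cur == cd & valid), 0L)
  names(now_cells) <- classes
  target_cells <- largest_remainder(
    project_demand(now_cells, transition, n_periods))
  names(target_cells) <- classes
  net <- target_cells - now_cells  # + needs growth, - has surplus

  frozen_cell <- matrix(FALSE, nrow(cur), ncol(cur))
  for (cl in scenario$frozen_classes)
    frozen_cell <- frozen_cell | cur == map_now$legend[[cl]]
  if (!is.null(scenario$protected_mask)) {
    pm <- scenario$protected_mask$bits == 1L
    for (cl in scenario$protected_classes)
      frozen_cell <- frozen_cell | (pm & cur == map_now$legend[[cl]])
  }

  set.seed(op_seed(seed, "allocate_ca"))
  jitter <- matrix(stats::runif(length(cur)) * 1e-12, nrow(cur), ncol(cur))

  class_of_code <- integer(max(codes))
  class_of_code[codes] <- seq_along(classes)

  growth <- names(net)[net > 0]
  quotas <- lapply(growth, function(cl)
    largest_remainder(rep(net[[cl]] / n_iterations, n_iterations)))
  names(quotas) <- growth

  logs <- list()
  converted_total <- stats::setNames(numeric(length(classes)), classes)
  remaining_net <- net
  for (it in seq_len(n_iterations)) {
    for (cl in growth) {
      quota <- quotas[[cl]][it]
      if (quota <= 0) next
      j <- which(classes == cl)
      # donors: valid, not frozen, not already target, P(cur->cl) > 0,
      # donor class has remaining surplus
      donor_classes <- classes[remaining_net < 0 &
                                 transition[, j][classes] > 0]
      donor_classes <- setdiff(donor_classes, cl)
      if (!length(donor_classes)) next
      elig <- valid & !frozen_cell &
        matrix(class_of_code[pmax(cur, 1L)] %in% which(classes %in%
                 donor_classes) & cur %in% codes, nrow(cur), ncol(cur))
      idx <- which(elig)
      if (!length(idx)) next
      ci <- class_of_code[cur[idx]]
      score <- suitability[[cl]]$values[idx] * transition[cbind(ci, j)] +
        jitter[idx]
      # respect per-donor-class surplus caps
      ord <- idx[order(score, decreasing = TRUE)]
      surplus <- -remaining_net[donor_classes]
      names(surplus) <- donor_classes
      take <- integer(0)
      for (cell in ord) {
        if (length(take) >= quota) break
        dcl <- classes[class_of_code[cur[cell]]]
        if (surplus[[dcl]] <= 0) next
        take <- c(take, cell)
        surplus[[dcl]] <- surplus[[dcl]] - 1
      }
      if (length(take)) {
        for (dcl in donor_classes) {
          moved <- sum(classes[class_of_code[cur[take]]] == dcl)
          remaining_net[[dcl]] <- remaining_net[[dcl]] + moved
        }
        cur[take] <- codes[j]
        remaining_net[[cl]] <- remaining_net[[cl]] - length(take)
        converted_total[[cl]] <- converted_total[[cl]] + length(take)
      }
      logs[[length(logs) + 1L]] <-
        data.frame(iteration = it, class = cl, quota = quota,
                   converted = length(take))
    }
  }
  achieved <- vapply(codes, function(cd) sum(cur == cd & valid), 0L)
  names(achieved) <- classes
  predicted <- land_raster(cur, map_now$frame, map_now$legend,
                           nodata_code = map_now$nodata_code)
  structure(list(predicted = predicted,
                 demand_km2 = target_cells * a_km2,
                 achieved_km2 = achieved * a_km2,
                 shortfall_km2 = pmax(target_cells - achieved, 0) * a_km2,
                 log = if (length(logs)) do.call(rbind, logs)
                       else data.frame(),
                 seed = seed),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat("<ca_result> CA-Markov allocation\n")
  print(data.frame(class = names(x$demand_km2),
                   demand_km2 = unname(x$demand_km2),
                   achieved_km2 = unname(x$achieved_km2),
                   shortfall_km2 = unname(x$shortfall_km2)))
  invisible(x)
}

#' Predict a future land-cover map under a scenario
#'
#' Couples the fitted Markov demand with the CA allocator: applies
#' scenario constraints to the transition matrix, builds the suitability
#' atlas, projects demand `n_periods` calibration intervals ahead
#' (`n_periods = round(horizon_years / interval_years)` when a horizon is
#' given), and allocates spatially.
#'
#' @param object A fitted [ca_markov()] model.
#' @param newdata `land_raster` to project from (e.g. the latest observed
#'   map).
#' @param scenario A [scenario_spec()]; default natural development.
#' @param dem Optional `cont_raster` DEM for terrain rules.
#' @param n_periods Markov steps; overrides `horizon_years`.
#' @param horizon_years Prediction horizon in calendar years.
#' @param n_iterations CA iterations.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A `ca_result` (see [allocate_ca()]).
#' @export
predict.ca_markov <- function(object, newdata,
                              scenario = scenario_natural(), dem = NULL,
                              n_periods = NULL, horizon_years = NULL,
                              n_iterations = 10L, seed = 1L, ...) {
  if (is.null(n_periods)) {
    if (is.null(horizon_years)) n_periods <- 1L
    else n_periods <- max(1L, as.integer(round(horizon_years /
                                                 object$interval_years)))
  }
  P <- apply_scenario(object$transition, scenario)
  atlas <- build_suitability(newdata, dem = dem, scenario = scenario)
  allocate_ca(newdata, P, atlas, scenario = scenario,
              n_periods = n_periods, n_iterations = n_iterations,
              seed = seed)
}

#' Simulate predicted maps under replicate seeds
#'
#' @param object A fitted `ca_markov` model.
#' @param nsim Number of replicates.
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param newdata,... Passed to [predict.ca_markov()].
#' @return List of `ca_result`s.
#' @export
simulate.ca_markov <- function(object, nsim = 1, seed = 1L, newdata, ...) {
  lapply(seq_len(nsim), function(r)
    predict(object, newdata = newdata, seed = seed + r - 1L, ...))
}

#' Validate a prediction against an observed map
#'
#' Cohen's kappa plus per-class producer and user agreement, with the
#' conventional verbal accuracy band: kappa in \[0.80, 1\] "very high",
#' \[0.60, 0.80) "high", below "low".
#'
#' @param predicted,actual Frame-compatible `land_raster`s.
#' @return An object of class `prediction_validation`: `kappa`, `band`,
#'   `agreement` (per-class data frame), `confusion`.
#' @export
validate_prediction <- function(predicted, actual) {
  tr <- cross_tabulate(predicted, actual, interval_years = 1)
  kap <- cohens_kappa(tr$counts)
  band <- if (kap >= 0.8) "very high" else if (kap >= 0.6) "high" else "low"
  cts <- tr$counts
  agree <- data.frame(
    class = rownames(cts),
    producer = ifelse(colSums(cts) > 0, diag(cts) / colSums(cts), NA),
    user = ifelse(rowSums(cts) > 0, diag(cts) / rowSums(cts), NA),
    row.names = NULL)
  structure(list(kappa = kap, band = band, agreement = agree,
                 confusion = cts),
            class = "prediction_validation")
}

#' @export
print.prediction_validation <- function(x, ...) {
  cat(sprintf("kappa = %.4f (prediction accuracy: %s)\n", x$kappa, x$band))
  print(x$agreement)
  invisible(x)
}
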