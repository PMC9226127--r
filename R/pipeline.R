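#' Run the full UGI analysis pipeline
#'
#' Orchestrates the framework end to end from one configuration:
#' land-cover series (read from files or generated synthetically) ->
#' MSPA per date -> per-period change rates -> CA-Markov fit and
#' multi-scenario prediction -> MSPA of each prediction -> core
#' barycenter track -> core-to-core connectivity -> report tables.
#' Fully deterministic given the config seeds; every intermediate raster
#' and table is written under `out_dir` along with a JSON manifest.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Recognised fields:
#'   \describe{
#'     \item{inputs}{named list date label -> `.asc` path; or absent when
#'       `synthetic` is given.}
#'     \item{synthetic}{list with `n_rows`, `n_cols`, `cell_size`,
#'       `proportions` (named), `contagion`, `n_dates`, `interval_years`,
#'       `transition` (row-major numeric vector or matrix, optional),
#'       `seed`.}
#'     \item{legend}{named list class -> code; default [default_legend()].}
#'     \item{foreground}{character vector of foreground classes; default
#'       cultivated/forest/grass/water.}
#'     \item{edge_width}{MSPA edge width in cells; default 1.}
#'     \item{scenarios}{character subset of `natural`,
#'       `ecological_priority`, `economic_priority`; default all three.}
#'     \item{redline_coverage}{coverage fraction of the synthetic
#'       red-line mask; default 0.3.}
#'     \item{unused_multiplier}{outflow boost for unused land under the
#'       economic scenario; default 1.5.}
#'     \item{horizon_years}{prediction horizon; default one calibration
#'       interval.}
#'     \item{major_core_km2}{major-core area threshold; default 10 (use a
#'       smaller value on small synthetic frames).}
#'     \item{resistance}{named list class -> resistance; default
#'       [default_resistance()].}
#'     \item{connectivity}{logical; run the corridor/pinch-point stage on
#'       the final observed date (default `TRUE`).}
#'     \item{seed}{top-level seed; default 1.}
#'     \item{out_dir}{output directory (created if missing).}
#'   }
#' @return An object of class `ugi_report`: list with `mspa_tables`,
#'   `rates`, `scenario_table`, `barycenter`, `connectivity`,
#'   `validation`, `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- config
  cfg$legend <- if (is.null(cfg$legend)) default_legend()
                else normalize_legend(cfg$legend)
  cfg$foreground <- cfg$foreground %||% c("cultivated", "forest", "grass",
                                          "water")
  cfg$edge_width <- cfg$edge_width %||% 1L
  cfg$scenarios <- cfg$scenarios %||% c("natural", "ecological_priority",
                                        "economic_priority")
  cfg$seed <- cfg$seed %||% 1L
  cfg$major_core_km2 <- cfg$major_core_km2 %||% 10
  cfg$unused_multiplier <- cfg$unused_multiplier %||% 1.5
  cfg$redline_coverage <- cfg$redline_coverage %||% 0.3
  cfg$connectivity <- cfg$connectivity %||% TRUE
  res_lookup <- if (is.null(cfg$resistance)) default_resistance()
                else unlist(cfg$resistance)
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  # --- stage 1: land-cover series -----------------------------------------
  stage <- "load_series"
  series <- tryCatch({
    if (!is.null(cfg$inputs)) {
      labs <- names(cfg$inputs)
      maps <- lapply(unlist(cfg$inputs), read_landcover, legend = cfg$legend)
      names(maps) <- labs
      interval <- cfg$interval_years %||% 10
      list(maps = maps, interval = interval, recipe = NULL)
    } else if (!is.null(cfg$synthetic)) {
      s <- cfg$synthetic
      fr <- grid_frame(s$n_rows, s$n_cols, s$cell_size %||% 30)
      trans <- s$transition
      k <- length(s$proportions)
      if (!is.null(trans)) trans <- matrix(unlist(trans), k, k, byrow = TRUE)
      rec <- landscape_recipe(fr, unlist(s$proportions),
                              contagion = s$contagion %||% 6,
                              seed = s$seed %||% cfg$seed,
                              n_dates = s$n_dates %||% 2L,
                              true_transition = trans,
                              interval_years = s$interval_years %||% 10,
                              legend = cfg$legend)
      maps <- evolve_series(generate_base_map(rec), rec)
      names(maps) <- paste0("date_", seq_along(maps))
      list(maps = maps, interval = rec$interval_years, recipe = rec)
    } else stop("config needs either 'inputs' or 'synthetic'")
  }, error = function(e) stop("stage ", stage, ": ", conditionMessage(e)))
  maps <- series$maps
  if (length(maps) < 2L)
    stop("stage load_series: need >= 2 dated inputs")
  interval <- series$interval
  frame <- check_frames(maps[[1]])
  landscape_km2 <- sum(maps[[1]]$codes != maps[[1]]$nodata_code) *
    cell_area_km2(frame)

  # --- stage 2: MSPA per date ---------------------------------------------
  stage <- "mspa"
  mspa_maps <- lapply(names(maps), function(lb) {
    classify_mspa(to_foreground(maps[[lb]], cfg$foreground),
                  edge_width_s = cfg$edge_width)
  })
  names(mspa_maps) <- names(maps)
  mspa_tables <- lapply(names(maps), function(lb)
    mspa_areas(mspa_maps[[lb]], date_label = lb))
  names(mspa_tables) <- names(maps)

  # --- stage 3: change rates per period -----------------------------------
  stage <- "rates"
  rate_tables <- lapply(seq_len(length(maps) - 1L), function(i)
    change_rates(mspa_maps[[i]], mspa_maps[[i + 1]], interval))
  names(rate_tables) <- paste(names(maps)[-length(maps)],
                              names(maps)[-1], sep = "_to_")

  # --- stage 4: CA-Markov prediction per scenario -------------------------
  stage <- "prediction"
  n <- length(maps)
  fit <- ca_markov(maps[[n - 1]], maps[[n]], interval_years = interval)
  dem <- generate_dem(frame, relief = 150, seed = cfg$seed, trend = c(1, 1))
  redline <- generate_mask(frame, cfg$redline_coverage, seed = cfg$seed)
  scen_objs <- lapply(cfg$scenarios, function(nm) {
    switch(nm,
           natural = scenario_natural(),
           ecological_priority = scenario_ecological(redline),
           economic_priority = scenario_economic(cfg$unused_multiplier),
           stop("unknown scenario: ", nm))
  })
  names(scen_objs) <- cfg$scenarios
  horizon <- cfg$horizon_years %||% interval
  predictions <- lapply(scen_objs, function(sc)
    predict(fit, newdata = maps[[n]], scenario = sc, dem = dem,
            horizon_years = horizon, seed = cfg$seed))

  # hold-out validation when >= 3 observed dates: refit on dates
  # (n-2, n-1) and compare the prediction of date n with the observation
  validation <- NULL
  if (n >= 3L) {
    fit_v <- ca_markov(maps[[n - 2]], maps[[n - 1]],
                       interval_years = interval)
    pred_v <- predict(fit_v, newdata = maps[[n - 1]],
                      scenario = scenario_natural(), dem = dem,
                      n_periods = 1L, seed = cfg$seed)
    validation <- validate_prediction(pred_v$predicted, maps[[n]])
  }

  # --- stage 5: MSPA of predictions + scenario table ----------------------
  stage <- "scenario_table"
  pred_mspa <- lapply(predictions, function(p)
    classify_mspa(to_foreground(p$predicted, cfg$foreground),
                  edge_width_s = cfg$edge_width))
  pred_tables <- lapply(names(pred_mspa), function(nm)
    mspa_areas(pred_mspa[[nm]], date_label = nm))
  names(pred_tables) <- names(pred_mspa)
  pred_rates <- vapply(names(pred_mspa), function(nm) {
    tr <- cross_tabulate(mspa_maps[[n]], pred_mspa[[nm]], horizon)
    comprehensive_change_rate(tr)
  }, 0)
  scen_tab <- scenario_table(pred_tables, landscape_km2, pred_rates)

  # --- stage 6: barycenter track ------------------------------------------
  stage <- "barycenter"
  track_maps <- c(mspa_maps,
                  pred_mspa[intersect("ecological_priority",
                                      names(pred_mspa))])
  bary <- tryCatch(
    migration_track(track_maps, class = "core",
                    date_labels = names(track_maps)),
    error = function(e) NULL)

  # --- stage 7: connectivity on the last observed date --------------------
  stage <- "connectivity"
  conn <- NULL
  if (isTRUE(cfg$connectivity)) {
    cores <- major_cores(mspa_maps[[n]], min_area_km2 = cfg$major_core_km2)
    if (nrow(cores) >= 2L) {
      resist <- build_resistance(maps[[n]], res_lookup)
      top2 <- cores$id[1:2]
      corridors <- least_cost_corridors(resist, cores,
                                        pairs = cbind(top2[1], top2[2]))
      lab <- attr(cores, "labels")
      current <- pinch_points(resist, lab == top2[1], lab == top2[2])
      profile <- corridor_landcover_profile(corridors$paths[[1]], maps[[n]])
      conn <- list(cores = cores, corridors = corridors, current = current,
                   profile = profile)
    }
  }

  report <- structure(
    list(mspa_tables = mspa_tables, rates = rate_tables,
         scenario_table = scen_tab, predictions = predictions,
         pred_mspa = pred_mspa, barycenter = bary, connectivity = conn,
         validation = validation, landscape_km2 = landscape_km2,
         fit = fit, config = cfg),
    class = "ugi_report")
  if (!is.null(out_dir)) write_report(report, mspa_maps, maps, out_dir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scenario summary table (per-class areas, shares and change rates)
#'
#' One row-group per scenario: the seven MSPA class areas, each class's
#' share of the scenario's UGI total, the total, the UGI share of the
#' whole landscape, and the comprehensive change rate against the last
#' observed date. Totals are exact sums of their parts.
#'
#' @param mspa_tables Named list of [mspa_areas()] tables, one per
#'   scenario.
#' @param landscape_km2 Total valid landscape area (km^2).
#' @param rates Named numeric of comprehensive change rates (percent per
#'   year), aligned with `mspa_tables`.
#' @return Data frame with columns `scenario`, `class`, `area_km2`,
#'   `share_pct`, plus per-scenario summary columns `total_km2`,
#'   `ugi_pct_of_landscape`, `comprehensive_rate_pct_yr` repeated on each
#'   row of the group.
#' @export
scenario_table <- function(mspa_tables, landscape_km2, rates) {
  if (landscape_km2 <= 0) stop("landscape area must be > 0")
  out <- lapply(names(mspa_tables), function(nm) {
    tab <- mspa_tables[[nm]]
    total <- sum(tab$area_km2)
    if (total <= 0) stop("scenario '", nm, "' has zero UGI area")
    data.frame(scenario = nm, class = tab$class, area_km2 = tab$area_km2,
               share_pct = 100 * tab$area_km2 / total,
               total_km2 = total,
               ugi_pct_of_landscape = 100 * total / landscape_km2,
               comprehensive_rate_pct_yr = unname(rates[nm]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.ugi_report <- function(x, ...) {
  cat("UGI pipeline report\n")
  cat(sprintf("  landscape area: %.4f km^2\n", x$landscape_km2))
  cat(sprintf("  dates: %s\n", paste(names(x$mspa_tables), collapse = ", ")))
  if (!is.null(x$validation))
    cat(sprintf("  hold-out kappa: %.4f (%s)\n", x$validation$kappa,
                x$validation$band))
  cat("  scenario totals (km^2):\n")
  st <- unique(x$scenario_table[, c("scenario", "total_km2",
                                    "ugi_pct_of_landscape")])
  print(st, row.names = FALSE)
  invisible(x)
}

# Write every table and raster of a pipeline run; no timestamps, so two
# runs with the same config are byte-identical.
write_report <- function(report, mspa_maps, maps, out_dir) {
  for (lb in names(maps))
    write_landcover(maps[[lb]], file.path(out_dir, paste0("lc_", lb, ".asc")))
  for (lb in names(mspa_maps))
    write_mspa(mspa_maps[[lb]], file.path(out_dir,
                                          paste0("mspa_", lb, ".asc")))
  for (nm in names(report$pred_mspa)) {
    write_landcover(report$predictions[[nm]]$predicted,
                    file.path(out_dir, paste0("pred_", nm, ".asc")))
    write_mspa(report$pred_mspa[[nm]],
               file.path(out_dir, paste0("mspa_pred_", nm, ".asc")))
  }
  for (lb in names(report$mspa_tables))
    utils::write.csv(report$mspa_tables[[lb]],
                     file.path(out_dir, paste0("areas_", lb, ".csv")),
                     row.names = FALSE)
  for (p in names(report$rates)) {
    tab <- report$rates[[p]]
    tab$comprehensive_rate_pct_yr <- attr(tab, "comprehensive")
    utils::write.csv(tab, file.path(out_dir, paste0("rates_", p, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(report$scenario_table,
                   file.path(out_dir, "scenario_table.csv"),
                   row.names = FALSE)
  if (!is.null(report$barycenter))
    utils::write.csv(report$barycenter$track,
                     file.path(out_dir, "barycenter_track.csv"),
                     row.names = FALSE)
  if (!is.null(report$connectivity)) {
    utils::write.csv(report$connectivity$cores,
                     file.path(out_dir, "major_cores.csv"),
                     row.names = FALSE)
    utils::write.csv(report$connectivity$corridors$corridors,
                     file.path(out_dir, "corridors.csv"), row.names = FALSE)
    write_continuous(report$connectivity$current$current,
                     file.path(out_dir, "current.asc"))
  }
  manifest <- list(
    seed = report$config$seed,
    edge_width = report$config$edge_width,
    scenarios = report$config$scenarios,
    landscape_km2 = report$landscape_km2,
    major_core_km2 = report$config$major_core_km2,
    validation_kappa = if (!is.null(report$validation))
      report$validation$kappa else NULL,
    resistance = as.list(report$connectivity$corridors$lookup %||%
                           default_resistance()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
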