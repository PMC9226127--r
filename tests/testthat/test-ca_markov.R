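make_series <- function(seed, nr = 120, P = NULL, n_dates = 2) {
  fr <- grid_frame(nr, nr, 30)
  p <- c(cultivated = 0.35, forest = 0.3, construction = 0.25, water = 0.1)
  if (is.null(P)) P <- diag(4)
  rec <- landscape_recipe(fr, p, contagion = 4, seed = seed,
                          n_dates = n_dates, true_transition = P,
                          interval_years = 10)
  evolve_series(generate_base_map(rec), rec)
}

test_that("transition estimation handles identity and forced moves", {
  s <- make_series(1)
  fit <- ca_markov(s[[1]], s[[2]], 10)
  expect_equal(unname(coef(fit)), diag(6), tolerance = 1e-12)

  fr <- grid_frame(3, 3, 30)
  lg <- c(cultivated = 1L, forest = 2L)
  a <- land_raster(matrix(1L, 3, 3), fr, lg)
  b <- land_raster(matrix(2L, 3, 3), fr, lg)
  P <- coef(ca_markov(a, b, 10))
  expect_equal(unname(P["cultivated", ]), c(0, 1))
  # class absent at start -> identity row, flagged
  fit2 <- ca_markov(a, b, 10)
  expect_true("forest" %in% fit2$empty_rows)
  expect_equal(unname(coef(fit2)["forest", ]), c(0, 1))
})

test_that("estimation recovers the generating matrix on synthetic pairs", {
  P4 <- matrix(c(0.85, 0.05, 0.10, 0,
                 0.02, 0.95, 0.03, 0,
                 0,    0,    1,    0,
                 0,    0.05, 0,    0.95), 4, 4, byrow = TRUE)
  cls <- c("cultivated", "forest", "construction", "water")
  errs <- sapply(1:5, function(seed) {
    s <- make_series(seed, nr = 200, P = P4)
    fit <- ca_markov(s[[1]], s[[2]], 10)
    max(abs(coef(fit)[cls, cls] - P4))
  })
  expect_lt(max(errs), 0.03)
})

test_that("demand projection is the matrix power of the chain", {
  P <- matrix(c(0.8, 0.1, 0.1,
                0.05, 0.9, 0.05,
                0, 0, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  areas <- c(a = 100, b = 50, c = 25)
  I3 <- structure(diag(3), dimnames = dimnames(P))
  expect_equal(project_demand(areas, I3, 3), areas, tolerance = 1e-12)
  two <- project_demand(areas, P, 2)
  brute <- as.numeric(matrix(areas, 1) %*% P %*% P)
  expect_equal(unname(two), brute)
  expect_equal(sum(two), sum(areas))
  # absorbing class c swallows everything as n grows
  far <- project_demand(areas, P, 200)
  expect_gt(far[["c"]], 170)
})

test_that("scenario adjustment freezes rows and rescales outflow", {
  P <- matrix(c(0.8, 0.1, 0.1,
                0.2, 0.7, 0.1,
                0.3, 0.1, 0.6), 3, 3, byrow = TRUE,
              dimnames = list(c("construction", "forest", "unused"),
                              c("construction", "forest", "unused")))
  expect_equal(apply_scenario(P, scenario_natural()), P)

  eco <- apply_scenario(P, scenario_spec("custom",
                                         frozen_classes = "construction"))
  expect_equal(unname(eco["construction", ]), c(1, 0, 0))

  # unused-land multiplier 1.5 on row [0.8, 0.1, 0.1] (diagonal first)
  Pu <- matrix(c(0.8, 0.1, 0.1,
                 0, 1, 0,
                 0.1, 0.1, 0.8), 3, 3, byrow = TRUE,
               dimnames = dimnames(P))
  Pu2 <- rbind(c(0.8, 0.15, 0.15) / 1.1, Pu[2:3, ])
  dimnames(Pu2) <- dimnames(Pu)
  got <- apply_scenario(Pu, scenario_spec("custom",
                          row_multipliers = c(construction = 1.5)))
  expect_equal(got, Pu2, tolerance = 1e-12)
  expect_equal(unname(got["construction", ]),
               c(0.727, 0.136, 0.136), tolerance = 5e-3)
  expect_error(apply_scenario(P, scenario_spec("custom",
                 row_multipliers = c(swamp = 2))), "swamp")
})

test_that("suitability atlas reflects neighborhood density", {
  fr <- grid_frame(10, 10, 30)
  lg <- c(cultivated = 1L, forest = 2L)
  uni <- land_raster(matrix(2L, 10, 10), fr, lg)
  atlas <- build_suitability(uni)
  expect_true(all(atlas$forest$values[3:8, 3:8] == 1))
  expect_true(all(atlas$cultivated$values == 0))

  chk <- matrix(rep_len(c(1L, 2L), 100), 10, 10)
  atlas2 <- build_suitability(land_raster(chk, fr, lg))
  expect_equal(atlas2$forest$values[5, 5], 0.5, tolerance = 0.21)
  expect_equal(atlas2$cultivated$values[5, 5] +
                 atlas2$forest$values[5, 5], 1)
  # window-count oracle at an interior cell
  win <- chk[3:7, 3:7]
  expect_equal(atlas2$forest$values[5, 5], mean(win == 2L))
})

test_that("terrain rules damp suitability inside the stated band", {
  fr <- grid_frame(12, 12, 30)
  lg <- c(cultivated = 1L, forest = 2L)
  lc <- land_raster(matrix(2L, 12, 12), fr, lg)
  dem <- generate_dem(fr, relief = 0, seed = 1, trend = c(0, 10))
  rule <- list(variable = "elevation", min = -Inf, max = 60,
               classes = "forest", factor = 0.25)
  sc <- scenario_spec("custom", terrain_rules = list(rule))
  atlas <- build_suitability(lc, dem = dem, scenario = sc)
  low <- dem$values < 60
  inner <- matrix(FALSE, 12, 12); inner[3:10, 3:10] <- TRUE
  expect_true(all(atlas$forest$values[low & inner] == 0.25))
  expect_true(all(atlas$forest$values[!low & inner] == 1))
})

test_that("identity transition allocates nothing", {
  s <- make_series(3, nr = 60)
  fit <- ca_markov(s[[1]], s[[2]], 10)
  pr <- predict(fit, newdata = s[[2]], seed = 5)
  expect_identical(pr$predicted$codes, s[[2]]$codes)
  expect_equal(sum(pr$shortfall_km2), 0)
})

test_that("allocation meets demand, picks top-scoring cells, conserves
           area and is deterministic", {
  fr <- grid_frame(100, 100, 30)
  lg <- c(forest = 2L, construction = 4L)
  set.seed(77)
  codes <- matrix(ifelse(runif(1e4) < 0.6, 2L, 4L), 100, 100)
  lc <- land_raster(codes, fr, lg)
  P <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(names(lg), names(lg)))
  atlas <- build_suitability(lc)
  r1 <- allocate_ca(lc, P, atlas, n_iterations = 10, seed = 1)
  r2 <- allocate_ca(lc, P, atlas, n_iterations = 10, seed = 1)
  expect_identical(r1$predicted$codes, r2$predicted$codes)

  a <- cell_area_km2(fr)
  # demand tracking within one cell-area per class
  expect_true(all(abs(r1$achieved_km2 - r1$demand_km2) <= a + 1e-12))
  # area conservation
  expect_equal(sum(table(r1$predicted$codes)), 1e4)
  expect_equal(sum(r1$achieved_km2), 1e4 * a)
  # converted cells are forest cells with top construction suitability
  conv <- which(codes == 2L & r1$predicted$codes == 4L)
  keep <- which(codes == 2L & r1$predicted$codes == 2L)
  if (length(conv) && length(keep)) {
    expect_gt(mean(atlas$construction$values[conv]),
              mean(atlas$construction$values[keep]))
  }
})

test_that("protected cells never convert", {
  fr <- grid_frame(40, 40, 30)
  lg <- c(forest = 2L, construction = 4L)
  set.seed(5)
  codes <- matrix(ifelse(runif(1600) < 0.7, 2L, 4L), 40, 40)
  lc <- land_raster(codes, fr, lg)
  mask <- mask_raster(matrix(c(rep(1L, 800), rep(0L, 800)), 40, 40), fr)
  sc <- scenario_spec("ecological_priority", protected_mask = mask,
                      protected_classes = "forest")
  P <- matrix(c(0.5, 0.5, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(names(lg), names(lg)))
  atlas <- build_suitability(lc, scenario = sc)
  r <- allocate_ca(lc, P, atlas, scenario = sc, seed = 2)
  inside_forest <- mask$bits == 1L & codes == 2L
  expect_true(all(r$predicted$codes[inside_forest] == 2L))
  # shortfall is logged, not thrown
  expect_true(sum(r$shortfall_km2) >= 0)
})

test_that("hold-out prediction of a synthetic third date scores high
           kappa", {
  P4 <- matrix(c(0.90, 0.02, 0.08, 0,
                 0.01, 0.97, 0.02, 0,
                 0,    0,    1,    0,
                 0,    0.02, 0.03, 0.95), 4, 4, byrow = TRUE)
  s <- make_series(11, nr = 120, P = P4, n_dates = 3)
  fit <- ca_markov(s[[1]], s[[2]], 10)
  pr <- predict(fit, newdata = s[[2]], n_periods = 1, seed = 3)
  v <- validate_prediction(pr$predicted, s[[3]])
  expect_gte(v$kappa, 0.6)
  expect_true(v$band %in% c("high", "very high"))
})

test_that("validation bands follow the conventional kappa ranges", {
  s <- make_series(2, nr = 40)
  v <- validate_prediction(s[[1]], s[[2]])  # identity series
  expect_equal(v$kappa, 1)
  expect_equal(v$band, "very high")

  # synthetic confusion pinned near kappa 0.70 -> "high"
  fr <- grid_frame(20, 20, 30)
  lg <- c(cultivated = 1L, forest = 2L)
  a <- matrix(rep(c(1L, 2L), each = 200), 20, 20)
  b <- a
  flip <- c(which(a == 1L)[1:30], which(a == 2L)[1:30])
  b[flip] <- 3L - b[flip]
  v2 <- validate_prediction(land_raster(a, fr, lg),
                            land_raster(b, fr, lg))
  expect_equal(v2$kappa, 0.7, tolerance = 1e-12)
  expect_equal(v2$band, "high")
})
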