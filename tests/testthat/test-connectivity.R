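
test_that("resistance lookup maps every class and rejects gaps", {
  r <- random_landcover(10, 10, seed = 2, k = 6)
  rs <- build_resistance(r)
  lk <- default_resistance()
  for (cl in names(test_legend)) {
    cells <- r$codes == test_legend[[cl]]
    expect_true(all(rs$values[cells] == lk[[cl]]))
  }
  expect_error(build_resistance(r, c(forest = 1)), "cultivated")
  expect_error(build_resistance(r, replace(lk, 1, -1)), "> 0")
  uni <- land_raster(matrix(2L, 4, 4), grid_frame(4, 4, 30), test_legend)
  expect_true(all(build_resistance(uni)$values == 1))
})

test_that("least-cost path is the straight line on uniform resistance", {
  R <- matrix(1, 5, 15)
  cores <- matrix(0L, 5, 15)
  cores[3, 2] <- 1L; cores[3, 13] <- 2L
  cs <- least_cost_corridors(res_surface(R), cores,
                             pairs = cbind(1L, 2L))
  expect_equal(cs$corridors$cost, 11)  # 11 unit steps between the cells
  expect_true(cs$corridors$reachable)
  expect_true(all(cs$paths[[1]][, "row"] == 3))
})

test_that("a high-resistance wall forces the path through the gap", {
  R <- matrix(1, 7, 9)
  R[, 5] <- 1e6
  R[4, 5] <- 1    # the gap
  cores <- matrix(0L, 7, 9)
  cores[2, 2] <- 1L; cores[6, 8] <- 2L
  cs <- least_cost_corridors(res_surface(R), cores, pairs = cbind(1L, 2L))
  path <- cs$paths[[1]]
  crossing <- path[path[, "col"] == 5, , drop = FALSE]
  expect_equal(unname(crossing[, "row"]), 4)
  expect_lt(cs$corridors$cost, 20)
})

test_that("impassable barriers are reported as disconnected", {
  R <- matrix(1, 5, 5)
  R[, 3] <- NA
  cores <- matrix(0L, 5, 5); cores[3, 1] <- 1L; cores[3, 5] <- 2L
  cs <- least_cost_corridors(res_surface(R), cores, pairs = cbind(1L, 2L))
  expect_false(cs$corridors$reachable)
  expect_equal(cs$corridors$cost, Inf)
})

test_that("least-cost cost matches exhaustive path enumeration", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- 4
    R <- matrix(exp(rnorm(n * n, 0, 1)), n, n)
    cores <- matrix(0L, n, n); cores[1, 1] <- 1L; cores[n, n] <- 2L
    cs <- least_cost_corridors(res_surface(R), cores,
                               pairs = cbind(1L, 2L))
    want <- bf_least_cost(R, c(1, 1), c(n, n))
    expect_equal(cs$corridors$cost, want, tolerance = 1e-10,
                 label = sprintf("seed %d", seed))
  }
  for (seed in 1:5) {
    set.seed(seed + 900)
    R <- matrix(exp(rnorm(25, 0, 1)), 5, 5)
    cores <- matrix(0L, 5, 5); cores[1, 1] <- 1L; cores[5, 5] <- 2L
    cs <- least_cost_corridors(res_surface(R), cores,
                               pairs = cbind(1L, 2L))
    expect_equal(cs$corridors$cost, bf_least_cost(R, c(1, 1), c(5, 5)),
                 tolerance = 1e-10)
  }
})

test_that("series strip gives the series resistance and unit currents", {
  R <- matrix(1, 1, 5)
  a <- matrix(FALSE, 1, 5); a[1, 1] <- TRUE
  b <- matrix(FALSE, 1, 5); b[1, 5] <- TRUE
  cm <- pinch_points(res_surface(R), a, b)
  expect_equal(cm$effective_resistance, 4, tolerance = 1e-10)
  # interior cells each carry the full unit current
  expect_equal(unname(cm$current$values[1, 2:4]), rep(1, 3),
               tolerance = 1e-10)
})

test_that("current splits evenly over two identical parallel corridors", {
  R <- matrix(NA_real_, 3, 5)
  R[1, ] <- 1; R[3, ] <- 1; R[1:3, 1] <- 1; R[1:3, 5] <- 1
  a <- matrix(FALSE, 3, 5); a[, 1] <- TRUE
  b <- matrix(FALSE, 3, 5); b[, 5] <- TRUE
  cm <- pinch_points(res_surface(R), a, b)
  expect_equal(cm$current$values[1, 3], cm$current$values[3, 3],
               tolerance = 1e-10)
  expect_equal(unname(cm$current$values[1, 3]), 0.5, tolerance = 1e-10)
})

test_that("effective resistance matches a dense Laplacian solve", {
  for (seed in 1:12) {
    set.seed(seed)
    R <- matrix(exp(rnorm(36, 0, 0.8)), 6, 6)
    a <- matrix(FALSE, 6, 6); a[1, 1] <- TRUE
    b <- matrix(FALSE, 6, 6); b[6, 6] <- TRUE
    cm <- pinch_points(res_surface(R), a, b)
    want <- bf_effective_resistance(R, 1L, 36L)
    expect_equal(cm$effective_resistance, want, tolerance = 1e-8,
                 label = sprintf("seed %d", seed))
  }
})

test_that("Kirchhoff: interior node currents balance and terminals carry
           the injected current", {
  set.seed(4)
  R <- matrix(exp(rnorm(64, 0, 0.5)), 8, 8)
  a <- matrix(FALSE, 8, 8); a[, 1] <- TRUE
  b <- matrix(FALSE, 8, 8); b[, 8] <- TRUE
  cm <- pinch_points(res_surface(R), a, b)
  # source and ground supernodes each carry current 1 (injection)
  expect_equal(unname(cm$current$values[1, 1]), 1, tolerance = 1e-8)
  expect_equal(unname(cm$current$values[1, 8]), 1, tolerance = 1e-8)
  expect_gt(cm$effective_resistance, 0)
})

test_that("raising a cell's resistance never lowers effective
           resistance (Rayleigh)", {
  for (seed in 1:8) {
    set.seed(seed + 300)
    R <- matrix(exp(rnorm(25, 0, 0.5)), 5, 5)
    a <- matrix(FALSE, 5, 5); a[, 1] <- TRUE
    b <- matrix(FALSE, 5, 5); b[, 5] <- TRUE
    r0 <- pinch_points(res_surface(R), a, b)$effective_resistance
    R2 <- R
    cell <- sample(which(!(col(R) %in% c(1, 5))), 1)
    R2[cell] <- R2[cell] * 5
    r1 <- pinch_points(res_surface(R2), a, b)$effective_resistance
    expect_gte(r1, r0 - 1e-10)
  }
})

test_that("disconnected terminals give infinite effective resistance", {
  R <- matrix(1, 3, 5)
  R[, 3] <- NA
  a <- matrix(FALSE, 3, 5); a[2, 1] <- TRUE
  b <- matrix(FALSE, 3, 5); b[2, 5] <- TRUE
  cm <- pinch_points(res_surface(R), a, b)
  expect_equal(cm$effective_resistance, Inf)
  expect_true(all(cm$current$values[is.finite(cm$current$values)] == 0))
})

test_that("pinch point sits on the corridor bottleneck", {
  # wide habitat narrowing to a single-cell neck in the middle
  R <- matrix(1e4, 7, 11)
  R[2:6, 1:4] <- 1; R[2:6, 8:11] <- 1; R[4, 5:7] <- 1
  a <- matrix(FALSE, 7, 11); a[2:6, 1] <- TRUE
  b <- matrix(FALSE, 7, 11); b[2:6, 11] <- TRUE
  cm <- pinch_points(res_surface(R), a, b)
  cur <- cm$current$values
  interior <- cur[, 2:10]
  expect_true(which.max(apply(interior, 2, max)) %in% 4:6)
  expect_gt(cur[4, 6], 0.9)
})

test_that("corridor land-cover profile tallies the path cells", {
  lc <- random_landcover(10, 10, seed = 3, k = 6)
  path <- cbind(row = rep(5, 10), col = 1:10)
  prof <- corridor_landcover_profile(path, lc)
  expect_equal(sum(prof$cells), 10)
  expect_equal(sum(prof$fraction), 1)
  for (i in seq_len(nrow(prof))) {
    code <- test_legend[[prof$class[i]]]
    expect_equal(prof$cells[i], sum(lc$codes[path] == code))
  }
  # all-water path
  wat <- land_raster(matrix(5L, 3, 12), grid_frame(3, 12, 30), test_legend)
  pw <- corridor_landcover_profile(cbind(row = rep(2, 12), col = 1:12), wat)
  expect_equal(attr(pw, "dominant"), "water")
  expect_equal(pw$fraction[1], 1)
  # 6 cultivated + 4 forest
  mix <- land_raster(matrix(c(rep(1L, 6), rep(2L, 4)), 1, 10),
                     grid_frame(1, 10, 30), test_legend)
  pm <- corridor_landcover_profile(cbind(row = rep(1, 10), col = 1:10), mix)
  expect_equal(attr(pm, "dominant"), "cultivated")
  expect_equal(pm$fraction[1], 0.6)
})
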