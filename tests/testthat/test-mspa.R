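test_that("foreground reclassification follows the legend", {
  r <- random_landcover(10, 10, seed = 31, k = 6)
  b <- to_foreground(r)
  ugi_codes <- c(1L, 2L, 3L, 5L)
  expect_equal(sum(b$foreground), sum(r$codes %in% ugi_codes))

  allcon <- land_raster(matrix(4L, 5, 5), grid_frame(5, 5, 30), test_legend)
  expect_equal(sum(to_foreground(allcon)$foreground), 0)
  allfor <- land_raster(matrix(2L, 5, 5), grid_frame(5, 5, 30), test_legend)
  expect_equal(sum(to_foreground(allfor)$foreground), 25)
  expect_error(to_foreground(r, c("forest", "swamp")), "swamp")
})

test_that("canonical MSPA configurations classify as expected", {
  # single isolated cell: no core possible -> islet
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  cl <- classify_mspa(binary_from_matrix(m), 1)
  expect_equal(mspa_names(cl)[3, 3], "islet")

  # solid 9x9 square in a sea: 7x7 core, 32-cell edge ring
  sq <- classify_mspa(square_in_sea(15, 9), 1)
  nm <- mspa_names(sq)
  expect_equal(sum(nm == "core"), 49)
  expect_equal(sum(nm == "edge"), 32)
  expect_equal(sum(!nm %in% c("core", "edge", "background")), 0)

  # two 5x5 squares joined by a 1-wide 3-cell corridor -> bridge
  m <- matrix(0L, 9, 15)
  m[3:7, 2:6] <- 1L; m[3:7, 10:14] <- 1L; m[5, 7:9] <- 1L
  nm <- mspa_names(classify_mspa(binary_from_matrix(m), 1))
  expect_true(all(nm[5, 7:9] == "bridge"))
  expect_equal(sum(nm == "core"), 18)

  # 11x11 square with one interior hole: perforation ring inside,
  # edge ring outside
  m <- matrix(0L, 13, 13)
  m[2:12, 2:12] <- 1L; m[7, 7] <- 0L
  nm <- mspa_names(classify_mspa(binary_from_matrix(m), 1))
  expect_true(all(nm[6:8, 6:8][-5] == "perforation"))
  expect_true(all(nm[2, 2:12] == "edge"))
})

test_that("classification matches the brute-force oracle on random maps", {
  for (seed in 1:60) {
    set.seed(seed)
    nr <- sample(4:15, 1); nc <- sample(4:15, 1)
    fg <- matrix(rbinom(nr * nc, 1, runif(1, 0.3, 0.8)), nr, nc)
    got <- mspa_names(classify_mspa(binary_from_matrix(fg), 1))
    want <- mspa_oracle(fg, 1)
    expect_identical(got, want,
                     label = sprintf("seed %d (%dx%d)", seed, nr, nc))
  }
})

test_that("oracle agreement holds for wider edge widths", {
  for (seed in 1:15) {
    set.seed(seed + 500)
    fg <- matrix(rbinom(15 * 15, 1, 0.7), 15, 15)
    for (s in 2:3) {
      got <- mspa_names(classify_mspa(binary_from_matrix(fg), s))
      want <- mspa_oracle(fg, s)
      expect_identical(got, want, label = sprintf("seed %d s=%d", seed, s))
    }
  }
})

test_that("every foreground cell gets exactly one MSPA class", {
  for (seed in c(3, 14, 27)) {
    b <- random_binary(20, 20, seed)
    cl <- classify_mspa(b, 1)
    nm <- mspa_names(cl)
    expect_true(all(nm[b$foreground] != "background"))
    expect_true(all(nm[!b$foreground] == "background"))
  }
})

test_that("core shrinks monotonically with edge width", {
  for (seed in c(8, 21)) {
    b <- random_binary(25, 25, seed, p_fg = 0.75)
    prev <- NULL
    for (s in 1:3) {
      core <- classify_mspa(b, s)$classes == mspa_codes()[["core"]]
      if (!is.null(prev)) expect_true(all(!(core & !prev)))
      prev <- core
    }
  }
})

test_that("translation into a larger empty canvas preserves class areas", {
  b <- random_binary(12, 12, seed = 4, p_fg = 0.7)
  big <- matrix(0L, 30, 30)
  big[10 + seq_len(12), 6 + seq_len(12)] <- b$foreground + 0L
  t1 <- mspa_areas(classify_mspa(b, 1))
  t2 <- mspa_areas(classify_mspa(binary_from_matrix(big), 1))
  expect_equal(t1$area_km2, t2$area_km2)
})

test_that("area tables are internally consistent", {
  b <- random_binary(18, 18, seed = 6)
  tab <- mspa_areas(classify_mspa(b, 1))
  expect_equal(sum(tab$area_km2), attr(tab, "total_km2"))
  expect_equal(sum(tab$share), 1, tolerance = 1e-9)
  expect_equal(tab$area_km2, tab$cells * 9e-4)

  empty <- classify_mspa(binary_from_matrix(rbind(c(0, 0), c(0, 1))), 1)
  emptier <- mspa_areas(empty)
  expect_equal(sum(emptier$area_km2), 9e-4)  # one islet cell
})

test_that("major cores respect the strict area threshold and ordering", {
  # rectangular blocks with known core sizes: an a x a block erodes to
  # an (a-2)^2-cell core at s = 1; cell area 9e-4 km^2
  m1 <- matrix(0L, 300, 300)
  put <- function(m, r, c, a, b) { m[r:(r + a - 1), c:(c + b - 1)] <- 1L; m }
  # target core areas 15, 12, 8 km^2 -> core cells 16667, 13334, 8889
  m1 <- put(m1, 2, 2, 131, 131)      # core 129^2 = 16641 -> 14.98 km^2
  m1 <- put(m1, 2, 150, 118, 118)    # core 116^2 = 13456 -> 12.11 km^2
  m1 <- put(m1, 160, 2, 96, 96)      # core 94^2  =  8836 ->  7.95 km^2
  cl <- classify_mspa(binary_from_matrix(m1), 1)
  mc <- major_cores(cl, min_area_km2 = 10)
  expect_equal(nrow(mc), 2)
  expect_equal(mc$area_km2, c(16641, 13456) * 9e-4)
  expect_true(all(diff(mc$area_km2) <= 0))

  # threshold arithmetic: a 49-cell core is far below 10 km^2
  sq <- classify_mspa(square_in_sea(15, 9), 1)
  expect_equal(nrow(major_cores(sq, 10)), 0)
  expect_equal(nrow(major_cores(sq, 0.01)), 1)

  none <- classify_mspa(binary_from_matrix(matrix(0L, 5, 5) + diag(5L)), 1)
  expect_equal(nrow(major_cores(none, 10)), 0)
})

test_that("nodata cells act as background but are excluded from areas", {
  r <- random_landcover(12, 12, seed = 40, k = 6, p_nodata = 0.15)
  b <- to_foreground(r)
  cl <- classify_mspa(b, 1)
  nm <- mspa_names(cl)
  expect_true(all(nm[!b$valid] == "background"))
  tab <- mspa_areas(cl)
  expect_equal(sum(tab$cells), sum(b$foreground))
})
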