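# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

test_legend <- c(cultivated = 1L, forest = 2L, grass = 3L,
                 construction = 4L, water = 5L, unused = 6L)

# Random land-cover raster with optional nodata holes.
random_landcover <- function(nr, nc, seed, k = 4, p_nodata = 0,
                             cell_size = 30) {
  set.seed(seed)
  fr <- grid_frame(nr, nc, cell_size)
  codes <- matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
  if (p_nodata > 0) {
    nd <- runif(nr * nc) < p_nodata
    codes[nd] <- -9999L
  }
  land_raster(codes, fr, test_legend[seq_len(k)])
}

# Random binary landscape on a clean frame.
random_binary <- function(nr, nc, seed, p_fg = 0.55) {
  set.seed(seed)
  fr <- grid_frame(nr, nc, 30)
  fg <- matrix(runif(nr * nc) < p_fg, nr, nc)
  structure(list(frame = fr, foreground = fg,
                 valid = matrix(TRUE, nr, nc), provenance = integer(0)),
            class = "binary_landscape")
}

# Binary landscape from an explicit 0/1 matrix.
binary_from_matrix <- function(m) {
  m <- as.matrix(m)
  fr <- grid_frame(nrow(m), ncol(m), 30)
  structure(list(frame = fr, foreground = m == 1,
                 valid = matrix(TRUE, nrow(m), ncol(m)),
                 provenance = integer(0)),
            class = "binary_landscape")
}

# Solid foreground square in a background sea.
square_in_sea <- function(n_sea, n_sq, offset = NULL) {
  m <- matrix(0L, n_sea, n_sea)
  if (is.null(offset)) offset <- (n_sea - n_sq) %/% 2
  m[offset + seq_len(n_sq), offset + seq_len(n_sq)] <- 1L
  binary_from_matrix(m)
}

# Pipeline run configuration used by pipeline and acceptance tests.
base_config <- function(out_dir = NULL, n_dates = 2, seed = 1,
                        nr = 50, scenarios = NULL) {
  P <- diag(6)
  P[1, ] <- c(0.90, 0.03, 0, 0.07, 0, 0)   # cultivated -> forest/constr
  P[3, ] <- c(0, 0.05, 0.90, 0.05, 0, 0)   # grass
  P[4, ] <- c(0.02, 0.03, 0, 0.95, 0, 0)   # construction reverts to green
  P[6, ] <- c(0, 0.05, 0, 0.10, 0, 0.85)   # unused -> construction
  cfg <- list(
    synthetic = list(
      n_rows = nr, n_cols = nr, cell_size = 30,
      proportions = list(cultivated = 0.25, forest = 0.30, grass = 0.10,
                         construction = 0.20, water = 0.10, unused = 0.05),
      contagion = 4, n_dates = n_dates, interval_years = 10,
      transition = as.list(as.data.frame(t(P))), seed = seed),
    major_core_km2 = 0.05,
    seed = seed, out_dir = out_dir)
  if (!is.null(scenarios)) cfg$scenarios <- scenarios
  cfg
}

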