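# Independent brute-force MSPA oracle. Implements the classification
# rules literally with per-cell scans and hand-rolled flood fills; shares
# no code with the package implementation.

# Chebyshev distance from cell (r, c) to the nearest cell of `cells`
# (two-column matrix of row/col); Inf when empty.
.bf_dist <- function(r, c, cells) {
  if (nrow(cells) == 0L) return(Inf)
  min(pmax(abs(cells[, 1] - r), abs(cells[, 2] - c)))
}

# Chebyshev distance to the world outside the grid.
.bf_dist_outside <- function(r, c, nr, nc) min(r, nr + 1 - r, c, nc + 1 - c)

# Flood-fill labeling of TRUE cells; conn 8 or 4.
.bf_label <- function(mask, conn = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (conn == 8) expand.grid(dr = -1:1, dc = -1:1)
         else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  nbr <- nbr[!(nbr$dr == 0 & nbr$dc == 0), ]
  k <- 0L
  for (idx in which(mask)) {
    if (lab[idx] != 0L) next
    k <- k + 1L
    queue <- idx
    lab[idx] <- k
    while (length(queue)) {
      cell <- queue[1]; queue <- queue[-1]
      r <- (cell - 1L) %% nr + 1L; c <- (cell - 1L) %/% nr + 1L
      for (j in seq_len(nrow(nbr))) {
        r2 <- r + nbr$dr[j]; c2 <- c + nbr$dc[j]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- k
          queue <- c(queue, (c2 - 1L) * nr + r2)
        }
      }
    }
  }
  lab
}

# Full brute-force MSPA classification of a 0/1 matrix. Returns a matrix
# of class names. Border is background.
mspa_oracle <- function(fg, s = 1) {
  fg <- as.matrix(fg) == 1
  nr <- nrow(fg); nc <- ncol(fg)
  bg_cells <- which(!fg, arr.ind = TRUE)
  out <- matrix("background", nr, nc)
  fgc <- which(fg, arr.ind = TRUE)
  if (nrow(fgc) == 0L) return(out)

  # core: distance to background (incl. outside) > s
  dist_bg <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(fgc))) {
    r <- fgc[i, 1]; c <- fgc[i, 2]
    dist_bg[r, c] <- min(.bf_dist(r, c, bg_cells),
                         .bf_dist_outside(r, c, nr, nc))
  }
  core <- fg & dist_bg > s

  comp <- .bf_label(fg, 8)
  core_comps <- unique(comp[core])
  for (i in seq_len(nrow(fgc))) {
    r <- fgc[i, 1]; c <- fgc[i, 2]
    if (core[r, c]) out[r, c] <- "core"
    else if (!(comp[r, c] %in% core_comps)) out[r, c] <- "islet"
  }

  # holes: 4-connected background components not touching the border
  bglab <- .bf_label(!fg, 4)
  border_labs <- setdiff(unique(c(bglab[1, ], bglab[nr, ], bglab[, 1],
                                  bglab[, nc])), 0L)
  hole_cells <- which(bglab > 0 &
                        !matrix(bglab %in% border_labs, nr, nc),
                      arr.ind = TRUE)
  open_cells <- which(!fg & matrix(bglab %in% border_labs, nr, nc),
                      arr.ind = TRUE)

  # boundary: within s of own-component core; perforation if the nearest
  # background is a hole (strictly closer than open background/outside)
  core_by_comp <- list()
  for (cc in core_comps)
    core_by_comp[[as.character(cc)]] <- which(core & comp == cc,
                                              arr.ind = TRUE)
  for (i in seq_len(nrow(fgc))) {
    r <- fgc[i, 1]; c <- fgc[i, 2]
    if (out[r, c] != "background") next
    own_core <- core_by_comp[[as.character(comp[r, c])]]
    if (is.null(own_core) || .bf_dist(r, c, own_core) > s) next
    d_hole <- .bf_dist(r, c, hole_cells)
    d_open <- min(.bf_dist(r, c, open_cells),
                  .bf_dist_outside(r, c, nr, nc))
    out[r, c] <- if (d_hole < d_open) "perforation" else "edge"
  }

  # connectors
  conn <- fg & out == "background"
  if (any(conn)) {
    core_lab <- .bf_label(core, 8)
    conn_lab <- .bf_label(conn, 8)
    all_core <- which(core, arr.ind = TRUE)
    # contact cells: connector cells within s + 1 of core
    contact <- matrix(FALSE, nr, nc)
    reach <- vector("list", nr * nc)
    for (idx in which(conn)) {
      r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
      if (nrow(all_core) && .bf_dist(r, c, all_core) <= s + 1) {
        contact[r, c] <- TRUE
        labs <- integer(0)
        for (cl in setdiff(unique(as.vector(core_lab)), 0L)) {
          cc <- which(core_lab == cl, arr.ind = TRUE)
          if (.bf_dist(r, c, cc) <= s + 1) labs <- c(labs, cl)
        }
        reach[[idx]] <- labs
      }
    }
    zone_lab <- .bf_label(contact, 8)
    for (k in setdiff(unique(as.vector(conn_lab)), 0L)) {
      cells <- which(conn_lab == k)
      zones <- setdiff(unique(zone_lab[cells]), 0L)
      cores_touched <- sort(unique(unlist(reach[cells])))
      lab <- if (length(cores_touched) >= 2) "bridge"
             else if (length(cores_touched) == 1 && length(zones) >= 2) "loop"
             else "branch"
      out[cells] <- lab
    }
  }
  out
}

# Convert an mspa_map's integer codes to the oracle's name matrix.
mspa_names <- function(mspa_map) {
  codes <- mspa_codes()
  matrix(names(codes)[match(mspa_map$classes, codes)],
         nrow(mspa_map$classes), ncol(mspa_map$classes))
}

# -- connectivity oracles ---------------------------------------------------

# Exact least-cost by depth-first enumeration of simple paths with
# cost pruning (admissible: all edge costs positive).
bf_least_cost <- function(R, start, goal) {
  nr <- nrow(R); nc <- ncol(R)
  best <- Inf
  visit <- matrix(FALSE, nr, nc)
  step <- function(r, c, cost) {
    if (cost >= best) return()
    if (r == goal[1] && c == goal[2]) { best <<- cost; return() }
    visit[r, c] <<- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (visit[r2, c2] || !is.finite(R[r2, c2])) next
      d <- if (dr != 0 && dc != 0) sqrt(2) else 1
      step(r2, c2, cost + (R[r, c] + R[r2, c2]) / 2 * d)
    }
    visit[r, c] <<- FALSE
  }
  step(start[1], start[2], 0)
  best
}

# Dense Laplacian solve of the same circuit definition, built with plain
# loops and base solve(); terminals are single cells here.
bf_effective_resistance <- function(R, a_idx, b_idx) {
  nr <- nrow(R); nc <- ncol(R)
  ok <- which(is.finite(R))
  id <- match(seq_len(nr * nc), ok)
  n <- length(ok)
  L <- matrix(0, n, n)
  for (u in seq_len(n)) {
    cell <- ok[u]
    r <- (cell - 1) %% nr + 1; c <- (cell - 1) %/% nr + 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      cell2 <- (c2 - 1) * nr + r2
      v <- id[cell2]
      if (is.na(v) || !is.finite(R[r2, c2])) next
      # harmonic mean of the two cell conductances
      g <- 2 * (1 / R[r, c]) * (1 / R[r2, c2]) /
        (1 / R[r, c] + 1 / R[r2, c2])
      if (dr != 0 && dc != 0) g <- g / sqrt(2)
      L[u, v] <- L[u, v] - g
      L[u, u] <- L[u, u] + g
    }
  }
  a <- id[a_idx]; b <- id[b_idx]
  keep <- setdiff(seq_len(n), b)
  rhs <- numeric(n); rhs[a] <- 1
  v <- solve(L[keep, keep], rhs[keep])
  v[match(a, keep)]
}

res_surface <- function(R, cell_size = 30) {
  r <- cont_raster(R, grid_frame(nrow(R), ncol(R), cell_size))
  class(r) <- c("resistance_surface", class(r))
  r
}

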