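# Internal grid helpers shared across modules.

# 8-neighbour offsets (dr, dc).
OFFSETS8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                  dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
OFFSETS4 <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))

# Shift a matrix by (dr, dc), padding exposed cells with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# One Chebyshev dilation of a logical matrix (3x3 structuring element);
# `border` gives the value assumed outside the raster.
dilate8 <- function(m, border = FALSE) {
  out <- m
  for (i in seq_len(nrow(OFFSETS8))) {
    out <- out | shift_mat(m, OFFSETS8[i, 1], OFFSETS8[i, 2], fill = border)
  }
  out
}

# Capped Chebyshev distance transform: distance from each cell to the
# nearest TRUE cell of `target`, computed by repeated dilation and capped
# at `cap` (cells at distance > cap get cap + 1). `border_true` treats the
# outside of the raster as part of the target.
chebyshev_dist_capped <- function(target, cap, border_true = FALSE) {
  dist <- matrix(cap + 1L, nrow(target), ncol(target))
  cur <- target
  dist[cur] <- 0L
  d <- 0L
  while (d < cap) {
    d <- d + 1L
    cur <- dilate8(cur, border = border_true)
    dist[cur & dist > d] <- d
  }
  dist
}

# Label connected components of a logical matrix (TRUE cells) using
# igraph; connectivity 8 or 4. Returns an integer matrix, 0 = not in any
# component, components numbered 1..k in order of their smallest cell
# index (deterministic).
label_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  offs <- if (connectivity == 8) OFFSETS8 else OFFSETS4
  # edges between TRUE cells and their TRUE neighbours
  cell_id <- matrix(0L, nr, nc)
  cell_id[idx] <- seq_along(idx)
  from <- integer(0); to <- integer(0)
  rc <- arrayInd(idx, c(nr, nc))
  for (i in seq_len(nrow(offs))) {
    r2 <- rc[, 1] + offs[i, 1]; c2 <- rc[, 2] + offs[i, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    if (!any(ok)) next
    nb <- cell_id[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    from <- c(from, cell_id[idx[ok]][keep])
    to <- c(to, nb[keep])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # renumber by first appearance in cell-index order
  first_seen <- !duplicated(comp)
  renum <- integer(max(comp))
  renum[comp[first_seen]] <- seq_len(sum(first_seen))
  lab[idx] <- renum[comp]
  lab
}

# Mean filter with a (2k+1)x(2k+1) window; cells outside the raster are
# excluded from the average (edge-aware). Input numeric matrix.
box_mean <- function(m, k) {
  ones <- matrix(1, nrow(m), ncol(m))
  s <- m; n <- ones
  for (dr in -k:k) for (dc in -k:k) {
    if (dr == 0 && dc == 0) next
    s <- s + shift_mat(m, dr, dc, fill = 0)
    n <- n + shift_mat(ones, dr, dc, fill = 0)
  }
  s / n
}

# Separable Gaussian smoothing with reflection padding; sigma in cells.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-k:k)^2) / (2 * sigma^2))
  w <- w / sum(w)
  smooth_1d <- function(x) {
    n <- length(x)
    # reflect pad
    xp <- c(rev(x[seq_len(min(k, n))]), x, rev(x[seq.int(n, by = -1,
            length.out = min(k, n))]))
    if (length(xp) < n + 2 * k) xp <- c(rep(xp[1], n + 2 * k - length(xp)), xp)
    stats::filter(xp, w, sides = 2)[(k + 1):(k + n)]
  }
  m2 <- apply(m, 2L, smooth_1d)
  t(apply(t(m2), 2L, smooth_1d))
}

# Seeded RNG stream per (seed, operation); keeps generators independent.
op_seed <- function(seed, op) {
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
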