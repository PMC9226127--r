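#' Build a resistance surface from land cover
#'
#' Each cell's resistance to animal movement is looked up from its class:
#' low for green classes, high for construction. The defaults (forest 1,
#' water 2, grass 3, cultivated 5, unused 50, construction 100) are
#' package conventions — resistance values are study choices and should
#' be set explicitly; the lookup used is recorded on the result.
#'
#' @param landcover A `land_raster`.
#' @param lookup Named numeric vector (class name -> resistance > 0)
#'   covering every legend class.
#' @return An object of class `resistance_surface`: a `cont_raster` plus
#'   the `lookup`. Nodata cells are impassable (`NA`).
#' @export
build_resistance <- function(landcover, lookup = default_resistance()) {
  missing_cl <- setdiff(names(landcover$legend), names(lookup))
  if (length(missing_cl))
    stop("resistance lookup missing class(es): ",
         paste(missing_cl, collapse = ", "))
  if (any(lookup <= 0)) stop("resistance values must be > 0")
  vals <- matrix(NA_real_, landcover$frame$n_rows, landcover$frame$n_cols)
  for (cl in names(landcover$legend)) {
    vals[landcover$codes == landcover$legend[[cl]]] <- lookup[[cl]]
  }
  r <- cont_raster(vals, landcover$frame)
  r$lookup <- lookup
  class(r) <- c("resistance_surface", class(r))
  r
}

#' @rdname build_resistance
#' @export
default_resistance <- function() {
  c(forest = 1, water = 2, grass = 3, cultivated = 5,
    unused = 50, construction = 100)
}

# Build the weighted 8-neighbour lattice graph over passable cells.
# Edge weight = mean of endpoint resistances x centre distance (1 for
# rook moves, sqrt(2) for diagonal), in cell units.
lattice_graph <- function(resistance) {
  R <- resistance$values
  nr <- nrow(R); nc <- ncol(R)
  ok <- is.finite(R)
  id <- matrix(0L, nr, nc)
  id[ok] <- seq_len(sum(ok))
  edges <- list(); wts <- list()
  offs <- cbind(dr = c(0, 1, 1, 1), dc = c(1, -1, 0, 1))  # forward half
  dist <- c(1, sqrt(2), 1, sqrt(2))
  rc <- arrayInd(which(ok), c(nr, nc))
  for (i in seq_len(nrow(offs))) {
    r2 <- rc[, 1] + offs[i, 1]; c2 <- rc[, 2] + offs[i, 2]
    keep <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    if (!any(keep)) next
    a <- id[ok][keep]
    b <- id[cbind(r2[keep], c2[keep])]
    good <- b > 0L
    edges[[i]] <- cbind(a[good], b[good])
    wts[[i]] <- (R[which(ok)][keep][good] +
                 R[cbind(r2[keep], c2[keep])][good]) / 2 * dist[i]
  }
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  igraph::E(g)$weight <- unlist(wts)
  n_ok <- sum(ok)
  if (igraph::vcount(g) < n_ok)
    g <- igraph::add_vertices(g, n_ok - igraph::vcount(g))
  list(graph = g, id = id, ok = ok)
}

#' Least-cost corridors between major cores
#'
#' Minimum-cost paths on the 8-neighbour lattice between every requested
#' pair of cores, with edge cost = mean of endpoint resistances times
#' centre distance (diagonal moves scaled by sqrt(2)). The path runs from
#' the best cell of core A to the best cell of core B (multi-source
#' shortest path via zero-cost virtual terminals). Unreachable pairs are
#' reported as disconnected, not errors.
#'
#' @param resistance A `resistance_surface` (or `cont_raster`).
#' @param cores A [major_cores()] result (needs its `labels` attribute),
#'   or an integer label matrix.
#' @param pairs Two-column matrix/data frame of core ids, or `"all"` for
#'   every unordered pair.
#' @return An object of class `corridor_set`: data frame `corridors`
#'   (`from`, `to`, `cost`, `n_cells`, `reachable`) and list `paths` of
#'   two-column (row, col) matrices of path cells.
#' @export
least_cost_corridors <- function(resistance, cores, pairs = "all") {
  lab <- if (is.matrix(cores)) cores else attr(cores, "labels")
  ids <- if (is.matrix(cores)) setdiff(sort(unique(as.vector(cores))), 0L)
         else cores$id
  if (length(ids) < 2L) stop("need >= 2 cores")
  if (identical(pairs, "all")) {
    pairs <- t(utils::combn(ids, 2))
  }
  pairs <- as.matrix(pairs)
  if (any(pairs[, 1] == pairs[, 2])) stop("pairs must be distinct cores")
  L <- lattice_graph(resistance)
  g <- L$graph; id <- L$id
  n <- igraph::vcount(g)
  # one virtual terminal per core, tied with zero-weight edges
  g <- igraph::add_vertices(g, length(ids))
  term <- stats::setNames(n + seq_along(ids), ids)
  extra <- list()
  for (i in seq_along(ids)) {
    cells <- id[lab == ids[i] & L$ok]
    cells <- cells[cells > 0L]
    if (!length(cells)) stop("core ", ids[i], " has no passable cells")
    extra[[i]] <- cbind(rep(term[[i]], length(cells)), cells)
  }
  eg <- do.call(rbind, extra)
  g <- igraph::add_edges(g, t(eg), attr = list(weight = rep(0, nrow(eg))))
  res <- vector("list", nrow(pairs))
  paths <- vector("list", nrow(pairs))
  dims <- dim(L$ok)
  cell_rc <- which(L$ok)
  for (p in seq_len(nrow(pairs))) {
    a <- as.character(pairs[p, 1]); b <- as.character(pairs[p, 2])
    sp <- suppressWarnings(igraph::shortest_paths(
      g, from = term[[a]], to = term[[b]], mode = "all",
      output = "both"))
    vp <- as.integer(sp$vpath[[1]])
    if (length(vp) == 0L) {
      res[[p]] <- data.frame(from = pairs[p, 1], to = pairs[p, 2],
                             cost = Inf, n_cells = 0L, reachable = FALSE)
      paths[[p]] <- matrix(integer(0), 0, 2)
      next
    }
    cost <- sum(igraph::E(g)$weight[as.integer(sp$epath[[1]])])
    vp <- vp[vp <= n]  # drop virtual terminals
    rc <- arrayInd(cell_rc[vp], dims)
    colnames(rc) <- c("row", "col")
    res[[p]] <- data.frame(from = pairs[p, 1], to = pairs[p, 2],
                           cost = cost, n_cells = nrow(rc),
                           reachable = TRUE)
    paths[[p]] <- rc
  }
  structure(list(corridors = do.call(rbind, res), paths = paths,
                 lookup = resistance$lookup),
            class = "corridor_set")
}

#' @export
print.corridor_set <- function(x, ...) {
  cat(sprintf("<corridor_set> %d corridor(s)\n", nrow(x$corridors)))
  print(x$corridors)
  invisible(x)
}

#' Circuit-theory pinch points between two cores
#'
#' Models the landscape as an electrical network: each passable cell is a
#' node with conductance `1 / resistance`; neighbouring cells are joined
#' by the harmonic mean of their conductances (diagonal links scaled by
#' `1 / sqrt(2)` to compensate path-length distortion). All cells of core
#' A are merged into a source injecting unit current, core B into ground;
#' node voltages solve the graph Laplacian system. High node current
#' marks pinch points — narrow passages whose loss would sever
#' connectivity.
#'
#' @param resistance A `resistance_surface`.
#' @param core_a,core_b Logical matrices (or cell index vectors) naming
#'   the two disjoint, nonempty core regions.
#' @param diagonal Include diagonal links (default `TRUE`).
#' @return An object of class `current_map`: `current` (`cont_raster`,
#'   node current; the merged terminals carry the injected current),
#'   `effective_resistance`, `voltage` (`cont_raster`).
#'   Disconnected terminals give `effective_resistance = Inf` and zero
#'   current.
#' @export
pinch_points <- function(resistance, core_a, core_b, diagonal = TRUE) {
  R <- resistance$values
  nr <- nrow(R); nc <- ncol(R)
  ok <- is.finite(R)
  to_idx <- function(x) {
    if (is.logical(x)) which(x) else as.integer(x)
  }
  ia <- intersect(to_idx(core_a), which(ok))
  ib <- intersect(to_idx(core_b), which(ok))
  if (!length(ia) || !length(ib)) stop("both cores must be nonempty")
  if (length(intersect(ia, ib))) stop("cores must be disjoint")

  id <- matrix(0L, nr, nc)
  id[ok] <- seq_len(sum(ok))
  n <- sum(ok)
  g_cell <- 1 / R[ok]

  offs <- cbind(dr = c(0, 1, 1, 1), dc = c(1, -1, 0, 1))
  diag_move <- c(FALSE, TRUE, FALSE, TRUE)
  rc <- arrayInd(which(ok), c(nr, nc))
  from <- integer(0); to <- integer(0); gw <- numeric(0)
  for (i in seq_len(nrow(offs))) {
    if (!diagonal && diag_move[i]) next
    r2 <- rc[, 1] + offs[i, 1]; c2 <- rc[, 2] + offs[i, 2]
    keep <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    if (!any(keep)) next
    a <- id[ok][keep]
    b <- id[cbind(r2[keep], c2[keep])]
    good <- b > 0L
    ga <- g_cell[a[good]]; gb <- g_cell[b[good]]
    w <- 2 * ga * gb / (ga + gb)  # harmonic mean of conductances
    if (diag_move[i]) w <- w / sqrt(2)
    from <- c(from, a[good]); to <- c(to, b[good]); gw <- c(gw, w)
  }

  # merge terminals into supernodes: map cell node -> solve node
  node_map <- seq_len(n)
  A_id <- id[ia]; B_id <- id[ib]
  src <- n + 1L; gnd <- n + 2L
  node_map[A_id] <- src
  node_map[B_id] <- gnd
  keep_nodes <- sort(unique(node_map))
  remap <- integer(n + 2L)
  remap[keep_nodes] <- seq_along(keep_nodes)
  f2 <- remap[node_map[from]]; t2 <- remap[node_map[to]]
  m <- length(keep_nodes)
  src2 <- remap[src]; gnd2 <- remap[gnd]

  # drop self-loops (edges internal to a supernode)
  sel <- f2 != t2
  f2 <- f2[sel]; t2 <- t2[sel]; gw2 <- gw[sel]

  # terminals in different graph components -> open circuit
  gg <- igraph::graph_from_edgelist(cbind(f2, t2), directed = FALSE)
  if (igraph::vcount(gg) < m) gg <- igraph::add_vertices(gg, m -
                                                           igraph::vcount(gg))
  memb <- igraph::components(gg)$membership
  if (memb[src2] != memb[gnd2]) {
    cur_r <- cont_raster(matrix(0, nr, nc), resistance$frame)
    volt <- cont_raster(matrix(NA_real_, nr, nc), resistance$frame)
    return(structure(list(current = cur_r, effective_resistance = Inf,
                          voltage = volt),
                     class = "current_map"))
  }

  # weighted Laplacian
  Lap <- Matrix::sparseMatrix(i = c(f2, t2), j = c(t2, f2),
                              x = -c(gw2, gw2), dims = c(m, m))
  d <- -Matrix::rowSums(Lap)
  Lap <- Lap + Matrix::Diagonal(m, d + 1e-300)

  # solve with ground removed
  free <- setdiff(seq_len(m), gnd2)
  b_vec <- numeric(m); b_vec[src2] <- 1
  v <- numeric(m)
  sol <- tryCatch(
    as.numeric(Matrix::solve(Lap[free, free, drop = FALSE], b_vec[free])),
    error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) {
    cur_r <- cont_raster(matrix(0, nr, nc), resistance$frame)
    volt <- cont_raster(matrix(NA_real_, nr, nc), resistance$frame)
    return(structure(list(current = cur_r, effective_resistance = Inf,
                          voltage = volt),
                     class = "current_map"))
  }
  v[free] <- sol
  # if source and ground are in different components the solve is rank
  # deficient; detect via absurd voltage
  if (!is.finite(v[src2]) || v[src2] > 1e12) {
    cur_r <- cont_raster(matrix(0, nr, nc), resistance$frame)
    volt <- cont_raster(matrix(NA_real_, nr, nc), resistance$frame)
    return(structure(list(current = cur_r, effective_resistance = Inf,
                          voltage = volt),
                     class = "current_map"))
  }

  # node current = half the sum of absolute link currents at the node
  link_cur <- abs((v[f2] - v[t2]) * gw2)
  node_cur <- numeric(m)
  agg1 <- tapply(link_cur, f2, sum)
  agg2 <- tapply(link_cur, t2, sum)
  node_cur[as.integer(names(agg1))] <- node_cur[as.integer(names(agg1))] +
    agg1
  node_cur[as.integer(names(agg2))] <- node_cur[as.integer(names(agg2))] +
    agg2
  node_cur <- node_cur / 2
  # the merged terminals carry the full injected current, not half
  node_cur[c(src2, gnd2)] <- node_cur[c(src2, gnd2)] * 2

  cur_mat <- matrix(NA_real_, nr, nc)
  volt_mat <- matrix(NA_real_, nr, nc)
  cell_nodes <- remap[node_map]  # per ok-cell solve node
  cur_mat[ok] <- node_cur[cell_nodes]
  volt_mat[ok] <- v[cell_nodes]
  structure(list(current = cont_raster(cur_mat, resistance$frame),
                 effective_resistance = v[src2],
                 voltage = cont_raster(volt_mat, resistance$frame)),
            class = "current_map")
}

#' @export
print.current_map <- function(x, ...) {
  cat(sprintf("<current_map> effective resistance %.6g\n",
              x$effective_resistance))
  invisible(x)
}

#' Land-cover composition of a corridor
#'
#' Tallies the land-cover classes the corridor path crosses and names the
#' dominant one.
#'
#' @param path Two-column (row, col) matrix of path cells (one element of
#'   `corridor_set$paths`).
#' @param landcover A `land_raster`.
#' @return Data frame (`class`, `cells`, `fraction`) sorted by descending
#'   fraction; attribute `dominant`.
#' @export
corridor_landcover_profile <- function(path, landcover) {
  if (nrow(path) == 0L)
    return(structure(data.frame(class = character(0), cells = integer(0),
                                fraction = numeric(0)), dominant = NA))
  codes <- landcover$codes[path]
  counts <- vapply(unname(landcover$legend), function(cd) sum(codes == cd),
                   0L)
  out <- data.frame(class = names(landcover$legend), cells = counts,
                    fraction = counts / nrow(path),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dominant") <- out$class[1L]
  out
}
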