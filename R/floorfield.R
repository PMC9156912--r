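#' Build the wall-avoidance slowness grid for a geometry
#'
#' Discretises the walkable domain on a regular node grid of spacing `dh` and
#' assigns each walkable node the slowness
#' `F = 1 + g * max(0, 1 - d/d_w)`, where `d` is the distance to the nearest
#' wall: the extra slowness ramps linearly from `g` at the wall down to zero
#' at the wall-avoidance distance `d_w`. Non-walkable nodes are masked.
#'
#' The grid is aligned so that the exit line `y = 0` falls exactly on a node
#' row; it spans the corridor width and reaches from the bottom of the
#' downstream passage up to `y = l_c`.
#'
#' @param geometry a `ped_geometry` object.
#' @param dh grid spacing (m).
#' @param d_w wall-avoidance distance (m); default 0.25.
#' @param g wall slowness gain (dimensionless); default 1, i.e. slowness
#'   doubles directly at a wall.
#' @return An object of class `ped_slowness`: grid origin, spacing, node
#'   counts, the slowness matrix `F` (`nx` x `ny`, `NA` outside the walkable
#'   polygon), the walkable mask, and the exit target node indices.
#' @export
build_slowness <- function(geometry, dh, d_w = 0.25, g = 1) {
  if (dh <= 0) stop("grid spacing dh must be positive")
  if (d_w < 0 || g < 0) stop("d_w and g must be non-negative")
  hb <- geometry$b / 2
  j0 <- ceiling(geometry$exit_depth / dh - 1e-9)
  y0 <- -j0 * dh
  nx <- ceiling(geometry$b / dh - 1e-9) + 1L
  ny <- j0 + ceiling(geometry$l_c / dh - 1e-9) + 1L
  x0 <- -hb

  xs <- x0 + (seq_len(nx) - 1L) * dh
  ys <- y0 + (seq_len(ny) - 1L) * dh
  nodes <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  walk <- matrix(cpp_in_polygon(nodes, geometry$polygon, 1e-9), nx, ny)

  d <- matrix(cpp_dist_segments(nodes, geometry$walls), nx, ny)
  F <- 1 + g * pmax(1 - d / d_w, 0)      # matrix-first keeps the dim
  F[!walk] <- NA_real_

  # target domain: the exit-line node row, thickened to one cell
  exit_row <- j0 + 1L
  on_exit <- abs(xs) <= geometry$w_e / 2 + 1e-9
  targets <- which(walk[, exit_row] & on_exit) + (exit_row - 1L) * nx
  if (length(targets) < 3L)
    stop("grid too coarse: only ", length(targets),
         " node(s) across the exit; need at least 3 (reduce dh)")

  structure(
    list(origin = c(x0, y0), dh = dh, nx = nx, ny = ny,
         slowness = F, walkable = walk, targets = targets,
         d_w = d_w, g = g, geometry = geometry),
    class = "ped_slowness")
}

#' Solve the Eikonal equation on a slowness grid
#'
#' First-order fast marching for `|grad c| = F` with `c = 0` on the target
#' cells. The returned time-cost is finite on every reachable walkable node,
#' non-decreasing away from the target along characteristics, and `+Inf` on
#' masked or unreachable nodes (a warning reports unreachable walkable
#' nodes).
#'
#' @param slowness a `ped_slowness` object from [build_slowness()].
#' @param targets 1-based node indices (into the `nx * ny` grid,
#'   column-major) with `c = 0`; defaults to the exit-line cells.
#' @return Cost matrix (`nx` x `ny`, seconds per unit slowness).
#' @export
solve_eikonal <- function(slowness, targets = slowness$targets) {
  if (length(targets) == 0L) stop("no target cells")
  F <- slowness$slowness
  walk <- as.vector(slowness$walkable)
  Fv <- as.vector(F)
  Fv[!walk] <- Inf
  cost <- cpp_fast_march(slowness$nx, slowness$ny, slowness$dh,
                         Fv, walk, as.integer(targets) - 1L)
  n_unreachable <- sum(walk & !is.finite(cost))
  if (n_unreachable > 0L)
    warning(n_unreachable, " walkable node(s) unreachable from the target")
  matrix(cost, slowness$nx, slowness$ny)
}

#' Build the complete floor field for a geometry
#'
#' Convenience wrapper: builds the slowness grid, solves the Eikonal
#' equation, and precomputes the cost gradient by central differences
#' (one-sided next to masked nodes) for fast direction queries.
#'
#' @inheritParams build_slowness
#' @return An object of class `ped_floor_field` containing the grid, the
#'   time-cost `cost`, the slowness, the gradient grids and the target cells.
#' @seealso [desired_direction()]
#' @export
floor_field <- function(geometry, dh = 0.01, d_w = 0.25, g = 1) {
  sl <- build_slowness(geometry, dh, d_w, g)
  cost <- solve_eikonal(sl)
  gr <- cost_gradient(cost, dh)
  tgt_xy <- cbind(sl$origin[1] + ((sl$targets - 1L) %% sl$nx) * dh,
                  sl$origin[2] + ((sl$targets - 1L) %/% sl$nx) * dh)
  structure(
    list(origin = sl$origin, dh = dh, nx = sl$nx, ny = sl$ny,
         cost = cost, slowness = sl$slowness, walkable = sl$walkable,
         gx = gr$gx, gy = gr$gy, valid = gr$valid,
         targets = sl$targets, target_xy = tgt_xy,
         d_w = d_w, g = g, geometry = geometry),
    class = "ped_floor_field")
}

# central differences of the cost grid; one-sided beside masked/infinite
# nodes, zero where no finite neighbour exists along an axis
cost_gradient <- function(cost, dh) {
  nx <- nrow(cost); ny <- ncol(cost)
  fin <- is.finite(cost)
  pad_x <- function(M, side) {
    if (side == "L") rbind(Inf, M[-nx, , drop = FALSE])
    else rbind(M[-1, , drop = FALSE], Inf)
  }
  pad_y <- function(M, side) {
    if (side == "D") cbind(Inf, M[, -ny, drop = FALSE])
    else cbind(M[, -1, drop = FALSE], Inf)
  }
  axis_grad <- function(CL, CR) {
    fl <- is.finite(CL); fr <- is.finite(CR)
    g <- matrix(0, nx, ny)
    both <- fl & fr
    g[both] <- (CR[both] - CL[both]) / (2 * dh)
    ronly <- fr & !fl & fin
    g[ronly] <- (CR[ronly] - cost[ronly]) / dh
    lonly <- fl & !fr & fin
    g[lonly] <- (cost[lonly] - CL[lonly]) / dh
    g
  }
  gx <- axis_grad(pad_x(cost, "L"), pad_x(cost, "R"))
  gy <- axis_grad(pad_y(cost, "D"), pad_y(cost, "U"))
  gx[!fin] <- 0; gy[!fin] <- 0
  list(gx = gx, gy = gy, valid = fin)
}

#' Desired walking direction from the floor field
#'
#' Returns the unit vector `e_0 = -grad(c)/|grad(c)|` at each query point,
#' with the nodal gradient interpolated bilinearly (masked corner nodes are
#' dropped from the interpolation stencil). Points inside the downstream
#' passage (`y <= 0`) head straight down the passage, `(0, -1)`. A point
#' whose interpolation stencil is entirely masked (inside a wall or an
#' unreachable pocket) raises an error; a flat spot of the field falls back
#' to the direction towards the nearest target cell (reported via a message).
#'
#' @param field a `ped_floor_field` object.
#' @param points point `c(x, y)` or two-column matrix (m).
#' @return Matrix of unit vectors, one row per query point.
#' @export
desired_direction <- function(field, points) {
  pts <- as_points(points)
  out <- matrix(NA_real_, nrow(pts), 2L)
  colnames(out) <- c("ex", "ey")
  below <- pts[, 2] <= 0
  if (any(below))
    out[below, ] <- matrix(c(0, -1), sum(below), 2L, byrow = TRUE)
  if (all(below)) return(out)
  up <- which(!below)
  xmax <- field$origin[1] + (field$nx - 1) * field$dh
  ymax <- field$origin[2] + (field$ny - 1) * field$dh
  oob <- pts[up, 1] < field$origin[1] - 1e-9 | pts[up, 1] > xmax + 1e-9 |
    pts[up, 2] > ymax + 1e-9
  if (any(oob))
    stop("desired_direction(): ", sum(oob),
         " point(s) outside the walkable domain")
  res <- cpp_dir_at(pts[up, , drop = FALSE], grid_info(field),
                    field$gx, field$gy,
                    matrix(as.integer(field$valid), field$nx, field$ny))
  bad <- res$code == 1L
  if (any(bad))
    stop("desired_direction(): ", sum(bad),
         " point(s) inside a wall or unreachable region")
  flat <- which(res$code == 2L)
  if (length(flat)) {
    message("desired_direction(): ", length(flat),
            " flat-spot point(s); falling back to nearest target cell")
    for (k in flat) {
      p <- pts[up[k], ]
      d2 <- (field$target_xy[, 1] - p[1])^2 + (field$target_xy[, 2] - p[2])^2
      tp <- field$target_xy[which.min(d2), ]
      v <- tp - p
      nv <- sqrt(sum(v^2))
      res$dir[k, ] <- if (nv < 1e-12) c(0, -1) else v / nv
    }
  }
  out[up, ] <- res$dir
  out
}

grid_info <- function(field) {
  c(field$origin[1], field$origin[2], field$dh, field$nx, field$ny)
}

#' @export
print.ped_floor_field <- function(x, ...) {
  cat(sprintf("<ped_floor_field> %d x %d nodes, dh = %g m, d_w = %g m, g = %g\n",
              x$nx, x$ny, x$dh, x$d_w, x$g))
  fin <- is.finite(x$cost)
  cat(sprintf("  cost range [0, %.3g] over %d reachable nodes; %d target cells\n",
              max(x$cost[fin]), sum(fin), length(x$targets)))
  invisible(x)
}
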