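#' Build a straight-corridor bottleneck geometry
#'
#' The corridor occupies `x` in `[-b/2, b/2]`, `y` in `[0, l_c]`. The exit is
#' the segment `x` in `[-w_e/2, w_e/2]` at `y = 0`, centred at the origin,
#' followed by a short downstream passage of width `w_e` and length
#' `exit_depth` below `y = 0`. The lower walls run along `y = 0` from the exit
#' edges to the side walls. The walkable polygon is closed at `y = l_c` so
#' that Voronoi cells stay bounded.
#'
#' @param b corridor width (m).
#' @param l_c corridor length (m), upstream of the exit line.
#' @param w_e exit (door) width (m), must not exceed `b`.
#' @param exit_depth length of the downstream passage below `y = 0` (m).
#' @return An object of class `ped_geometry` with fields `variant`, `b`,
#'   `l_c`, `w_e`, `exit_depth`, `walls` (matrix of segments, columns
#'   `x1,y1,x2,y2`), and `polygon` (closed walkable polygon, one vertex per
#'   row).
#' @seealso [build_hopper()], [distance_to_walls()], [measurement_area()]
#' @export
build_corridor <- function(b, l_c, w_e = 0.5, exit_depth = 1) {
  check_geometry_args(b, l_c, w_e, exit_depth)
  hb <- b / 2; hw <- w_e / 2
  walls <- rbind(
    c(-hb, 0, -hb, l_c),             # left side wall
    c( hb, 0,  hb, l_c),             # right side wall
    c(-hb, 0, -hw, 0),               # left lower wall
    c( hw, 0,  hb, 0),               # right lower wall
    c(-hw, 0, -hw, -exit_depth),     # passage walls
    c( hw, 0,  hw, -exit_depth))
  polygon <- rbind(
    c(-hw, -exit_depth), c(hw, -exit_depth), c(hw, 0),
    c(hb, 0), c(hb, l_c), c(-hb, l_c), c(-hb, 0), c(-hw, 0))
  new_geometry("corridor", b, l_c, w_e, exit_depth, walls, polygon,
               funnel_height = 0)
}

#' Build a hopper (45-degree funnel) bottleneck geometry
#'
#' Like [build_corridor()], but the straight lower walls are replaced by
#' 45-degree segments running from the exit edges `(+/- w_e/2, 0)` up to their
#' intersection with the side walls at `y = (b - w_e)/2`; the vertical side
#' walls start from that height.
#'
#' @inheritParams build_corridor
#' @return A `ped_geometry` object (`variant = "hopper"`); the funnel apex
#'   height `(b - w_e)/2` is stored as `funnel_height`.
#' @export
build_hopper <- function(b, l_c, w_e = 0.5, exit_depth = 1) {
  check_geometry_args(b, l_c, w_e, exit_depth)
  hb <- b / 2; hw <- w_e / 2
  fh <- (b - w_e) / 2
  if (fh >= l_c)
    stop("hopper funnel (height ", fh, " m) does not fit into corridor length ",
         l_c, " m")
  walls <- rbind(
    c(-hb, fh, -hb, l_c),            # side walls above the funnel
    c( hb, fh,  hb, l_c),
    c(-hw, 0, -hb, fh),              # 45-degree funnel walls
    c( hw, 0,  hb, fh),
    c(-hw, 0, -hw, -exit_depth),     # passage walls
    c( hw, 0,  hw, -exit_depth))
  polygon <- rbind(
    c(-hw, -exit_depth), c(hw, -exit_depth), c(hw, 0),
    c(hb, fh), c(hb, l_c), c(-hb, l_c), c(-hb, fh), c(-hw, 0))
  new_geometry("hopper", b, l_c, w_e, exit_depth, walls, polygon,
               funnel_height = fh)
}

check_geometry_args <- function(b, l_c, w_e, exit_depth) {
  for (nm in c("b", "l_c", "w_e", "exit_depth")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("geometry dimension `", nm, "` must be a positive number")
  }
  if (w_e > b)
    stop("exit width w_e = ", w_e, " m is wider than the corridor b = ", b, " m")
  invisible(TRUE)
}

new_geometry <- function(variant, b, l_c, w_e, exit_depth, walls, polygon,
                         funnel_height) {
  colnames(walls) <- c("x1", "y1", "x2", "y2")
  colnames(polygon) <- c("x", "y")
  structure(
    list(variant = variant, b = b, l_c = l_c, w_e = w_e,
         exit_depth = exit_depth, walls = walls, polygon = polygon,
         funnel_height = funnel_height),
    class = "ped_geometry")
}

#' @export
print.ped_geometry <- function(x, ...) {
  cat(sprintf("<ped_geometry> %s: b = %g m, l_c = %g m, w_e = %g m, exit_depth = %g m\n",
              x$variant, x$b, x$l_c, x$w_e, x$exit_depth))
  cat(sprintf("  walkable area %.4g m^2 (%.4g m^2 upstream of y = 0), %d wall segments\n",
              geometry_area(x), geometry_area(x) - x$w_e * x$exit_depth,
              nrow(x$walls)))
  invisible(x)
}

#' Walkable polygon area of a geometry
#'
#' @param geometry a `ped_geometry` object.
#' @return Area of the walkable polygon in m^2 (including the downstream
#'   passage).
#' @export
geometry_area <- function(geometry) {
  cpp_polygon_area(geometry$polygon)
}

#' Corridor length from the target initial density
#'
#' The upstream corridor length is sized so that `N` agents spread over the
#' corridor realise the drawn initial density `rho_i`: `l_c = N/(b * rho_i)`,
#' bounded below by `l_min` (the physical corridor length; once the formula
#' falls below it the length stays constant at `l_min`).
#'
#' @param N number of agents.
#' @param b corridor width (m).
#' @param rho_i target initial density (agents per m^2).
#' @param l_min lower bound on the corridor length (m); default 7.
#' @return Corridor length in metres.
#' @export
corridor_length <- function(N, b, rho_i, l_min = 7) {
  if (any(c(N, b, rho_i, l_min) <= 0) || any(!is.finite(c(N, b, rho_i, l_min))))
    stop("corridor_length() needs positive finite N, b, rho_i, l_min")
  max(N / (b * rho_i), l_min)
}

#' Distance to the nearest wall
#'
#' Euclidean distance from each query point to the nearest wall segment of a
#' geometry. Used by the wall-avoidance slowness ramp of the floor field and
#' by the stepping guard.
#'
#' @param geometry a `ped_geometry` object.
#' @param points numeric vector `c(x, y)` or a two-column matrix of points (m).
#' @return Numeric vector of distances (m), zero exactly on a wall.
#' @export
distance_to_walls <- function(geometry, points) {
  pts <- as_points(points)
  cpp_dist_segments(pts, geometry$walls)
}

as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 2L) stop("a point must be c(x, y)")
    points <- matrix(points, ncol = 2L)
  }
  pts <- as.matrix(points)
  if (ncol(pts) != 2L) stop("points must have two columns (x, y)")
  storage.mode(pts) <- "double"
  pts
}

#' Rectangular measurement area
#'
#' Axis-aligned rectangle used for density measurements. The default is the
#' standard density rectangle in front of the exit: `x` in `[-0.4, 0.4]` m,
#' `y` in `[0.5, 1.3]` m.
#'
#' @param x_min,x_max,y_min,y_max rectangle bounds in metres.
#' @return An object of class `ped_area` (named numeric vector with an `area`
#'   attribute).
#' @export
measurement_area <- function(x_min = -0.4, x_max = 0.4,
                             y_min = 0.5, y_max = 1.3) {
  if (!(x_min < x_max) || !(y_min < y_max))
    stop("measurement area needs x_min < x_max and y_min < y_max")
  structure(c(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max),
            area = (x_max - x_min) * (y_max - y_min),
            class = "ped_area")
}

#' Test whether points lie in the walkable polygon
#'
#' @param geometry a `ped_geometry` object.
#' @param points point `c(x, y)` or two-column matrix (m).
#' @param tol boundary tolerance (m); points within `tol` of the boundary
#'   count as inside.
#' @return Logical vector.
#' @export
in_walkable <- function(geometry, points, tol = 1e-9) {
  cpp_in_polygon(as_points(points), geometry$polygon, tol)
}

#' Export wall segments as a data frame
#'
#' One row per wall segment with columns `x1, y1, x2, y2`; convenient for
#' plotting or writing to CSV.
#'
#' @param geometry a `ped_geometry` object.
#' @return A data frame.
#' @export
wall_segments <- function(geometry) {
  as.data.frame(geometry$walls)
}
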