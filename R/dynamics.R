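#' Model parameters of the collision-free speed model
#'
#' Bundles the per-run constants: desired speed `v0`, agent (disc) diameter
#' `l`, slope factor `T` (small `T` = high motivation, gaps are closed
#' aggressively; large `T` = low motivation), noise scale `sigma` of the
#' directional white noise, and the time step `dt`.
#'
#' `sigma` follows the convention of the model description: it is the
#' *variance* of each noise component (standard deviation `sqrt(sigma)`).
#' Set `sigma_is_variance = FALSE` to interpret it as a standard deviation.
#' For `T > 0` the step must satisfy `dt <= T/2` so that the speed function
#' bounds the mutual approach of two agents within one synchronous step.
#'
#' @param v0 desired free speed (m/s).
#' @param l agent diameter / hard-core exclusion (m).
#' @param T slope factor (s); `T = 0` gives pure volume exclusion.
#' @param sigma noise variance (dimensionless), see Details.
#' @param dt time step (s).
#' @param sigma_is_variance interpret `sigma` as variance (default) or as a
#'   standard deviation.
#' @return Object of class `ped_params`.
#' @export
model_params <- function(v0 = 1.34, l = 0.35, T = 1.3, sigma = 0.7,
                         dt = 0.01, sigma_is_variance = TRUE) {
  if (v0 <= 0) stop("v0 must be positive")
  if (l <= 0) stop("agent diameter l must be positive")
  if (T < 0) stop("slope factor T must be non-negative")
  if (sigma < 0) stop("sigma must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (T > 0 && dt > T / 2 + 1e-12)
    stop("dt = ", dt, " exceeds the overlap-safety bound T/2 = ", T / 2)
  if (T == 0 && dt > 0.05 + 1e-12)
    stop("with T = 0, dt must not exceed 0.05 s")
  structure(
    list(v0 = v0, l = l, T = T, sigma = sigma, dt = dt,
         noise_sd = if (sigma_is_variance) sqrt(sigma) else sigma,
         sigma_is_variance = sigma_is_variance),
    class = "ped_params")
}

#' @export
print.ped_params <- function(x, ...) {
  cat(sprintf(
    "<ped_params> v0 = %g m/s, l = %g m, T = %g s, sigma = %g (%s), dt = %g s\n",
    x$v0, x$l, x$T, x$sigma,
    if (x$sigma_is_variance) "variance" else "sd", x$dt))
  invisible(x)
}

#' Headway speed function
#'
#' `V(s) = min(v0, max(0, (s - l)/T))`: zero at contact (`s = l`), rising
#' linearly with slope `1/T`, capped at the desired speed `v0` (reached at
#' `s = l + v0*T`). An infinite spacing (empty headway set) gives `v0`. In
#' the limit `T = 0` the function reduces to pure volume exclusion: `v0`
#' whenever `s > l`, else 0.
#'
#' @param s spacing(s) to the nearest agent ahead (m); may be `Inf`.
#' @param params a `ped_params` object.
#' @return Speed(s) in m/s.
#' @export
speed_function <- function(s, params) {
  if (any(s < 0, na.rm = TRUE)) stop("spacing s must be non-negative")
  if (params$T > 0) {
    out <- pmin(params$v0, pmax(0, (s - params$l) / params$T))
    out[is.infinite(s)] <- params$v0
    out
  } else {
    ifelse(s > params$l, params$v0, 0)
  }
}

#' Headway neighbour set and minimal spacing
#'
#' An agent `j` is in the headway set of agent `i` when it lies in the
#' forward half-plane of `i`'s movement direction (non-negative dot product
#' of the direction with the vector from `i` to `j`) and its perpendicular
#' offset from `i`'s movement line is below one body diameter `l`.
#' `minimal_spacing()` reduces the set to the minimum effective headway --
#' the free walking distance along the movement direction until contact,
#' expressed as an equivalent centre distance
#' `e.r - sqrt(l^2 - perp^2) + l`, which equals the centre-to-centre
#' distance for an agent dead ahead -- and the index of the agent realising
#' it (ties break to the lowest index).
#'
#' @param i agent index (1-based).
#' @param positions two-column matrix of agent positions (m).
#' @param directions two-column matrix of unit movement directions (only row
#'   `i` is used by these helpers).
#' @param params a `ped_params` object.
#' @return `neighbor_set()`: integer vector of headway member indices.
#'   `minimal_spacing()`: list with `spacing` (m, `Inf` if the set is empty)
#'   and `neighbor` (index or `NA`).
#' @export
neighbor_set <- function(i, positions, directions, params) {
  pos <- as_points(positions)
  e <- directions[i, ]
  r <- sweep(pos, 2L, pos[i, ])
  fdot <- r[, 1] * e[1] + r[, 2] * e[2]
  perp <- abs(e[1] * r[, 2] - e[2] * r[, 1])
  idx <- which(fdot >= 0 & perp < params$l)
  setdiff(idx, i)
}

#' @rdname neighbor_set
#' @export
minimal_spacing <- function(i, positions, directions, params) {
  pos <- as_points(positions)
  res <- cpp_headway(pos, as_points(directions), params$l)
  list(spacing = res$spacing[i],
       neighbor = if (is.na(res$neighbor[i])) NA_integer_ else res$neighbor[i])
}

#' Perturb a desired direction with white noise
#'
#' Adds independent zero-mean normal noise (standard deviation
#' `params$noise_sd`) to both components of the unit desired direction and
#' renormalises: `e = (e0 + zeta) / |e0 + zeta|`. With `sigma = 0` the input
#' is returned unchanged. Degenerate draws (`|e0 + zeta|` numerically zero)
#' are redrawn.
#'
#' @param e0 unit vector `c(x, y)` or a two-column matrix of unit vectors.
#' @param params a `ped_params` object.
#' @return Unit vector(s) of the same shape as the input.
#' @export
perturb_direction <- function(e0, params) {
  e <- as_points(e0)
  if (params$sigma == 0) {
    return(if (is.null(dim(e0))) e0 else e)
  }
  n <- nrow(e)
  v <- e + matrix(rnorm(2L * n, sd = params$noise_sd), n, 2L)
  nv <- sqrt(rowSums(v^2))
  while (any(nv < 1e-12)) {
    k <- which(nv < 1e-12)
    v[k, ] <- e[k, , drop = FALSE] +
      matrix(rnorm(2L * length(k), sd = params$noise_sd), length(k), 2L)
    nv <- sqrt(rowSums(v^2))
  }
  out <- v / nv
  if (is.null(dim(e0))) out[1, ] else out
}

#' Run a simulation from explicit initial positions
#'
#' Advances the agents in fixed time steps. Each step, every active agent in
#' ascending id order gets its desired direction from the floor field at its
#' current position, perturbs it with directional noise, computes its speed
#' from the minimal headway spacing (walls ahead limit speed like a
#' neighbour at their ray distance with body clearance `l/2`), and moves for
#' `dt`; a move that would bring it within `l` of another agent or across a
#' wall segment is rejected and the agent keeps its position with velocity 0
#' for that step, so pairwise centre distances never drop below `l`
#' (hard-core exclusion) and walls are never penetrated. Wall *avoidance*
#' acts through the floor-field slowness ramp. Agents crossing the `y = 0`
#' line inside the exit opening are recorded with a linearly interpolated
#' crossing time and by default removed from the simulation at the crossing
#' (`remove_at_exit = FALSE` instead walks them down the passage, still
#' excluding space, until they leave its open end).
#'
#' Uses R's RNG stream: call `set.seed()` beforehand for reproducibility.
#'
#' @param geometry a `ped_geometry` object.
#' @param params a `ped_params` object.
#' @param positions N x 2 matrix of initial agent positions (m); must be
#'   inside the walkable polygon with pairwise distance >= `l` and wall
#'   clearance >= `l/2`.
#' @param field optional precomputed `ped_floor_field`; built on the fly
#'   (at `dh = 0.05` m) when omitted.
#' @param max_time simulation horizon (s); the run stops early once every
#'   agent has crossed the exit line.
#' @param record_stride record every `record_stride`-th step (frame 0 is the
#'   initial state).
#' @param remove_at_exit drop agents at the exit-line crossing (default) or
#'   keep simulating them through the downstream passage.
#' @return Object of class `ped_trajectory`: `pos` (array `N x 2 x frames`,
#'   `NA` once an agent has left the passage), `times` (frame times, s),
#'   `exits` (data frame `id`, `time`, ordered by crossing time), plus the
#'   run metadata (`params`, `geometry`, `dt`, `stride`, diagnostics).
#' @export
simulate_run <- function(geometry, params, positions, field = NULL,
                         max_time = 60, record_stride = 1L,
                         remove_at_exit = TRUE) {
  pos <- as_points(positions)
  if (is.null(field))
    field <- floor_field(geometry, dh = 0.05)
  if (!all(in_walkable(geometry, pos)))
    stop("initial positions must lie inside the walkable polygon")
  start_dir <- tryCatch(desired_direction(field, pos), error = function(e)
    stop("floor field unreachable from an initial position: ",
         conditionMessage(e)))
  stopifnot(all(is.finite(start_dir)))

  max_steps <- as.integer(ceiling(max_time / params$dt))
  # walls plus the upstream closing edge: agents may touch but not cross
  containment <- rbind(geometry$walls,
                       c(-geometry$b / 2, geometry$l_c,
                         geometry$b / 2, geometry$l_c))
  res <- cpp_simulate(
    pos, grid_info(field), field$gx, field$gy,
    matrix(as.integer(field$valid), field$nx, field$ny),
    containment, geometry$w_e / 2, geometry$exit_depth,
    params$v0, params$l, params$T, params$noise_sd, params$dt,
    max_steps, as.integer(record_stride), isTRUE(remove_at_exit))

  n <- nrow(pos)
  frames <- res$n_frames
  pos_arr <- array(res$pos[seq_len(frames * n * 2L)], dim = c(n, 2L, frames))
  times <- (seq_len(frames) - 1L) * params$dt * record_stride
  et <- res$exit_time
  ord <- order(et, na.last = NA)
  exits <- data.frame(id = ord, time = et[ord])
  if (res$n_exited < n && res$steps_run >= max_steps)
    warning(n - res$n_exited, " agent(s) still inside at the ", max_time,
            " s horizon")
  structure(
    list(pos = pos_arr, times = times, exits = exits,
         n_agents = n, params = params, geometry = geometry,
         dt = params$dt, stride = as.integer(record_stride),
         n_exited = res$n_exited,
         diagnostics = list(fallbacks = res$fallbacks,
                            freeze_events = res$freeze_events,
                            steps_run = res$steps_run)),
    class = "ped_trajectory")
}

#' @export
print.ped_trajectory <- function(x, ...) {
  cat(sprintf("<ped_trajectory> %d agents, %d frames (dt = %g s, stride %d), %d exited\n",
              x$n_agents, length(x$times), x$dt, x$stride, x$n_exited))
  if (nrow(x$exits) > 0)
    cat(sprintf("  first exit %.2f s, last recorded exit %.2f s\n",
                min(x$exits$time), max(x$exits$time)))
  invisible(x)
}

#' Agent positions at a given frame or time
#'
#' @param trajectory a `ped_trajectory`.
#' @param time time in seconds (snapped to the nearest recorded frame).
#' @param frame frame index (1-based); overrides `time`.
#' @param drop_inactive drop agents with no recorded position (already left
#'   through the passage).
#' @return Two-column matrix of positions with agent ids as rownames.
#' @export
positions_at <- function(trajectory, time = NULL, frame = NULL,
                         drop_inactive = TRUE) {
  if (is.null(frame)) {
    if (is.null(time)) stop("give either `time` or `frame`")
    frame <- which.min(abs(trajectory$times - time))
  }
  p <- trajectory$pos[, , frame, drop = FALSE]
  dim(p) <- dim(trajectory$pos)[1:2]
  rownames(p) <- seq_len(nrow(p))
  if (drop_inactive) p <- p[!is.na(p[, 1]), , drop = FALSE]
  p
}
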