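#' Mean Voronoi density in a measurement area
#'
#' Builds the Voronoi diagram of all active agents, clips each cell to the
#' walkable polygon (so cell areas are finite and exact), and evaluates the
#' Voronoi density of the rectangle `A`:
#' `rho = sum_i |R_i intersect A| / (A_i * |A|)`, where `A_i` is agent `i`'s
#' clipped cell area. Each agent carries the probability density `1/A_i` on
#' its own cell, so the density integrates to the agent count over the whole
#' domain. Areas are exact polygon areas, not grid samples.
#'
#' @param positions two-column matrix of agent positions (m), all inside the
#'   walkable polygon.
#' @param geometry a `ped_geometry` object.
#' @param area a [measurement_area()] rectangle.
#' @return Density in 1/m^2 (0, with attribute `empty = TRUE`, when no agent
#'   is present).
#' @export
voronoi_mean_density <- function(positions, geometry,
                                 area = measurement_area()) {
  pos <- as_points(positions)
  pos <- pos[!is.na(pos[, 1]), , drop = FALSE]
  if (nrow(pos) == 0L)
    return(structure(0, empty = TRUE))
  if (!all(in_walkable(geometry, pos, tol = 1e-7)))
    stop("voronoi_mean_density(): agent outside the walkable polygon")
  cells <- cpp_voronoi_cells(pos, geometry$polygon,
                             as.numeric(area[c("x_min", "x_max",
                                               "y_min", "y_max")]))
  ok <- cells$cell_area > 1e-12
  sum(cells$rect_area[ok] / cells$cell_area[ok]) / attr(area, "area")
}

#' Voronoi cell areas clipped to the walkable polygon
#'
#' @inheritParams voronoi_mean_density
#' @return Numeric vector of exact clipped cell areas (m^2); they partition
#'   the walkable polygon.
#' @export
voronoi_cell_areas <- function(positions, geometry) {
  pos <- as_points(positions)
  cpp_voronoi_cells(pos, geometry$polygon, numeric(0))$cell_area
}

#' Voronoi density time series and interval mean
#'
#' Evaluates [voronoi_mean_density()] on every recorded frame inside the
#' window (optionally thinned to one sample per `sample_dt` seconds) and
#' averages over the window.
#'
#' @param trajectory a `ped_trajectory`.
#' @param geometry geometry to clip against; defaults to the trajectory's.
#' @param area a [measurement_area()] rectangle.
#' @param window `c(t0, t1)` in seconds.
#' @param sample_dt spacing of density samples (s); `NULL` uses every frame.
#' @return List with `samples` (data frame `time`, `density`) and `mean`
#'   (time average over the window).
#' @export
density_timeseries <- function(trajectory, geometry = trajectory$geometry,
                               area = measurement_area(), window = c(10, 15),
                               sample_dt = NULL) {
  if (window[1] < min(trajectory$times) - 1e-9 ||
      window[2] > max(trajectory$times) + 1e-9)
    stop("window [", window[1], ", ", window[2],
         "] s outside the trajectory span")
  sel <- which(trajectory$times >= window[1] - 1e-9 &
                 trajectory$times <= window[2] + 1e-9)
  if (!is.null(sample_dt)) {
    stride <- max(1L, round(sample_dt / (trajectory$dt * trajectory$stride)))
    sel <- sel[seq(1L, length(sel), by = stride)]
  }
  dens <- vapply(sel, function(f) {
    as.numeric(voronoi_mean_density(positions_at(trajectory, frame = f),
                                    geometry, area))
  }, numeric(1))
  list(samples = data.frame(time = trajectory$times[sel], density = dens),
       mean = mean(dens))
}

#' Gaussian-kernel density field
#'
#' Superposes an isotropic two-dimensional Gaussian kernel
#' `(1/(pi a^2)) exp(-|r - r_i|^2/a^2)` (unit integral) on every agent in
#' every frame of the window, then averages over frames. This resolves the
#' lane structure that the cell-based Voronoi estimate smooths away.
#'
#' @param trajectory a `ped_trajectory`.
#' @param a kernel width (m); default 0.2, about the agent radius scale.
#' @param spacing grid spacing (m); must be at most `a/2`.
#' @param window `c(t0, t1)` in seconds.
#' @param sample_dt spacing of the averaged frames (s); `NULL` = every frame.
#' @return Object of class `ped_density_field`: `x`, `y` node coordinates,
#'   `values` matrix (1/m^2), `a`, `window`, `n_frames`.
#' @export
gaussian_density_field <- function(trajectory, a = 0.2, spacing = a / 2,
                                   window = c(10, 15), sample_dt = NULL) {
  if (a <= 0) stop("kernel width a must be positive")
  if (spacing > a / 2 + 1e-12)
    stop("grid spacing must be at most a/2 to resolve the kernel")
  sel <- which(trajectory$times >= window[1] - 1e-9 &
                 trajectory$times <= window[2] + 1e-9)
  if (!is.null(sample_dt)) {
    stride <- max(1L, round(sample_dt / (trajectory$dt * trajectory$stride)))
    sel <- sel[seq(1L, length(sel), by = stride)]
  }
  if (length(sel) == 0L) stop("window contains no recorded frame")
  pts <- do.call(rbind, lapply(sel, function(f)
    positions_at(trajectory, frame = f)))
  geom <- trajectory$geometry
  xg <- seq(-geom$b / 2, geom$b / 2, by = spacing)
  yg <- seq(-geom$exit_depth, geom$l_c, by = spacing)
  vals <- cpp_gaussian_field(pts, length(sel), xg, yg, a)
  structure(list(x = xg, y = yg, values = vals, a = a, window = window,
                 n_frames = length(sel)),
            class = "ped_density_field")
}

#' @export
print.ped_density_field <- function(x, ...) {
  cat(sprintf("<ped_density_field> %d x %d nodes, a = %g m, %d frames, peak %.3g 1/m^2\n",
              length(x$x), length(x$y), x$a, x$n_frames, max(x$values)))
  invisible(x)
}

#' Interaction angles near the exit
#'
#' For every recorded frame at `t >= t_min` (thinned to `sample_dt`), every
#' agent within `radius` of the exit centre whose headway set is non-empty
#' contributes the angle between its *noiseless* desired direction (the
#' floor-field direction at its position) and the unit vector towards the
#' neighbour that realises its minimal spacing. The headway set itself is
#' evaluated with the *noisy* movement direction, as during stepping (the
#' noise is white, so redrawing it here is statistically equivalent to the
#' draws used at simulation time, which makes the measure computable from
#' positions alone); only the angle's reference direction is noiseless.
#' Because the movement direction can point anywhere, the interacting
#' neighbour may lie at any bearing and angles cover the full `[0, 180]`
#' degrees (a head-on deadlock partner of a retreating agent sits at 180).
#' Uses R's RNG stream; seed it for reproducibility. Agents already inside
#' the downstream passage are skipped.
#'
#' @param trajectory a `ped_trajectory`.
#' @param field a `ped_floor_field` for the trajectory's geometry; defaults
#'   to the one attached by [run_scenario()].
#' @param params model parameters; default the trajectory's.
#' @param radius sampling radius around the exit centre (m); default 1.
#' @param t_min first sampled time (s); default 10.
#' @param sample_dt frame spacing (s); default 0.5.
#' @param noisy evaluate headway membership with noise-perturbed directions
#'   (the stepping rule); `FALSE` uses the bare floor-field direction.
#' @return Data frame with columns `time`, `id`, `neighbor`, `angle`.
#' @export
interaction_angles <- function(trajectory, field = trajectory$field,
                               params = trajectory$params, radius = 1,
                               t_min = 10, sample_dt = 0.5, noisy = TRUE) {
  if (is.null(field))
    field <- floor_field(trajectory$geometry, dh = 0.05)
  sel <- which(trajectory$times >= t_min - 1e-9)
  if (!is.null(sample_dt)) {
    stride <- max(1L, round(sample_dt / (trajectory$dt * trajectory$stride)))
    sel <- sel[seq(1L, length(sel), by = stride)]
  }
  out <- lapply(sel, function(f) {
    pos <- positions_at(trajectory, frame = f)
    if (nrow(pos) < 2L) return(NULL)
    up <- pos[, 2] > 0
    if (!any(up)) return(NULL)
    e0 <- desired_direction(field, pos)
    e_move <- if (noisy) perturb_direction(e0, params) else e0
    hw <- cpp_headway(pos, e_move, params$l)
    keep <- which(up & !is.na(hw$neighbor) &
                    sqrt(rowSums(pos^2)) <= radius)
    if (length(keep) == 0L) return(NULL)
    ang <- vapply(keep, function(i) {
      j <- hw$neighbor[i]
      v <- pos[j, ] - pos[i, ]
      v <- v / sqrt(sum(v^2))
      acos(max(-1, min(1, sum(e0[i, ] * v)))) * 180 / pi
    }, numeric(1))
    data.frame(time = trajectory$times[f],
               id = as.integer(rownames(pos)[keep]),
               neighbor = as.integer(rownames(pos)[hw$neighbor[keep]]),
               angle = ang)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(time = numeric(0), id = integer(0),
                      neighbor = integer(0), angle = numeric(0))
  out
}

#' Normalised interaction-angle histogram
#'
#' Probability-per-bin histogram of angle samples over `[0, 180]` degrees,
#' with a 3-bin moving-average smoothing used for peak extraction.
#'
#' @param angles numeric vector of angles (degrees) or the data frame from
#'   [interaction_angles()].
#' @param bin_width bin width in degrees; must divide 180.
#' @return Data frame with `mid` (bin centre), `prob` (bin mass, sums to 1)
#'   and `smooth` (3-bin moving average of `prob`, edge bins averaged over
#'   the available neighbours).
#' @export
angle_histogram <- function(angles, bin_width = 5) {
  if (is.data.frame(angles)) angles <- angles$angle
  if (abs(180 / bin_width - round(180 / bin_width)) > 1e-9)
    stop("bin_width must divide 180")
  if (length(angles) == 0L) stop("no angle samples")
  if (any(angles < 0 | angles > 180)) stop("angles must lie in [0, 180]")
  breaks <- seq(0, 180, by = bin_width)
  cnt <- tabulate(pmin(floor(angles / bin_width) + 1L, length(breaks) - 1L),
                  nbins = length(breaks) - 1L)
  prob <- cnt / sum(cnt)
  n <- length(prob)
  sm <- vapply(seq_len(n), function(i) {
    mean(prob[max(1L, i - 1L):min(n, i + 1L)])
  }, numeric(1))
  data.frame(mid = breaks[-length(breaks)] + bin_width / 2,
             prob = prob, smooth = sm)
}

#' Peaks of an angle histogram
#'
#' Local maxima of the smoothed histogram (strictly above the left
#' neighbour, at least as high as the right one; edge bins qualify via their
#' single neighbour), filtered by topographic prominence: a maximum only
#' counts as a mode when it rises above the deepest valley separating it
#' from a higher maximum by at least `min_prominence` times the tallest
#' peak's height. This keeps sampling wiggles on plateaus from registering
#' as modes. Peaks are labelled narrow/wide by the probability mass within
#' one bin of the peak.
#'
#' @param hist data frame from [angle_histogram()].
#' @param min_prob discard maxima whose smoothed height is below this.
#' @param min_prominence prominence threshold as a fraction of the highest
#'   smoothed bin.
#' @return Data frame with `angle` (bin centre), `height` (smoothed),
#'   `prominence` and `mass` (probability within +/- 1 bin), sorted by
#'   angle.
#' @export
histogram_peaks <- function(hist, min_prob = 0.005, min_prominence = 0.25) {
  s <- hist$smooth
  n <- length(s)
  left <- c(-Inf, s[-n])
  right <- c(s[-1], -Inf)
  idx <- which(s > left & s >= right & s >= min_prob)
  if (length(idx) == 0L)
    return(data.frame(angle = numeric(0), height = numeric(0),
                      prominence = numeric(0), mass = numeric(0)))
  prom <- vapply(idx, function(i) {
    # walk outwards to the nearest higher bin on each side; the prominence
    # is the drop from the peak to the higher of the two intervening valleys
    key <- s[i]
    side_valley <- function(js) {        # js: indices walking away from i
      v <- key
      for (j in js) {
        if (s[j] > key) return(v)        # reached higher ground
        v <- min(v, s[j])
      }
      v                                  # no higher ground on this side
    }
    lv <- side_valley(rev(seq_len(max(0L, i - 1L))))
    rv <- side_valley(if (i < n) (i + 1L):n else integer(0))
    key - max(lv, rv)
  }, numeric(1))
  keep <- prom >= min_prominence * max(s) | s[idx] == max(s)
  idx <- idx[keep]; prom <- prom[keep]
  mass <- vapply(idx, function(i)
    sum(hist$prob[max(1L, i - 1L):min(n, i + 1L)]), numeric(1))
  data.frame(angle = hist$mid[idx], height = s[idx], prominence = prom,
             mass = mass)
}

#' Waiting-time samples (distance to exit vs time-to-exit)
#'
#' At each sample time `t` in the window (default 10-20 s in 0.5 s steps),
#' every agent that has not yet crossed the exit line but eventually does
#' contributes one sample: its straight-line distance `r` to the exit centre
#' and its remaining waiting time `T_w = t_exit - t`. Agents that never exit
#' are skipped; their count is attached as attribute `n_skipped`.
#'
#' @param trajectory a `ped_trajectory`.
#' @param window `c(t0, t1)` sampling window (s).
#' @param sample_dt sampling interval (s).
#' @return Data frame with columns `t`, `id`, `r`, `Tw`.
#' @export
waiting_time_samples <- function(trajectory, window = c(10, 20),
                                 sample_dt = 0.5) {
  exit_time <- rep(NA_real_, trajectory$n_agents)
  exit_time[trajectory$exits$id] <- trajectory$exits$time
  n_skipped <- sum(is.na(exit_time))
  ts <- seq(window[1], min(window[2], max(trajectory$times)), by = sample_dt)
  out <- lapply(ts, function(t) {
    f <- which.min(abs(trajectory$times - t))
    pos <- positions_at(trajectory, frame = f, drop_inactive = FALSE)
    act <- which(!is.na(exit_time) & exit_time > t & !is.na(pos[, 1]))
    if (length(act) == 0L) return(NULL)
    data.frame(t = t, id = act,
               r = sqrt(pos[act, 1]^2 + pos[act, 2]^2),
               Tw = exit_time[act] - t)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(t = numeric(0), id = integer(0), r = numeric(0),
                      Tw = numeric(0))
  structure(out, n_skipped = n_skipped)
}

#' Fit the waiting-time power law
#'
#' Ordinary least squares of `log(T_w)` on `log(r)` restricted to
#' `r` in `[r_min, r_max]` (defaults 0.3-1.5 m, the range over which the
#' power law holds before boundary effects cut it off). The slope is the
#' exponent `alpha`: about 1 for single-file flow, about 2 for radially
#' converging flow.
#'
#' @param samples data frame with columns `r` and `Tw`, e.g. from
#'   [waiting_time_samples()] (several runs may be row-bound and pooled).
#' @param r_min,r_max fit range in metres.
#' @return Object of class `ped_powerlaw`: `exponent`, `prefactor`,
#'   `std_error`, `r_min`, `r_max`, `n`.
#' @export
fit_power_law <- function(samples, r_min = 0.3, r_max = 1.5) {
  sub <- samples[samples$r >= r_min & samples$r <= r_max &
                   samples$Tw > 0, , drop = FALSE]
  if (nrow(sub) < 10L)
    stop("fit_power_law(): only ", nrow(sub),
         " samples in [", r_min, ", ", r_max, "] m; need at least 10")
  fit <- lm(log(Tw) ~ log(r), data = sub)
  structure(
    list(exponent = unname(coef(fit)[2]),
         prefactor = exp(unname(coef(fit)[1])),
         std_error = unname(suppressWarnings(
           summary(fit))$coefficients[2, 2]),
         r_min = r_min, r_max = r_max, n = nrow(sub)),
    class = "ped_powerlaw")
}

#' @export
print.ped_powerlaw <- function(x, ...) {
  cat(sprintf("<ped_powerlaw> T_w ~ %.3g * r^%.3f (se %.3f, n = %d, r in [%g, %g] m)\n",
              x$prefactor, x$exponent, x$std_error, x$n, x$r_min, x$r_max))
  invisible(x)
}

#' Exit time gaps and the N-t curve
#'
#' Sorts the exit crossing times, drops the first and last `exclude` agents
#' (transients at the start and the trailing stragglers), and averages the
#' consecutive time gaps; the gap is proportional to the inverse flow. Also
#' returns the cumulative-exits curve.
#'
#' @param exits data frame with a `time` column ([simulate_run()]'s `exits`).
#' @param exclude number of agents dropped at each end; default 10.
#' @return List with `mean_gap` (s, `NA` with `empty = TRUE` flag when fewer
#'   than `2*exclude + 2` exits), `gaps` (s), `n_used`, and `nt_curve`
#'   (data frame `time`, `n_out`).
#' @export
exit_time_gaps <- function(exits, exclude = 10) {
  tt <- sort(exits$time)
  nt <- data.frame(time = tt, n_out = seq_along(tt))
  if (length(tt) < 2 * exclude + 2)
    return(list(mean_gap = NA_real_, gaps = numeric(0), n_used = 0L,
                nt_curve = nt, empty = TRUE))
  mid <- tt[(exclude + 1):(length(tt) - exclude)]
  gaps <- diff(mid)
  list(mean_gap = mean(gaps), gaps = gaps, n_used = length(mid),
       nt_curve = nt, empty = FALSE)
}

#' Maximal crowd density from hexagonal disc packing
#'
#' The densest packing of identical discs of radius `r` covers the fraction
#' `eta = pi/sqrt(12)` of the plane, so at most `eta/(pi r^2)` disc centres
#' fit per unit area. Used to bound physically admissible densities: for
#' `r = 0.175` m this gives about 9.4 per square metre.
#'
#' @param r disc radius (m).
#' @return Maximal density in 1/m^2.
#' @export
max_packing_density <- function(r) {
  if (any(r <= 0)) stop("radius r must be positive")
  eta <- pi / sqrt(12)
  eta / (pi * r^2)
}
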