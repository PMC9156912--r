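#' Scenario configuration
#'
#' Collects everything needed to reproduce a bottleneck run: geometry
#' variant, corridor width, agent count, model parameters, floor-field
#' settings, the initial-density sampling interval, the analysis windows and
#' the simulation horizon. The defaults are the reference study conditions:
#' `v0 = 1.34` m/s, `l = 0.35` m, `sigma = 0.7` (variance), `N = 55`,
#' `d_w = 0.25` m, `T` in `{0.1, 1.3}` s, initial density drawn from
#' U(2.0, 3.0) per square metre, density windows 5-10 s and 10-15 s.
#'
#' The floor-field resolution defaults to `dh = 0.01` m; sweeps and tests may
#' coarsen it (0.02-0.05 m) since the flow statistics converge well before
#' the centimetre scale.
#'
#' @param variant `"corridor"` or `"hopper"`.
#' @param b corridor width (m).
#' @param N number of agents.
#' @param T slope factor (s).
#' @param v0,l,sigma,dt,sigma_is_variance see [model_params()].
#' @param dh,d_w,g floor-field settings, see [build_slowness()].
#' @param w_e,exit_depth exit geometry, see [build_corridor()].
#' @param rho_range interval of the uniform initial-density draw (1/m^2).
#' @param l_min lower bound of the corridor length (m).
#' @param max_time simulation horizon (s).
#' @param record_stride trajectory recording stride (steps).
#' @param windows list of density measurement windows (s).
#' @return Object of class `ped_config` (a validated list).
#' @export
scenario_config <- function(variant = c("corridor", "hopper"), b = 5.6,
                            N = 55, T = 1.3, v0 = 1.34, l = 0.35,
                            sigma = 0.7, sigma_is_variance = TRUE,
                            dt = 0.01, dh = 0.01, d_w = 0.25, g = 1,
                            w_e = 0.5, exit_depth = 1,
                            rho_range = c(2, 3), l_min = 7,
                            max_time = 60, record_stride = 5L,
                            windows = list(c(5, 10), c(10, 15))) {
  variant <- match.arg(variant)
  params <- model_params(v0 = v0, l = l, T = T, sigma = sigma, dt = dt,
                         sigma_is_variance = sigma_is_variance)
  if (b < w_e) stop("corridor width b must be at least the exit width w_e")
  if (N < 1) stop("N must be at least 1")
  if (length(rho_range) != 2L || any(rho_range <= 0) || diff(rho_range) < 0)
    stop("rho_range must be an increasing positive interval")
  structure(
    list(variant = variant, b = b, N = as.integer(N), params = params,
         dh = dh, d_w = d_w, g = g, w_e = w_e, exit_depth = exit_depth,
         rho_range = rho_range, l_min = l_min, max_time = max_time,
         record_stride = as.integer(record_stride), windows = windows),
    class = "ped_config")
}

#' @export
print.ped_config <- function(x, ...) {
  cat(sprintf("<ped_config> %s, b = %g m, N = %d, T = %g s, dh = %g m, horizon %g s\n",
              x$variant, x$b, x$N, x$params$T, x$dh, x$max_time))
  invisible(x)
}

#' Draw an initial density
#'
#' Uniform draw from the configured initial-density interval (default
#' U(2.0, 3.0) agents per m^2). Uses R's RNG stream.
#'
#' @param rho_range interval `c(lo, hi)` in 1/m^2.
#' @return One density draw.
#' @export
sample_initial_density <- function(rho_range = c(2, 3)) {
  runif(1L, rho_range[1], rho_range[2])
}

#' Place agents in the upstream corridor
#'
#' Uniform random positions over the upstream corridor rectangle,
#' rejection-sampled so that all pairwise centre distances are at least `l`
#' and every agent keeps at least `l/2` clearance from the walls. Fails with
#' a descriptive error when the requested configuration is infeasible
#' (packing bound) or when the bounded retry budget is exhausted.
#'
#' @param geometry a `ped_geometry` object.
#' @param N number of agents.
#' @param l agent diameter (m).
#' @param attempts per-agent draw budget.
#' @param restarts whole-configuration restarts.
#' @return N x 2 matrix of positions.
#' @export
place_agents <- function(geometry, N, l = 0.35, attempts = 2000L,
                         restarts = 25L) {
  area <- geometry_area(geometry) - geometry$w_e * geometry$exit_depth
  if (N * pi * (l / 2)^2 >= 0.5 * area)
    stop("infeasible placement: N * pi * (l/2)^2 = ",
         signif(N * pi * (l / 2)^2, 4), " m^2 is not below half the corridor",
         " area ", signif(area, 4), " m^2")
  cpp_place_agents(as.integer(N), -geometry$b / 2, geometry$b / 2,
                   0, geometry$l_c, geometry$walls, geometry$polygon, l,
                   as.integer(attempts), as.integer(restarts))
}

# floor fields are deterministic given (variant, b, l_c, w_e, exit_depth,
# dh, d_w, g); cache them across replicate runs
cached_floor_field <- function(config, l_c) {
  # pad the corridor length up to the grid so the cached field's domain
  # always covers the run's geometry
  l_pad <- ceiling(l_c / config$dh) * config$dh
  key <- sprintf("%s_%.4f_%.4f_%.4f_%.4f_%.4f_%.4f_%.4f",
                 config$variant, config$b, l_pad,
                 config$w_e, config$exit_depth, config$dh, config$d_w,
                 config$g)
  if (!is.null(.ff_cache[[key]])) return(.ff_cache[[key]])
  geom <- scenario_geometry(config, l_pad)
  ff <- floor_field(geom, dh = config$dh, d_w = config$d_w, g = config$g)
  # keep the cache from growing without bound during wide sweeps
  if (length(ls(.ff_cache)) > 64L)
    rm(list = ls(.ff_cache)[1L], envir = .ff_cache)
  assign(key, ff, envir = .ff_cache)
  ff
}

scenario_geometry <- function(config, l_c) {
  builder <- if (config$variant == "hopper") build_hopper else build_corridor
  builder(config$b, l_c, config$w_e, config$exit_depth)
}

#' Run one scenario realisation
#'
#' Draws the initial density, derives the corridor length
#' `l_c = max(N/(b rho_i), l_min)`, places the agents, and simulates. The
#' whole realisation is a deterministic function of the seed.
#'
#' @param config a `ped_config` object.
#' @param seed integer seed for this run.
#' @return A `ped_trajectory` with extra fields `seed`, `rho_i` and `l_c`.
#' @export
run_scenario <- function(config, seed) {
  set.seed(seed)
  rho_i <- sample_initial_density(config$rho_range)
  l_c <- corridor_length(config$N, config$b, rho_i, config$l_min)
  geom <- scenario_geometry(config, l_c)
  ff <- cached_floor_field(config, l_c)
  pos <- place_agents(geom, config$N, config$params$l)
  traj <- simulate_run(geom, config$params, pos, field = ff,
                       max_time = config$max_time,
                       record_stride = config$record_stride)
  traj$seed <- seed
  traj$rho_i <- rho_i
  traj$l_c <- l_c
  traj$field <- ff
  traj
}

#' Run replicates of a scenario and tabulate per-run metrics
#'
#' Runs the scenario with seeds `base_seed + 1, ..., base_seed + n_runs`,
#' computing for each run the interval mean Voronoi densities in the
#' standard measurement rectangle, a per-run waiting-time power-law fit, the
#' mean exit time gap, and bookkeeping columns. Each run depends only on its
#' own seed, so the table is invariant under the execution order. Individual
#' run failures are recorded (`ok = FALSE`, metrics `NA`), not fatal.
#'
#' @param config a `ped_config` object.
#' @param n_runs number of replicates.
#' @param base_seed seeds are `base_seed + k`, `k = 1..n_runs`.
#' @param area measurement rectangle, default [measurement_area()].
#' @param density_dt time between density samples (s); `NULL` = every frame.
#' @return Data frame with one row per run.
#' @export
run_replicates <- function(config, n_runs, base_seed,
                           area = measurement_area(), density_dt = NULL) {
  if (n_runs < 1) stop("n_runs must be at least 1")
  rows <- lapply(seq_len(n_runs), function(k) {
    seed <- base_seed + k
    tryCatch(replicate_row(config, seed, area, density_dt),
             error = function(e) {
               warning("run with seed ", seed, " failed: ",
                       conditionMessage(e))
               empty_row(config, seed)
             })
  })
  do.call(rbind, rows)
}

replicate_row <- function(config, seed, area, density_dt) {
  traj <- run_scenario(config, seed)
  dens <- vapply(config$windows, function(w) {
    # a fully evacuated run can end before the window closes
    tryCatch(density_timeseries(traj, window = w,
                                sample_dt = density_dt)$mean,
             error = function(e) NA_real_)
  }, numeric(1))
  ws <- waiting_time_samples(traj)
  fit <- tryCatch(fit_power_law(ws), error = function(e) NULL)
  gaps <- exit_time_gaps(traj$exits)
  data.frame(
    seed = seed, variant = config$variant, b = config$b, T = config$params$T,
    N = config$N, rho_i = traj$rho_i, l_c = traj$l_c,
    n_exited = traj$n_exited,
    t_last_exit = if (nrow(traj$exits)) max(traj$exits$time) else NA_real_,
    dens_w1 = dens[1], dens_w2 = if (length(dens) > 1) dens[2] else NA_real_,
    alpha = if (is.null(fit)) NA_real_ else fit$exponent,
    alpha_n = if (is.null(fit)) 0L else fit$n,
    mean_gap = gaps$mean_gap, ok = TRUE)
}

empty_row <- function(config, seed) {
  data.frame(seed = seed, variant = config$variant, b = config$b,
             T = config$params$T, N = config$N, rho_i = NA_real_,
             l_c = NA_real_, n_exited = NA_integer_, t_last_exit = NA_real_,
             dens_w1 = NA_real_, dens_w2 = NA_real_, alpha = NA_real_,
             alpha_n = 0L, mean_gap = NA_real_, ok = FALSE)
}

#' Summarise replicate tables over a sweep
#'
#' Groups a per-run table (or the row-bound tables of several sweep cells) by
#' `(b, T)` and reports, for the named metric columns, the mean and the
#' 2.5th-97.5th percentile interval across runs.
#'
#' @param results per-run data frame(s) from [run_replicates()].
#' @param metrics columns to summarise.
#' @return Data frame with one row per `(b, T)` cell and columns
#'   `<metric>_mean`, `<metric>_lo`, `<metric>_hi`, plus `n_runs`.
#' @export
summarize_sweep <- function(results,
                            metrics = c("dens_w1", "dens_w2", "alpha",
                                        "mean_gap")) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  cells <- unique(results[, c("b", "T")])
  out <- lapply(seq_len(nrow(cells)), function(k) {
    sub <- results[results$b == cells$b[k] & results$T == cells$T[k] &
                     results$ok, , drop = FALSE]
    if (nrow(sub) < 2)
      stop("summarize_sweep() needs at least 2 successful runs per cell")
    row <- data.frame(b = cells$b[k], T = cells$T[k], n_runs = nrow(sub))
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[is.finite(v)]
      if (length(v) == 0L) {
        row[[paste0(m, "_mean")]] <- NA_real_
        row[[paste0(m, "_lo")]] <- NA_real_
        row[[paste0(m, "_hi")]] <- NA_real_
        next
      }
      q <- quantile(v, c(0.025, 0.975), names = FALSE)
      row[[paste0(m, "_mean")]] <- mean(v)
      row[[paste0(m, "_lo")]] <- q[1]
      row[[paste0(m, "_hi")]] <- q[2]
    }
    row
  })
  do.call(rbind, out)
}
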