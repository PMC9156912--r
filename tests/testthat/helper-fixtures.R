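# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small corridor + floor field used by most dynamics/metric tests
fix_geom <- function() memo("geom", build_corridor(2, 5))

fix_field <- function(dh = 0.05) {
  memo(paste0("field_", dh), floor_field(fix_geom(), dh = dh))
}

# a completed small run (12 agents, low motivation), deterministic
fix_run <- function() {
  memo("run", {
    set.seed(7)
    pos <- place_agents(fix_geom(), 12)
    simulate_run(fix_geom(), model_params(T = 1.3), pos,
                 field = fix_field(), max_time = 60)
  })
}

# closed rectangular box "geometry" (no exit) for Voronoi unit checks
box_geometry <- function(w, h) {
  structure(
    list(variant = "box", b = w, l_c = h, w_e = w, exit_depth = 0,
         walls = matrix(numeric(0), 0, 4,
                        dimnames = list(NULL, c("x1", "y1", "x2", "y2"))),
         polygon = cbind(x = c(0, w, w, 0), y = c(0, 0, h, h)),
         funnel_height = 0),
    class = "ped_geometry")
}

# hand-built static trajectory: positions fixed over n frames
static_trajectory <- function(positions, geometry, n_frames = 11, dt = 0.5,
                              exits = data.frame(id = integer(0),
                                                 time = numeric(0))) {
  n <- nrow(positions)
  pos <- array(NA_real_, dim = c(n, 2L, n_frames))
  for (f in seq_len(n_frames)) pos[, , f] <- positions
  structure(
    list(pos = pos, times = (seq_len(n_frames) - 1L) * dt, exits = exits,
         n_agents = n, params = model_params(sigma = 0), geometry = geometry,
         dt = dt, stride = 1L, n_exited = nrow(exits),
         diagnostics = list()),
    class = "ped_trajectory")
}

min_pairwise <- function(p) {
  if (nrow(p) < 2) return(Inf)
  min(dist(p))
}
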