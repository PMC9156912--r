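test_that("one agent in a closed box carries the whole density", {
  box <- box_geometry(1, 1)
  a <- measurement_area(0, 1, 0, 1)
  expect_equal(voronoi_mean_density(matrix(c(0.3, 0.7), 1), box, a), 1)
  # empty domain flags zero
  d0 <- voronoi_mean_density(matrix(numeric(0), 0, 2), box, a)
  expect_equal(as.numeric(d0), 0)
  expect_true(attr(d0, "empty"))
  expect_error(voronoi_mean_density(matrix(c(2, 2), 1), box, a), "outside")
})

test_that("lattice density matches the dense-grid sampling oracle", {
  box <- box_geometry(2.5, 2.5)
  xs <- 0.25 + 0.5 * (0:4)
  pos <- as.matrix(expand.grid(xs, xs))
  a <- measurement_area(1, 1.5, 1, 1.5)
  got <- voronoi_mean_density(pos, box, a)
  expect_equal(got, 4, tolerance = 1e-9)   # centre cell is 0.5 x 0.5

  # oracle: sample p(x) = 1/A_nearest on a fine grid
  gs <- 1 / 400
  gx <- seq(gs / 2, 2.5 - gs / 2, by = gs)
  grid <- as.matrix(expand.grid(gx, gx))
  nearest <- apply(grid, 1, function(q)
    which.min((pos[, 1] - q[1])^2 + (pos[, 2] - q[2])^2))
  cell_area <- tabulate(nearest, nbins = nrow(pos)) * gs^2
  in_a <- grid[, 1] >= 1 & grid[, 1] <= 1.5 & grid[, 2] >= 1 & grid[, 2] <= 1.5
  oracle <- sum(1 / cell_area[nearest[in_a]]) * gs^2 / 0.25
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("Voronoi cells partition the domain and conserve agent count", {
  g <- fix_geom()
  set.seed(5)
  pos <- place_agents(g, 15)
  areas <- voronoi_cell_areas(pos, g)
  expect_equal(sum(areas), geometry_area(g), tolerance = 1e-9)
  # a rectangle covering the whole domain integrates p to exactly N
  poly <- g$polygon
  whole <- measurement_area(min(poly[, 1]), max(poly[, 1]),
                            min(poly[, 2]), max(poly[, 2]))
  got <- voronoi_mean_density(pos, g, whole)
  expect_equal(got * attr(whole, "area"), 15, tolerance = 1e-9)
})

test_that("density time series averages per-frame densities", {
  box <- box_geometry(2, 2)
  pos <- rbind(c(0.5, 0.5), c(1.5, 1.5), c(0.5, 1.5))
  tr <- static_trajectory(pos, box, n_frames = 11, dt = 0.5)
  a <- measurement_area(0, 2, 0, 2)
  res <- density_timeseries(tr, geometry = box, area = a, window = c(1, 4))
  per_frame <- voronoi_mean_density(pos, box, a)
  expect_equal(res$samples$density, rep(per_frame, 7))
  expect_equal(res$mean, mean(res$samples$density))    # naive-average oracle
  expect_equal(res$mean, 3 / 4)

  # empty measurement area
  a2 <- measurement_area(1.7, 1.9, 0.1, 0.3)
  res2 <- density_timeseries(tr, geometry = box, area = a2, window = c(1, 4))
  expect_true(all(res2$samples$density < 3))
  expect_error(density_timeseries(tr, geometry = box, area = a,
                                  window = c(1, 99)), "span")
})

test_that("gaussian density field integrates to the agent count", {
  g <- build_corridor(4, 4)
  tr <- static_trajectory(rbind(c(0, 2)), g, n_frames = 5, dt = 0.5)
  f <- gaussian_density_field(tr, a = 0.2, spacing = 0.1, window = c(0, 2))
  sp <- f$x[2] - f$x[1]
  expect_equal(sum(f$values) * sp^2, 1, tolerance = 0.01)
  peak <- which(f$values == max(f$values), arr.ind = TRUE)
  expect_equal(f$x[peak[1]], 0, tolerance = 0.05)
  expect_equal(f$y[peak[2]], 2, tolerance = 0.05)

  # two well-separated agents: two equal unit lobes
  tr2 <- static_trajectory(rbind(c(-1, 1), c(1, 3)), g, n_frames = 3)
  f2 <- gaussian_density_field(tr2, a = 0.15, spacing = 0.075,
                               window = c(0, 1))
  sp2 <- f2$x[2] - f2$x[1]
  left <- f2$x < 0
  expect_equal(sum(f2$values[left, ]) * sp2^2, 1, tolerance = 0.02)
  expect_equal(sum(f2$values[!left, ]) * sp2^2, 1, tolerance = 0.02)
  expect_error(gaussian_density_field(tr2, a = 0.2, spacing = 0.15), "a/2")
})

test_that("gaussian field values match a naive double-loop evaluation", {
  g <- build_corridor(2, 2)
  pos <- rbind(c(0.2, 0.8), c(-0.3, 1.4))
  tr <- static_trajectory(pos, g, n_frames = 2, dt = 1)
  f <- gaussian_density_field(tr, a = 0.3, spacing = 0.15, window = c(0, 1))
  aa <- 0.3
  naive <- outer(seq_along(f$x), seq_along(f$y), Vectorize(function(ix, iy) {
    s <- 0
    for (k in seq_len(nrow(pos)))
      s <- s + exp(-((f$x[ix] - pos[k, 1])^2 +
                       (f$y[iy] - pos[k, 2])^2) / aa^2) / (pi * aa^2)
    s
  }))
  expect_equal(f$values, naive, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("interaction angles read off the local geometry", {
  g <- fix_geom()
  ff <- fix_field()
  p0 <- model_params(sigma = 0)           # noiseless membership for clarity
  # follower directly behind a leader on the exit axis
  tr <- static_trajectory(rbind(c(0, 0.9), c(0, 0.5)), g, n_frames = 3,
                          dt = 10)
  tr$field <- ff
  tr$params <- p0
  a <- interaction_angles(tr, t_min = 10, sample_dt = 10)
  follower <- a[a$id == 1, ]
  expect_equal(follower$angle, rep(0, nrow(follower)), tolerance = 2)
  expect_equal(unique(follower$neighbor), 2L)

  # neighbour perpendicular to the desired direction
  tr2 <- static_trajectory(rbind(c(0, 0.7), c(0.3, 0.7)), g, n_frames = 3,
                           dt = 10)
  tr2$field <- ff
  tr2$params <- p0
  a2 <- interaction_angles(tr2, t_min = 10, sample_dt = 10)
  first <- a2[a2$id == 1, ]
  expect_equal(first$angle, rep(90, nrow(first)), tolerance = 3)

  # an agent whose only neighbour is behind it emits nothing (empty headway)
  tr3 <- static_trajectory(rbind(c(0, 0.5), c(0, 3)), g, n_frames = 3,
                           dt = 10)
  tr3$field <- ff
  tr3$params <- p0
  a3 <- interaction_angles(tr3, t_min = 10, sample_dt = 10)
  expect_false(1 %in% a3$id)
  expect_true(all(a3$angle >= 0 & a3$angle <= 180))
})

test_that("angle histograms are normalised with locatable modes", {
  h <- angle_histogram(rep(30, 50))
  expect_equal(sum(h$prob), 1)
  pk <- histogram_peaks(h)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$angle - 30), 2.5)     # the bin containing 30

  set.seed(8)
  u <- runif(2e4, 0, 180)
  hu <- angle_histogram(u)
  expect_equal(sum(hu$prob), 1)
  expect_true(max(abs(hu$prob - 1 / 36)) < 0.01)   # flat within noise

  expect_error(angle_histogram(numeric(0)), "no angle")
  expect_error(angle_histogram(c(10, 200)), "0, 180")
  expect_error(angle_histogram(u, bin_width = 7), "divide")
})

test_that("waiting-time samples follow the ballistic limit", {
  g <- fix_geom()
  # analytic straight-down walker through the origin at v0
  v0 <- 1.34
  nf <- 61
  dt <- 0.5
  y0 <- 18
  ys <- y0 - v0 * dt * (0:(nf - 1))
  pos <- array(NA_real_, dim = c(1, 2, nf))
  pos[1, 1, ] <- 0
  pos[1, 2, ] <- ys
  pos[1, , ys <= 0] <- NA
  tr <- structure(
    list(pos = pos, times = (0:(nf - 1)) * dt,
         exits = data.frame(id = 1L, time = y0 / v0),
         n_agents = 1L, params = model_params(sigma = 0),
         geometry = g, dt = dt, stride = 1L, n_exited = 1L,
         diagnostics = list()),
    class = "ped_trajectory")
  ws <- waiting_time_samples(tr, window = c(1, 10), sample_dt = 0.5)
  expect_equal(ws$Tw, ws$r / v0, tolerance = 1e-9)
  fit <- fit_power_law(ws, r_min = 0.1, r_max = 20)
  expect_equal(fit$exponent, 1, tolerance = 1e-9)

  # recount oracle: one sample per sample time while the agent is en route
  expect_equal(nrow(ws), sum(sapply(seq(1, 10, 0.5), function(t)
    t < y0 / v0)))
  # no samples after the exit
  ws2 <- waiting_time_samples(tr, window = c(14, 20), sample_dt = 0.5)
  expect_equal(nrow(ws2), 0)
})

test_that("the power-law fitter recovers known exponents", {
  r <- exp(seq(log(0.3), log(1.5), length.out = 200))
  f2 <- fit_power_law(data.frame(r = r, Tw = 2 * r^2))
  expect_equal(f2$exponent, 2, tolerance = 1e-9)
  expect_equal(f2$prefactor, 2, tolerance = 1e-9)
  f1 <- fit_power_law(data.frame(r = r, Tw = 0.7 * r))
  expect_equal(f1$exponent, 1, tolerance = 1e-9)

  set.seed(21)
  rn <- exp(runif(1e4, log(0.3), log(1.5)))
  noisy <- data.frame(r = rn, Tw = 3 * rn^1.5 * exp(rnorm(1e4, 0, 0.3)))
  fn <- fit_power_law(noisy)
  expect_lte(abs(fn$exponent - 1.5), 3 * fn$std_error)

  # scale covariance: rescaling T_w leaves the exponent unchanged
  f_scaled <- fit_power_law(data.frame(r = rn, Tw = 7 * noisy$Tw))
  expect_equal(f_scaled$exponent, fn$exponent, tolerance = 1e-12)

  expect_error(fit_power_law(data.frame(r = c(1, 1.2), Tw = c(1, 2))),
               "2 samples")
})

test_that("exit time gaps drop the head and tail agents", {
  ex <- data.frame(id = 1:30, time = 1:30)
  gp <- exit_time_gaps(ex, exclude = 10)
  expect_equal(gp$mean_gap, 1)
  expect_equal(gp$n_used, 10)
  expect_equal(gp$nt_curve$n_out, 1:30)

  ex22 <- data.frame(id = 1:22, time = sort(runif(22, 0, 60)))
  gp22 <- exit_time_gaps(ex22, exclude = 10)
  expect_equal(length(gp22$gaps), 1)

  gp_small <- exit_time_gaps(data.frame(id = 1:21, time = 1:21), exclude = 10)
  expect_true(gp_small$empty)
  expect_true(is.na(gp_small$mean_gap))
})

test_that("hexagonal packing density matches a literal lattice count", {
  expect_equal(pi / sqrt(12), 0.9069, tolerance = 5e-5)
  expect_equal(round(max_packing_density(0.175), 1), 9.4)
  expect_equal(max_packing_density(0.5), (pi / sqrt(12)) / (pi * 0.25))
  r <- c(0.1, 0.175, 0.3, 1)
  expect_equal(max_packing_density(r) * pi * r^2 / (pi / sqrt(12)),
               rep(1, 4))

  # lattice-count oracle: hexagonal lattice of spacing 2r in a large box;
  # rows dy = 2r*sqrt(3)/2 apart, alternate rows offset by r
  r0 <- 0.175
  L <- 60
  dy <- 2 * r0 * sqrt(3) / 2
  rows <- floor(L / dy)
  count <- sum(vapply(seq_len(rows), function(k) {
    off <- if (k %% 2 == 0) r0 else 0
    floor((L - off) / (2 * r0)) + 1
  }, numeric(1)))
  density <- count / (L * rows * dy)
  expect_equal(density, max_packing_density(r0), tolerance = 0.02)

  expect_error(max_packing_density(0), "positive")
})

test_that("measured densities respect the packing bound", {
  tr <- fix_run()
  bound <- max_packing_density(tr$params$l / 2) * 1.02
  for (f in seq(1, length(tr$times), by = 50)) {
    d <- voronoi_mean_density(positions_at(tr, frame = f), tr$geometry)
    expect_lte(as.numeric(d), bound)
  }
})
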