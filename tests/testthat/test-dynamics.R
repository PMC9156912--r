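test_that("speed function matches the headway law", {
  p <- model_params(T = 1.3)
  expect_equal(speed_function(0.35, p), 0)
  # kink: full speed exactly at s = l + v0*T = 2.092
  expect_equal(speed_function(0.35 + 1.34 * 1.3, p), 1.34)
  expect_lt(speed_function(0.35 + 1.34 * 1.3 - 1e-6, p), 1.34)
  expect_equal(speed_function(1.65, p), 1.3 / 1.3)
  expect_equal(speed_function(Inf, p), 1.34)
  expect_equal(speed_function(c(0, 0.35, 10), p), c(0, 0, 1.34))

  p0 <- model_params(T = 0, dt = 0.05)
  expect_equal(speed_function(0.36, p0), 1.34)   # volume exclusion
  expect_equal(speed_function(0.35, p0), 0)
  expect_error(speed_function(-1, p), "non-negative")
})

test_that("smaller T never decreases the speed", {
  s <- seq(0.35, 3, by = 0.05)
  v_hi <- speed_function(s, model_params(T = 0.1))
  v_lo <- speed_function(s, model_params(T = 1.3))
  expect_true(all(v_hi >= v_lo - 1e-12))
})

test_that("parameter validation enforces the overlap-safety bound", {
  expect_error(model_params(T = 0.1, dt = 0.06), "T/2")
  expect_error(model_params(T = 0, dt = 0.1), "0.05")
  expect_error(model_params(v0 = -1), "positive")
  expect_silent(model_params(T = 0.1, dt = 0.05))
  # sigma interpretation switch
  expect_equal(model_params(sigma = 0.7)$noise_sd, sqrt(0.7))
  expect_equal(model_params(sigma = 0.7,
                            sigma_is_variance = FALSE)$noise_sd, 0.7)
})

test_that("headway membership uses the forward half-plane and lateral band", {
  p <- model_params()
  dirs <- rbind(c(0, 1), c(0, 1))
  pos <- rbind(c(0, 0), c(0, 1))
  expect_equal(neighbor_set(1, pos, dirs, p), 2L)       # dead ahead
  pos2 <- rbind(c(0, 0), c(0, -1))
  expect_equal(length(neighbor_set(1, pos2, dirs, p)), 0L)  # behind
  pos3 <- rbind(c(0, 0), c(0.4, 1))
  expect_equal(length(neighbor_set(1, pos3, dirs, p)), 0L)  # offset 0.4 > l
  pos4 <- rbind(c(0, 0), c(0.3, 1))
  expect_equal(neighbor_set(1, pos4, dirs, p), 2L)          # offset 0.3 < l
})

test_that("minimal spacing picks the nearest headway agent, lowest id on ties", {
  p <- model_params()
  dirs <- rbind(c(0, 1), c(0, 1), c(0, 1))
  pos <- rbind(c(0, 0), c(0, 1), c(0, 0.6))
  ms <- minimal_spacing(1, pos, dirs, p)
  expect_equal(ms$spacing, 0.6)
  expect_equal(ms$neighbor, 3L)

  ms2 <- minimal_spacing(1, rbind(c(0, 0), c(0, 2)), dirs[1:2, ], p)
  expect_equal(ms2$spacing, 2)
  ms3 <- minimal_spacing(2, rbind(c(0, 5), c(0, 0)),
                         rbind(c(0, 1), c(0, -1)), p)
  expect_true(is.infinite(ms3$spacing))                 # empty headway
  expect_true(is.na(ms3$neighbor))

  # exact tie: symmetric pair ahead, lowest id wins
  post <- rbind(c(0, 0), c(0.2, 1), c(-0.2, 1))
  mst <- minimal_spacing(1, post, rbind(c(0, 1), 0, 0), p)
  expect_equal(mst$neighbor, 2L)
})

test_that("direction noise preserves unit norm and matches a Monte Carlo oracle", {
  p <- model_params(sigma = 0.7)
  expect_equal(perturb_direction(c(0, 1), model_params(sigma = 0)), c(0, 1))

  set.seed(42)
  e <- perturb_direction(matrix(rep(c(0, 1), each = 1e4), 1e4, 2), p)
  expect_equal(sqrt(rowSums(e^2)), rep(1, 1e4), tolerance = 1e-12)

  # independently coded oracle for the mean absolute angular deviation of
  # normalize(e0 + zeta), zeta ~ N(0, sigma I)
  set.seed(99)
  sd <- sqrt(0.7)
  zx <- rnorm(2e5, 0, sd); zy <- rnorm(2e5, 0, sd)
  oracle <- mean(abs(atan2(zx, 1 + zy)))
  set.seed(1234)
  e2 <- perturb_direction(matrix(rep(c(0, 1), each = 2e5), 2e5, 2), p)
  got <- mean(abs(atan2(e2[, 1], e2[, 2])))
  expect_equal(got, oracle, tolerance = 0.01)
  # symmetric about zero
  expect_lt(abs(mean(atan2(e2[, 1], e2[, 2]))), 0.01)
})

test_that("a rear agent at contact stands while the front agent walks", {
  g <- fix_geom()
  p <- model_params(T = 1.3, sigma = 0)
  # id 1 is the rear agent so the sequential update moves it first
  pos <- rbind(c(0, 1.35), c(0, 1.0))
  tr <- suppressWarnings(simulate_run(g, p, pos, field = fix_field(),
                                      max_time = p$dt, record_stride = 1L))
  after <- tr$pos[, , 2]
  expect_equal(after[1, ], pos[1, ])                    # rear frozen: s = l
  expect_equal(after[2, 2], 1.0 - 1.34 * p$dt, tolerance = 1e-9)
})

test_that("a free walker moves at v0 and exits on schedule", {
  g <- fix_geom()
  p <- model_params(T = 1.3, sigma = 0)
  tr <- simulate_run(g, p, matrix(c(0, 3), 1), field = fix_field(),
                     max_time = 10)
  expect_equal(nrow(tr$exits), 1)
  expect_equal(tr$exits$time, 3 / 1.34, tolerance = 0.05 * 3 / 1.34)
  # per-step displacement is v0*dt while en route
  d <- sqrt(diff(tr$pos[1, 1, 1:20])^2 + diff(tr$pos[1, 2, 1:20])^2)
  expect_equal(d, rep(1.34 * p$dt * tr$stride, 19), tolerance = 1e-9)
})

test_that("hard-core exclusion and speed bounds hold over noisy runs", {
  tr <- fix_run()
  p <- tr$params
  v_max <- 0
  for (f in seq_along(tr$times)) {
    pos <- positions_at(tr, frame = f)
    expect_gte(min_pairwise(pos), p$l - 1e-9)
    if (f > 1) {
      prev <- positions_at(tr, frame = f - 1, drop_inactive = FALSE)
      cur <- positions_at(tr, frame = f, drop_inactive = FALSE)
      act <- !is.na(prev[, 1]) & !is.na(cur[, 1])
      if (any(act)) {
        d <- sqrt(rowSums((cur[act, , drop = FALSE] -
                             prev[act, , drop = FALSE])^2))
        v_max <- max(v_max, d / (p$dt * tr$stride))
      }
    }
  }
  expect_lte(v_max, p$v0 + 1e-9)
})

test_that("the active count is monotone and all agents eventually exit", {
  tr <- fix_run()
  active <- vapply(seq_along(tr$times), function(f) {
    sum(tr$exits$time > tr$times[f]) +
      (tr$n_agents - nrow(tr$exits))
  }, numeric(1))
  expect_true(all(diff(active) <= 0))
  expect_equal(tr$n_exited, tr$n_agents)
  expect_true(all(diff(tr$exits$time) >= 0))
})

test_that("same seed gives bit-identical runs", {
  cfg <- scenario_config(b = 2, N = 8, T = 1.3, dh = 0.05, max_time = 20)
  t1 <- run_scenario(cfg, 123)
  t2 <- run_scenario(cfg, 123)
  expect_identical(t1$pos, t2$pos)
  expect_identical(t1$exits, t2$exits)
  expect_identical(t1$rho_i, t2$rho_i)
})

test_that("noiseless dynamics are mirror-symmetric about the exit axis", {
  g <- fix_geom()
  p <- model_params(T = 1.3, sigma = 0)
  pos <- rbind(c(0.31, 2.2), c(-0.17, 1.4), c(0.53, 3.1), c(-0.62, 2.7))
  mpos <- pos
  mpos[, 1] <- -mpos[, 1]
  t1 <- suppressWarnings(simulate_run(g, p, pos, field = fix_field(),
                                      max_time = 1))
  t2 <- suppressWarnings(simulate_run(g, p, mpos, field = fix_field(),
                                      max_time = 1))
  expect_equal(t2$pos[, 1, ], -t1$pos[, 1, ], tolerance = 1e-8)
  expect_equal(t2$pos[, 2, ], t1$pos[, 2, ], tolerance = 1e-8)
})

test_that("a default-sized scenario fully evacuates", {
  cfg <- scenario_config(b = 5.6, N = 55, T = 1.3, dh = 0.05, max_time = 120)
  tr <- run_scenario(cfg, 4242)
  expect_equal(tr$n_exited, 55)
  expect_setequal(tr$exits$id, 1:55)
})
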