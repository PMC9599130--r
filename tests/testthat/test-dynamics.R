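test_that("release fills the cleft cylinder uniformly", {
  cfg <- simulation_config(n_molecules = 1e5, duration = 1)
  cleft <- list(center = c(0, 0, 0), radius = 0.06, half_height = 0.01)
  ens <- init_release(cfg, cleft, seed = 1)
  expect_equal(nrow(ens$positions), 1e5)
  expect_true(all(ens$state == 0L))
  expect_true(all(ens$shell_clock == 0))
  r <- sqrt(ens$positions[, 1]^2 + ens$positions[, 2]^2)
  expect_lte(max(r), 0.06)
  expect_lte(max(abs(ens$positions[, 3])), 0.01)
  # uniform-cylinder moments: E[pos] = 0, E[r^2] = R^2/2
  expect_equal(colMeans(ens$positions), c(0, 0, 0), tolerance = 1e-2)
  expect_equal(mean(r^2), 0.06^2 / 2, tolerance = 0.02)

  ens1 <- init_release(simulation_config(n_molecules = 1, duration = 1),
                       cleft, seed = 2)
  expect_equal(nrow(ens1$positions), 1)
})

test_that("proposed steps have exact length and isotropic directions", {
  pos <- matrix(0, 1e5, 3)
  set.seed(3)
  d <- propose_step(pos, 0.005)
  expect_equal(sqrt(rowSums(d^2)), rep(0.005, 1e5), tolerance = 1e-12)
  expect_equal(colMeans(d), c(0, 0, 0), tolerance = 1e-4)
  # each Cartesian component of a uniform direction has variance 1/3
  expect_equal(apply(d, 2, var), rep(0.005^2 / 3, 3), tolerance = 0.02)
})

test_that("motion resolution reflects specularly and never penetrates", {
  # identity when nothing is crossed
  g0 <- empty_geometry()
  old <- matrix(c(0.5, 0.5, 0.5), 1, 3)
  prop <- old + 0.004
  res <- resolve_motion(old, prop, g0)
  expect_equal(res$final, prop)
  expect_false(any(res$rejected))

  # mirror closed form at an arena wall: overshoot comes straight back
  old_w <- matrix(c(2 - 0.001, 0.3, 0.3), 1, 3)    # 1 nm from +x wall
  prop_w <- old_w + matrix(c(0.004, 0, 0), 1, 3)   # 4 nm step head-on
  res_w <- resolve_motion(old_w, prop_w, g0)
  expect_equal(res_w$final[1, 1], 2 - 0.003, tolerance = 1e-8)
  expect_equal(res_w$final[1, 2:3], c(0.3, 0.3))
  expect_equal(res_w$reflections[1], 1L)

  # mirror closed form at a sphere surface, head-on along x
  gs <- toy_geometry(c(1, 0, 0), 0.2)
  old_s <- matrix(c(1 - 0.2 - 0.001, 0, 0), 1, 3)
  prop_s <- old_s + matrix(c(0.004, 0, 0), 1, 3)
  res_s <- resolve_motion(old_s, prop_s, gs)
  expect_equal(res_s$final[1, 1], 1 - 0.2 - 0.003, tolerance = 1e-6)

  # dense random geometry: thousands of random steps, zero penetrations
  g <- small_geometry(seed = 21)
  start <- sample_ecs(2000, g, seed = 22)
  set.seed(23)
  pos <- start
  for (k in 1:5) {
    res <- resolve_motion(pos, pos + propose_step(pos, 0.005), g)
    pos <- res$final
    expect_gte(min(brute_min_distance(pos, g)), -1e-9)
  }
  # path stays inside the arena too
  expect_lte(max(abs(pos)), 1 + 1e-12)
})

test_that("binding respects the zero-hazard and no-astroglia limits", {
  g <- small_geometry(seed = 31)
  cfg <- simulation_config(n_molecules = 100, duration = 0.05,
                           snapshot_times = 0.05, psi = Inf)
  rec <- simulate_release(g, cfg, seed = 32)
  expect_equal(sum(get_snapshot(rec, 0.05)$state), 0)

  g_na <- small_geometry(seed = 33, astro_fraction_target = 0)
  expect_equal(sum(g_na$kinds == 2L), 0)
  cfg2 <- simulation_config(n_molecules = 100, duration = 0.05,
                            snapshot_times = 0.05, psi = 0.3)
  rec2 <- simulate_release(g_na, cfg2, seed = 34)
  expect_equal(sum(get_snapshot(rec2, 0.05)$state), 0)
  expect_equal(max(rec2$bound_series$bound), 0)
})

test_that("clamped-particle binding times follow the exponential law", {
  # particles held inside the shell of a large astroglial sphere; the
  # constant-hazard law must give Exponential(mean psi) binding times
  g <- toy_geometry(c(0, 0, -1), 0.9, kinds = 2L)
  n <- 2000
  for (psi in c(0.3, 1, 3)) {
    dt <- psi / 100
    ens <- structure(list(
      positions = matrix(rep(c(0, 0, -1 + 0.9 + 0.003), each = n), n, 3,
                         byrow = FALSE),
      state = integer(n), bound_time = rep(NA_real_, n),
      shell_clock = numeric(n), time = 0), class = "particle_ensemble")
    ens$positions <- matrix(c(rep(0, n), rep(0, n), rep(-1 + 0.9 + 0.003, n)),
                            n, 3)
    set.seed(1000 + psi * 10)
    for (k in seq_len(1500)) {
      if (all(ens$state == 1L)) break
      ens <- update_binding(ens, g, dt = dt, psi = psi)
    }
    bt <- ens$bound_time[!is.na(ens$bound_time)]
    expect_gt(length(bt), 0.99 * n)
    ks <- suppressWarnings(stats::ks.test(bt, "pexp", rate = 1 / psi))
    expect_gt(ks$p.value, 0.01)
    expect_equal(mean(bt), psi, tolerance = 0.1)
  }
})

test_that("free diffusion in an empty arena obeys MSD = 6 D t", {
  p <- geometry_params(arena_edge = 12, alpha_target = 0.9999,
                       astro_fraction_target = 0, alpha_tolerance = 0.01,
                       n_calib_points = 1e4, n_test_points = 1e4)
  g <- generate_geometry(p, seed = 41)
  g$centers <- g$centers[0, , drop = FALSE]   # strictly obstacle-free
  g$radii <- numeric(0); g$kinds <- integer(0); g$n_spheres <- 0L
  cfg <- simulation_config(n_molecules = 1500, duration = 1, psi = Inf,
                           snapshot_times = c(0.1, 0.5, 1))
  rec <- simulate_release(g, cfg, seed = 42)
  for (t in c(0.1, 0.5, 1)) {
    m <- ensemble_msd(rec, t)
    expect_lt(abs(m$msd - 6 * 0.5 * m$time), 3 * m$se)
  }
})

test_that("crowding hinders diffusion below the free-medium coefficient", {
  g <- small_geometry(seed = 51, arena_edge = 3, astro_fraction_target = 0)
  cfg <- simulation_config(n_molecules = 400, duration = 0.5, psi = Inf,
                           snapshot_times = c(0.25, 0.5))
  rec <- simulate_release(g, cfg, seed = 52)
  m <- ensemble_msd(rec, 0.5)
  d_eff <- m$msd / (6 * 0.5)
  expect_lt(d_eff + 3 * m$se / (6 * 0.5), cfg$D)
})

test_that("simulation conserves molecules and binding is monotone", {
  g <- small_geometry(seed = 61)
  cfg <- simulation_config(n_molecules = 300, duration = 0.4, psi = 0.3,
                           snapshot_times = c(0.1, 0.2, 0.4))
  rec <- simulate_release(g, cfg, seed = 62)
  for (s in rec$snapshots) {
    expect_equal(sum(s$state == 0L) + sum(s$state == 1L), 300)
    # no free particle strictly inside any sphere
    freep <- s$positions[s$state == 0L, , drop = FALSE]
    expect_gte(min(brute_min_distance(freep, g)), -1e-9)
    # bound particles carry a binding time within the simulated window
    expect_true(all(!is.na(s$bound_time[s$state == 1L])))
  }
  expect_true(all(diff(rec$bound_series$bound) >= 0))
  bound_per_snap <- vapply(rec$snapshots, function(s) sum(s$state), integer(1))
  expect_true(all(diff(bound_per_snap) >= 0))
  # bound particles never move after binding
  s2 <- get_snapshot(rec, 0.2); s3 <- get_snapshot(rec, 0.4)
  was_bound <- s2$state == 1L
  expect_identical(s3$positions[was_bound, ], s2$positions[was_bound, ])
})

test_that("a zero-duration run returns only the release snapshot", {
  g <- empty_geometry()
  cfg <- simulation_config(n_molecules = 50, duration = 0,
                           snapshot_times = numeric(0))
  rec <- simulate_release(g, cfg, seed = 71)
  expect_length(rec$snapshots, 1)
  expect_equal(rec$times, 0)
  expect_equal(sum(rec$snapshots[[1]]$state), 0)
})

test_that("recordings are deterministic in (geometry, seed)", {
  g <- small_geometry(seed = 81)
  cfg <- simulation_config(n_molecules = 120, duration = 0.2, psi = 0.5,
                           snapshot_times = c(0.1, 0.2))
  r1 <- simulate_release(g, cfg, seed = 82)
  r2 <- simulate_release(g, cfg, seed = 82)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$bound_series, r2$bound_series)
  r3 <- simulate_release(g, cfg, seed = 83)
  expect_false(identical(r1$snapshots, r3$snapshots))
})

test_that("the compiled loop matches the stepwise R composition exactly", {
  for (law in c("hazard", "episode")) {
    g <- small_geometry(seed = 91)
    cfg <- simulation_config(n_molecules = 30, duration = 40 * 8.333334e-6,
                             psi = 0.01, binding_law = law,
                             snapshot_times = 40 * 8.333334e-6)
    cfg$snapshot_times <- 40 * cfg$dt   # exactly the 40th step
    # reference: explicit propose / resolve / bind loop through the R API
    set.seed(92)
    ens <- init_release(cfg, g$cleft)
    for (k in 1:40) {
      free <- ens$state == 0L
      old <- ens$positions[free, , drop = FALSE]
      disp <- propose_step(old, cfg$step_length)
      ens$positions[free, ] <- resolve_motion(old, old + disp, g,
                                              cfg$max_reflect)$final
      ens <- update_binding(ens, g, cfg$dt, cfg$psi, cfg$binding_shell,
                            binding_law = law)
    }
    rec <- simulate_release(g, cfg, seed = 92)
    snap <- rec$snapshots[[length(rec$snapshots)]]
    expect_identical(snap$positions, ens$positions)
    expect_identical(snap$state, ens$state)
    expect_equal(snap$shell_clock, ens$shell_clock, tolerance = 1e-12)
  }
})
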