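# Fixtures are built in code: hand-placed sphere sets with known volumes,
# and small calibrated geometries for integration-style tests.

# geometry object from an explicit sphere list, bypassing calibration
toy_geometry <- function(centers, radii, kinds = NULL, arena_edge = 4,
                         params = NULL) {
  if (is.null(params)) params <- geometry_params(arena_edge = arena_edge)
  centers <- matrix(centers, ncol = 3)
  if (is.null(kinds)) kinds <- rep(1L, nrow(centers))
  structure(list(
    params = params,
    centers = centers, radii = as.numeric(radii), kinds = as.integer(kinds),
    cleft = list(center = c(0, 0, 0), radius = params$cleft_radius,
                 half_height = params$cleft_half_height, axis = c(0, 0, 1)),
    realized_alpha = NA_real_, realized_astro_fraction = NA_real_,
    realized_neuronal_fraction = NA_real_, se_alpha = NA_real_,
    n_spheres = nrow(centers), seed = NA_integer_,
    cell_edge = neuropilsim:::.cell_edge(params)
  ), class = "neuropil_geometry")
}

empty_geometry <- function(arena_edge = 4, params = NULL) {
  toy_geometry(matrix(numeric(0), ncol = 3), numeric(0),
               arena_edge = arena_edge, params = params)
}

# small calibrated geometry, cheap enough for unit tests
small_geometry <- function(seed = 1, arena_edge = 2, alpha_target = 0.2,
                           astro_fraction_target = 0.1, ...) {
  generate_geometry(
    geometry_params(arena_edge = arena_edge, alpha_target = alpha_target,
                    astro_fraction_target = astro_fraction_target,
                    n_calib_points = 5e4, n_test_points = 5e4,
                    alpha_tolerance = 0.015, ...),
    seed = seed)
}

# random particle ensemble (positions anywhere; for analysis bookkeeping)
random_ensemble <- function(n, geometry, time = 1, p_bound = 0.3,
                            seed = 1) {
  set.seed(seed)
  half <- geometry$params$arena_edge / 2
  structure(list(
    positions = matrix(runif(3 * n, -half, half), ncol = 3),
    state = as.integer(runif(n) < p_bound),
    bound_time = rep(NA_real_, n),
    shell_clock = numeric(n),
    time = time
  ), class = "particle_ensemble")
}

# uniform sample over the ECS of a geometry, by rejection
sample_ecs <- function(n, geometry, seed = 1) {
  set.seed(seed)
  half <- geometry$params$arena_edge / 2
  out <- matrix(numeric(0), ncol = 3)
  while (nrow(out) < n) {
    pts <- matrix(runif(3 * 2 * n, -half, half), ncol = 3)
    cls <- neuropilsim:::.classify(pts, geometry$centers, geometry$radii,
                                   geometry$kinds, geometry$params)
    out <- rbind(out, pts[cls == 0L, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

# brute-force signed distance from points to every sphere (oracle)
brute_min_distance <- function(points, geometry) {
  points <- matrix(points, ncol = 3)
  apply(points, 1, function(p) {
    if (geometry$n_spheres == 0) return(Inf)
    min(sqrt(colSums((t(geometry$centers) - p)^2)) - geometry$radii)
  })
}
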