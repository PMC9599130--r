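#' Release glutamate molecules into the synaptic cleft
#'
#' Draws `n_molecules` positions uniformly over the cleft cylinder volume
#' (instantaneous release of one vesicle's content); all particles start
#' free with zero proximity clocks.
#'
#' @param config A [simulation_config()].
#' @param cleft Cleft description, e.g. `geometry$cleft` (list with
#'   `center`, `radius`, `half_height`).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Object of class `particle_ensemble`: `positions` (n x 3, um),
#'   `state` (0 free, 1 bound), `bound_time`, `shell_clock`, `time`.
#' @export
init_release <- function(config, cleft, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_molecules
  r <- cleft$radius * sqrt(runif(n))
  phi <- 2 * pi * runif(n)
  z <- runif(n, -cleft$half_height, cleft$half_height)
  pos <- cbind(cleft$center[1] + r * cos(phi),
               cleft$center[2] + r * sin(phi),
               cleft$center[3] + z)
  structure(list(
    positions = pos,
    state = integer(n),
    bound_time = rep(NA_real_, n),
    shell_clock = numeric(n),
    time = 0
  ), class = "particle_ensemble")
}

#' Propose fixed-length isotropic random-walk displacements
#'
#' Each displacement has length exactly `step_length` and a direction
#' uniform on the sphere (two uniform deviates per particle: cos-latitude
#' and azimuth). With the step time `dt = step_length^2 / (6 D)` this walk
#' reproduces free diffusion with coefficient `D`.
#'
#' @param positions n x 3 matrix; only its row count is used.
#' @param step_length Step length in um.
#' @return n x 3 matrix of displacements.
#' @export
propose_step <- function(positions, step_length) {
  n <- nrow(positions)
  u <- matrix(runif(2 * n), nrow = 2)
  z <- 2 * u[1, ] - 1
  s <- sqrt(pmax(0, 1 - z^2))
  phi <- 2 * pi * u[2, ]
  step_length * cbind(s * cos(phi), s * sin(phi), z, deparse.level = 0)
}

#' Resolve proposed motion against cell surfaces, walls, and the cleft
#'
#' Moves each particle from `old` towards `proposed`, reflecting
#' specularly (elastic mirror collision) off sphere surfaces (neuronal and
#' astroglial alike -- cells are impermeable), the arena walls, and the two
#' cleft membrane disks, preserving path length at every bounce. A step
#' that cannot be completed within `max_reflect` reflections is rejected
#' and the particle stays put.
#'
#' @param old,proposed n x 3 position matrices (um).
#' @param geometry A `neuropil_geometry`.
#' @param max_reflect Maximum reflections per step. Default 8.
#' @return List with `final` (n x 3), `rejected` (logical), and
#'   `reflections` (integer counts).
#' @export
resolve_motion <- function(old, proposed, geometry, max_reflect = 8) {
  stopifnot(inherits(geometry, "neuropil_geometry"),
            nrow(old) == nrow(proposed))
  cpp_resolve_motion(old, proposed, geometry$centers,
                     as.numeric(geometry$radii),
                     as.integer(geometry$kinds),
                     geometry$params$arena_edge, geometry$cell_edge,
                     geometry$cleft$radius, geometry$cleft$half_height,
                     as.integer(max_reflect))
}

#' Apply the astroglial binding hazard to an ensemble
#'
#' Free particles within `binding_shell` of an astroglial surface advance
#' their proximity clock by `dt` and bind with probability
#' `1 - exp(-dt / psi)` -- the per-step hazard of the first-order lifetime
#' law `P(t) = 1 - exp(-t / psi)`. Clocks reset to zero once a particle is
#' farther than the shell from every astroglial surface. Bound particles
#' are frozen in place and never unbind within the simulated window.
#'
#' @param ensemble A `particle_ensemble`.
#' @param geometry A `neuropil_geometry`.
#' @param dt Step time, ms.
#' @param psi Binding time constant, ms (`Inf` disables binding).
#' @param binding_shell Shell half-width, um. Default 0.005 (5 nm).
#' @param binding_law `"hazard"` (constant per-step hazard, the default)
#'   or `"episode"` (probability evaluated at the proximity-episode age);
#'   see [simulation_config()].
#' @return The updated ensemble, with `time` advanced by `dt`.
#' @export
update_binding <- function(ensemble, geometry, dt, psi,
                           binding_shell = 0.005,
                           binding_law = c("hazard", "episode")) {
  binding_law <- match.arg(binding_law)
  stopifnot(inherits(ensemble, "particle_ensemble"), dt > 0, psi > 0)
  free <- which(ensemble$state == 0L)
  new_time <- ensemble$time + dt
  if (length(free)) {
    q <- query_surface(ensemble$positions[free, , drop = FALSE], geometry,
                       max_radius = max(2 * binding_shell, 0.02))
    in_shell <- q$astro_distance <= binding_shell
    ensemble$shell_clock[free[!in_shell]] <- 0
    idx <- free[in_shell]
    if (length(idx)) {
      ensemble$shell_clock[idx] <- ensemble$shell_clock[idx] + dt
      p_bind <- if (is.infinite(psi)) 0 else if (binding_law == "episode")
        1 - exp(-ensemble$shell_clock[idx] / psi)
      else 1 - exp(-dt / psi)
      hit <- runif(length(idx)) < p_bind
      ensemble$state[idx[hit]] <- 1L
      ensemble$bound_time[idx[hit]] <- new_time
    }
  }
  ensemble$time <- new_time
  ensemble
}

#' Simulate glutamate release, diffusion, and astroglial uptake
#'
#' Releases molecules into the cleft and alternates proposal, reflection,
#' and binding until `config$duration`, recording particle snapshots at
#' `config$snapshot_times` and a bound-count time series. The run is fully
#' deterministic given the geometry and the seed. The heavy stepping runs
#' in compiled code, consuming R's RNG stream in exactly the order of the
#' equivalent [propose_step()] / [resolve_motion()] / [update_binding()]
#' composition.
#'
#' @param geometry A `neuropil_geometry`.
#' @param config A [simulation_config()].
#' @param seed Seed for release and trajectory noise; defaults to
#'   `config$seed`. When `NULL`, the current RNG stream is used.
#' @return Object of class `glu_recording`: `snapshots` (list of
#'   `particle_ensemble`, the first at time 0), `bound_series`
#'   (data.frame time/bound, non-decreasing), `n_rejected`, `config`,
#'   and geometry provenance in `geometry_info`.
#' @examples
#' \donttest{
#' g <- generate_geometry(geometry_params(), seed = 1)
#' rec <- simulate_release(g, simulation_config(duration = 0.3,
#'                                              snapshot_times = 0.3), seed = 2)
#' rec
#' }
#' @export
simulate_release <- function(geometry, config, seed = config$seed) {
  stopifnot(inherits(geometry, "neuropil_geometry"),
            inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ens0 <- init_release(config, geometry$cleft)
  n_steps <- round(config$duration / config$dt)
  snap_steps <- sort(unique(pmin(n_steps, pmax(1L, round(
    config$snapshot_times / config$dt)))))
  snap_steps <- snap_steps[snap_steps >= 1L]
  stride <- max(1L, n_steps %/% max(1L, config$series_points))
  if (n_steps > 0) {
    res <- cpp_simulate(ens0$positions, geometry$centers,
                        as.numeric(geometry$radii),
                        as.integer(geometry$kinds),
                        geometry$params$arena_edge, geometry$cell_edge,
                        geometry$cleft$radius, geometry$cleft$half_height,
                        config$step_length, config$dt, config$psi,
                        config$binding_shell, as.integer(n_steps),
                        as.integer(snap_steps), as.integer(stride),
                        config$max_reflect, .scan_radius(geometry),
                        if (identical(config$binding_law, "episode")) 1L else 0L)
    snaps <- c(list(ens0), lapply(res$snapshots, function(s) {
      structure(list(positions = s$positions, state = s$state,
                     bound_time = s$bound_time,
                     shell_clock = s$shell_clock,
                     time = s$time), class = "particle_ensemble")
    }))
    series <- data.frame(time = c(0, res$series_time),
                         bound = c(0L, res$series_bound))
    n_rejected <- res$n_rejected
  } else {
    snaps <- list(ens0)
    series <- data.frame(time = 0, bound = 0L)
    n_rejected <- 0L
  }
  structure(list(
    snapshots = snaps,
    times = vapply(snaps, `[[`, numeric(1), "time"),
    bound_series = series,
    n_rejected = n_rejected,
    config = config,
    geometry_info = list(seed = geometry$seed,
                         n_spheres = geometry$n_spheres,
                         realized_alpha = geometry$realized_alpha,
                         realized_astro = geometry$realized_astro_fraction,
                         arena_edge = geometry$params$arena_edge)
  ), class = "glu_recording")
}

# scan radius for the free-flight clearance cache: a compromise between
# scan cost and the number of skipped geometry queries
.scan_radius <- function(geometry) {
  max(0.03, geometry$cell_edge / 3)
}

#' Simulate a release in a generated geometry
#'
#' S3 [stats::simulate()] method; a convenience wrapper around
#' [simulate_release()].
#'
#' @param object A `neuropil_geometry`.
#' @param nsim Number of releases (each with its own derived seed).
#' @param seed Integer seed.
#' @param config A [simulation_config()].
#' @param ... Ignored.
#' @return A `glu_recording`, or a list of them when `nsim > 1`.
#' @importFrom stats simulate
#' @export
simulate.neuropil_geometry <- function(object, nsim = 1, seed = NULL,
                                       config = simulation_config(), ...) {
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max, nsim) else {
    set.seed(as.integer(seed))
    sample.int(.Machine$integer.max, nsim)
  }
  recs <- lapply(seeds, function(s) simulate_release(object, config, seed = s))
  if (nsim == 1) recs[[1]] else recs
}

#' Extract the snapshot nearest to a requested time
#'
#' @param recording A `glu_recording`.
#' @param time Requested time, ms.
#' @return A `particle_ensemble`.
#' @export
get_snapshot <- function(recording, time) {
  stopifnot(inherits(recording, "glu_recording"))
  i <- which.min(abs(recording$times - time))
  if (abs(recording$times[i] - time) > max(0.05, 2 * recording$config$dt))
    warning(sprintf("nearest snapshot is at %.4g ms (requested %.4g ms)",
                    recording$times[i], time))
  recording$snapshots[[i]]
}

#' @export
print.particle_ensemble <- function(x, ...) {
  cat(sprintf("Particle ensemble at t = %.4g ms: %d free, %d bound\n",
              x$time, sum(x$state == 0L), sum(x$state == 1L)))
  invisible(x)
}

#' @export
print.glu_recording <- function(x, ...) {
  n <- x$config$n_molecules
  nb <- sum(x$snapshots[[length(x$snapshots)]]$state == 1L)
  cat("Glutamate release recording\n")
  cat(sprintf("  %d molecules, D = %g um^2/ms, Psi = %g ms, %g ms simulated\n",
              n, x$config$D, x$config$psi, x$config$duration))
  cat(sprintf("  snapshots at %s ms\n",
              paste(signif(x$times, 3), collapse = ", ")))
  cat(sprintf("  bound at end: %d/%d (%.1f%%); rejected steps: %d\n",
              nb, n, 100 * nb / n, x$n_rejected))
  invisible(x)
}

#' Mean squared displacement of an ensemble snapshot
#'
#' MSD of all particles (or free particles only) at a snapshot relative to
#' their release positions; in obstacle-free space the expectation is
#' `6 D t`.
#'
#' @param recording A `glu_recording`.
#' @param time Snapshot time, ms.
#' @param free_only Restrict to particles still free at that time.
#' @return List with `msd` (um^2), `se`, `n`, and `time`.
#' @export
ensemble_msd <- function(recording, time, free_only = FALSE) {
  s0 <- recording$snapshots[[1]]
  st <- get_snapshot(recording, time)
  keep <- if (free_only) st$state == 0L else rep(TRUE, nrow(st$positions))
  d2 <- rowSums((st$positions[keep, , drop = FALSE] -
                   s0$positions[keep, , drop = FALSE])^2)
  list(msd = mean(d2), se = sd(d2) / sqrt(length(d2)), n = sum(keep),
       time = st$time)
}
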