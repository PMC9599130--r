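#' Geometry parameters for the stochastic neuropil
#'
#' Defines the simulation arena, the sphere radius distribution, the
#' target extracellular (alpha) and astroglial volume fractions, and the
#' synaptic cleft dimensions. Lengths follow the field's reporting
#' conventions: the arena edge in micrometres, everything at the synaptic
#' scale in nanometres.
#'
#' @param arena_edge Edge of the cubic arena, um. Default 4.
#' @param radius_min,radius_max Sphere radius range, nm; radii are drawn
#'   uniformly over this interval. Defaults 50 and 300.
#' @param alpha_target Target extracellular volume fraction, in (0, 1).
#'   Default 0.2 (the empirical value for cortical neuropil).
#' @param astro_fraction_target Target astroglial share of total tissue
#'   volume (astroglia belong to the cellular, not the extracellular,
#'   compartment). Default 0.10.
#' @param cleft_diameter Diameter of the synaptic cleft disk, nm. Default 120.
#' @param cleft_height Height of the cleft disk, nm. Default 20.
#' @param cleft_exclusion Minimal clearance between any sphere surface and
#'   the cleft, nm. Default 10; this keeps an escape corridor around the
#'   cleft rim open.
#' @param alpha_tolerance Acceptable |realized - target| for the measured
#'   extracellular fraction. Default 0.01.
#' @param astro_tolerance Same for the astroglial fraction. Default 0.01.
#' @param n_test_points Uniform test points used to measure the realized
#'   volume fractions of a finished geometry. Default 1e5.
#' @param n_calib_points Test points used inside the calibration loop
#'   while spheres are being added. Default 2e5, so that calibration
#'   noise stays well below the reporting error of the realized
#'   fractions.
#'
#' @return An object of class `geometry_params`; all lengths converted to
#'   micrometres internally.
#' @examples
#' p <- geometry_params(alpha_target = 0.15)
#' p$cleft_radius  # 0.06 um
#' @export
geometry_params <- function(arena_edge = 4,
                            radius_min = 50, radius_max = 300,
                            alpha_target = 0.2,
                            astro_fraction_target = 0.10,
                            cleft_diameter = 120, cleft_height = 20,
                            cleft_exclusion = 10,
                            alpha_tolerance = 0.01,
                            astro_tolerance = 0.01,
                            n_test_points = 1e5,
                            n_calib_points = 2e5) {
  stopifnot(arena_edge > 0, radius_min > 0, cleft_diameter > 0,
            cleft_height > 0, cleft_exclusion >= 0,
            alpha_tolerance > 0, n_test_points >= 1000)
  if (!(alpha_target > 0 && alpha_target < 1))
    stop("alpha_target must lie strictly within (0, 1)")
  if (radius_min >= radius_max)
    stop("radius_min must be smaller than radius_max")
  if (astro_fraction_target < 0 || astro_fraction_target + alpha_target >= 1)
    stop("astro_fraction_target + alpha_target must be < 1 ",
         "(astroglia are part of the cellular volume)")
  if (cleft_diameter / 1000 >= arena_edge || cleft_height / 1000 >= arena_edge)
    stop("cleft must fit inside the arena")
  structure(list(
    arena_edge = arena_edge,
    radius_min = radius_min / 1000,
    radius_max = radius_max / 1000,
    alpha_target = alpha_target,
    astro_fraction_target = astro_fraction_target,
    cleft_radius = cleft_diameter / 2000,
    cleft_half_height = cleft_height / 2000,
    cleft_exclusion = cleft_exclusion / 1000,
    alpha_tolerance = alpha_tolerance,
    astro_tolerance = astro_tolerance,
    n_test_points = as.integer(n_test_points),
    n_calib_points = as.integer(n_calib_points)
  ), class = "geometry_params")
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("Neuropil geometry parameters\n")
  cat(sprintf("  arena: %.2f um cube; sphere radii U(%g, %g) nm\n",
              x$arena_edge, x$radius_min * 1000, x$radius_max * 1000))
  cat(sprintf("  alpha (ECS) target: %.3f +/- %.3f; astroglial target: %.3f\n",
              x$alpha_target, x$alpha_tolerance, x$astro_fraction_target))
  cat(sprintf("  cleft: %g nm diameter x %g nm height, %g nm exclusion\n",
              x$cleft_radius * 2000, x$cleft_half_height * 2000,
              x$cleft_exclusion * 1000))
  invisible(x)
}

#' Simulation parameters for glutamate release and uptake
#'
#' The random walk uses fixed-length isotropic steps of `step_length` nm,
#' with the step time set by the three-dimensional relation
#' `dt = step_length^2 / (6 D)`. The binding hazard applied while a free
#' particle is within `binding_shell` nm of an astroglial surface is the
#' first-order lifetime law `P(bind in dt) = 1 - exp(-dt / psi)`; bound
#' particles stay bound (transporter unbinding takes tens of ms, beyond
#' the simulated window).
#'
#' @param n_molecules Glutamate molecules released into the cleft. Default
#'   1000 (one vesicle's worth, at the conservative end).
#' @param D Free diffusion coefficient, um^2/ms. Default 0.5.
#' @param psi Binding time constant Psi, ms; larger means weaker uptake.
#'   `Inf` disables binding. Default 1.
#' @param step_length Random-walk step, nm. Must not exceed
#'   `binding_shell`, so the proximity shell cannot be jumped over.
#'   Default 5.
#' @param duration Simulated time, ms. Default 3. Values beyond ~5 ms
#'   trigger a warning: transporter unbinding, not modelled, starts to
#'   matter on that scale.
#' @param binding_shell Astroglial proximity shell within which the
#'   binding hazard applies, nm. Default 5.
#' @param snapshot_times Times (ms) at which particle snapshots are
#'   recorded; times beyond `duration` are dropped.
#' @param binding_law How the binding probability is evaluated while a
#'   free particle sits inside the shell. `"hazard"` (default): constant
#'   per-step hazard `1 - exp(-dt/psi)`, the memoryless discretization
#'   under which a particle held at an astroglial surface has an
#'   exponentially distributed binding time with mean `psi`. `"episode"`:
#'   per-step probability `1 - exp(-t/psi)` evaluated at the age `t` of
#'   the current proximity episode (the lifetime expression applied
#'   literally at every evaluation), an accelerating-hazard law.
#' @param seed Optional integer seed used by [simulate_release()].
#' @param max_reflect Maximum reflections resolved within one step before
#'   the step is rejected. Default 8.
#' @param series_points Approximate number of points kept in the
#'   bound-count time series. Default 512.
#'
#' @return An object of class `simulation_config` (lengths in um, with
#'   the derived step time `dt` in ms).
#' @examples
#' cfg <- simulation_config(psi = 0.5, duration = 1)
#' cfg$dt  # (0.005)^2 / (6 * 0.5)
#' @export
simulation_config <- function(n_molecules = 1000, D = 0.5, psi = 1,
                              step_length = 5, duration = 3,
                              binding_shell = 5,
                              snapshot_times = c(0.1, 0.3, 1, 3),
                              binding_law = c("hazard", "episode"),
                              seed = NULL, max_reflect = 8,
                              series_points = 512) {
  binding_law <- match.arg(binding_law)
  stopifnot(n_molecules >= 1, D > 0, step_length > 0, duration >= 0,
            binding_shell > 0, max_reflect >= 1)
  if (!(psi > 0)) stop("psi must be positive (use Inf to disable binding)")
  if (step_length > binding_shell)
    stop("step_length must not exceed binding_shell ",
         "(the proximity shell must not be jumped over)")
  if (duration > 5.5)
    warning("duration > ~5 ms: transporter unbinding is not modelled ",
            "on that time scale", call. = FALSE)
  step_um <- step_length / 1000
  structure(list(
    n_molecules = as.integer(n_molecules),
    D = D, psi = psi,
    step_length = step_um,
    dt = step_um^2 / (6 * D),
    duration = duration,
    binding_shell = binding_shell / 1000,
    snapshot_times = sort(unique(snapshot_times[snapshot_times <= duration])),
    binding_law = binding_law,
    seed = seed,
    max_reflect = as.integer(max_reflect),
    series_points = as.integer(series_points)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Glutamate simulation parameters\n")
  cat(sprintf("  %d molecules; D = %g um^2/ms; Psi = %g ms\n",
              x$n_molecules, x$D, x$psi))
  cat(sprintf("  step %g nm (dt = %.3g ms), duration %g ms, shell %g nm\n",
              x$step_length * 1000, x$dt, x$duration,
              x$binding_shell * 1000))
  cat(sprintf("  snapshots at: %s ms; binding law: %s\n",
              paste(x$snapshot_times, collapse = ", "), x$binding_law))
  invisible(x)
}

#' Specification of a Psi-by-alpha parameter sweep
#'
#' @param psi_values Binding time constants, ms.
#' @param alpha_values Extracellular volume fractions; must stay within
#'   the physiological 0.1-0.3 range for which the geometry model was
#'   validated.
#' @param timepoints Times (ms) at which length constants are read out.
#' @param n_trials Independent geometry+release trials per grid cell.
#' @param base_config A [simulation_config()]; `psi` and `snapshot_times`
#'   are overridden per cell.
#' @param base_geometry_params A [geometry_params()]; `alpha_target` is
#'   overridden per cell.
#' @param seed_root Integer seed from which all per-trial seeds derive.
#' @param paired If `TRUE` (default) the same trial seeds are reused in
#'   every grid cell (common random numbers, sharpening Psi/alpha
#'   contrasts); if `FALSE` every (cell, trial) gets its own stream.
#' @param bin_width Profile bin width, nm, for the per-cell profiles.
#'
#' @return Object of class `sweep_spec`.
#' @export
sweep_spec <- function(psi_values = c(0.3, 0.6, 1, 2, 4),
                       alpha_values = c(0.10, 0.15, 0.20, 0.25, 0.30),
                       timepoints = c(0.3, 3),
                       n_trials = 10,
                       base_config = simulation_config(),
                       base_geometry_params = geometry_params(),
                       seed_root = 1L,
                       paired = TRUE,
                       bin_width = 25) {
  stopifnot(length(psi_values) >= 1, length(alpha_values) >= 1,
            length(timepoints) >= 1, n_trials >= 1,
            inherits(base_config, "simulation_config"),
            inherits(base_geometry_params, "geometry_params"))
  if (any(alpha_values < 0.1 - 1e-9 | alpha_values > 0.3 + 1e-9))
    stop("alpha_values must lie within the validated range [0.1, 0.3]")
  if (any(psi_values <= 0)) stop("psi_values must be positive")
  if (any(timepoints > base_config$duration))
    stop("all timepoints must lie within base_config$duration")
  structure(list(
    psi_values = psi_values, alpha_values = alpha_values,
    timepoints = timepoints, n_trials = as.integer(n_trials),
    base_config = base_config,
    base_geometry_params = base_geometry_params,
    seed_root = as.integer(seed_root), paired = isTRUE(paired),
    bin_width = bin_width
  ), class = "sweep_spec")
}

#' @export
print.sweep_spec <- function(x, ...) {
  cat("Psi x alpha sweep specification\n")
  cat("  Psi (ms):  ", paste(x$psi_values, collapse = ", "), "\n")
  cat("  alpha:     ", paste(x$alpha_values, collapse = ", "), "\n")
  cat(sprintf("  %d trial(s)/cell, timepoints %s ms, %s seeds\n",
              x$n_trials, paste(x$timepoints, collapse = ", "),
              if (x$paired) "paired" else "independent"))
  invisible(x)
}
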