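#' Generate a stochastic overlapping-sphere neuropil
#'
#' Fills a cubic arena with randomly scattered, overlapping spheres whose
#' radii are uniform over `[radius_min, radius_max]`, leaving a sphere-free
#' synaptic cleft (a disk) at the centre with a `cleft_exclusion` clearance.
#' Spheres are added until the extracellular volume fraction, measured by
#' uniform test points, reaches `alpha_target`; the sphere count is then
#' fine-tuned by a prefix binary search (the measured fraction is exactly
#' monotone in the number of spheres for a fixed test-point set). Each
#' sphere is finally labelled astroglial with a probability calibrated by
#' bisection so that astroglia occupy `astro_fraction_target` of the total
#' tissue volume; a test point covered by both kinds counts as astroglial
#' (the binding surface wins overlap attribution).
#'
#' A fresh geometry should be generated for every simulation trial: each
#' realization is one random sample of the 'average' synaptic environment.
#'
#' @param params A [geometry_params()] object.
#' @param seed Integer seed; fixes the realization completely.
#' @return An object of class `neuropil_geometry` with elements `centers`
#'   (n x 3, um), `radii` (um), `kinds` (1 = neuronal, 2 = astroglial),
#'   `cleft`, `realized_alpha`, `realized_astro_fraction`, and the
#'   measurement standard error `se_alpha`.
#' @examples
#' \donttest{
#' g <- generate_geometry(geometry_params(), seed = 1)
#' g$realized_alpha
#' }
#' @export
generate_geometry <- function(params, seed) {
  stopifnot(inherits(params, "geometry_params"))
  set.seed(as.integer(seed))
  half <- params$arena_edge / 2
  v_arena <- params$arena_edge^3
  # mean sphere volume, for batch sizing only
  er3 <- (params$radius_max^4 - params$radius_min^4) /
    (4 * (params$radius_max - params$radius_min))
  vbar <- 4 / 3 * pi * er3

  calib <- matrix(runif(3 * params$n_calib_points, -half, half), ncol = 3)
  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  alpha_hat <- 1
  target <- params$alpha_target
  iter <- 0L
  while (alpha_hat > target) {
    iter <- iter + 1L
    if (iter > 500L || nrow(centers) > 3e5)
      stop("geometry calibration did not converge: alpha_target = ",
           target, " not reached after ", nrow(centers),
           " spheres (infeasible parameter combination?)")
    expected <- log(alpha_hat / target) * v_arena / vbar
    batch <- max(1L, min(2000L, ceiling(0.6 * expected)))
    cand <- matrix(runif(3 * batch, -half, half), ncol = 3)
    r <- runif(batch, params$radius_min, params$radius_max)
    keep <- .cleft_clearance(cand, r, params) >= params$cleft_exclusion
    if (any(keep)) {
      centers <- rbind(centers, cand[keep, , drop = FALSE])
      radii <- c(radii, r[keep])
      alpha_hat <- .ecs_fraction(calib, centers, radii, params)
    }
  }
  # prefix binary search: measured alpha is monotone in the sphere count
  lo <- 0L; hi <- nrow(centers)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    a <- .ecs_fraction(calib, centers[seq_len(mid), , drop = FALSE],
                       radii[seq_len(mid)], params)
    if (a > target) lo <- mid else hi <- mid
  }
  a_lo <- .ecs_fraction(calib, centers[seq_len(lo), , drop = FALSE],
                        radii[seq_len(lo)], params)
  a_hi <- .ecs_fraction(calib, centers[seq_len(hi), , drop = FALSE],
                        radii[seq_len(hi)], params)
  n_keep <- if (abs(a_lo - target) < abs(a_hi - target)) lo else hi
  centers <- centers[seq_len(n_keep), , drop = FALSE]
  radii <- radii[seq_len(n_keep)]

  # astroglia labelling: threshold a fixed uniform mark per sphere and
  # bisect the threshold on the measured astroglial tissue share
  kinds <- rep(1L, n_keep)
  if (params$astro_fraction_target > 0 && n_keep > 0) {
    mark <- runif(n_keep)
    measure <- function(p) {
      k <- ifelse(mark < p, 2L, 1L)
      cls <- .classify(calib, centers, radii, k, params)
      mean(cls == 2L)
    }
    if (measure(1) < params$astro_fraction_target - params$astro_tolerance)
      stop("astro_fraction_target unreachable: cellular volume is only ",
           signif(measure(1), 3))
    plo <- 0; phi <- 1
    for (i in 1:30) {
      pm <- (plo + phi) / 2
      if (measure(pm) < params$astro_fraction_target) plo <- pm else phi <- pm
    }
    p_star <- (plo + phi) / 2
    kinds <- ifelse(mark < p_star, 2L, 1L)
  }

  # realized fractions from a fresh, larger test-point sample
  fresh <- matrix(runif(3 * params$n_test_points, -half, half), ncol = 3)
  cls <- .classify(fresh, centers, radii, kinds, params)
  ecs <- mean(cls == 0L)
  astro <- mean(cls == 2L)

  geom <- structure(list(
    params = params,
    centers = centers, radii = radii, kinds = kinds,
    cleft = list(center = c(0, 0, 0), radius = params$cleft_radius,
                 half_height = params$cleft_half_height, axis = c(0, 0, 1)),
    realized_alpha = ecs,
    realized_astro_fraction = astro,
    realized_neuronal_fraction = 1 - ecs - astro,
    se_alpha = sqrt(ecs * (1 - ecs) / params$n_test_points),
    n_spheres = n_keep,
    seed = as.integer(seed),
    cell_edge = .cell_edge(params)
  ), class = "neuropil_geometry")
  if (abs(ecs - target) > params$alpha_tolerance)
    stop(sprintf(
      "geometry calibration failed: realized alpha %.4f vs target %.3f (tolerance %.3f)",
      ecs, target, params$alpha_tolerance))
  geom
}

# distance from sphere surfaces to the solid cleft disk (vectorized);
# returns centre-to-cleft distance minus radius
.cleft_clearance <- function(centers, radii, params) {
  rho <- sqrt(centers[, 1]^2 + centers[, 2]^2)
  dr <- pmax(0, rho - params$cleft_radius)
  dz <- pmax(0, abs(centers[, 3]) - params$cleft_half_height)
  sqrt(dr^2 + dz^2) - radii
}

.cell_edge <- function(params) {
  max(params$radius_max / 2, params$arena_edge / 128)
}

.classify <- function(points, centers, radii, kinds, params) {
  cpp_classify_points(points, centers, as.numeric(radii), as.integer(kinds),
                      params$arena_edge, .cell_edge(params))
}

.ecs_fraction <- function(points, centers, radii, params) {
  if (nrow(centers) == 0) return(1)
  mean(.classify(points, centers, radii, rep(1L, nrow(centers)), params) == 0L)
}

#' Measure volume fractions of a geometry by uniform test points
#'
#' Scatters `n_points` uniform test points over the arena and classifies
#' each as extracellular (inside no sphere), astroglial (inside at least
#' one astroglial sphere), or neuronal. The three fractions sum to one.
#'
#' @param geometry A `neuropil_geometry`.
#' @param n_points Number of test points (>= 1e4 recommended for reported
#'   estimates).
#' @param seed Optional seed for the test-point sample.
#' @return Object of class `volume_fractions`: `ecs`, `astro`, `neuronal`,
#'   `n_points`, and `se`, the binomial standard error of the ECS estimate.
#' @export
estimate_fractions <- function(geometry, n_points = 1e5, seed = NULL) {
  stopifnot(inherits(geometry, "neuropil_geometry"), n_points >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  half <- geometry$params$arena_edge / 2
  pts <- matrix(runif(3 * n_points, -half, half), ncol = 3)
  cls <- .classify(pts, geometry$centers, geometry$radii, geometry$kinds,
                   geometry$params)
  ecs <- mean(cls == 0L)
  structure(list(
    ecs = ecs,
    astro = mean(cls == 2L),
    neuronal = mean(cls == 1L),
    n_points = as.integer(n_points),
    se = sqrt(ecs * (1 - ecs) / n_points)
  ), class = "volume_fractions")
}

#' @export
print.volume_fractions <- function(x, ...) {
  cat(sprintf(
    "Volume fractions (%d test points): ECS %.4f +/- %.4f, astroglial %.4f, neuronal %.4f\n",
    x$n_points, x$ecs, x$se, x$astro, x$neuronal))
  invisible(x)
}

#' Signed distance from points to the nearest cell surface
#'
#' Exact signed distance to the union surface of all spheres within
#' `max_radius` of each query point (positive in the extracellular space,
#' negative inside a cell), together with the kind and index of the
#' nearest sphere and the distance to the nearest astroglial surface.
#' Uses the uniform-grid spatial index; `use_index = FALSE` scans every
#' sphere and must give identical results.
#'
#' @param points Numeric 3-vector or n x 3 matrix (um).
#' @param geometry A `neuropil_geometry`.
#' @param max_radius Search radius, um; spheres whose surface is farther
#'   are ignored (`nearest_kind` = "none", distances `Inf`).
#' @param use_index Use the spatial index (default) or brute force.
#' @return data.frame with columns `distance`, `nearest_kind`
#'   ("neuronal", "astroglial", or "none"), `nearest_id`, `astro_distance`.
#' @export
query_surface <- function(points, geometry, max_radius = 0.5,
                          use_index = TRUE) {
  stopifnot(inherits(geometry, "neuropil_geometry"), max_radius > 0)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  res <- cpp_query_surface(points, geometry$centers,
                           as.numeric(geometry$radii),
                           as.integer(geometry$kinds),
                           geometry$params$arena_edge, geometry$cell_edge,
                           max_radius, isTRUE(use_index))
  data.frame(
    distance = res$distance,
    nearest_kind = c("none", "neuronal", "astroglial")[res$nearest_kind + 1L],
    nearest_id = res$nearest_id,
    astro_distance = res$astro_distance
  )
}

#' Minimal clearance between sphere surfaces and the synaptic cleft
#'
#' Computed analytically against the cleft cylinder; by construction it is
#' at least `cleft_exclusion` for every generated geometry.
#'
#' @param geometry A `neuropil_geometry`.
#' @return Minimal surface-to-cleft distance in um (`Inf` if no spheres).
#' @export
min_cleft_clearance <- function(geometry) {
  if (geometry$n_spheres == 0) return(Inf)
  min(.cleft_clearance(geometry$centers, geometry$radii, geometry$params))
}

#' @export
print.neuropil_geometry <- function(x, ...) {
  cat("Stochastic neuropil geometry (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  %d overlapping spheres (%d astroglial) in a %.2f um cube\n",
              x$n_spheres, sum(x$kinds == 2L), x$params$arena_edge))
  cat(sprintf("  realized alpha (ECS) %.4f (target %.3f, se %.4f)\n",
              x$realized_alpha, x$params$alpha_target, x$se_alpha))
  cat(sprintf("  realized astroglial tissue fraction %.4f (target %.3f)\n",
              x$realized_astro_fraction, x$params$astro_fraction_target))
  invisible(x)
}

#' Plot a cross-section of a neuropil geometry
#'
#' Draws the circles in which spheres intersect the plane `z = at`, with
#' neuronal spheres in green and astroglial in magenta, plus the cleft
#' outline when visible.
#'
#' @param x A `neuropil_geometry`.
#' @param at z position of the section plane, um. Default 0.
#' @param ... Passed to [graphics::plot()].
#' @importFrom graphics symbols rect legend
#' @export
plot.neuropil_geometry <- function(x, at = 0, ...) {
  half <- x$params$arena_edge / 2
  dz <- abs(x$centers[, 3] - at)
  vis <- dz < x$radii
  plot(NA, xlim = c(-half, half), ylim = c(-half, half), asp = 1,
       xlab = "x (um)", ylab = "y (um)",
       main = sprintf("neuropil section at z = %g um", at), ...)
  if (any(vis)) {
    rr <- sqrt(x$radii[vis]^2 - dz[vis]^2)
    col <- ifelse(x$kinds[vis] == 2L, grDevices::adjustcolor("magenta", 0.4),
                  grDevices::adjustcolor("darkgreen", 0.3))
    symbols(x$centers[vis, 1], x$centers[vis, 2], circles = rr,
            inches = FALSE, add = TRUE, fg = NA, bg = col)
  }
  if (abs(at) < x$cleft$half_height)
    symbols(0, 0, circles = x$cleft$radius, inches = FALSE, add = TRUE,
            fg = "black", bg = "white")
  legend("topright", legend = c("neuronal", "astroglial"), pch = 16,
         col = c("darkgreen", "magenta"), bty = "n", cex = 0.8)
  invisible(x)
}
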