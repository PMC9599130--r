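#' Radial concentration profile of free and bound glutamate
#'
#' Bins particles into concentric spherical shells centred on the cleft
#' centre, starting at the cleft boundary (the cleft radius, 60 nm by
#' default), and converts counts to micromolar via
#' `C = n / (N_A * V_ecs)`, where `V_ecs` is the extracellular volume of
#' each shell estimated by uniform test points. Free particles are binned
#' by current position; bound particles by their (frozen) binding site,
#' using the same ECS shell volume as denominator, so that bound glutamate
#' is reported in the same concentration units. Shells with zero estimated
#' ECS volume get `NA` concentrations (missing, not zero).
#'
#' Particles inside the cleft (below the first bin) and beyond `r_max`
#' are tallied in the `out_lo_*` / `out_hi_*` attributes, so that binned
#' counts plus out-of-range counts always equal the number of molecules.
#'
#' @param snapshot A `particle_ensemble` (see [get_snapshot()]).
#' @param geometry The `neuropil_geometry` the snapshot was simulated in.
#' @param bin_width Shell width, nm. Default 25.
#' @param n_test_points Test points for the shell-volume estimate.
#' @param seed Optional seed for the test-point sample.
#' @param r_max Outer profile radius, um. Default: half the arena edge.
#' @return A data.frame of class `concentration_profile` with columns
#'   `r_lo`, `r_hi`, `r_mid` (um from the cleft centre), `dist` (um beyond
#'   the cleft boundary), `free_n`, `bound_n`, `ecs_vol` (um^3),
#'   `free_uM`, `bound_uM`; snapshot time and out-of-range counts are
#'   carried as attributes.
#' @export
radial_profile <- function(snapshot, geometry, bin_width = 25,
                           n_test_points = 1e5, seed = NULL, r_max = NULL) {
  stopifnot(inherits(snapshot, "particle_ensemble"),
            inherits(geometry, "neuropil_geometry"))
  r0 <- geometry$cleft$radius
  if (is.null(r_max)) r_max <- geometry$params$arena_edge / 2
  bw <- bin_width / 1000
  edges <- seq(r0, r_max + bw / 2, by = bw)
  nb <- length(edges) - 1L
  ctr <- geometry$cleft$center

  pr <- sqrt(rowSums(sweep(snapshot$positions, 2, ctr)^2))
  free <- snapshot$state == 0L
  bin_of <- function(r) findInterval(r, edges, rightmost.closed = FALSE)
  tab <- function(r) tabulate(bin_of(r)[r >= edges[1] & r < edges[nb + 1]], nb)
  free_n <- tab(pr[free])
  bound_n <- tab(pr[!free])

  if (!is.null(seed)) set.seed(as.integer(seed))
  half <- geometry$params$arena_edge / 2
  pts <- matrix(runif(3 * n_test_points, -half, half), ncol = 3)
  cls <- .classify(pts, geometry$centers, geometry$radii, geometry$kinds,
                   geometry$params)
  tr <- sqrt(rowSums(sweep(pts, 2, ctr)^2))[cls == 0L]
  vol <- tabulate(bin_of(tr)[tr >= edges[1] & tr < edges[nb + 1]], nb) /
    n_test_points * geometry$params$arena_edge^3
  conc <- function(n) ifelse(vol > 0, .conc_uM(n, vol), NA_real_)

  out <- data.frame(
    r_lo = edges[-(nb + 1)], r_hi = edges[-1],
    r_mid = (edges[-(nb + 1)] + edges[-1]) / 2,
    dist = (edges[-(nb + 1)] + edges[-1]) / 2 - r0,
    free_n = free_n, bound_n = bound_n, ecs_vol = vol,
    free_uM = conc(free_n), bound_uM = conc(bound_n)
  )
  structure(out,
            class = c("concentration_profile", "data.frame"),
            time = snapshot$time, n_trials = 1L,
            n_molecules = nrow(snapshot$positions),
            cleft_radius = r0, bin_width = bin_width,
            out_lo_free = sum(free & pr < edges[1]),
            out_lo_bound = sum(!free & pr < edges[1]),
            out_hi_free = sum(free & pr >= edges[nb + 1]),
            out_hi_bound = sum(!free & pr >= edges[nb + 1]))
}

#' Average concentration profiles across trials
#'
#' Per-bin means of free and bound concentrations (and counts) across
#' trial profiles computed with identical binning, with per-bin standard
#' errors of the mean.
#'
#' @param profiles List of `concentration_profile` objects with identical
#'   bin edges.
#' @return A `concentration_profile` with added `free_se` and `bound_se`
#'   columns; attribute `n_trials` records the number averaged.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ref <- profiles[[1]]
  for (p in profiles)
    if (nrow(p) != nrow(ref) || any(abs(p$r_lo - ref$r_lo) > 1e-12))
      stop("profiles must share identical bin edges")
  n <- length(profiles)
  pull <- function(col)
    matrix(vapply(profiles, function(p) p[[col]], numeric(nrow(ref))),
           nrow = nrow(ref))
  avg <- ref
  for (col in c("free_n", "bound_n", "ecs_vol", "free_uM", "bound_uM"))
    avg[[col]] <- rowMeans(pull(col), na.rm = TRUE)
  avg$free_se <- apply(pull("free_uM"), 1, sd) / sqrt(n)
  avg$bound_se <- apply(pull("bound_uM"), 1, sd) / sqrt(n)
  for (a in c("out_lo_free", "out_lo_bound", "out_hi_free", "out_hi_bound"))
    attr(avg, a) <- mean(vapply(profiles, attr, numeric(1), a))
  attr(avg, "n_trials") <- sum(vapply(profiles, attr, integer(1), "n_trials"))
  avg
}

#' Per-bin free/bound concentration ratio
#'
#' Because free and bound species share the ECS shell-volume denominator,
#' the concentration ratio equals the raw count ratio bin by bin. Bins
#' with zero bound glutamate give `Inf` (or `NaN` when both are zero);
#' they are reported, never dropped.
#'
#' @param profile A `concentration_profile`.
#' @return data.frame with `r_mid`, `dist`, and `ratio`.
#' @export
free_bound_ratio <- function(profile) {
  stopifnot(inherits(profile, "concentration_profile"))
  data.frame(r_mid = profile$r_mid, dist = profile$dist,
             ratio = profile$free_uM / profile$bound_uM)
}

#' Free/bound ratio over a radial region
#'
#' Aggregates counts over all bins overlapping `[from, to]` and returns
#' the free/bound ratio of the region (shell volumes cancel).
#'
#' @param profile A `concentration_profile`.
#' @param from,to Region limits in nm.
#' @param origin `"center"`: distances from the cleft centre;
#'   `"boundary"`: distances beyond the cleft boundary.
#' @return Ratio of free to bound counts in the region (`Inf`/`NaN` when
#'   the bound count is zero).
#' @export
region_ratio <- function(profile, from, to, origin = c("center", "boundary")) {
  origin <- match.arg(origin)
  r0 <- if (origin == "boundary") attr(profile, "cleft_radius") else 0
  lo <- r0 + from / 1000
  hi <- r0 + to / 1000
  sel <- profile$r_hi > lo + 1e-12 & profile$r_lo < hi - 1e-12
  sum(profile$free_n[sel]) / sum(profile$bound_n[sel])
}

#' Length constant of a radial concentration profile
#'
#' The distance over which the profile decays to 1/e of its reference
#' value, the concentration in the first bin beyond the cleft boundary.
#' The crossing is located by linear interpolation between the bracketing
#' bins and measured from the centre of the reference bin, so an exactly
#' exponential profile returns its true constant irrespective of the bin
#' width. Profiles that never cross the 1/e level within the profiled
#' range are flagged undefined (`lambda = NA`).
#'
#' @param profile A `concentration_profile`.
#' @param species `"free"` or `"bound"`.
#' @return Object of class `length_constant`: `lambda` (um),
#'   `reference_value` (uM), `time` (ms), `species`, `defined`.
#' @export
length_constant <- function(profile, species = c("free", "bound")) {
  species <- match.arg(species)
  stopifnot(inherits(profile, "concentration_profile"))
  vals <- profile[[paste0(species, "_uM")]]
  r <- profile$r_mid
  if (is.na(vals[1]))
    stop("reference bin [", signif(profile$r_lo[1], 3), ", ",
         signif(profile$r_hi[1], 3), ") um has no estimated ECS volume")
  c0 <- vals[1]
  ok <- !is.na(vals)
  v <- vals[ok]; rr <- r[ok]
  res <- list(lambda = NA_real_, reference_value = c0,
              time = attr(profile, "time"), species = species,
              defined = FALSE)
  if (c0 > 0) {
    tgt <- c0 / exp(1)
    j <- which(v <= tgt)[1]
    if (!is.na(j) && j > 1) {
      r_star <- rr[j - 1] + (tgt - v[j - 1]) * (rr[j] - rr[j - 1]) /
        (v[j] - v[j - 1])
      res$lambda <- r_star - rr[1]
      res$defined <- TRUE
    }
  }
  structure(res, class = "length_constant")
}

#' @export
print.length_constant <- function(x, ...) {
  if (x$defined)
    cat(sprintf("lambda(%s, t = %.3g ms) = %.3f um (C0 = %.3g uM)\n",
                x$species, x$time, x$lambda, x$reference_value))
  else
    cat(sprintf("lambda(%s, t = %.3g ms) undefined (no 1/e decay; C0 = %.3g uM)\n",
                x$species, x$time, x$reference_value))
  invisible(x)
}

#' Space-averaged free glutamate concentration near the release site
#'
#' Counts free molecules within `r_max` of the cleft centre and divides by
#' Avogadro's number times the test-point-estimated extracellular volume
#' of that ball.
#'
#' @param snapshot A `particle_ensemble`.
#' @param geometry The matching `neuropil_geometry`.
#' @param r_max Radius of the averaging ball, um (at most half the arena
#'   edge).
#' @param n_test_points Test points for the ECS volume estimate.
#' @param seed Optional seed for the test-point sample.
#' @return Concentration in uM.
#' @export
space_average_concentration <- function(snapshot, geometry, r_max,
                                        n_test_points = 1e5, seed = NULL) {
  stopifnot(inherits(snapshot, "particle_ensemble"),
            r_max <= geometry$params$arena_edge / 2)
  ctr <- geometry$cleft$center
  pr <- sqrt(rowSums(sweep(snapshot$positions, 2, ctr)^2))
  n_free <- sum(snapshot$state == 0L & pr <= r_max)
  if (!is.null(seed)) set.seed(as.integer(seed))
  half <- geometry$params$arena_edge / 2
  pts <- matrix(runif(3 * n_test_points, -half, half), ncol = 3)
  cls <- .classify(pts, geometry$centers, geometry$radii, geometry$kinds,
                   geometry$params)
  inside <- sqrt(rowSums(sweep(pts, 2, ctr)^2)) <= r_max
  vol <- mean(cls == 0L & inside) * geometry$params$arena_edge^3
  if (vol == 0) return(0)
  .conc_uM(n_free, vol)
}

#' @export
print.concentration_profile <- function(x, ...) {
  cat(sprintf(
    "Radial concentration profile at t = %.3g ms (%d bins of %g nm, %d trial(s))\n",
    attr(x, "time"), nrow(x), attr(x, "bin_width"), attr(x, "n_trials")))
  print.data.frame(utils::head(as.data.frame(x), 8), digits = 4)
  if (nrow(x) > 8) cat("  ...", nrow(x) - 8, "more bins\n")
  invisible(x)
}

#' Plot free and bound concentration profiles
#'
#' @param x A `concentration_profile`.
#' @param log Plot concentrations on a log axis (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @importFrom graphics lines legend
#' @export
plot.concentration_profile <- function(x, log = TRUE, ...) {
  d <- x$dist * 1000
  ylim <- range(c(x$free_uM, x$bound_uM), na.rm = TRUE, finite = TRUE)
  if (log) ylim[1] <- max(ylim[1], 1e-3)
  plot(d, pmax(x$free_uM, if (log) 1e-3 else -Inf), type = "l", col = "red",
       log = if (log) "y" else "", ylim = ylim,
       xlab = "distance beyond cleft boundary (nm)",
       ylab = "concentration (uM)",
       main = sprintf("glutamate at t = %.3g ms", attr(x, "time")), ...)
  lines(d, pmax(x$bound_uM, if (log) 1e-3 else -Inf), col = "blue")
  legend("topright", c("free", "bound"), col = c("red", "blue"), lty = 1,
         bty = "n")
  invisible(x)
}
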