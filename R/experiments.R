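#' Run repeated release trials in fresh geometries
#'
#' Generates `n_trials` independent geometry realizations (one per trial,
#' mirroring the idea that every simulation run samples a new 'average'
#' synaptic environment), simulates a release in each, and averages the
#' radial concentration profiles per snapshot time. All per-trial seeds
#' derive deterministically from `seed_root` by one `sample.int()` draw,
#' so any trial can be reproduced in isolation.
#'
#' @param geometry_params A [geometry_params()].
#' @param config A [simulation_config()].
#' @param n_trials Number of independent trials. Default 10.
#' @param seed_root Integer master seed.
#' @param bin_width Profile bin width, nm.
#' @param n_test_points Test points per shell-volume estimate.
#' @param r_max Outer profile radius, um (default half arena edge).
#' @param keep_recordings Retain full recordings and geometries (memory
#'   permitting); profiles are always retained.
#' @return Object of class `trial_set`: `profiles` (trial-averaged
#'   [radial_profile()] per snapshot time, with per-bin standard errors),
#'   `per_trial` (per-trial profiles), `seeds`, and optionally
#'   `recordings` and `geometries`.
#' @export
run_trials <- function(geometry_params, config, n_trials = 10,
                       seed_root = 1L, bin_width = 25,
                       n_test_points = 1e5, r_max = NULL,
                       keep_recordings = FALSE) {
  stopifnot(inherits(geometry_params, "geometry_params"),
            inherits(config, "simulation_config"), n_trials >= 1)
  set.seed(as.integer(seed_root))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_trials),
                  ncol = 3,
                  dimnames = list(NULL, c("geometry", "release", "profile")))
  times <- config$snapshot_times
  per_trial <- vector("list", n_trials)
  recs <- if (keep_recordings) vector("list", n_trials)
  geoms <- if (keep_recordings) vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    g <- tryCatch(generate_geometry(geometry_params, seed = seeds[i, 1]),
                  error = function(e)
                    stop("trial ", i, " (geometry): ", conditionMessage(e)))
    rec <- tryCatch(simulate_release(g, config, seed = seeds[i, 2]),
                    error = function(e)
                      stop("trial ", i, " (release): ", conditionMessage(e)))
    set.seed(seeds[i, 3])
    per_trial[[i]] <- lapply(times, function(t)
      radial_profile(get_snapshot(rec, t), g, bin_width = bin_width,
                     n_test_points = n_test_points, r_max = r_max))
    names(per_trial[[i]]) <- as.character(times)
    if (keep_recordings) { recs[[i]] <- rec; geoms[[i]] <- g }
  }
  profiles <- lapply(as.character(times), function(t)
    average_profiles(lapply(per_trial, `[[`, t)))
  names(profiles) <- as.character(times)
  structure(list(
    profiles = profiles, per_trial = per_trial,
    recordings = recs, geometries = geoms,
    n_trials = as.integer(n_trials), seeds = seeds,
    config = config, geometry_params = geometry_params
  ), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("Trial set: %d trials, snapshots at %s ms\n", x$n_trials,
              paste(names(x$profiles), collapse = ", ")))
  invisible(x)
}

#' Sweep the binding time constant Psi against the ECS fraction alpha
#'
#' For every (Psi, alpha) grid cell, runs [run_trials()] and extracts the
#' length constant lambda of the free and bound glutamate profiles at each
#' requested timepoint. With `paired = TRUE` (the default) all cells share
#' the same per-trial seeds, so Psi/alpha contrasts are evaluated under
#' common random numbers.
#'
#' @param spec A [sweep_spec()].
#' @return Object of class `psi_alpha_sweep`: arrays `lambda_free` and
#'   `lambda_bound` of shape (Psi, alpha, time) in um (NA where the
#'   profile never decays to 1/e: masked, not zero), matching `se_*`
#'   arrays from the per-trial spread, and a tidy long-format `table`.
#' @export
sweep_psi_alpha <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  np <- length(spec$psi_values); na <- length(spec$alpha_values)
  nt <- length(spec$timepoints)
  dims <- c(np, na, nt)
  dn <- list(psi = as.character(spec$psi_values),
             alpha = as.character(spec$alpha_values),
             time = as.character(spec$timepoints))
  lf <- lb <- sf <- sb <- array(NA_real_, dims, dimnames = dn)
  set.seed(spec$seed_root)
  cell_seeds <- matrix(sample.int(.Machine$integer.max - 1L, np * na), np, na)
  rows <- list()
  for (i in seq_len(np)) for (j in seq_len(na)) {
    cfg <- spec$base_config
    cfg$psi <- spec$psi_values[i]
    cfg$snapshot_times <- sort(unique(spec$timepoints))
    par <- spec$base_geometry_params
    par$alpha_target <- spec$alpha_values[j]
    root <- if (spec$paired) spec$seed_root else cell_seeds[i, j]
    ts <- run_trials(par, cfg, n_trials = spec$n_trials, seed_root = root,
                     bin_width = spec$bin_width)
    for (k in seq_len(nt)) {
      tk <- as.character(spec$timepoints[k])
      for (sp in c("free", "bound")) {
        lam <- length_constant(ts$profiles[[tk]], sp)
        per <- vapply(ts$per_trial, function(pt) {
          l <- tryCatch(length_constant(pt[[tk]], sp), error = function(e) NULL)
          if (is.null(l) || !l$defined) NA_real_ else l$lambda
        }, numeric(1))
        se <- if (sum(!is.na(per)) > 1)
          sd(per, na.rm = TRUE) / sqrt(sum(!is.na(per))) else NA_real_
        if (sp == "free") {
          lf[i, j, k] <- if (lam$defined) lam$lambda else NA_real_
          sf[i, j, k] <- se
        } else {
          lb[i, j, k] <- if (lam$defined) lam$lambda else NA_real_
          sb[i, j, k] <- se
        }
        rows[[length(rows) + 1L]] <- data.frame(
          psi_ms = spec$psi_values[i], alpha = spec$alpha_values[j],
          time_ms = spec$timepoints[k], species = sp,
          lambda_um = if (lam$defined) lam$lambda else NA_real_,
          se = se, n_trials = spec$n_trials)
      }
    }
  }
  structure(list(
    lambda_free = lf, lambda_bound = lb, se_free = sf, se_bound = sb,
    table = do.call(rbind, rows), spec = spec
  ), class = "psi_alpha_sweep")
}

#' @export
print.psi_alpha_sweep <- function(x, ...) {
  cat("Psi x alpha sweep of glutamate length constants\n")
  for (k in dimnames(x$lambda_bound)$time) {
    cat(sprintf("  lambda_bound (um) at t = %s ms:\n", k))
    print(round(x$lambda_bound[, , k, drop = TRUE], 3))
  }
  invisible(x)
}

#' Heatmap of sweep length constants
#'
#' @param x A `psi_alpha_sweep`.
#' @param species `"bound"` or `"free"`.
#' @param time Timepoint (one of `spec$timepoints`). Default: last.
#' @param ... Passed to [graphics::image()].
#' @importFrom graphics image axis
#' @export
plot.psi_alpha_sweep <- function(x, species = c("bound", "free"),
                                 time = NULL, ...) {
  species <- match.arg(species)
  tp <- x$spec$timepoints
  if (is.null(time)) time <- tp[length(tp)]
  arr <- if (species == "bound") x$lambda_bound else x$lambda_free
  m <- arr[, , as.character(time), drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, length(x$spec$psi_values))
  image(seq_along(x$spec$psi_values), seq_along(x$spec$alpha_values), m,
        xlab = "Psi (ms)", ylab = "alpha", axes = FALSE,
        main = sprintf("lambda_%s (um) at %g ms", species, time), ...)
  axis(1, seq_along(x$spec$psi_values), x$spec$psi_values)
  axis(2, seq_along(x$spec$alpha_values), x$spec$alpha_values)
  invisible(x)
}
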