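# Activation-enthalpy estimators over an ensemble of adiabatic reaction
# paths.
#
# Two estimators, which differ because max/min do not commute with
# averaging:
#   * per-path:  average over paths of (highest energy on the path minus the
#     lowest energy at negative reaction coordinate), then subtract the
#     ZPE/thermal correction;
#   * mean-profile: average the profiles at each reaction-coordinate point
#     first, then take the extrema of the averaged profile.
# The per-path estimate always dominates the mean-profile one; their gap is
# a diagnostic for how well the transition-state positions of the paths
# align.

# Coerce a path or plain profile to data.frame(R, E_kcal).
.as_profile <- function(p) {
  if (inherits(p, "efmo_reaction_path")) {
    if (!all(p$converged)) {
      stop("path contains unconverged frames; rerun or pass allow_unconverged = TRUE")
    }
    return(data.frame(R = p$R, E = p$E * efmo_units$hartree_to_kcalmol))
  }
  if (is.data.frame(p) && all(c("R", "E") %in% names(p))) {
    return(data.frame(R = p$R, E = p$E))
  }
  stop("each path must be an efmo_reaction_path or a data.frame with R and E (kcal/mol)")
}

.profiles <- function(paths, allow_unconverged = FALSE) {
  if (inherits(paths, "efmo_reaction_path") || is.data.frame(paths)) {
    paths <- list(paths)
  }
  lapply(seq_along(paths), function(k) {
    p <- paths[[k]]
    if (allow_unconverged && inherits(p, "efmo_reaction_path")) {
      p <- data.frame(R = p$R, E = p$E * efmo_units$hartree_to_kcalmol)
    }
    prof <- tryCatch(.as_profile(p), error = function(e) {
      stop("path ", k, ": ", conditionMessage(e))
    })
    if (!any(prof$R < 0)) {
      stop("path ", k, " has no frame with a negative reaction coordinate")
    }
    prof
  })
}

#' Activation enthalpy: average of per-path barriers
#'
#' For each path the barrier is the highest energy anywhere on the path
#' minus the lowest energy among frames with negative reaction coordinate;
#' the estimate is the mean of those barriers minus the ZPE/thermal
#' correction, with the sample standard deviation across paths.
#'
#' @param paths A list of `efmo_reaction_path` objects and/or data frames
#'   with columns `R` (angstrom) and `E` (kcal/mol).
#' @param correction ZPE + thermal correction subtracted from the
#'   electronic barrier (kcal/mol); sign is taken as given.
#' @param allow_unconverged Accept paths with unconverged frames?
#' @return List: `barrier` (kcal/mol), `sd`, `se` (uncertainty of the mean,
#'   `sd/sqrt(N)`), `per_path` (data frame with each path's extrema).
#' @export
barrier_per_path <- function(paths, correction = 1.6,
                             allow_unconverged = FALSE) {
  profs <- .profiles(paths, allow_unconverged)
  per <- do.call(rbind, lapply(seq_along(profs), function(k) {
    p <- profs[[k]]
    imax <- which.max(p$E)
    neg <- p[p$R < 0, , drop = FALSE]
    imin <- which.min(neg$E)
    data.frame(path = k, E_max = p$E[imax], R_max = p$R[imax],
               E_min_negR = neg$E[imin], R_min = neg$R[imin],
               barrier = p$E[imax] - neg$E[imin])
  }))
  n <- nrow(per)
  list(barrier = mean(per$barrier) - correction,
       sd = if (n > 1) stats::sd(per$barrier) else 0,
       se = if (n > 1) stats::sd(per$barrier) / sqrt(n) else 0,
       n_paths = n, correction = correction, per_path = per)
}

#' Activation enthalpy: barrier of the averaged profile
#'
#' Averages the ensemble's energies at each reaction-coordinate grid point
#' first, then takes (maximum) minus (minimum at negative R) of the averaged
#' profile, minus the correction.  Paths scanned on one common grid align
#' exactly; paths on different grids are linearly interpolated onto the
#' shared overlapping grid (flagged in the result).
#'
#' @inheritParams barrier_per_path
#' @param align_tol Grid points closer than this (angstrom) are considered
#'   identical across paths.
#' @return List: `barrier` (kcal/mol), `profile` (data frame `R`, `E`),
#'   `resampled` flag, `n_paths`, `correction`.
#' @export
barrier_mean_profile <- function(paths, correction = 1.6,
                                 allow_unconverged = FALSE,
                                 align_tol = 1e-6) {
  profs <- .profiles(paths, allow_unconverged)
  grids <- lapply(profs, `[[`, "R")
  ref <- grids[[1]]
  same <- all(vapply(grids, function(g) {
    length(g) == length(ref) && max(abs(g - ref)) <= align_tol
  }, TRUE))
  resampled <- FALSE
  if (same) {
    E <- rowMeans(vapply(profs, `[[`, numeric(length(ref)), "E"))
    grid <- ref
  } else {
    lo <- max(vapply(grids, min, 0))
    hi <- min(vapply(grids, max, 0))
    if (lo >= hi) stop("path grids do not overlap; cannot average profiles")
    grid <- sort(unique(unlist(lapply(grids, function(g) g[g >= lo & g <= hi]))))
    E <- rowMeans(vapply(profs, function(p) {
      stats::approx(p$R, p$E, xout = grid)$y
    }, numeric(length(grid))))
    resampled <- TRUE
  }
  if (!any(grid < 0)) stop("averaged profile has no negative reaction coordinate")
  barrier <- max(E) - min(E[grid < 0]) - correction
  list(barrier = barrier, profile = data.frame(R = grid, E = E),
       resampled = resampled, n_paths = length(profs), correction = correction)
}

#' Summarize an ensemble of reaction paths
#'
#' Runs both activation-enthalpy estimators and reports their gap (a
#' transition-state-alignment diagnostic: the per-path estimator always
#' dominates, and the two agree when every path peaks at the same reaction
#' coordinate).
#'
#' @inheritParams barrier_per_path
#' @return An object of class `efmo_ensemble`: `n_paths`,
#'   `barrier_per_path` (+/- `sd`, `se`), `barrier_mean_profile`, `gap`,
#'   `correction`, `per_path`, `mean_profile`.
#' @export
ensemble_barriers <- function(paths, correction = 1.6,
                              allow_unconverged = FALSE) {
  e17 <- barrier_per_path(paths, correction, allow_unconverged)
  e18 <- barrier_mean_profile(paths, correction, allow_unconverged)
  structure(
    list(n_paths = e17$n_paths,
         barrier_per_path = e17$barrier, sd = e17$sd, se = e17$se,
         barrier_mean_profile = e18$barrier,
         gap = e17$barrier - e18$barrier,
         correction = correction,
         per_path = e17$per_path, mean_profile = e18$profile),
    class = "efmo_ensemble")
}

#' @export
print.efmo_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d reaction paths (correction %.2f kcal/mol):\n",
              x$n_paths, x$correction))
  cat(sprintf("  per-path barrier     : %.2f +/- %.2f kcal/mol (se %.2f)\n",
              x$barrier_per_path, x$sd, x$se))
  cat(sprintf("  mean-profile barrier : %.2f kcal/mol\n", x$barrier_mean_profile))
  cat(sprintf("  gap (TS alignment)   : %.2f kcal/mol\n", x$gap))
  invisible(x)
}
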