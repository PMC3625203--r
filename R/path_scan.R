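# Adiabatic reaction-path mapping: restrained minimization of the active
# region at stepped reaction-coordinate targets.
#
# The reaction coordinate is R = r(bond1) - r(bond2), the difference between
# the breaking-bond and forming-bond lengths (negative at the reactant,
# positive at the product).  Each scan step minimizes
#   E_FD(D) + sum_m 1/2 k (r_m - r_m,target)^2
# over the mobile Cartesian coordinates, starting from the previous step's
# optimized geometry, with both bond targets advanced by +/- dR/2 so R steps
# by dR.

#' Specify the two scanned bonds and the restraint force constant
#'
#' @param bond1 Length-2 integer vector: atoms of the breaking bond.
#' @param bond2 Length-2 integer vector: atoms of the forming bond.
#' @param k_force Harmonic force constant, kcal mol^-1 angstrom^-2.
#' @return An object of class `efmo_restraints`.
#' @export
restraint_spec <- function(bond1, bond2, k_force = 500) {
  stopifnot(length(bond1) == 2, length(bond2) == 2, k_force > 0)
  if (bond1[1] == bond1[2] || bond2[1] == bond2[2]) {
    stop("restrained bonds need two distinct atoms")
  }
  structure(list(bond1 = as.integer(bond1), bond2 = as.integer(bond2),
                 k_force = k_force),
            class = "efmo_restraints")
}

#' Reaction coordinate of a geometry
#'
#' `R = r(bond1) - r(bond2)` in angstrom: the breaking-bond length minus
#' the forming-bond length.
#'
#' @param system An `efmo_system`.
#' @param bond1,bond2 Length-2 atom index vectors (or an `efmo_restraints`
#'   as `bond1`).
#' @return Numeric (angstrom).
#' @export
reaction_coordinate <- function(system, bond1, bond2 = NULL) {
  if (inherits(bond1, "efmo_restraints")) {
    bond2 <- bond1$bond2
    bond1 <- bond1$bond1
  }
  xyz <- coords(system)
  r1 <- sqrt(sum((xyz[bond1[1], ] - xyz[bond1[2], ])^2))
  r2 <- sqrt(sum((xyz[bond2[1], ] - xyz[bond2[2], ])^2))
  r1 - r2
}

# restraint penalty and its gradient (hartree, hartree/bohr on system atoms)
.restraint_energy <- function(xyz, restraints, targets) {
  k_au <- restraints$k_force * efmo_units$kcalmol_to_hartree
  e <- 0
  g <- matrix(0, nrow(xyz), 3)
  bonds <- list(restraints$bond1, restraints$bond2)
  for (m in 1:2) {
    i <- bonds[[m]][1]; j <- bonds[[m]][2]
    d <- xyz[i, ] - xyz[j, ]
    r <- sqrt(sum(d^2))
    dr <- r - targets[m]
    e <- e + 0.5 * k_au * dr^2
    f <- k_au * dr * d / r * efmo_units$bohr_to_angstrom  # per-bohr gradient
    g[i, ] <- g[i, ] + f
    g[j, ] <- g[j, ] - f
  }
  list(energy = e, gradient = g)
}

#' Restrained minimization of the active region at fixed bond targets
#'
#' Quasi-Newton (L-BFGS-B) minimization of the frozen-domain energy plus the
#' harmonic bond restraints over the mobile Cartesian coordinates, converged
#' when the maximum absolute component of the objective gradient on mobile
#' atoms falls below `opttol`.  Frozen atoms are never touched.  The frame
#' stores the unrestrained energy and the restraint penalty separately.
#'
#' @param system A fragmented `efmo_system`.
#' @param regions An `efmo_regions` assignment; each restrained bond needs
#'   at least one mobile atom.
#' @param restraints An [restraint_spec()].
#' @param targets Length-2 numeric: target lengths for bond1 and bond2
#'   (angstrom).
#' @param opttol Gradient threshold, hartree/bohr.
#' @param mode `"FDD"` or `"FD"`.
#' @param levels Level specification (see [efmo_energy()]).
#' @param R_resdim Unitless dimer threshold.
#' @param session Calculation session (shared across a scan for caching).
#' @param max_iter Iteration cap; exceeding it flags the frame unconverged.
#' @return An `efmo_path_frame`: `system`, `R`, `E` (unrestrained, hartree),
#'   `E_restraint`, `converged`, `n_gradient_calls`, `targets`.
#' @export
restrained_minimize <- function(system, regions, restraints, targets,
                                opttol = 5e-4, mode = "FDD",
                                levels = level_spec(), R_resdim = 1.5,
                                session = new_session(), max_iter = 200) {
  mobile <- regions$mobile_atoms
  for (bd in list(restraints$bond1, restraints$bond2)) {
    if (!any(bd %in% mobile)) {
      stop("restrained bond ", bd[1], "-", bd[2], " has no mobile atom")
    }
  }
  a2b <- efmo_units$angstrom_to_bohr
  grad_calls <- 0L

  # L-BFGS-B asks for fn and gr at the same iterate; one evaluation with
  # gradient serves both
  memo <- new.env(parent = emptyenv())
  evaluate <- function(x_bohr) {
    if (!is.null(memo$x) && identical(memo$x, x_bohr)) return(memo$val)
    val <- tryCatch({
      sys <- system
      xyz <- coords(sys)
      xyz[mobile, ] <- matrix(x_bohr, ncol = 3) / a2b
      coords(sys) <- xyz
      rep <- .assemble(sys, regions, mode, R_resdim, levels, session, TRUE)
      pen <- .restraint_energy(coords(sys), restraints, targets)
      list(f = rep$E_total + pen$energy,
           g = as.numeric(rep$gradient[mobile, , drop = FALSE] +
                            pen$gradient[mobile, , drop = FALSE]))
    }, error = function(e) NULL)
    if (is.null(val) || !is.finite(val$f) || !all(is.finite(val$g))) {
      # line-search probe hit a singular or overflowing geometry: report a
      # large finite value so the optimizer backtracks
      val <- list(f = 1e6, g = rep(0, length(x_bohr)))
    }
    memo$x <- x_bohr
    memo$val <- val
    val
  }
  objective <- function(x_bohr) evaluate(x_bohr)$f
  gradient_fn <- function(x_bohr) {
    grad_calls <<- grad_calls + 1L
    evaluate(x_bohr)$g
  }

  x <- as.numeric(coords(system)[mobile, , drop = FALSE] * a2b)
  converged <- FALSE
  iter_left <- max_iter
  while (iter_left > 0) {
    chunk <- min(50L, iter_left)
    opt <- stats::optim(x, objective, gradient_fn, method = "L-BFGS-B",
                        control = list(maxit = chunk, factr = 10))
    x <- opt$par
    iter_left <- iter_left - chunk
    if (max(abs(gradient_fn(x))) <= opttol) { converged <- TRUE; break }
    if (opt$convergence == 0 && max(abs(gradient_fn(x))) > opttol) {
      # optimizer thinks it is done but the gradient test disagrees: nudge
      # on with a fresh L-BFGS memory; if no progress, give up below
      if (opt$counts[1] <= 1) break
    }
  }

  xyz <- coords(system)
  xyz[mobile, ] <- matrix(x, ncol = 3) / a2b
  out_sys <- system
  coords(out_sys) <- xyz
  rep <- .assemble(out_sys, regions, mode, R_resdim, levels, session, FALSE)
  pen <- .restraint_energy(coords(out_sys), restraints, targets)
  structure(
    list(system = out_sys, R = reaction_coordinate(out_sys, restraints),
         E = rep$E_total, E_restraint = pen$energy, converged = converged,
         n_gradient_calls = grad_calls, targets = targets),
    class = "efmo_path_frame")
}

#' Map an adiabatic reaction path by stepped restrained minimization
#'
#' Starting from the reactant geometry, the reaction coordinate target is
#' stepped by `dR` from `R_start` to `R_end`; each step's minimization
#' starts from the previous optimized geometry (adiabatic continuation).
#' The two bond targets move symmetrically by `dR/2` in opposite
#' directions.  Reported energies exclude the restraint penalty (both are
#' stored).
#'
#' @inheritParams restrained_minimize
#' @param R_start,R_end Scan end points for the reaction coordinate
#'   (angstrom); direction is normalized internally.
#' @param dR Step size, angstrom.
#' @param previous Optional `efmo_reaction_path` with identical settings to
#'   resume from its last converged frame.
#' @return An `efmo_reaction_path`: list of frames plus vectors `R`, `E`,
#'   `E_restraint`, `converged`, the settings `provenance` string and the
#'   total gradient-call count.
#' @export
scan_path <- function(system, regions, restraints, R_start, R_end, dR = 0.1,
                      opttol = 5e-4, mode = "FDD", levels = level_spec(),
                      R_resdim = 1.5, session = new_session(),
                      max_iter = 200, previous = NULL) {
  # the scan runs in the requested direction (adiabatic continuation from
  # the supplied geometry); frames are returned ordered by ascending R
  if (R_start == R_end) {
    Rtargets <- R_start
  } else {
    Rtargets <- seq(R_start, R_end, by = sign(R_end - R_start) * abs(dR))
  }

  xyz <- coords(system)
  r1_0 <- sqrt(sum((xyz[restraints$bond1[1], ] - xyz[restraints$bond1[2], ])^2))
  r2_0 <- sqrt(sum((xyz[restraints$bond2[1], ] - xyz[restraints$bond2[2], ])^2))
  R_0 <- r1_0 - r2_0

  provenance <- paste("scan", paste(restraints$bond1, collapse = "-"),
                      paste(restraints$bond2, collapse = "-"),
                      restraints$k_force, R_start, R_end, dR, opttol, mode,
                      R_resdim, sep = "|")
  frames <- list()
  start_idx <- 1L
  current <- system
  if (!is.null(previous)) {
    if (!identical(previous$provenance, provenance)) {
      stop("cannot resume: scan settings differ from the previous path")
    }
    done <- which(previous$converged)
    if (length(done)) {
      keep <- seq_len(max(done))
      frames <- previous$frames[keep]
      start_idx <- max(done) + 1L
      current <- frames[[length(frames)]]$system
    }
  }

  for (s in seq_len(length(Rtargets) - start_idx + 1L) + start_idx - 1L) {
    Rt <- Rtargets[s]
    targets <- c(r1_0 + (Rt - R_0) / 2, r2_0 - (Rt - R_0) / 2)
    frame <- restrained_minimize(current, regions, restraints, targets,
                                 opttol, mode, levels, R_resdim, session,
                                 max_iter)
    frames[[s]] <- frame
    current <- frame$system
  }

  frames <- frames[order(vapply(frames, `[[`, 0, "R"))]
  structure(
    list(frames = frames,
         R = vapply(frames, `[[`, 0, "R"),
         E = vapply(frames, `[[`, 0, "E"),
         E_restraint = vapply(frames, `[[`, 0, "E_restraint"),
         converged = vapply(frames, `[[`, TRUE, "converged"),
         n_gradient_calls = sum(vapply(frames, `[[`, 0L, "n_gradient_calls")),
         provenance = provenance),
    class = "efmo_reaction_path")
}

#' @export
print.efmo_reaction_path <- function(x, ...) {
  cat(sprintf("Reaction path: %d frames, R in [%.3f, %.3f] A, %d gradient calls%s\n",
              length(x$frames), min(x$R), max(x$R), x$n_gradient_calls,
              if (all(x$converged)) "" else "  [UNCONVERGED FRAMES]"))
  invisible(x)
}

#' @export
as.data.frame.efmo_reaction_path <- function(x, ...) {
  data.frame(step = seq_along(x$R), R_angstrom = x$R, E_hartree = x$E,
             E_rel_kcal = (x$E - x$E[1]) * efmo_units$hartree_to_kcalmol,
             E_restraint = x$E_restraint, converged = x$converged)
}

#' @export
plot.efmo_reaction_path <- function(x, ...) {
  df <- as.data.frame(x)
  plot(df$R_angstrom, df$E_rel_kcal, type = "b", pch = 19,
       xlab = "reaction coordinate R (angstrom)",
       ylab = "relative energy (kcal/mol)", ...)
  invisible(x)
}

#' Write a reaction path as an annotated multi-frame XYZ plus CSV profile
#'
#' @param path An `efmo_reaction_path`.
#' @param xyz_file,csv_file Output paths (either may be `NULL` to skip).
#' @return Invisibly, the path object.
#' @export
write_path <- function(path, xyz_file = NULL, csv_file = NULL) {
  if (!is.null(xyz_file)) {
    write_frames(lapply(path$frames, `[[`, "system"), xyz_file,
                 R = path$R, energy = path$E)
  }
  if (!is.null(csv_file)) {
    utils::write.csv(as.data.frame(path), csv_file, row.names = FALSE)
  }
  invisible(path)
}
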