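# Assembly of the EFMO total energy and gradient, full-system or
# frozen-domain.
#
# Full EFMO energy of N fragments:
#   E = sum_I E_I
#     + sum_{near pairs} [ (E_IJ - E_I - E_J) - E_pol,IJ ]
#     + sum_{far pairs}  E_es,IJ
#     + E_pol,tot
# where "near" means unitless interfragment distance below R_resdim (bonded
# neighbor pairs, which share an atom, are always near), E_es is the
# classical multipole electrostatic energy, E_pol,IJ the isolated-pair
# polarization energy and E_pol,tot the many-body polarization energy of
# the whole system.
#
# Frozen-domain (FD) variant for a region assignment A / b / F: all
# F-internal terms are constant and dropped; every coupling that touches F
# is classical; monomers and dimers are evaluated only inside B = A + b.
# FDD additionally skips QM dimers with both fragments in the buffer, which
# cannot contribute to the energy or gradient of A.  The total polarization
# energy always spans the whole system.
#
# One engine implements both, so fd_energy with empty buffer and frozen
# regions is *identical* (bit-for-bit) to efmo_energy.

# Resolve the level used for a fragment or a pair under multilayer tags.
.frag_level <- function(fragment, levels) {
  if (inherits(levels, "efmo_level")) return(levels)
  if (identical(fragment$layer, "high") && !is.null(levels$high)) levels$high else levels$low
}

.pair_level <- function(fi, fj, levels) {
  if (inherits(levels, "efmo_level")) return(levels)
  # mixed-layer pairs are computed at the low level
  if (identical(fi$layer, "high") && identical(fj$layer, "high") &&
      !is.null(levels$high)) levels$high else levels$low
}

#' Classify fragment pairs at a dimer threshold
#'
#' Near pairs (unitless interfragment distance below `R_resdim`) receive a
#' QM dimer correction; far pairs are treated with classical multipole
#' electrostatics.  Pairs of covalently bonded fragments (which share a
#' boundary atom) are always near.  Ordering is deterministic (`I < J`).
#'
#' @param system A fragmented `efmo_system`.
#' @param R_resdim Unitless distance threshold (`0` sends every non-bonded
#'   pair to the classical class).
#' @return List with data frames `near` and `far`, each with columns `I`,
#'   `J`, `R` and `bonded`.
#' @export
select_dimers <- function(system, R_resdim = 1.5) {
  stopifnot(R_resdim >= 0)
  frs <- system$fragments
  ids <- sort(vapply(frs, `[[`, 0L, "id"))
  np <- length(ids) * (length(ids) - 1L) %/% 2L
  I <- integer(np); J <- integer(np); R <- numeric(np); bonded <- logical(np)
  k <- 0L
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      k <- k + 1L
      I[k] <- ids[b]; J[k] <- ids[a]
      fi <- frs[[match(I[k], ids)]]; fj <- frs[[match(J[k], ids)]]
      bonded[k] <- length(intersect(fi$atoms, fj$atoms)) > 0
      R[k] <- interfragment_distance(system, I[k], J[k])
    }
  }
  all <- data.frame(I = I, J = J, R = R, bonded = bonded)
  near <- bonded | R < R_resdim
  list(near = all[near, , drop = FALSE], far = all[!near, , drop = FALSE])
}

#' Tag fragments with multilayer levels
#'
#' Fragments in `high_fragments` get the `"high"` layer tag, all others
#' `"low"`.  During assembly a fragment is computed at its own layer's
#' level; a pair spanning the two layers is computed at the low level.
#'
#' @param system A fragmented `efmo_system`.
#' @param high_fragments Fragment ids forming the high layer (may be empty).
#' @return The system with per-fragment `layer` tags set.
#' @export
assign_layers <- function(system, high_fragments = integer(0)) {
  ids <- vapply(system$fragments, `[[`, 0L, "id")
  if (!all(high_fragments %in% ids)) {
    stop("high_fragments contains unknown fragment id(s)")
  }
  for (k in seq_along(system$fragments)) {
    system$fragments[[k]]$layer <-
      if (ids[k] %in% high_fragments) "high" else "low"
  }
  system
}

# --- the engine ------------------------------------------------------------

# mode: "full", "FD", "FDD".  levels: an efmo_level or list(high=, low=).
# Returns the full decomposed report; gradient over all atoms when requested.
.assemble <- function(system, regions = NULL, mode = "full", R_resdim = 1.5,
                      levels = level_spec(), session = new_session(),
                      gradient = FALSE, pol_tol = 1e-8, pol_grad_h = 1e-4) {
  frs <- system$fragments
  if (is.null(frs)) stop("system has no fragments; run fragment_by_residue() first")
  ids <- sort(vapply(frs, `[[`, 0L, "id"))
  fr_of <- function(id) frs[[match(id, vapply(frs, `[[`, 0L, "id"))]]

  if (mode == "full") {
    A <- ids; B <- ids; Fz <- integer(0); bb <- integer(0)
  } else {
    if (is.null(regions)) stop("frozen-domain mode requires a region assignment")
    A <- regions$active; bb <- regions$buffer; Fz <- regions$frozen
    B <- sort(c(A, bb))
  }

  dimers <- select_dimers(system, R_resdim)
  allpairs <- rbind(
    if (nrow(dimers$near)) cbind(dimers$near, near = TRUE),
    if (nrow(dimers$far)) cbind(dimers$far, near = FALSE))
  if (is.null(allpairs)) {
    allpairs <- data.frame(I = integer(0), J = integer(0), R = numeric(0),
                           bonded = logical(0), near = logical(0))
  }

  # frozen-domain sanity: A must not be covalently bonded to F
  if (mode != "full" && nrow(allpairs)) {
    bad <- allpairs$bonded &
      ((allpairs$I %in% A & allpairs$J %in% Fz) |
         (allpairs$J %in% A & allpairs$I %in% Fz))
    if (any(bad)) {
      stop("active fragment covalently bonded to a frozen fragment; ",
           "enlarge the buffer so A and F are separated")
    }
  }

  n <- n_atoms(system)
  grad <- if (gradient) matrix(0, n, 3) else NULL
  add_backend_grad <- function(res, sign = 1) {
    if (gradient) grad[res$atoms, ] <<- grad[res$atoms, ] + sign * res$gradient
  }

  # monomers (inside B only; F-internal energies are constant and dropped)
  E_monomers <- stats::setNames(numeric(length(B)), B)
  for (id in B) {
    res <- compute_monomer(system, id, .frag_level(fr_of(id), levels),
                           session, gradient)
    E_monomers[as.character(id)] <- res$energy
    add_backend_grad(res)
  }

  any_pol <- .system_is_polarizable(system, levels, session)

  # pair terms
  dE_dimer <- numeric(0)
  E_es_far <- numeric(0)
  pair_class <- character(nrow(allpairs))
  if (nrow(allpairs)) {
    for (k in seq_len(nrow(allpairs))) {
      I <- allpairs$I[k]; J <- allpairs$J[k]
      near <- allpairs$near[k]
      inB <- (I %in% B) && (J %in% B)
      touchesF <- (I %in% Fz) || (J %in% Fz)
      bothF <- (I %in% Fz) && (J %in% Fz)
      bothb <- (I %in% bb) && (J %in% bb)
      key <- paste0(I, "-", J)
      lev <- .pair_level(fr_of(I), fr_of(J), levels)

      if (bothF) { cls <- "dropped (F-F)" }
      else if (near && inB && !(mode == "FDD" && bothb)) {
        resIJ <- compute_dimer(system, I, J, lev, session, gradient)
        resI <- compute_monomer(system, I, lev, session, gradient)
        resJ <- compute_monomer(system, J, lev, session, gradient)
        epIJ <- if (any_pol) pol_energy_pair(system, I, J, lev, session, pol_tol) else 0
        dE <- (resIJ$energy - resI$energy - resJ$energy) - epIJ
        dE_dimer[key] <- dE
        add_backend_grad(resIJ)
        add_backend_grad(resI, -1)
        add_backend_grad(resJ, -1)
        if (gradient && any_pol && epIJ != 0) {
          gp <- .pol_pair_grad_fd(system, I, J, lev, session, pol_tol, pol_grad_h)
          grad <- grad - gp
        }
        cls <- "near"
      } else if (near && inB && mode == "FDD" && bothb) {
        cls <- "skipped (b-b dimer, FDD)"
      } else if (!near && inB || (touchesF && !bothF)) {
        # classical electrostatics: far pairs inside B, and every coupling
        # between B and F (near or far -- F couplings are always classical)
        MI <- fragment_multipoles(system, I, .frag_level(fr_of(I), levels), session)
        MJ <- fragment_multipoles(system, J, .frag_level(fr_of(J), levels), session)
        E_es_far[key] <- pair_es_energy(MI, MJ)
        if (gradient) {
          ge <- pair_es_gradient(MI, MJ)
          grad[MI$atoms, ] <- grad[MI$atoms, ] + ge$grad_I
          grad[MJ$atoms, ] <- grad[MJ$atoms, ] + ge$grad_J
        }
        cls <- if (!near) "far" else "classical (F coupling)"
      } else {
        cls <- "dropped"
      }
      pair_class[k] <- cls
    }
  }

  # many-body polarization over the whole system, added once
  E_pol_tot <- if (any_pol) as.numeric(pol_energy_total(system, levels, session, pol_tol)) else 0
  if (gradient && any_pol && E_pol_tot != 0) {
    grad <- grad + .pol_total_grad_fd(system, levels, session, pol_tol, pol_grad_h)
  }

  E_total <- sum(E_monomers) + sum(dE_dimer) + sum(E_es_far) + E_pol_tot
  structure(
    list(E_total = E_total, E_monomers = E_monomers, dE_dimer = dE_dimer,
         E_es_far = E_es_far, E_pol_tot = E_pol_tot, gradient = grad,
         pair_list = if (nrow(allpairs)) cbind(allpairs[, c("I", "J", "R", "bonded")],
                                               class = pair_class) else NULL,
         mode = mode, R_resdim = R_resdim, regions = regions),
    class = "efmo_energy_report")
}

.system_is_polarizable <- function(system, levels, session) {
  levlist <- if (inherits(levels, "efmo_level")) list(levels) else
    Filter(Negate(is.null), levels)
  key <- paste("polflag", paste(vapply(levlist, .level_key, ""), collapse = "&"),
               sep = "|")
  hit <- session$moment_cache[[key]]
  if (!is.null(hit)) return(hit)
  ids <- vapply(system$fragments, `[[`, 0L, "id")
  flag <- FALSE
  for (id in ids) {
    lev <- .frag_level(system$fragments[[match(id, ids)]], levels)
    P <- fragment_polarizabilities(system, id, lev, session)
    if (any(vapply(P$alpha, function(a) max(abs(a)) > 0, TRUE))) { flag <- TRUE; break }
  }
  session$moment_cache[[key]] <- flag
  flag
}

# Central finite-difference gradients of the polarization energies.  The
# default build uses numeric polarization gradients (analytic response terms
# are out of scope); h is in bohr.
.pol_total_grad_fd <- function(system, levels, session, tol, h) {
  .fd_grad_all(system, function(s) {
    as.numeric(pol_energy_total(s, levels, session, tol))
  }, h)
}

.pol_pair_grad_fd <- function(system, I, J, lev, session, tol, h) {
  .fd_grad_all(system, function(s) pol_energy_pair(s, I, J, lev, session, tol), h)
}

.fd_grad_all <- function(system, fn, h) {
  hA <- h * efmo_units$bohr_to_angstrom
  xyz <- coords(system)
  g <- matrix(0, nrow(xyz), 3)
  for (i in seq_len(nrow(xyz))) {
    for (d in 1:3) {
      xp <- xyz; xp[i, d] <- xp[i, d] + hA
      xm <- xyz; xm[i, d] <- xm[i, d] - hA
      sp <- system; coords(sp) <- xp
      sm <- system; coords(sm) <- xm
      g[i, d] <- (fn(sp) - fn(sm)) / (2 * h)
    }
  }
  g
}

#' Full EFMO energy of a fragmented system
#'
#' Monomer energies plus QM dimer corrections for near pairs, classical
#' multipole electrostatics for far pairs, and the many-body polarization
#' energy added once.  The report is fully decomposed; its components sum
#' to `E_total` by construction.
#'
#' @param system A fragmented `efmo_system`.
#' @param levels An [level_spec()], or `list(high =, low =)` for multilayer
#'   runs with [assign_layers()] tags.
#' @param R_resdim Unitless dimer threshold (near pairs get QM dimers).
#' @param session Calculation session ([new_session()]).
#' @param gradient Also compute the analytic gradient?
#' @param pol_tol Induced-dipole solver tolerance.
#' @return An `efmo_energy_report`.
#' @export
efmo_energy <- function(system, levels = level_spec(), R_resdim = 1.5,
                        session = new_session(), gradient = FALSE,
                        pol_tol = 1e-8) {
  .assemble(system, NULL, "full", R_resdim, levels, session, gradient, pol_tol)
}

#' @rdname efmo_energy
#' @return `efmo_gradient()`: the `n x 3` gradient matrix (hartree/bohr).
#' @export
efmo_gradient <- function(system, levels = level_spec(), R_resdim = 1.5,
                          session = new_session(), pol_tol = 1e-8) {
  .assemble(system, NULL, "full", R_resdim, levels, session, TRUE, pol_tol)$gradient
}

#' Frozen-domain EFMO energy
#'
#' Energy of a region-partitioned system: the frozen region's internal
#' energy is constant and dropped, every coupling with the frozen region is
#' classical, monomers and QM dimers are evaluated only inside the active +
#' buffer block, and (in FDD mode) buffer-internal QM dimers are skipped as
#' well since they cannot affect the active region's energy or gradient.
#' The many-body polarization energy still spans the whole system.
#'
#' With empty buffer and frozen regions this reduces exactly to
#' [efmo_energy()].
#'
#' @inheritParams efmo_energy
#' @param regions An `efmo_regions` assignment.
#' @param mode `"FDD"` (skip buffer-internal dimers; the default) or `"FD"`.
#' @return An `efmo_energy_report` (with `mode` recorded).
#' @export
fd_energy <- function(system, regions, mode = c("FDD", "FD"),
                      levels = level_spec(), R_resdim = 1.5,
                      session = new_session(), gradient = FALSE,
                      pol_tol = 1e-8) {
  mode <- match.arg(mode)
  .assemble(system, regions, mode, R_resdim, levels, session, gradient, pol_tol)
}

#' @rdname fd_energy
#' @return `fd_gradient()`: gradient rows for the mobile atoms only, as a
#'   matrix with `rownames` giving the atom indices.
#' @export
fd_gradient <- function(system, regions, mode = c("FDD", "FD"),
                        levels = level_spec(), R_resdim = 1.5,
                        session = new_session(), pol_tol = 1e-8) {
  mode <- match.arg(mode)
  rep <- .assemble(system, regions, mode, R_resdim, levels, session, TRUE, pol_tol)
  g <- rep$gradient[regions$mobile_atoms, , drop = FALSE]
  rownames(g) <- regions$mobile_atoms
  g
}

#' @export
print.efmo_energy_report <- function(x, ...) {
  lab <- switch(x$mode, full = "EFMO", FD = "EFMO/FD", FDD = "EFMO/FDD")
  cat(sprintf("%s energy report (R_resdim = %g)\n", lab, x$R_resdim))
  cat(sprintf("  monomers      : %3d   sum = %+.10f hartree\n",
              length(x$E_monomers), sum(x$E_monomers)))
  cat(sprintf("  QM dimer corr.: %3d   sum = %+.10f\n",
              length(x$dE_dimer), sum(x$dE_dimer)))
  cat(sprintf("  classical ES  : %3d   sum = %+.10f\n",
              length(x$E_es_far), sum(x$E_es_far)))
  cat(sprintf("  E_pol,tot     :       %+.10f\n", x$E_pol_tot))
  cat(sprintf("  E_total       :       %+.10f hartree\n", x$E_total))
  invisible(x)
}
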