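# Synthetic-system generators: deterministic desk-scale fixtures exercising
# every part of the formalism -- water clusters (non-bonded fragmentation),
# covalently bonded chains (shared-atom fragmentation), a toy proton-transfer
# reaction with a two-bond reaction coordinate, and a small "protein" (chain
# plus solvent) for region assignment.
#
# Same (kind, parameters, seed) always yields a bit-identical system: all
# randomness goes through R's RNG seeded locally (the caller's RNG state is
# restored afterwards).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.random_rotation <- function() {
  # QR of a random normal matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# rigid water: O at origin, H's in the xz-plane at the mock equilibrium
# geometry (bond = covalent-radius sum, angle = the mock equilibrium angle),
# so an isolated water has exactly zero mock energy
.water_template <- function() {
  r0 <- covalent_radius("O") + covalent_radius("H")
  th <- mock_model_definition()$theta0
  rbind(O = c(0, 0, 0),
        H1 = r0 * c(sin(th / 2), 0, cos(th / 2)),
        H2 = r0 * c(-sin(th / 2), 0, cos(th / 2)))
}

.place_points <- function(n, radius, min_sep, max_attempts = 2000,
                          max_restarts = 200) {
  # sequential rejection sampling can dead-end at tight packings, so a
  # failed molecule restarts the whole configuration
  for (r in seq_len(max_restarts)) {
    pts <- matrix(0, 0, 3)
    for (k in seq_len(n)) {
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        p <- stats::runif(3, -radius, radius)
        if (sum(p^2) > radius^2) next
        if (nrow(pts) == 0 ||
            min(sqrt(rowSums((pts - matrix(p, nrow(pts), 3,
                                           byrow = TRUE))^2))) >= min_sep) {
          ok <- TRUE; break
        }
      }
      if (!ok) break
      pts <- rbind(pts, p)
    }
    if (nrow(pts) == n) return(pts)
  }
  stop("cannot place ", n, " molecules with separation ", min_sep,
       " angstrom in a sphere of radius ", radius, " angstrom")
}

#' Generate a random water cluster
#'
#' `n` rigid waters at the mock equilibrium geometry, oxygen positions drawn
#' uniformly in a sphere with a minimum O--O separation, random rigid
#' orientations; deterministic under `seed`.  The default sphere radius
#' scales as `1.93 n^(1/3)` angstrom (bulk-water-like density); a smaller
#' radius gives a compact hydrogen-bond-scale droplet.  The system comes
#' back bond-detected and fragmented at one water per fragment.
#'
#' @param n Number of waters.
#' @param seed RNG seed.
#' @param radius Placement sphere radius (angstrom); default `1.93 n^(1/3)`.
#' @param min_sep Minimum O--O separation (angstrom).
#' @return A fragmented `efmo_system`.
#' @export
make_water_cluster <- function(n, seed = 1, radius = NULL, min_sep = 2.6) {
  stopifnot(n >= 1)
  if (is.null(radius)) radius <- 1.93 * n^(1/3)
  tmpl <- .water_template()
  with_seed(seed, {
    centers <- if (n == 1) matrix(0, 1, 3) else .place_points(n, radius, min_sep)
    rows <- list()
    for (k in seq_len(n)) {
      Q <- .random_rotation()
      xyz <- tmpl %*% t(Q) + matrix(centers[k, ], 3, 3, byrow = TRUE)
      rows[[k]] <- data.frame(element = c("O", "H", "H"),
                              x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                              name = c("O", "H1", "H2"),
                              residue_id = k, residue_name = "HOH")
    }
    sys <- molecular_system(do.call(rbind, rows))
    fragment_by_residue(detect_bonds(sys))
  })
}

#' Generate a covalently bonded chain with shared-atom fragmentation
#'
#' A planar zig-zag chain of `n_frag` four-atom C/N units bonded head to
#' tail; every junction bond survives fragmentation as a shared boundary
#' atom, so the chain exercises the cross-region shared-atom machinery.
#' Bond lengths and angles sit at the mock equilibrium values, plus a small
#' deterministic jitter so no pair sits exactly on a classification
#' threshold.
#'
#' @param n_frag Number of units (>= 2); each becomes one fragment.
#' @param seed RNG seed for the jitter.
#' @param jitter Coordinate jitter amplitude (angstrom).
#' @return A fragmented `efmo_system` with `n_frag - 1` shared atoms.
#' @export
make_bonded_chain <- function(n_frag, seed = 1, jitter = 0.01) {
  stopifnot(n_frag >= 2)
  L <- covalent_radius("C") + covalent_radius("N")
  th <- mock_model_definition()$theta0
  gamma <- (pi - th) / 2
  n_atoms_total <- 4L * n_frag
  pos <- matrix(0, n_atoms_total, 3)
  for (k in 2:n_atoms_total) {
    dir <- if (k %% 2 == 0) c(cos(gamma), sin(gamma), 0) else c(cos(gamma), -sin(gamma), 0)
    pos[k, ] <- pos[k - 1, ] + L * dir
  }
  with_seed(seed, {
    pos <- pos + matrix(stats::runif(3 * n_atoms_total, -jitter, jitter),
                        n_atoms_total, 3)
    atoms <- data.frame(
      element = rep(c("C", "N", "C", "N"), n_frag),
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      residue_id = rep(seq_len(n_frag), each = 4L),
      residue_name = "UNT")
    fragment_by_residue(detect_bonds(molecular_system(atoms)))
  })
}

#' Generate a toy proton-transfer reaction
#'
#' A three-center exchange system on the mock potential: a proton (its own
#' `+1` fragment) shuttling along the axis between two anionic oxygen sites
#' (`-1` each), embedded in a shell of frozen waters.  The breaking bond is
#' donor--proton, the forming bond acceptor--proton, giving a reaction
#' coordinate running from about `-1.2` to `+1.2` angstrom with a barrier
#' near the midpoint.  The reference profile is computed at generation time
#' by dense constrained minimization of the proton position over an
#' `(r1, r2)` grid -- an oracle independent of the restrained-scan
#' machinery.
#'
#' @param seed RNG seed (placement of the solvent shell).
#' @param n_water Number of shell waters.
#' @param R_range Reaction-coordinate end points of the suggested scan
#'   (angstrom).
#' @param reference Also compute the grid-minimization reference profile?
#' @return List: `system` (fragmented), `restraints`
#'   ([restraint_spec()] with the paper-style 500 kcal/mol/A^2 constant),
#'   `regions` (proton active, donor/acceptor buffer, waters frozen),
#'   `R_range`, and `reference` (data frame `R`, `E_kcal` relative to the
#'   reactant well, plus attribute `"barrier_kcal"`).
#' @export
make_toy_reaction <- function(seed = 1, n_water = 6, R_range = c(-1.35, 1.35),
                              reference = TRUE) {
  b2a <- efmo_units$bohr_to_angstrom
  d <- 7.0 * b2a                      # donor-acceptor separation, angstrom
  r1_start <- (d + R_range[1]) / 2    # reactant donor-proton distance
  solute <- data.frame(
    element = c("O", "O", "H"),
    x = c(-d / 2, d / 2, -d / 2 + r1_start), y = 0, z = 0,
    name = c("OD", "OA", "HT"),
    residue_id = 1:3,
    residue_name = c("DNR", "ACC", "PRT"))
  tmpl <- .water_template()
  sys <- with_seed(seed, {
    # shell placement: radius 5.0-6.4 angstrom from the origin, 2.6 apart
    # (outside the buffer radius from any proton position along the scan)
    centers <- matrix(0, 0, 3)
    for (k in seq_len(n_water)) {
      ok <- FALSE
      for (a in 1:5000) {
        p <- stats::runif(3, -6.4, 6.4)
        r <- sqrt(sum(p^2))
        if (r < 5.0 || r > 6.4) next
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums((centers - matrix(p, nrow(centers), 3,
                                               byrow = TRUE))^2))) >= 2.6) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("cannot place the solvent shell")
      centers <- rbind(centers, p)
    }
    rows <- list(solute)
    for (k in seq_len(n_water)) {
      Q <- .random_rotation()
      xyz <- tmpl %*% t(Q) + matrix(centers[k, ], 3, 3, byrow = TRUE)
      rows[[k + 1]] <- data.frame(element = c("O", "H", "H"),
                                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                  name = c("O", "H1", "H2"),
                                  residue_id = 3L + k, residue_name = "HOH")
    }
    molecular_system(do.call(rbind, rows),
                     residue_charges = c("1" = -1, "2" = -1, "3" = 1))
  })
  sys <- fragment_by_residue(detect_bonds(sys))
  restraints <- restraint_spec(bond1 = c(1L, 3L), bond2 = c(2L, 3L),
                               k_force = 500)
  regions <- assign_regions(sys, target = 3L, R_active = 0.8, R_buffer = 3.0)
  ref <- if (reference) {
    toy_reaction_reference(sys, seq(R_range[1], R_range[2], by = 0.1))
  } else NULL
  list(system = sys, restraints = restraints, regions = regions,
       R_range = R_range, reference = ref)
}

#' Constrained-minimization reference profile for the toy reaction
#'
#' Independent oracle for [scan_path()]: the only proton-dependent terms of
#' the toy's frozen-domain energy are the proton's pair interactions (LJ +
#' Coulomb with the donor/acceptor oxygens, Coulomb with the frozen shell
#' charges), so the profile E(R) can be minimized directly over the proton
#' position parameterized by (r1, ring angle phi) with r2 = r1 - R held
#' exactly -- dense grid search refined by Nelder--Mead, no restraints and
#' no adiabatic continuation.  Returns the profile relative to the
#' reactant-side (R < 0) minimum, with the barrier as attribute
#' `"barrier_kcal"`.
#'
#' @param sys The toy reaction system from [make_toy_reaction()].
#' @param R_grid Reaction-coordinate values (angstrom) at which to evaluate.
#' @return Data frame `R`, `E_kcal` with attribute `"barrier_kcal"`.
#' @export
toy_reaction_reference <- function(sys, R_grid) {
  a2b <- efmo_units$angstrom_to_bohr
  mm <- mock_model_definition()
  q <- atom_charges(sys)
  xyz <- coords(sys) * a2b
  pOD <- xyz[1, ]; pOA <- xyz[2, ]
  d <- sqrt(sum((pOA - pOD)^2))
  u <- (pOA - pOD) / d
  n1 <- c(-u[2], u[1], 0); n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(u[2] * n1[3] - u[3] * n1[2],
          u[3] * n1[1] - u[1] * n1[3],
          u[1] * n1[2] - u[2] * n1[1])
  others <- setdiff(seq_len(nrow(xyz)), 3L)
  lj_atoms <- c(1L, 2L)   # donor/acceptor oxygens: QM dimers -> LJ + Coulomb
  eH <- function(p) {
    e <- 0
    for (j in others) {
      r <- sqrt(sum((p - xyz[j, ])^2))
      e <- e + q[3] * q[j] / r
      if (j %in% lj_atoms) {
        s6 <- (mm$sigma / r)^6
        e <- e + 4 * mm$epsilon * (s6^2 - s6)
      }
    }
    e
  }
  place <- function(r1, R, phi) {
    r2 <- r1 - R
    xproj <- (r1^2 - r2^2 + d^2) / (2 * d)
    rho2 <- r1^2 - xproj^2
    if (rho2 < 0) return(NULL)
    pOD + xproj * u + sqrt(rho2) * (cos(phi) * n1 + sin(phi) * n2)
  }
  E <- vapply(R_grid, function(Ra) {
    R <- Ra * a2b
    r1s <- seq((d + R) / 2 + 1e-6, (d + R) / 2 + 2.0, by = 0.02)
    phis <- seq(0, 2 * pi, length.out = 9)[-9]
    best <- Inf; best_par <- c(r1s[1], 0)
    for (r1 in r1s) {
      for (phi in phis) {
        p <- place(r1, R, phi)
        if (is.null(p)) next
        e <- eH(p)
        if (e < best) { best <- e; best_par <- c(r1, phi) }
      }
    }
    opt <- stats::optim(best_par, function(par) {
      p <- place(par[1], R, par[2])
      if (is.null(p)) return(Inf)
      eH(p)
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-12, maxit = 500))
    opt$value
  }, 0)
  Ek <- (E - min(E[R_grid < 0])) * efmo_units$hartree_to_kcalmol
  out <- data.frame(R = R_grid, E_kcal = Ek)
  attr(out, "barrier_kcal") <- max(Ek) - min(Ek[R_grid < 0])
  out
}

#' Generate a toy protein: bonded chain plus a solvent shell
#'
#' A [make_bonded_chain()] backbone surrounded by waters, for exercising
#' region assignment and frozen-domain bookkeeping on a system that has
#' both covalent inter-fragment boundaries and free solvent.
#'
#' @param n_res Number of chain units.
#' @param n_water Number of waters.
#' @param seed RNG seed.
#' @return A fragmented `efmo_system` (chain fragments first, then waters).
#' @export
make_toy_protein <- function(n_res = 6, n_water = 8, seed = 1) {
  chain <- make_bonded_chain(n_res, seed = seed)
  cxyz <- coords(chain)
  center <- colMeans(cxyz)
  span <- max(sqrt(rowSums((cxyz - matrix(center, nrow(cxyz), 3, byrow = TRUE))^2)))
  tmpl <- .water_template()
  with_seed(seed + 1000L, {
    rows <- list(chain$atoms[, c("element", "x", "y", "z", "name",
                                 "residue_id", "residue_name")])
    placed <- cxyz
    k <- 0L
    attempts <- 0L
    while (k < n_water) {
      attempts <- attempts + 1L
      if (attempts > 20000L) stop("cannot place solvent shell")
      p <- center + stats::runif(3, -(span + 6), span + 6)
      dmin <- min(sqrt(rowSums((placed - matrix(p, nrow(placed), 3, byrow = TRUE))^2)))
      if (dmin < 2.8 || dmin > 4.5) next
      k <- k + 1L
      Q <- .random_rotation()
      xyz <- tmpl %*% t(Q) + matrix(p, 3, 3, byrow = TRUE)
      rows[[k + 1]] <- data.frame(element = c("O", "H", "H"),
                                  x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                  name = c("O", "H1", "H2"),
                                  residue_id = n_res + k, residue_name = "HOH")
      placed <- rbind(placed, xyz)
    }
    sys <- molecular_system(do.call(rbind, rows))
    fragment_by_residue(detect_bonds(sys))
  })
}
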