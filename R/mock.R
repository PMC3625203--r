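# The deterministic analytic mock backend.
#
# The mock "QM" energy of any atom set is a tiny classical potential:
#   E = sum_bonds 1/2 k_b (r - r0)^2
#     + sum_angles 1/2 k_theta (theta - theta0)^2
#     + sum_{nonbonded pairs} [ 4 eps ((sigma/r)^12 - (sigma/r)^6) + q_i q_j / r ]
# in atomic units (bohr, hartree).  Bonds and angles come from the roster's
# bond topology; nonbonded pairs are all pairs excluding 1-2 and 1-3
# neighbors.  Equilibrium bond lengths r0 are covalent-radius sums; the
# equilibrium angle is one global constant.  Partial charges are the
# residue-neutralized element charges of [atom_charges()]; cap atoms carry
# charge 0.  Every constant lives in [mock_model_definition()].

#' Constants of the mock fragment backend
#'
#' Returns the full, versioned table of constants defining the analytic mock
#' potential and its electrostatic model.  These are package constants chosen
#' for numerical convenience, not values of any physical force field.
#'
#' @return Named list: `k_bond` (hartree/bohr^2), `k_angle` (hartree/rad^2),
#'   `theta0` (rad), `epsilon` (hartree), `sigma` (bohr), `element_charges`
#'   (e), `polarizability` (bohr^3, used by the `"mock-pol"` variant),
#'   `version`.
#' @export
mock_model_definition <- function() {
  list(
    version = "1",
    k_bond = 0.5,            # hartree / bohr^2
    k_angle = 0.1,           # hartree / rad^2
    theta0 = 104.52 * pi / 180,
    epsilon = 3e-4,          # hartree
    sigma = 3.0,             # bohr
    element_charges = c(O = -0.8, H = 0.4, N = -0.4, C = 0.0),
    # isotropic site polarizabilities for the "mock-pol" variant; small
    # enough that the undamped point-dipole model stays well away from the
    # polarization catastrophe at bonded distances
    polarizability = c(H = 0.4, O = 1.2, N = 1.5, C = 1.8)
  )
}

# Topology of a roster: angles (central atom + two bonded neighbors) and the
# nonbonded pair list (all pairs minus 1-2 and 1-3).
.mock_topology <- function(n, bonds) {
  nbr <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  angles <- list()
  for (c0 in seq_len(n)) {
    nb <- sort(nbr[[c0]])
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      for (k in seq_len(ncol(cmb))) {
        angles[[length(angles) + 1L]] <- c(cmb[1, k], c0, cmb[2, k])
      }
    }
  }
  excl <- matrix(FALSE, n, n)
  if (nrow(bonds)) {
    excl[bonds] <- TRUE
    excl[bonds[, c(2, 1), drop = FALSE]] <- TRUE
    for (c0 in seq_len(n)) {
      nb <- nbr[[c0]]
      if (length(nb) >= 2) {
        cmb <- utils::combn(nb, 2)
        excl[t(cmb)] <- TRUE
        excl[t(cmb[c(2, 1), , drop = FALSE])] <- TRUE
      }
    }
  }
  nb_pairs <- which(!excl & upper.tri(excl), arr.ind = TRUE)
  list(angles = angles, nonbonded = nb_pairs)
}

# Evaluate the mock potential for a roster.
#   xyz: n x 3 matrix in bohr; bonds: 2-col matrix of roster-local indices;
#   q: charges (e).  params may override constants (k_bond, k_angle, theta0,
#   epsilon, sigma, shift).
# Returns list(energy, gradient) with gradient in hartree/bohr (n x 3).
mock_eval <- function(elements, xyz, bonds, q, params = list(), gradient = TRUE) {
  mm <- utils::modifyList(mock_model_definition(), params)
  n <- nrow(xyz)
  g <- matrix(0, n, 3)
  e <- if (is.null(mm$shift)) 0 else mm$shift
  r0v <- covalent_radius(elements) * efmo_units$angstrom_to_bohr
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      i <- bonds[k, 1]; j <- bonds[k, 2]
      d <- xyz[i, ] - xyz[j, ]
      r <- sqrt(sum(d^2))
      r0 <- r0v[i] + r0v[j]
      e <- e + 0.5 * mm$k_bond * (r - r0)^2
      if (gradient) {
        f <- mm$k_bond * (r - r0) * d / r
        g[i, ] <- g[i, ] + f
        g[j, ] <- g[j, ] - f
      }
    }
  }
  topo <- .mock_topology(n, bonds)
  for (ang in topo$angles) {
    a <- ang[1]; c0 <- ang[2]; b <- ang[3]
    u <- xyz[a, ] - xyz[c0, ]
    v <- xyz[b, ] - xyz[c0, ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    ct <- sum(u * v) / (nu * nv)
    ct <- max(-1, min(1, ct))
    th <- acos(ct)
    e <- e + 0.5 * mm$k_angle * (th - mm$theta0)^2
    if (gradient) {
      st <- sqrt(max(1e-12, 1 - ct^2))
      ga <- (ct * u / nu - v / nv) / (nu * st)
      gb <- (ct * v / nv - u / nu) / (nv * st)
      pref <- mm$k_angle * (th - mm$theta0)
      g[a, ] <- g[a, ] + pref * ga
      g[b, ] <- g[b, ] + pref * gb
      g[c0, ] <- g[c0, ] - pref * (ga + gb)
    }
  }
  nb <- topo$nonbonded
  if (nrow(nb)) {
    di <- xyz[nb[, 1], , drop = FALSE] - xyz[nb[, 2], , drop = FALSE]
    r <- sqrt(rowSums(di^2))
    s6 <- (mm$sigma / r)^6
    qq <- q[nb[, 1]] * q[nb[, 2]]
    e <- e + sum(4 * mm$epsilon * (s6^2 - s6) + qq / r)
    if (gradient) {
      # dE/dr for LJ + Coulomb
      dEdr <- 4 * mm$epsilon * (-12 * s6^2 + 6 * s6) / r - qq / r^2
      fk <- di * (dEdr / r)
      for (k in seq_len(nrow(nb))) {
        g[nb[k, 1], ] <- g[nb[k, 1], ] + fk[k, ]
        g[nb[k, 2], ] <- g[nb[k, 2], ] - fk[k, ]
      }
    }
  }
  list(energy = e, gradient = if (gradient) g else NULL)
}
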