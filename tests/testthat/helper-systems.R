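# Shared fixtures and independent oracles, built in code.

A2B <- efmo_units$angstrom_to_bohr
B2A <- efmo_units$bohr_to_angstrom
H2K <- efmo_units$hartree_to_kcalmol

# a single water at the mock equilibrium geometry, O at `center`
water_atoms <- function(center = c(0, 0, 0), residue_id = 1L, rot = diag(3)) {
  r0 <- covalent_radius("O") + covalent_radius("H")
  th <- mock_model_definition()$theta0
  base <- rbind(c(0, 0, 0),
                r0 * c(sin(th / 2), 0, cos(th / 2)),
                r0 * c(-sin(th / 2), 0, cos(th / 2)))
  xyz <- base %*% t(rot) + matrix(center, 3, 3, byrow = TRUE)
  data.frame(element = c("O", "H", "H"), x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], residue_id = residue_id, residue_name = "HOH")
}

# n waters with O's at given centers (list or matrix of rows), fragmented
water_system <- function(centers, rots = NULL) {
  centers <- matrix(centers, ncol = 3)
  rows <- lapply(seq_len(nrow(centers)), function(k) {
    rot <- if (is.null(rots)) diag(3) else rots[[k]]
    water_atoms(centers[k, ], residue_id = k, rot = rot)
  })
  fragment_by_residue(detect_bonds(molecular_system(do.call(rbind, rows))))
}

# treat a fragmented system as one supermolecule fragment
as_single_fragment <- function(sys) {
  sys$fragments <- list(efmo:::new_fragment(1L, seq_len(n_atoms(sys))))
  sys
}

supermolecule_energy <- function(sys, level = level_spec()) {
  compute_monomer(as_single_fragment(sys), 1L, level, gradient = FALSE)$energy
}

random_rotation_matrix <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigid_transform <- function(sys, rot = random_rotation_matrix(),
                            shift = stats::rnorm(3)) {
  coords(sys) <- coords(sys) %*% t(rot) +
    matrix(shift, n_atoms(sys), 3, byrow = TRUE)
  sys
}

# brute-force Coulomb double sum between point-charge sets (positions bohr)
brute_coulomb <- function(p1, q1, p2, q2) {
  e <- 0
  for (i in seq_len(nrow(p1))) {
    for (j in seq_len(nrow(p2))) {
      e <- e + q1[i] * q2[j] / sqrt(sum((p1[i, ] - p2[j, ])^2))
    }
  }
  e
}

# central finite-difference gradient of an energy function of an efmo_system
fd_gradient_of <- function(sys, energy_fn, atoms = seq_len(n_atoms(sys)),
                           h_bohr = 1e-4) {
  g <- matrix(0, length(atoms), 3)
  hA <- h_bohr * B2A
  for (a in seq_along(atoms)) {
    for (d in 1:3) {
      sp <- sys; xyz <- coords(sp); xyz[atoms[a], d] <- xyz[atoms[a], d] + hA
      coords(sp) <- xyz
      sm <- sys; xyz <- coords(sm); xyz[atoms[a], d] <- xyz[atoms[a], d] - hA
      coords(sm) <- xyz
      g[a, d] <- (energy_fn(sp) - energy_fn(sm)) / (2 * h_bohr)
    }
  }
  g
}

# random multipole set: n sites near `center` with charges, dipoles and
# traceless quadrupoles
random_multipoles <- function(n, center = c(0, 0, 0), spread = 1) {
  pos <- matrix(stats::rnorm(3 * n, sd = spread), n, 3) +
    matrix(center, n, 3, byrow = TRUE)
  theta <- lapply(seq_len(n), function(i) {
    m <- matrix(stats::rnorm(9), 3, 3)
    m <- (m + t(m)) / 2
    m - diag(3) * sum(diag(m)) / 3
  })
  multipole_set(pos, q = stats::rnorm(n), mu = matrix(stats::rnorm(3 * n), n, 3),
                theta = theta)
}

# point-charge realization of one (q, mu, theta) site at `origin`: six
# charges on the axes at +-s plus structure reproducing the moments is
# awkward; instead draw random small-extent charges and *compute* their
# moments -- used the other way around (brute force vs multipole expansion)
random_charge_cloud <- function(origin = c(0, 0, 0), scale = 0.05, n = 8) {
  pts <- matrix(stats::runif(3 * n, -scale, scale), n, 3)
  qs <- stats::rnorm(n)
  th <- matrix(0, 3, 3)
  for (k in seq_len(n)) {
    r <- pts[k, ]
    th <- th + 0.5 * qs[k] * (3 * outer(r, r) - sum(r^2) * diag(3))
  }
  list(pts = pts + matrix(origin, n, 3, byrow = TRUE), qs = qs,
       q = sum(qs), mu = colSums(qs * pts), theta = th, origin = origin)
}

cloud_multipoles <- function(cloud) {
  multipole_set(matrix(cloud$origin, 1, 3), q = cloud$q,
                mu = matrix(cloud$mu, 1), theta = list(cloud$theta))
}

# independent dense solver for the induced-dipole equations: builds the
# 3N x 3N linear system from the textbook dipole field tensor
dense_induced_oracle <- function(pos, alphas, F_static) {
  n <- nrow(pos)
  Tij <- function(i, j) {
    R <- pos[j, ] - pos[i, ]
    r <- sqrt(sum(R^2))
    (3 * outer(R, R) - r^2 * diag(3)) / r^5
  }
  A <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    A[(i - 1) * 3 + 1:3, (i - 1) * 3 + 1:3] <- solve(alphas[[i]])
    for (j in seq_len(n)) {
      if (j != i) A[(i - 1) * 3 + 1:3, (j - 1) * 3 + 1:3] <- -Tij(i, j)
    }
  }
  mu <- solve(A, as.numeric(t(F_static)))
  mu <- matrix(mu, n, 3, byrow = TRUE)
  list(mu = mu, E_pol = -0.5 * sum(mu * F_static))
}

# random synthetic reaction-profile ensemble (kcal/mol), for the estimator
# oracles: each path has its own noisy double-well-ish shape on a common grid
random_ensemble <- function(n_paths, grid = seq(-2, 2, by = 0.2)) {
  lapply(seq_len(n_paths), function(k) {
    peak <- stats::runif(1, -0.5, 0.5)
    height <- stats::runif(1, 5, 25)
    E <- height * exp(-(grid - peak)^2) + stats::rnorm(length(grid), sd = 1)
    data.frame(R = grid, E = E)
  })
}
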