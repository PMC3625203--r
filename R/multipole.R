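# Distributed multipole electrostatics: atom-centered charges, dipoles and
# traceless (Buckingham) quadrupoles, interacting through Cartesian
# interaction tensors T^(n) = grad^n (1/r).  Energies, analytic gradients
# (frozen-moment convention) and electric fields.
#
# All quantities are atomic units: positions bohr, charges e, dipoles
# e*bohr, quadrupoles e*bohr^2, energies hartree.

#' Construct a multipole set
#'
#' @param pos `n x 3` matrix of site positions (bohr).
#' @param q Numeric vector of site charges (e).
#' @param mu `n x 3` matrix of site dipoles (e bohr), or `NULL` for zeros.
#' @param theta List of `n` traceless symmetric `3 x 3` quadrupoles
#'   (e bohr^2, Buckingham convention), or `NULL` for zeros.
#' @param atoms Optional integer vector mapping sites to system atoms.
#' @return An object of class `efmo_multipoles`.
#' @export
multipole_set <- function(pos, q, mu = NULL, theta = NULL, atoms = NULL) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  n <- nrow(pos)
  stopifnot(length(q) == n)
  if (is.null(mu)) mu <- matrix(0, n, 3)
  mu <- matrix(as.numeric(mu), ncol = 3)
  if (is.null(theta)) theta <- replicate(n, matrix(0, 3, 3), simplify = FALSE)
  for (k in seq_len(n)) {
    th <- theta[[k]]
    if (max(abs(th - t(th))) > 1e-12) stop("quadrupole ", k, " not symmetric")
    if (abs(sum(diag(th))) > 1e-12) stop("quadrupole ", k, " not traceless")
  }
  if (!all(is.finite(pos)) || !all(is.finite(q)) || !all(is.finite(mu))) {
    stop("non-finite multipole entries")
  }
  structure(list(pos = pos, q = as.numeric(q), mu = mu, theta = theta,
                 atoms = if (is.null(atoms)) rep(NA_integer_, n) else as.integer(atoms)),
            class = "efmo_multipoles")
}

#' Construct a polarizability set
#'
#' @param pos `n x 3` matrix of site positions (bohr).
#' @param alpha List of symmetric positive-semidefinite `3 x 3` tensors
#'   (bohr^3), or a numeric vector of isotropic values.
#' @param atoms Optional integer vector mapping sites to system atoms.
#' @return An object of class `efmo_polarizabilities`.
#' @export
polarizability_set <- function(pos, alpha, atoms = NULL) {
  pos <- matrix(as.numeric(pos), ncol = 3)
  n <- nrow(pos)
  if (is.numeric(alpha)) alpha <- lapply(alpha, function(a) diag(3) * a)
  stopifnot(length(alpha) == n)
  for (k in seq_len(n)) {
    a <- alpha[[k]]
    if (max(abs(a - t(a))) > 1e-12) stop("polarizability ", k, " not symmetric")
    if (min(eigen(a, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
      stop("polarizability ", k, " has a negative eigenvalue")
    }
  }
  structure(list(pos = pos, alpha = alpha,
                 atoms = if (is.null(atoms)) rep(NA_integer_, n) else as.integer(atoms)),
            class = "efmo_polarizabilities")
}

n_sites <- function(x) nrow(x$pos)

.has_higher_moments <- function(M) {
  max(abs(M$mu)) > 0 || any(vapply(M$theta, function(t) max(abs(t)), 0) > 0)
}

# --- interaction tensors ---------------------------------------------------

.dfact <- function(k) if (k <= 0) 1 else prod(seq(k, 1, by = -2))

# T^(n)(R) = grad^n (1/|R|) as a full 3^n array (n = 0..5), from the standard
# double-factorial expansion: (-1)^n [ (2n-1)!! R..R
#   - (2n-3)!! r^2 sum_{1 pair} delta R..R
#   + (2n-5)!! r^4 sum_{2 pairs} delta delta R..R ] / r^(2n+1).
t_tensor <- function(R, n) {
  r2 <- sum(R^2)
  r <- sqrt(r2)
  if (n == 0) return(1 / r)
  idx <- as.matrix(expand.grid(rep(list(1:3), n)))
  pairs <- if (n >= 2) utils::combn(n, 2) else NULL
  dpairs <- NULL
  if (n >= 4 && !is.null(pairs)) {
    np <- ncol(pairs)
    for (a in seq_len(np - 1)) {
      for (b in seq((a + 1), np)) {
        if (length(intersect(pairs[, a], pairs[, b])) == 0) {
          dpairs <- cbind(dpairs, c(pairs[, a], pairs[, b]))
        }
      }
    }
  }
  c0 <- .dfact(2 * n - 1)
  c1 <- .dfact(2 * n - 3)
  c2 <- .dfact(2 * n - 5)
  vals <- apply(idx, 1, function(ii) {
    v <- c0 * prod(R[ii])
    if (!is.null(pairs)) {
      s1 <- 0
      for (p in seq_len(ncol(pairs))) {
        pq <- pairs[, p]
        if (ii[pq[1]] == ii[pq[2]]) s1 <- s1 + prod(R[ii[-pq]])
      }
      v <- v - c1 * r2 * s1
    }
    if (!is.null(dpairs)) {
      s2 <- 0
      for (p in seq_len(ncol(dpairs))) {
        pq <- dpairs[, p]
        if (ii[pq[1]] == ii[pq[2]] && ii[pq[3]] == ii[pq[4]]) {
          s2 <- s2 + prod(R[ii[-pq]])
        }
      }
      v <- v + c2 * r2^2 * s2
    }
    v
  })
  array((-1)^n * vals / r^(2 * n + 1), dim = rep(3, n))
}

# Interaction energy of two single sites; R = pos_j - pos_i.
.site_pair_energy <- function(R, qi, mui, thi, qj, muj, thj) {
  T0 <- t_tensor(R, 0); T1 <- t_tensor(R, 1); T2 <- t_tensor(R, 2)
  e <- qi * qj * T0 +
    qi * sum(T1 * muj) - qj * sum(T1 * mui) +
    (qi * sum(T2 * thj) + qj * sum(T2 * thi)) / 3 -
    as.numeric(mui %*% T2 %*% muj)
  if (max(abs(thi)) > 0 || max(abs(thj)) > 0) {
    T3 <- t_tensor(R, 3)
    # contract T3_abc with mu_a theta_bc
    con3 <- function(mu, th) {
      s <- 0
      for (a in 1:3) s <- s + mu[a] * sum(T3[a, , ] * th)
      s
    }
    e <- e + (con3(muj, thi) - con3(mui, thj)) / 3
    T4 <- t_tensor(R, 4)
    s4 <- 0
    for (a in 1:3) for (b in 1:3) {
      s4 <- s4 + thi[a, b] * sum(T4[a, b, , ] * thj)
    }
    e <- e + s4 / 9
  }
  e
}

# d/dR of the pair energy (frozen moments); returns length-3 vector.
.site_pair_denergy <- function(R, qi, mui, thi, qj, muj, thj) {
  T1 <- t_tensor(R, 1); T2 <- t_tensor(R, 2); T3 <- t_tensor(R, 3)
  g <- numeric(3)
  for (e in 1:3) {
    g[e] <- qi * qj * T1[e] +
      qi * sum(T2[e, ] * muj) - qj * sum(T2[e, ] * mui) +
      (qi * sum(T3[e, , ] * thj) + qj * sum(T3[e, , ] * thi)) / 3 -
      as.numeric(mui %*% T3[e, , ] %*% muj)
  }
  if (max(abs(thi)) > 0 || max(abs(thj)) > 0) {
    T4 <- t_tensor(R, 4)
    T5 <- t_tensor(R, 5)
    for (e in 1:3) {
      s <- 0
      for (a in 1:3) {
        s <- s + (muj[a] * sum(T4[e, a, , ] * thi) -
                  mui[a] * sum(T4[e, a, , ] * thj)) / 3
      }
      s5 <- 0
      for (a in 1:3) for (b in 1:3) {
        s5 <- s5 + thi[a, b] * sum(T5[e, a, b, , ] * thj)
      }
      g[e] <- g[e] + s + s5 / 9
    }
  }
  g
}

.check_site_separation <- function(PI, PJ) {
  for (i in seq_len(n_sites(PI))) {
    d2 <- rowSums((PJ$pos - matrix(PI$pos[i, ], n_sites(PJ), 3, byrow = TRUE))^2)
    if (any(d2 < 1e-12)) {
      stop("singular geometry: multipole sites closer than 1e-6 bohr")
    }
  }
}

#' Classical electrostatic energy of two multipole sets
#'
#' Sum over site pairs of all interaction terms through
#' quadrupole--quadrupole, in the traceless Cartesian (Buckingham)
#' convention.  Symmetric under exchange of the two sets.  Charge-only sets
#' reduce exactly to the Coulomb double sum.
#'
#' @param M_I,M_J `efmo_multipoles` sets (no coincident sites across sets).
#' @return Energy in hartree.
#' @export
pair_es_energy <- function(M_I, M_J) {
  .check_site_separation(M_I, M_J)
  if (!.has_higher_moments(M_I) && !.has_higher_moments(M_J)) {
    # fast charge-only path (what the mock backend produces)
    d2 <- outer(rowSums(M_I$pos^2), rowSums(M_J$pos^2), `+`) -
      2 * M_I$pos %*% t(M_J$pos)
    return(sum(outer(M_I$q, M_J$q) / sqrt(pmax(d2, 0))))
  }
  e <- 0
  for (i in seq_len(n_sites(M_I))) {
    for (j in seq_len(n_sites(M_J))) {
      e <- e + .site_pair_energy(M_J$pos[j, ] - M_I$pos[i, ],
                                 M_I$q[i], M_I$mu[i, ], M_I$theta[[i]],
                                 M_J$q[j], M_J$mu[j, ], M_J$theta[[j]])
    }
  }
  e
}

#' Gradient of the classical electrostatic pair energy
#'
#' Analytic `-dE/dx` style derivatives under the frozen-moment convention
#' (multipole magnitudes and orientations held fixed, matching the
#' once-per-step moment evaluation of the energy model).  Returned as
#' `+dE/dx` per site, i.e. the gradient; Newton's third law holds between
#' the two sets.
#'
#' @inheritParams pair_es_energy
#' @return List with `grad_I`, `grad_J` (`n x 3` matrices, hartree/bohr) and
#'   `atoms_I`, `atoms_J` (site-to-atom maps carried by the sets).
#' @export
pair_es_gradient <- function(M_I, M_J) {
  .check_site_separation(M_I, M_J)
  nI <- n_sites(M_I); nJ <- n_sites(M_J)
  gI <- matrix(0, nI, 3); gJ <- matrix(0, nJ, 3)
  charge_only <- !.has_higher_moments(M_I) && !.has_higher_moments(M_J)
  for (i in seq_len(nI)) {
    for (j in seq_len(nJ)) {
      R <- M_J$pos[j, ] - M_I$pos[i, ]
      if (charge_only) {
        r <- sqrt(sum(R^2))
        dU <- -M_I$q[i] * M_J$q[j] * R / r^3
      } else {
        dU <- .site_pair_denergy(R, M_I$q[i], M_I$mu[i, ], M_I$theta[[i]],
                                 M_J$q[j], M_J$mu[j, ], M_J$theta[[j]])
      }
      gJ[j, ] <- gJ[j, ] + dU
      gI[i, ] <- gI[i, ] - dU
    }
  }
  list(grad_I = gI, grad_J = gJ, atoms_I = M_I$atoms, atoms_J = M_J$atoms)
}

#' Electric field of multipole sources at probe positions
#'
#' Field from charges, dipoles and quadrupoles of one or more sets,
#' evaluated at probe points (which must not coincide with source sites).
#'
#' @param sources A single `efmo_multipoles` set or a list of them.
#' @param probes `m x 3` matrix of probe positions (bohr).
#' @return `m x 3` matrix of fields (hartree/(e bohr)).
#' @export
field_at_sites <- function(sources, probes) {
  if (inherits(sources, "efmo_multipoles")) sources <- list(sources)
  probes <- matrix(as.numeric(probes), ncol = 3)
  F <- matrix(0, nrow(probes), 3)
  for (src in sources) {
    higher <- .has_higher_moments(src)
    for (p in seq_len(nrow(probes))) {
      for (s in seq_len(n_sites(src))) {
        R <- probes[p, ] - src$pos[s, ]
        r2 <- sum(R^2)
        if (r2 < 1e-12) stop("singular geometry: probe coincides with a source site")
        if (!higher) {
          F[p, ] <- F[p, ] + src$q[s] * R / (r2 * sqrt(r2))
          next
        }
        T1 <- t_tensor(R, 1); T2 <- t_tensor(R, 2); T3 <- t_tensor(R, 3)
        for (e in 1:3) {
          F[p, e] <- F[p, e] - (src$q[s] * T1[e] - sum(T2[e, ] * src$mu[s, ]) +
                                  sum(T3[e, , ] * src$theta[[s]]) / 3)
        }
      }
    }
  }
  F
}

#' Dump or restore multipole sets as plain text
#'
#' One site per line: `x y z q mux muy muz txx txy txz tyy tyz tzz`
#' (positions bohr, upper triangle of the traceless quadrupole).
#'
#' @param M An `efmo_multipoles` set.
#' @param path File path.
#' @return `write_multipoles()` invisibly returns `path`;
#'   `read_multipoles()` returns an `efmo_multipoles` set.
#' @export
write_multipoles <- function(M, path) {
  lines <- vapply(seq_len(n_sites(M)), function(i) {
    th <- M$theta[[i]]
    paste(sprintf("%.17g", c(M$pos[i, ], M$q[i], M$mu[i, ],
                             th[1, 1], th[1, 2], th[1, 3], th[2, 2], th[2, 3], th[3, 3])),
          collapse = " ")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_multipoles
#' @export
read_multipoles <- function(path) {
  m <- as.matrix(utils::read.table(path))
  theta <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, 8:13]
    matrix(c(v[1], v[2], v[3], v[2], v[4], v[5], v[3], v[5], v[6]), 3, 3)
  })
  multipole_set(m[, 1:3, drop = FALSE], q = m[, 4], mu = m[, 5:7, drop = FALSE],
                theta = theta)
}
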