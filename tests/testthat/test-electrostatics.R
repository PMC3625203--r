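# Distributed multipole electrostatics against closed forms and point-charge
# brute force.

test_that("charge-charge interactions follow Coulomb's law in atomic units", {
  M1 <- multipole_set(matrix(0, 1, 3), q = 1)
  M2 <- multipole_set(matrix(c(1, 0, 0), 1, 3), q = 1)
  expect_equal(pair_es_energy(M1, M2), 1)

  # force magnitude 1/R^2, repulsive for like charges
  M3 <- multipole_set(matrix(c(0, 0, 4), 1, 3), q = 1)
  g <- pair_es_gradient(M1, M3)
  expect_equal(g$grad_J[1, ], c(0, 0, -1 / 16), tolerance = 1e-14)
  expect_equal(g$grad_I[1, ], -g$grad_J[1, ], tolerance = 1e-14)
})

test_that("charge-dipole energy matches the closed form", {
  # dipole aligned with the separation: E = -q mu / R^2
  q <- 2; mu <- 0.3; R <- 5
  M1 <- multipole_set(matrix(0, 1, 3), q = q)
  M2 <- multipole_set(matrix(c(0, 0, R), 1, 3), q = 0,
                      mu = matrix(c(0, 0, mu), 1))
  expect_equal(pair_es_energy(M1, M2), -q * mu / R^2, tolerance = 1e-14)
  # anti-aligned flips the sign
  M3 <- multipole_set(matrix(c(0, 0, R), 1, 3), q = 0,
                      mu = matrix(c(0, 0, -mu), 1))
  expect_equal(pair_es_energy(M1, M3), q * mu / R^2, tolerance = 1e-14)
})

test_that("multipole expansion converges to charge-cloud brute force", {
  set.seed(31)
  A <- random_charge_cloud(c(0, 0, 0), scale = 0.05)
  err_at <- function(R) {
    B <- random_charge_cloud(R, scale = 0.05)
    e_mp <- pair_es_energy(cloud_multipoles(A), cloud_multipoles(B))
    e_bf <- brute_coulomb(A$pts, A$qs, B$pts, B$qs)
    abs(e_mp - e_bf) / abs(e_bf)
  }
  e20 <- err_at(c(20, 0, 0))
  e40 <- err_at(c(40, 0, 0))
  expect_lt(e20, 1e-4)
  expect_lt(e40, e20)   # truncation error falls off with distance
})

test_that("analytic pair gradients match finite differences", {
  set.seed(33)
  h <- 1e-5
  for (rep in 1:5) {
    MI <- random_multipoles(2, c(0, 0, 0))
    MJ <- random_multipoles(2, c(12, 3, -5))
    g <- pair_es_gradient(MI, MJ)
    for (s in 1:2) {
      for (d in 1:3) {
        Mp <- MJ; Mp$pos[s, d] <- Mp$pos[s, d] + h
        Mm <- MJ; Mm$pos[s, d] <- Mm$pos[s, d] - h
        fd <- (pair_es_energy(MI, Mp) - pair_es_energy(MI, Mm)) / (2 * h)
        expect_lt(abs(fd - g$grad_J[s, d]), 1e-7)
      }
    }
    # momentum conservation between the two sets
    expect_lt(max(abs(colSums(g$grad_I) + colSums(g$grad_J))), 1e-12)
  }
})

test_that("pair energy is exchange symmetric and rotation invariant", {
  set.seed(35)
  rot_set <- function(M, Q) {
    M$pos <- M$pos %*% t(Q)
    M$mu <- M$mu %*% t(Q)
    M$theta <- lapply(M$theta, function(th) Q %*% th %*% t(Q))
    M
  }
  for (rep in 1:5) {
    MI <- random_multipoles(3, c(0, 0, 0))
    MJ <- random_multipoles(3, c(15, -4, 8))
    e <- pair_es_energy(MI, MJ)
    expect_equal(pair_es_energy(MJ, MI), e, tolerance = 1e-12)
    Q <- random_rotation_matrix()
    expect_equal(pair_es_energy(rot_set(MI, Q), rot_set(MJ, Q)), e,
                 tolerance = 1e-10)
  }
})

test_that("charge-only sets reproduce the Coulomb double sum exactly", {
  set.seed(37)
  p1 <- matrix(stats::rnorm(9), 3, 3)
  p2 <- matrix(stats::rnorm(9), 3, 3) + 10
  q1 <- stats::rnorm(3); q2 <- stats::rnorm(3)
  M1 <- multipole_set(p1, q = q1)
  M2 <- multipole_set(p2, q = q2)
  expect_equal(pair_es_energy(M1, M2), brute_coulomb(p1, q1, p2, q2),
               tolerance = 1e-14)
})

test_that("coincident sites across sets are a singular-geometry error", {
  M1 <- multipole_set(matrix(0, 1, 3), q = 1)
  M2 <- multipole_set(matrix(1e-8, 1, 3), q = 1)
  expect_error(pair_es_energy(M1, M2), "singular")
})

test_that("fields follow closed forms and superpose linearly", {
  Mq <- multipole_set(matrix(0, 1, 3), q = 1)
  expect_equal(field_at_sites(Mq, matrix(c(2, 0, 0), 1)),
               matrix(c(0.25, 0, 0), 1), tolerance = 1e-14)

  # physical two-charge dipole vs the point-dipole field at 30 bohr
  mu <- c(0.2, -0.1, 0.3)
  Q <- 10
  phys <- multipole_set(rbind(mu / (2 * Q), -mu / (2 * Q)), q = c(Q, -Q))
  pt <- multipole_set(matrix(0, 1, 3), q = 0, mu = matrix(mu, 1))
  probe <- matrix(c(30, 5, -4), 1)
  Fp <- field_at_sites(phys, probe)
  Ft <- field_at_sites(pt, probe)
  expect_lt(sqrt(sum((Fp - Ft)^2)) / sqrt(sum(Ft^2)), 1e-3)

  # superposition
  set.seed(39)
  S1 <- random_multipoles(2, c(0, 0, 0))
  S2 <- random_multipoles(2, c(8, 8, 0))
  probes <- matrix(stats::rnorm(6) + 20, 2, 3)
  expect_equal(field_at_sites(list(S1, S2), probes),
               field_at_sites(S1, probes) + field_at_sites(S2, probes),
               tolerance = 1e-12)
})

test_that("multipole sets validate and round-trip through the text dump", {
  expect_error(multipole_set(matrix(0, 1, 3), q = 1,
                             theta = list(diag(3))), "traceless")
  bad <- matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(multipole_set(matrix(0, 1, 3), q = 1, theta = list(bad)),
               "symmetric")
  set.seed(41)
  M <- random_multipoles(3, c(0, 0, 0))
  f <- withr::local_tempfile()
  write_multipoles(M, f)
  back <- read_multipoles(f)
  expect_equal(back$pos, M$pos)
  expect_equal(back$q, M$q)
  expect_equal(back$mu, M$mu)
  for (k in 1:3) expect_equal(back$theta[[k]], M$theta[[k]])
})
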