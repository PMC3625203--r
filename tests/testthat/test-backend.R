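# The mock fragment backend: closed forms, caps, gradients, invariances and
# call accounting.

test_that("mock monomer energy vanishes at the equilibrium water geometry", {
  w <- water_system(c(0, 0, 0))
  res <- compute_monomer(w, 1L)
  expect_equal(res$energy, 0)
  expect_lt(max(abs(res$gradient)), 1e-12)
})

test_that("an O-H stretch costs the closed-form harmonic energy", {
  w <- water_system(c(0, 0, 0))
  xyz <- coords(w)
  u <- xyz[2, ] - xyz[1, ]
  xyz[2, ] <- xyz[1, ] + (1 + 0.1 / sqrt(sum(u^2))) * u   # +0.1 angstrom
  coords(w) <- xyz
  k_b <- mock_model_definition()$k_bond
  expect_equal(compute_monomer(w, 1L, gradient = FALSE)$energy,
               0.5 * k_b * (0.1 * A2B)^2, tolerance = 1e-12)
})

test_that("monomer energy and gradient are translation invariant", {
  w <- make_water_cluster(1, seed = 3)
  xyz <- coords(w); xyz[2, ] <- xyz[2, ] + c(0.08, -0.03, 0.05)  # distort
  coords(w) <- xyz
  base <- compute_monomer(w, 1L)
  wt <- w
  coords(wt) <- coords(wt) + matrix(c(5, -3, 2), n_atoms(w), 3, byrow = TRUE)
  moved <- compute_monomer(wt, 1L)
  expect_equal(moved$energy, base$energy, tolerance = 1e-12)
  expect_equal(moved$gradient, base$gradient, tolerance = 1e-12)
})

test_that("mock energy is invariant under global rotation", {
  set.seed(21)
  sys <- as_single_fragment(make_water_cluster(3, seed = 21, radius = 2.2))
  e0 <- compute_monomer(sys, 1L, gradient = FALSE)$energy
  for (k in 1:10) {
    er <- compute_monomer(rigid_transform(sys), 1L, gradient = FALSE)$energy
    expect_equal(er, e0, tolerance = 1e-10)
  }
})

test_that("dimer correction equals the intermolecular pair sum", {
  sys <- water_system(rbind(c(0, 0, 0), c(3, 0, 0)))
  s <- new_session()
  eI <- compute_monomer(sys, 1L, session = s, gradient = FALSE)$energy
  eJ <- compute_monomer(sys, 2L, session = s, gradient = FALSE)$energy
  eIJ <- compute_dimer(sys, 1L, 2L, session = s, gradient = FALSE)$energy
  # oracle: direct LJ + Coulomb sum over the 9 intermolecular pairs
  mm <- mock_model_definition()
  q <- atom_charges(sys)
  xyz <- coords(sys) * A2B
  e_ref <- 0
  for (i in 1:3) {
    for (j in 4:6) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      s6 <- (mm$sigma / r)^6
      e_ref <- e_ref + 4 * mm$epsilon * (s6^2 - s6) + q[i] * q[j] / r
    }
  }
  expect_equal(eIJ - eI - eJ, e_ref, tolerance = 1e-13)
})

test_that("a far-separated dimer correction reduces to the point-charge sum", {
  sys <- water_system(rbind(c(0, 0, 0), c(50, 0, 0)))
  eI <- compute_monomer(sys, 1L, gradient = FALSE)$energy
  eJ <- compute_monomer(sys, 2L, gradient = FALSE)$energy
  eIJ <- compute_dimer(sys, 1L, 2L, gradient = FALSE)$energy
  q <- atom_charges(sys)
  xyz <- coords(sys) * A2B
  e_coul <- brute_coulomb(xyz[1:3, ], q[1:3], xyz[4:6, ], q[4:6])
  expect_lt(abs((eIJ - eI - eJ) - e_coul), 1e-10)
  expect_error(compute_dimer(sys, 1L, 1L), "distinct")
})

test_that("link caps sit on the severed bond axis and map back by chain rule", {
  ch <- make_bonded_chain(2, seed = 7)
  fr <- ch$fragments[[1]]
  capped <- cap_fragment(ch, fr$atoms, d_cap = 1.09)
  expect_equal(nrow(capped$caps), 1)
  a <- capped$caps$anchor[1]; b <- capped$caps$partner[1]
  xyz <- coords(ch)
  u <- xyz[b, ] - xyz[a, ]
  cap <- as.numeric(capped$caps[1, c("x", "y", "z")])
  # on the axis, at d_cap from the anchor
  expect_equal(sqrt(sum((cap - xyz[a, ])^2)), 1.09, tolerance = 1e-12)
  cross <- c(u[2] * (cap - xyz[a, ])[3] - u[3] * (cap - xyz[a, ])[2],
             u[3] * (cap - xyz[a, ])[1] - u[1] * (cap - xyz[a, ])[3],
             u[1] * (cap - xyz[a, ])[2] - u[2] * (cap - xyz[a, ])[1])
  expect_lt(max(abs(cross)), 1e-12)

  # d_cap equal to the bond length puts the cap on the partner atom
  capped2 <- cap_fragment(ch, fr$atoms, d_cap = sqrt(sum(u^2)))
  expect_equal(as.numeric(capped2$caps[1, c("x", "y", "z")]), unname(xyz[b, ]),
               tolerance = 1e-12)

  # a fragment with no severed bonds needs no caps
  w <- water_system(c(0, 0, 0))
  expect_equal(nrow(cap_fragment(w, 1:3)$caps), 0)
})

test_that("capped monomer gradients match finite differences, including the
           cap chain rule onto boundary atoms", {
  ch <- make_bonded_chain(3, seed = 9)
  res <- compute_monomer(ch, 2L)
  # differentiate w.r.t. every atom the gradient claims to touch (roster
  # plus outside cap partners)
  for (a in res$atoms) {
    fd <- fd_gradient_of(ch, function(s) {
      compute_monomer(s, 2L, gradient = FALSE)$energy
    }, atoms = a)
    expect_lt(max(abs(fd - res$gradient[match(a, res$atoms), ])), 1e-7)
  }
})

test_that("isolated-system mock gradients carry no net force or torque", {
  sys <- as_single_fragment(make_water_cluster(4, seed = 13, radius = 2.2))
  res <- compute_monomer(sys, 1L)
  expect_lt(max(abs(colSums(res$gradient))), 1e-8)
  xyz <- coords(sys) * A2B
  forces <- -res$gradient
  torque <- c(0, 0, 0)
  for (i in seq_len(nrow(xyz))) {
    r <- xyz[i, ]; f <- forces[i, ]
    torque <- torque + c(r[2] * f[3] - r[3] * f[2],
                         r[3] * f[1] - r[1] * f[3],
                         r[1] * f[2] - r[2] * f[1])
  }
  expect_lt(max(abs(torque)), 1e-8)
})

test_that("the backend registry is pure: identical inputs, identical results", {
  w <- make_water_cluster(2, seed = 17)
  r1 <- compute_monomer(w, 1L)
  r2 <- compute_monomer(w, 1L)
  expect_identical(r1$energy, r2$energy)
  expect_identical(r1$gradient, r2$gradient)
  expect_error(level_spec("no-such-backend"), "no backend registered")
})

test_that("sessions cache by coordinates and count only real backend calls", {
  w <- make_water_cluster(2, seed = 19)
  s <- new_session()
  compute_monomer(w, 1L, session = s)
  compute_monomer(w, 1L, session = s)                    # cache hit
  expect_equal(unname(session_counts(s)["monomer"]), 1L)
  wm <- w
  coords(wm) <- coords(wm) + 0.1                          # geometry changed
  compute_monomer(wm, 1L, session = s)
  expect_equal(unname(session_counts(s)["monomer"]), 2L)
})

test_that("level parameters reach the mock potential", {
  w <- water_system(c(0, 0, 0))
  xyz <- coords(w); xyz[2, 1] <- xyz[2, 1] + 0.05; coords(w) <- xyz
  e1 <- compute_monomer(w, 1L, level_spec("mock"), gradient = FALSE)$energy
  e2 <- compute_monomer(w, 1L, level_spec("mock", params = list(k_bond = 1.0)),
                        gradient = FALSE)$energy
  expect_gt(e2, e1)
  e3 <- compute_monomer(w, 1L, level_spec("mock", params = list(shift = 0.25)),
                        gradient = FALSE)$energy
  expect_equal(e3, e1 + 0.25, tolerance = 1e-13)
})
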