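# Restrained minimization and adiabatic scanning: coordinate bookkeeping,
# convergence semantics and the frozen-atom contract.  (The full
# barrier-recovery comparison against the grid oracle lives in the
# acceptance suite.)

test_that("the reaction coordinate is the breaking minus forming bond length", {
  sys <- molecular_system(data.frame(
    element = c("C", "O", "C", "C"),
    x = c(0, 2.0, 5.0, 6.5), y = 0, z = 0, residue_id = 1:4))
  expect_equal(reaction_coordinate(sys, c(1, 2), c(3, 4)), 0.5)  # 2.0 - 1.5
  expect_equal(reaction_coordinate(sys, c(1, 2), c(1, 2)), 0)
  # bond lengths chosen to realize a reactant-like coordinate of -1.95
  sys2 <- molecular_system(data.frame(
    element = c("O", "C", "C", "C"),
    x = c(0, 1.42, 5.0, 8.37), y = 0, z = 0, residue_id = 1:4))
  expect_equal(reaction_coordinate(sys2, c(1, 2), c(3, 4)), -1.95)
})

test_that("a restraint at the potential minimum converges with ~zero penalty", {
  # both restrained bonds of a lone water held at their equilibrium lengths
  w <- water_system(c(0, 0, 0))
  reg <- region_assignment(w, active = 1L, buffer = integer(0),
                           frozen = integer(0))
  r0 <- covalent_radius("O") + covalent_radius("H")
  frame <- restrained_minimize(w, reg, restraint_spec(c(1, 2), c(1, 3)),
                               targets = c(r0, r0))
  expect_true(frame$converged)
  expect_lt(frame$E_restraint, 1e-10)
  expect_lt(abs(frame$E), 1e-10)
})

test_that("a stiff spring drives the bonds onto their targets", {
  # both O-H bonds of a water pulled off equilibrium; at k = 1e5 the
  # residual displacement F/k falls below 1e-3 angstrom
  w <- water_system(c(0, 0, 0))
  reg <- region_assignment(w, active = 1L, buffer = integer(0),
                           frozen = integer(0))
  r0 <- covalent_radius("O") + covalent_radius("H")
  stiff <- restraint_spec(c(1, 2), c(1, 3), k_force = 1e5)
  targets <- c(r0 + 0.05, r0 - 0.04)
  frame <- restrained_minimize(w, reg, stiff, targets, opttol = 1e-5)
  xyz <- coords(frame$system)
  r1 <- sqrt(sum((xyz[1, ] - xyz[2, ])^2))
  r2 <- sqrt(sum((xyz[1, ] - xyz[3, ])^2))
  expect_lt(abs(r1 - targets[1]), 1e-3)
  expect_lt(abs(r2 - targets[2]), 1e-3)
})

test_that("frozen atoms are bit-identical before and after minimization", {
  toy <- make_toy_reaction(seed = 3, reference = FALSE)
  frame <- restrained_minimize(toy$system, toy$regions, toy$restraints,
                               targets = c(1.3, 2.4))
  frozen <- which(toy$regions$frozen_atoms)
  expect_identical(coords(frame$system)[frozen, ],
                   coords(toy$system)[frozen, ])
})

test_that("restraints on fully frozen bonds are refused", {
  toy <- make_toy_reaction(seed = 4, reference = FALSE)
  bad <- restraint_spec(c(1, 2), c(2, 3))   # donor-acceptor: both frozen
  expect_error(
    restrained_minimize(toy$system, toy$regions, bad, targets = c(3.7, 2.4)),
    "no mobile atom")
})

test_that("a zero-length scan is a single restrained minimization", {
  toy <- make_toy_reaction(seed = 5, reference = FALSE)
  path <- scan_path(toy$system, toy$regions, toy$restraints,
                    R_start = -1.0, R_end = -1.0)
  expect_length(path$frames, 1)
  expect_true(path$converged)
})

test_that("scan frames keep consistent coordinate and energy bookkeeping", {
  toy <- make_toy_reaction(seed = 1, reference = FALSE)
  s <- new_session()
  path <- scan_path(toy$system, toy$regions, toy$restraints,
                    R_start = -0.2, R_end = 0.2, session = s)
  expect_length(path$frames, 5)
  expect_true(all(path$converged))
  # stored R equals the coordinate recomputed from the stored geometry
  for (fr in path$frames) {
    expect_equal(fr$R, reaction_coordinate(fr$system, toy$restraints),
                 tolerance = 1e-10)
  }
  expect_true(all(diff(path$R) > 0))
  # reported energy excludes the restraint penalty; adding it back gives the
  # optimizer's objective
  for (fr in path$frames) {
    rep <- fd_energy(fr$system, toy$regions, mode = "FDD", session = s)
    pen_target <- fr$E + fr$E_restraint
    expect_equal(rep$E_total + fr$E_restraint, pen_target, tolerance = 1e-12)
    expect_equal(rep$E_total, fr$E, tolerance = 1e-12)
  }
  # the gradient-call ledger adds up
  expect_equal(path$n_gradient_calls,
               sum(vapply(path$frames, `[[`, 0L, "n_gradient_calls")))
  expect_gt(path$n_gradient_calls, 0)

  # profile export round-trips through the annotated XYZ and CSV formats
  xyzf <- withr::local_tempfile(fileext = ".xyz")
  csvf <- withr::local_tempfile(fileext = ".csv")
  write_path(path, xyzf, csvf)
  back <- read_frames(xyzf)
  expect_length(back, 5)
  expect_equal(vapply(back, attr, 0, "R"), path$R, tolerance = 1e-9)
  prof <- utils::read.csv(csvf)
  expect_equal(prof$E_hartree, path$E, tolerance = 1e-12)

  # resuming with identical settings reuses converged frames
  resumed <- scan_path(toy$system, toy$regions, toy$restraints,
                       R_start = -0.2, R_end = 0.2, session = s,
                       previous = path)
  expect_equal(resumed$R, path$R, tolerance = 1e-12)
  expect_error(scan_path(toy$system, toy$regions, toy$restraints,
                         R_start = -0.2, R_end = 0.3, previous = path),
               "settings differ")
})
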