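# Region assignment and frozen-domain energies/gradients: identities against
# full EFMO, the FD/FDD relation, and the backend-call audit.

# a manually partitioned compact water cluster: 2 active, 3 buffer, 2 frozen
fd_fixture <- function(seed = 69) {
  w <- make_water_cluster(7, seed = seed, radius = 3.4)
  regions <- region_assignment(w, active = c(1, 2), buffer = c(3, 4, 5),
                               frozen = c(6, 7))
  list(system = w, regions = regions)
}

test_that("assign_regions applies the distance predicate from the target", {
  # linear 5-water chain, 2.5 A spacing, target the middle
  w <- water_system(cbind(seq(0, 10, by = 2.5), 0, 0))
  reg <- assign_regions(w, target = 3L, R_active = 3.0, R_buffer = 2.5)
  expect_setequal(reg$active, 2:4)
  expect_true(all(c(1, 5) %in% c(reg$buffer, reg$frozen)))
  # partition completeness
  expect_equal(sort(c(reg$active, reg$buffer, reg$frozen)), 1:5)

  # an effectively infinite radius absorbs everything into A
  reg_all <- assign_regions(w, target = 3L, R_active = 1e6, R_buffer = 2.5)
  expect_setequal(reg_all$active, 1:5)
  expect_length(reg_all$frozen, 0)
  expect_equal(length(reg_all$mobile_atoms), n_atoms(w))

  expect_error(assign_regions(w, target = 99L), "not found")
})

test_that("buffer and frozen atoms are flagged frozen; shared boundary atoms
           are mobile only when both owners are active", {
  ch <- make_bonded_chain(5, seed = 71)
  reg <- region_assignment(ch, active = c(2, 3), buffer = c(1, 4), frozen = 5)
  ids <- vapply(ch$fragments, `[[`, 0L, "id")
  # atoms of buffer/frozen fragments are frozen
  for (id in c(1, 4, 5)) {
    expect_true(all(reg$frozen_atoms[ch$fragments[[match(id, ids)]]$atoms]))
  }
  # the atom shared between active 2 and active 3 is mobile; the atom
  # shared between active 3 and buffer 4 is frozen
  sh23 <- intersect(ch$fragments[[2]]$atoms, ch$fragments[[3]]$atoms)
  sh34 <- intersect(ch$fragments[[3]]$atoms, ch$fragments[[4]]$atoms)
  expect_false(any(reg$frozen_atoms[sh23]))
  expect_true(all(reg$frozen_atoms[sh34]))
})

test_that("region atom counts are disjoint and exhaustive", {
  tp <- make_toy_protein(n_res = 4, n_water = 6, seed = 73)
  reg <- assign_regions(tp, target = 2L, R_active = 2.0, R_buffer = 2.5)
  counts <- region_atom_counts(tp, reg)
  expect_equal(sum(counts), n_atoms(tp))
  rep <- region_report(tp, reg)
  expect_equal(sort(unique(rep$fragment_region)),
               sort(unique(c("A", "b", "F")[c(length(reg$active) > 0,
                                              length(reg$buffer) > 0,
                                              length(reg$frozen) > 0)])))
})

test_that("with empty buffer and frozen regions FD reduces to full EFMO", {
  w <- make_water_cluster(4, seed = 75, radius = 2.6)
  reg <- region_assignment(w, active = 1:4, buffer = integer(0),
                           frozen = integer(0))
  for (mode in c("FD", "FDD")) {
    e_fd <- fd_energy(w, reg, mode = mode)
    e_full <- efmo_energy(w)
    expect_identical(e_fd$E_total, e_full$E_total)
  }
})

test_that("FDD differs from FD by exactly the buffer-internal dimer sum", {
  fx <- fd_fixture()
  s <- new_session()
  e_fd <- fd_energy(fx$system, fx$regions, mode = "FD", session = s)
  e_fdd <- fd_energy(fx$system, fx$regions, mode = "FDD", session = s)
  bb_keys <- names(e_fd$dE_dimer)[vapply(names(e_fd$dE_dimer), function(k) {
    ij <- as.integer(strsplit(k, "-")[[1]])
    all(ij %in% fx$regions$buffer)
  }, TRUE)]
  expect_gt(length(bb_keys), 0)   # the fixture has near buffer-buffer pairs
  expect_equal(e_fdd$E_total - e_fd$E_total, -sum(e_fd$dE_dimer[bb_keys]),
               tolerance = 1e-12)
  # and FDD's decomposition has no buffer-buffer dimer entries
  expect_false(any(bb_keys %in% names(e_fdd$dE_dimer)))
})

test_that("FD and FDD gradients agree on active atoms", {
  fx <- fd_fixture()
  g_fd <- fd_gradient(fx$system, fx$regions, mode = "FD")
  g_fdd <- fd_gradient(fx$system, fx$regions, mode = "FDD")
  expect_identical(rownames(g_fd), rownames(g_fdd))
  expect_lt(max(abs(g_fd - g_fdd)), 1e-8)
})

test_that("frozen-domain gradients match finite differences on mobile atoms", {
  ch <- make_bonded_chain(5, seed = 77)
  reg <- region_assignment(ch, active = 3L, buffer = c(2, 4), frozen = c(1, 5))
  g <- fd_gradient(ch, reg, mode = "FDD")
  fd <- fd_gradient_of(ch, function(s) fd_energy(s, reg, mode = "FDD")$E_total,
                       atoms = reg$mobile_atoms)
  expect_lt(max(abs(g - fd)), 1e-6)
})

test_that("the backend-call audit shows no QM work on the frozen region and
           no buffer-buffer dimers under FDD", {
  fx <- fd_fixture()
  for (mode in c("FD", "FDD")) {
    s <- new_session()
    fd_energy(fx$system, fx$regions, mode = mode, session = s)
    log <- session_log(s)
    qm <- log[log$kind %in% c("monomer", "dimer"), , drop = FALSE]
    touched <- strsplit(qm$fragments, "+", fixed = TRUE)
    expect_false(any(vapply(touched, function(v) {
      any(as.integer(v) %in% fx$regions$frozen)
    }, TRUE)))
    if (mode == "FDD") {
      dimers <- strsplit(qm$fragments[qm$kind == "dimer"], "+", fixed = TRUE)
      expect_false(any(vapply(dimers, function(v) {
        all(as.integer(v) %in% fx$regions$buffer)
      }, TRUE)))
    }
  }
})

test_that("moving only frozen atoms changes classical terms without new QM calls", {
  fx <- fd_fixture()
  s <- new_session()
  e1 <- fd_energy(fx$system, fx$regions, mode = "FDD", session = s)
  counts_before <- session_counts(s)

  moved <- fx$system
  ids <- vapply(moved$fragments, `[[`, 0L, "id")
  f_atoms <- unlist(lapply(moved$fragments[match(fx$regions$frozen, ids)],
                           `[[`, "atoms"))
  xyz <- coords(moved)
  xyz[f_atoms, 1] <- xyz[f_atoms, 1] + 0.37
  coords(moved) <- xyz
  e2 <- fd_energy(moved, fx$regions, mode = "FDD", session = s)
  counts_after <- session_counts(s)

  expect_identical(counts_after[c("monomer", "dimer")],
                   counts_before[c("monomer", "dimer")])
  # the energy difference is carried by the classical terms alone
  expect_equal(e2$E_total - e1$E_total,
               (sum(e2$E_es_far) - sum(e1$E_es_far)) +
                 (e2$E_pol_tot - e1$E_pol_tot), tolerance = 1e-12)
  expect_equal(e2$E_monomers, e1$E_monomers)
  expect_equal(e2$dE_dimer, e1$dE_dimer)
})

test_that("an active fragment bonded to a frozen fragment is refused", {
  ch <- make_bonded_chain(3, seed = 79)
  reg <- region_assignment(ch, active = 1L, buffer = integer(0), frozen = 2:3)
  expect_error(fd_energy(ch, reg), "bonded to a frozen")
})

test_that("an empty active region yields an empty gradient and no dimer calls", {
  w <- make_water_cluster(4, seed = 81, radius = 2.6)
  reg <- region_assignment(w, active = integer(0), buffer = 1:2, frozen = 3:4)
  s <- new_session()
  g <- fd_gradient(w, reg, mode = "FDD", session = s)
  expect_equal(nrow(g), 0)
  expect_equal(unname(session_counts(s)["dimer"]), 0L)
})
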