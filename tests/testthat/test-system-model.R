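# Structure I/O, bond detection, residue fragmentation with shared boundary
# atoms, and the unitless interfragment distance.

test_that("read_xyz echoes a simple water file and selects frames", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water", "O 0.0 0.0 0.0", "H 0.757 0.0 0.586",
               "H -0.757 0.0 0.586"), f)
  sys <- read_xyz(f)
  expect_equal(n_atoms(sys), 3)
  expect_equal(sys$atoms$element, c("O", "H", "H"))
  expect_equal(sys$atoms$x, c(0, 0.757, -0.757))

  # multi-frame: first frame by default, others selectable
  writeLines(c("1", "frame 1", "O 0 0 0", "1", "frame 2", "O 1 2 3"), f)
  expect_equal(coords(read_xyz(f))[1, ], c(x = 0, y = 0, z = 0))
  expect_equal(unname(coords(read_xyz(f, frame = 2))[1, ]), c(1, 2, 3))
})

test_that("malformed XYZ input raises parse errors naming the line", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(character(0), f)
  expect_error(read_xyz(f), "empty file")

  writeLines(c("2", "bad coords", "O 0 0 0", "H aa 0 0"), f)
  expect_error(read_xyz(f), "non-numeric coordinate \\(line 4\\)")

  writeLines(c("x", "bad count", "O 0 0 0"), f)
  expect_error(read_xyz(f), "bad atom count")

  writeLines(c("1", "unknown element", "Xx 0 0 0"), f)
  expect_error(read_xyz(f), "unknown element")
})

test_that("read_pdb parses residues, elements and waters from the fixture", {
  sys <- read_pdb(test_path("glygly.pdb"))
  expect_equal(length(unique(sys$atoms$residue_id)), 3)
  expect_equal(sys$atoms$element[1:4], c("N", "C", "C", "O"))
  expect_equal(sys$atoms$residue_name[10], "HOH")
})

test_that("read_pdb deduces elements from atom names and honors icodes", {
  f <- withr::local_tempfile(fileext = ".pdb")
  # no element columns; residue identity must include the insertion code
  writeLines(c(
    "ATOM      1 CA   GLY A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2 N    GLY A   2       2.000   0.000   0.000  1.00  0.00",
    "ATOM      3 N    GLY A   2A      4.000   0.000   0.000  1.00  0.00",
    "END"), f)
  sys <- read_pdb(f)
  expect_equal(sys$atoms$element, c("C", "N", "N"))
  expect_equal(length(unique(sys$atoms$residue_id)), 3)
})

test_that("detect_bonds uses covalent-radius sums", {
  w <- water_system(c(0, 0, 0))
  expect_equal(nrow(w$bonds), 2)            # two O-H, no H-H
  expect_true(all(w$bonds[, 1] == 1))

  w2 <- water_system(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(nrow(w2$bonds), 4)           # no inter-molecular bond

  w0 <- detect_bonds(water_system(c(0, 0, 0)), scale = 0)
  expect_equal(nrow(w0$bonds), 0)
})

test_that("fragment_by_residue makes one fragment per residue with shared cut atoms", {
  # dipeptide: boundary at the C-alpha--C(carbonyl) bond, C-alpha shared
  pep <- fragment_by_residue(detect_bonds(read_pdb(test_path("glygly.pdb"))))
  expect_equal(length(pep$fragments), 3)
  sh <- pep$fragments[[1]]$shared
  expect_equal(nrow(sh), 1)
  expect_equal(pep$atoms$name[sh$atom], "CA")
  expect_true(sh$atom %in% pep$fragments[[2]]$atoms)

  # isolated waters: no shared atoms
  w5 <- water_system(cbind(seq(0, 20, by = 5), 0, 0))
  expect_equal(length(w5$fragments), 5)
  expect_equal(sum(vapply(w5$fragments, function(f) nrow(f$shared), 0L)), 0L)

  # single residue: fragment identical to the system
  w1 <- water_system(c(0, 0, 0))
  expect_equal(w1$fragments[[1]]$atoms, 1:3)
})

test_that("fragmentation partitions the system up to shared atoms", {
  for (n in c(2, 3, 5)) {
    ch <- make_bonded_chain(n, seed = n)
    roster_sum <- sum(vapply(ch$fragments, function(f) length(f$atoms), 0L))
    shared_pairs <- sum(vapply(ch$fragments,
                               function(f) sum(f$shared$owner == f$id), 0L))
    expect_equal(roster_sum - shared_pairs, n_atoms(ch))
    expect_equal(shared_pairs, n - 1L)
  }
})

test_that("interfragment distance is the vdW-normalized minimum contact", {
  # two bare O-like fragments at exactly the vdW touching distance
  sys <- molecular_system(data.frame(element = "O", x = c(0, 3.04), y = 0,
                                     z = 0, residue_id = 1:2))
  sys <- fragment_by_residue(detect_bonds(sys))
  expect_equal(interfragment_distance(sys, 1, 2), 1.0)

  sys2 <- molecular_system(data.frame(element = "O", x = c(0, 0), y = 0,
                                      z = 0, residue_id = 1:2))
  sys2 <- fragment_by_residue(sys2)
  expect_equal(interfragment_distance(sys2, 1, 2), 0)

  expect_error(interfragment_distance(sys, 1, 1), "distinct")
})

test_that("interfragment distance is symmetric and rigid-motion invariant", {
  set.seed(11)
  w <- make_water_cluster(6, seed = 11)
  pairs <- utils::combn(6, 2)
  base <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    base[k] <- interfragment_distance(w, i, j)
    expect_identical(base[k], interfragment_distance(w, j, i))
  }
  for (rep in 1:5) {
    wt <- rigid_transform(w)
    for (k in seq_len(ncol(pairs))) {
      expect_equal(interfragment_distance(wt, pairs[1, k], pairs[2, k]),
                   base[k], tolerance = 1e-10)
    }
  }
})

test_that("write_frames round-trips coordinates and annotations", {
  frames <- lapply(1:3, function(k) {
    w <- water_system(c(0, 0, 0))
    coords(w) <- coords(w) + k * 0.123456
    w
  })
  f <- withr::local_tempfile(fileext = ".xyz")
  write_frames(frames, f, R = c(-1.95, 0, 1.42), energy = c(-10.0, -9.5, -9.8))
  back <- read_frames(f)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_lt(max(abs(coords(back[[k]]) - coords(frames[[k]]))), 1e-6)
    expect_identical(back[[k]]$atoms$element, frames[[k]]$atoms$element)
  }
  expect_equal(attr(back[[1]], "R"), -1.95)
  expect_equal(attr(back[[1]], "energy"), -10.0)

  # zero frames: empty file, no error
  write_frames(list(), f)
  expect_length(readLines(f), 0)

  # roster mismatch across frames is refused
  other <- molecular_system(data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_error(write_frames(list(frames[[1]], other), f), "roster")
})

test_that("fragment map files record rosters and charges", {
  w <- make_water_cluster(3, seed = 5)
  f <- withr::local_tempfile()
  write_fragment_map(w, f)
  lines <- readLines(f)
  expect_length(lines, 3)
  expect_match(lines[1], "^1 .*charge=0$")
})
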