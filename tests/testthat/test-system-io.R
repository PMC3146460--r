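test_that("prmtop subset decodes to the hand-decoded parameter table", {
  path <- writeTinyPrmtop(tempfile(fileext = ".prmtop"))
  top <- readTopology(path, "amber-prmtop")
  a <- atoms(top)
  expect_equal(a$charge, c(1, -0.5, 0, 0.5, -1), tolerance = 1e-6)
  # amber N type: rmin/2 1.8240, eps 0.17; C type: 1.9080, 0.1094
  expect_equal(a$rminHalf, c(1.8240, 1.9080, 1.9080, 1.9080, 1.8240),
               tolerance = 1e-3)
  expect_equal(a$epsilon, c(0.17, 0.1094, 0.1094, 0.1094, 0.17),
               tolerance = 1e-4)
  expect_equal(a$resname, c("ALA", "ALA", "ALA", "GLY", "GLY"))
  expect_equal(residues(top)$first, c(1L, 4L))
  b <- bonds(top)
  expect_setequal(paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])),
                  c("1 2", "2 3"))
  expect_equal(a$gbRadius, c(1.55, 1.7, 1.7, 1.7, 1.5))
  expect_equal(a$gbScreen, c(0.79, 0.72, 0.72, 0.72, 0.85))
})

test_that("prmtop unit convention: internal charge 18.2223 is 1 e, A=B=0 is eps 0", {
  path <- writeTinyPrmtop(tempfile(fileext = ".prmtop"))
  top <- readTopology(path, "amber-prmtop")
  expect_identical(atoms(top)$charge[1], 1)
  # type pair (N,C) off-diagonal points at A=B=0; diagonals are nonzero,
  # so build a variant where one diagonal is zeroed
  txt <- readLines(path)
  i <- grep("LENNARD_JONES_ACOEF", txt) + 2L
  txt[i] <- paste(sprintf("%16.8E", c(0, 0, 1043080.23)), collapse = "")
  j <- grep("LENNARD_JONES_BCOEF", txt) + 2L
  txt[j] <- paste(sprintf("%16.8E", c(0, 0, 675.612247)), collapse = "")
  p2 <- tempfile(fileext = ".prmtop"); writeLines(txt, p2)
  top2 <- readTopology(p2, "amber-prmtop")
  expect_identical(atoms(top2)$epsilon[1], 0)
  expect_identical(atoms(top2)$rminHalf[1], 0)
})

test_that("missing mandatory prmtop sections raise a format error naming them", {
  path <- writeTinyPrmtop(tempfile(fileext = ".prmtop"))
  txt <- readLines(path)
  drop <- grep("FLAG CHARGE", txt)
  p2 <- tempfile(fileext = ".prmtop")
  writeLines(txt[-(drop:(drop + 2L))], p2)
  expect_error(readTopology(p2, "amber-prmtop"), "CHARGE")
})

test_that("missing RADII falls back to the documented default table", {
  path <- writeTinyPrmtop(tempfile(fileext = ".prmtop"), radii = FALSE)
  top <- suppressMessages(readTopology(path, "amber-prmtop"))
  # elements N C C C O under the mbondi-style defaults
  expect_equal(atoms(top)$gbRadius, c(1.55, 1.7, 1.7, 1.7, 1.5))
})

test_that("param-table round-trips a topology including groups, also gzipped", {
  toy <- makeToyComplex(toySpec(seed = 3))
  p <- tempfile(fileext = ".tbl")
  writeParamTable(toy$topology, p)
  top2 <- readTopology(p, "param-table")
  expect_equal(atoms(top2), atoms(toy$topology), tolerance = 1e-9)
  expect_equal(groups(top2), groups(toy$topology))
  expect_equal(bonds(top2), bonds(toy$topology), ignore_attr = TRUE)
  pz <- paste0(p, ".gz")
  con <- gzfile(pz, "w"); writeLines(readLines(p), con); close(con)
  top3 <- readTopology(pz, "param-table")
  expect_equal(atoms(top3), atoms(toy$topology), tolerance = 1e-9)
})

test_that("solvent residues are stripped on load", {
  a <- rbind(simpleAtoms(3, resid = c(1, 1, 1), resname = "ALA"),
             simpleAtoms(3, resid = c(2, 2, 2), resname = "WAT"),
             simpleAtoms(1, resid = 3, resname = "Na+"))
  top <- Topology(a)
  p <- tempfile(); writeParamTable(top, p)
  top2 <- suppressMessages(readTopology(p, "param-table"))
  expect_identical(natoms(top2), 3L)
  expect_false(any(atoms(top2)$resname %in% c("WAT", "Na+")))
})

test_that("multi-model PDB and DCD round-trip coordinates in file order", {
  toy <- makeToyComplex(toySpec(seed = 2))
  set.seed(9)
  nf <- 7L
  arr <- array(rnorm(natoms(toy$topology) * 3 * nf, sd = 4),
               c(natoms(toy$topology), 3L, nf))
  traj <- Trajectory(arr)
  pp <- tempfile(fileext = ".pdb")
  writeTrajectory(traj, pp, toy$topology, format = "pdb")
  back <- readTrajectory(pp, toy$topology, format = "pdb")
  expect_equal(nframes(back), nf)
  expect_lt(max(abs(back@coords - arr)), 1e-3 + 1e-9)  # fixed-column %.3f
  pd <- tempfile(fileext = ".dcd")
  writeTrajectory(traj, pd, format = "dcd")
  back2 <- readTrajectory(pd, toy$topology, format = "dcd")
  expect_lt(max(abs(back2@coords - arr)), 1e-4)        # float32 precision
})

test_that("DCD written here is readable by an independent reader (bio3d)", {
  set.seed(4)
  arr <- array(rnorm(10 * 3 * 5, sd = 5), c(10L, 3L, 5L))
  p <- tempfile(fileext = ".dcd")
  writeTrajectory(Trajectory(arr), p, format = "dcd")
  ref <- bio3d::read.dcd(p, verbose = FALSE)
  mine <- readTrajectory(p, simpleTopology(10), format = "dcd")
  for (f in 1:5)
    expect_equal(matrix(ref[f, ], 10, 3, byrow = TRUE),
                 mine@coords[, , f], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a generated 500-frame file reads back with 500 frames", {
  arr <- array(rep(seq_len(500), each = 9), c(3L, 3L, 500L))
  p <- tempfile(fileext = ".dcd")
  writeTrajectory(Trajectory(arr), p, format = "dcd")
  expect_identical(nframes(readTrajectory(p, simpleTopology(3), "dcd")), 500L)
})

test_that("truncated trajectories report the last complete frame", {
  arr <- array(seq_len(5 * 3 * 4), c(5L, 3L, 4L))
  p <- tempfile(fileext = ".dcd")
  writeTrajectory(Trajectory(arr), p, format = "dcd")
  sz <- file.size(p)
  con <- file(p, "r+b"); seek(con, sz - 30L); truncate(con); close(con)
  expect_error(readTrajectory(p, simpleTopology(5), "dcd"),
               "last complete frame is 3")
  top <- simpleTopology(2)
  pp <- tempfile(fileext = ".pdb")
  writeTrajectory(Trajectory(array(1, c(2, 3, 3))), pp, top, "pdb")
  txt <- readLines(pp)
  writeLines(head(txt, length(txt) - 3L), pp)  # drop one atom of model 3
  expect_error(readTrajectory(pp, top, "pdb"), "last complete frame is 2")
})

test_that("atom-count mismatch between trajectory and topology errors", {
  arr <- array(1, c(4L, 3L, 1L))
  p <- tempfile(fileext = ".dcd")
  writeTrajectory(Trajectory(arr), p, format = "dcd")
  expect_error(readTrajectory(p, simpleTopology(5), "dcd"), "4 atoms")
})

test_that("RMSD obeys its closed forms and symmetry", {
  set.seed(11)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(frameRMSD(a, a), 0)
  b <- sweep(a, 2, c(3, 4, 0), `+`)
  expect_equal(frameRMSD(b, a, superpose = TRUE), 0, tolerance = 1e-6)
  expect_gt(frameRMSD(b, a, superpose = FALSE), 4.99)
  # 2-atom case, one atom displaced by 1 A, no fit: sqrt(1/2)
  x <- rbind(c(0, 0, 0), c(2, 0, 0))
  y <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_equal(frameRMSD(y, x, superpose = FALSE), sqrt(0.5),
               tolerance = 1e-9)
  cc <- a + matrix(rnorm(30, sd = 0.3), 10, 3)
  expect_equal(frameRMSD(a, cc, superpose = TRUE),
               frameRMSD(cc, a, superpose = TRUE), tolerance = 1e-6)
  expect_error(frameRMSD(a, a, selection = integer(0)), "empty selection")
})

test_that("group partition invariants are enforced on construction", {
  a <- simpleAtoms(4)
  expect_error(Topology(a, groups = list(receptor = 1:3, ligand = 3:4)),
               "overlap")
  expect_error(Topology(a, groups = list(receptor = 1:2, ligand = c(3L, 9L))),
               "out-of-range")
  top <- Topology(a, groups = list(receptor = 1:2, ligand = 3:4))
  expect_true(length(intersect(groups(top)$receptor,
                               groups(top)$ligand)) == 0)
})
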