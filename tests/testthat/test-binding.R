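test_that("derived-term arithmetic reproduces printed decomposition rows", {
  # global FHA main-site row
  d <- combineComponents(2.50, -34.34, 37.83, 0.75)
  expect_equal(unname(d["eEle"]), 3.49, tolerance = 0.005)
  expect_equal(unname(d["eTot"]), 6.74, tolerance = 0.005)
  expect_equal(unname(d["eTotNp"]), 5.99, tolerance = 0.005)
  # WW-domain row: derived total from the printed electrostatic sum
  expect_equal(-2.96 + (-1.03) + (-0.01), -4.00, tolerance = 0.005)
  # local FHA row
  dl <- combineComponents(3.12, -8.36, 5.71, 0.03)
  expect_equal(unname(dl["eEle"]), -2.65, tolerance = 0.005)
  expect_true(dl["eTot"] >= 0.49 - 0.005 && dl["eTot"] <= 0.50 + 0.005)
  expect_identical(unname(combineComponents(0, 0, 0, 0)), c(0, 0, 0))
})

test_that("single-frame interaction energy equals brute-force complex-minus-parts", {
  sys <- randomSystem(6, seed = 17, spread = 5)
  top <- sys$top; top@groups <- list(receptor = 1:3, ligand = 4:6)
  cfg <- energyConfig(sasaPoints = 960)
  ec <- interactionEnergyFrame(top, sys$xyz, config = cfg)
  a <- atoms(top)
  expect_equal(unname(components(ec)["uCoul"]),
               coulombOracle(sys$xyz, a$charge, 1:3, 4:6), tolerance = 1e-8)
  expect_equal(unname(components(ec)["uVdw"]),
               ljOracle(sys$xyz, a$rminHalf, a$epsilon, 1:3, 4:6),
               tolerance = 1e-8)
  wp <- gbEnergy(top, sys$xyz, 1:6) - gbEnergy(top, sys$xyz, 1:3) -
    gbEnergy(top, sys$xyz, 4:6)
  expect_equal(unname(components(ec)["wPolar"]), wp, tolerance = 1e-9)
  np <- function(g) nonpolarEnergy(sasa(top, sys$xyz, g)$total)
  expect_equal(unname(components(ec)["wNp"]),
               np(1:6) - np(1:3) - np(4:6), tolerance = 1e-9)
})

test_that("well-separated groups have vanishing interaction terms", {
  top <- simpleTopology(4, charge = c(0.5, -0.5, 0.4, -0.4))
  top@groups <- list(receptor = 1:2, ligand = 3:4)
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(500, 0, 0), c(502, 0, 0))
  ec <- interactionEnergyFrame(top, xyz, config = energyConfig(sasaPoints = 240))
  expect_identical(unname(components(ec)["uVdw"]), 0)
  expect_identical(unname(components(ec)["uCoul"]), 0)
  expect_lt(abs(components(ec)["wPolar"]), 0.01)
})

test_that("Coulomb term is bilinear: doubling charges quadruples it", {
  sys <- randomSystem(6, seed = 3)
  top <- sys$top; top@groups <- list(receptor = 1:3, ligand = 4:6)
  cfg <- energyConfig(sasaPoints = 60)
  e1 <- components(interactionEnergyFrame(top, sys$xyz, config = cfg))["uCoul"]
  top2 <- top; top2@atoms$charge <- 2 * top@atoms$charge
  e2 <- components(interactionEnergyFrame(top2, sys$xyz, config = cfg))["uCoul"]
  expect_equal(unname(e2), 4 * unname(e1), tolerance = 1e-9)
})

test_that("ensemble averaging: identical frames give the frame value, SEM 0", {
  sys <- randomSystem(6, seed = 23)
  top <- sys$top; top@groups <- list(receptor = 1:3, ligand = 4:6)
  cfg <- energyConfig(sasaPoints = 240)
  arr <- array(sys$xyz, c(6, 3, 4))
  ens <- SeedEnsemble(list(Trajectory(arr), Trajectory(arr)), 1:2)
  avg <- interactionEnergy(top, ens, config = cfg)
  single <- interactionEnergyFrame(top, sys$xyz, config = cfg)
  expect_equal(components(avg), components(single), tolerance = 1e-10)
  expect_true(all(standardError(avg) == 0))
})

test_that("two seeds with per-seed means a and b average to (a+b)/2", {
  sys <- randomSystem(6, seed = 29)
  top <- sys$top; top@groups <- list(receptor = 1:3, ligand = 4:6)
  cfg <- energyConfig(sasaPoints = 240)
  xyzB <- sys$xyz + 0.35
  ens <- SeedEnsemble(list(Trajectory(array(sys$xyz, c(6, 3, 2))),
                           Trajectory(array(xyzB, c(6, 3, 2)))), 1:2)
  avg <- interactionEnergy(top, ens, config = cfg)
  ea <- components(interactionEnergyFrame(top, sys$xyz, config = cfg))
  eb <- components(interactionEnergyFrame(top, xyzB, config = cfg))
  expect_equal(components(avg), (ea + eb) / 2, tolerance = 1e-9)
  ps <- perSeedTable(avg)
  expect_identical(nrow(ps), 2L)
  expect_equal(unname(unlist(ps[1, -1])), unname(ea), tolerance = 1e-10)
})

test_that("delta-delta records difference mutant minus wild, antisymmetrically", {
  sys <- randomSystem(6, seed = 31)
  top <- sys$top; top@groups <- list(receptor = 1:3, ligand = 4:6)
  cfg <- energyConfig(sasaPoints = 240)
  w <- interactionEnergyFrame(top, sys$xyz, config = cfg)
  m <- interactionEnergyFrame(top, sys$xyz + 0.2, config = cfg)
  expect_true(all(components(deltaDelta(w, w)) == 0))
  fw <- deltaDelta(w, m); bw <- deltaDelta(m, w)
  expect_equal(components(fw), -components(bw), tolerance = 1e-12)
  # the record's derived terms equal combineComponents of the differenced inputs
  d <- components(fw)
  cc <- combineComponents(d[["uVdw"]], d[["uCoul"]], d[["wPolar"]],
                          d[["wNp"]])
  expect_equal(d[c("eEle", "eTot", "eTotNp")], cc, tolerance = 1e-12)
  w2 <- w; w2@polarModel <- "PB"
  expect_error(deltaDelta(w2, m), "mismatch")
})

test_that("shell selection: constructed distances, monotonicity, containment", {
  toy <- makeToyComplex(toySpec(seed = 6))
  s5 <- shellSelect(toy$topology, toy$xyz, toy$phosphoResidue, cutoff = 5)
  s7 <- shellSelect(toy$topology, toy$xyz, toy$phosphoResidue, cutoff = 7)
  expect_true(all(s5@residues$index %in% s7@residues$index))
  big <- shellSelect(toy$topology, toy$xyz, toy$phosphoResidue, cutoff = 500)
  recRes <- which(vapply(seq_len(nrow(residues(toy$topology))), function(ri)
    all(phosdelta:::residueAtoms(toy$topology, ri) %in%
          groups(toy$topology)$receptor), logical(1)))
  expect_setequal(big@residues$index, recRes)
  expect_false(toy$phosphoResidue %in% s7@residues$index)
  # constructed two-residue case: 4 A in, 8 A out at 6 A cutoff
  a <- rbind(simpleAtoms(2, resid = c(1, 1), resname = "TPO",
                         name = c("P", "O1P")),
             simpleAtoms(1, resid = 2, resname = "NEAR"),
             simpleAtoms(1, resid = 3, resname = "FARR"))
  top <- Topology(a, groups = list(ligand = 1:2, receptor = 3:4))
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 4, 0), c(0, 8, 0))
  sel <- shellSelect(top, xyz, 1L, cutoff = 6)
  expect_identical(sel@residues$index, 2L)
  expect_error(shellSelect(top, xyz, 2L, cutoff = 6), "phosphate")
})

test_that("local energy with an all-covering shell equals the global GB result", {
  toy <- makeToyComplex(toySpec(seed = 4))
  model <- defaultDihedralModel(toy$topology, toy$xyz)
  ens <- sampleEnsemble(toy$topology, toy$xyz, model, nSeeds = 2,
                        nFrames = 5, seed = 2)
  cfg <- energyConfig(sasaPoints = 240)
  shell <- shellSelect(toy$topology, toy$xyz, toy$phosphoResidue,
                       cutoff = 500, neighbors = 10L)
  loc <- localInteractionEnergy(toy$topology, ens, shell, config = cfg)
  glob <- interactionEnergy(toy$topology, ens, polarModel = "GB",
                            config = cfg)
  expect_equal(components(loc), components(glob), tolerance = 1e-6)
  emptyShell <- shell
  emptyShell@residues <- shell@residues[0, ]
  expect_error(localInteractionEnergy(toy$topology, ens, emptyShell,
                                      config = cfg), "empty shell")
})

test_that("local energy restricted to a toy shell matches brute-force sums", {
  toy <- makeToyComplex(toySpec(seed = 4))
  shell <- shellSelect(toy$topology, toy$xyz, toy$phosphoResidue, cutoff = 6)
  expect_gt(nrow(shell@residues), 0)
  recAtoms <- unlist(lapply(shell@residues$index,
                            phosdelta:::residueAtoms, topology = toy$topology))
  ligAtoms <- unlist(lapply(shell@ligandResidues,
                            phosdelta:::residueAtoms, topology = toy$topology))
  ens <- SeedEnsemble(list(Trajectory(array(toy$xyz,
                                            c(natoms(toy$topology), 3, 1)))))
  cfg <- energyConfig(sasaPoints = 240)
  loc <- localInteractionEnergy(toy$topology, ens, shell, config = cfg)
  a <- atoms(toy$topology)
  expect_equal(unname(components(loc)["uCoul"]),
               coulombOracle(toy$xyz, a$charge, recAtoms, ligAtoms),
               tolerance = 1e-8)
  expect_equal(unname(components(loc)["uVdw"]),
               ljOracle(toy$xyz, a$rminHalf, a$epsilon, recAtoms, ligAtoms),
               tolerance = 1e-8)
})

test_that("central frame is the one minimising mean RMSD to the others", {
  toy <- makeToyComplex(toySpec(seed = 9))
  model <- defaultDihedralModel(toy$topology, toy$xyz)
  ens <- sampleEnsemble(toy$topology, toy$xyz, model, nSeeds = 2,
                        nFrames = 6, seed = 5)
  ref <- centralFrame(ens, maxFrames = 12L)
  expect_true(ref$seed %in% 1:2 && ref$frame %in% 1:6)
})
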