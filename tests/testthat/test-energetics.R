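test_that("Coulomb kernel: closed form, cutoff, symmetry, additivity", {
  top <- simpleTopology(2, charge = 1)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(coulombEnergy(top, xyz, 1L, 2L), 332.0636, tolerance = 1e-9)
  xyz2 <- rbind(c(0, 0, 0), c(40.01, 0, 0))
  expect_identical(coulombEnergy(top, xyz2, 1L, 2L), 0)
  expect_equal(coulombEnergy(top, xyz, 1L, 2L, dielectric = 4),
               332.0636 / 4, tolerance = 1e-9)
  sys <- randomSystem(12, seed = 21)
  ia <- 1:5; ib <- 6:12
  expect_equal(coulombEnergy(sys$top, sys$xyz, ia, ib),
               coulombEnergy(sys$top, sys$xyz, ib, ia), tolerance = 1e-12)
  expect_equal(coulombEnergy(sys$top, sys$xyz, ia, ib),
               coulombEnergy(sys$top, sys$xyz, ia, 6:8) +
                 coulombEnergy(sys$top, sys$xyz, ia, 9:12),
               tolerance = 1e-12)
  expect_error(coulombEnergy(sys$top, sys$xyz, 1:5, 5:8), "overlap")
  xyz[2, ] <- c(1e-9, 0, 0)
  expect_error(coulombEnergy(top, xyz, 1L, 2L), "singular")
})

test_that("LJ kernel: minimum at rmin, zero crossing, oracle equality", {
  top <- simpleTopology(2, rminHalf = 1.7, epsilon = 0.2)
  rmin <- 3.4
  expect_equal(ljEnergy(top, rbind(c(0, 0, 0), c(rmin, 0, 0)), 1L, 2L),
               -0.2, tolerance = 1e-12)
  expect_equal(ljEnergy(top, rbind(c(0, 0, 0), c(rmin / 2^(1 / 6), 0, 0)),
                        1L, 2L), 0, tolerance = 1e-12)
  sys <- randomSystem(8, seed = 5)
  a <- atoms(sys$top)
  expect_equal(ljEnergy(sys$top, sys$xyz, 1:4, 5:8),
               ljOracle(sys$xyz, a$rminHalf, a$epsilon, 1:4, 5:8),
               tolerance = 1e-8)
})

test_that("GB energy: Born-ion limit and separability limit", {
  # no offset: a single ion of intrinsic radius 2.0 A
  top1 <- simpleTopology(1, charge = 1, gbRadius = 2.0)
  born <- function(q, a) -166.0318 * (1 - 1 / 80) * q^2 / a
  expect_equal(gbEnergy(top1, matrix(0, 1, 3), 1L, offset = 0),
               born(1, 2), tolerance = 1e-4)
  # igb=1 offset convention: effective radius is rho - 0.09
  expect_equal(gbEnergy(top1, matrix(0, 1, 3), 1L, offset = 0.09),
               born(1, 2 - 0.09), tolerance = 1e-4)
  top2 <- simpleTopology(2, charge = 0.5, gbRadius = 2.0)
  # the screened charge-charge term decays as 1/r, so true separability
  # needs a very large gap; at 100 A the residual tail is ~0.8 kcal/mol
  vfar <- rbind(c(0, 0, 0), c(1e5, 0, 0))
  expect_equal(gbEnergy(top2, vfar, 1:2, offset = 0),
               2 * born(0.5, 2), tolerance = 1e-4)
  far <- rbind(c(0, 0, 0), c(100, 0, 0))
  expect_equal(gbEnergy(top2, far, 1:2, offset = 0),
               2 * born(0.5, 2), tolerance = 0.03)
})

test_that("HCT effective radii match the numeric descreening integral", {
  # pair geometries spanning separated, overlapping and engulfed regimes
  off <- 0.09
  cases <- list(c(r = 3.0, rho1 = 1.7, rho2 = 1.5, s2 = 0.8),
                c(r = 1.2, rho1 = 1.7, rho2 = 1.5, s2 = 0.8),
                c(r = 0.5, rho1 = 1.2, rho2 = 2.1, s2 = 1.0))
  for (cs in cases) {
    top <- simpleTopology(2, gbRadius = c(cs["rho1"], cs["rho2"]),
                          gbScreen = c(1, cs["s2"]))
    xyz <- rbind(c(0, 0, 0), c(cs["r"], 0, 0))
    reff <- bornRadii(top, xyz, 1:2, offset = off)
    rhoTi <- cs["rho1"] - off
    Inum <- hctIntegralNumeric(cs["r"], rhoTi, cs["s2"] * (cs["rho2"] - off))
    expect_equal(unname(reff[1]), unname(1 / (1 / rhoTi - Inum)),
                 tolerance = 1e-4)
  }
  # 5-atom cluster: pairwise sums of numeric integrals
  sys <- randomSystem(5, seed = 33, spread = 4)
  a <- atoms(sys$top)
  reff <- bornRadii(sys$top, sys$xyz, 1:5, offset = off)
  for (i in 1:5) {
    rhoTi <- a$gbRadius[i] - off
    Isum <- 0
    for (j in setdiff(1:5, i)) {
      r <- sqrt(sum((sys$xyz[i, ] - sys$xyz[j, ])^2))
      Isum <- Isum + hctIntegralNumeric(r, rhoTi,
                                        a$gbScreen[j] * (a$gbRadius[j] - off))
    }
    expect_equal(unname(reff[i]), 1 / (1 / rhoTi - Isum), tolerance = 1e-4)
  }
})

test_that("GB energy is invariant under rigid-body motion", {
  sys <- randomSystem(8, seed = 12, spread = 5)
  sys$top@atoms$charge <- round(runif(8, -1, 1), 2)
  e1 <- gbEnergy(sys$top, sys$xyz, 1:8)
  rot <- phosdelta:::rotateAboutAxis(sys$xyz, c(1, 2, 3), c(1, 1, 0), 77)
  rot <- sweep(rot, 2, c(5, -3, 11), `+`)
  expect_equal(gbEnergy(sys$top, rot, 1:8), e1, tolerance = 1e-9)
})

test_that("SASA: isolated sphere, buried atom, spherical-cap oracle", {
  top <- simpleTopology(1, rminHalf = 1.7)
  s <- sasa(top, matrix(0, 1, 3), 1L, probe = 1.4, nPoints = 960)
  expect_equal(s$total, 4 * pi * 3.1^2, tolerance = 0.01 * 4 * pi * 3.1^2)
  # per-atom areas sum to the total
  sys <- randomSystem(6, seed = 2, spread = 4)
  s2 <- sasa(sys$top, sys$xyz, 1:6)
  expect_equal(sum(s2$perAtom), s2$total, tolerance = 1e-9)
  # atom enclosed by a shell of neighbours has zero area
  shellPts <- 3.0 * rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                          c(0,0,1), c(0,0,-1),
                          c(1,1,1)/sqrt(3), c(-1,1,1)/sqrt(3),
                          c(1,-1,1)/sqrt(3), c(1,1,-1)/sqrt(3),
                          c(-1,-1,1)/sqrt(3), c(-1,1,-1)/sqrt(3),
                          c(1,-1,-1)/sqrt(3), c(-1,-1,-1)/sqrt(3))
  topS <- simpleTopology(nrow(shellPts) + 1L, rminHalf = 2.5)
  sB <- sasa(topS, rbind(c(0, 0, 0), shellPts), seq_len(nrow(shellPts) + 1L))
  expect_equal(unname(sB$perAtom[1]), 0)
  # two overlapping spheres vs the analytic cap formula
  r1 <- 1.7 + 1.4; r2 <- 1.5 + 1.4; d <- 2.2
  top2 <- simpleTopology(2, rminHalf = c(1.7, 1.5))
  s3 <- sasa(top2, rbind(c(0, 0, 0), c(d, 0, 0)), 1:2)
  expect_equal(unname(s3$perAtom[1]), twoSphereArea1(r1, r2, d),
               tolerance = 0.01 * 4 * pi * r1^2)
})

test_that("SASA decreases monotonically as a second molecule approaches", {
  top <- simpleTopology(2, rminHalf = 1.8)
  tot <- vapply(seq(8, 2, by = -0.5), function(d)
    sasa(top, rbind(c(0, 0, 0), c(d, 0, 0)), 1:2, nPoints = 960)$total,
    numeric(1))
  expect_true(all(diff(tot) <= 1e-9))
})

test_that("non-polar model is the stated linear form", {
  expect_equal(nonpolarEnergy(0), 0.92)
  expect_equal(nonpolarEnergy(1000), 0.00542 * 1000 + 0.92)
  expect_equal(nonpolarEnergy(200, gamma = 0.005, beta = 0), 1.0)
  expect_error(nonpolarEnergy(-5), "sasaValue")
  cfg <- energyConfig(npPreset = "gb")
  expect_equal(c(cfg$npGamma, cfg$npBeta), c(0.005, 0))
})

test_that("PB is an adapter: absent solver errors, supplied solver is used", {
  sys <- randomSystem(4, seed = 8)
  sys$top@groups <- list(receptor = 1:2, ligand = 3:4)
  expect_error(interactionEnergyFrame(sys$top, sys$xyz, polarModel = "PB"),
               "external solver")
  cfg <- energyConfig(sasaPoints = 60)
  cfg$pbSolver <- function(topology, xyz, group) -1.0 * length(group)
  ec <- interactionEnergyFrame(sys$top, sys$xyz, polarModel = "PB",
                               config = cfg)
  # W(complex) - W(receptor) - W(ligand) = -4 + 2 + 2 = 0 under the stub
  expect_equal(unname(components(ec)["wPolar"]), 0)
  expect_identical(polarModel(ec), "PB")
})

test_that("non-positive Born radii are reported with the atom", {
  # one tiny atom engulfed by several strongly-screening giants
  top <- simpleTopology(4, gbRadius = c(0.2, 2.5, 2.5, 2.5), gbScreen = 1)
  xyz <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(-0.3, 0, 0), c(0, 0.3, 0))
  expect_error(bornRadii(top, xyz, 1:4), "Born radius")
})
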