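test_that("dihedral angle: planar cis/trans, constructed gauche, errors", {
  cis <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, 1, 0))
  expect_equal(dihedralAngle(cis, 1:4), 0, tolerance = 1e-9)
  trans <- rbind(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0), c(2, -1, 0))
  expect_identical(dihedralAngle(trans, 1:4), -180)  # range convention
  # gauche built at +60 about the z-axis; value cross-checked against the
  # standard convention (bio3d::torsion.xyz agrees)
  gauche <- rbind(c(1, 0, -0.5), c(0, 0, 0), c(0, 0, 1.5),
                  c(cos(pi / 3), sin(pi / 3), 2.3))
  expect_equal(dihedralAngle(gauche, 1:4), 60, tolerance = 1e-6)
  expect_equal(dihedralAngle(gauche, 1:4),
               as.numeric(bio3d::torsion.xyz(as.vector(t(gauche)),
                                             atm.inc = 4)),
               tolerance = 1e-6)
  lin <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedralAngle(lin, 1:4), "collinear")
  expect_error(dihedralAngle(cis, c(1, 2, 2, 4)), "distinct")
})

test_that("dihedral extraction: chain ends, pocket residues, phospho chis", {
  toy <- makeToyComplex(toySpec(seed = 1))
  defs <- suppressWarnings(extractDihedrals(toy$topology, 1:3))
  expect_false("res1.phi" %in% defs$label)   # N-terminal residue: no phi
  expect_false("res3.psi" %in% defs$label)   # C-terminal residue: no psi
  expect_true(all(c("res2.phi", "res2.psi", "res2.omega") %in% defs$label))
  expect_true(all(c("res2.chi1", "res2.chi2", "res2.chi3", "res2.chim")
                  %in% defs$label))
  expect_warning(extractDihedrals(toy$topology), "without backbone")
  # the pSer variant lacks only the methyl torsion; phosphate chis match
  toyS <- makeToyComplex(toySpec(phosphoKind = "pser-like", seed = 1))
  defsS <- suppressWarnings(extractDihedrals(toyS$topology, 1:3))
  expect_false("res2.chim" %in% defsS$label)
  expect_true(all(c("res2.chi1", "res2.chi2", "res2.chi3") %in% defsS$label))
})

test_that("Gibbs entropy: delta and uniform closed forms, bin convention", {
  R <- 1.9872e-3
  expect_equal(gibbsEntropy(rep(10.2, 500))$TS, 0)
  width <- 10
  centers <- seq(-175, 175, by = width)
  g <- gibbsEntropy(rep(centers, 100), bins = 36, temperature = 300)
  expect_equal(g$TS, R * 300 * log(36), tolerance = 1e-12)
  # left-closed right-open bins: +180 wraps onto -180 (first bin), while
  # an angle just below 180 stays in the last bin
  g2 <- gibbsEntropy(c(-180, 180), bins = 36)
  expect_equal(sum(g2$p > 0), 1)
  g3 <- gibbsEntropy(c(-180, 179.9999), bins = 36)
  expect_equal(sum(g3$p > 0), 2)
  expect_error(gibbsEntropy(numeric(0)))
  expect_error(gibbsEntropy(1, bins = 1))
})

test_that("entropy is rotation-invariant and maximal iff uniform", {
  set.seed(41)
  x <- sampleVonMisesMixture(20000, vonMisesMixture(c(0.6, 0.4),
                                                    c(-50, 80), c(4, 9)))
  s1 <- gibbsEntropy(x)$S
  # exact invariance for rotations by a whole number of bins
  expect_equal(gibbsEntropy(wrapAngle(x + 70))$S, s1, tolerance = 1e-15)
  # near-invariance for arbitrary rotations
  expect_equal(gibbsEntropy(wrapAngle(x + 73.3))$S, s1, tolerance = 5e-3)
  expect_lt(s1, 1.9872e-3 * log(36))
})

test_that("entropy estimate recovers von Mises ground truth and converges", {
  set.seed(7)
  model <- vonMisesMixture(1, 0, 2)
  truth <- groundTruthEntropy(model, bins = 36, temperature = 300)$TS
  est <- gibbsEntropy(sampleVonMisesMixture(1e5, model), bins = 36,
                      temperature = 300)$TS
  expect_lt(abs(est - truth), 0.02)
  # plug-in bias shrinks with sample size (averaged over repeats)
  errAt <- function(n, reps = 8) mean(vapply(seq_len(reps), function(i)
    abs(gibbsEntropy(sampleVonMisesMixture(n, model))$TS / 300 -
          truth / 300), numeric(1)))
  expect_lt(errAt(40000), errAt(1000))
})

test_that("class decomposition sums to the printed totals", {
  # entropy-change rows: class sums reproduce the printed totals
  expect_equal(0.10 + (-0.01) + 0.00 + 1.03, 1.12, tolerance = 1e-9)
  expect_equal(-0.08 + 0.01 + 0.00 + 0.35, 0.28, tolerance = 1e-9)
})

test_that("entropy decomposition: identity, antisymmetry, unmatched handling", {
  toy <- makeToyComplex(toySpec(seed = 2))
  defs <- suppressWarnings(extractDihedrals(toy$topology, 1:3))
  model <- defaultDihedralModel(toy$topology, toy$xyz)
  ens <- sampleEnsemble(toy$topology, toy$xyz, model, nSeeds = 2,
                        nFrames = 40, seed = 11)
  ser <- dihedralSeries(ens, defs)
  same <- entropyDecomposition(ser, ser)
  expect_true(all(same@classTerms == 0))
  expect_identical(same@tdsTotal, 0)
  # mutant side: drop the methyl torsion, widen chi2
  mut <- makeToyComplex(toySpec(phosphoKind = "pser-like", seed = 2))
  mdefs <- suppressWarnings(extractDihedrals(mut$topology, 1:3))
  mmodel <- defaultDihedralModel(mut$topology, mut$xyz, kappaChi = 5)
  mens <- sampleEnsemble(mut$topology, mut$xyz, mmodel, nSeeds = 2,
                         nFrames = 40, seed = 12)
  mser <- dihedralSeries(mens, mdefs)
  fw <- entropyDecomposition(ser, mser)
  bw <- entropyDecomposition(mser, ser)
  expect_equal(fw@classTerms, -bw@classTerms, tolerance = 1e-12)
  expect_equal(fw@tdsTotal, sum(fw@classTerms), tolerance = 1e-12)
  expect_true("2.chim" %in% fw@unmatched$label)
  expect_false("2.chim" %in% fw@perDihedral$label)
  expect_error(entropyDecomposition(ser[ser$name == "chim", ], mser),
               "no matchable")
})

test_that("rotamer analysis recovers modes, populations and mean shifts", {
  set.seed(13)
  uni <- sampleVonMisesMixture(5000, vonMisesMixture(1, 40, 8))
  r1 <- rotamerStates(uni)
  expect_identical(r1$nStates, 1L)
  expect_equal(r1$populations, 1)
  expect_equal(r1$means[1], 40, tolerance = 3)
  two <- sampleVonMisesMixture(8000, vonMisesMixture(c(0.5, 0.5),
                                                     c(-60, 60), c(8, 8)))
  r2 <- rotamerStates(two)
  expect_identical(r2$nStates, 2L)
  expect_equal(sort(r2$populations), c(0.5, 0.5), tolerance = 0.05)
  expect_equal(sort(r2$means), c(-60, 60), tolerance = 5)
  expect_equal(sum(r2$populations), 1, tolerance = 1e-12)
  # reported shift between unimodal series at 115 and 162 degrees
  a <- sampleVonMisesMixture(5000, vonMisesMixture(1, 115, 30))
  b <- sampleVonMisesMixture(5000, vonMisesMixture(1, 162, 30))
  shift <- abs(circularDiff(rotamerStates(b)$means[1],
                            rotamerStates(a)$means[1]))
  expect_equal(shift, 47, tolerance = 2)
  expect_warning(rotamerStates(runif(50, -180, 180)), "100 samples")
})
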