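# Fixtures are built in code; independent brute-force oracles live here and
# never call the kernels they check.

KE <- 332.0636

simpleAtoms <- function(n, charge = 0, rminHalf = 1.9, epsilon = 0.1,
                        gbRadius = 1.7, gbScreen = 0.8, mass = 12,
                        resid = seq_len(n), name = paste0("X", seq_len(n)),
                        resname = "XXX") {
  data.frame(name = name, resid = resid, resname = resname,
             charge = rep_len(charge, n), rminHalf = rep_len(rminHalf, n),
             epsilon = rep_len(epsilon, n), gbRadius = rep_len(gbRadius, n),
             gbScreen = rep_len(gbScreen, n), mass = rep_len(mass, n),
             stringsAsFactors = FALSE)
}

simpleTopology <- function(n, ..., groups = list()) {
  Topology(simpleAtoms(n, ...), groups = groups)
}

randomSystem <- function(n, seed, spread = 6) {
  set.seed(seed)
  top <- simpleTopology(n, charge = round(runif(n, -1, 1), 3),
                        rminHalf = runif(n, 1.2, 2.1),
                        epsilon = runif(n, 0.02, 0.3),
                        gbRadius = runif(n, 1.2, 2.1),
                        gbScreen = runif(n, 0.6, 1.0))
  list(top = top, xyz = matrix(runif(3 * n, 0, spread), n, 3))
}

# O(N^2) double-loop oracles (plain R)
coulombOracle <- function(xyz, q, ia, ib, cutoff = 40, dielectric = 1) {
  e <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r <= cutoff) e <- e + KE * q[i] * q[j] / (dielectric * r)
  }
  e
}

ljOracle <- function(xyz, rminHalf, eps, ia, ib, cutoff = 40) {
  e <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r > cutoff) next
    em <- sqrt(eps[i] * eps[j]); rm <- rminHalf[i] + rminHalf[j]
    e <- e + em * ((rm / r)^12 - 2 * (rm / r)^6)
  }
  e
}

# Numeric descreening integral (1/4pi int r^-4 dV over the screened sphere
# of j outside radius rhoTi of i), the independent check on HCT radii.
hctIntegralNumeric <- function(r, rhoTi, sr, nR = 20000) {
  if (rhoTi >= r + sr) return(0)
  lo <- max(rhoTi, abs(r - sr)); hi <- r + sr
  s <- seq(lo, hi, length.out = nR)
  ct <- pmin(pmax((r^2 + s^2 - sr^2) / (2 * r * s), -1), 1)
  frac <- (1 - ct) / 2
  val <- sum((frac / s^2)[-1] * diff(s))
  if (rhoTi < sr - r) {
    s2 <- seq(rhoTi, sr - r, length.out = nR)
    val <- val + sum((1 / s2^2)[-1] * diff(s2))
  }
  val
}

# Exact accessible area of sphere 1 partially covered by sphere 2
# (spherical-cap formula); radii are already probe-expanded.
twoSphereArea1 <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * r1^2)
  if (d + r1 <= r2) return(0)
  ca <- (d^2 + r1^2 - r2^2) / (2 * d * r1)
  h <- r1 * (1 - ca)
  4 * pi * r1^2 - 2 * pi * r1 * h
}

# Two-atom bonded diatomic for mutation-free sanity checks
diatomic <- function(d = 1.5) {
  top <- Topology(simpleAtoms(2, resid = c(1, 1)),
                  bonds = matrix(c(1L, 2L), ncol = 2))
  list(top = top, xyz = rbind(c(0, 0, 0), c(d, 0, 0)))
}

# Tiny hand-decodable prmtop (5 atoms, 2 residues, amber N/C type pairs)
writeTinyPrmtop <- function(path, radii = TRUE) {
  fmtE <- function(x) paste(sprintf("%16.8E", x), collapse = "")
  fmtI <- function(x) paste(sprintf("%8d", x), collapse = "")
  lines <- c(
    "%VERSION  VERSION_STAMP = V0001.000",
    "%FLAG POINTERS", "%FORMAT(10I8)",
    fmtI(c(5, 2, 1, 2, 0, 0, 0, 0, 0, 0)),
    fmtI(c(0, 2, 0, 0, 0, 0, 0, 0, 0, 0)),
    fmtI(rep(0, 10)), fmtI(0),
    "%FLAG ATOM_NAME", "%FORMAT(20a4)", "N   CA  CB  C   O   ",
    "%FLAG CHARGE", "%FORMAT(5E16.8)",
    fmtE(18.2223 * c(1, -0.5, 0, 0.5, -1)),
    "%FLAG MASS", "%FORMAT(5E16.8)",
    fmtE(c(14.01, 12.01, 12.01, 12.01, 16)),
    "%FLAG ATOM_TYPE_INDEX", "%FORMAT(10I8)", fmtI(c(1, 2, 2, 2, 1)),
    "%FLAG NONBONDED_PARM_INDEX", "%FORMAT(10I8)", fmtI(c(1, 2, 2, 3)),
    "%FLAG RESIDUE_LABEL", "%FORMAT(20a4)", "ALA GLY ",
    "%FLAG RESIDUE_POINTER", "%FORMAT(10I8)", fmtI(c(1, 4)),
    "%FLAG LENNARD_JONES_ACOEF", "%FORMAT(5E16.8)",
    fmtE(c(944293.233, 0, 1043080.23)),
    "%FLAG LENNARD_JONES_BCOEF", "%FORMAT(5E16.8)",
    fmtE(c(801.323529, 0, 675.612247)),
    "%FLAG BONDS_INC_HYDROGEN", "%FORMAT(10I8)", fmtI(c(0, 3, 1)),
    "%FLAG BONDS_WITHOUT_HYDROGEN", "%FORMAT(10I8)",
    fmtI(c(0, 3, 1, 3, 6, 1)))
  if (radii) lines <- c(lines,
    "%FLAG RADII", "%FORMAT(5E16.8)", fmtE(c(1.55, 1.7, 1.7, 1.7, 1.5)),
    "%FLAG SCREEN", "%FORMAT(5E16.8)", fmtE(c(0.79, 0.72, 0.72, 0.72, 0.85)))
  writeLines(lines, path)
  path
}
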