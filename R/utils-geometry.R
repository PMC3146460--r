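# Units: Angstrom, kcal/mol, elementary charge, degrees, Kelvin.
COULOMB_K <- 332.0636          # kcal*A/(mol*e^2)
PRMTOP_CHARGE_SCALE <- 18.2223 # prmtop internal charge unit -> e
GAS_CONSTANT <- 1.9872e-3      # kcal/(mol*K)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

unitv <- function(a) a / vnorm(a)

#' Wrap angles into [-180, 180)
#' @param x angles in degrees.
#' @return wrapped angles; +180 maps to -180 by the half-open convention.
#' @export
wrapAngle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y >= 180] <- -180
  y
}

#' Circular mean of angles in degrees
#' @param x angles in degrees.
#' @return circular mean in [-180, 180).
#' @export
circularMean <- function(x) {
  r <- x * pi / 180
  wrapAngle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Minimal signed circular difference a - b in degrees
#' @param a,b angles in degrees.
#' @return signed difference in [-180, 180).
#' @export
circularDiff <- function(a, b) wrapAngle(a - b)

# Signed torsion (degrees, [-180, 180)) for one frame; p* are xyz vectors.
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined torsion: three collinear atoms")
  m1 <- vcross(n1, unitv(b2))
  wrapAngle(-atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi)
}

# Vectorized torsion over frames: P1..P4 are F x 3 matrices.
torsionAngleFrames <- function(P1, P2, P3, P4) {
  b1 <- P2 - P1; b2 <- P3 - P2; b3 <- P4 - P3
  crossM <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- crossM(b1, b2); n2 <- crossM(b2, b3)
  nn1 <- sqrt(rowSums(n1^2)); nn2 <- sqrt(rowSums(n2^2))
  if (any(nn1 < 1e-9) || any(nn2 < 1e-9))
    stop("undefined torsion: three collinear atoms")
  b2u <- b2 / sqrt(rowSums(b2^2))
  m1 <- crossM(n1, b2u)
  wrapAngle(-atan2(rowSums(m1 * n2), rowSums(n1 * n2)) * 180 / pi)
}

# NeRF placement: position D bonded to C with |CD| = bond,
# angle(B,C,D) = angleDeg and torsion(A,B,C,D) = torsionDeg.
placeAtom <- function(a, b, c, bond, angleDeg, torsionDeg) {
  ang <- angleDeg * pi / 180; tor <- torsionDeg * pi / 180
  bc <- unitv(c - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-9) stop("collinear reference atoms in placeAtom")
  n <- unitv(n)
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotate points (k x 3) about the axis through `origin` along `axis`.
rotateAboutAxis <- function(pts, origin, axis, angleDeg) {
  th <- angleDeg * pi / 180
  u <- unitv(axis)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(pts, 2, origin) %*% t(R), 2, origin, `+`)
}

# Atoms on the p4 side when the bond p2-p3 of a torsion is cut (BFS over the
# bond graph); used to move the downstream branch when a torsion is set.
movedAtomSet <- function(bonds, natoms, axisFrom, axisTo) {
  adj <- vector("list", natoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(natoms)
  seen[axisFrom] <- TRUE   # block crossing back through the axis bond
  queue <- axisTo
  seen[axisTo] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  out <- which(seen)
  setdiff(out, axisFrom)
}

# Set torsion (a1,a2,a3,a4) to targetDeg by rotating `moved` about a2->a3.
setTorsionCoords <- function(xyz, quad, moved, targetDeg) {
  cur <- torsionAngle(xyz[quad[1], ], xyz[quad[2], ],
                      xyz[quad[3], ], xyz[quad[4], ])
  delta <- wrapAngle(targetDeg - cur)
  if (abs(delta) < 1e-12) return(xyz)
  xyz[moved, ] <- rotateAboutAxis(xyz[moved, , drop = FALSE],
                                  xyz[quad[2], ],
                                  xyz[quad[3], ] - xyz[quad[2], ], delta)
  xyz
}

# Pairs excluded from clash checks: bonded (1-2) and angle (1-3) pairs.
excludedPairs <- function(bonds, natoms) {
  key <- function(i, j) ifelse(i < j, i * (natoms + 1L) + j,
                               j * (natoms + 1L) + i)
  k12 <- key(bonds[, 1], bonds[, 2])
  adj <- vector("list", natoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  k13 <- integer(0)
  for (v in seq_len(natoms)) {
    nb <- adj[[v]]
    if (length(nb) > 1L) {
      cmb <- utils::combn(nb, 2L)
      k13 <- c(k13, key(cmb[1, ], cmb[2, ]))
    }
  }
  unique(c(k12, k13))
}

resolveGroup <- function(topology, group) {
  if (is.character(group) && length(group) == 1L) {
    idx <- topology@groups[[group]]
    if (is.null(idx)) stop(sprintf("no group named '%s' in topology", group))
    return(idx)
  }
  idx <- as.integer(group)
  if (any(idx < 1L) || any(idx > natoms(topology)))
    stop("atom indices out of range")
  idx
}

# Atom range (indices) of residue `ri`.
residueAtoms <- function(topology, ri) {
  r <- topology@residues
  seq.int(r$first[ri], r$last[ri])
}

sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
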