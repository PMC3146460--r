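#' Von Mises mixture specification
#'
#' @param weights mixture weights (sum to 1 after normalisation).
#' @param means component means, degrees.
#' @param kappas component concentrations (>= 0; 0 = circular uniform).
#' @return object of class `vonMisesMixture`.
#' @export
vonMisesMixture <- function(weights, means, kappas) {
  stopifnot(length(weights) == length(means),
            length(means) == length(kappas),
            all(weights > 0), all(kappas >= 0))
  structure(list(weights = weights / sum(weights), means = means,
                 kappas = kappas), class = "vonMisesMixture")
}

# Best-Fisher (1979) rejection sampler for von Mises(mu = 0, kappa).
rvonmises0 <- function(n, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, -pi, pi))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.3 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cq <- kappa * (r - f)
    ok <- (cq * (2 - cq) - u2 > 0) | (log(cq / u2) + 1 - cq >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
    out <- c(out, th)
  }
  out[seq_len(n)]
}

#' Sample angles (degrees) from a von Mises mixture
#'
#' @param n sample size.
#' @param model a [vonMisesMixture()].
#' @return angles in degrees in `[-180, 180)`.
#' @export
sampleVonMisesMixture <- function(n, model) {
  comp <- sample.int(length(model$weights), n, replace = TRUE,
                     prob = model$weights)
  out <- numeric(n)
  for (k in seq_along(model$weights)) {
    idx <- which(comp == k)
    if (!length(idx)) next
    out[idx] <- wrapAngle(rvonmises0(length(idx), model$kappas[k]) *
                            180 / pi + model$means[k])
  }
  out
}

#' Von Mises mixture density over degrees
#'
#' @param x angles in degrees.
#' @param model a [vonMisesMixture()].
#' @return density per degree (integrates to 1 over 360 degrees).
#' @export
vonMisesMixtureDensity <- function(x, model) {
  xr <- x * pi / 180
  d <- 0
  for (k in seq_along(model$weights)) {
    mu <- model$means[k] * pi / 180; kap <- model$kappas[k]
    # exp-scaled Bessel keeps large concentrations finite
    d <- d + model$weights[k] *
      exp(kap * (cos(xr - mu) - 1)) / (2 * pi * besselI(kap, 0, TRUE))
  }
  d * pi / 180
}

#' Exact binned entropy of a von Mises mixture (ground truth)
#'
#' Bin probabilities by numerical integration (Simpson's rule on a fine
#' sub-grid per bin) of the mixture density, then the Gibbs formula
#' applied analytically: the oracle against which histogram entropy
#' estimates from finite samples are judged.
#'
#' @param model a [vonMisesMixture()].
#' @param bins histogram bin count (default 36).
#' @param temperature Kelvin (default 300).
#' @return list with `S` (kcal/(mol K)), `TS` (kcal/mol), `p`.
#' @export
groundTruthEntropy <- function(model, bins = 36L, temperature = 300) {
  width <- 360 / bins
  edges <- seq(-180, 180, by = width)
  nsub <- 40L
  p <- vapply(seq_len(bins), function(b) {
    xs <- seq(edges[b], edges[b + 1], length.out = nsub + 1L)
    ys <- vonMisesMixtureDensity(xs, model)
    h <- width / nsub
    h / 3 * (ys[1] + ys[nsub + 1] + 4 * sum(ys[seq(2, nsub, 2)]) +
               2 * sum(ys[seq(3, nsub - 1, 2)]))
  }, numeric(1))
  p <- p / sum(p)
  S <- -GAS_CONSTANT * sum(p[p > 0] * log(p[p > 0]))
  list(S = S, TS = S * temperature, p = p)
}

#' Specification of a synthetic toy complex
#'
#' The toy complex emulates the geometry that matters for phosphoresidue
#' recognition: a short peptide carrying one phospho-analog residue, a
#' charged pocket with two Arg-like positive pseudo-atoms at hydrogen-bond
#' distance of the phosphate oxygens, and -- in the `"enclosed-cavity"`
#' variant -- nonpolar pocket atoms 3.6-4.2 A from the methyl site (a
#' methyl-sized cavity); the `"open-loop"` variant places those atoms far
#' from the methyl site, emulating a binding site without the cavity.
#'
#' @param nPocketAtoms total pocket pseudo-atoms (default 24).
#' @param pocketGeometry `"enclosed-cavity"` or `"open-loop"`.
#' @param peptideLength peptide residue count (default 3; phosphoresidue
#'   in the middle).
#' @param phosphoKind `"pthr-like"` or `"pser-like"`.
#' @param chargeScheme currently `"default"` (+1 on each Arg-like atom,
#'   neutral elsewhere in the pocket).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return a list of class `toySpec`.
#' @export
toySpec <- function(nPocketAtoms = 24L,
                    pocketGeometry = c("enclosed-cavity", "open-loop"),
                    peptideLength = 3L,
                    phosphoKind = c("pthr-like", "pser-like"),
                    chargeScheme = "default", seed = 1L) {
  structure(list(nPocketAtoms = as.integer(nPocketAtoms),
                 pocketGeometry = match.arg(pocketGeometry),
                 peptideLength = as.integer(peptideLength),
                 phosphoKind = match.arg(phosphoKind),
                 chargeScheme = chargeScheme, seed = as.integer(seed)),
            class = "toySpec")
}

ALA_PARAMS <- local({
  df <- rbind(
    data.frame(name = "N",  charge = -0.40, rminHalf = 1.824,
               epsilon = 0.17, gbRadius = 1.55, gbScreen = 0.79,
               mass = 14.01),
    data.frame(name = "CA", charge = 0.10, rminHalf = 1.908,
               epsilon = 0.1094, gbRadius = 1.70, gbScreen = 0.72,
               mass = 12.01),
    data.frame(name = "CB", charge = 0.00, rminHalf = 1.908,
               epsilon = 0.1094, gbRadius = 1.70, gbScreen = 0.72,
               mass = 12.01),
    data.frame(name = "C",  charge = 0.50, rminHalf = 1.908,
               epsilon = 0.1094, gbRadius = 1.70, gbScreen = 0.72,
               mass = 12.01),
    data.frame(name = "O",  charge = -0.20, rminHalf = 1.661,
               epsilon = 0.21, gbRadius = 1.50, gbScreen = 0.85,
               mass = 16.00))
  df
})


# Internal-coordinate peptide builder.  Ideal bond geometry; the default
# torsions were chosen (once) to maximise the smallest non-bonded distance
# of the reference conformation, so that torsion resampling rarely clashes.
buildPeptide <- function(resnames, phi = -120, psi = 80, chi1 = 60,
                         chi2 = 150, cbTor = -122, methylBranch = -120,
                         opOffset = -40) {
  env <- new.env()
  env$atoms <- list(); env$xyz <- list(); env$bonds <- list()
  addAtom <- function(name, resid, resname, pos, par) {
    i <- length(env$atoms) + 1L
    p <- par[par$name == name, ]
    env$atoms[[i]] <- data.frame(name = name, resid = resid,
                                 resname = resname, charge = p$charge,
                                 rminHalf = p$rminHalf, epsilon = p$epsilon,
                                 gbRadius = p$gbRadius,
                                 gbScreen = p$gbScreen, mass = p$mass,
                                 stringsAsFactors = FALSE)
    env$xyz[[i]] <- pos
    i
  }
  addBond <- function(i, j)
    env$bonds[[length(env$bonds) + 1L]] <- c(unname(i), unname(j))
  at <- function(i) env$xyz[[i]]
  idx <- vector("list", length(resnames))
  for (ri in seq_along(resnames)) {
    rn <- resnames[ri]
    par <- switch(rn, TPO = phosphoResidueParams("pthr"),
                  SEP = phosphoResidueParams("pser"), ALA_PARAMS)
    if (ri == 1L) {
      iN <- addAtom("N", ri, rn, c(0, 0, 0), par)
      iCA <- addAtom("CA", ri, rn, c(1.458, 0, 0), par)
      ang <- (180 - 111) * pi / 180
      iC <- addAtom("C", ri, rn,
                    c(1.458 + 1.525 * cos(ang), 1.525 * sin(ang), 0), par)
    } else {
      p <- idx[[ri - 1L]]
      iN <- addAtom("N", ri, rn,
                    placeAtom(at(p[["N"]]), at(p[["CA"]]), at(p[["C"]]),
                              1.329, 116.6, psi), par)
      iCA <- addAtom("CA", ri, rn,
                     placeAtom(at(p[["CA"]]), at(p[["C"]]), at(iN),
                               1.458, 121.7, 180), par)
      iC <- addAtom("C", ri, rn,
                    placeAtom(at(p[["C"]]), at(iN), at(iCA),
                              1.525, 111, phi), par)
      addBond(p[["C"]], iN)
    }
    addBond(iN, iCA); addBond(iCA, iC)
    iO <- addAtom("O", ri, rn,
                  placeAtom(at(iN), at(iCA), at(iC), 1.231, 120.5,
                            wrapAngle(psi + 180)), par)
    addBond(iC, iO)
    idx[[ri]] <- list(N = iN, CA = iCA, C = iC)
    iCB <- addAtom("CB", ri, rn,
                   placeAtom(at(iC), at(iN), at(iCA), 1.526, 110.5, cbTor),
                   par)
    addBond(iCA, iCB)
    if (rn %in% c("TPO", "SEP")) {
      ogName <- if (rn == "TPO") "OG1" else "OG"
      iOG <- addAtom(ogName, ri, rn,
                     placeAtom(at(iN), at(iCA), at(iCB), 1.43, 109.5, chi1),
                     par)
      addBond(iCB, iOG)
      if (rn == "TPO") {
        iCG2 <- addAtom("CG2", ri, rn,
                        placeAtom(at(iN), at(iCA), at(iCB), 1.525, 109.5,
                                  wrapAngle(chi1 + methylBranch)), par)
        addBond(iCB, iCG2)
        for (k in 1:3) {
          iH <- addAtom(paste0("HG2", k), ri, rn,
                        placeAtom(at(iOG), at(iCB), at(iCG2), 1.09, 109.5,
                                  c(60, 180, -60)[k]), par)
          addBond(iCG2, iH)
        }
      }
      iP <- addAtom("P", ri, rn,
                    placeAtom(at(iCA), at(iCB), at(iOG), 1.61, 119, chi2),
                    par)
      addBond(iOG, iP)
      for (k in 1:3) {
        iOP <- addAtom(paste0("O", k, "P"), ri, rn,
                       placeAtom(at(iCB), at(iOG), at(iP), 1.48, 109.5,
                                 wrapAngle(c(60, 180, -60)[k] + opOffset)), par)
        addBond(iP, iOP)
      }
    }
  }
  list(atoms = do.call(rbind, env$atoms),
       xyz = do.call(rbind, env$xyz),
       bonds = do.call(rbind, env$bonds))
}

pocketAtomRow <- function(name, resname, resid, charge, kind) {
  if (kind == "N")
    data.frame(name = name, resid = resid, resname = resname,
               charge = charge, rminHalf = 1.824, epsilon = 0.17,
               gbRadius = 1.55, gbScreen = 0.79, mass = 14.01,
               stringsAsFactors = FALSE)
  else
    data.frame(name = name, resid = resid, resname = resname,
               charge = charge, rminHalf = 1.908, epsilon = 0.1094,
               gbRadius = 1.70, gbScreen = 0.72, mass = 12.01,
               stringsAsFactors = FALSE)
}

#' Build a synthetic domain-phosphopeptide toy complex
#'
#' Deterministic given the spec (including its seed).  The peptide is built
#' at ideal internal coordinates with the phosphoresidue central; the
#' pocket consists of single-atom pseudo-residues: two Arg-like +1 atoms at
#' hydrogen-bond distance (2.9 A) of two phosphate oxygens, a ring of
#' nonpolar cavity atoms 3.6-4.2 A from the methyl site (enclosed-cavity;
#' moved to >= 8.5 A for open-loop), and neutral filler atoms on a shell
#' around the phosphate that give distance structure to shell selections.
#' Filler placement uses seeded jitter with clash rejection (< 1.5 A
#' regenerates, error after 100 attempts).
#'
#' @param spec a [toySpec()].
#' @return list with `topology` (groups `receptor` / `ligand` assigned),
#'   `xyz`, `phosphoResidue` (residue index) and `methylSite` (xyz of the
#'   CG2 position, actual or virtual).
#' @export
makeToyComplex <- function(spec) {
  stopifnot(inherits(spec, "toySpec"))
  L <- spec$peptideLength
  stopifnot(L >= 1L)
  mid <- ceiling(L / 2)
  resnames <- rep("ALA", L)
  resnames[mid] <- if (spec$phosphoKind == "pthr-like") "TPO" else "SEP"
  pep <- buildPeptide(resnames)
  nm <- pep$atoms$name; rid <- pep$atoms$resid
  gi <- function(name) which(nm == name & rid == mid)
  pCB <- pep$xyz[gi("CB"), ]
  pOG <- pep$xyz[gi(if (resnames[mid] == "TPO") "OG1" else "OG"), ]
  pP <- pep$xyz[gi("P"), ]
  methylSite <- if (resnames[mid] == "TPO") pep$xyz[gi("CG2"), ] else {
    # virtual CG2: the tetrahedral branch anti to the O-P bond, matching
    # the geometry the pSer -> pThr mutation would build
    pN <- pep$xyz[gi("N"), ]; pCA <- pep$xyz[gi("CA"), ]
    chi1 <- torsionAngle(pN, pCA, pCB, pOG)
    cand <- lapply(c(120, -120), function(dt)
      placeAtom(pN, pCA, pCB, 1.525, 109.5, wrapAngle(chi1 + dt)))
    anti <- vapply(cand, function(p)
      abs(abs(torsionAngle(pP, pOG, pCB, p)) - 180), numeric(1))
    cand[[which.min(anti)]]
  }
  withr::with_seed(spec$seed, {
    pocket <- list(); pxyz <- list()
    addP <- function(row, pos) {
      pocket[[length(pocket) + 1L]] <<- row
      pxyz[[length(pxyz) + 1L]] <<- pos
    }
    resid0 <- L
    # two Arg-like guanidinium-analog atoms H-bonded to phosphate oxygens
    for (k in 1:2) {
      o <- pep$xyz[gi(paste0("O", k, "P")), ]
      addP(pocketAtomRow("NH1", "PKR", resid0 + k, +1, "N"),
           o + 2.9 * unitv(o - pP))
    }
    # cavity atoms around the methyl site: candidate directions on a cone
    # about the CB->methyl axis, keeping those clear of the peptide
    u <- unitv(methylSite - pCB)
    ref <- unitv(vcross(u, if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    ref2 <- vcross(u, ref)
    nCav <- 4L
    cands <- c(list(u), lapply(seq(0, 330, 30) * pi / 180, function(az)
      unitv(u * cos(65 * pi / 180) +
              sin(65 * pi / 180) * (cos(az) * ref + sin(az) * ref2))))
    # smallest distance in [3.6, 4.2] that keeps the cavity atom outside
    # the repulsive range of the rotating methyl-hydrogen cone (H at
    # 1.09 A, 70.5 degrees off the CB->CG2 axis)
    minCavDist <- function(dir) {
      alpha <- acos(pmin(pmax(sum(dir * u), -1), 1))
      thMin <- abs(alpha - 70.5 * pi / 180)
      for (d in seq(3.6, 4.2, by = 0.02)) {
        distH <- sqrt(d^2 + 1.09^2 - 2 * 1.09 * d * cos(thMin))
        if (distH >= 2.95) return(d)
      }
      4.2
    }
    methylIdx <- which(rid == mid & nm %in% c("CG2", "HG21", "HG22", "HG23"))
    screenXYZ <- rbind(pep$xyz[setdiff(seq_len(nrow(pep$xyz)), methylIdx), ,
                               drop = FALSE],
                       do.call(rbind, pxyz))
    score <- vapply(cands, function(d) {
      pos <- methylSite + 3.9 * d
      min(sqrt(rowSums(sweep(screenXYZ, 2, pos)^2)))
    }, numeric(1))
    # greedy pick: clearest direction first, >= 60 degrees apart
    take <- integer(0); remaining <- order(score, decreasing = TRUE)
    while (length(take) < nCav && length(remaining)) {
      cnd <- remaining[1]; remaining <- remaining[-1]
      sep <- vapply(take, function(t)
        acos(pmin(pmax(sum(cands[[cnd]] * cands[[t]]), -1), 1)) * 180 / pi,
        numeric(1))
      if (all(sep >= 60)) take <- c(take, cnd)
    }
    for (k in seq_along(take)) {
      d <- if (spec$pocketGeometry == "enclosed-cavity")
        stats::runif(1, minCavDist(cands[[take[k]]]), 4.2) else
        stats::runif(1, 8.5, 10)
      addP(pocketAtomRow("CV", "PKC", resid0 + 2L + k, 0, "C"),
           methylSite + d * cands[[take[k]]])
    }
    nCav <- length(take)
    # filler shell around the phosphate, clash-rejected
    nFill <- max(0L, spec$nPocketAtoms - 2L - nCav)
    placed <- do.call(rbind, c(list(pep$xyz), pxyz))
    for (k in seq_len(nFill)) {
      ok <- FALSE
      for (try in 1:100) {
        v <- stats::rnorm(3); v <- unitv(v)
        r <- stats::runif(1, 6.5, 9.5)
        pos <- pP + r * v
        dmin <- min(sqrt(rowSums(sweep(placed, 2, pos)^2)))
        # keep the filler shell clear of the methyl zone: only the
        # deliberate cavity atoms may pack against the methyl site
        dMe <- sqrt(sum((pos - methylSite)^2))
        if (dmin >= 3.0 && dMe >= 5.5) { ok <- TRUE; break }
      }
      if (!ok) stop("infeasible pocket geometry after 100 attempts")
      addP(pocketAtomRow("CF", "PKF", resid0 + 2L + nCav + k, 0, "C"), pos)
      placed <- rbind(placed, pos)
    }
    atoms <- rbind(pep$atoms, do.call(rbind, pocket))
    xyz <- rbind(pep$xyz, do.call(rbind, pxyz))
    rownames(atoms) <- rownames(xyz) <- NULL
    top <- Topology(atoms, pep$bonds,
                    groups = list(receptor = nrow(pep$atoms) +
                                    seq_len(length(pocket)),
                                  ligand = seq_len(nrow(pep$atoms))))
    list(topology = top, xyz = xyz, phosphoResidue = mid,
         methylSite = methylSite)
  })
}

#' Reference von Mises dihedral model for a toy complex
#'
#' One unimodal von Mises component per rotatable peptide dihedral,
#' centred at the reference-frame value: tightly concentrated backbone
#' (kappa 400, circular sd about 3 degrees) and softer sidechains
#' (kappa 50, about 8 degrees), emulating a peptide fluctuating in its
#' bound well over 1 ns.
#'
#' @param topology,xyz toy complex from [makeToyComplex()].
#' @param residueSet peptide residues to model (default: ligand residues).
#' @param kappaBackbone,kappaChi concentrations for backbone / sidechain.
#' @return named list (by dihedral label) of [vonMisesMixture()] objects;
#'   the dihedral table is attached as attribute `"defs"`.
#' @export
defaultDihedralModel <- function(topology, xyz, residueSet = NULL,
                                 kappaBackbone = 400, kappaChi = 50) {
  if (is.null(residueSet)) {
    lig <- resolveGroup(topology, "ligand")
    residueSet <- which(vapply(seq_len(nrow(topology@residues)),
                               function(ri)
                                 all(residueAtoms(topology, ri) %in% lig),
                               logical(1)))
  }
  defs <- suppressWarnings(extractDihedrals(topology, residueSet))
  model <- list()
  for (d in seq_len(nrow(defs))) {
    cur <- dihedralAngle(xyz, c(defs$a1[d], defs$a2[d], defs$a3[d],
                                defs$a4[d]))
    kap <- if (defs$class[d] == "sidechain") kappaChi else kappaBackbone
    model[[defs$label[d]]] <- vonMisesMixture(1, cur, kap)
  }
  attr(model, "defs") <- defs
  model
}

#' Widen (and optionally shift) the sidechain model of one residue
#'
#' Emulates the extra rotameric freedom of a phosphoresidue whose methyl
#' anchor was removed: sidechain concentrations of the residue are divided
#' by `factor^2` (width scales by `factor`) and means shifted by
#' `shiftDeg`.
#'
#' @param model model from [defaultDihedralModel()].
#' @param residue residue index whose sidechain entries are modified.
#' @param factor width multiplier (default 3).
#' @param shiftDeg mean shift in degrees (default 0).
#' @param names optional specific dihedral names (default: all sidechain).
#' @return modified model (attributes preserved).
#' @export
widenChiModel <- function(model, residue, factor = 3, shiftDeg = 0,
                          names = NULL) {
  defs <- attr(model, "defs")
  sel <- defs$residue == residue & defs$class == "sidechain"
  if (!is.null(names)) sel <- sel & defs$name %in% names
  for (lab in defs$label[sel]) {
    m <- model[[lab]]
    if (is.null(m)) next
    model[[lab]] <- vonMisesMixture(m$weights,
                                    wrapAngle(m$means + shiftDeg),
                                    m$kappas / factor^2)
  }
  model
}

#' Sample a multi-seed trajectory ensemble from a dihedral model
#'
#' The pocket is held rigid; per frame, every modelled peptide dihedral is
#' resampled from its von Mises mixture and the downstream atoms rotated
#' accordingly; frames with any non-bonded pair (1-2 and 1-3 exclusions)
#' closer than `clashTol` are rejected and resampled.  Each seed uses an
#' independent random stream derived from `(seed, seed index)`; sampling
#' is deterministic given those.
#'
#' @param topology,xyz toy complex from [makeToyComplex()].
#' @param model named list of [vonMisesMixture()] with attribute `"defs"`
#'   (see [defaultDihedralModel()]).
#' @param nSeeds number of independent seeds (default 5).
#' @param nFrames frames per seed (default 1000, i.e. 1 ns at 1 frame/ps).
#' @param seed master seed.
#' @param clashTol rejection threshold in Angstrom (default 2.0).
#' @return A [SeedEnsemble-class].
#' @export
sampleEnsemble <- function(topology, xyz, model, nSeeds = 5L,
                           nFrames = 1000L, seed = 1L, clashTol = 2.0) {
  defs <- attr(model, "defs")
  defs <- defs[defs$label %in% names(model), , drop = FALSE]
  if (!nrow(defs)) stop("model covers no dihedrals of this topology")
  nat <- natoms(topology)
  moved <- lapply(seq_len(nrow(defs)), function(d)
    movedAtomSet(topology@bonds, nat, defs$a2[d], defs$a3[d]))
  excl <- excludedPairs(topology@bonds, nat)
  keyOf <- function(i, j) ifelse(i < j, i * (nat + 1L) + j,
                                 j * (nat + 1L) + i)
  movers <- sort(unique(unlist(moved)))
  pairIdx <- which(lower.tri(matrix(0, nat, nat)), arr.ind = TRUE)
  pairOK <- !(keyOf(pairIdx[, 1], pairIdx[, 2]) %in% excl) &
    (pairIdx[, 1] %in% movers | pairIdx[, 2] %in% movers)
  pairIdx <- pairIdx[pairOK, , drop = FALSE]
  trs <- vector("list", nSeeds)
  for (s in seq_len(nSeeds)) {
    streamSeed <- (abs(seed) %% 1000000L) * 1000L + s
    trs[[s]] <- withr::with_seed(streamSeed, {
      arr <- array(0, c(nat, 3L, nFrames))
      rejects <- 0L; accepted <- 0L
      f <- 1L
      while (f <= nFrames) {
        co <- xyz
        for (d in seq_len(nrow(defs))) {
          target <- sampleVonMisesMixture(1L, model[[defs$label[d]]])
          co <- setTorsionCoords(co, c(defs$a1[d], defs$a2[d], defs$a3[d],
                                       defs$a4[d]), moved[[d]], target)
        }
        dmin <- min(sqrt(rowSums((co[pairIdx[, 1], , drop = FALSE] -
                                  co[pairIdx[, 2], , drop = FALSE])^2)))
        if (dmin < clashTol) {
          rejects <- rejects + 1L
          if (rejects + accepted > 50L &&
              rejects / (rejects + accepted) > 0.99)
            stop("clash rejection rate above 99%: revise the dihedral model")
          next
        }
        arr[, , f] <- co
        accepted <- accepted + 1L
        f <- f + 1L
      }
      Trajectory(arr, times = seq_len(nFrames))
    })
  }
  SeedEnsemble(trs, seq_len(nSeeds))
}

#' Paired wild/mutant benchmark with known ground truth
#'
#' Builds a toy complex, samples a wild-type ensemble, and derives the
#' methyl-deletion mutant by removing the (charge-neutral) CG2 methyl
#' pseudo-group while keeping every frame otherwise identical.  For the
#' enclosed-cavity geometry the deleted methyl sits in an attractive
#' nonpolar cavity, so the mutant loses van der Waals attraction and
#' `ddUVdw = uVdw(mutant) - uVdw(wild) > 0`; for the open-loop geometry
#' the cavity atoms are far away and `|ddUVdw|` is small.  Because the
#' methyl is neutral and frames are shared, `ddUCoul` is exactly zero.
#' An independently resampled mutant ensemble with a widened/shifted
#' phospho-sidechain model is included for entropy comparisons.
#'
#' @param spec a [toySpec()] (wild type must be `"pthr-like"`).
#' @param nSeeds,nFrames ensemble size per seed.
#' @param seed master seed for sampling.
#' @param chiWiden width factor for the resampled mutant sidechain.
#' @param chiShift mean shift (degrees) for the resampled mutant chi2.
#' @return list with `wild` / `mutant` (each `topology`, `xyz`,
#'   `ensemble`), `mutantResampled` (mutant topology + independent
#'   ensemble), `phosphoResidue` and `expected` (documented sign pattern).
#' @export
methylDeletionBenchmark <- function(spec = toySpec(), nSeeds = 5L,
                                    nFrames = 200L, seed = 1L,
                                    chiWiden = 3, chiShift = 47) {
  stopifnot(spec$phosphoKind == "pthr-like")
  toy <- makeToyComplex(spec)
  model <- defaultDihedralModel(toy$topology, toy$xyz)
  wildEns <- sampleEnsemble(toy$topology, toy$xyz, model, nSeeds = nSeeds,
                            nFrames = nFrames, seed = seed)
  idx <- residueAtoms(toy$topology, toy$phosphoResidue)
  drop <- idx[toy$topology@atoms$name[idx] %in% METHYL_ATOMS]
  keep <- setdiff(seq_len(natoms(toy$topology)), drop)
  mutTop <- subsetTopology(toy$topology, keep)
  mutEns <- SeedEnsemble(lapply(trajectories(wildEns), function(tr)
    Trajectory(tr@coords[keep, , , drop = FALSE], tr@times)),
    seedIds(wildEns))
  mutXYZ <- toy$xyz[keep, , drop = FALSE]
  mutModel <- defaultDihedralModel(mutTop, mutXYZ)
  mutModel <- widenChiModel(mutModel, toy$phosphoResidue,
                            factor = chiWiden, shiftDeg = chiShift,
                            names = "chi2")
  mutResampled <- sampleEnsemble(mutTop, mutXYZ, mutModel, nSeeds = nSeeds,
                                 nFrames = nFrames, seed = seed + 1L)
  list(wild = list(topology = toy$topology, xyz = toy$xyz,
                   ensemble = wildEns),
       mutant = list(topology = mutTop, xyz = mutXYZ, ensemble = mutEns),
       mutantResampled = list(topology = mutTop, xyz = mutXYZ,
                              ensemble = mutResampled),
       phosphoResidue = toy$phosphoResidue,
       expected = paste("enclosed-cavity: ddUVdw > 0;",
                        "open-loop: |ddUVdw| strictly smaller;",
                        "ddUCoul = 0 exactly (shared frames, neutral methyl)"))
}
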