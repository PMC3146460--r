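# Phospho-residue templates.  Heavy atoms plus the methyl hydrogens; the
# methyl carries zero partial charge so that deleting it leaves the Coulomb
# sum untouched.  These blocks are the package's self-contained synthetic
# parameter set (charges in e, rminHalf in A, epsilon in kcal/mol); real
# studies supply their own blocks in the same shape.

PHOSPHO_NAMES <- c(pthr = "TPO", pser = "SEP")
HYDROXYL_NAME <- c(pthr = "OG1", pser = "OG")
METHYL_ATOMS <- c("CG2", "HG21", "HG22", "HG23")

phosphoParamRow <- function(name, charge, rminHalf, epsilon, gbRadius,
                            gbScreen, mass) {
  data.frame(name = name, charge = charge, rminHalf = rminHalf,
             epsilon = epsilon, gbRadius = gbRadius, gbScreen = gbScreen,
             mass = mass, stringsAsFactors = FALSE)
}

#' Parameter blocks for the toy phosphothreonine / phosphoserine residues
#'
#' Self-contained per-atom parameters (charge, Lennard-Jones, GB radius and
#' screen, mass) for a phosphoresidue with heavy atoms plus methyl
#' hydrogens.  The methyl group is neutral by construction.  Mutation
#' operations require such a block for the residue being created; these are
#' the defaults used by the synthetic systems and may be replaced by any
#' data.frame of the same shape (e.g. published phosphoresidue charges).
#'
#' @param kind `"pthr"` or `"pser"`.
#' @return data.frame with columns `name`, `charge`, `rminHalf`, `epsilon`,
#'   `gbRadius`, `gbScreen`, `mass`.
#' @export
phosphoResidueParams <- function(kind = c("pthr", "pser")) {
  kind <- match.arg(kind)
  bb <- rbind(
    phosphoParamRow("N",  -0.40, 1.824, 0.17,   1.55, 0.79, 14.01),
    phosphoParamRow("CA",  0.10, 1.908, 0.1094, 1.70, 0.72, 12.01),
    phosphoParamRow("CB",  0.10, 1.908, 0.1094, 1.70, 0.72, 12.01))
  og <- phosphoParamRow(HYDROXYL_NAME[[kind]],
                        -0.50, 1.721, 0.2104, 1.50, 0.85, 16.00)
  methyl <- rbind(
    phosphoParamRow("CG2",  0.00, 1.908, 0.1094, 1.70, 0.72, 12.01),
    phosphoParamRow("HG21", 0.00, 1.387, 0.0157, 1.30, 0.85, 1.008),
    phosphoParamRow("HG22", 0.00, 1.387, 0.0157, 1.30, 0.85, 1.008),
    phosphoParamRow("HG23", 0.00, 1.387, 0.0157, 1.30, 0.85, 1.008))
  phos <- rbind(
    phosphoParamRow("P",    1.30, 2.100, 0.20,   1.85, 0.86, 30.97),
    phosphoParamRow("O1P", -1.00, 1.661, 0.21,   1.50, 0.85, 16.00),
    phosphoParamRow("O2P", -1.00, 1.661, 0.21,   1.50, 0.85, 16.00),
    phosphoParamRow("O3P", -1.00, 1.661, 0.21,   1.50, 0.85, 16.00))
  tail <- rbind(
    phosphoParamRow("C",    0.55, 1.908, 0.1094, 1.70, 0.72, 12.01),
    phosphoParamRow("O",   -0.55, 1.661, 0.21,   1.50, 0.85, 16.00))
  if (kind == "pthr") rbind(bb, og, methyl, phos, tail) else
    rbind(bb, og, phos, tail)
}

# Canonical bond lengths (A) used by the geometry validator and builders.
REF_BOND_LENGTHS <- c(
  "N-CA" = 1.458, "CA-C" = 1.525, "C-O" = 1.231, "C-N" = 1.329,
  "CA-CB" = 1.526, "CB-OG" = 1.43, "CB-OG1" = 1.43, "CB-CG2" = 1.525,
  "CG2-HG21" = 1.09, "CG2-HG22" = 1.09, "CG2-HG23" = 1.09,
  "OG-P" = 1.61, "OG1-P" = 1.61, "P-O1P" = 1.48, "P-O2P" = 1.48,
  "P-O3P" = 1.48)

refBondLength <- function(n1, n2) {
  v <- REF_BOND_LENGTHS[paste0(n1, "-", n2)]
  if (is.na(v)) v <- REF_BOND_LENGTHS[paste0(n2, "-", n1)]
  unname(v)
}

applyResidueParams <- function(topology, ri, params) {
  idx <- residueAtoms(topology, ri)
  m <- match(topology@atoms$name[idx], params$name)
  if (anyNA(m))
    stop(sprintf("parameter block lacks atom(s): %s",
                 paste(topology@atoms$name[idx][is.na(m)], collapse = ", ")))
  for (col in c("charge", "rminHalf", "epsilon", "gbRadius", "gbScreen",
                "mass"))
    topology@atoms[[col]][idx] <- params[[col]][m]
  topology
}

checkTemplate <- function(topology, ri, required) {
  have <- topology@atoms$name[residueAtoms(topology, ri)]
  missing <- setdiff(required, have)
  if (length(missing))
    stop(sprintf("residue %d lacks template atom(s): %s", ri,
                 paste(missing, collapse = ", ")))
}

#' Mutate phosphothreonine to phosphoserine in silico
#'
#' Removes the CG2 methyl carbon and its three hydrogens, renames the
#' hydroxyl oxygen (OG1 to OG) and the residue, and re-parameterises the
#' residue from a user-supplied phosphoserine parameter block; charges are
#' never re-derived.  All other atoms keep their coordinates bit-identically.
#'
#' @param topology a [Topology-class].
#' @param xyz an `N x 3` coordinate matrix (one frame).
#' @param residueIndex residue to mutate (row of `residues(topology)`).
#' @param params phosphoserine parameter block
#'   (see [phosphoResidueParams()]); mandatory.
#' @param naming named character vector with entries `pthr` and `pser`
#'   giving residue names (defaults TPO / SEP).
#' @return list with elements `topology` and `xyz`.
#' @export
mutatePthrToPser <- function(topology, xyz, residueIndex,
                             params = NULL, naming = PHOSPHO_NAMES) {
  if (is.null(params))
    stop("parameter error: a phosphoserine parameter block must be supplied")
  checkTemplate(topology, residueIndex,
                c("CB", "OG1", METHYL_ATOMS, "P", "O1P", "O2P", "O3P"))
  idx <- residueAtoms(topology, residueIndex)
  drop <- idx[topology@atoms$name[idx] %in% METHYL_ATOMS]
  keep <- setdiff(seq_len(natoms(topology)), drop)
  top2 <- subsetTopology(topology, keep)
  idx2 <- residueAtoms(top2, residueIndex)
  top2@atoms$name[idx2][top2@atoms$name[idx2] == "OG1"] <- "OG"
  top2@atoms$resname[idx2] <- naming[["pser"]]
  top2@residues$resname[residueIndex] <- naming[["pser"]]
  top2 <- applyResidueParams(top2, residueIndex, params)
  validObject(top2)
  list(topology = top2, xyz = xyz[keep, , drop = FALSE])
}

#' Mutate phosphoserine to phosphothreonine in silico
#'
#' Builds the CG2 methyl at ideal geometry: C-C bond 1.525 A, tetrahedral
#' angles, torsion staggered anti to the O-P branch; three hydrogens at
#' standard geometry.  A placed methyl atom closer than 1 A to any
#' non-bonded atom triggers a warning (not an error).  No minimisation is
#' performed.
#'
#' @inheritParams mutatePthrToPser
#' @param params phosphothreonine parameter block; mandatory.
#' @return list with elements `topology` and `xyz`.
#' @export
mutatePserToPthr <- function(topology, xyz, residueIndex,
                             params = NULL, naming = PHOSPHO_NAMES) {
  if (is.null(params))
    stop("parameter error: a phosphothreonine parameter block must be supplied")
  checkTemplate(topology, residueIndex,
                c("N", "CA", "CB", "OG", "P", "O1P", "O2P", "O3P"))
  idx <- residueAtoms(topology, residueIndex)
  nm <- topology@atoms$name[idx]
  gi <- function(x) idx[match(x, nm)]
  pN <- xyz[gi("N"), ]; pCA <- xyz[gi("CA"), ]; pCB <- xyz[gi("CB"), ]
  pOG <- xyz[gi("OG"), ]; pP <- xyz[gi("P"), ]
  chi1 <- torsionAngle(pN, pCA, pCB, pOG)
  cand <- lapply(c(120, -120), function(dt)
    placeAtom(pN, pCA, pCB, 1.525, 109.5, wrapAngle(chi1 + dt)))
  # pick the branch anti to the O-P bond: |torsion(P, OG, CB, CG2)| near 180
  anti <- vapply(cand, function(p)
    abs(abs(torsionAngle(pP, pOG, pCB, p)) - 180), numeric(1))
  pCG2 <- cand[[which.min(anti)]]
  hTor <- c(60, 180, -60)
  hPos <- lapply(hTor, function(t) placeAtom(pOG, pCB, pCG2, 1.09, 109.5, t))
  newNames <- METHYL_ATOMS
  newXYZ <- rbind(pCG2, do.call(rbind, hPos))

  after <- gi("OG")                     # insert methyl after the hydroxyl O
  nOld <- natoms(topology)
  map <- seq_len(nOld) + 4L * (seq_len(nOld) > after)
  a <- topology@atoms
  newRows <- a[rep(gi("CB"), 4L), ]
  newRows$name <- newNames
  aNew <- rbind(a[seq_len(after), ], newRows,
                a[setdiff(seq_len(nOld), seq_len(after)), ])
  rownames(aNew) <- NULL
  cg2New <- after + 1L
  b <- topology@bonds
  if (nrow(b)) b <- cbind(map[b[, 1]], map[b[, 2]])
  b <- rbind(b, cbind(map[gi("CB")], cg2New),
             cbind(cg2New, cg2New + 1:3))
  grp <- lapply(topology@groups, function(g) {
    g2 <- map[g]
    if (map[gi("CB")] %in% g2) g2 <- sort(c(g2, cg2New + 0:3))
    g2
  })
  top2 <- Topology(aNew, b, grp)
  idx2 <- residueAtoms(top2, residueIndex)
  top2@atoms$name[idx2][top2@atoms$name[idx2] == "OG"] <- "OG1"
  top2@atoms$resname[idx2] <- naming[["pthr"]]
  top2@residues$resname[residueIndex] <- naming[["pthr"]]
  top2 <- applyResidueParams(top2, residueIndex, params)
  validObject(top2)

  xyz2 <- rbind(xyz[seq_len(after), , drop = FALSE], newXYZ,
                xyz[setdiff(seq_len(nOld), seq_len(after)), , drop = FALSE])
  dimnames(xyz2) <- NULL
  # steric check: placed methyl vs non-bonded atoms
  newIdx <- cg2New + 0:3
  bonded <- unique(c(b[b[, 1] %in% newIdx, 2], b[b[, 2] %in% newIdx, 1]))
  others <- setdiff(seq_len(nrow(xyz2)), c(newIdx, bonded))
  d2 <- outer(rowSums(xyz2[newIdx, , drop = FALSE]^2),
              rowSums(xyz2[others, , drop = FALSE]^2), `+`) -
        2 * xyz2[newIdx, , drop = FALSE] %*% t(xyz2[others, , drop = FALSE])
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1.0))
    warning(sprintf("placed methyl clashes (< 1 A) with %d atom(s)",
                    sum(apply(d < 1.0, 2, any))))
  list(topology = top2, xyz = xyz2)
}

#' Compare topologies before and after a mutation
#'
#' Report-only check: atom-count delta, renamed residues, bond-count
#' changes, and (when coordinates are given) bond lengths within changed
#' residues against canonical template lengths; any deviation above 0.1 A
#' marks the report as failed.
#'
#' @param before,after [Topology-class] objects with equal residue counts.
#' @param beforeXYZ,afterXYZ optional coordinate matrices for the geometry
#'   check.
#' @param tol allowed bond-length deviation in Angstrom (default 0.1).
#' @return list with `atomDelta`, `renamedResidues`, `addedAtoms`,
#'   `removedAtoms`, `bondDelta`, `geometryViolations`, `passed`.
#' @export
validateMutation <- function(before, after, beforeXYZ = NULL,
                             afterXYZ = NULL, tol = 0.1) {
  stopifnot(nrow(before@residues) == nrow(after@residues))
  changed <- integer(0); ren <- list()
  for (ri in seq_len(nrow(before@residues))) {
    nb <- before@atoms$name[residueAtoms(before, ri)]
    na_ <- after@atoms$name[residueAtoms(after, ri)]
    rnB <- before@residues$resname[ri]; rnA <- after@residues$resname[ri]
    if (!identical(sort(nb), sort(na_)) || rnB != rnA) {
      changed <- c(changed, ri)
      ren[[length(ren) + 1L]] <- data.frame(index = ri, from = rnB, to = rnA,
                                            stringsAsFactors = FALSE)
    }
  }
  renamed <- if (length(ren)) do.call(rbind, ren) else
    data.frame(index = integer(), from = character(), to = character())
  added <- removed <- character(0)
  for (ri in changed) {
    nb <- before@atoms$name[residueAtoms(before, ri)]
    na_ <- after@atoms$name[residueAtoms(after, ri)]
    added <- c(added, setdiff(na_, nb))
    removed <- c(removed, setdiff(nb, na_))
  }
  violations <- data.frame(residue = integer(), atom1 = character(),
                           atom2 = character(), length = numeric(),
                           expected = numeric())
  if (!is.null(afterXYZ) && length(changed)) {
    for (ri in changed) {
      idx <- residueAtoms(after, ri)
      b <- after@bonds
      inRes <- b[b[, 1] %in% idx & b[, 2] %in% idx, , drop = FALSE]
      for (k in seq_len(nrow(inRes))) {
        i <- inRes[k, 1]; j <- inRes[k, 2]
        ref <- refBondLength(after@atoms$name[i], after@atoms$name[j])
        if (is.na(ref)) next
        len <- vnorm(afterXYZ[i, ] - afterXYZ[j, ])
        if (abs(len - ref) > tol)
          violations <- rbind(violations, data.frame(
            residue = ri, atom1 = after@atoms$name[i],
            atom2 = after@atoms$name[j], length = len, expected = ref))
      }
    }
  }
  list(atomDelta = natoms(after) - natoms(before),
       renamedResidues = renamed, addedAtoms = added,
       removedAtoms = removed,
       bondDelta = nrow(after@bonds) - nrow(before@bonds),
       geometryViolations = violations,
       passed = nrow(violations) == 0L)
}
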