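# Sidechain torsion definitions by residue name.  chi1/chi2/chi3 follow the
# usual convention; "chim" is the methyl torsion of (phospho)threonine, the
# torsion that exists only where the CG2 methyl does.
CHI_DEFS <- list(
  TPO = list(chi1 = c("N", "CA", "CB", "OG1"),
             chi2 = c("CA", "CB", "OG1", "P"),
             chi3 = c("CB", "OG1", "P", "O1P"),
             chim = c("OG1", "CB", "CG2", "HG21")),
  SEP = list(chi1 = c("N", "CA", "CB", "OG"),
             chi2 = c("CA", "CB", "OG", "P"),
             chi3 = c("CB", "OG", "P", "O1P")),
  THR = list(chi1 = c("N", "CA", "CB", "OG1")),
  SER = list(chi1 = c("N", "CA", "CB", "OG")),
  VAL = list(chi1 = c("N", "CA", "CB", "CG1")),
  ALA = list(),
  GLY = list())

classOf <- function(name) ifelse(name %in% c("phi", "psi", "omega"),
                                 name, "sidechain")

#' Enumerate phi/psi/omega and sidechain dihedrals
#'
#' Backbone torsions are emitted where the flanking residue exists and is
#' covalently linked (no phi at the N-terminus, no psi/omega at the
#' C-terminus); sidechain chi chains come from a per-residue-name table
#' that includes the phosphoresidues (chi1 = N-CA-CB-OG/OG1, chi2 =
#' CA-CB-OG-P, chi3 over the phosphate, and the pThr methyl torsion
#' `chim`).  Residues without backbone atoms (e.g. pocket pseudo-atoms)
#' are skipped with one summary warning.
#'
#' @param topology a [Topology-class].
#' @param residueSet residue indices to scan (default: all).
#' @return data.frame with columns `residue`, `name`, `class`, `a1..a4`,
#'   `label`.
#' @export
extractDihedrals <- function(topology, residueSet = NULL) {
  if (is.null(residueSet)) residueSet <- seq_len(nrow(topology@residues))
  b <- topology@bonds
  bondKey <- paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  bonded <- function(i, j) paste(min(i, j), max(i, j)) %in% bondKey
  atomIn <- function(ri, nm) {
    ra <- residueAtoms(topology, ri)
    ra[match(nm, topology@atoms$name[ra])]
  }
  out <- list(); skipped <- integer(0)
  nres <- nrow(topology@residues)
  for (ri in residueSet) {
    N <- atomIn(ri, "N"); CA <- atomIn(ri, "CA"); C <- atomIn(ri, "C")
    if (anyNA(c(N, CA, C))) { skipped <- c(skipped, ri); next }
    add <- function(name, quad)
      out[[length(out) + 1L]] <<- data.frame(
        residue = ri, name = name, class = classOf(name),
        a1 = quad[1], a2 = quad[2], a3 = quad[3], a4 = quad[4],
        label = sprintf("res%d.%s", ri, name), stringsAsFactors = FALSE)
    if (ri > 1L) {
      Cp <- atomIn(ri - 1L, "C")
      if (!is.na(Cp) && bonded(Cp, N)) add("phi", c(Cp, N, CA, C))
    }
    if (ri < nres) {
      Nn <- atomIn(ri + 1L, "N"); CAn <- atomIn(ri + 1L, "CA")
      if (!is.na(Nn) && bonded(C, Nn)) {
        add("psi", c(N, CA, C, Nn))
        if (!is.na(CAn)) add("omega", c(CA, C, Nn, CAn))
      }
    }
    chis <- CHI_DEFS[[topology@residues$resname[ri]]]
    for (cn in names(chis)) {
      quad <- vapply(chis[[cn]], function(nm) atomIn(ri, nm), numeric(1))
      if (!anyNA(quad)) add(cn, quad)
    }
  }
  if (length(skipped))
    warning(sprintf("skipped %d residue(s) without backbone atoms", length(skipped)))
  if (!length(out))
    return(data.frame(residue = integer(), name = character(),
                      class = character(), a1 = integer(), a2 = integer(),
                      a3 = integer(), a4 = integer(), label = character()))
  do.call(rbind, out)
}

#' Signed dihedral angle of four atoms in one frame
#'
#' Standard atan2 construction; result in degrees in `[-180, 180)` (the
#' planar trans arrangement reports as -180).
#'
#' @param xyz `N x 3` coordinate matrix.
#' @param quad four distinct atom indices (a1, a2, a3, a4).
#' @return angle in degrees.
#' @export
dihedralAngle <- function(xyz, quad) {
  quad <- as.integer(quad)
  if (length(unique(quad)) != 4L) stop("four distinct atoms required")
  torsionAngle(xyz[quad[1], ], xyz[quad[2], ], xyz[quad[3], ],
               xyz[quad[4], ])
}

#' Dihedral time series over a trajectory or seed ensemble
#'
#' @param x a [Trajectory-class] or [SeedEnsemble-class].
#' @param defs dihedral table from [extractDihedrals()].
#' @return long data.frame: `label`, `name`, `class`, `residue`, `seed`,
#'   `frame`, `angle` (degrees in `[-180, 180)`).
#' @export
dihedralSeries <- function(x, defs) {
  if (is(x, "Trajectory")) {
    trs <- list(x); ids <- 1L
  } else {
    trs <- trajectories(x); ids <- seedIds(x)
  }
  out <- list()
  for (s in seq_along(trs)) {
    co <- trs[[s]]@coords
    nf <- dim(co)[3]
    for (d in seq_len(nrow(defs))) {
      ang <- torsionAngleFrames(t(co[defs$a1[d], , ]), t(co[defs$a2[d], , ]),
                                t(co[defs$a3[d], , ]), t(co[defs$a4[d], , ]))
      out[[length(out) + 1L]] <- data.frame(
        label = defs$label[d], name = defs$name[d], class = defs$class[d],
        residue = defs$residue[d], seed = ids[s], frame = seq_len(nf),
        angle = ang, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
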