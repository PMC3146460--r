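#' @import methods
NULL

ATOM_COLUMNS <- c("name", "resid", "resname", "charge", "rminHalf",
                  "epsilon", "gbRadius", "gbScreen", "mass")

#' Topology: atoms, bonds, residues and named atom groups
#'
#' A `Topology` carries everything the energy kernels need about a molecular
#' system: per-atom partial charges (e), Lennard-Jones parameters
#' (`rminHalf` in Angstrom, `epsilon` in kcal/mol), generalized-Born intrinsic
#' radii and screening factors, masses, the covalent bond list, the residue
#' table derived from the atom table, and named atom-index groups (at least
#' `"receptor"` and `"ligand"` for binding calculations).  All indices are
#' 1-based.
#'
#' @slot atoms data.frame with columns `name`, `resid`, `resname`, `charge`,
#'   `rminHalf`, `epsilon`, `gbRadius`, `gbScreen`, `mass`.
#' @slot bonds two-column integer matrix of 1-based atom indices.
#' @slot residues data.frame with columns `resname`, `first`, `last`
#'   (inclusive atom-index range); ranges partition the atom list.
#' @slot groups named list of integer vectors of atom indices.
#'
#' @aliases Topology-class
#' @exportClass Topology
setClass("Topology",
         slots = c(atoms = "data.frame", bonds = "matrix",
                   residues = "data.frame", groups = "list"))

setValidity("Topology", function(object) {
  a <- object@atoms
  msgs <- character()
  if (!all(ATOM_COLUMNS %in% names(a)))
    return(paste("atoms table lacks columns:",
                 paste(setdiff(ATOM_COLUMNS, names(a)), collapse = ", ")))
  n <- nrow(a)
  if (any(!is.finite(a$charge))) msgs <- c(msgs, "non-finite charge")
  if (any(a$epsilon < 0)) msgs <- c(msgs, "negative lj epsilon")
  if (any(!is.finite(a$gbRadius)) || any(a$gbRadius <= 0))
    msgs <- c(msgs, "gbRadius must be positive")
  r <- object@residues
  if (nrow(r) > 0L) {
    if (r$first[1] != 1L || r$last[nrow(r)] != n ||
        (nrow(r) > 1L && any(r$first[-1] != r$last[-nrow(r)] + 1L)))
      msgs <- c(msgs, "residue ranges do not partition the atom list")
  } else if (n > 0L) {
    msgs <- c(msgs, "empty residue table for non-empty atom list")
  }
  b <- object@bonds
  if (length(b) && (ncol(b) != 2L || any(b < 1L) || any(b > n)))
    msgs <- c(msgs, "bond indices out of range")
  for (g in names(object@groups)) {
    idx <- object@groups[[g]]
    if (length(idx) && (any(idx < 1L) || any(idx > n)))
      msgs <- c(msgs, sprintf("group '%s' has out-of-range indices", g))
  }
  if (all(c("receptor", "ligand") %in% names(object@groups)) &&
      length(intersect(object@groups$receptor, object@groups$ligand)))
    msgs <- c(msgs, "receptor and ligand groups overlap")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a Topology from an atom table
#'
#' The residue table is derived from consecutive runs of `resid` in `atoms`.
#'
#' @param atoms data.frame, see [Topology-class].
#' @param bonds two-column integer matrix (1-based atom indices).
#' @param groups named list of integer atom-index vectors.
#' @return A [Topology-class] object.
#' @export
Topology <- function(atoms, bonds = matrix(integer(), ncol = 2L),
                     groups = list()) {
  atoms <- as.data.frame(atoms)
  rle.res <- rle(atoms$resid)
  last <- cumsum(rle.res$lengths)
  first <- c(1L, head(last, -1L) + 1L)
  residues <- data.frame(resname = atoms$resname[first],
                         first = as.integer(first), last = as.integer(last),
                         stringsAsFactors = FALSE)
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  new("Topology", atoms = atoms, bonds = bonds, residues = residues,
      groups = lapply(groups, as.integer))
}

#' Trajectory: ordered coordinate frames
#'
#' Coordinates are a dense `natoms x 3 x nframes` array in Angstrom.
#'
#' @slot coords numeric array `N x 3 x F`.
#' @slot times numeric frame times in ps (may be length 0 if unknown).
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory", slots = c(coords = "array", times = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L) return("coords must be an N x 3 x F array")
  if (any(!is.finite(object@coords))) return("non-finite coordinates")
  if (length(object@times) && length(object@times) != d[3])
    return("times length must equal frame count")
  TRUE
})

#' Construct a Trajectory
#' @param coords `N x 3 x F` array, or an `N x 3` matrix for one frame.
#' @param times optional frame times (ps).
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(coords, times = numeric()) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  new("Trajectory", coords = coords, times = as.numeric(times))
}

#' SeedEnsemble: independent-seed trajectories of one system
#'
#' Holds one [Trajectory-class] per random-number seed of a repeated
#' simulation, all sharing a single topology (same atom count).
#'
#' @slot trajectories list of [Trajectory-class].
#' @slot seedIds integer seed labels, one per trajectory.
#' @aliases SeedEnsemble-class
#' @exportClass SeedEnsemble
setClass("SeedEnsemble",
         slots = c(trajectories = "list", seedIds = "integer"))

setValidity("SeedEnsemble", function(object) {
  tr <- object@trajectories
  if (length(tr) < 1L) return("at least one trajectory required")
  if (!all(vapply(tr, is, logical(1), "Trajectory")))
    return("all elements must be Trajectory objects")
  nat <- vapply(tr, function(t) dim(t@coords)[1], integer(1))
  if (length(unique(nat)) != 1L)
    return("trajectories do not share one topology (atom counts differ)")
  if (length(object@seedIds) != length(tr))
    return("seedIds length must match trajectory count")
  TRUE
})

#' Construct a SeedEnsemble
#' @param trajectories list of [Trajectory-class] objects.
#' @param seedIds integer seed labels (default `seq_along(trajectories)`).
#' @return A [SeedEnsemble-class] object.
#' @export
SeedEnsemble <- function(trajectories, seedIds = seq_along(trajectories)) {
  new("SeedEnsemble", trajectories = trajectories,
      seedIds = as.integer(seedIds))
}

ENERGY_TERMS <- c("uVdw", "uCoul", "wPolar", "wNp", "eEle", "eTotNp", "eTot")

#' EnergyComponents: the terms of an interaction-energy decomposition
#'
#' Carries the four independent terms -- intermolecular van der Waals `uVdw`,
#' intermolecular Coulomb `uCoul`, polar solvation difference `wPolar`
#' (GB or PB), non-polar solvation difference `wNp` -- and the derived
#' `eEle = uCoul + wPolar`, `eTot = eEle + uVdw + wNp`,
#' `eTotNp = eTot - wNp`, all in kcal/mol.  For ensemble results the
#' per-seed means and the across-seed standard error are attached.
#'
#' @slot terms named numeric of the seven terms (kcal/mol).
#' @slot polarModel `"GB"` or `"PB"`.
#' @slot perSeed data.frame of per-seed term means (possibly 0 rows).
#' @slot sem named numeric standard errors across seeds (possibly empty).
#' @aliases EnergyComponents-class
#' @exportClass EnergyComponents
setClass("EnergyComponents",
         slots = c(terms = "numeric", polarModel = "character",
                   perSeed = "data.frame", sem = "numeric"))

setValidity("EnergyComponents", function(object) {
  tm <- object@terms
  if (!all(ENERGY_TERMS %in% names(tm))) return("missing energy terms")
  tol <- 1e-6
  if (abs(tm["eEle"] - (tm["uCoul"] + tm["wPolar"])) > tol)
    return("identity eEle = uCoul + wPolar violated")
  if (abs(tm["eTot"] - (tm["eEle"] + tm["uVdw"] + tm["wNp"])) > tol)
    return("identity eTot = eEle + uVdw + wNp violated")
  if (abs(tm["eTotNp"] - (tm["eTot"] - tm["wNp"])) > tol)
    return("identity eTotNp = eTot - wNp violated")
  if (!object@polarModel %in% c("GB", "PB")) return("polarModel must be GB or PB")
  TRUE
})

#' Assemble EnergyComponents from the four independent terms
#'
#' @param uVdw,uCoul,wPolar,wNp energies in kcal/mol.
#' @param polarModel `"GB"` (default) or `"PB"`.
#' @param perSeed optional data.frame of per-seed means.
#' @param sem optional named numeric of across-seed standard errors.
#' @return An [EnergyComponents-class] object with derived terms filled in.
#' @export
energyComponents <- function(uVdw, uCoul, wPolar, wNp, polarModel = "GB",
                             perSeed = data.frame(), sem = numeric()) {
  d <- combineComponents(uVdw, uCoul, wPolar, wNp)
  terms <- c(uVdw = uVdw, uCoul = uCoul, wPolar = wPolar, wNp = wNp, d)
  new("EnergyComponents", terms = terms[ENERGY_TERMS],
      polarModel = polarModel, perSeed = perSeed, sem = sem)
}

#' DeltaDeltaRecord: mutant-minus-wild energy differences
#'
#' One row of a mutation table: the seven [EnergyComponents-class] terms
#' differenced mutant minus wild (positive = mutation unfavorable), with
#' per-seed paired differences and their standard error.
#'
#' @slot label system label (e.g. domain name).
#' @slot site mutated phospho site (1 or 2).
#' @slot mutation `"pT->pS"` or `"pS->pT"`.
#' @slot delta named numeric of the seven differenced terms (kcal/mol).
#' @slot perSeed data.frame of per-seed differences.
#' @slot sem named numeric standard error across seeds.
#' @slot polarModel `"GB"` or `"PB"`.
#' @aliases DeltaDeltaRecord-class
#' @exportClass DeltaDeltaRecord
setClass("DeltaDeltaRecord",
         slots = c(label = "character", site = "numeric",
                   mutation = "character", delta = "numeric",
                   perSeed = "data.frame", sem = "numeric",
                   polarModel = "character"))

setValidity("DeltaDeltaRecord", function(object) {
  d <- object@delta
  if (!all(ENERGY_TERMS %in% names(d))) return("missing delta terms")
  tol <- 1e-6
  if (abs(d["eEle"] - (d["uCoul"] + d["wPolar"])) > tol ||
      abs(d["eTot"] - (d["eEle"] + d["uVdw"] + d["wNp"])) > tol ||
      abs(d["eTotNp"] - (d["eTot"] - d["wNp"])) > tol)
    return("delta-delta arithmetic identities violated")
  TRUE
})

#' ShellSelection: domain residues near the phosphate group
#'
#' @slot cutoff distance cutoff in Angstrom.
#' @slot phosphateAtoms atom names defining the phosphate group.
#' @slot residues data.frame (`index`, `resname`) of selected domain residues.
#' @slot ligandResidues integer residue indices retained on the peptide side.
#' @slot referenceFrame frame index the selection was made on.
#' @slot phosphoResidue residue index of the phosphoresidue.
#' @aliases ShellSelection-class
#' @exportClass ShellSelection
setClass("ShellSelection",
         slots = c(cutoff = "numeric", phosphateAtoms = "character",
                   residues = "data.frame", ligandResidues = "integer",
                   referenceFrame = "integer", phosphoResidue = "integer"))

setValidity("ShellSelection", function(object) {
  if (object@cutoff <= 0) return("cutoff must be positive")
  if (object@phosphoResidue %in% object@residues$index)
    return("phosphoresidue must be excluded from the domain-side selection")
  TRUE
})

#' EntropyRecord: dihedral-entropy change decomposed by class
#'
#' `T * dS` (kcal/mol) for the backbone classes phi, psi, omega and the
#' pooled sidechain class, plus their total, at a stated temperature and
#' histogram bin count; per-dihedral values and any unmatched dihedrals
#' (e.g. the pThr methyl torsion) are attached.
#'
#' @slot classTerms named numeric `c(phi=, psi=, omega=, sidechain=)`.
#' @slot tdsTotal sum of the class terms (kcal/mol).
#' @slot temperature Kelvin.
#' @slot bins histogram bin count used.
#' @slot perDihedral data.frame of matched per-dihedral entropies.
#' @slot unmatched data.frame of dihedrals present on one side only.
#' @aliases EntropyRecord-class
#' @exportClass EntropyRecord
setClass("EntropyRecord",
         slots = c(classTerms = "numeric", tdsTotal = "numeric",
                   temperature = "numeric", bins = "integer",
                   perDihedral = "data.frame", unmatched = "data.frame"))

setValidity("EntropyRecord", function(object) {
  if (!all(c("phi", "psi", "omega", "sidechain") %in%
           names(object@classTerms)))
    return("classTerms must name phi, psi, omega, sidechain")
  if (abs(object@tdsTotal - sum(object@classTerms)) > 1e-9)
    return("tdsTotal must equal the sum of class terms")
  TRUE
})
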