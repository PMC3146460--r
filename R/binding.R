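#' Derived energy terms from the four independent components
#'
#' `eEle = uCoul + wPolar`; `eTot = eEle + uVdw + wNp`;
#' `eTotNp = eTot - wNp`.
#'
#' @param uVdw,uCoul,wPolar,wNp energies in kcal/mol (finite).
#' @return named numeric `c(eEle, eTot, eTotNp)`.
#' @export
combineComponents <- function(uVdw, uCoul, wPolar, wNp) {
  stopifnot(is.finite(uVdw), is.finite(uCoul), is.finite(wPolar),
            is.finite(wNp))
  eEle <- uCoul + wPolar
  eTot <- eEle + uVdw + wNp
  c(eEle = eEle, eTot = eTot, eTotNp = eTot - wNp)
}

#' Single-trajectory interaction energy of one frame
#'
#' The single-trajectory contract: complex, receptor and ligand are all
#' evaluated on the same coordinates, so every intramolecular (valence)
#' term cancels and `uVdw` / `uCoul` reduce to the intermolecular pair
#' sums.  Solvation terms are complex-minus-parts differences on identical
#' coordinates: `wPolar = W(complex) - W(receptor) - W(ligand)` (GB, or an
#' external PB solver via the adapter), and `wNp` likewise from the SASA
#' model.
#'
#' @param topology a [Topology-class] with the groups present.
#' @param xyz an `N x 3` coordinate matrix.
#' @param receptor,ligand group names or disjoint atom-index vectors.
#' @param polarModel `"GB"` (implemented) or `"PB"` (adapter; see
#'   [energyConfig()]).
#' @param config an [energyConfig()] list.
#' @return An [EnergyComponents-class].
#' @export
interactionEnergyFrame <- function(topology, xyz, receptor = "receptor",
                                   ligand = "ligand", polarModel = "GB",
                                   config = energyConfig()) {
  ia <- resolveGroup(topology, receptor)
  ib <- resolveGroup(topology, ligand)
  checkDisjoint(ia, ib)
  both <- c(ia, ib)
  uVdw <- ljEnergy(topology, xyz, ia, ib, cutoff = config$cutoff)
  uCoul <- coulombEnergy(topology, xyz, ia, ib, cutoff = config$cutoff,
                         dielectric = config$dielectric)
  wPolar <- polarSolvation(topology, xyz, both, polarModel, config) -
    polarSolvation(topology, xyz, ia, polarModel, config) -
    polarSolvation(topology, xyz, ib, polarModel, config)
  sasaOf <- function(g) sasa(topology, xyz, g, probe = config$sasaProbe,
                             nPoints = config$sasaPoints)$total
  np <- function(s) nonpolarEnergy(s, config$npGamma, config$npBeta)
  wNp <- np(sasaOf(both)) - np(sasaOf(ia)) - np(sasaOf(ib))
  energyComponents(uVdw, uCoul, wPolar, wNp, polarModel = polarModel)
}

#' Ensemble-averaged interaction energy over independent seeds
#'
#' Per-frame components are averaged within each seed, then summarised as
#' the mean across seeds with its standard error (frames within a short run
#' are autocorrelated; seeds are the independent unit).
#'
#' @param topology a [Topology-class].
#' @param ensemble a [SeedEnsemble-class].
#' @inheritParams interactionEnergyFrame
#' @return An [EnergyComponents-class] with the per-seed table and SEM.
#' @export
interactionEnergy <- function(topology, ensemble, receptor = "receptor",
                              ligand = "ligand", polarModel = "GB",
                              config = energyConfig()) {
  trs <- trajectories(ensemble)
  perSeed <- vector("list", length(trs))
  for (s in seq_along(trs)) {
    nf <- nframes(trs[[s]])
    if (nf < 1L) stop("empty trajectory in ensemble")
    frames <- seq(1L, nf, by = config$stride)
    acc <- matrix(0, length(frames), length(ENERGY_TERMS),
                  dimnames = list(NULL, ENERGY_TERMS))
    for (k in seq_along(frames)) {
      ec <- interactionEnergyFrame(topology, getFrame(trs[[s]], frames[k]),
                                   receptor, ligand, polarModel, config)
      acc[k, ] <- components(ec)
    }
    perSeed[[s]] <- colMeans(acc)
  }
  tab <- as.data.frame(do.call(rbind, perSeed))
  tab <- cbind(seed = seedIds(ensemble), tab)
  m <- colMeans(tab[ENERGY_TERMS])
  s <- vapply(tab[ENERGY_TERMS], sem, numeric(1))
  energyComponents(m[["uVdw"]], m[["uCoul"]], m[["wPolar"]], m[["wNp"]],
                   polarModel = polarModel, perSeed = tab, sem = s)
}

#' Mutant-minus-wild difference of two energy decompositions
#'
#' Every component is differenced mutant minus wild, so a positive entry
#' means the mutation is unfavorable.  Per-seed values are paired by seed
#' where both sides carry per-seed tables with equal seed sets.
#'
#' @param wild,mutant [EnergyComponents-class] objects with the same polar
#'   model.
#' @param label system label.
#' @param site mutated phospho site (1 or 2).
#' @param mutation `"pT->pS"` or `"pS->pT"`.
#' @return A [DeltaDeltaRecord-class].
#' @export
deltaDelta <- function(wild, mutant, label = "system", site = 1,
                       mutation = "pT->pS") {
  if (polarModel(wild) != polarModel(mutant))
    stop("polar model mismatch between wild and mutant")
  d <- components(mutant) - components(wild)
  perSeed <- data.frame(); semOut <- numeric()
  pw <- perSeedTable(wild); pm <- perSeedTable(mutant)
  if (nrow(pw) && nrow(pm) && identical(pw$seed, pm$seed)) {
    perSeed <- cbind(seed = pw$seed, pm[ENERGY_TERMS] - pw[ENERGY_TERMS])
    semOut <- vapply(perSeed[ENERGY_TERMS], sem, numeric(1))
  }
  new("DeltaDeltaRecord", label = label, site = as.numeric(site),
      mutation = mutation, delta = d, perSeed = perSeed, sem = semOut,
      polarModel = polarModel(wild))
}

#' Select domain residues within a cutoff of the phosphate group
#'
#' A receptor residue is selected iff any of its atoms lies within `cutoff`
#' of any phosphate atom of the phosphoresidue (residue-level, any-atom
#' criterion).  On the peptide side the phosphoresidue plus `neighbors`
#' flanking residues are retained.  The selection is made on a single
#' reference frame and reused, so wild-type and mutant are compared over
#' the same residue set.
#'
#' @param topology a [Topology-class] with receptor/ligand groups.
#' @param xyz reference-frame coordinates (`N x 3`).
#' @param phosphoResidue residue index of the phosphoresidue.
#' @param cutoff shell radius in Angstrom (default 6, the midpoint of the
#'   5-7 A range; any value in that range is conventional).
#' @param phosphateAtoms atom names defining the phosphate group.
#' @param neighbors flanking peptide residues kept (default 1 each side).
#' @param referenceFrame frame index recorded in the selection.
#' @return A [ShellSelection-class].
#' @export
shellSelect <- function(topology, xyz, phosphoResidue, cutoff = 6,
                        phosphateAtoms = c("P", "O1P", "O2P", "O3P",
                                           "OG", "OG1"),
                        neighbors = 1L, referenceFrame = 1L) {
  stopifnot(cutoff > 0)
  pidx <- residueAtoms(topology, phosphoResidue)
  phos <- pidx[topology@atoms$name[pidx] %in% phosphateAtoms]
  if (!length(phos))
    stop(sprintf("no phosphate atoms (%s) found in residue %d",
                 paste(phosphateAtoms, collapse = "/"), phosphoResidue))
  rec <- resolveGroup(topology, "receptor")
  # residue rows whose atoms belong to the receptor group
  recRows <- which(vapply(seq_len(nrow(topology@residues)), function(ri)
    all(residueAtoms(topology, ri) %in% rec), logical(1)))
  phosXYZ <- xyz[phos, , drop = FALSE]
  sel <- recRows[vapply(recRows, function(ri) {
    ra <- residueAtoms(topology, ri)
    d2 <- outer(rowSums(xyz[ra, , drop = FALSE]^2), rowSums(phosXYZ^2), `+`) -
      2 * xyz[ra, , drop = FALSE] %*% t(phosXYZ)
    sqrt(max(0, min(d2))) <= cutoff
  }, logical(1))]
  lig <- resolveGroup(topology, "ligand")
  ligRows <- which(vapply(seq_len(nrow(topology@residues)), function(ri)
    all(residueAtoms(topology, ri) %in% lig), logical(1)))
  ligKeep <- intersect(seq(phosphoResidue - neighbors,
                           phosphoResidue + neighbors), ligRows)
  new("ShellSelection", cutoff = cutoff,
      phosphateAtoms = phosphateAtoms,
      residues = data.frame(index = sel,
                            resname = topology@residues$resname[sel],
                            stringsAsFactors = FALSE),
      ligandResidues = as.integer(ligKeep),
      referenceFrame = as.integer(referenceFrame),
      phosphoResidue = as.integer(phosphoResidue))
}

#' Frame minimising the mean RMSD to all other frames
#'
#' Default reference for [shellSelect()] on an ensemble: the most central
#' frame of the pooled wild-type ensemble.
#'
#' @param ensemble a [SeedEnsemble-class].
#' @param selection atom indices for the RMSD (default all).
#' @param maxFrames subsample cap to keep the all-vs-all scan cheap.
#' @return list with `seed` (position in the ensemble) and `frame` index.
#' @export
centralFrame <- function(ensemble, selection = NULL, maxFrames = 100L) {
  trs <- trajectories(ensemble)
  pool <- list(); ids <- list()
  for (s in seq_along(trs)) {
    nf <- nframes(trs[[s]])
    take <- unique(round(seq(1L, nf, length.out = min(nf, ceiling(maxFrames / length(trs))))))
    for (f in take) {
      pool[[length(pool) + 1L]] <- getFrame(trs[[s]], f)
      ids[[length(ids) + 1L]] <- c(s, f)
    }
  }
  n <- length(pool)
  md <- numeric(n)
  for (i in seq_len(n))
    md[i] <- mean(vapply(seq_len(n)[-i], function(j)
      frameRMSD(pool[[i]], pool[[j]], selection), numeric(1)))
  best <- which.min(md)
  list(seed = ids[[best]][1], frame = ids[[best]][2])
}

#' Local (phosphate-shell) interaction energy
#'
#' Restricts the calculation to the shell residues on the domain side and
#' the phosphoresidue plus its configured neighbors on the peptide side;
#' GB radii and SASA are evaluated on the reduced subsystem (set
#' `fullComplexRadii = TRUE` to descreen GB radii within the full complex
#' instead).  Averaged exactly as [interactionEnergy()]; the polar model is
#' GB.
#'
#' @param topology a [Topology-class].
#' @param ensemble a [SeedEnsemble-class].
#' @param shell a [ShellSelection-class] (non-empty).
#' @param config an [energyConfig()] list.
#' @param fullComplexRadii descreen Born radii within the full complex
#'   rather than the reduced subsystem (default FALSE: subsystem radii).
#' @return An [EnergyComponents-class] with per-seed table and SEM.
#' @export
localInteractionEnergy <- function(topology, ensemble, shell,
                                   config = energyConfig(),
                                   fullComplexRadii = FALSE) {
  if (!nrow(shell@residues)) stop("empty shell selection")
  recAtoms <- unlist(lapply(shell@residues$index, residueAtoms,
                            topology = topology))
  ligAtoms <- unlist(lapply(shell@ligandResidues, residueAtoms,
                            topology = topology))
  if (fullComplexRadii) {
    # evaluate on the full topology so descreening sees every complex atom
    config$gbDescreenBy <- sort(c(resolveGroup(topology, "receptor"),
                                  resolveGroup(topology, "ligand")))
    return(interactionEnergy(topology, ensemble, receptor = recAtoms,
                             ligand = ligAtoms, polarModel = "GB",
                             config = config))
  }
  keep <- sort(c(recAtoms, ligAtoms))
  sub <- subsetTopology(topology, keep)
  sub@groups$receptor <- match(recAtoms, keep)
  sub@groups$ligand <- match(ligAtoms, keep)
  trs <- lapply(trajectories(ensemble), function(tr)
    Trajectory(tr@coords[keep, , , drop = FALSE]))
  subEns <- SeedEnsemble(trs, seedIds(ensemble))
  interactionEnergy(sub, subEns, polarModel = "GB", config = config)
}
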