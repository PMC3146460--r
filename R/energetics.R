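#' Energy configuration
#'
#' Collects every tunable of the MM-GBSA kernels in one place so that all
#' results are self-describing.  Non-polar presets follow the two Amber
#' conventions: `"pb"` uses gamma = 0.00542 kcal/(mol*A^2), beta = 0.92
#' kcal/mol; `"gb"` uses gamma = 0.005, beta = 0.
#'
#' @param cutoff non-bonded cutoff in Angstrom (hard truncation, Coulomb/LJ).
#' @param dielectric Coulomb dielectric.
#' @param epsIn,epsOut GB interior/exterior dielectric constants.
#' @param gbOffset intrinsic-radius offset in Angstrom (igb=1 convention).
#' @param npPreset `"pb"` or `"gb"`; sets `npGamma`/`npBeta` unless given.
#' @param npGamma,npBeta non-polar SASA coefficients, kcal/(mol*A^2), kcal/mol.
#' @param sasaProbe solvent probe radius, Angstrom.
#' @param sasaPoints sphere sample points per atom (Shrake-Rupley).
#' @param stride frame stride for ensemble averaging.
#' @param pbSolver optional function `(topology, frame, group) -> kcal/mol`
#'   adapting an external Poisson-Boltzmann solver; required for
#'   `polarModel = "PB"`.
#' @return a named list of settings.
#' @export
energyConfig <- function(cutoff = 40, dielectric = 1, epsIn = 1, epsOut = 80,
                         gbOffset = 0.09, npPreset = c("pb", "gb"),
                         npGamma = NULL, npBeta = NULL, sasaProbe = 1.4,
                         sasaPoints = 960L, stride = 1L, pbSolver = NULL) {
  npPreset <- match.arg(npPreset)
  preset <- if (npPreset == "pb") c(0.00542, 0.92) else c(0.005, 0)
  list(cutoff = cutoff, dielectric = dielectric, epsIn = epsIn,
       epsOut = epsOut, gbOffset = gbOffset, npPreset = npPreset,
       npGamma = if (is.null(npGamma)) preset[1] else npGamma,
       npBeta = if (is.null(npBeta)) preset[2] else npBeta,
       sasaProbe = sasaProbe, sasaPoints = as.integer(sasaPoints),
       stride = as.integer(stride), pbSolver = pbSolver,
       gbDescreenBy = NULL)
}

checkDisjoint <- function(ia, ib) {
  if (length(intersect(ia, ib)))
    stop("groups overlap: intermolecular energies require disjoint groups")
}

#' Intermolecular Coulomb energy between two atom groups
#'
#' Hard-truncated pair sum `k_e * q_i * q_j / (dielectric * r_ij)` over pairs
#' with `r_ij <= cutoff`, `k_e` = 332.0636 kcal*A/(mol*e^2).  No switching,
#' no intra-group terms.
#'
#' @param topology a [Topology-class].
#' @param xyz an `N x 3` coordinate matrix (one frame).
#' @param groupA,groupB group names or atom-index vectors; must be disjoint.
#' @param cutoff cutoff in Angstrom (default 40).
#' @param dielectric relative dielectric (default 1).
#' @return energy in kcal/mol.
#' @export
coulombEnergy <- function(topology, xyz, groupA, groupB, cutoff = 40,
                          dielectric = 1) {
  ia <- resolveGroup(topology, groupA); ib <- resolveGroup(topology, groupB)
  checkDisjoint(ia, ib)
  pairCoulombCpp(xyz, topology@atoms$charge, ia, ib, cutoff, dielectric,
                 COULOMB_K)
}

#' Intermolecular Lennard-Jones energy between two atom groups
#'
#' `sum eps * ((rmin/r)^12 - 2 (rmin/r)^6)` with Lorentz-Berthelot-style
#' combining on the rmin/2 + epsilon parameterisation:
#' `rmin = rminHalf_i + rminHalf_j`, `eps = sqrt(eps_i * eps_j)`.
#'
#' @inheritParams coulombEnergy
#' @return energy in kcal/mol.
#' @export
ljEnergy <- function(topology, xyz, groupA, groupB, cutoff = 40) {
  ia <- resolveGroup(topology, groupA); ib <- resolveGroup(topology, groupB)
  checkDisjoint(ia, ib)
  pairLJCpp(xyz, topology@atoms$rminHalf, topology@atoms$epsilon, ia, ib,
            cutoff)
}

#' Effective Born radii by HCT pairwise descreening
#'
#' Hawkins-Cramer-Truhlar pairwise-descreening integrals (the `igb = 1`
#' analogue): each atom's inverse effective radius is its inverse offset
#' intrinsic radius minus the sum of closed-form descreening integrals over
#' all other atoms' screened spheres.  No cutoff is applied.
#'
#' @inheritParams coulombEnergy
#' @param group group name or atom-index vector.
#' @param offset intrinsic-radius offset in Angstrom (default 0.09).
#' @return numeric vector of effective radii (Angstrom), named by atom index.
#' @export
bornRadii <- function(topology, xyz, group, offset = 0.09) {
  ig <- resolveGroup(topology, group)
  a <- topology@atoms
  r <- hctRadiiCpp(xyz[ig, , drop = FALSE], a$gbRadius[ig], a$gbScreen[ig],
                   offset)
  if (any(r <= 0))
    stop(sprintf("non-positive effective Born radius for atom(s) %s",
                 paste(ig[r <= 0], collapse = ", ")))
  names(r) <- ig
  r
}

#' GB polar solvation free energy of an atom group
#'
#' Effective radii from [bornRadii()], then the canonical generalized-Born
#' pair sum `-1/2 k_e (1/epsIn - 1/epsOut) sum_ij q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + Ri Rj exp(-r^2 / (4 Ri Rj)))` and self terms
#' (`f_GB = Ri`).  The group is treated as an isolated subsystem: radii are
#' descreened by group members only.
#'
#' @inheritParams bornRadii
#' @param epsIn,epsOut interior/exterior dielectrics (defaults 1 and 80).
#' @param descreenBy optional atom set whose union with `group` defines the
#'   descreening environment for the Born radii (default: the group itself).
#' @return energy in kcal/mol.
#' @export
gbEnergy <- function(topology, xyz, group, epsIn = 1, epsOut = 80,
                     offset = 0.09, descreenBy = NULL) {
  ig <- resolveGroup(topology, group)
  env <- if (is.null(descreenBy)) ig else
    sort(union(ig, resolveGroup(topology, descreenBy)))
  reff <- bornRadii(topology, xyz, env, offset = offset)
  reff <- reff[match(ig, env)]
  gbPairSumCpp(xyz[ig, , drop = FALSE], topology@atoms$charge[ig], reff,
               epsIn, epsOut, COULOMB_K)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Point-count estimate on a deterministic golden-spiral sphere per atom.
#' Van der Waals radii default to the atoms' `rminHalf`.
#'
#' @inheritParams bornRadii
#' @param probe probe radius in Angstrom (default 1.4).
#' @param nPoints sphere sample points per atom (default 960).
#' @param radii optional explicit vdW radii (length `natoms(topology)`).
#' @return list with `total` (A^2) and `perAtom` (named numeric, A^2).
#' @export
sasa <- function(topology, xyz, group, probe = 1.4, nPoints = 960L,
                 radii = NULL) {
  ig <- resolveGroup(topology, group)
  if (is.null(radii)) radii <- topology@atoms$rminHalf
  per <- sasaCpp(xyz[ig, , drop = FALSE], radii[ig], probe,
                 as.integer(nPoints))
  names(per) <- ig
  list(total = sum(per), perAtom = per)
}

#' Non-polar solvation energy from SASA
#'
#' The linear SASA model `gamma * SASA + beta`.  Defaults are the PB-style
#' Amber coefficients; see [energyConfig()] for the GB-style preset.
#'
#' @param sasaValue surface area in A^2 (must be non-negative).
#' @param gamma surface tension coefficient, kcal/(mol*A^2).
#' @param beta offset, kcal/mol.
#' @return energy in kcal/mol.
#' @export
nonpolarEnergy <- function(sasaValue, gamma = 0.00542, beta = 0.92) {
  stopifnot(sasaValue >= 0)
  gamma * sasaValue + beta
}

# Polar solvation of one group under the configured model.
polarSolvation <- function(topology, xyz, group, polarModel, config) {
  if (polarModel == "GB") {
    gbEnergy(topology, xyz, group, epsIn = config$epsIn,
             epsOut = config$epsOut, offset = config$gbOffset,
             descreenBy = config$gbDescreenBy)
  } else {
    if (is.null(config$pbSolver))
      stop("polarModel = 'PB' requires an external solver via ",
           "energyConfig(pbSolver = ...)")
    config$pbSolver(topology, xyz, group)
  }
}
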