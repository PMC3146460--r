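#' @include AllClasses.R
NULL

#' Accessors for phosdelta containers
#'
#' Small accessor family: `atoms()`, `bonds()`, `residues()`, `groups()`,
#' `natoms()`, `nframes()`, `getFrame()`, `trajectories()`, `seedIds()`,
#' `components()`, `polarModel()`, `perSeedTable()`, `standardError()`.
#'
#' @param x a phosdelta object.
#' @param i frame index for `getFrame()`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
#' @rdname accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))
#' @rdname accessors
#' @export
setGeneric("natoms", function(x) standardGeneric("natoms"))
#' @rdname accessors
#' @export
setGeneric("nframes", function(x) standardGeneric("nframes"))
#' @rdname accessors
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
#' @rdname accessors
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))
#' @rdname accessors
#' @export
setGeneric("seedIds", function(x) standardGeneric("seedIds"))
#' @rdname accessors
#' @export
setGeneric("components", function(x) standardGeneric("components"))
#' @rdname accessors
#' @export
setGeneric("polarModel", function(x) standardGeneric("polarModel"))
#' @rdname accessors
#' @export
setGeneric("perSeedTable", function(x) standardGeneric("perSeedTable"))
#' @rdname accessors
#' @export
setGeneric("standardError", function(x) standardGeneric("standardError"))

#' @rdname accessors
setMethod("atoms", "Topology", function(x) x@atoms)
#' @rdname accessors
setMethod("bonds", "Topology", function(x) x@bonds)
#' @rdname accessors
setMethod("residues", "Topology", function(x) x@residues)
#' @rdname accessors
setMethod("groups", "Topology", function(x) x@groups)
#' @rdname accessors
setMethod("natoms", "Topology", function(x) nrow(x@atoms))
#' @rdname accessors
setMethod("natoms", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
setMethod("nframes", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname accessors
setMethod("getFrame", "Trajectory", function(x, i) x@coords[, , i, drop = TRUE])
#' @rdname accessors
setMethod("trajectories", "SeedEnsemble", function(x) x@trajectories)
#' @rdname accessors
setMethod("seedIds", "SeedEnsemble", function(x) x@seedIds)
#' @rdname accessors
setMethod("nframes", "SeedEnsemble",
          function(x) sum(vapply(x@trajectories, nframes, integer(1))))
#' @rdname accessors
setMethod("components", "EnergyComponents", function(x) x@terms)
#' @rdname accessors
setMethod("components", "DeltaDeltaRecord", function(x) x@delta)
#' @rdname accessors
setMethod("polarModel", "EnergyComponents", function(x) x@polarModel)
#' @rdname accessors
setMethod("polarModel", "DeltaDeltaRecord", function(x) x@polarModel)
#' @rdname accessors
setMethod("perSeedTable", "EnergyComponents", function(x) x@perSeed)
#' @rdname accessors
setMethod("perSeedTable", "DeltaDeltaRecord", function(x) x@perSeed)
#' @rdname accessors
setMethod("standardError", "EnergyComponents", function(x) x@sem)
#' @rdname accessors
setMethod("standardError", "DeltaDeltaRecord", function(x) x@sem)

setMethod("show", "Topology", function(object) {
  cat(sprintf("Topology: %d atoms, %d residues, %d bonds\n",
              nrow(object@atoms), nrow(object@residues), nrow(object@bonds)))
  for (g in names(object@groups))
    cat(sprintf("  group '%s': %d atoms\n", g, length(object@groups[[g]])))
  invisible(object)
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d atoms x %d frames\n",
              dim(object@coords)[1], dim(object@coords)[3]))
  invisible(object)
})

setMethod("show", "SeedEnsemble", function(object) {
  nf <- vapply(object@trajectories, nframes, integer(1))
  cat(sprintf("SeedEnsemble: %d seeds (%s), %d atoms, frames per seed: %s\n",
              length(object@trajectories),
              paste(object@seedIds, collapse = ","),
              natoms(object@trajectories[[1]]),
              paste(nf, collapse = ",")))
  invisible(object)
})

setMethod("show", "EnergyComponents", function(object) {
  cat(sprintf("EnergyComponents (%s polar model), kcal/mol:\n",
              object@polarModel))
  print(round(object@terms, 4))
  if (length(object@sem)) {
    cat("SEM across seeds:\n"); print(round(object@sem, 4))
  }
  invisible(object)
})

setMethod("show", "DeltaDeltaRecord", function(object) {
  cat(sprintf("DeltaDeltaRecord %s site %s (%s), mutant - wild, kcal/mol:\n",
              object@label, object@site, object@mutation))
  print(round(object@delta, 4))
  invisible(object)
})

setMethod("show", "ShellSelection", function(object) {
  cat(sprintf(
    "ShellSelection: %d domain residues within %.1f A of phosphate (frame %d)\n",
    nrow(object@residues), object@cutoff, object@referenceFrame))
  invisible(object)
})

setMethod("show", "EntropyRecord", function(object) {
  cat(sprintf("EntropyRecord (T = %g K, %d bins), T*dS in kcal/mol:\n",
              object@temperature, object@bins))
  print(round(c(object@classTerms, total = object@tdsTotal), 4))
  if (nrow(object@unmatched))
    cat(sprintf("  %d unmatched dihedral(s) excluded, reported separately\n",
                nrow(object@unmatched)))
  invisible(object)
})
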