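# Default intrinsic GB radii / screening factors (mbondi-style table, keyed
# by element), used when a prmtop lacks RADII/SCREEN sections.
MBONDI_RADII <- c(H = 1.2, C = 1.7, N = 1.55, O = 1.5, F = 1.5,
                  P = 1.85, S = 1.8, CL = 1.7)
GB_SCREEN <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, F = 0.88,
               P = 0.86, S = 0.96, CL = 0.8)
DEFAULT_RADIUS <- 1.5
DEFAULT_SCREEN <- 0.8

SOLVENT_RESNAMES <- c("WAT", "HOH", "Na+", "NA+", "Cl-", "CL-")

elementOf <- function(name) {
  e <- toupper(sub("^[0-9]*", "", name))
  ifelse(substr(e, 1, 2) == "CL", "CL", substr(e, 1, 1))
}

defaultGbRadius <- function(names) {
  e <- elementOf(names)
  r <- MBONDI_RADII[e]
  r[is.na(r)] <- DEFAULT_RADIUS
  unname(r)
}

defaultGbScreen <- function(names) {
  e <- elementOf(names)
  s <- GB_SCREEN[e]
  s[is.na(s)] <- DEFAULT_SCREEN
  unname(s)
}

PRMTOP_REQUIRED <- c("POINTERS", "ATOM_NAME", "CHARGE", "MASS",
                     "ATOM_TYPE_INDEX", "NONBONDED_PARM_INDEX",
                     "RESIDUE_LABEL", "RESIDUE_POINTER",
                     "LENNARD_JONES_ACOEF", "LENNARD_JONES_BCOEF",
                     "BONDS_INC_HYDROGEN", "BONDS_WITHOUT_HYDROGEN")

# Decompress a gz file to a tempfile when needed; returns a readable path.
ungzPath <- function(path) {
  if (!grepl("\\.gz$", path)) return(path)
  out <- tempfile(fileext = paste0(".", sub("\\.gz$", "", basename(path))))
  inc <- gzfile(path, "rb"); on.exit(close(inc))
  outc <- file(out, "wb"); on.exit(close(outc), add = TRUE)
  repeat {
    chunk <- readBin(inc, "raw", n = 1048576L)
    if (!length(chunk)) break
    writeBin(chunk, outc)
  }
  out
}

#' Read a molecular topology
#'
#' Supports a subset of the AMBER parameter-topology (prmtop) format and the
#' package's own plain-text parameter table (see [writeParamTable()]).
#' prmtop charges are converted from the internal unit to elementary charges
#' (divide by 18.2223) and per-type Lennard-Jones A/B coefficients are
#' converted to the `(rminHalf, epsilon)` parameterisation.  Missing RADII /
#' SCREEN sections are filled from an mbondi-style element table.  Water and
#' counter-ion residues (WAT/HOH/Na+/Cl-) are stripped on load, since all
#' downstream energetics are implicit-solvent.  Gzip-compressed files are
#' accepted.
#'
#' @param path file path (optionally `.gz`).
#' @param format `"amber-prmtop"` or `"param-table"`.
#' @param stripSolvent drop water/ion residues (default TRUE).
#' @return A [Topology-class].  prmtop files carry no group definitions;
#'   assign them afterwards with [assignGroups()].
#' @export
readTopology <- function(path, format = c("amber-prmtop", "param-table"),
                         stripSolvent = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  top <- if (format == "amber-prmtop") readPrmtop(path) else
    readParamTable(path)
  if (stripSolvent) {
    drop <- which(top@atoms$resname %in% SOLVENT_RESNAMES)
    if (length(drop)) {
      message(sprintf("stripping %d solvent/ion atoms", length(drop)))
      top <- subsetTopology(top, setdiff(seq_len(natoms(top)), drop))
    }
  }
  top
}

readPrmtop <- function(path) {
  p <- bio3d::read.prmtop(ungzPath(path))
  present <- names(p)
  missing <- setdiff(PRMTOP_REQUIRED, present)
  if ("RADII" %in% missing || "SCREEN" %in% missing)
    missing <- setdiff(missing, c("RADII", "SCREEN"))
  if (length(missing))
    stop(sprintf("prmtop format error: missing mandatory section(s) %s",
                 paste(missing, collapse = ", ")))
  known <- c(PRMTOP_REQUIRED, "RADII", "SCREEN", "call", "TITLE",
             "AMBER_ATOM_TYPE", "ATOMIC_NUMBER")
  extra <- setdiff(present, known)
  if (length(extra))
    message(sprintf("ignoring prmtop section(s): %s",
                    paste(extra, collapse = ", ")))
  natom <- p$POINTERS[1]; ntypes <- p$POINTERS[2]
  for (sec in c("ATOM_NAME", "CHARGE", "MASS", "ATOM_TYPE_INDEX"))
    if (length(p[[sec]]) != natom)
      stop(sprintf("prmtop consistency error: section %s has %d entries, POINTERS says %d atoms",
                   sec, length(p[[sec]]), natom))
  charge <- p$CHARGE / PRMTOP_CHARGE_SCALE
  # per-type LJ from the diagonal of the type-pair tables
  rminHalfT <- numeric(ntypes); epsT <- numeric(ntypes)
  for (t in seq_len(ntypes)) {
    ico <- p$NONBONDED_PARM_INDEX[ntypes * (t - 1) + t]
    A <- 0; B <- 0
    if (ico > 0) { A <- p$LENNARD_JONES_ACOEF[ico]; B <- p$LENNARD_JONES_BCOEF[ico] }
    if (A > 0 && B > 0) {
      rminHalfT[t] <- 0.5 * (2 * A / B)^(1 / 6)
      epsT[t] <- B^2 / (4 * A)
    }
  }
  name <- trimws(p$ATOM_NAME)
  radii <- if ("RADII" %in% present) p$RADII else {
    message("prmtop has no RADII section; using mbondi-style defaults")
    defaultGbRadius(name)
  }
  screen <- if ("SCREEN" %in% present) p$SCREEN else defaultGbScreen(name)
  rp <- p$RESIDUE_POINTER
  resid <- rep(seq_along(rp), diff(c(rp, natom + 1L)))
  atomsDF <- data.frame(
    name = name, resid = as.integer(resid),
    resname = trimws(p$RESIDUE_LABEL)[resid],
    charge = charge,
    rminHalf = rminHalfT[p$ATOM_TYPE_INDEX],
    epsilon = epsT[p$ATOM_TYPE_INDEX],
    gbRadius = radii, gbScreen = screen, mass = p$MASS,
    stringsAsFactors = FALSE)
  braw <- c(p$BONDS_INC_HYDROGEN, p$BONDS_WITHOUT_HYDROGEN)
  bonds <- matrix(integer(), ncol = 2L)
  if (length(braw)) {
    bm <- matrix(braw, ncol = 3L, byrow = TRUE)
    bonds <- cbind(bm[, 1] %/% 3L + 1L, bm[, 2] %/% 3L + 1L)
  }
  Topology(atomsDF, bonds)
}

#' Write / read the plain-text parameter-table topology format
#'
#' A self-contained tabular carrier for everything the energy kernels need:
#' an `[atoms]` section (one row per atom, all per-atom parameters), a
#' `[bonds]` section and a `[groups]` section.  The format round-trips a
#' [Topology-class] exactly (to printed precision) and is the topology
#' format emitted for synthetic systems.
#'
#' @param topology a [Topology-class].
#' @param path output (input) file path; `.gz` supported on read.
#' @return `writeParamTable` returns `path` invisibly; `readParamTable`
#'   returns a [Topology-class].
#' @export
writeParamTable <- function(topology, path) {
  a <- topology@atoms
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# phosdelta parameter table v1", con)
  writeLines("[atoms]", con)
  writeLines("index name resname resid charge rmin_half epsilon gb_radius gb_screen mass",
             con)
  writeLines(sprintf("%d %s %s %d %.10g %.10g %.10g %.10g %.10g %.10g",
                     seq_len(nrow(a)), a$name, a$resname, a$resid, a$charge,
                     a$rminHalf, a$epsilon, a$gbRadius, a$gbScreen, a$mass),
             con)
  writeLines("[bonds]", con)
  if (nrow(topology@bonds))
    writeLines(sprintf("%d %d", topology@bonds[, 1], topology@bonds[, 2]), con)
  writeLines("[groups]", con)
  for (g in names(topology@groups))
    writeLines(paste(g, paste(topology@groups[[g]], collapse = " ")), con)
  invisible(path)
}

#' @rdname writeParamTable
#' @export
readParamTable <- function(path) {
  lines <- readLines(gzfile(path))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  secAt <- grep("^\\[", lines)
  if (!length(secAt) || lines[secAt[1]] != "[atoms]")
    stop("param-table format error: missing [atoms] section")
  secs <- split(lines, cumsum(grepl("^\\[", lines)))
  parts <- list()
  for (s in secs) parts[[gsub("\\[|\\]", "", s[1])]] <- s[-1]
  if (is.null(parts$atoms) || length(parts$atoms) < 2L)
    stop("param-table format error: empty [atoms] section")
  hdr <- strsplit(parts$atoms[1], "\\s+")[[1]]
  tab <- read.table(text = parts$atoms[-1], col.names = hdr,
                    stringsAsFactors = FALSE)
  atomsDF <- data.frame(name = as.character(tab$name),
                        resid = as.integer(tab$resid),
                        resname = as.character(tab$resname),
                        charge = tab$charge, rminHalf = tab$rmin_half,
                        epsilon = tab$epsilon, gbRadius = tab$gb_radius,
                        gbScreen = tab$gb_screen, mass = tab$mass,
                        stringsAsFactors = FALSE)
  bonds <- matrix(integer(), ncol = 2L)
  if (!is.null(parts$bonds) && length(parts$bonds))
    bonds <- as.matrix(read.table(text = parts$bonds))
  grp <- list()
  if (!is.null(parts$groups))
    for (ln in parts$groups) {
      tok <- strsplit(ln, "\\s+")[[1]]
      grp[[tok[1]]] <- as.integer(tok[-1])
    }
  Topology(atomsDF, bonds, grp)
}

#' Assign receptor / ligand groups by residue index
#'
#' @param topology a [Topology-class].
#' @param receptor,ligand residue indices (rows of `residues(topology)`).
#' @return the topology with `"receptor"` and `"ligand"` atom groups set.
#' @export
assignGroups <- function(topology, receptor, ligand) {
  recAtoms <- unlist(lapply(receptor, residueAtoms, topology = topology))
  ligAtoms <- unlist(lapply(ligand, residueAtoms, topology = topology))
  topology@groups$receptor <- as.integer(recAtoms)
  topology@groups$ligand <- as.integer(ligAtoms)
  validObject(topology)
  topology
}

#' Subset a topology to a set of atoms
#'
#' Bonds and groups are remapped to the new indices; bonds or group members
#' outside the kept set are dropped.
#'
#' @param topology a [Topology-class].
#' @param keep integer atom indices to keep (in increasing order).
#' @return A [Topology-class] over the kept atoms.
#' @export
subsetTopology <- function(topology, keep) {
  keep <- sort(unique(as.integer(keep)))
  map <- integer(natoms(topology))
  map[keep] <- seq_along(keep)
  a <- topology@atoms[keep, , drop = FALSE]
  rownames(a) <- NULL
  b <- topology@bonds
  if (nrow(b)) {
    ok <- b[, 1] %in% keep & b[, 2] %in% keep
    b <- cbind(map[b[ok, 1]], map[b[ok, 2]])
  }
  grp <- lapply(topology@groups, function(g) map[intersect(g, keep)])
  Topology(a, b, grp)
}
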