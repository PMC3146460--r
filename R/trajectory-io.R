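#' Read a trajectory
#'
#' DCD (CHARMM/X-PLOR binary) and multi-model PDB are supported; frames come
#' back in file order with coordinates in Angstrom.  A file whose last frame
#' is incomplete raises an error naming the last complete frame.  Gzip input
#' is accepted for both formats.
#'
#' @param path trajectory file (optionally `.gz`).
#' @param topology the matching [Topology-class]; atom counts must agree.
#' @param format `"dcd"` or `"pdb"`.
#' @return A [Trajectory-class].
#' @export
readTrajectory <- function(path, topology, format = c("dcd", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  traj <- if (format == "dcd") readDCD(ungzPath(path)) else
    readMultiModelPDB(path)
  if (dim(traj@coords)[1] != natoms(topology))
    stop(sprintf("trajectory has %d atoms per frame, topology has %d",
                 dim(traj@coords)[1], natoms(topology)))
  traj
}

#' Write a trajectory
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file.
#' @param topology the matching [Topology-class] (needed for PDB records).
#' @param format `"dcd"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path, topology = NULL,
                            format = c("dcd", "pdb")) {
  format <- match.arg(format)
  if (format == "dcd") return(writeDCD(trajectory, path))
  if (is.null(topology)) stop("PDB output requires a topology")
  writeMultiModelPDB(trajectory, topology, path)
}

# --- DCD ------------------------------------------------------------------
# CHARMM-style DCD: Fortran unformatted records with 4-byte length markers;
# header "CORD" + 20 control ints (version slot 20 marks CHARMM dialect),
# title block, atom-count block, then X/Y/Z float32 records per frame and an
# optional unit-cell record (skipped on read).

readDCD <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  rec <- function(what, n, size) {
    len <- readBin(con, "integer", 1, 4, endian = "little")
    if (!length(len)) return(NULL)
    dat <- readBin(con, what, n, size, endian = "little")
    if (length(dat) < n) return(NULL)
    tail <- readBin(con, "integer", 1, 4, endian = "little")
    if (!length(tail) || tail != len) return(NULL)
    dat
  }
  hdr <- readBin(con, "integer", 1, 4, endian = "little")
  magic <- readChar(con, 4)
  if (!identical(magic, "CORD")) stop("not a DCD file (missing CORD magic)")
  icntrl <- readBin(con, "integer", 20, 4, endian = "little")
  readBin(con, "integer", 1, 4, endian = "little")  # trailing marker
  charmm <- icntrl[20] != 0
  hasCell <- charmm && icntrl[11] == 1L
  tlen <- readBin(con, "integer", 1, 4, endian = "little")
  ntitle <- readBin(con, "integer", 1, 4, endian = "little")
  if (ntitle > 0) readChar(con, 80 * ntitle, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little")
  nat <- rec("integer", 1, 4)
  if (is.null(nat)) stop("truncated DCD header")
  frames <- list()
  repeat {
    if (hasCell) {
      cell <- rec("numeric", 6, 8)
      if (is.null(cell)) break
    }
    x <- rec("numeric", nat, 4)
    if (is.null(x)) break
    y <- rec("numeric", nat, 4)
    z <- rec("numeric", nat, 4)
    if (is.null(y) || is.null(z))
      stop(sprintf("truncated DCD frame; last complete frame is %d",
                   length(frames)))
    frames[[length(frames) + 1L]] <- cbind(x, y, z, deparse.level = 0)
  }
  if (!length(frames)) stop("DCD contains no complete frames")
  Trajectory(array(unlist(frames), c(nat, 3L, length(frames))))
}

writeDCD <- function(trajectory, path) {
  coords <- trajectory@coords
  nf <- dim(coords)[3]; nat <- dim(coords)[1]
  con <- file(path, "wb"); on.exit(close(con))
  mark <- function(n) writeBin(as.integer(n), con, 4, endian = "little")
  mark(84)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  writeBin(icntrl[1:9], con, 4, endian = "little")
  writeBin(1.0, con, size = 4, endian = "little")  # timestep placeholder
  writeBin(icntrl[11:20], con, 4, endian = "little")
  mark(84)
  mark(84)  # title record: ntitle int + one 80-char line
  writeBin(1L, con, 4, endian = "little")
  writeChar(formatC("written by phosdelta", width = 80, flag = "-"), con,
            nchars = 80, eos = NULL)
  mark(84)
  mark(4); writeBin(as.integer(nat), con, 4, endian = "little"); mark(4)
  for (f in seq_len(nf)) {
    for (k in 1:3) {
      mark(4 * nat)
      writeBin(as.numeric(coords[, k, f]), con, size = 4, endian = "little")
      mark(4 * nat)
    }
  }
  invisible(path)
}

# --- multi-model PDB ------------------------------------------------------

writeMultiModelPDB <- function(trajectory, topology, path) {
  a <- topology@atoms
  nm <- ifelse(nchar(a$name) < 4L, sprintf(" %-3s", a$name),
               sprintf("%-4s", a$name))
  pre <- sprintf("ATOM  %5d %s %-3s A%4d    ", seq_len(nrow(a)), nm,
                 a$resname, a$resid)
  con <- file(path, "w"); on.exit(close(con))
  coords <- trajectory@coords
  for (f in seq_len(dim(coords)[3])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf("%s%8.3f%8.3f%8.3f%6.2f%6.2f", pre,
                       coords[, 1, f], coords[, 2, f], coords[, 3, f],
                       1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

readMultiModelPDB <- function(path) {
  lines <- readLines(gzfile(path))
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  modelStart <- grepl("^MODEL", lines)
  if (!any(isAtom)) stop("no ATOM records in PDB file")
  modelId <- if (any(modelStart)) cumsum(modelStart) else
    rep(1L, length(lines))
  at <- which(isAtom)
  xyz <- cbind(as.numeric(substr(lines[at], 31, 38)),
               as.numeric(substr(lines[at], 39, 46)),
               as.numeric(substr(lines[at], 47, 54)))
  if (any(!is.finite(xyz))) stop("malformed coordinates in PDB file")
  byModel <- split(seq_along(at), modelId[at])
  counts <- lengths(byModel)
  nat <- counts[[1]]
  if (any(counts != nat)) {
    lastComplete <- max(0L, which(counts != nat)[1] - 1L)
    stop(sprintf("truncated PDB model; last complete frame is %d",
                 lastComplete))
  }
  nf <- length(byModel)
  arr <- array(0, c(nat, 3L, nf))
  for (f in seq_len(nf)) arr[, , f] <- xyz[byModel[[f]], , drop = FALSE]
  Trajectory(arr)
}

#' Root-mean-square deviation between two frames
#'
#' With `superpose = TRUE` the optimal rigid-body least-squares fit
#' (Kabsch, via bio3d) is applied over the selection before the RMSD is
#' taken, so rigid motions contribute nothing.
#'
#' @param xyz,reference `N x 3` coordinate matrices.
#' @param selection atom indices used for both fit and RMSD
#'   (default: all atoms).
#' @param superpose apply the rigid-body fit first (default TRUE).
#' @return RMSD in Angstrom.
#' @export
frameRMSD <- function(xyz, reference, selection = NULL, superpose = TRUE) {
  if (is.null(selection)) selection <- seq_len(nrow(xyz))
  if (!length(selection)) stop("empty selection")
  if (any(selection < 1L) || any(selection > nrow(xyz)))
    stop("selection out of range")
  a <- xyz[selection, , drop = FALSE]
  b <- reference[selection, , drop = FALSE]
  if (superpose) {
    inds <- seq_len(3L * nrow(a))
    fitted <- bio3d::fit.xyz(as.vector(t(b)), as.vector(t(a)),
                             fixed.inds = inds, mobile.inds = inds)
    a <- matrix(fitted, ncol = 3, byrow = TRUE)
  }
  sqrt(mean(rowSums((a - b)^2)))
}
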