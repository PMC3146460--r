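DD_COLUMNS <- c("ddU_vdw", "ddU_coul", "ddW_polar", "ddE_ele",
                "ddE_tot_np", "ddW_np", "ddE_tot")
DD_TERM_ORDER <- c("uVdw", "uCoul", "wPolar", "eEle", "eTotNp", "wNp",
                   "eTot")

#' Read a flat keyword-value configuration file
#'
#' One `key = value` pair per line; `#` comments; `include <path>` pulls in
#' another file (relative to the including file), with later keys
#' overriding earlier ones.  Values are parsed as numbers or logicals when
#' they look like them.
#'
#' @param path configuration file.
#' @return named list.
#' @export
readConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    if (grepl("^include\\s+", ln)) {
      inc <- file.path(dirname(path), trimws(sub("^include\\s+", "", ln)))
      out <- utils::modifyList(out, readConfig(inc))
      next
    }
    kv <- strsplit(ln, "\\s*=\\s*")[[1]]
    if (length(kv) != 2L) stop(sprintf("malformed config line: '%s'", ln))
    val <- kv[2]
    parsed <- suppressWarnings(as.numeric(val))
    out[[kv[1]]] <- if (!is.na(parsed)) parsed
      else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  out
}

ddRow <- function(record) {
  d <- components(record)[DD_TERM_ORDER]
  row <- data.frame(domain = record@label, mutated_site = record@site,
                    mutation = record@mutation, stringsAsFactors = FALSE)
  for (k in seq_along(DD_COLUMNS)) row[[DD_COLUMNS[k]]] <- unname(d[k])
  row
}

#' Render result tables as TSV
#'
#' Mutation-energy records go out in the conventional column order
#' (domain, mutated site, mutation, ddU_vdw, ddU_coul, ddW_polar, ddE_ele,
#' ddE_tot_np, ddW_np, ddE_tot), entropy records as (domain, site,
#' mutation, TdS_phi, TdS_psi, TdS_omega, TdS_sidechain, TdS_total);
#' values are formatted to two decimals and run metadata is embedded as
#' `#` header comments.
#'
#' @param records list of [DeltaDeltaRecord-class], or for
#'   `renderEntropyTable` a list of lists with `label`, `site`,
#'   `mutation`, `record` (an [EntropyRecord-class]).
#' @param path output TSV path.
#' @param metadata named list echoed into the header.
#' @return the formatted data.frame, invisibly.
#' @export
renderTables <- function(records, path, metadata = list()) {
  rows <- if (length(records)) do.call(rbind, lapply(records, ddRow)) else
    data.frame(domain = character(), mutated_site = numeric(),
               mutation = character())
  if (!length(records)) for (cn in DD_COLUMNS) rows[[cn]] <- numeric()
  fmt <- rows
  for (cn in DD_COLUMNS) if (cn %in% names(fmt))
    fmt[[cn]] <- sprintf("%.2f", fmt[[cn]])
  writeTSVWithHeader(fmt, path, metadata)
  invisible(rows)
}

#' @rdname renderTables
#' @export
renderEntropyTable <- function(records, path, metadata = list()) {
  rows <- lapply(records, function(r) {
    ct <- r$record@classTerms
    data.frame(domain = r$label, mutated_site = r$site,
               mutation = r$mutation,
               TdS_phi = ct[["phi"]], TdS_psi = ct[["psi"]],
               TdS_omega = ct[["omega"]],
               TdS_sidechain = ct[["sidechain"]],
               TdS_total = r$record@tdsTotal, stringsAsFactors = FALSE)
  })
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(domain = character(), mutated_site = numeric(),
               mutation = character(), TdS_phi = numeric(),
               TdS_psi = numeric(), TdS_omega = numeric(),
               TdS_sidechain = numeric(), TdS_total = numeric())
  fmt <- rows
  for (cn in grep("^TdS_", names(fmt), value = TRUE))
    fmt[[cn]] <- sprintf("%.2f", as.numeric(fmt[[cn]]))
  writeTSVWithHeader(fmt, path, metadata)
  invisible(rows)
}

writeTSVWithHeader <- function(df, path, metadata) {
  con <- file(path, "w"); on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s = %s", k,
                       paste(format(metadata[[k]]), collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export dihedral distributions as two-column TSV files
#'
#' One file per dihedral label: bin center (degrees) and probability.
#'
#' @param series dihedral series data.frame from [dihedralSeries()].
#' @param dir output directory (created if needed).
#' @param bins histogram bins (default 36).
#' @return named character vector of written paths, invisibly.
#' @export
exportDistributions <- function(series, dir, bins = 36L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- unique(series$label)
  paths <- character(0)
  for (lab in labs) {
    g <- gibbsEntropy(series$angle[series$label == lab], bins)
    p <- file.path(dir, paste0(gsub("[^A-Za-z0-9._-]", "_", lab), ".tsv"))
    utils::write.table(data.frame(angle = g$mids, probability = g$p), p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths[lab] <- p
  }
  invisible(paths)
}

BUNDLE_REQUIRED <- c("version", "config", "globalDeltaDelta",
                     "localDeltaDelta", "entropy", "rotamers",
                     "distributions")

#' Check a report bundle against the shipped schema
#'
#' Verifies the presence and basic types of the required top-level fields
#' (the machine-readable schema lives in `inst/extdata/bundle-schema.json`).
#'
#' @param bundle list as produced by [runPipeline()].
#' @return TRUE (invisibly) or an error describing the missing field.
#' @export
validateBundle <- function(bundle) {
  missing <- setdiff(BUNDLE_REQUIRED, names(bundle))
  if (length(missing))
    stop(sprintf("bundle lacks required field(s): %s",
                 paste(missing, collapse = ", ")))
  invisible(TRUE)
}

pipelineLog <- function(stage, t0) {
  message(sprintf("[phosdelta] %-18s %6.1f s", stage,
                  as.numeric(proc.time()[3] - t0)))
}

#' Run the full wild-vs-mutant analysis pipeline
#'
#' Generates (toy mode) or loads the wild-type and mutant systems, then
#' emits: (i) the global mutation-energy table, (ii) the local
#' (phosphate-shell) table, (iii) the entropy-decomposition table,
#' (iv) per-dihedral distribution TSVs and (v) a machine-readable JSON
#' bundle carrying every number plus the full configuration and package
#' version.  Deterministic given the configured seeds (the JSON contains
#' no timestamps).
#'
#' @param config named list (or path to a [readConfig()] file).  Toy-mode
#'   keys (with defaults): `pocketGeometry` ("enclosed-cavity"),
#'   `nPocketAtoms` (24), `peptideLength` (3), `seed` (1), `nSeeds` (5),
#'   `nFrames` (200), `shellCutoff` (6), `bins` (36), `temperature` (300),
#'   `chiWiden` (3), `chiShift` (47), `sasaPoints` (240), `label`,
#'   `site`, `mutation`.
#' @param outDir output directory.
#' @return the bundle list, invisibly.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("phosdelta")) {
  if (is.character(config)) config <- readConfig(config)
  defaults <- list(mode = "toy", pocketGeometry = "enclosed-cavity",
                   nPocketAtoms = 24, peptideLength = 3, seed = 1,
                   nSeeds = 5, nFrames = 200, shellCutoff = 6, bins = 36,
                   temperature = 300, chiWiden = 3, chiShift = 47,
                   sasaPoints = 240, label = "toy-FHA", site = 1,
                   mutation = "pT->pS")
  config <- utils::modifyList(defaults, config)
  if (config$mode != "toy")
    stop("validation error: only mode = 'toy' is built in; supply ",
         "topologies/ensembles directly to the analysis functions otherwise")
  if (config$peptideLength < 1)
    stop("validation error: no phosphoresidue (peptideLength < 1)")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[3]
  econf <- energyConfig(sasaPoints = config$sasaPoints)

  bench <- methylDeletionBenchmark(
    toySpec(nPocketAtoms = config$nPocketAtoms,
            pocketGeometry = config$pocketGeometry,
            peptideLength = config$peptideLength,
            phosphoKind = "pthr-like", seed = config$seed),
    nSeeds = config$nSeeds, nFrames = config$nFrames, seed = config$seed,
    chiWiden = config$chiWiden, chiShift = config$chiShift)
  pipelineLog("generate", t0)

  wildGlobal <- interactionEnergy(bench$wild$topology, bench$wild$ensemble,
                                  config = econf)
  mutGlobal <- interactionEnergy(bench$mutant$topology,
                                 bench$mutant$ensemble, config = econf)
  ddGlobal <- deltaDelta(wildGlobal, mutGlobal, label = config$label,
                         site = config$site, mutation = config$mutation)
  pipelineLog("global energy", t0)

  ref <- centralFrame(bench$wild$ensemble,
                      selection = resolveGroup(bench$wild$topology,
                                               "ligand"),
                      maxFrames = 25L)
  refXYZ <- getFrame(trajectories(bench$wild$ensemble)[[ref$seed]], ref$frame)
  shell <- shellSelect(bench$wild$topology, refXYZ, bench$phosphoResidue,
                       cutoff = config$shellCutoff,
                       referenceFrame = ref$frame)
  wildLocal <- localInteractionEnergy(bench$wild$topology,
                                      bench$wild$ensemble, shell,
                                      config = econf)
  mutLocal <- localInteractionEnergy(bench$mutant$topology,
                                     bench$mutant$ensemble, shell,
                                     config = econf)
  ddLocal <- deltaDelta(wildLocal, mutLocal, label = config$label,
                        site = config$site, mutation = config$mutation)
  pipelineLog("local energy", t0)

  wildDefs <- suppressWarnings(
    extractDihedrals(bench$wild$topology,
                     seq_len(config$peptideLength)))
  mutDefs <- suppressWarnings(
    extractDihedrals(bench$mutantResampled$topology,
                     seq_len(config$peptideLength)))
  wildSeries <- dihedralSeries(bench$wild$ensemble, wildDefs)
  mutSeries <- dihedralSeries(bench$mutantResampled$ensemble, mutDefs)
  ent <- entropyDecomposition(wildSeries, mutSeries, bins = config$bins,
                              temperature = config$temperature)
  pipelineLog("entropy", t0)

  chiLabel <- sprintf("res%d.chi2", bench$phosphoResidue)
  rotWild <- rotamerStates(wildSeries$angle[wildSeries$label == chiLabel])
  rotMut <- rotamerStates(mutSeries$angle[mutSeries$label == chiLabel])
  rot <- list(
    dihedral = chiLabel,
    wild = rotWild[c("nStates", "populations", "means", "widths")],
    mutant = rotMut[c("nStates", "populations", "means", "widths")],
    meanShift = abs(circularDiff(rotMut$means[1], rotWild$means[1])))
  pipelineLog("rotamers", t0)

  meta <- config[vapply(config, function(x)
    is.numeric(x) || is.character(x) || is.logical(x), logical(1))]
  globalTab <- renderTables(list(ddGlobal),
                            file.path(outDir, "global_dd.tsv"), meta)
  localTab <- renderTables(list(ddLocal),
                           file.path(outDir, "local_dd.tsv"), meta)
  entTab <- renderEntropyTable(
    list(list(label = config$label, site = config$site,
              mutation = config$mutation, record = ent)),
    file.path(outDir, "entropy.tsv"), meta)
  dists <- exportDistributions(rbind(wildSeries[wildSeries$label == chiLabel, ],
                                     transform(mutSeries[mutSeries$label == chiLabel, ],
                                               label = paste0(chiLabel, ".mutant"))),
                               file.path(outDir, "distributions"),
                               bins = config$bins)
  bundle <- list(
    version = as.character(utils::packageVersion("phosdelta")),
    config = meta,
    globalDeltaDelta = globalTab,
    localDeltaDelta = localTab,
    shell = list(cutoff = shell@cutoff,
                 residues = shell@residues$index,
                 referenceFrame = shell@referenceFrame),
    entropy = entTab,
    entropyPerDihedral = ent@perDihedral,
    entropyUnmatched = ent@unmatched,
    rotamers = rot,
    distributions = basename(unname(dists)))
  validateBundle(bundle)
  jsonlite::write_json(bundle, file.path(outDir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipelineLog("report", t0)
  invisible(bundle)
}
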