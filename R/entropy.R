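binAngles <- function(angles, bins) {
  width <- 360 / bins
  # left-closed, right-open bins on [-180, 180)
  idx <- floor((wrapAngle(angles) + 180) / width) + 1L
  idx[idx > bins] <- bins
  tabulate(idx, nbins = bins)
}

#' Gibbs entropy of a binned dihedral distribution
#'
#' `S = -R * sum p ln p` over an equal-width periodic histogram of
#' `[-180, 180)` (left-closed, right-open bins; `0 ln 0 := 0`),
#' R = 1.9872e-3 kcal/(mol K).  Seeds are pooled before histogramming by
#' the callers that deal with ensembles.
#'
#' @param angles numeric angles in degrees (any range; wrapped).
#' @param bins histogram bin count (default 36, i.e. 10 degree bins).
#' @param temperature Kelvin (default 300).
#' @return list with `S` (kcal/(mol K)), `TS` (kcal/mol), `p`
#'   (bin probabilities) and `mids` (bin centers, degrees).
#' @export
gibbsEntropy <- function(angles, bins = 36L, temperature = 300) {
  stopifnot(length(angles) >= 1L, bins >= 2L)
  counts <- binAngles(angles, bins)
  p <- counts / sum(counts)
  S <- -GAS_CONSTANT * sum(p[p > 0] * log(p[p > 0]))
  width <- 360 / bins
  list(S = S, TS = S * temperature, p = p,
       mids = seq(-180 + width / 2, 180 - width / 2, by = width))
}

#' Entropy change decomposed over dihedral classes
#'
#' For every dihedral matched between the wild-type and mutant series (by
#' residue and torsion name), computes `T * (S_mut - S_wild)` from pooled
#' histograms and sums within the classes phi, psi, omega and sidechain;
#' the total is the sum of the class terms.  Dihedrals present on one side
#' only (e.g. the pThr methyl torsion, which pSer does not have) are
#' excluded from the decomposition and reported separately.  Per-seed
#' entropies are attached as across-seed standard deviations.
#'
#' @param wild,mutant dihedral series data.frames from [dihedralSeries()].
#' @param bins histogram bin count (default 36).
#' @param temperature Kelvin (default 300).
#' @return An [EntropyRecord-class] (mutant minus wild).
#' @export
entropyDecomposition <- function(wild, mutant, bins = 36L,
                                 temperature = 300) {
  key <- function(df) paste(df$residue, df$name, sep = ".")
  wild$key <- key(wild); mutant$key <- key(mutant)
  matched <- intersect(unique(wild$key), unique(mutant$key))
  if (!length(matched)) stop("no matchable dihedrals between wild and mutant")
  per <- lapply(matched, function(k) {
    aw <- wild$angle[wild$key == k]; am <- mutant$angle[mutant$key == k]
    Sw <- gibbsEntropy(aw, bins, temperature)$S
    Sm <- gibbsEntropy(am, bins, temperature)$S
    sdOf <- function(df) {
      bySeed <- split(df$angle[df$key == k], df$seed[df$key == k])
      if (length(bySeed) < 2L) return(0)
      stats::sd(vapply(bySeed, function(a)
        gibbsEntropy(a, bins, temperature)$S, numeric(1)))
    }
    data.frame(label = k, class = wild$class[wild$key == k][1],
               sWild = Sw, sMut = Sm, tds = temperature * (Sm - Sw),
               sdWildSeeds = sdOf(wild), sdMutSeeds = sdOf(mutant),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  cls <- c("phi", "psi", "omega", "sidechain")
  classTerms <- vapply(cls, function(cl)
    sum(per$tds[per$class == cl]), numeric(1))
  un <- list()
  for (side in c("wild", "mutant")) {
    df <- if (side == "wild") wild else mutant
    only <- setdiff(unique(df$key), matched)
    for (k in only)
      un[[length(un) + 1L]] <- data.frame(
        label = k, side = side, class = df$class[df$key == k][1],
        S = gibbsEntropy(df$angle[df$key == k], bins, temperature)$S,
        TS = temperature *
          gibbsEntropy(df$angle[df$key == k], bins, temperature)$S,
        stringsAsFactors = FALSE)
  }
  unmatched <- if (length(un)) do.call(rbind, un) else
    data.frame(label = character(), side = character(),
               class = character(), S = numeric(), TS = numeric())
  new("EntropyRecord", classTerms = classTerms,
      tdsTotal = sum(classTerms), temperature = temperature,
      bins = as.integer(bins), perDihedral = per, unmatched = unmatched)
}

#' Rotamer-state analysis of a dihedral distribution
#'
#' The angle histogram (1 degree bins) is smoothed with a circular von
#' Mises kernel; maximal arcs between valleys of the smoothed density are
#' candidate states, states below a population floor are merged into their
#' stronger neighbour, and each state reports its population, circular
#' mean and circular standard deviation (well width).  The number of
#' occupied wells is the conformational part of the usual
#' conformational/vibrational reading of dihedral entropy; well widths
#' carry the vibrational part.
#'
#' @param angles numeric angles in degrees.
#' @param bandwidth kernel bandwidth in degrees (default 15).
#' @param floor minimal state population retained (default 0.01).
#' @return list with `nStates`, `populations`, `means`, `widths`
#'   (degrees), and `density` (the smoothed 1-degree grid, summing to 1).
#' @export
rotamerStates <- function(angles, bandwidth = 15, floor = 0.01) {
  if (length(angles) < 100L)
    warning("fewer than 100 samples: rotamer analysis may be unstable")
  grid <- 360L
  h <- binAngles(angles, grid)
  kappa <- (180 / (pi * bandwidth))^2
  offs <- seq(0, 359) * pi / 180
  kern <- exp(kappa * (cos(offs) - 1))
  kern <- kern / sum(kern)
  dens <- as.numeric(stats::convolve(h, kern, conj = TRUE, type = "circular"))
  dens <- pmax(dens, 0); dens <- dens / sum(dens)
  nb <- function(i, d) ((i - 1 + d) %% grid) + 1
  isMin <- vapply(seq_len(grid), function(i)
    dens[i] < dens[nb(i, -1)] & dens[i] <= dens[nb(i, 1)], logical(1))
  valleys <- which(isMin)
  assign <- integer(grid)
  if (length(valleys) < 2L) {
    assign[] <- 1L
  } else {
    # state k: bins in the arc (valleys[k], valleys[k+1]]
    for (k in seq_along(valleys)) {
      from <- valleys[k]
      to <- if (k < length(valleys)) valleys[k + 1L] else valleys[1L]
      i <- nb(from, 1)
      while (TRUE) {
        assign[i] <- k
        if (i == to) break
        i <- nb(i, 1)
      }
    }
  }
  binOf <- floor((wrapAngle(angles) + 180)) + 1L
  binOf[binOf > grid] <- grid
  state <- assign[binOf]
  repeat {
    tab <- table(factor(state, levels = sort(unique(assign))))
    pops <- as.numeric(tab) / length(state)
    if (all(pops >= floor) || length(pops) == 1L) break
    weak <- as.integer(names(tab))[which.min(pops)]
    peaks <- vapply(sort(unique(assign)), function(k)
      max(dens[assign == k]), numeric(1))
    others <- setdiff(sort(unique(assign)), weak)
    target <- others[which.max(peaks[match(others, sort(unique(assign)))])]
    assign[assign == weak] <- target
    state[state == weak] <- target
  }
  states <- sort(unique(state))
  pops <- vapply(states, function(k) mean(state == k), numeric(1))
  means <- vapply(states, function(k) circularMean(angles[state == k]),
                  numeric(1))
  widths <- vapply(states, function(k) {
    a <- angles[state == k] * pi / 180
    rbar <- sqrt(mean(sin(a))^2 + mean(cos(a))^2)
    sqrt(pmax(-2 * log(rbar), 0)) * 180 / pi
  }, numeric(1))
  ord <- order(pops, decreasing = TRUE)
  list(nStates = length(states), populations = pops[ord],
       means = means[ord], widths = widths[ord], density = dens)
}
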