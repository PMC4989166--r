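# Generators with known truth: a structured-coalescent haplotype simulator
# (island model, optional stepwise expansion, finite- or infinite-sites
# mutation on a haploid non-recombining locus) and a synthetic-landscape
# generator (spatially autocorrelated climate fields with occurrences drawn
# from a declared niche).

#' Define a structured-coalescent scenario
#'
#' Demes sit on a west-to-east axis with coordinates emitted, so spatial
#' analyses (contiguity, latitude regressions) can run on simulated data.
#' The truth record carries \eqn{\theta = 2 N_e \mu g k} (haploid, per
#' sequence) and \eqn{\tau = 2 \mu g k t} for an expansion t generations
#' ago.
#'
#' @param nPerDeme integer vector of sample sizes (one per deme).
#' @param Ne present-day effective size per deme (haploid individuals).
#' @param migration per-lineage per-generation migration probability
#'   (island model; ignored with one deme).
#' @param expansion NULL, or list(time = generations ago, ratio =
#'   present/ancestral size ratio > 0).
#' @param mu substitution rate per site per year.
#' @param seqLength sequence length k (sites).
#' @param generationTime generation time g (years).
#' @param infiniteSites give every mutation a fresh site (clean theory
#'   checks); default FALSE (finite sites, recurrent hits possible).
#' @export
coalescentScenario <- function(nPerDeme, Ne, migration = 0,
                               expansion = NULL, mu = 1e-9,
                               seqLength = 1500L, generationTime = 10,
                               infiniteSites = FALSE) {
  if (any(nPerDeme < 1L)) stop("every deme needs a positive sample size")
  if (Ne <= 0 || migration < 0 || mu <= 0 || seqLength < 1L ||
      generationTime <= 0)
    stop("rates and sizes must be positive")
  if (!is.null(expansion) &&
      (expansion$time <= 0 || expansion$ratio <= 0))
    stop("expansion needs positive time and ratio")
  structure(list(nPerDeme = as.integer(nPerDeme), Ne = Ne,
                 migration = migration, expansion = expansion, mu = mu,
                 seqLength = as.integer(seqLength),
                 generationTime = generationTime,
                 infiniteSites = infiniteSites),
            class = "coalescentScenario")
}

#' Simulate haplotype data under a structured coalescent
#'
#' Island-model genealogy by competing exponential events (within-deme
#' coalescence, symmetric migration), optional stepwise size change, and
#' Poisson mutations on branches. Returns the exact objects the analysis
#' modules consume plus a truth record sufficient to score every estimator.
#'
#' @param sc a \code{\link{coalescentScenario}}.
#' @param seed RNG seed (same seed, same alignment).
#' @return list with \code{alignment} (\linkS4class{HapAlignment}),
#'   \code{populations} (population table), \code{truth}.
#' @export
simulateCoalescent <- function(sc, seed = 1L) {
  stopifnot(inherits(sc, "coalescentScenario"))
  set.seed(seed)
  nd <- length(sc$nPerDeme)
  n <- sum(sc$nPerDeme)
  tExp <- if (is.null(sc$expansion)) Inf else sc$expansion$time
  Nanc <- if (is.null(sc$expansion)) sc$Ne else sc$Ne / sc$expansion$ratio
  sizeAt <- function(t) if (t < tExp) sc$Ne else Nanc

  nNodes <- 2L * n - 1L
  parentOf <- integer(nNodes)
  nodeTime <- numeric(nNodes)
  active <- seq_len(n)
  deme <- rep(seq_len(nd), sc$nPerDeme)
  nextNode <- n + 1L
  t <- 0
  while (length(active) > 1L) {
    kd <- tabulate(deme, nd)
    coalRates <- kd * (kd - 1) / 2 / sizeAt(t)
    migRate <- if (nd > 1L) length(active) * sc$migration else 0
    R <- sum(coalRates) + migRate
    dt <- rexp(1L, R)
    if (t < tExp && t + dt > tExp) { t <- tExp; next }
    t <- t + dt
    if (runif(1L) < migRate / R) {
      i <- sample.int(length(active), 1L)
      deme[i] <- sample(setdiff(seq_len(nd), deme[i]), 1L)
    } else {
      d <- sample.int(nd, 1L, prob = coalRates)
      here <- which(deme == d)
      pair <- here[sample.int(length(here), 2L)]
      parentOf[active[pair]] <- nextNode
      nodeTime[nextNode] <- t
      active <- c(active[-pair], nextNode)
      deme <- c(deme[-pair], d)
      nextNode <- nextNode + 1L
    }
  }
  root <- active

  perGen <- sc$mu * sc$generationTime * sc$seqLength
  branchLen <- nodeTime[parentOf[-root]] - nodeTime[-root]
  nMut <- integer(nNodes)
  nMut[-root] <- rpois(nNodes - 1L, branchLen * perGen)
  if (sc$infiniteSites && sum(nMut) > sc$seqLength)
    stop("infinite-sites simulation exceeded seqLength; increase k")

  bases <- c("A", "C", "G", "T")
  seqs <- matrix(NA_character_, nNodes, sc$seqLength)
  seqs[root, ] <- sample(bases, sc$seqLength, replace = TRUE)
  childrenOf <- split(seq_len(nNodes)[-root], parentOf[-root])
  queue <- root
  issCounter <- 0L
  while (length(queue)) {
    p <- queue[1L]; queue <- queue[-1L]
    for (ch in childrenOf[[as.character(p)]]) {
      sq <- seqs[p, ]
      if (nMut[ch] > 0L) {
        if (sc$infiniteSites) {
          sites <- issCounter + seq_len(nMut[ch])
          issCounter <- issCounter + nMut[ch]
        } else {
          sites <- sample.int(sc$seqLength, nMut[ch], replace = TRUE)
        }
        for (s in sites) sq[s] <- sample(setdiff(bases, sq[s]), 1L)
      }
      seqs[ch, ] <- sq
      if (ch > n) queue <- c(queue, ch)
    }
  }

  popCode <- sprintf("P%02d", seq_len(nd))
  sid <- sprintf("%s_%d", popCode[rep(seq_len(nd), sc$nPerDeme)],
                 unlist(lapply(sc$nPerDeme, seq_len)))
  m <- seqs[seq_len(n), , drop = FALSE]
  rownames(m) <- sid
  pops <- data.frame(
    population = popCode[rep(seq_len(nd), sc$nPerDeme)],
    latitude = 28,
    longitude = 100 + 2 * (rep(seq_len(nd), sc$nPerDeme) - 1L),
    sample_id = sid)
  if (nd == 1L) pops$latitude <- 28   # keep shape stable
  truth <- list(
    theta = 2 * sc$Ne * perGen,
    thetaAncestral = 2 * Nanc * perGen,
    tau = if (is.finite(tExp)) 2 * perGen * tExp else NA_real_,
    expansionTime = if (is.finite(tExp)) tExp else NA_real_,
    assignment = setNames(pops$population, sid),
    scenario = sc, seed = seed)
  list(alignment = HapAlignment(m), populations = pops, truth = truth)
}

#' Write simulated haplotype data in the formats the readers consume
#'
#' FASTA alignment, population CSV and truth JSON; round-trips through
#' \code{\link{readAlignment}} / \code{\link{readPopulationTable}}.
#'
#' @param sim output of \code{\link{simulateCoalescent}}.
#' @param dir output directory.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "alignment.fasta")
  ss <- Biostrings::DNAStringSet(
    apply(sim$alignment@seqs, 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(ss, fa)
  pt <- file.path(dir, "populations.csv")
  write.csv(sim$populations, pt, row.names = FALSE)
  tj <- file.path(dir, "truth.json")
  tr <- sim$truth; tr$scenario <- unclass(tr$scenario)
  jsonlite::write_json(tr, tj, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(alignment = fa, populations = pt, truth = tj))
}

#' Define a synthetic-landscape scenario
#'
#' @param nrow,ncol grid size.
#' @param nVars number of environmental variables.
#' @param smoothing Gaussian smoothing length (cells) giving the fields
#'   their spatial autocorrelation.
#' @param niches named list, one per species: list(optimum = numeric vector
#'   of length nVars, width = positive vector, n = occurrences >= 10).
#' @export
landscapeScenario <- function(nrow = 60L, ncol = 60L, nVars = 5L,
                              smoothing = 6, niches) {
  stopifnot(length(niches) >= 1L, !is.null(names(niches)))
  for (ni in niches) {
    if (any(ni$width <= 0)) stop("niche widths must be positive")
    if (ni$n < 10L) stop("at least 10 occurrences per species")
  }
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 nVars = as.integer(nVars), smoothing = smoothing,
                 niches = niches),
            class = "landscapeScenario")
}

# smoothed standard-normal random field
.gaussianField <- function(nr, nc, smoothing) {
  pad <- ceiling(3 * smoothing)
  z <- matrix(rnorm((nr + 2 * pad) * (nc + 2 * pad)), nr + 2 * pad)
  kx <- exp(-0.5 * ((-pad):pad / smoothing)^2)
  kx <- kx / sum(kx)
  sm <- apply(z, 2L, function(col) as.numeric(stats::filter(col, kx)))
  sm <- t(apply(sm, 1L, function(row) as.numeric(stats::filter(row, kx))))
  f <- sm[pad + seq_len(nr), pad + seq_len(nc)]
  if (sd(f) == 0) stop("degenerate (zero-variance) field")
  (f - mean(f)) / sd(f)
}

#' Simulate a landscape with species occurrences from known niches
#'
#' Environmental variables are smoothed Gaussian random fields; each
#' species' true suitability is a Gaussian kernel in environmental space
#' around its declared optimum; occurrences are sampled proportional to
#' suitability. The truth record carries the true surfaces and the
#' analytically computed pairwise D/I between species.
#'
#' @param ls a \code{\link{landscapeScenario}}.
#' @param seed RNG seed (same seed, same rasters).
#' @return list with \code{stack} (\linkS4class{EnvStack}),
#'   \code{occurrences} (data.frame species, lon, lat), \code{truth}.
#' @export
simulateLandscape <- function(ls, seed = 1L) {
  stopifnot(inherits(ls, "landscapeScenario"))
  set.seed(seed)
  nm <- paste0("VAR", seq_len(ls$nVars))
  layers <- setNames(lapply(nm, function(x)
    .gaussianField(ls$nrow, ls$ncol, ls$smoothing)), nm)
  stack <- EnvStack(layers, xll = 100, yll = 24, cellsize = 0.1)

  suitOf <- function(ni) {
    s <- matrix(0, ls$nrow, ls$ncol)
    for (v in seq_len(ls$nVars))
      s <- s + ((layers[[v]] - ni$optimum[v]) / ni$width[v])^2
    exp(-0.5 * s)
  }
  trueSuit <- lapply(ls$niches, suitOf)

  cellLon <- stack@xll + (seq_len(ls$ncol) - 0.5) * stack@cellsize
  cellLat <- stack@yll + (ls$nrow - seq_len(ls$nrow) + 0.5) * stack@cellsize
  occ <- do.call(rbind, lapply(names(ls$niches), function(sp) {
    w <- as.vector(trueSuit[[sp]])
    if (sum(w) <= 0)
      stop("declared niche for ", sp, " has no suitable cells on this landscape")
    cells <- sample.int(length(w), ls$niches[[sp]]$n, replace = TRUE,
                        prob = w)
    rc <- arrayInd(cells, c(ls$nrow, ls$ncol))
    data.frame(species = sp, lon = cellLon[rc[, 2L]], lat = cellLat[rc[, 1L]])
  }))

  sps <- names(ls$niches)
  trueOverlap <- NULL
  if (length(sps) > 1L) {
    for (pr in combn(sps, 2L, simplify = FALSE)) {
      p <- as.vector(trueSuit[[pr[1L]]]); p <- p / sum(p)
      q <- as.vector(trueSuit[[pr[2L]]]); q <- q / sum(q)
      trueOverlap <- rbind(trueOverlap, data.frame(
        species1 = pr[1L], species2 = pr[2L],
        D = 1 - sum(abs(p - q)) / 2,
        I = 1 - sum((sqrt(p) - sqrt(q))^2) / 2))
    }
  }
  list(stack = stack,
       occurrences = occ,
       truth = list(suitability = trueSuit, overlap = trueOverlap,
                    scenario = ls, seed = seed))
}

#' Write simulated landscape data in the formats the niche module reads
#' @param sim output of \code{\link{simulateLandscape}}.
#' @param dir output directory.
#' @export
writeLandscapeData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ascs <- writeAsciiGridStack(sim$stack, file.path(dir, "env"))
  oc <- file.path(dir, "occurrences.csv")
  write.csv(sim$occurrences, oc, row.names = FALSE)
  tj <- file.path(dir, "truth.json")
  tr <- sim$truth
  tr$suitability <- NULL            # surfaces stay in memory; JSON keeps D/I
  tr$scenario <- unclass(tr$scenario)
  jsonlite::write_json(tr, tj, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(occurrences = oc, truth = tj, rasters = ascs))
}
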