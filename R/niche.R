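# Climatic-niche comparison: collinearity filtering of environmental
# layers, transparent suitability models (the overlap machinery is
# model-agnostic, so an externally produced suitability raster can be
# compared directly), AUC evaluation, Schoener's D / Hellinger I and the
# pooled-pseudoreplicate identity test.

#' Construct an environmental raster stack
#'
#' @param layers named list of numeric matrices on a shared grid (row 1 =
#'   northern edge).
#' @param xll,yll lower-left corner (decimal degrees).
#' @param cellsize cell size in degrees.
#' @param mask optional logical validity matrix; defaults to cells finite
#'   in every layer.
#' @return an \linkS4class{EnvStack}
#' @export
EnvStack <- function(layers, xll = 0, yll = 0, cellsize = 1, mask = NULL) {
  stopifnot(length(layers) >= 1L, !is.null(names(layers)))
  arr <- array(unlist(layers, use.names = FALSE),
               dim = c(dim(layers[[1L]]), length(layers)),
               dimnames = list(NULL, NULL, names(layers)))
  if (is.null(mask))
    mask <- apply(arr, c(1L, 2L), function(v) all(is.finite(v)))
  new("EnvStack", layers = arr, mask = mask, xll = xll, yll = yll,
      cellsize = cellsize)
}

#' Read/write headered ASCII grids (ESRI .asc)
#'
#' @param paths named character vector of .asc files (names become layer
#'   names; defaults to file basenames).
#' @return an \linkS4class{EnvStack}
#' @export
readAsciiGridStack <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.asc$", "", basename(paths))
  parse1 <- function(p) {
    ln <- readLines(p, n = 6L)
    kv <- strsplit(trimws(ln), "\\s+")
    hdr <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                    tolower(vapply(kv, `[`, "", 1L)))
    m <- as.matrix(read.table(p, skip = 6L))
    dimnames(m) <- NULL
    m[m == hdr[["nodata_value"]]] <- NA_real_
    list(m = m, hdr = hdr)
  }
  gs <- lapply(paths, parse1)
  hdr <- gs[[1L]]$hdr
  EnvStack(lapply(gs, `[[`, "m"),
           xll = hdr[["xllcorner"]], yll = hdr[["yllcorner"]],
           cellsize = hdr[["cellsize"]])
}

#' @rdname readAsciiGridStack
#' @param stack an \linkS4class{EnvStack}.
#' @param dir output directory (one .asc per layer).
#' @export
writeAsciiGridStack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack@layers)
  for (nm in layerNames(stack)) {
    m <- stack@layers[, , nm]
    m[!stack@mask] <- -9999
    p <- file.path(dir, paste0(nm, ".asc"))
    writeLines(c(paste("ncols", d[2L]), paste("nrows", d[1L]),
                 paste("xllcorner", stack@xll), paste("yllcorner", stack@yll),
                 paste("cellsize", stack@cellsize),
                 paste("NODATA_value", -9999)), p)
    write.table(m, p, append = TRUE, row.names = FALSE, col.names = FALSE)
  }
  invisible(file.path(dir, paste0(layerNames(stack), ".asc")))
}

#' Greedy collinearity filter for environmental layers
#'
#' Scans layers in order; a layer is dropped when its absolute Pearson
#' correlation (over valid cells) with any already-retained layer exceeds
#' \code{rMax}. The retained set the original study used
#' (BIO1, BIO2, BIO3, BIO4, BIO12, BIO15, BIO19) is available as
#' \code{bioclimRetainedPreset()}.
#'
#' @param stack an \linkS4class{EnvStack} with at least two layers.
#' @param rMax correlation threshold (default 0.70).
#' @return list with \code{stack} (reduced), \code{retained},
#'   \code{dropped} (data.frame layer, against, r).
#' @export
filterVariables <- function(stack, rMax = 0.70) {
  nm <- layerNames(stack)
  if (length(nm) < 2L) stop("at least two layers required")
  vals <- vapply(nm, function(l) stack@layers[, , l][stack@mask],
                 numeric(sum(stack@mask)))
  keep <- character(0)
  dropped <- data.frame(layer = character(0), against = character(0),
                        r = numeric(0))
  for (l in nm) {
    if (sd(vals[, l]) == 0) {
      warning("layer ", l, " is constant: correlation undefined, retained")
      keep <- c(keep, l)
      next
    }
    rs <- vapply(keep, function(k) {
      if (sd(vals[, k]) == 0) return(NA_real_)
      abs(cor(vals[, l], vals[, k]))
    }, numeric(1L))
    hit <- which(is.finite(rs) & rs > rMax)
    if (length(hit)) {
      dropped <- rbind(dropped, data.frame(layer = l,
                                           against = keep[hit[1L]],
                                           r = rs[hit[1L]]))
    } else keep <- c(keep, l)
  }
  red <- EnvStack(setNames(lapply(keep, function(l) stack@layers[, , l]), keep),
                  xll = stack@xll, yll = stack@yll,
                  cellsize = stack@cellsize, mask = stack@mask)
  list(stack = red, retained = keep, dropped = dropped)
}

#' @rdname filterVariables
#' @export
bioclimRetainedPreset <- function() {
  c("BIO1", "BIO2", "BIO3", "BIO4", "BIO12", "BIO15", "BIO19")
}

# snap lon/lat points to (row, col); row 1 = northern edge
.snapToCells <- function(stack, lon, lat) {
  nr <- dim(stack@layers)[1L]; nc <- dim(stack@layers)[2L]
  col <- floor((lon - stack@xll) / stack@cellsize) + 1L
  row <- nr - floor((lat - stack@yll) / stack@cellsize)
  ok <- col >= 1L & col <= nc & row >= 1L & row <= nr
  ok[ok] <- stack@mask[cbind(row[ok], col[ok])]
  cbind(row = row, col = col)[ok, , drop = FALSE]
}

.occEnv <- function(stack, occ, dedup = TRUE) {
  cells <- .snapToCells(stack, occ$lon, occ$lat)
  if (dedup) cells <- unique(cells)
  if (nrow(cells) == 0L) stop("no occurrences fall on valid cells")
  vapply(layerNames(stack),
         function(l) stack@layers[, , l][cells],
         numeric(nrow(cells)))
}

#' Fit a suitability surface from presence records
#'
#' Two transparent presence-only models: \code{gaussian_envelope} scores a
#' cell by the product of per-variable Gaussian kernels centred on the
#' presence mean (rescaled so the best cell scores 1), and
#' \code{bioclim_percentile} by the classic percentile-envelope minimum
#' score. Both emit logistic-like suitabilities in [0, 1].
#'
#' @param occ data.frame with columns lon, lat (a species' presences).
#' @param stack an \linkS4class{EnvStack}.
#' @param model one of "gaussian_envelope", "bioclim_percentile".
#' @param dedup drop duplicate presences per cell.
#' @param minPresences minimum presences after dedup (default 10).
#' @return a \linkS4class{SuitabilityRaster}
#' @export
fitSuitability <- function(occ, stack,
                           model = c("gaussian_envelope", "bioclim_percentile"),
                           dedup = TRUE, minPresences = 10L) {
  model <- match.arg(model)
  env <- .occEnv(stack, occ, dedup)
  if (nrow(env) < minPresences)
    stop("at least ", minPresences, " presences on valid cells required (got ",
         nrow(env), ")")
  nm <- layerNames(stack)
  d <- dim(stack@layers)
  vals <- matrix(NA_real_, d[1L], d[2L])
  cellVals <- vapply(nm, function(l) stack@layers[, , l][stack@mask],
                     numeric(sum(stack@mask)))
  if (model == "gaussian_envelope") {
    mu <- colMeans(env)
    sdv <- pmax(apply(env, 2L, sd), 1e-8)
    z2 <- sweep(sweep(cellVals, 2L, mu), 2L, sdv, "/")^2
    score <- exp(-0.5 * rowSums(z2))
    score <- score / max(score)
    fitted <- list(model = model, mu = mu, sd = sdv)
  } else {
    score <- rep(1, nrow(cellVals))
    for (l in nm) {
      F <- ecdf(env[, l])
      fr <- F(cellVals[, l])
      score <- pmin(score, 1 - 2 * abs(fr - 0.5))
    }
    fitted <- list(model = model, env = env)
  }
  vals[stack@mask] <- score
  new("SuitabilityRaster", values = vals, mask = stack@mask,
      xll = stack@xll, yll = stack@yll, cellsize = stack@cellsize,
      model = fitted)
}

#' AUC of a suitability model on held-out presences
#'
#' Splits presences into train/test, fits on the training share, and scores
#' test presences against uniformly sampled background (valid) cells; AUC
#' is the Mann-Whitney rank statistic with ties counted half.
#'
#' @inheritParams fitSuitability
#' @param trainFrac training fraction (0 < trainFrac < 1).
#' @param nBackground number of background cells (> 0).
#' @param seed RNG seed.
#' @return list with auc, nTrain, nTest, nBackground.
#' @export
evaluateAuc <- function(occ, stack,
                        model = c("gaussian_envelope", "bioclim_percentile"),
                        trainFrac = 0.8, nBackground = 10000L, seed = 1L) {
  model <- match.arg(model)
  if (nBackground < 1L) stop("nBackground must be positive")
  n <- nrow(occ)
  nTrain <- floor(trainFrac * n)
  if (nTrain < 1L || nTrain >= n)
    stop("trainFrac must leave both a training and a non-empty test split")
  set.seed(seed)
  idx <- sample.int(n, nTrain)
  s <- fitSuitability(occ[idx, ], stack, model)
  test <- .snapToCells(stack, occ$lon[-idx], occ$lat[-idx])
  if (nrow(test) == 0L) stop("no test presences fall on valid cells")
  pres <- s@values[test]
  validCells <- which(stack@mask, arr.ind = TRUE)
  bg <- validCells[sample.int(nrow(validCells), nBackground, replace = TRUE), ,
                   drop = FALSE]
  bgS <- s@values[bg]
  r <- rank(c(pres, bgS))
  auc <- (sum(r[seq_along(pres)]) - length(pres) * (length(pres) + 1) / 2) /
    (length(pres) * length(bgS))
  list(auc = auc, nTrain = nTrain, nTest = nrow(test),
       nBackground = nBackground)
}

#' Schoener's D and Hellinger-based I niche overlap
#'
#' Both surfaces are normalised to probability distributions over the
#' shared valid cells; \eqn{D = 1 - \frac12 \sum |p_i - q_i|} and
#' \eqn{I = 1 - \frac12 \sum (\sqrt{p_i} - \sqrt{q_i})^2}. Both equal 1 iff
#' the normalised surfaces are identical and 0 for disjoint supports.
#'
#' @param s1,s2 \linkS4class{SuitabilityRaster}s on the same grid/mask.
#' @return named vector c(D = , I = ).
#' @export
nicheOverlap <- function(s1, s2) {
  if (!identical(dim(s1@values), dim(s2@values)) ||
      !identical(s1@mask, s2@mask))
    stop("suitability rasters must share grid and mask")
  p <- s1@values[s1@mask]; q <- s2@values[s2@mask]
  if (sum(p) <= 0 || sum(q) <= 0) stop("all-zero suitability surface")
  p <- p / sum(p); q <- q / sum(q)
  c(D = 1 - sum(abs(p - q)) / 2,
    I = 1 - sum((sqrt(p) - sqrt(q))^2) / 2)
}

#' Niche identity test from pooled pseudoreplicates
#'
#' Observed D and I come from the two species' fitted surfaces; the null
#' distribution pools all presence points, randomly repartitions them into
#' the original sample sizes, and refits both models, \code{nReps} times.
#' The test is one-tailed (niche difference pushes the observed overlap
#' below the null): \eqn{p = (1 + \#\{null \le obs\})/(nReps + 1)}. The
#' null split always assigns the smaller sample size first, so swapping the
#' two species with the same seed reproduces the same null values.
#'
#' @param occ1,occ2 presence data.frames (columns lon, lat).
#' @param stack an \linkS4class{EnvStack}.
#' @param model suitability model passed to \code{\link{fitSuitability}}.
#' @param nReps pseudoreplicates (default 100; < 10 draws a warning).
#' @param seed RNG seed.
#' @return a \code{NicheOverlap} with observed D/I, null vectors and p-values.
#' @export
identityTest <- function(occ1, occ2, stack,
                         model = c("gaussian_envelope", "bioclim_percentile"),
                         nReps = 100L, seed = 1L) {
  model <- match.arg(model)
  if (nReps < 10L) warning("nReps < 10: identity-test p-values will be coarse")
  s1 <- fitSuitability(occ1, stack, model)
  s2 <- fitSuitability(occ2, stack, model)
  obs <- nicheOverlap(s1, s2)
  pool <- rbind(occ1[, c("lon", "lat")], occ2[, c("lon", "lat")])
  pool <- pool[order(pool$lon, pool$lat), ]   # argument-order invariance
  nSmall <- min(nrow(occ1), nrow(occ2))
  set.seed(seed)
  nullD <- nullI <- numeric(nReps)
  for (b in seq_len(nReps)) {
    idx <- sample.int(nrow(pool), nSmall)
    sa <- fitSuitability(pool[idx, ], stack, model)
    sb <- fitSuitability(pool[-idx, ], stack, model)
    ov <- nicheOverlap(sa, sb)
    nullD[b] <- ov[["D"]]; nullI[b] <- ov[["I"]]
  }
  new("NicheOverlap", D = obs[["D"]], I = obs[["I"]],
      nullD = nullD, nullI = nullI,
      pD = (1 + sum(nullD <= obs[["D"]])) / (nReps + 1),
      pI = (1 + sum(nullI <= obs[["I"]])) / (nReps + 1),
      nReps = as.integer(nReps), seed = as.integer(seed))
}
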