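# Hierarchical analysis of molecular variance on squared mutational
# distances (Phi-statistics convention) and the spatially constrained
# simulated-annealing search for maximally differentiated, geographically
# contiguous population groups.

# cross-product matrix M[i,j] = sum_{k,l} c_ik c_jl d2_kl for population
# haplotype count rows; every AMOVA sum of squares is a linear combination
# of its entries, which is what makes the annealing loop cheap.
.amovaPrecompute <- function(X, d2) {
  M <- X %*% d2 %*% t(X)
  n <- rowSums(X)
  list(M = M, n = n, N = sum(n),
       ssdT = sum(M) / (2 * sum(n)),
       ssdWP = sum(diag(M) / (2 * n)))
}

.amovaComponents <- function(pre, groupOf) {
  M <- pre$M; n <- pre$n; N <- pre$N; P <- length(n)
  gs <- split(seq_len(P), groupOf)
  G <- length(gs)
  Ng <- vapply(gs, function(i) sum(n[i]), numeric(1L))
  ssdWG <- sum(vapply(seq_along(gs), function(g) {
    i <- gs[[g]]
    sum(M[i, i]) / (2 * Ng[g])
  }, numeric(1L)))
  ssdAP <- ssdWG - pre$ssdWP
  ssdAG <- pre$ssdT - ssdWG
  dfWP <- N - P
  sigC <- pre$ssdWP / dfWP
  if (G == 1L) {
    msAP <- (pre$ssdT - pre$ssdWP) / (P - 1L)
    n0 <- (N - sum(n^2) / N) / (P - 1L)
    sigA <- (msAP - sigC) / n0
    return(list(sigma = c(a = NA_real_, b = sigA, c = sigC),
                ssd = c(AG = NA_real_, AP = pre$ssdT - pre$ssdWP, WP = pre$ssdWP),
                df = c(AG = NA_real_, AP = P - 1L, WP = dfWP),
                phi = c(FCT = NA_real_, FSC = NA_real_,
                        FST = sigA / (sigA + sigC))))
  }
  sumNg2 <- vapply(seq_along(gs), function(g) sum(n[gs[[g]]]^2) / Ng[g],
                   numeric(1L))
  msAP <- ssdAP / (P - G)
  msAG <- ssdAG / (G - 1L)
  nP <- (N - sum(sumNg2)) / (P - G)
  nPP <- (sum(sumNg2) - sum(n^2) / N) / (G - 1L)
  nPPP <- (N - sum(Ng^2) / N) / (G - 1L)
  sigB <- (msAP - sigC) / nP
  sigA <- (msAG - sigC - nPP * sigB) / nPPP
  tot <- sigA + sigB + sigC
  list(sigma = c(a = sigA, b = sigB, c = sigC),
       ssd = c(AG = ssdAG, AP = ssdAP, WP = pre$ssdWP),
       df = c(AG = G - 1L, AP = P - G, WP = dfWP),
       phi = c(FCT = sigA / tot, FSC = sigB / (sigB + sigC),
               FST = (sigA + sigB) / tot))
}

#' Analysis of molecular variance
#'
#' Nested AMOVA of individuals in populations in groups, on squared
#' mutational distances between haplotypes, with the standard coefficient
#' corrections for unequal sample sizes. Negative variance-component
#' estimates are reported as-is and flagged. With a single group only the
#' two-level decomposition (F_ST) is computed.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param d mutational-step distance matrix between haplotypes.
#' @param grouping named vector mapping every population (rownames of
#'   \code{popCounts(h)}) to a group identifier.
#' @return an \code{AmovaResult} (variance components sigma_a/b/c, Phi
#'   statistics F_CT, F_SC, F_ST, sums of squares, flags).
#' @export
amova <- function(h, d = pairwiseDifferences(h), grouping) {
  stopifnot(is(h, "HaplotypeSet"))
  X <- h@popCounts
  pops <- rownames(X)
  if (!all(pops %in% names(grouping)))
    stop("grouping must cover every population")
  d2 <- (d[h@labels, h@labels])^2
  pre <- .amovaPrecompute(X, d2)
  cmp <- .amovaComponents(pre, as.character(grouping[pops]))
  flags <- character(0)
  sig <- cmp$sigma
  if (any(is.finite(sig) & sig < 0))
    flags <- c(flags, "negative variance component estimate")
  if (isTRUE(all.equal(sum(sig[is.finite(sig)]), 0)) ||
      !any(is.finite(cmp$phi))) {
    flags <- c(flags, "no molecular variance: Phi statistics undefined")
    cmp$phi[] <- NA_real_
  }
  ssTab <- data.frame(level = names(cmp$ssd), ssd = unname(cmp$ssd),
                      df = unname(cmp$df))
  new("AmovaResult", sigma = cmp$sigma, phi = cmp$phi, ss = ssTab,
      flags = flags)
}

## ---- geographic contiguity ---------------------------------------------

#' Build a population contiguity graph
#'
#' Delaunay triangulation of population coordinates on the (lon, lat) plane
#' (plate carree; study extents of a few degrees keep distortion harmless),
#' computed by the empty-circumcircle criterion with a deterministic
#' symbolic perturbation that resolves co-circular ties. Collinear layouts
#' fall back to a chain along the axis; duplicated coordinates are jittered
#' with a warning.
#'
#' @param pops population table (one coordinate pair per population).
#' @return list with \code{populations}, \code{coords}, \code{edges}
#'   (two-column character matrix) and \code{adjacency} (named list).
#' @export
buildContiguity <- function(pops) {
  cc <- unique(pops[, c("population", "latitude", "longitude")])
  P <- nrow(cc)
  if (P < 2L) stop("at least two populations required")
  xy <- cbind(cc$longitude, cc$latitude)
  if (anyDuplicated(xy)) {
    warning("duplicate population coordinates: applying deterministic jitter")
    dup <- duplicated(xy)
    xy[dup, ] <- xy[dup, ] + 1e-5 * which(dup)
  }
  scale <- max(apply(xy, 2L, function(v) diff(range(v))), 1e-9)
  # symbolic perturbation so co-circular quadruples triangulate uniquely
  pert <- cbind(seq_len(P), seq_len(P)^2 %% 97) * 1e-9 * scale
  xyp <- xy + pert

  edges <- NULL
  v1 <- xy[2L, ] - xy[1L, ]
  cross <- apply(xy, 1L, function(p)
    (p[1] - xy[1, 1]) * v1[2] - (p[2] - xy[1, 2]) * v1[1])
  if (P == 2L || all(abs(cross) < 1e-9 * scale^2)) {
    proj <- xy %*% v1 / sqrt(sum(v1^2))
    o <- order(proj, xy[, 1L], xy[, 2L])
    edges <- cbind(o[-P], o[-1L])
  } else {
    for (tri in combn(P, 3L, simplify = FALSE)) {
      a <- xyp[tri[1L], ]; b <- xyp[tri[2L], ]; c <- xyp[tri[3L], ]
      den <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                    c[1] * (a[2] - b[2]))
      if (abs(den) < 1e-12 * scale^2) next
      ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
               (sum(c^2)) * (a[2] - b[2])) / den
      uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
               (sum(c^2)) * (b[1] - a[1])) / den
      r2 <- sum((a - c(ux, uy))^2)
      others <- setdiff(seq_len(P), tri)
      d2 <- (xyp[others, 1L] - ux)^2 + (xyp[others, 2L] - uy)^2
      if (all(d2 > r2 * (1 - 1e-12)))
        edges <- rbind(edges, cbind(tri[c(1, 1, 2)], tri[c(2, 3, 3)]))
    }
    edges <- unique(edges)
  }
  nm <- cc$population
  adj <- lapply(seq_len(P), function(i)
    nm[unique(c(edges[edges[, 1L] == i, 2L], edges[edges[, 2L] == i, 1L]))])
  names(adj) <- nm
  list(populations = nm, coords = xy,
       edges = cbind(nm[edges[, 1L]], nm[edges[, 2L]]),
       adjacency = adj)
}

# is the set of populations `set` connected in adjacency list `adj`?
.connectedSet <- function(set, adj) {
  if (length(set) <= 1L) return(TRUE)
  seen <- set[1L]; frontier <- set[1L]
  while (length(frontier)) {
    nxt <- setdiff(intersect(unlist(adj[frontier]), set), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  length(seen) == length(set)
}

.randomContiguousPartition <- function(pops, adj, K) {
  g <- setNames(rep(NA_integer_, length(pops)), pops)
  g[sample(pops, K)] <- seq_len(K)
  while (anyNA(g)) {
    cand <- names(g)[is.na(g)]
    cand <- cand[vapply(cand, function(p) any(!is.na(g[adj[[p]]])), logical(1L))]
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    nb <- g[adj[[p]]]
    nb <- nb[!is.na(nb)]
    g[p] <- if (length(nb) == 1L) nb else sample(nb, 1L)
  }
  g
}

#' Spatial analysis of molecular variance (simulated annealing)
#'
#' Searches assignments of populations to K geographically contiguous
#' groups maximising the among-group variance fraction F_CT. Moves reassign
#' a boundary population to an adjacent group when both the source and
#' target groups stay connected in the contiguity graph; geometric cooling,
#' best state over independent restarts returned.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param d mutational-step distance matrix.
#' @param pops population table with coordinates.
#' @param K number of groups (2 <= K < number of populations).
#' @param nStarts independent annealing runs.
#' @param seed RNG seed (same seed, same result).
#' @param schedule list with T0, cool, iter (moves per temperature), Tmin.
#' @param contiguity optional precomputed \code{\link{buildContiguity}}.
#' @return a \code{SamovaResult}.
#' @export
samova <- function(h, d = pairwiseDifferences(h), pops, K,
                   nStarts = 100L, seed = 1L,
                   schedule = list(T0 = 1, cool = 0.95, iter = 100L,
                                   Tmin = 1e-3),
                   contiguity = NULL) {
  X <- h@popCounts
  P <- nrow(X)
  if (K < 2L || K >= P) stop("K must satisfy 2 <= K < number of populations")
  if (is.null(contiguity)) contiguity <- buildContiguity(pops)
  adj <- contiguity$adjacency[rownames(X)]
  pre <- .amovaPrecompute(X, (d[h@labels, h@labels])^2)
  fct <- function(g) .amovaComponents(pre, g[rownames(X)])$phi[["FCT"]]

  set.seed(seed)
  best <- NULL; bestF <- -Inf
  trace <- data.frame(start = integer(0), fct = numeric(0),
                      accepted = integer(0))
  for (s in seq_len(nStarts)) {
    g <- .randomContiguousPartition(rownames(X), adj, K)
    f <- fct(g)
    runBest <- g; runBestF <- if (is.na(f)) -Inf else f; acc <- 0L
    Temp <- schedule$T0
    while (Temp >= schedule$Tmin) {
      for (it in seq_len(schedule$iter)) {
        movers <- names(g)[vapply(names(g), function(p) {
          grp <- g[[p]]
          sum(g == grp) > 1L &&
            any(g[adj[[p]]] != grp) &&
            .connectedSet(setdiff(names(g)[g == grp], p), adj)
        }, logical(1L))]
        if (!length(movers)) break
        p <- if (length(movers) == 1L) movers else sample(movers, 1L)
        tg <- unique(g[adj[[p]]])
        tg <- tg[tg != g[[p]]]
        newg <- g
        newg[p] <- if (length(tg) == 1L) tg else sample(tg, 1L)
        fNew <- fct(newg)
        if (is.na(fNew)) next
        if (is.na(f) || fNew > f || runif(1L) < exp((fNew - f) / Temp)) {
          g <- newg; f <- fNew; acc <- acc + 1L
          if (f > runBestF) { runBest <- g; runBestF <- f }
        }
      }
      Temp <- Temp * schedule$cool
    }
    trace <- rbind(trace, data.frame(start = s, fct = runBestF,
                                     accepted = acc))
    if (runBestF > bestF) { bestF <- runBestF; best <- runBest }
  }
  grp <- setNames(as.integer(factor(best, levels = unique(best[rownames(X)]))),
                  names(best))
  am <- amova(h, d, grouping = grp)
  new("SamovaResult", K = as.integer(K), grouping = grp,
      fct = am@phi[["FCT"]], amova = am, trace = trace,
      seed = as.integer(seed))
}

#' Profile F_CT over a range of K
#'
#' Runs \code{\link{samova}} for each K and reports the F_CT profile. The
#' suggested K is the smallest at which the forward increase in F_CT drops
#' below \code{plateau}; when no K reaches \code{reliableFloor} the result
#' is flagged as carrying no reliable grouping.
#'
#' @inheritParams samova
#' @param Krange integer vector of group counts to scan.
#' @param plateau forward-increase threshold declaring a plateau.
#' @param reliableFloor minimum F_CT for a grouping to count as reliable.
#' @param ... passed to \code{\link{samova}}.
#' @return list with \code{profile} (data.frame K, FCT, FSC, FST),
#'   \code{suggestedK}, \code{reliable}, \code{results}.
#' @export
samovaScan <- function(h, d = pairwiseDifferences(h), pops, Krange,
                       plateau = 0.01, reliableFloor = 0.5, ...) {
  contiguity <- buildContiguity(pops)
  res <- lapply(Krange, function(K)
    samova(h, d, pops, K, contiguity = contiguity, ...))
  prof <- data.frame(K = Krange,
                     FCT = vapply(res, function(r) r@fct, numeric(1L)),
                     FSC = vapply(res, function(r) r@amova@phi[["FSC"]], numeric(1L)),
                     FST = vapply(res, function(r) r@amova@phi[["FST"]], numeric(1L)))
  suggestedK <- Krange[length(Krange)]
  if (length(Krange) > 1L) {
    inc <- diff(prof$FCT)
    flat <- which(inc < plateau)
    if (length(flat)) suggestedK <- Krange[flat[1L]]
  }
  reliable <- any(is.finite(prof$FCT) & prof$FCT >= reliableFloor)
  list(profile = prof, suggestedK = suggestedK, reliable = reliable,
       results = setNames(res, paste0("K", Krange)))
}
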