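# Independent oracle implementations, written from the definitions with
# explicit loops; they deliberately share no code with the package.

# ordered/unordered differentiation via direct double sums
oracleDifferentiation <- function(popCounts, d) {
  P <- nrow(popCounts)
  n <- rowSums(popCounts)
  H <- ncol(popCounts)
  within <- function(kernel) {
    tot <- 0
    for (i in seq_len(P)) {
      s <- 0
      for (k in seq_len(H)) for (l in seq_len(H)) if (k != l || kernel[k, l] != 0)
        s <- s + (popCounts[i, k] / n[i]) * (popCounts[i, l] / n[i]) * kernel[k, l]
      tot <- tot + n[i] / (n[i] - 1) * s
    }
    as.numeric(tot / P)
  }
  harm <- P / sum(1 / n)
  xbar <- numeric(H)
  for (k in seq_len(H)) xbar[k] <- mean(popCounts[, k] / n)
  total <- function(kernel, wS) {
    s <- 0
    for (k in seq_len(H)) for (l in seq_len(H)) s <- s + xbar[k] * xbar[l] * kernel[k, l]
    s + wS / (P * harm)
  }
  ident <- 1 - diag(H)
  hS <- within(ident); hT <- total(ident, hS)
  vS <- within(d);     vT <- total(d, vS)
  list(hS = hS, hT = hT, GST = 1 - hS / hT, NST = 1 - vS / vT)
}

# AMOVA from the individual-level squared-distance matrix, explicit sums
oracleAmova <- function(popCounts, d, groupOfPop) {
  P <- nrow(popCounts); H <- ncol(popCounts)
  indHap <- integer(0); indPop <- integer(0)
  for (i in seq_len(P)) for (k in seq_len(H))
    if (popCounts[i, k] > 0L) {
      indHap <- c(indHap, rep(k, popCounts[i, k]))
      indPop <- c(indPop, rep(i, popCounts[i, k]))
    }
  N <- length(indHap)
  D2 <- matrix(0, N, N)
  for (a in seq_len(N)) for (b in seq_len(N))
    D2[a, b] <- d[indHap[a], indHap[b]]^2
  ssOf <- function(idx) {
    s <- 0
    for (a in idx) for (b in idx) s <- s + D2[a, b]
    s / (2 * length(idx))
  }
  grpOf <- groupOfPop[rownames(popCounts)]
  groups <- unique(grpOf)
  G <- length(groups)
  ssdT <- ssOf(seq_len(N))
  ssdWP <- sum(vapply(seq_len(P), function(i) ssOf(which(indPop == i)),
                      numeric(1)))
  ssdWG <- sum(vapply(groups, function(g)
    ssOf(which(indPop %in% which(grpOf == g))), numeric(1)))
  ssdAP <- ssdWG - ssdWP
  ssdAG <- ssdT - ssdWG
  nI <- rowSums(popCounts)
  Ng <- vapply(groups, function(g) sum(nI[grpOf == g]), numeric(1))
  sumNg2 <- vapply(seq_along(groups), function(gi)
    sum(nI[grpOf == groups[gi]]^2) / Ng[gi], numeric(1))
  sigC <- ssdWP / (N - P)
  msAP <- ssdAP / (P - G)
  msAG <- ssdAG / (G - 1)
  nP <- (N - sum(sumNg2)) / (P - G)
  nPP <- (sum(sumNg2) - sum(nI^2) / N) / (G - 1)
  nPPP <- (N - sum(Ng^2) / N) / (G - 1)
  sigB <- (msAP - sigC) / nP
  sigA <- (msAG - sigC - nPP * sigB) / nPPP
  c(a = sigA, b = sigB, c = sigC)
}

# Tajima's D straight from the published constants
oracleTajimaD <- function(n, S, pi) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# all partitions of populations into K connected, non-empty groups
# (brute force over labelings, canonicalised by first appearance)
enumerateContiguousPartitions <- function(popNames, edges, K) {
  P <- length(popNames)
  adj <- lapply(popNames, function(p)
    unique(c(edges[edges[, 1] == p, 2], edges[edges[, 2] == p, 1])))
  names(adj) <- popNames
  connected <- function(set) {
    if (length(set) <= 1L) return(TRUE)
    seen <- set[1]
    repeat {
      nxt <- setdiff(intersect(unlist(adj[seen]), set), seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
    }
    length(seen) == length(set)
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), P)))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    lab <- grid[r, ]
    canon <- as.integer(factor(lab, levels = unique(lab)))
    if (!identical(canon, unname(lab))) next         # dedupe relabelings
    if (length(unique(lab)) != K) next
    ok <- all(vapply(seq_len(K), function(g)
      connected(popNames[lab == g]), logical(1)))
    if (ok) out[[length(out) + 1L]] <- setNames(lab, popNames)
  }
  out
}

# total MST length by exhaustive Prim-free check: min over all spanning
# trees is hard; use Kruskal coded independently
oracleMSTLength <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  o <- order(d[pairs])
  comp <- seq_len(n)
  len <- 0
  for (e in o) {
    a <- pairs[e, 1]; b <- pairs[e, 2]
    if (comp[a] != comp[b]) {
      len <- len + d[a, b]
      comp[comp == comp[b]] <- comp[a]
    }
  }
  len
}
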