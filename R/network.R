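# Median-joining haplotype networks on the recoded character matrix.
# The epsilon-relaxed minimum spanning network is characterised through MST
# bottleneck (minimax) distances: a link (u,v) belongs to the network iff
# d(u,v) <= bottleneck(u,v) + epsilon, which for epsilon = 0 yields the
# union of all minimum spanning trees.

# Prim MST on a dense distance matrix; deterministic lexicographic
# tie-breaking on (node index pair). Returns edge matrix and total length.
.primMST <- function(d) {
  n <- nrow(d)
  if (n == 1L) return(list(edges = matrix(integer(0), 0, 2), length = 0))
  inTree <- c(TRUE, rep(FALSE, n - 1L))
  bestD <- d[1L, ]; bestFrom <- rep(1L, n)
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_len(n - 1L)) {
    cand <- which(!inTree)
    v <- cand[order(bestD[cand], bestFrom[cand], cand)][1L]
    edges[k, ] <- c(bestFrom[v], v)
    inTree[v] <- TRUE
    upd <- !inTree & (d[v, ] < bestD | (d[v, ] == bestD & v < bestFrom))
    bestD[upd] <- d[v, upd]; bestFrom[upd] <- v
  }
  list(edges = edges, length = sum(d[edges]))
}

# minimax (bottleneck) distances over the MST: B[u,v] = largest edge weight
# on the tree path between u and v.
.bottleneck <- function(d, mst) {
  n <- nrow(d)
  B <- matrix(0, n, n)
  adjlist <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(mst$edges))) {
    e <- mst$edges[k, ]
    adjlist[[e[1L]]] <- c(adjlist[[e[1L]]], e[2L])
    adjlist[[e[2L]]] <- c(adjlist[[e[2L]]], e[1L])
  }
  for (root in seq_len(n)) {
    seen <- rep(FALSE, n); seen[root] <- TRUE
    queue <- root
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adjlist[[u]]) if (!seen[v]) {
        seen[v] <- TRUE
        B[root, v] <- max(B[root, u], d[u, v])
        queue <- c(queue, v)
      }
    }
  }
  B
}

.msnEdges <- function(d, epsilon) {
  mst <- .primMST(d)
  B <- .bottleneck(d, mst)
  n <- nrow(d)
  keep <- which(upper.tri(d) & d <= B + epsilon, arr.ind = TRUE)
  list(edges = keep, mstLength = mst$length)
}

#' Median-joining haplotype network
#'
#' Builds the epsilon-relaxed minimum spanning network over the recoded
#' haplotype vectors, repeatedly adds majority-consensus median (Steiner)
#' vectors of connected triplets while they strictly shorten the network,
#' then prunes median vectors that no shortest connection needs. Every
#' recoded column carries weight 1, so edge weights are mutational steps.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param epsilon non-negative integer relaxation of the spanning criterion.
#' @param maxMedians cap on added median vectors.
#' @return a \code{HaplotypeNetwork} with node and edge tables.
#' @export
medianJoiningNetwork <- function(h, epsilon = 0L, maxMedians = 1000L) {
  stopifnot(is(h, "HaplotypeSet"))
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (length(h@labels) < 2L) stop("at least two haplotypes required")
  states <- h@vectors
  isMedian <- rep(FALSE, nrow(states))
  baseMstLength <- .primMST(.hammingMatrix(states))$length

  medianOfTriple <- function(s) {
    apply(s, 2L, function(col) {
      tb <- table(col)
      if (max(tb) >= 2L) names(tb)[which.max(tb)] else sort(col)[1L]
    })
  }

  repeat {
    d <- .hammingMatrix(states)
    net <- .msnEdges(d, epsilon)
    curLen <- net$mstLength
    adjm <- matrix(FALSE, nrow(d), nrow(d))
    adjm[net$edges] <- TRUE; adjm <- adjm | t(adjm)
    cand <- list()
    nn <- nrow(states)
    for (i in seq_len(nn)) {
      nb <- which(adjm[i, ])
      if (length(nb) < 2L) next
      for (pair in combn(nb, 2L, simplify = FALSE)) {
        tri <- c(i, pair)
        med <- medianOfTriple(states[tri, , drop = FALSE])
        key <- paste(med, collapse = "")
        if (key %in% apply(states, 1L, paste, collapse = "")) next
        cand[[key]] <- med
      }
    }
    if (!length(cand) || sum(isMedian) >= maxMedians) break
    scores <- vapply(names(cand), function(key) {
      aug <- rbind(states, cand[[key]])
      .primMST(.hammingMatrix(aug))$length
    }, numeric(1L))
    o <- order(scores, names(cand))
    if (scores[o[1L]] >= curLen) break
    pick <- cand[[names(cand)[o[1L]]]]
    states <- rbind(states, pick)
    rownames(states)[nrow(states)] <- paste0("mv", sum(isMedian) + 1L)
    isMedian <- c(isMedian, TRUE)
  }

  ## prune obsolete median vectors
  repeat {
    curLen <- .primMST(.hammingMatrix(states))$length
    removed <- FALSE
    for (i in rev(which(isMedian))) {
      redLen <- .primMST(.hammingMatrix(states[-i, , drop = FALSE]))$length
      if (redLen <= curLen) {
        states <- states[-i, , drop = FALSE]
        isMedian <- isMedian[-i]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  d <- .hammingMatrix(states)
  net <- .msnEdges(d, epsilon)
  ids <- rownames(states)
  freq <- colSums(h@popCounts)
  nodes <- data.frame(id = ids, isMedian = isMedian,
                      frequency = ifelse(isMedian, 0L,
                                         as.integer(freq[ids])))
  pc <- matrix(0L, length(ids), nrow(h@popCounts),
               dimnames = list(ids, rownames(h@popCounts)))
  pc[!isMedian, ] <- t(h@popCounts[, ids[!isMedian], drop = FALSE])
  nodes <- cbind(nodes, as.data.frame(pc))
  edges <- data.frame(node1 = ids[net$edges[, 1L]],
                      node2 = ids[net$edges[, 2L]],
                      steps = d[net$edges])
  edges <- edges[order(edges$node1, edges$node2), , drop = FALSE]
  rownames(edges) <- NULL
  new("HaplotypeNetwork", nodes = nodes, edges = edges, states = states,
      totalLength = net$mstLength, mstLength = baseMstLength)
}

#' Write a haplotype network as edge-list and node-table CSVs
#' @param net a \code{HaplotypeNetwork}.
#' @param edgeFile,nodeFile output CSV paths.
#' @export
writeNetwork <- function(net, edgeFile, nodeFile) {
  write.csv(net@edges, edgeFile, row.names = FALSE)
  write.csv(net@nodes, nodeFile, row.names = FALSE)
  invisible(NULL)
}
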