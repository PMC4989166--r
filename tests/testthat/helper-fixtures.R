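# Fixture builders: everything is generated in code at test time.

# build a HaplotypeSet directly from haplotype vectors and a count table
makeHapSet <- function(vectors, popCounts, L = ncol(vectors)) {
  labels <- rownames(vectors)
  mem <- unlist(lapply(seq_len(ncol(popCounts)), function(k)
    rep(labels[k], sum(popCounts[, k]))))
  names(mem) <- paste0("s", seq_along(mem))
  new("HaplotypeSet", labels = labels, vectors = vectors,
      membership = mem, popCounts = popCounts,
      meta = data.frame(type = rep("substitution", ncol(vectors)),
                        start = seq_len(ncol(vectors)),
                        end = seq_len(ncol(vectors))),
      alignmentLength = as.integer(L),
      monomorphic = nrow(vectors) == 1L)
}

# H haplotype vectors that are pairwise distinct (one private column each)
makeDistinctVectors <- function(H, extraCols = 2L) {
  v <- matrix("A", H, H + extraCols,
              dimnames = list(paste0("H", seq_len(H)), NULL))
  for (i in seq_len(H)) v[i, i] <- "T"
  v
}

# random multi-population instance: counts + a random integer distance matrix
randomIslandInstance <- function(P, H, seed) {
  set.seed(seed)
  repeat {
    pc <- matrix(rpois(P * H, 1.5), P, H,
                 dimnames = list(paste0("P", seq_len(P)),
                                 paste0("H", seq_len(H))))
    storage.mode(pc) <- "integer"
    if (all(rowSums(pc) >= 2L) && all(colSums(pc) >= 1L)) break
  }
  d <- matrix(0L, H, H, dimnames = dimnames(pc)[c(2L, 2L)])
  d[upper.tri(d)] <- sample(1:8, H * (H - 1) / 2, replace = TRUE)
  d <- d + t(d)
  list(hset = makeHapSet(makeDistinctVectors(H), pc), popCounts = pc, d = d)
}

# write a small FASTA from named sequences
writeTestFasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  path
}

popTableFor <- function(sampleIds, popOf, lat = NULL, lon = NULL) {
  pops <- unique(popOf)
  if (is.null(lat)) lat <- setNames(28 + seq_along(pops) * 0.5, pops)
  if (is.null(lon)) lon <- setNames(100 + seq_along(pops) * 2, pops)
  data.frame(population = popOf, latitude = unname(lat[popOf]),
             longitude = unname(lon[popOf]), sample_id = sampleIds)
}

linePopTable <- function(P, perPop = 1L) {
  do.call(rbind, lapply(seq_len(P), function(i)
    data.frame(population = paste0("P", i), latitude = 28,
               longitude = 100 + 2 * (i - 1),
               sample_id = paste0("P", i, "_", seq_len(perPop)))))
}
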