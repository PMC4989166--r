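# Internal coalescent machinery shared by the neutrality-test p-values and
# the mismatch parametric bootstrap. Time is measured in mutational units
# (expected pairwise differences), in which the pair-coalescence hazard is
# 1/theta and branches accumulate mutations at rate 1/2 per unit.

# Neutral constant-size sample summary: mean pairwise differences, number
# of segregating sites and (optionally) number of distinct haplotypes under
# infinite sites. O(n) intervals; mutation placement by lineage.
.simCoalSummary <- function(n, theta, needK = FALSE) {
  sizes <- rep(1L, n)
  piSum <- 0; S <- 0L
  if (needK) {
    parent <- seq_len(n)                  # union-find over leaf classes
    findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    clean <- seq_len(n)                   # class reachable from lineage top
    pending <- integer(n)                 # mutations on the open branch
  }
  j <- n
  while (j > 1L) {
    Ts <- rexp(1L, j * (j - 1) / 2 / theta)
    M <- rpois(1L, j * Ts / 2)
    if (M > 0L) {
      idx <- sample.int(j, M, replace = TRUE)
      piSum <- piSum + sum(sizes[idx] * (n - sizes[idx]))
      S <- S + M
      if (needK) {
        tb <- tabulate(idx, j)
        pending <- pending + tb
      }
    }
    pair <- sample.int(j, 2L)
    a <- min(pair); b <- max(pair)
    if (needK) {
      ca <- if (pending[a] == 0L) clean[a] else NA_integer_
      cb <- if (pending[b] == 0L) clean[b] else NA_integer_
      newClean <- NA_integer_
      if (!is.na(ca) && !is.na(cb)) {
        ra <- findRoot(ca); rb <- findRoot(cb)
        if (ra != rb) parent[rb] <- ra
        newClean <- ra
      } else if (!is.na(ca)) newClean <- ca else if (!is.na(cb)) newClean <- cb
      clean[a] <- newClean; pending[a] <- 0L
      clean <- clean[-b]; pending <- pending[-b]
    }
    sizes[a] <- sizes[a] + sizes[b]
    sizes <- sizes[-b]
    j <- j - 1L
  }
  K <- if (needK) length(unique(vapply(seq_len(n), findRoot, integer(1L))))
       else NA_integer_
  list(pi = piSum / (n * (n - 1) / 2), S = S, K = K)
}

# Pairwise-difference histogram of a sample of size n under the sudden
# (stepwise) expansion model: theta = theta1 for mutational time s < tau,
# theta0 beyond. Returns counts over d = 0, 1, ... (index d+1).
.simExpansionHist <- function(n, theta0, theta1, tau) {
  theta0 <- max(theta0, 1e-8); theta1 <- max(theta1, 1e-8)
  leaves <- as.list(seq_len(n))
  mutUp <- lapply(seq_len(n), function(i) 0)
  pending <- numeric(n)
  hist <- numeric(1L)
  s <- 0; j <- n
  while (j > 1L) {
    th <- if (s < tau) theta1 else theta0
    Ts <- rexp(1L, j * (j - 1) / 2 / th)
    if (s < tau && s + Ts > tau) {
      dt <- tau - s
      M <- rpois(1L, j * dt / 2)
      if (M > 0L) pending <- pending + tabulate(sample.int(j, M, TRUE), j)
      s <- tau
      next
    }
    M <- rpois(1L, j * Ts / 2)
    if (M > 0L) pending <- pending + tabulate(sample.int(j, M, TRUE), j)
    s <- s + Ts
    pair <- sample.int(j, 2L)
    a <- min(pair); b <- max(pair)
    ma <- mutUp[[a]] + pending[a]
    mb <- mutUp[[b]] + pending[b]
    dvals <- as.integer(outer(ma, mb, "+"))
    top <- max(dvals) + 1L
    if (top > length(hist)) hist <- c(hist, numeric(top - length(hist)))
    tb <- tabulate(dvals + 1L, length(hist))
    hist <- hist + tb
    leaves[[a]] <- c(leaves[[a]], leaves[[b]])
    mutUp[[a]] <- c(ma, mb)
    pending[a] <- 0
    leaves <- leaves[-b]; mutUp <- mutUp[-b]; pending <- pending[-b]
    j <- j - 1L
  }
  counts <- as.integer(round(hist))
  names(counts) <- as.character(seq_along(counts) - 1L)
  counts
}
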