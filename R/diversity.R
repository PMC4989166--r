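# Diversity and differentiation statistics in the Pons & Petit tradition:
# unordered (identity kernel) h_S/h_T/G_ST and ordered (mutational-distance
# kernel) v_S/v_T/N_ST, with a permutation U-test contrasting the two.

#' Per-population haplotype and nucleotide diversity
#'
#' For a population of size n with haplotype frequencies p_k, haplotype
#' diversity is the unbiased \eqn{h = n/(n-1) (1 - \sum p_k^2)} and
#' nucleotide diversity is
#' \eqn{\pi = n/(n-1) \sum_{k<l} 2 p_k p_l d_{kl} / L}, where d counts one
#' difference per mutational event (substitution site, indel, inversion) and
#' L is the full alignment length. Populations of size 1 report h and pi as
#' NA.
#'
#' @param h a \linkS4class{HaplotypeSet} built with a population table.
#' @param pops the population table (adds coordinates to the output).
#' @param includeIndels passed to \code{\link{pairwiseDifferences}} so indel
#'   and inversion events can be excluded from pi.
#' @return data.frame with population, n, nHaplotypes, h, pi, latitude,
#'   longitude.
#' @export
perPopulationDiversity <- function(h, pops = NULL, includeIndels = TRUE) {
  stopifnot(is(h, "HaplotypeSet"))
  d <- pairwiseDifferences(h, includeIndels = includeIndels)
  X <- h@popCounts
  L <- h@alignmentLength
  res <- data.frame(population = rownames(X),
                    n = rowSums(X),
                    nHaplotypes = rowSums(X > 0L),
                    h = NA_real_, pi = NA_real_)
  for (i in seq_len(nrow(X))) {
    n <- res$n[i]
    if (n < 2L) next
    p <- X[i, ] / n
    res$h[i] <- n / (n - 1) * (1 - sum(p^2))
    res$pi[i] <- n / (n - 1) * as.numeric(t(p) %*% d %*% p) / L
  }
  if (!is.null(pops)) {
    cc <- unique(pops[, c("population", "latitude", "longitude")])
    res$latitude <- cc$latitude[match(res$population, cc$population)]
    res$longitude <- cc$longitude[match(res$population, cc$population)]
  }
  rownames(res) <- NULL
  res
}

# core estimator shared by differentiation() and the permutation test.
# X: counts (pops x haplotypes, n_i >= 2 each); kernel: 0/1 identity or d.
.ponsPetit <- function(X, d) {
  n <- rowSums(X)
  P <- nrow(X)
  freq <- X / n
  ident <- 1 - diag(nrow(d))            # unordered kernel
  within <- function(K) {
    w <- vapply(seq_len(P), function(i) {
      p <- freq[i, ]
      n[i] / (n[i] - 1) * as.numeric(t(p) %*% K %*% p)
    }, numeric(1L))
    mean(w)
  }
  nh <- P / sum(1 / n)                  # harmonic mean sample size
  xbar <- colMeans(freq)
  total <- function(K, wS) as.numeric(t(xbar) %*% K %*% xbar) + wS / (P * nh)
  hS <- within(ident); hT <- total(ident, hS)
  vS <- within(d);     vT <- total(d, vS)
  list(hS = hS, hT = hT, vS = vS, vT = vT,
       GST = 1 - hS / hT, NST = 1 - vS / vT)
}

#' Ordered and unordered population differentiation
#'
#' Computes within-population and total diversity with unweighted population
#' means and the harmonic-mean small-sample correction, for the unordered
#' identity kernel (h_S, h_T, G_ST) and the ordered mutational-distance
#' kernel (v_S, v_T, N_ST). Populations with fewer than two samples are
#' excluded with a warning. N_ST > G_ST signals phylogeographic structure.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param d distance matrix from \code{\link{pairwiseDifferences}}.
#' @return list with hS, hT, vS, vT, GST, NST, nPops, excluded.
#' @export
differentiation <- function(h, d = pairwiseDifferences(h)) {
  stopifnot(is(h, "HaplotypeSet"))
  X <- h@popCounts
  small <- rowSums(X) < 2L
  if (any(small)) {
    warning("excluding populations with n < 2: ",
            paste(rownames(X)[small], collapse = ", "))
    X <- X[!small, , drop = FALSE]
  }
  if (nrow(X) < 2L) stop("at least two populations with n >= 2 required")
  est <- .ponsPetit(X, d[h@labels, h@labels])
  if (est$hT <= 0) {
    warning("species monomorphic (h_T = 0): differentiation undefined")
    est$GST <- NA_real_; est$NST <- NA_real_
  }
  c(est, list(nPops = nrow(X), excluded = rownames(h@popCounts)[small]))
}

#' Permutation U-test for phylogeographic structure (N_ST vs G_ST)
#'
#' The null distribution of N_ST is built by permuting haplotype labels on
#' the distance matrix (haplotype frequencies untouched), which preserves
#' G_ST while destroying the association between frequency and mutational
#' distance. U standardises the observed N_ST against that null; the
#' one-tailed p-value uses the +1 correction.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param d distance matrix.
#' @param nPerm number of permutations (> 0).
#' @param seed RNG seed.
#' @return list with NST, GST, U, p, nPerm, null (permuted N_ST values).
#' @export
nstGstPermutationTest <- function(h, d = pairwiseDifferences(h),
                                  nPerm = 1000, seed = 1L) {
  if (nPerm < 1L) stop("nPerm must be positive")
  obs <- differentiation(h, d)
  X <- h@popCounts
  X <- X[rowSums(X) >= 2L, , drop = FALSE]
  dd <- d[h@labels, h@labels]
  H <- nrow(dd)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(b) {
    p <- sample.int(H)
    .ponsPetit(X, dd[p, p])$NST
  }, numeric(1L))
  s <- sd(null)
  if (!is.finite(s) || s == 0) {
    U <- NA_real_; p <- 1
  } else {
    U <- (obs$NST - mean(null)) / s
    p <- (1 + sum(null >= obs$NST)) / (nPerm + 1)
  }
  list(NST = obs$NST, GST = obs$GST, U = U, p = p, nPerm = nPerm, null = null)
}

#' Regression of haplotype diversity on latitude
#'
#' Ordinary least squares of per-population h on latitude; a significantly
#' negative slope is the classic leading-edge-expansion signature.
#'
#' @param perPop output of \code{\link{perPopulationDiversity}} (needs
#'   columns h and latitude).
#' @return list with slope, t, p (two-sided), r.squared, n, fit.
#' @export
diversityVsLatitude <- function(perPop) {
  ok <- is.finite(perPop$h) & is.finite(perPop$latitude)
  if (sum(ok) < 3L) stop("at least three populations with defined h required")
  dat <- perPop[ok, ]
  if (var(dat$latitude) == 0) stop("zero variance in latitude")
  fit <- lm(h ~ latitude, data = dat)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2L]),
       t = sm$coefficients[2L, "t value"],
       p = sm$coefficients[2L, "Pr(>|t|)"],
       r.squared = sm$r.squared,
       n = nrow(dat), fit = fit)
}
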