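# Neutrality tests, mismatch-distribution analysis under the sudden
# (stepwise) expansion model, parametric-bootstrap goodness of fit and
# calendar dating of the inferred expansion.

.tajimaConstants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

.tajimaDValue <- function(n, S, pi) {
  k <- .tajimaConstants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# individual-level mean pairwise differences from haplotype counts
.meanPairwiseDiff <- function(counts, d) {
  n <- sum(counts)
  as.numeric(t(counts) %*% d %*% counts) / 2 / (n * (n - 1) / 2)
}

#' Tajima's D with coalescent p-value
#'
#' D contrasts the mean pairwise difference estimator of theta with the
#' segregating-sites estimator S/a1; significantly negative values indicate
#' an excess of rare variants, as after population growth. The p-value is
#' obtained from neutral constant-size coalescent simulations conditioned
#' on n and theta-hat = S/a1 (two-tailed).
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param d mutational-step distance matrix.
#' @param nSim number of coalescent simulations (0 skips the p-value).
#' @param seed RNG seed.
#' @return list with D, p, n, S, pi, thetaW.
#' @export
tajimaD <- function(h, d = pairwiseDifferences(h), nSim = 10000L, seed = 1L) {
  counts <- colSums(h@popCounts)
  n <- sum(counts)
  if (n < 4L) stop("Tajima's D requires n >= 4")
  S <- ncol(h@vectors)
  if (S < 1L) {
    warning("no segregating sites: D undefined")
    return(list(D = NA_real_, p = NA_real_, n = n, S = 0L, pi = 0,
                thetaW = 0))
  }
  pi <- .meanPairwiseDiff(counts, d[h@labels, h@labels])
  D <- .tajimaDValue(n, S, pi)
  thetaW <- S / .tajimaConstants(n)$a1
  p <- NA_real_
  if (nSim > 0L) {
    set.seed(seed)
    sims <- vapply(seq_len(nSim), function(b) {
      s <- .simCoalSummary(n, thetaW)
      if (s$S < 1L) return(NA_real_)
      .tajimaDValue(n, s$S, s$pi)
    }, numeric(1L))
    sims <- sims[is.finite(sims)]
    lo <- mean(sims <= D); hi <- mean(sims >= D)
    p <- min(1, 2 * min(lo, hi))
  }
  list(D = D, p = p, n = n, S = S, pi = pi, thetaW = thetaW)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n)
.logStirlingRow <- function(n) {
  L <- 0                                  # row 1: |s(1,1)| = 1
  if (n == 1L) return(L)
  for (m in 2:n) {
    prev <- c(-Inf, L)                    # |s(m, k)| term from s(m-1, k-1)
    shifted <- c(L, -Inf) + log(m - 1)    # (m-1) * |s(m-1, k)|
    hi <- pmax(prev, shifted)
    L <- hi + log1p(exp(pmin(prev, shifted) - hi))
    L[!is.finite(hi)] <- -Inf
  }
  L
}

# Pr(K >= k | theta, n) under the Ewens sampling formula
.ewensPrKgeq <- function(k, n, theta, logStirling = .logStirlingRow(n)) {
  if (theta <= 0) return(if (k <= 1L) 1 else 0)
  lp <- logStirling + seq_len(n) * log(theta) -
    sum(log(theta + 0:(n - 1L)))
  mx <- max(lp)
  w <- exp(lp - mx)
  sum(w[k:n]) / sum(w)
}

#' Fu's F_S with coalescent p-value
#'
#' S' is the Ewens-sampling-formula probability of observing at least the
#' observed number of haplotypes given theta-hat = pi, computed through the
#' unsigned-Stirling-number recursion; F_S = ln(S'/(1-S')). Strongly
#' negative values indicate an excess of haplotypes, as after expansion.
#' The p-value is the fraction of neutral coalescent simulations with
#' F_S at or below the observed value.
#'
#' @inheritParams tajimaD
#' @return list with FS, Sprime, p, n, K, pi.
#' @export
fuFs <- function(h, d = pairwiseDifferences(h), nSim = 1000L, seed = 1L) {
  counts <- colSums(h@popCounts)
  n <- sum(counts)
  if (n < 2L) stop("Fu's F_S requires n >= 2")
  if (h@monomorphic) {
    warning("monomorphic sample: F_S undefined")
    return(list(FS = NA_real_, Sprime = NA_real_, p = NA_real_, n = n,
                K = 1L, pi = 0))
  }
  K <- length(h@labels)
  pi <- .meanPairwiseDiff(counts, d[h@labels, h@labels])
  lsr <- .logStirlingRow(n)
  Sp <- .ewensPrKgeq(K, n, pi, lsr)
  FS <- if (Sp >= 1) Inf else if (Sp <= 0) -Inf else log(Sp / (1 - Sp))
  p <- NA_real_
  if (nSim > 0L && is.finite(FS)) {
    set.seed(seed)
    sims <- vapply(seq_len(nSim), function(b) {
      s <- .simCoalSummary(n, pi, needK = TRUE)
      sp <- .ewensPrKgeq(s$K, n, s$pi, lsr)
      if (sp >= 1) Inf else if (sp <= 0) -Inf else log(sp / (1 - sp))
    }, numeric(1L))
    p <- mean(sims <= FS)
  }
  list(FS = FS, Sprime = Sp, p = p, n = n, K = K, pi = pi)
}

#' Histogram of pairwise differences between individuals
#'
#' All n(n-1)/2 individual pairs, using the mutational-step distance between
#' their haplotypes; optionally restricted to a subset of populations.
#'
#' @param h a \linkS4class{HaplotypeSet}.
#' @param d distance matrix.
#' @param populations optional character vector of population codes.
#' @return named integer vector of pair counts over d = 0..d_max.
#' @export
mismatchHistogram <- function(h, d = pairwiseDifferences(h),
                              populations = NULL) {
  X <- h@popCounts
  if (!is.null(populations)) {
    miss <- setdiff(populations, rownames(X))
    if (length(miss)) stop("unknown populations: ", paste(miss, collapse = ", "))
    X <- X[populations, , drop = FALSE]
  }
  counts <- colSums(X)
  n <- sum(counts)
  if (n < 3L) stop("at least three individuals required")
  dd <- d[h@labels, h@labels, drop = FALSE]
  dmax <- max(dd[counts > 0L, counts > 0L, drop = FALSE])
  out <- integer(dmax + 1L)
  for (k in seq_along(counts)) {
    if (counts[k] > 1L)
      out[1L] <- out[1L] + counts[k] * (counts[k] - 1L) / 2L
    if (k < length(counts)) {
      for (l in (k + 1L):length(counts)) {
        np <- counts[k] * counts[l]
        if (np > 0L) out[dd[k, l] + 1L] <- out[dd[k, l] + 1L] + np
      }
    }
  }
  names(out) <- as.character(0:dmax)
  out
}

#' Expected mismatch distribution under sudden expansion
#'
#' Probability of observing i pairwise differences when a stationary
#' population of scaled size theta0 jumped to theta1 at mutational time tau
#' before present. At tau = 0 this reduces to the stationary geometric
#' \eqn{F_i(\theta) = \theta^i/(1+\theta)^{i+1}}. Evaluated in log space
#' through regularized incomplete-gamma tails, so it is stable for large
#' tau and extreme theta.
#'
#' @param i vector of difference counts (>= 0).
#' @param tau,theta0,theta1 model parameters (all >= 0, theta1 >= theta0).
#' @return vector of probabilities.
#' @export
expectedMismatch <- function(i, tau, theta0, theta1) {
  stopifnot(all(i >= 0), tau >= 0, theta0 >= 0, theta1 >= theta0)
  theta1 <- max(theta1, 1e-10)
  logFhat <- function(i, th) {
    if (th <= 0) return(ifelse(i == 0L, 0, -Inf))
    i * log(th) - (i + 1) * log1p(th)
  }
  a1 <- (theta1 + 1) / theta1
  t1 <- logFhat(i, theta1) +
    pgamma(a1 * tau, i + 1, lower.tail = TRUE, log.p = TRUE)
  if (theta0 <= 1e-10) {
    t2 <- -tau / theta1 + dpois(i, tau, log = TRUE)
  } else {
    a0 <- (theta0 + 1) / theta0
    t2 <- logFhat(i, theta0) + tau * (1 / theta0 - 1 / theta1) +
      pgamma(a0 * tau, i + 1, lower.tail = FALSE, log.p = TRUE)
  }
  exp(t1) + exp(t2)
}

#' Harpending's raggedness index
#'
#' Sum of squared successive differences of the relative mismatch
#' frequencies, with the x_{-1} = 0 convention (d_max + 1 terms). Smooth
#' unimodal expansion curves score low; multi-spike histograms score high.
#'
#' @param hist counts as from \code{\link{mismatchHistogram}}.
#' @export
raggedness <- function(hist) {
  x <- hist / sum(hist)
  sum(diff(c(0, x))^2)
}

# SSD between observed relative frequencies and the model over 0..dmax with
# the expected tail mass folded into the last bin.
.mismatchSSD <- function(obs, tau, theta0, theta1) {
  dmax <- length(obs) - 1L
  e <- expectedMismatch(0:dmax, tau, theta0, theta1)
  e[dmax + 1L] <- max(0, 1 - sum(e[seq_len(dmax)]))
  sum((obs - e)^2)
}

#' Fit the sudden-expansion model to a mismatch histogram
#'
#' Minimises the sum of squared deviations between observed and expected
#' relative frequencies over (tau, theta0, theta1) with tau, theta0 >= 0 and
#' theta1 >= theta0, using a moment-informed multistart grid refined by
#' Nelder-Mead on transformed (squared) parameters.
#'
#' @param hist counts as from \code{\link{mismatchHistogram}}.
#' @param n number of individuals behind the histogram.
#' @param fast use the reduced start grid (parametric-bootstrap refits).
#' @param init optional c(tau, theta0, theta1) added to the start grid.
#' @return a \linkS4class{MismatchFit}.
#' @export
fitSuddenExpansion <- function(hist, n, fast = FALSE, init = NULL) {
  if (sum(hist) < 1L || length(hist) < 2L)
    stop("degenerate mismatch histogram")
  obs <- hist / sum(hist)
  dmax <- length(obs) - 1L
  m1 <- sum((0:dmax) * obs)
  obj <- function(par) {
    tau <- par[1L]^2; th0 <- par[2L]^2; th1 <- th0 + par[3L]^2
    .mismatchSSD(obs, tau, th0, th1)
  }
  starts <- list(c(max(m1, 0.1), 0.1, max(4 * m1, 5)),
                 c(max(m1 / 2, 0.05), 0.5, max(10 * m1, 20)))
  if (!fast)
    starts <- c(starts, list(
      c(0.05, max(m1, 0.1), max(2 * m1, 2)),
      c(1.5 * m1 + 0.1, 0.05, 100),
      c(max(m1 - 1, 0.05), 1, max(20 * m1, 50)),
      c(0.01, 0.01, max(m1, 1))))
  if (!is.null(init))
    starts <- c(list(init + 1e-6), starts)
  bestVal <- Inf; best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(sqrt(pmax(s0, 1e-8)), obj, method = "Nelder-Mead",
            control = list(maxit = if (fast) 200L else 500L,
                           reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < bestVal) {
      bestVal <- fit$value; best <- fit
    }
  }
  if (is.null(best)) stop("expansion-model fit failed to converge from all starts")
  tau <- best$par[1L]^2
  th0 <- best$par[2L]^2
  th1 <- th0 + best$par[3L]^2
  eFull <- expectedMismatch(0:(dmax + 20L), tau, th0, th1)
  eFull[length(eFull)] <- max(0, 1 - sum(eFull[-length(eFull)]))
  new("MismatchFit", observed = as.integer(hist), n = as.integer(n),
      tau = tau, theta0 = th0, theta1 = th1, ssd = bestVal,
      raggedness = raggedness(hist), expected = eFull,
      modality = classifyModality(hist), gof = list())
}

#' Parametric-bootstrap goodness of fit for the expansion model
#'
#' Simulates \code{nBoot} coalescent samples of the original size under the
#' fitted sudden-expansion parameters, refits each, and reports the
#' fraction of replicates whose SSD (and raggedness) reach the observed
#' values, plus the percentile confidence interval of tau.
#'
#' @param fit a \linkS4class{MismatchFit}.
#' @param nBoot bootstrap replicates (values below 100 draw a warning).
#' @param seed RNG seed.
#' @param level CI level for tau.
#' @return the fit with the \code{gof} slot filled (pSSD, pRag, tauCI,
#'   tauBoot).
#' @export
expansionGof <- function(fit, nBoot = 1000L, seed = 1L, level = 0.95) {
  stopifnot(is(fit, "MismatchFit"))
  if (nBoot < 100L) warning("nBoot < 100: bootstrap p-values will be coarse")
  set.seed(seed)
  ssdB <- ragB <- tauB <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    hb <- .simExpansionHist(fit@n, fit@theta0, fit@theta1, fit@tau)
    fb <- fitSuddenExpansion(hb, fit@n, fast = TRUE,
                             init = c(fit@tau, fit@theta0, fit@theta1))
    ssdB[b] <- fb@ssd
    ragB[b] <- fb@raggedness
    tauB[b] <- fb@tau
  }
  al <- (1 - level) / 2
  fit@gof <- list(
    pSSD = (1 + sum(ssdB >= fit@ssd)) / (nBoot + 1),
    pRag = (1 + sum(ragB >= fit@raggedness)) / (nBoot + 1),
    tauCI = unname(quantile(tauB, c(al, 1 - al))),
    tauBoot = tauB, nBoot = nBoot, seed = seed)
  fit
}

#' Species-specific dating inputs used for the three focal species
#'
#' Substitution rate (substitutions/site/year), average analysed sequence
#' length (bp) and generation time (years) for Castanopsis tibetana,
#' Machilus thunbergii and Schima superba.
#' @return data.frame with columns species, mu, k, g.
#' @export
datingPresets <- function() {
  data.frame(
    species = c("C. tibetana", "M. thunbergii", "S. superba"),
    mu = c(0.71e-9, 4e-9, 0.6e-9),
    k = c(1826, 1450, 1399),
    g = c(25, 10, 8))
}

#' Calendar date of a sudden expansion
#'
#' Converts the expansion parameter tau to time before present through
#' \eqn{T = \tau / (2 \mu k g)}, with mu the substitution rate per site per
#' year, k the analysed sequence length in bp and g the generation time in
#' years. The "published" rounding mode floors the result to the nearest
#' hundred years, the convention under which the published dates for all
#' three focal species are recovered exactly.
#'
#' @param tau expansion parameter (mutational units, >= 0).
#' @param mu,k,g dating inputs, all strictly positive.
#' @param rounding "none" or "published" (floor to hundreds).
#' @param tauCI optional c(lower, upper) CI for tau, transformed alike.
#' @return list with T, CI, rounding.
#' @export
dateExpansion <- function(tau, mu, k, g, rounding = c("none", "published"),
                          tauCI = NULL) {
  rounding <- match.arg(rounding)
  if (tau < 0) stop("tau must be >= 0")
  if (any(c(mu, k, g) <= 0)) stop("mu, k and g must be strictly positive")
  conv <- function(x) {
    v <- x / (2 * mu * k * g)
    if (rounding == "published") v <- floor(v / 100) * 100
    v
  }
  list(T = conv(tau),
       CI = if (is.null(tauCI)) NULL else conv(sort(tauCI)),
       rounding = rounding)
}

#' Classify mismatch-distribution modality
#'
#' Counts local maxima of the moving-average-smoothed relative-frequency
#' curve and labels the histogram unimodal, bimodal or multimodal.
#'
#' @param hist counts as from \code{\link{mismatchHistogram}}.
#' @param window moving-average window (odd number of bins).
#' @export
classifyModality <- function(hist, window = 3L) {
  if (!length(hist)) stop("empty histogram")
  x <- as.numeric(hist) / sum(hist)
  half <- (window - 1L) %/% 2L
  sm <- vapply(seq_along(x), function(i) {
    idx <- max(1L, i - half):min(length(x), i + half)
    mean(x[idx])
  }, numeric(1L))
  r <- rle(sm)
  v <- r$values
  if (length(v) == 1L) return("unimodal")
  peaks <- 0L
  for (i in seq_along(v)) {
    up <- i == 1L || v[i] > v[i - 1L]
    down <- i == length(v) || v[i] > v[i + 1L]
    if (up && down) peaks <- peaks + 1L
  }
  if (peaks <= 1L) "unimodal" else if (peaks == 2L) "bimodal" else "multimodal"
}
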