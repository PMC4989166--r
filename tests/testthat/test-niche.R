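test_that("ASCII grid stacks round-trip through files", {
  set.seed(3)
  ls <- landscapeScenario(nrow = 15, ncol = 12, nVars = 3, smoothing = 3,
                          niches = list(sp = list(optimum = rep(0, 3),
                                                  width = rep(1, 3), n = 30)))
  sim <- simulateLandscape(ls, seed = 5)
  dir <- tempfile()
  writeAsciiGridStack(sim$stack, dir)
  back <- readAsciiGridStack(list.files(dir, full.names = TRUE))
  expect_equal(layerNames(back), sort(layerNames(sim$stack)))
  for (nm in layerNames(sim$stack))
    expect_equal(back@layers[, , nm], sim$stack@layers[, , nm],
                 tolerance = 1e-6)
  expect_equal(back@cellsize, sim$stack@cellsize)
})

test_that("the greedy collinearity filter keeps exactly the independent factors", {
  set.seed(8)
  ncell <- 900
  factors <- matrix(rnorm(ncell * 7), ncell, 7)
  layers <- list()
  for (i in 1:7) layers[[paste0("F", i)]] <- matrix(factors[, i], 30, 30)
  for (j in 1:12) {
    src <- ((j - 1) %% 7) + 1
    layers[[paste0("M", j)]] <-
      matrix(factors[, src] * runif(1, 0.5, 2) + rnorm(ncell, 0, 0.2), 30, 30)
  }
  stack <- EnvStack(layers)
  res <- filterVariables(stack, 0.70)
  expect_equal(res$retained, paste0("F", 1:7))
  expect_equal(nrow(res$dropped), 12L)

  # duplicated layer is dropped; uncorrelated layers are all retained
  dup <- EnvStack(list(A = layers$F1, B = layers$F1, C = layers$F2))
  expect_equal(filterVariables(dup, 0.7)$retained, c("A", "C"))
  indep <- EnvStack(layers[paste0("F", 1:4)])
  expect_equal(filterVariables(indep, 0.7)$retained, paste0("F", 1:4))

  # constant layer: warned about, retained
  cst <- EnvStack(list(A = layers$F1, K = matrix(1, 30, 30)))
  expect_warning(rk <- filterVariables(cst, 0.7), "constant")
  expect_true("K" %in% rk$retained)
})

test_that("suitability models honour presence envelopes", {
  g <- matrix(rep(seq_len(50), each = 50), 50, 50)   # g[i, j] = j
  stack <- EnvStack(list(V1 = g), xll = 0, yll = 0, cellsize = 1)
  # all presences at one climate value -> those cells score 1
  occ <- data.frame(lon = rep(24.5, 12), lat = seq(0.5, 11.5))
  s <- fitSuitability(occ, stack, dedup = FALSE)
  expect_equal(max(s@values[, 25]), 1)
  expect_lt(max(s@values[, c(1, 50)]), 1e-6)   # far outside the envelope
  expect_error(fitSuitability(occ[1:5, ], stack), "presences")

  sb <- fitSuitability(occ, stack, model = "bioclim_percentile",
                       dedup = FALSE)
  expect_true(all(sb@values[stack@mask] >= 0 & sb@values[stack@mask] <= 1))
})

test_that("a fitted Gaussian niche correlates strongly with the truth", {
  ls <- landscapeScenario(nrow = 40, ncol = 40, nVars = 4, smoothing = 5,
                          niches = list(sp = list(optimum = c(0.5, 0, 0, 0),
                                                  width = rep(1, 4), n = 200)))
  cors <- vapply(c(11, 12, 13), function(sd) {
    sim <- simulateLandscape(ls, seed = sd)
    s <- fitSuitability(sim$occurrences, sim$stack)
    cor(sim$truth$suitability$sp[sim$stack@mask],
        s@values[sim$stack@mask])
  }, numeric(1))
  expect_gt(mean(cors), 0.9)
})

test_that("AUC reaches 1 under perfect separation and 0.5 under noise", {
  g <- matrix(rep(seq_len(100), each = 100), 100, 100)
  stack <- EnvStack(list(V1 = g), xll = 0, yll = 0, cellsize = 1)
  occ <- data.frame(lon = rep(49.5, 50), lat = seq(0.5, 49.5))
  a <- evaluateAuc(occ, stack, nBackground = 500, seed = 1)
  expect_gte(a$auc, 0.99)    # ties with background on presence cells only

  # model scores carry no information -> AUC near 1/2
  set.seed(9)
  noise <- EnvStack(list(V1 = matrix(rnorm(10000), 100)))
  aucs <- vapply(1:10, function(s) {
    occ2 <- data.frame(lon = runif(250, 0, 100), lat = runif(250, 0, 100))
    evaluateAuc(occ2, noise, nBackground = 1000, seed = s)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)

  expect_error(evaluateAuc(occ, stack, trainFrac = 1), "test")
  expect_error(evaluateAuc(occ, stack, nBackground = 0), "positive")
})

test_that("niche overlap metrics hit their analytic anchors", {
  m1 <- matrix(runif(100, 0.2, 1), 10, 10)
  mask <- matrix(TRUE, 10, 10)
  mk <- function(v) new("SuitabilityRaster", values = v, mask = mask,
                        xll = 0, yll = 0, cellsize = 1, model = list())
  s1 <- mk(m1)
  ov <- nicheOverlap(s1, mk(m1))
  expect_equal(unname(ov[["D"]]), 1, tolerance = 1e-12)
  expect_equal(unname(ov[["I"]]), 1, tolerance = 1e-12)

  # disjoint supports -> both zero
  a <- matrix(0, 10, 10); a[, 1:5] <- 1
  b <- matrix(0, 10, 10); b[, 6:10] <- 1
  ov0 <- nicheOverlap(mk(a), mk(b))
  expect_equal(unname(ov0[["D"]]), 0)
  expect_equal(unname(ov0[["I"]]), 0)

  # uniform over 2N cells vs uniform over N of them -> D = 1/2
  u2 <- matrix(1, 10, 10)
  u1 <- matrix(0, 10, 10); u1[1:5, ] <- 1
  expect_equal(unname(nicheOverlap(mk(u2), mk(u1))[["D"]]), 0.5,
               tolerance = 1e-12)

  # symmetry and scale invariance
  s2 <- mk(matrix(runif(100), 10, 10))
  expect_equal(nicheOverlap(s1, s2), nicheOverlap(s2, s1))
  expect_equal(nicheOverlap(mk(m1 * 0.37), s2), nicheOverlap(s1, s2),
               tolerance = 1e-12)
  expect_error(nicheOverlap(mk(matrix(0, 10, 10)), s2), "all-zero")
})

test_that("the identity test tells shared from separated niches", {
  ls <- landscapeScenario(nrow = 40, ncol = 40, nVars = 4, smoothing = 5,
    niches = list(
      sp1 = list(optimum = c(0.5, 0, 0, 0), width = rep(1, 4), n = 150),
      sp2 = list(optimum = c(0.5, 0, 0, 0), width = rep(1, 4), n = 120),
      sp3 = list(optimum = c(-2.5, 2.5, 0, 0), width = rep(0.4, 4), n = 120)))
  sim <- simulateLandscape(ls, seed = 11)
  oc <- function(sp) sim$occurrences[sim$occurrences$species == sp, ]
  same <- identityTest(oc("sp1"), oc("sp2"), sim$stack, nReps = 50, seed = 5)
  expect_gt(same@pD, 0.05)
  expect_gt(same@pI, 0.05)
  diff <- identityTest(oc("sp1"), oc("sp3"), sim$stack, nReps = 50, seed = 5)
  expect_lte(diff@pD, 1 / 51 + 1e-9)
  expect_lt(diff@D, min(diff@nullD))

  # same seed -> identical null; swapped species -> same null multiset
  diff2 <- identityTest(oc("sp1"), oc("sp3"), sim$stack, nReps = 50, seed = 5)
  expect_identical(diff@nullD, diff2@nullD)
  swap <- identityTest(oc("sp3"), oc("sp1"), sim$stack, nReps = 50, seed = 5)
  expect_equal(sort(swap@nullD), sort(diff@nullD))
  expect_warning(identityTest(oc("sp1"), oc("sp2"), sim$stack, nReps = 5,
                              seed = 1), "coarse")
})
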