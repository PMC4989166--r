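test_that("Tajima's D is zero when pi equals S/a1 and matches the oracle", {
  # n = 4, counts (2,1,1), 11 recoded columns arranged so pi = S/a1 exactly
  v <- matrix("A", 3, 11, dimnames = list(c("H1", "H2", "H3"), NULL))
  v[1, 1:3] <- "T"; v[2, 4:7] <- "T"; v[3, 8:11] <- "T"
  pc <- matrix(c(2L, 1L, 1L), 1, 3, dimnames = list("all", rownames(v)))
  res <- tajimaD(makeHapSet(v, pc), nSim = 0)
  expect_equal(res$D, 0, tolerance = 1e-12)
  expect_equal(res$pi, res$S / sum(1 / (1:3)), tolerance = 1e-12)

  # random toy configurations against the independently coded formula
  set.seed(61)
  for (rep in 1:6) {
    H <- sample(3:6, 1)
    v <- makeDistinctVectors(H, extraCols = sample(0:3, 1))
    cnt <- matrix(as.integer(rmultinom(1, sample(6:15, 1), rep(1, H))), 1,
                  dimnames = list("all", rownames(v)))
    if (any(cnt == 0)) cnt[cnt == 0] <- 1L
    h <- makeHapSet(v, cnt)
    res <- tajimaD(h, nSim = 0)
    expect_equal(res$D, oracleTajimaD(res$n, res$S, res$pi),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D needs polymorphism and enough samples", {
  v <- makeDistinctVectors(2)
  pc <- matrix(c(2L, 1L), 1, 2, dimnames = list("all", c("H1", "H2")))
  expect_error(tajimaD(makeHapSet(v, pc)), "n >= 4")
})

test_that("Fu's F_S matches the Ewens closed form at n = 2", {
  # two sequences, 1 difference: S' = theta/(1+theta) = 0.5, F_S = 0
  v1 <- matrix(c("A", "T"), 2, 1, dimnames = list(c("H1", "H2"), NULL))
  pc <- matrix(c(1L, 1L), 1, 2, dimnames = list("all", c("H1", "H2")))
  r1 <- fuFs(makeHapSet(v1, pc), nSim = 0)
  expect_equal(r1$FS, 0, tolerance = 1e-12)
  expect_equal(r1$Sprime, 0.5, tolerance = 1e-12)

  # 3 differences: S' = 3/4, F_S = ln 3
  v3 <- matrix(c("A", "A", "A", "T", "T", "T"), 2, 3, byrow = TRUE,
               dimnames = list(c("H1", "H2"), NULL))
  r3 <- fuFs(makeHapSet(v3, pc), nSim = 0)
  expect_equal(r3$FS, log(3), tolerance = 1e-12)

  # monomorphic flagged
  vm <- matrix("A", 1, 2, dimnames = list("H1", NULL))
  pcm <- matrix(4L, 1, 1, dimnames = list("all", "H1"))
  expect_warning(rm <- fuFs(makeHapSet(vm, pcm), nSim = 0), "monomorphic")
  expect_true(is.na(rm$FS))
})

test_that("neutrality statistics ignore sample order", {
  inst <- randomIslandInstance(P = 3, H = 5, seed = 71)
  h <- inst$hset
  perm <- sample(5)
  pc2 <- h@popCounts[, perm]
  colnames(pc2) <- paste0("H", 1:5)
  d2 <- inst$d[perm, perm]; dimnames(d2) <- dimnames(inst$d)
  h2 <- makeHapSet(makeDistinctVectors(5), pc2)
  expect_equal(tajimaD(h, inst$d, nSim = 0)$D,
               tajimaD(h2, d2, nSim = 0)$D, tolerance = 1e-12)
  expect_equal(fuFs(h, inst$d, nSim = 0)$FS,
               fuFs(h2, d2, nSim = 0)$FS, tolerance = 1e-12)
})

test_that("mismatch histograms count all pairs correctly", {
  # {A, A, B, B} with d(A,B) = 3 -> {0: 2, 3: 4}
  v <- matrix(c("A", "A", "A", "T", "T", "T"), 2, 3, byrow = TRUE,
              dimnames = list(c("H1", "H2"), NULL))
  pc <- matrix(c(2L, 2L), 1, 2, dimnames = list("all", c("H1", "H2")))
  hist <- mismatchHistogram(makeHapSet(v, pc))
  expect_equal(unname(hist[c("0", "3")]), c(2L, 4L))
  expect_equal(sum(hist), 6L)

  # monomorphic: all pairs at zero
  vm <- matrix("A", 1, 2, dimnames = list("H1", NULL))
  pcm <- matrix(5L, 1, 1, dimnames = list("all", "H1"))
  hm <- suppressWarnings(mismatchHistogram(makeHapSet(vm, pcm)))
  expect_equal(unname(hm), 10L)

  # pooled pairs = within-population pairs + cross pairs
  pc2 <- matrix(c(2L, 1L, 1L, 2L), 2, 2,
                dimnames = list(c("P1", "P2"), c("H1", "H2")))
  h2 <- makeHapSet(v, pc2)
  pooled <- mismatchHistogram(h2)
  p1 <- mismatchHistogram(h2, populations = "P1")
  p2 <- mismatchHistogram(h2, populations = "P2")
  expect_equal(sum(pooled), choose(6, 2))
  expect_equal(sum(pooled) - sum(p1) - sum(p2), 3 * 3)  # cross pairs
})

test_that("the expected mismatch distribution is a proper distribution", {
  for (par in list(c(0, 2, 2), c(3, 1, 20), c(8, 0.5, 60), c(2, 0, 10))) {
    p <- expectedMismatch(0:600, par[1], par[2], par[3])
    expect_equal(sum(p), 1, tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
  # tau = 0 reduces to the stationary geometric form
  th <- 2.5
  expect_equal(expectedMismatch(0:20, 0, th, th * 2),
               th^(0:20) / (1 + th)^(1:21), tolerance = 1e-12)
})

test_that("fitting recovers the stationary model from exact-curve data", {
  set.seed(42)
  e <- expectedMismatch(0:60, 0, 2, 2)
  e[61] <- 1 - sum(e[1:60])
  hist <- as.integer(rmultinom(1, 10000, e))
  names(hist) <- 0:60
  fit <- fitSuddenExpansion(hist, 100)
  expect_lt(fit@tau, 0.3)
  expect_equal(fit@theta0, 2, tolerance = 0.1)
  expect_s4_class(fit, "MismatchFit")
})

test_that("raggedness ranks smooth curves below spiky ones", {
  smooth <- as.integer(round(1000 * expectedMismatch(0:20, 5, 0.5, 50)))
  names(smooth) <- 0:20
  spiky <- integer(21); spiky[1] <- sum(smooth) %/% 2L
  spiky[21] <- sum(smooth) - spiky[1]
  names(spiky) <- 0:20
  expect_lt(raggedness(smooth), raggedness(spiky))
})

test_that("parametric bootstrap rejects a bimodal two-clade histogram", {
  hist <- integer(21); hist[1] <- 600L; hist[21] <- 625L
  names(hist) <- 0:20
  fit <- fitSuddenExpansion(hist, 50)
  expect_equal(fit@modality, "bimodal")
  fit <- expansionGof(fit, nBoot = 100, seed = 3)
  expect_lte(fit@gof$pSSD, 0.05)
  # same seed, same p-values
  fit2 <- expansionGof(fitSuddenExpansion(hist, 50), nBoot = 100, seed = 3)
  expect_identical(fit@gof$pSSD, fit2@gof$pSSD)
  expect_identical(fit@gof$tauCI, fit2@gof$tauCI)
  expect_warning(expansionGof(fit, nBoot = 50, seed = 1), "coarse")
})

test_that("expansion dating reproduces closed forms and scaling laws", {
  expect_equal(dateExpansion(0, 1e-9, 1000, 10)$T, 0)
  expect_error(dateExpansion(-1, 1e-9, 1000, 10), "tau")
  expect_error(dateExpansion(1, 0, 1000, 10), "positive")
  # linear in tau, inverse in mu, k, g
  base <- dateExpansion(1, 1e-9, 1500, 10)$T
  expect_equal(dateExpansion(3, 1e-9, 1500, 10)$T, 3 * base, tolerance = 1e-12)
  expect_equal(dateExpansion(1, 2e-9, 1500, 10)$T, base / 2, tolerance = 1e-12)
  expect_equal(dateExpansion(1, 1e-9, 3000, 10)$T, base / 2, tolerance = 1e-12)
  expect_equal(dateExpansion(1, 1e-9, 1500, 20)$T, base / 2, tolerance = 1e-12)
  # CI endpoints transform with the point estimate
  r <- dateExpansion(0.625, 0.71e-9, 1826, 25, rounding = "published",
                     tauCI = c(0, 3.438))
  expect_equal(r$T, 9600)
  expect_equal(r$CI[1], 0)
})

test_that("modality labels match curve shape", {
  uni <- as.integer(round(1000 * expectedMismatch(0:15, 4, 0.5, 40)))
  names(uni) <- 0:15
  expect_equal(classifyModality(uni), "unimodal")
  bi <- integer(25); bi[2] <- 300L; bi[20] <- 280L
  names(bi) <- 0:24
  expect_equal(classifyModality(bi), "bimodal")
  flat <- c("0" = 45L)
  expect_equal(classifyModality(flat), "unimodal")
})
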