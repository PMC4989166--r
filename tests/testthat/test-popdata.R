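test_that("readAlignment validates records, lengths and alphabet", {
  fa <- writeTestFasta(list(a = "acgtacgtac", b = "ACGTACGTAC",
                            c = "ACGTACGTAT", d = "ACG-ACGTAC"))
  aln <- readAlignment(fa)
  expect_s4_class(aln, "HapAlignment")
  expect_equal(dim(aln@seqs), c(4L, 10L))
  expect_equal(unname(aln@seqs[1L, 1:4]), c("A", "C", "G", "T"))  # upper-cased

  bad <- writeTestFasta(list(a = "ACGTACGTAC", b = "ACGTACGTA"))
  expect_error(readAlignment(bad), "same length")
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_error(readAlignment(empty), "no records")
  ill <- writeTestFasta(list(a = "ACGTX", b = "ACGTA"))
  expect_error(readAlignment(ill), "illegal")
  expect_error(readAlignment(tempfile()), "not found")
})

test_that("locus bounds must partition the alignment", {
  fa <- writeTestFasta(list(a = "ACGTACGTAC", b = "ACGTACGTAT"))
  aln <- readAlignment(fa, locusBounds = list(c(0, 6), c(6, 10)))
  expect_equal(nrow(aln@locusBounds), 2L)
  expect_error(readAlignment(fa, locusBounds = list(c(0, 5), c(6, 10))),
               "partition")
})

test_that("population tables are validated", {
  tab <- data.frame(population = c("P1", "P1", "P2"),
                    latitude = c(28, 28, 29), longitude = c(110, 110, 112),
                    sample_id = c("a", "b", "c"))
  f <- tempfile(fileext = ".csv"); write.csv(tab, f, row.names = FALSE)
  pt <- readPopulationTable(f)
  expect_equal(length(unique(pt$population)), 2L)

  expect_error(validatePopulationTable(transform(tab, sample_id = c("a", "a", "c"))),
               "duplicated sample_id")
  expect_error(validatePopulationTable(transform(tab, latitude = c(95, 28, 29))),
               "out of range")
  expect_error(validatePopulationTable(tab[, -1L]), "lacks columns")
})

test_that("gap runs collapse to single indel columns", {
  # identical except a 3-bp gap -> exactly one variable column
  fa <- writeTestFasta(list(a = "ACGTACGTAC", b = "ACG---GTAC"))
  mm <- recodeMutations(readAlignment(fa))
  expect_equal(ncol(mm@states), 1L)
  expect_equal(mm@meta$type, "indel")

  # 2 substitutions + one 5-bp indel -> 3 variable columns
  fa <- writeTestFasta(list(a = "ACGTACGTACGT", b = "TCG-----ACGA"))
  mm <- recodeMutations(readAlignment(fa))
  expect_equal(ncol(mm@states), 3L)
  expect_equal(sort(mm@meta$type), c("indel", "substitution", "substitution"))

  # nested gap spans get separate columns
  fa <- writeTestFasta(list(a = "ACGTACGTAC", b = "ACG---GTAC",
                            c = "AC-----TAC"))
  mm <- recodeMutations(readAlignment(fa))
  expect_equal(sum(mm@meta$type == "indel"), 2L)
})

test_that("declared inversions become one orientation column", {
  # reverse complement of ACGT is ACGT; use AGGT (revcomp ACCT)
  fa <- writeTestFasta(list(a = "TTAGGTCC", b = "TTAGGTCC",
                            c = "TTACCTCC", d = "TTACCTCC"))
  mm <- recodeMutations(readAlignment(fa), inversions = list(c(2, 6)))
  expect_equal(ncol(mm@states), 1L)
  expect_equal(mm@meta$type, "inversion")
  expect_equal(length(unique(mm@states[, 1L])), 2L)
  expect_error(recodeMutations(readAlignment(fa),
                               inversions = list(c(2, 6), c(4, 8))),
               "overlapping")
})

test_that("columns containing N are excluded from haplotype definition", {
  fa <- writeTestFasta(list(a = "ACGTA", b = "ACGTN", c = "ACGAA"))
  mm <- recodeMutations(readAlignment(fa))
  # position 5 (N in b) is dropped; position 4 remains
  expect_equal(mm@meta$start, 4L)
  expect_equal(ncol(mm@states), 1L)
})

test_that("haplotypes collapse in order of first appearance", {
  fa <- writeTestFasta(list(s1 = "ACGT", s2 = "ACGA", s3 = "ACGT",
                            s4 = "ACGA"))
  h <- collapseHaplotypes(recodeMutations(readAlignment(fa)),
                          labelPrefix = "CH")
  expect_equal(haplotypeLabels(h), c("CH1", "CH2"))
  expect_equal(unname(membership(h)), c("CH1", "CH2", "CH1", "CH2"))
  expect_equal(as.vector(popCounts(h)), c(2L, 2L))

  # monomorphic
  fa1 <- writeTestFasta(list(s1 = "ACGT", s2 = "ACGT"))
  h1 <- collapseHaplotypes(recodeMutations(readAlignment(fa1)))
  expect_true(h1@monomorphic)
  expect_equal(length(haplotypeLabels(h1)), 1L)

  # all distinct
  fa3 <- writeTestFasta(list(s1 = "ACGT", s2 = "ACGA", s3 = "ACTT"))
  h3 <- collapseHaplotypes(recodeMutations(readAlignment(fa3)))
  expect_equal(length(haplotypeLabels(h3)), 3L)
})

test_that("collapse round-trips the sample-to-vector mapping", {
  set.seed(31)
  m <- matrix(sample(c("A", "C", "G", "T"), 20 * 30, replace = TRUE,
                     prob = c(0.7, 0.1, 0.1, 0.1)), 20, 30,
              dimnames = list(paste0("s", 1:20), NULL))
  aln <- HapAlignment(m)
  mm <- recodeMutations(aln)
  h <- collapseHaplotypes(mm)
  rebuilt <- h@vectors[membership(h)[rownames(mm@states)], , drop = FALSE]
  expect_equal(unname(rebuilt), unname(mm@states))
})

test_that("recoding is independent of sample order", {
  set.seed(7)
  m <- matrix(sample(c("A", "T"), 12 * 15, replace = TRUE), 12, 15,
              dimnames = list(paste0("s", 1:12), NULL))
  perm <- sample(12)
  h1 <- collapseHaplotypes(recodeMutations(HapAlignment(m)))
  h2 <- collapseHaplotypes(recodeMutations(HapAlignment(m[perm, ])))
  d1 <- pairwiseDifferences(h1)
  d2 <- pairwiseDifferences(h2)
  # same sample -> same distances to every other sample, regardless of labels
  m1 <- membership(h1); m2 <- membership(h2)
  for (a in rownames(m)[1:5]) for (b in rownames(m)[6:10])
    expect_equal(d1[m1[[a]], m1[[b]]], d2[m2[[a]], m2[[b]]])
})

test_that("distances equal Hamming distance for gap-free alignments", {
  set.seed(11)
  m <- matrix(sample(c("A", "C", "G", "T"), 10 * 40, replace = TRUE,
                     prob = c(0.85, 0.05, 0.05, 0.05)), 10, 40,
              dimnames = list(paste0("s", 1:10), NULL))
  h <- collapseHaplotypes(recodeMutations(HapAlignment(m)))
  d <- pairwiseDifferences(h)
  mem <- membership(h)
  for (i in 1:9) for (j in (i + 1):10) {
    direct <- sum(m[i, ] != m[j, ])   # per-site oracle
    expect_equal(unname(d[mem[[i]], mem[[j]]]), direct)
  }
  # distinct haplotypes always differ by >= 1
  expect_true(all(d[upper.tri(d)] >= 1L))
})

test_that("haplotype set and distance matrix write to CSV", {
  fa <- writeTestFasta(list(s1 = "ACGT", s2 = "ACGA", s3 = "ACGT"))
  pt <- popTableFor(c("s1", "s2", "s3"), c("P1", "P1", "P2"))
  h <- collapseHaplotypes(recodeMutations(readAlignment(fa)), pt)
  d <- pairwiseDifferences(h)
  mf <- tempfile(fileext = ".csv"); cf <- tempfile(fileext = ".csv")
  df <- tempfile(fileext = ".csv")
  writeHaplotypeSet(h, mf, cf)
  writeDistanceMatrix(d, df)
  expect_equal(nrow(read.csv(mf)), 3L)
  cnt <- read.csv(cf, check.names = FALSE)
  expect_equal(sum(cnt[, -1L]), 3L)
  expect_equal(unname(as.matrix(read.csv(df)[, -1L])), unname(d))
})
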