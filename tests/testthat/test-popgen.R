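test_that("nucleotide diversity matches the double-loop oracle", {
  expect_equal(nucleotide_diversity(c(a = "AAAAAAAAAA",
                                      b = "AAAAAAAAAT"))$pi, 0.1)
  expect_equal(nucleotide_diversity(c(a = "ACGT", b = "ACGT"))$pi, 0)
  expect_error(nucleotide_diversity(c(a = "ACGT")), "two sequences")

  set.seed(90)
  seqs <- random_seqs(20, 500)
  # inject missing data
  s <- strsplit(seqs[1], "")[[1]]
  s[1:20] <- "N"
  seqs[1] <- paste(s, collapse = "")
  res <- nucleotide_diversity(seqs)
  mats <- do.call(rbind, strsplit(seqs, ""))
  pis <- c()
  diffs <- c()
  for (i in 1:19) {
    for (j in (i + 1):20) {
      ok <- mats[i, ] != "N" & mats[j, ] != "N"
      d <- sum(mats[i, ok] != mats[j, ok])
      pis <- c(pis, d / sum(ok))
      diffs <- c(diffs, d)
    }
  }
  expect_equal(res$pi, mean(pis))
  expect_equal(res$mean_pairwise_diff, mean(diffs))
})

test_that("pi is invariant to collapsing haplotypes with multiplicities", {
  set.seed(91)
  hap <- random_seqs(4, 300, names = paste0("h", 1:4))
  mult <- c(5L, 3L, 2L, 1L)
  expanded <- stats::setNames(
    rep(hap, mult),
    paste0("s", seq_len(sum(mult)))
  )
  direct <- nucleotide_diversity(expanded)$pi
  # weighted oracle from the distinct haplotypes
  n <- sum(mult)
  d <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j) {
    sum(strsplit(hap[i], "")[[1]] != strsplit(hap[j], "")[[1]])
  }))
  num <- 0
  for (i in 1:4) {
    for (j in 1:4) {
      w <- if (i == j) mult[i] * (mult[i] - 1) / 2 else
        if (i < j) mult[i] * mult[j] else 0
      num <- num + w * d[i, j] / 300
    }
  }
  expect_equal(direct, num / choose(n, 2))
})

test_that("haplotype diversity follows the unbiased frequency formula", {
  expect_equal(haplotype_diversity(rep(1L, 4)), 1)
  expect_equal(haplotype_diversity(4L), 0)
  expect_equal(haplotype_diversity(c(2L, 2L)), 2 / 3, tolerance = 1e-4)
  expect_error(haplotype_diversity(1L), "two samples")
})

test_that("haplogroup frequencies and over-representation tests behave", {
  asg <- data.frame(
    sample_id = paste0("s", 1:50),
    population = "Israel",
    haplogroup = c(rep("A", 46), rep("B", 4))
  )
  ft <- haplogroup_frequency_table(asg)
  expect_equal(unname(ft$frequencies["Israel", c("A", "B")]),
               c(0.92, 0.08))
  one <- haplogroup_frequency_table(data.frame(
    sample_id = "s1", population = "P", haplogroup = "A"
  ))
  expect_equal(unname(one$frequencies[1, 1]), 1)
  expect_error(haplogroup_frequency_table(
    data.frame(sample_id = character(0), population = character(0),
               haplogroup = character(0))), "empty")
  asg$haplogroup[1] <- NA
  expect_error(haplogroup_frequency_table(asg), "s1")

  counts <- matrix(c(10L, 0L, 0L, 10L), 2, byrow = TRUE,
                   dimnames = list(c("P1", "P2"), c("A", "B")))
  chi <- overrepresentation_chi2(counts, "A")
  expect_equal(chi$chi2, 20)
  expect_identical(chi$df, 1L)

  eq <- matrix(c(5L, 5L, 5L, 5L), 2, byrow = TRUE,
               dimnames = list(c("P1", "P2"), c("A", "B")))
  chi_eq <- overrepresentation_chi2(eq, "A")
  expect_equal(chi_eq$chi2, 0)
  expect_equal(chi_eq$p, 1)

  # textbook oracle on random tables
  set.seed(93)
  for (i in 1:20) {
    m <- matrix(rpois(6, 8) + 1L, 3, 2,
                dimnames = list(paste0("P", 1:3), c("A", "B")))
    chi <- overrepresentation_chi2(m, "A")
    tab <- cbind(m[, "A"], rowSums(m) - m[, "A"])
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_lt(abs(chi$chi2 - sum((tab - E)^2 / E)), 1e-10)
  }
})

test_that("PhiST spans no-differentiation to fixation and matches AMOVA sums", {
  set.seed(94)
  # permuted fixture: one pool of sequences randomly split in two: ~0
  seqs <- random_seqs(40, 200)
  pops <- sample(rep(c("X", "Y"), each = 20))
  ph <- phist(seqs, pops)
  expect_lt(abs(ph["X", "Y"]), 0.05)

  # fixed 50-difference haplotypes, no within-group variation: 1
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 50), strrep("A", 50))
  seqs2 <- c(rep(a, 5), rep(b, 5))
  names(seqs2) <- paste0("t", 1:10)
  ph2 <- phist(seqs2, rep(c("X", "Y"), each = 5))
  expect_equal(unname(ph2["X", "Y"]), 1)

  # independent sums-of-squares oracle for the two-population components
  seqs3 <- random_seqs(12, 150)
  pops3 <- rep(c("X", "Y"), each = 6)
  d <- as.matrix(ape::dist.dna(mitophylo:::seqs_to_DNAbin(seqs3),
                               model = "N", pairwise.deletion = TRUE))
  comp <- mitophylo:::amova_components(d, pops3)
  n <- 12; per <- 6
  ss_tot <- sum(d[upper.tri(d)]) / n
  ssw <- sum(d[1:6, 1:6][upper.tri(d[1:6, 1:6])]) / per +
    sum(d[7:12, 7:12][upper.tri(d[7:12, 7:12])]) / per
  msd_a <- (ss_tot - ssw) / 1
  msd_w <- ssw / (n - 2)
  s2a <- (msd_a - msd_w) / per
  expect_lt(abs(comp$phist - s2a / (s2a + msd_w)), 1e-10)

  # invariance to population relabeling
  ph3a <- phist(seqs3, pops3)
  ph3b <- phist(seqs3, c(Y = "X", X = "Y")[pops3])
  expect_equal(unname(ph3a["X", "Y"]), unname(ph3b["Y", "X"]))

  expect_warning(phist(seqs3, c(rep("X", 6), rep("Y", 5), "Z")), "n < 2")
})

test_that("great-circle distances hit the closed-form anchors", {
  g <- geographic_distance(c(0, 0), c(0, 1))
  expect_equal(g[1, 2], 111.195, tolerance = 1e-5)
  expect_equal(geographic_distance(c(10, 10), c(20, 20))[1, 2], 0)
  anti <- geographic_distance(c(0, 0), c(0, 180))
  expect_equal(anti[1, 2], 20015.1, tolerance = 1e-5)
  m <- geographic_distance(c(0, NA, 10), c(0, 5, 10))
  expect_identical(attr(m, "missing"), 2L)
  expect_true(all(is.na(m[2, -2])))
  expect_error(geographic_distance(95, 0), "out of range")
})

test_that("Mantel test is seeded, bounded and exact on identical matrices", {
  set.seed(95)
  pts <- cbind(runif(8, 0, 50), runif(8, 0, 50))
  g <- as.matrix(dist(pts))
  res <- mantel_test(g, g, n_perm = 99, seed = 7)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
  res2 <- mantel_test(g, g, n_perm = 99, seed = 7)
  expect_identical(res, res2)
  expect_error(mantel_test(g, g[1:5, 1:5]), "dimensions differ")
  expect_error(mantel_test(g[1:2, 1:2], g[1:2, 1:2]), "at least 3")
})

test_that("diversity-latitude regression detects a gradient and respects n>=3", {
  set.seed(96)
  lat <- seq(35, 55, length.out = 9)
  div <- 0.30 - 0.01 * (lat - 35) / 2 + rnorm(9, 0, 0.003)
  fit <- diversity_latitude_regression(div, lat)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p, 0.05)
  expect_error(diversity_latitude_regression(c(1, 2), c(1, 2)),
               "three populations")
  expect_error(diversity_latitude_regression(c(1, 2, 3), c(5, 5, 5)),
               "latitude variance")

  # null: flat diversity keeps p above 0.05 most of the time
  rej <- 0
  for (r in 1:100) {
    divn <- rnorm(9, 0.2, 0.01)
    rej <- rej + (diversity_latitude_regression(divn, lat)$p < 0.05)
  }
  expect_lte(rej, 10)
})
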