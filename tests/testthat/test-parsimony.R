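test_that("parsimony score matches hand computation and is rooting-invariant", {
  seqs <- c(a = "AA", b = "AT", c = "TA", d = "TT")
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_identical(parsimony_score(tr, seqs), 3L)

  same <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  expect_identical(parsimony_score(ape::read.tree(text = "((a,b),c);"), same),
                   0L)

  # unrooted invariance
  set.seed(2)
  seqs2 <- random_seqs(6, 40)
  tr2 <- ape::unroot(ape::rtree(6, tip.label = names(seqs2)))
  s0 <- parsimony_score(tr2, seqs2)
  for (og in names(seqs2)[1:3]) {
    rooted <- ape::root(tr2, outgroup = og, resolve.root = TRUE)
    expect_identical(parsimony_score(rooted, seqs2), s0)
  }
  expect_error(parsimony_score(tr2, seqs2[-1]), "without sequence")
})

test_that("our Fitch kernel agrees with an independent implementation", {
  set.seed(4)
  for (i in 1:15) {
    n <- sample(5:10, 1)
    seqs <- random_seqs(n, sample(20:60, 1))
    # sprinkle missing data
    if (i %% 3 == 0) {
      s <- strsplit(seqs[1], "")[[1]]
      s[sample(length(s), 4)] <- "N"
      seqs[1] <- paste(s, collapse = "")
    }
    tr <- ape::unroot(ape::rtree(n, tip.label = sample(names(seqs))))
    expect_equal(
      parsimony_score(tr, seqs),
      as.integer(phangorn::parsimony(tr, mitophylo:::seqs_to_phyDat(seqs),
                                     method = "fitch"))
    )
  }
})

test_that("exhaustive search finds the enumerated optimum and counts ties", {
  seqs <- c(a = "AA", b = "AT", c = "TA", d = "TT")
  ex <- exhaustive_mp(seqs)
  expect_identical(ex$score, 3L)
  # independent check over the three 4-taxon topologies
  tops <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  scores <- vapply(tops, function(t) {
    parsimony_score(ape::read.tree(text = t), seqs)
  }, integer(1))
  expect_identical(ex$score, min(scores))
  expect_identical(ex$n_ties, sum(scores == min(scores)))
})

test_that("tree building recovers a perfect phylogeny with clean annotation", {
  fx <- perfect_phylogeny_fixture(k = 3L)
  x <- build_mp_tree(fx$haplotypes, fx$outgroup)
  # generating clades are recovered exactly
  for (cl in fx$clades) {
    expect_true(ape::is.monophyletic(x$tree, cl))
  }
  # every mutation on exactly one branch, no recurrence
  expect_false(any(x$mutations$recurrent))
  expect_identical(nrow(x$mutations), 18L)  # 6 marked branches x 3
  expect_identical(x$parsimony_score, 18L)
  expect_silent(replay_mutations(x))
})

test_that("a lone haplotype joins the outgroup via one annotated branch", {
  root <- strrep("A", 30)
  ht <- paste0(strrep("A", 27), "GGG")
  x <- build_mp_tree(c(h1 = ht), c(og = root))
  ig_edges <- x$mutations[x$mutations$child ==
                            which(x$tree$tip.label == "h1"), ]
  expect_identical(nrow(ig_edges), 3L)
  expect_setequal(ig_edges$position_np, 28:30)
})

test_that("independent parallel mutations are flagged recurrent", {
  # site 9 arises independently in one tip of each strongly marked clade,
  # so no topology can explain it with a single change
  mk <- function(sites) {
    s <- rep("A", 10)
    s[sites] <- "G"
    paste(s, collapse = "")
  }
  seqs <- c(
    t1 = mk(c(1, 2, 3, 9)), t2 = mk(c(1, 2, 3)),
    t3 = mk(c(4, 5, 6, 9)), t4 = mk(c(4, 5, 6))
  )
  og <- c(og = mk(integer(0)))
  x <- build_mp_tree(seqs, og)
  m9 <- x$mutations[x$mutations$position_np == 9L, ]
  expect_identical(nrow(m9), 2L)
  expect_true(all(m9$recurrent))
  expect_false(any(x$mutations$recurrent[x$mutations$position_np == 1L]))
})

test_that("zero-variation alignments annotate to nothing", {
  seqs <- c(a = "ACGT", b = "ACGT")
  tr <- ape::read.tree(text = "(a,b);")
  ann <- annotate_mutations(tr, seqs)
  expect_identical(nrow(ann$mutations), 0L)
  expect_error(build_mp_tree(c(h = "ACGT"), c(og = "ACGT")), "degenerate")
})

test_that("mutation replay reproduces every leaf on random simulated builds", {
  set.seed(8)
  for (i in 1:5) {
    cfg <- small_sim_config(genome_length = 600L, rate = 1e-6)
    ds <- simulate_dataset(cfg, seed = 20 + i)
    samples <- setdiff(names(ds$sequences),
                       c("outgroup1", "outgroup2"))
    hap <- vapply(samples, function(id) ds$sequences[[id]], character(1))
    og <- c(outgroup1 = ds$sequences[["outgroup1"]])
    hap_u <- hap[!duplicated(hap)]
    if (length(hap_u) < 2) next
    x <- build_mp_tree(hap_u, og)
    expect_silent(replay_mutations(x))
    # MP optimality sanity bound: the inferred ingroup topology scores no
    # worse than the true generating topology on the same haplotypes
    inferred_ig <- ape::drop.tip(x$tree, "outgroup1")
    true_ig <- ape::keep.tip(ds$truth$tree, names(hap_u))
    expect_lte(parsimony_score(inferred_ig, hap_u),
               parsimony_score(true_ig, hap_u))
  }
})

test_that("haplogroup nomenclature is deterministic and nested", {
  fx <- perfect_phylogeny_fixture(k = 3L)
  x <- build_mp_tree(fx$haplotypes, fx$outgroup)
  defs <- define_haplogroups(x, min_clade_size = 2L,
                             min_defining_mutations = 1L)
  top <- defs$table[defs$table$parent == "root", ]
  expect_identical(sort(top$label), c("A", "B"))
  expect_identical(unname(vapply(strsplit(top$defining, ";"), length,
                                 integer(1))), c(3L, 3L))

  # a deeper fixture: two nested levels get number then letter suffixes
  root <- strrep("A", 40)
  mk <- function(sites) {
    s <- strsplit(root, "")[[1]]
    s[sites] <- "G"
    paste(s, collapse = "")
  }
  seqs <- c(
    h1 = mk(c(1, 2, 10, 11, 20)), h2 = mk(c(1, 2, 10, 11, 21)),
    h3 = mk(c(1, 2, 12)), h4 = mk(c(5, 6)), h5 = mk(c(5, 7))
  )
  x2 <- build_mp_tree(seqs, c(og = root))
  d2 <- define_haplogroups(x2)
  expect_true(all(c("A", "B") %in% d2$table$label))
  labs <- d2$table$label
  nested <- labs[nchar(labs) > 1]
  expect_true(all(grepl("^[A-Z][0-9]+[a-z]*", nested)))
  # children of A carry the A1 prefix pattern
  expect_true(any(grepl("^A1", labs)) || all(d2$table$parent != "A"))
})

test_that("profiles assign to the haplogroup whose defining path they carry", {
  # B sub-clade defined by two diagnostic transitions at high positions,
  # mirroring a two-transition clade definition
  L <- 14300L
  root <- strrep("A", L)
  mk <- function(sites, to = "G") {
    s <- strsplit(root, "")[[1]]
    s[sites] <- to
    paste(s, collapse = "")
  }
  seqs <- c(
    a1 = mk(c(100, 200, 300)), a2 = mk(c(100, 200, 301)),
    b1 = mk(c(500, 600)), b2 = mk(c(500, 601)),
    bsub1 = mk(c(500, 602, 14235, 14243)),
    bsub2 = mk(c(500, 603, 14235, 14243))
  )
  x <- build_mp_tree(seqs, c(og = root))
  defs <- define_haplogroups(x)
  sch <- region_scheme(1, L)
  # carrier of the B path plus the two diagnostic transitions
  carrier <- diff_to_reference(mk(c(500, 14235, 14243)), root, sch, "q")
  hit <- assign_haplogroup(carrier, defs)
  sub_label <- defs$table$label[vapply(defs$table$defining, function(d) {
    all(c("A14235G", "A14243G") %in% strsplit(d, ";")[[1]])
  }, logical(1))]
  expect_identical(hit$label, sub_label)

  # full defining path of a clade: zero mismatches
  full <- diff_to_reference(seqs[["a1"]], root, sch, "f")
  hf <- assign_haplogroup(full, defs)
  expect_identical(length(hf$mismatched), 0L)

  # empty profile falls back to the root label
  empty <- diff_to_reference(root, root, sch, "e")
  expect_identical(assign_haplogroup(empty, defs)$label, "root")
})

test_that("bootstrap support is reproducible and saturates on clean clades", {
  fx <- perfect_phylogeny_fixture(k = 4L)
  x <- build_mp_tree(fx$haplotypes, fx$outgroup)
  sup <- bootstrap_support(x, n_replicates = 200L, seed = 77L)
  expect_true(all(sup >= 0 & sup <= 100, na.rm = TRUE))
  # the two marked clades must be near-unanimous
  for (cl in fx$clades) {
    nd <- ape::getMRCA(x$tree, cl)
    expect_gte(sup[[as.character(nd)]], 95)
  }
  sup2 <- bootstrap_support(x, n_replicates = 200L, seed = 77L)
  expect_identical(sup, sup2)
})
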