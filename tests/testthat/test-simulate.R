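test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- small_sim_config(genome_length = 500L)
  d1 <- simulate_dataset(cfg, seed = 5)
  d2 <- simulate_dataset(cfg, seed = 5)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$metadata, d2$metadata)
  expect_identical(d1$truth$events, d2$truth$events)
  d3 <- simulate_dataset(cfg, seed = 6)
  expect_false(identical(d1$sequences, d3$sequences))
  expect_error(simulate_dataset(cfg), "seed is mandatory")
})

test_that("one sample per clade reproduces the skeleton topology and ages", {
  cfg <- small_sim_config(
    genome_length = 500L,
    sizes = c(A = 1L, B = 1L, C = 1L, D = 1L)
  )
  gen <- simulate_genealogy(cfg, seed = 9)
  tr <- gen$tree
  expect_identical(sort(tr$tip.label),
                   c("A_001", "B_001", "C_001", "D_001"))
  expect_true(ape::is.monophyletic(tr, c("A_001", "B_001")))
  expect_true(ape::is.monophyletic(tr, c("C_001", "D_001")))
  h <- mitophylo:::node_heights(tr)
  expect_equal(max(h), 27690, tolerance = 1e-8)
  ab <- ape::getMRCA(tr, c("A_001", "B_001"))
  expect_equal(h[ab], 11560, tolerance = 1e-8)
})

test_that("clade crowns are conditioned exactly on the configured ages", {
  cfg <- small_sim_config(genome_length = 500L)
  gen <- simulate_genealogy(cfg, seed = 10)
  h <- mitophylo:::node_heights(gen$tree)
  for (cl in c("A", "B", "C", "D")) {
    tips <- names(gen$tip_clade)[gen$tip_clade == cl]
    crown <- ape::getMRCA(gen$tree, tips)
    expect_equal(h[crown], unname(cfg$clade_ages[cl]), tolerance = 1e-6)
  }
  expect_true(ape::is.ultrametric(gen$tree, tol = 1e-4))
})

test_that("pairwise coalescence time matches the constant-size expectation", {
  set.seed(12)
  ne <- 4000
  tm <- vapply(seq_len(800), function(i) {
    tr <- simulate_coalescent(2, list(ne_present = ne, growth_rate = 0,
                                      growth_start = 1e4))
    max(mitophylo:::node_heights(tr))
  }, numeric(1))
  se <- ne / sqrt(800)   # TMRCA ~ Exp(mean ne)
  expect_lt(abs(mean(tm) - ne), 3 * se)
})

test_that("per-branch mutation counts follow the Poisson clock", {
  # mu * L = 1/2616 per year; branch of 261,600 years -> mean 100 events
  L <- 1000L
  cfg <- sim_config(
    clade_ages = c(A = 261600),
    skeleton_ages = c(root = 261601),
    skeleton_parents = c(A = "root"),
    populations = data.frame(
      population = "P", clade = "A", subspecies = "r", size = 2L,
      latitude = 0, longitude = 0
    ),
    rate = 1 / 2616 / L,
    scheme = region_scheme(1L, L), genome_length = L,
    alpha = 1000,
    outgroup = list(n = 0L, split_time = 3e6, og_split = 1e6),
    ibd = list(mode = "panmictic", mixing = 1)
  )
  tree <- ape::read.tree(text = "(A_1:261600,A_2:261600);")
  set.seed(13)
  counts <- vapply(seq_len(200), function(i) {
    sq <- simulate_sequences(tree, cfg, seed = 1000 + i)
    nrow(sq$events) / 2
  }, numeric(1))
  se <- sqrt(100 / 2) / sqrt(200)
  expect_lt(abs(mean(counts) - 100), 3 * se)

  # zero rate leaves all tips identical to the root
  cfg0 <- cfg
  cfg0$rate <- 1e-30
  sq0 <- simulate_sequences(tree, cfg0, seed = 3)
  expect_identical(unname(sq0$sequences["A_1"]), sq0$reference)
})

test_that("replaying truth events reproduces every emitted sequence", {
  cfg <- small_sim_config(genome_length = 800L)
  ds <- simulate_dataset(cfg, seed = 21)
  tree <- ds$truth$tree
  ev <- ds$truth$events
  post <- stats::reorder(tree, "postorder")
  root <- post$edge[nrow(post$edge), 1L]
  state <- list()
  state[[as.character(root)]] <- strsplit(ds$reference, "")[[1]]
  for (i in rev(seq_len(nrow(post$edge)))) {
    p <- post$edge[i, 1]; ch <- post$edge[i, 2]
    s <- state[[as.character(p)]]
    rows <- ev[ev$parent == p & ev$child == ch, , drop = FALSE]
    if (nrow(rows) > 0) {
      for (r in seq_len(nrow(rows))) s[rows$position_np[r]] <- rows$to[r]
    }
    state[[as.character(ch)]] <- s
    if (ch <= length(post$tip.label)) {
      expect_identical(paste(s, collapse = ""),
                       unname(ds$sequences[post$tip.label[ch]]),
                       label = post$tip.label[ch])
    }
  }
})

test_that("geography assignment is seeded and respects population sizes", {
  cfg <- small_sim_config(genome_length = 500L)
  gen <- simulate_genealogy(cfg, seed = 30)
  md1 <- simulate_geography(cfg, gen, seed = 31)
  md2 <- simulate_geography(cfg, gen, seed = 31)
  expect_identical(md1, md2)
  expect_identical(as.integer(table(md1$population)[c("P1", "P2", "P3", "P4")]),
                   c(10L, 6L, 4L, 6L))
})

test_that("isolation-by-distance mode produces a positive Mantel signal", {
  pops <- data.frame(
    population = paste0("P", 1:8), clade = "A", subspecies = "rustica",
    size = 8L, latitude = seq(36, 57, length.out = 8),
    longitude = seq(3, 24, length.out = 8)
  )
  cfg <- sim_config(
    clade_ages = c(A = 5710), skeleton_ages = c(root = 27690),
    skeleton_parents = c(A = "root"), populations = pops,
    demography = list(ne_present = 2e4, growth_rate = 2e-3,
                      growth_start = 1170),
    rate = 2.45e-7, scheme = region_scheme(1L, 3000L),
    genome_length = 3000L, alpha = 1000,
    outgroup = list(n = 1L, split_time = 9.34e5, og_split = 4.5e5),
    ibd = list(mode = "ibd", mixing = 0.1)
  )
  ds <- simulate_dataset(cfg, seed = 33)
  md <- ds$metadata
  seqs <- vapply(md$sample_id, function(id) ds$sequences[[id]],
                 character(1))
  ph <- phist(seqs, md$population)
  coords <- unique(md[, c("population", "latitude", "longitude")])
  coords <- coords[match(rownames(ph), coords$population), ]
  geo <- geographic_distance(coords$latitude, coords$longitude,
                             labels = rownames(ph))
  mt <- mantel_test(ph, geo, n_perm = 199, seed = 34)
  expect_gt(mt$r, 0)
  expect_lt(mt$p, 0.05)
})
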