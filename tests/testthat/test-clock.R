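# Build a small mp_tree by hand: a star of three tips under the ingroup node
# with known per-branch mutation counts, plus an outgroup.
star_mp_tree <- function(counts = c(1L, 2L, 3L)) {
  tr <- ape::read.tree(text = "(og,(a,b,c));")
  ig <- ape::getMRCA(tr, c("a", "b", "c"))
  kids <- match(c("a", "b", "c"), tr$tip.label)
  muts <- do.call(rbind, lapply(seq_along(kids), function(i) {
    if (counts[i] == 0L) return(NULL)
    data.frame(parent = ig, child = kids[i],
               position_np = seq_len(counts[i]) + 10L * i,
               from = "A", to = "G", recurrent = FALSE)
  }))
  structure(
    list(tree = tr, mutations = muts, ingroup_node = ig,
         root_state = strrep("A", 100), parsimony_score = sum(counts),
         n_ties = NA_integer_, positions = 1:100,
         alignment = c(a = strrep("A", 100), b = strrep("A", 100),
                       c = strrep("A", 100), og = strrep("A", 100)),
         outgroup = "og"),
    class = "mp_tree"
  )
}

test_that("years-per-mutation conversion reproduces the published clock", {
  expect_identical(years_per_mutation(2.45e-8, 15601), 2616)
  expect_identical(years_per_mutation(0.5, 2), 1)
  expect_identical(years_per_mutation(1e-9, 2075), 481928)
  expect_error(years_per_mutation(0, 100), "positive")
  cm <- clock_model()
  expect_equal(cm$years_per_mutation, 1 / (2.45e-8 * 15601))
})

test_that("rho ages scale mean mutation counts by the clock", {
  clock <- clock_model(rate_per_site_per_year = 1 / 2616, region_length = 1)
  x <- star_mp_tree(c(2L, 2L, 2L))
  ra <- rho_age(x, clock = clock)
  expect_equal(ra$rho, 2)
  expect_equal(ra$age_years, 5232)

  x2 <- star_mp_tree(c(1L, 2L, 3L))
  ra2 <- rho_age(x2, clock = clock)
  expect_equal(ra2$rho, 2)
  expect_equal(ra2$age_years, 5232)
  # Saillard-style error on a star: sqrt(sum m_b / n^2)
  expect_equal(ra2$se_years, sqrt(6) / 3 * 2616)
})

test_that("rho is unbiased under a Poisson clock on simulated clades", {
  set.seed(30)
  clock <- clock_model(rate_per_site_per_year = 1 / 2616, region_length = 1)
  lambda <- 8
  n_rep <- 120
  rhos <- vapply(seq_len(n_rep), function(r) {
    counts <- stats::rpois(3L, lambda)
    rho_age(star_mp_tree(counts), clock = clock)$rho
  }, numeric(1))
  se <- sqrt(lambda / 3) / sqrt(n_rep)
  expect_lt(abs(mean(rhos) - lambda), 3 * se)
})

test_that("age monotonicity violations are reported, not clipped", {
  # two-level tree where the child clade has more mutations than the parent
  tr <- ape::read.tree(text = "(og,((a,b)x,c));")
  ig <- ape::getMRCA(tr, c("a", "b", "c"))
  nx <- ape::getMRCA(tr, c("a", "b"))
  muts <- rbind(
    data.frame(parent = ig, child = nx, position_np = 1L,
               from = "A", to = "G", recurrent = FALSE),
    data.frame(parent = nx, child = match("a", tr$tip.label),
               position_np = 2:9, from = "A", to = "G", recurrent = FALSE),
    data.frame(parent = nx, child = match("b", tr$tip.label),
               position_np = 12:19, from = "A", to = "G", recurrent = FALSE)
  )
  x <- structure(
    list(tree = tr, mutations = muts, ingroup_node = ig,
         root_state = strrep("A", 100), parsimony_score = nrow(muts),
         n_ties = NA_integer_, positions = 1:100,
         alignment = c(a = strrep("A", 100), b = strrep("A", 100),
                       c = strrep("A", 100), og = strrep("A", 100)),
         outgroup = "og"),
    class = "mp_tree"
  )
  ages <- rho_ages(x)
  viol <- attr(ages, "violations")
  expect_gt(length(viol), 0)
  # raw table keeps child older than parent
  a_ig <- ages$age_years[ages$node == ig]
  a_nx <- ages$age_years[ages$node == nx]
  expect_gt(a_nx, a_ig)
  # the dated tree for the skyline enforces monotonicity and says so
  dated <- date_tree_rho(x)
  expect_true(ape::is.ultrametric(dated, tol = 1e-6))
  expect_gt(attr(dated, "adjusted"), 0)
})

test_that("rate calibration follows distance / split-time", {
  r <- calibrate_rate(0.228830, 9.34e6)
  expect_equal(signif(r$rate, 3), 2.45e-8)
  r_lo <- calibrate_rate(0.228830, 5.8e6)
  expect_equal(signif(r_lo$rate, 3), 3.95e-8)
  expect_warning(r0 <- calibrate_rate(0, 9.34e6), "zero distance")
  expect_identical(r0$rate, 0)
  # CI comes from the calibration CI only
  expect_equal(r$rate_ci, sort(0.228830 / c(5.8e6, 13.2e6)))
})

test_that("ML clock dating handles degenerate and two-taxon cases", {
  clock <- clock_model(ncat = 4L)
  tr <- ape::read.tree(text = "(a:1,b:1);")
  same <- c(a = strrep("ACGT", 100), b = strrep("ACGT", 100))
  res0 <- ml_clock_ages(tr, same, clock)
  expect_true(all(res0$ages$age_years == 0))

  # two taxa d apart: root age ~ (JC-corrected d / 2) / rate
  set.seed(41)
  L <- 4000L
  a <- random_seqs(1, L)[[1]]
  s <- strsplit(a, "")[[1]]
  flip <- sample(L, 40L)
  s[flip] <- vapply(s[flip], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, character(1))
  seqs <- c(a = a, b = paste(s, collapse = ""))
  res <- ml_clock_ages(tr, seqs, clock)
  p <- 40 / L
  d_jc <- -3 / 4 * log(1 - 4 / 3 * p)
  expect_equal(res$ages$age_years,
               (d_jc / 2) / clock$rate_per_site_per_year,
               tolerance = 0.02)
})

test_that("strict-clock ML recovers node times on a small simulation", {
  cfg <- small_sim_config(genome_length = 2000L,
                          sizes = c(A = 6L, B = 4L, C = 3L, D = 3L))
  ds <- simulate_dataset(cfg, seed = 55)
  samples <- setdiff(names(ds$sequences), c("outgroup1", "outgroup2"))
  hap <- vapply(samples, function(id) ds$sequences[[id]], character(1))
  hap <- hap[!duplicated(hap)]
  og <- c(outgroup1 = ds$sequences[["outgroup1"]])
  x <- build_mp_tree(hap, og)
  clade <- ape::extract.clade(x$tree, x$ingroup_node)
  clock <- clock_model(rate_per_site_per_year = cfg$rate,
                       region_length = 2000L, ncat = 4L)
  res <- ml_clock_ages(clade, x$alignment, clock)
  expect_true(res$converged)
  # ages are monotone along every root-to-leaf path by construction
  # (tolerance of 1 year on a tree ~3e4 years deep)
  expect_true(ape::is.ultrametric(res$tree, tol = 1))
  root_true <- max(mitophylo:::node_heights(ds$truth$tree))
  root_est <- max(res$ages$age_years)
  expect_lt(abs(root_est - root_true) / root_true, 0.5)

  # likelihood at the optimum is no worse than at the true node times
  pd <- mitophylo:::seqs_to_phyDat(x$alignment[clade$tip.label])
  true_clade <- ape::keep.tip(ds$truth$tree, clade$tip.label)
  true_clade$edge.length <- true_clade$edge.length *
    clock$rate_per_site_per_year
  ll_true <- phangorn::pml(ape::multi2di(true_clade, random = FALSE), pd,
                           model = "HKY", k = 4)$logLik
  expect_gte(res$loglik + 1e-6, ll_true)
})
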