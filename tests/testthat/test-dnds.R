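test_that("codon-effect classification is strand- and code-aware", {
  ann <- tiny_annotation()
  ref <- tiny_reference()
  getb <- function(np) substring(ref, np, np)

  # third-position TTT -> TTC is synonymous (Phe/Phe); build the context
  s <- strsplit(ref, "")[[1]]
  s[10:12] <- c("T", "T", "T")
  ctx <- function(np) s[np]
  cls <- classify_mutation(12L, "T", "C", ann, ctx)
  expect_identical(cls$effect, "synonymous")
  expect_identical(cls$gene, "pcgA")
  expect_identical(cls$codon_pos, 3L)

  # ATA -> ATG: both Met under the vertebrate mitochondrial code, though the
  # codons differ in the standard code (Ile vs Met)
  s[10:12] <- c("A", "T", "A")
  cls2 <- classify_mutation(12L, "A", "G", ann, function(np) s[np])
  expect_identical(cls2$effect, "synonymous")
  std <- Biostrings::getGeneticCode("1")
  expect_false(std[["ATA"]] == std[["ATG"]])

  # tRNA position is noncoding
  cls3 <- classify_mutation(140L, getb(140L), "A", ann, getb)
  expect_identical(cls3$effect, "noncoding")

  # minus-strand gene: a mutation whose effect must be computed on the
  # reverse complement; set codon (coding strand) to TTT via the template
  s <- strsplit(ref, "")[[1]]
  s[277:279] <- c("A", "A", "A")  # codingstrand codon 1 of pcgB = TTT
  # np 277 is third codon position on the minus strand (end_np 279 is first)
  cls4 <- classify_mutation(277L, "A", "G", ann, function(np) s[np])
  expect_identical(cls4$gene, "pcgB")
  expect_identical(cls4$codon_pos, 3L)
  # TTT -> TTC (G on template = C on coding strand): synonymous
  expect_identical(cls4$effect, "synonymous")

  # stop-involved change
  s <- strsplit(ref, "")[[1]]
  s[10:12] <- c("T", "A", "T")  # Tyr
  cls5 <- classify_mutation(12L, "T", "A", ann, function(np) s[np])
  expect_identical(cls5$effect, "stop_involved")  # TAT -> TAA (stop)
})

test_that("NG86 site counts match per-codon enumeration", {
  cs <- count_sites("TTT")
  expect_equal(unname(cs["syn_sites"]), 1 / 3)
  expect_equal(sum(cs), 3)

  # four-fold Leu family: third position is one full synonymous site
  cs2 <- count_sites("CTT")
  expect_equal(unname(cs2["syn_sites"]), 1)

  expect_equal(unname(count_sites("")), c(0, 0))
  expect_error(count_sites("TTTA"), "divisible by 3")
  expect_error(count_sites("TTTAGA"), "stop codon at codon index 2")

  # totals always tile the sequence length (stop-targets count as nonsyn)
  set.seed(71)
  for (i in 1:5) {
    cds <- gene_cds(tiny_reference(seed = 100 + i),
                    tiny_annotation()$genes[1, ])
    cs <- count_sites(cds)
    expect_equal(sum(cs), nchar(cds))
  }
})

test_that("site counting agrees with an independent translation oracle", {
  # enumeration over a sample of codons using seqinr's vertebrate-mito
  # translation as the oracle
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  code <- Biostrings::getGeneticCode("2")
  ok <- codons[code[codons] != "*"]
  oracle_syn <- function(codon) {
    aa <- seqinr::translate(strsplit(codon, "")[[1]], numcode = 2)
    syn <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substring(codon, p, p))) {
        alt <- codon
        substring(alt, p, p) <- b
        aa2 <- seqinr::translate(strsplit(alt, "")[[1]], numcode = 2)
        if (aa2 == aa) syn <- syn + 1 / 3
      }
    }
    syn
  }
  for (codon in sample(ok, 12)) {
    expect_equal(unname(count_sites(codon)["syn_sites"]),
                 oracle_syn(codon), info = codon)
  }
})

test_that("tree mutation classification conserves coding mutation counts", {
  ann <- tiny_annotation(400L)
  cfg <- small_sim_config(genome_length = 400L,
                          sizes = c(A = 6L, B = 4L, C = 3L, D = 3L))
  cfg$annotation <- ann
  ds <- simulate_dataset(cfg, seed = 77)
  samples <- setdiff(names(ds$sequences), c("outgroup1", "outgroup2"))
  hap <- vapply(samples, function(id) ds$sequences[[id]], character(1))
  hap <- hap[!duplicated(hap)]
  og <- c(outgroup1 = ds$sequences[["outgroup1"]])
  x <- build_mp_tree(hap, og)
  cls <- classify_tree_mutations(x, ann)
  # no overlapping genes in this annotation: one row per tree mutation
  expect_identical(nrow(cls), nrow(x$mutations))
  in_pcg <- vapply(cls$position_np, function(np) {
    any(ann$genes$category == "protein_coding" &
          ann$genes$start_np <= np & ann$genes$end_np >= np)
  }, logical(1))
  # conservation: coding mutations all classified, the rest noncoding
  expect_true(all(cls$effect[in_pcg] %in%
                    c("synonymous", "nonsynonymous", "stop_involved")))
  expect_true(all(cls$effect[!in_pcg] == "noncoding"))
})

test_that("Fisher exact matches enumeration and the stats oracle", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2,
                                               byrow = TRUE)))

  # independent enumeration oracle built from choose()
  oracle <- function(tab) {
    m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - m2):min(m1, k)
    pr <- choose(m1, support) * choose(m2, k - support) / choose(m1 + m2, k)
    p_obs <- pr[support == tab[1, 1]]
    sum(pr[pr <= p_obs * (1 + 1e-7)])
  }
  set.seed(81)
  for (i in 1:60) {
    tab <- matrix(rpois(4, 6) + (i %% 3 == 0), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)
    expect_lt(abs(p - oracle(tab)), 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
    # symmetry under row and column swaps
    expect_equal(p, fisher_exact_2x2(tab[2:1, ]))
    expect_equal(p, fisher_exact_2x2(tab[, 2:1]))
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("time-partitioned dN/dS reproduces a constructed young/old contrast", {
  # young branches: 20 N / 100 S; old branches: 8 N / 100 S
  mk_rows <- function(n_count, s_count, parent, child) {
    data.frame(
      parent = parent, child = child,
      position_np = seq_len(n_count + s_count),
      from = "A", to = "G", recurrent = FALSE,
      gene = "g", codon_index = 1L, codon_pos = 1L,
      effect = c(rep("nonsynonymous", n_count), rep("synonymous", s_count)),
      overlapping = FALSE
    )
  }
  cls <- rbind(mk_rows(20L, 100L, 10L, 1L), mk_rows(8L, 100L, 11L, 10L))
  ages <- c(`10` = 10000, `11` = 40000, `1` = 0)
  res <- dnds_partitioned(cls, ages, c(nonsyn_sites = 500, syn_sites = 500),
                          cutoff_age_years = 11700)
  expect_identical(unname(res$counts),
                   c(20L, 100L, 8L, 100L))
  # equal site counts cancel in the ratio of ratios
  expect_equal(res$dnds_young / res$dnds_old, 2.5)
  expect_equal(res$fisher_p,
               stats::fisher.test(matrix(c(20, 100, 8, 100), 2,
                                         byrow = TRUE))$p.value,
               tolerance = 1e-9)

  # all-synonymous edge case
  cls2 <- cls[cls$effect == "synonymous", ]
  res2 <- dnds_partitioned(cls2, ages,
                           c(nonsyn_sites = 500, syn_sites = 500))
  expect_equal(res2$dnds_young, 0)
  expect_equal(res2$dnds_old, 0)
  expect_equal(res2$fisher_p, 1)

  # undated branches are an error
  expect_error(
    dnds_partitioned(cls, ages[1], c(nonsyn_sites = 1, syn_sites = 1)),
    "undated"
  )
})
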