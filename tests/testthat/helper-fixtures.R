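# Shared fixture builders: everything is generated in code at test time.

random_seqs <- function(n, L, names = sprintf("s%d", seq_len(n))) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n)
  stats::setNames(apply(m, 1L, paste, collapse = ""), names)
}

# A perfect-phylogeny fixture: a known rooted topology in which every clade is
# marked by `k` private mutations at dedicated sites. Returns the haplotype
# sequences, an outgroup equal to the root state, and the true clades.
perfect_phylogeny_fixture <- function(k = 3L) {
  L <- 12L * k + 40L
  root <- paste(rep("A", L), collapse = "")
  mutate_at <- function(seq, sites, to = "G") {
    s <- strsplit(seq, "")[[1L]]
    s[sites] <- to
    paste(s, collapse = "")
  }
  blocks <- split(seq_len(12L * k), rep(1:12, each = k))
  # topology: ((t1,t2)c12,(t3,t4)c34) with clade marks and tip marks
  anc12 <- mutate_at(root, blocks[[1L]])
  anc34 <- mutate_at(root, blocks[[2L]])
  seqs <- c(
    t1 = mutate_at(anc12, blocks[[3L]]),
    t2 = mutate_at(anc12, blocks[[4L]]),
    t3 = mutate_at(anc34, blocks[[5L]]),
    t4 = mutate_at(anc34, blocks[[6L]])
  )
  list(
    haplotypes = seqs,
    outgroup = c(og = root),
    clades = list(c12 = c("t1", "t2"), c34 = c("t3", "t4")),
    root = root, k = k, L = L
  )
}

# Minimal annotation with one plus-strand and one minus-strand protein gene,
# a tRNA and a control region, on a short reference.
tiny_annotation <- function(len = 400L) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(
    gene = c("pcgA", "tRNA-X", "pcgB", "CR"),
    start_np = c(10L, 130L, 160L, 280L),
    end_np = c(129L, 150L, 279L, 380L),
    strand = c("+", "+", "-", "+"),
    category = c("protein_coding", "tRNA", "protein_coding",
                 "control_region")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_annotation(path, reference_id = "tiny", length = len)
}

# Reference of length `len` whose tiny_annotation() genes are stop-free.
tiny_reference <- function(len = 400L, seed = 42L) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  g <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
              prob = c(.3, .3, .15, .25))
  g <- mitophylo:::sanitize_genome(g, tiny_annotation(len),
                                   c(A = .3, C = .3, G = .15, T = .25))
  paste(g, collapse = "")
}

# Small simulation configuration for pipeline-level tests: the study-like
# conditions scaled down 10x in time with a 10x faster clock (so per-branch
# divergences match the full-size setting) on a short genome.
small_sim_config <- function(genome_length = 1200L, rate = 2.45e-7,
                             sizes = c(A = 10L, B = 6L, C = 4L, D = 6L),
                             ibd = list(mode = "panmictic", mixing = 1)) {
  pops <- data.frame(
    population = c("P1", "P2", "P3", "P4"),
    clade = c("A", "B", "C", "D"),
    subspecies = c("rustica", "transitiva", "gutturalis", "erythrogaster"),
    size = as.integer(sizes),
    latitude = c(50, 32, 26, 41),
    longitude = c(10, 35, 98, -98)
  )
  sim_config(
    clade_ages = c(A = 5710, B = 1890, C = 3110, D = 5110),
    skeleton_ages = c(root = 27690, AB = 11560, CD = 15640),
    populations = pops,
    demography = list(ne_present = 2e4, growth_rate = 2e-3,
                      growth_start = 1170),
    scheme = region_scheme(1L, genome_length, "test_region"),
    genome_length = genome_length,
    rate = rate,
    alpha = 1000,
    outgroup = list(n = 2L, split_time = 9.34e5, og_split = 4.5e5),
    ibd = ibd
  )
}
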