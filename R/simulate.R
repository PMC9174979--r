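# Seeded simulator for every input the pipeline consumes: a dated genealogy
# built from a haplogroup skeleton with within-clade coalescents, Poisson
# mutation accumulation under HKY with gamma site rates, outgroup sequences at
# calibration divergence, sample geography, and per-site read-fraction tables
# -- together with the generating truth for recovery experiments.

#' Default population layout for the study-like configuration
#'
#' Sampling populations with sizes, coordinates and subspecies mirroring the
#' default 411-sample survey design (341 rustica across Europe and Algeria,
#' 50 transitiva from Israel, 5 gutturalis from China, 15 erythrogaster from
#' Nebraska).
#'
#' @return data.frame with `population`, `clade`, `subspecies`, `size`,
#'   `latitude`, `longitude`.
#' @export
default_populations <- function() {
  data.frame(
    population = c("Denmark", "Italy_N", "Italy_S", "Poland", "Spain",
                   "Switzerland", "Ukraine", "Algeria",
                   "Israel", "China", "USA_Nebraska"),
    clade = c(rep("A", 8L), "B", "C", "D"),
    subspecies = c(rep("rustica", 8L), "transitiva", "gutturalis",
                   "erythrogaster"),
    size = c(31L, 86L, 86L, 35L, 31L, 20L, 20L, 32L, 50L, 5L, 15L),
    latitude = c(55.7, 45.5, 40.8, 52.2, 40.4, 46.9, 50.4, 36.8,
                 32.1, 25.9, 41.1),
    longitude = c(12.6, 9.2, 14.3, 21.0, -3.7, 7.4, 30.5, 3.1,
                  34.9, 98.8, -98.0),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults reproduce the study-like conditions: a four-haplogroup skeleton
#' (root 276.9 ky; AB 115.6 ky; CD 156.4 ky; A 57.1 ky; B 18.9 ky; C 31.1 ky;
#' D 51.1 ky), 411 samples split 341/50/5/15 across subspecies, a coding
#' region of 15,601 bp, a clock of 2.45e-8 substitutions/site/year, HKY with
#' kappa 10 and gamma shape 0.3 site rates, and within-clade demography that
#' is constant before 11.7 ky with exponential growth toward the present
#' after it.
#'
#' @param clade_ages Named crown ages (years) for the sampled clades.
#' @param skeleton_ages Named ages for internal skeleton nodes (must include
#'   `root`).
#' @param skeleton_parents Named map child -> parent over clades and internal
#'   skeleton nodes (parents of top nodes = "root").
#' @param populations Population table as in [default_populations()].
#' @param demography List with `ne_present`, `growth_rate` (per year; 0 =
#'   constant), `growth_start` (years before present).
#' @param rate Substitution rate per site per year.
#' @param scheme Region scheme that evolves (default: the coding region).
#' @param genome_length Total emitted sequence length (reference coordinates).
#' @param kappa,alpha HKY transition/transversion ratio and gamma shape.
#' @param base_freqs Equilibrium base frequencies (A, C, G, T).
#' @param outgroup List with `n`, `split_time` (calibration split, years) and
#'   `og_split` (split among the outgroups).
#' @param ibd List with `mode` ("ibd" or "panmictic") and `mixing` (fraction
#'   of within-clade samples reassigned uniformly across populations).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(clade_ages = c(A = 57100, B = 18900,
                                      C = 31100, D = 51100),
                       skeleton_ages = c(root = 276900, AB = 115600,
                                         CD = 156400),
                       skeleton_parents = c(A = "AB", B = "AB", C = "CD",
                                            D = "CD", AB = "root",
                                            CD = "root"),
                       populations = default_populations(),
                       demography = list(ne_present = 2e5,
                                         growth_rate = 2e-4,
                                         growth_start = 11700),
                       rate = 2.45e-8,
                       scheme = coding_region_scheme(),
                       genome_length = 18143L,
                       kappa = 10, alpha = 0.3,
                       base_freqs = c(A = 0.30, C = 0.32, G = 0.14,
                                      T = 0.24),
                       outgroup = list(n = 2L, split_time = 9.34e6,
                                       og_split = 4.5e6),
                       ibd = list(mode = "ibd", mixing = 0.15),
                       annotation = NULL) {
  ages <- c(clade_ages, skeleton_ages)
  for (nd in names(skeleton_parents)) {
    p <- skeleton_parents[[nd]]
    if (!is.na(ages[nd]) && !is.na(ages[p]) && ages[nd] >= ages[p]) {
      stop("child age must be below parent age: ", nd, " vs ", p)
    }
  }
  if (!all(names(clade_ages) %in% populations$clade)) {
    stop("every clade needs at least one population")
  }
  if (rate <= 0) stop("rate must be positive")
  structure(
    list(
      clade_ages = clade_ages, skeleton_ages = skeleton_ages,
      skeleton_parents = skeleton_parents, populations = populations,
      demography = demography, rate = rate, scheme = scheme,
      genome_length = as.integer(genome_length),
      kappa = kappa, alpha = alpha,
      base_freqs = base_freqs / sum(base_freqs),
      outgroup = outgroup, ibd = ibd,
      annotation = annotation
    ),
    class = "sim_config"
  )
}

# Resample stop codons out of the protein-coding genes of a sampled root
# genome (a real mitogenome has no internal stops). Overlapping genes are
# handled by iterating until no gene retains an internal stop.
sanitize_genome <- function(genome, annotation, base_freqs) {
  code <- vertebrate_mito_code()
  stops <- names(code)[code == "*"]
  ok_codons <- setdiff(names(code), stops)
  w <- vapply(ok_codons, function(cd) {
    prod(base_freqs[strsplit(cd, "")[[1L]]])
  }, numeric(1))
  pcg <- annotation$genes[annotation$genes$category == "protein_coding", ,
                          drop = FALSE]
  pcg <- pcg[pcg$end_np <= length(genome), , drop = FALSE]
  for (pass in 1:25) {
    dirty <- FALSE
    for (i in seq_len(nrow(pcg))) {
      g <- pcg[i, ]
      nps <- if (g$strand == "+") g$start_np:g$end_np else g$end_np:g$start_np
      len <- (length(nps) %/% 3L) * 3L
      nps <- nps[seq_len(len)]
      b <- genome[nps]
      if (g$strand == "-") b <- unname(complement_base(b))
      n_codons <- len %/% 3L
      for (ci in seq_len(n_codons)) {
        idx <- (ci - 1L) * 3L + 1:3
        codon <- paste(b[idx], collapse = "")
        # the terminal codon may be a genuine stop
        if (ci == n_codons) next
        if (code[[codon]] == "*") {
          new <- sample(ok_codons, 1L, prob = w)
          nb <- strsplit(new, "")[[1L]]
          if (g$strand == "-") nb <- unname(complement_base(nb))
          genome[nps[idx]] <- nb
          b[idx] <- strsplit(new, "")[[1L]]
          dirty <- TRUE
        }
      }
    }
    if (!dirty) return(genome)
  }
  stop("could not sanitize overlapping reading frames")
}

clade_sizes <- function(config) {
  vapply(names(config$clade_ages), function(cl) {
    sum(config$populations$size[config$populations$clade == cl])
  }, integer(1))
}

# Waiting time to the next coalescence from time t0 with k lineages under the
# piecewise demography (exponential growth toward the present until
# growth_start, constant ancestral size beyond).
sample_coal_time <- function(t0, k, dem) {
  k2 <- k * (k - 1) / 2
  E <- stats::rexp(1)
  g <- dem$growth_rate
  np <- dem$ne_present
  tc <- dem$growth_start
  if (g == 0) return(t0 + E * np / k2)
  n_anc <- np * exp(-g * tc)
  if (t0 >= tc) return(t0 + E * n_anc / k2)
  # N(s) = np * exp(-g s) on [0, tc]
  val <- exp(g * t0) + E * g * np / k2
  t <- log(val) / g
  if (t <= tc) return(t)
  used <- k2 * (exp(g * tc) - exp(g * t0)) / (g * np)
  tc + (E - used) * n_anc / k2
}

#' Simulate a coalescent genealogy within one deme
#'
#' Standard n-coalescent under the configured demography, with time in years
#' (generation time 1). Used on its own for skyline experiments and as the
#' within-clade component of [simulate_genealogy()].
#'
#' @param n Number of tips.
#' @param demography List (`ne_present`, `growth_rate`, `growth_start`).
#' @param labels Tip labels.
#' @param crown_age If not NULL, all event times are rescaled so the TMRCA
#'   equals this age exactly (how clades are conditioned onto the skeleton).
#' @param seed Optional seed.
#' @return `phylo` with branch lengths in years (ultrametric).
#' @export
simulate_coalescent <- function(n, demography = list(ne_present = 1e4,
                                                     growth_rate = 0,
                                                     growth_start = 11700),
                                labels = sprintf("t%d", seq_len(n)),
                                crown_age = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frag <- coalescent_fragment(n, demography, labels, crown_age)
  ape::read.tree(text = paste0(frag$newick, ";"))
}

# Newick fragment (no trailing ";") plus crown height for a simulated
# within-deme coalescent.
coalescent_fragment <- function(n, dem, labels, crown_age = NULL) {
  stopifnot(n >= 1L, length(labels) == n)
  if (n == 1L) return(list(newick = labels, height = 0))
  times <- numeric(n - 1L)
  t <- 0
  k <- n
  for (i in seq_len(n - 1L)) {
    t <- sample_coal_time(t, k, dem)
    times[i] <- t
    k <- k - 1L
  }
  if (!is.null(crown_age)) times <- times * crown_age / times[n - 1L]
  frags <- as.list(labels)
  heights <- rep(0, n)
  for (i in seq_len(n - 1L)) {
    idx <- sample.int(length(frags), 2L)
    a <- idx[1L]
    b <- idx[2L]
    nf <- sprintf("(%s:%.8f,%s:%.8f)",
                  frags[[a]], times[i] - heights[a],
                  frags[[b]], times[i] - heights[b])
    keep <- setdiff(seq_along(frags), c(a, b))
    frags <- c(frags[keep], nf)
    heights <- c(heights[keep], times[i])
  }
  list(newick = frags[[1L]], height = times[length(times)])
}

#' Simulate the full dated genealogy on the haplogroup skeleton
#'
#' Within each clade a coalescent under the configured demography is
#' conditioned (by global rescaling of its event times) to have its crown at
#' the clade's skeleton age, then grafted onto the skeleton. Tips are
#' contemporaneous (time 0); the tree is ultrametric with branch lengths in
#' years.
#'
#' @param config A [sim_config()].
#' @param seed Seed (mandatory for reproducibility).
#' @return List with `tree` (`phylo`), `tip_clade` (named map sample ->
#'   clade), `ages` (named node ages of the skeleton nodes and clade crowns).
#' @export
simulate_genealogy <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  sizes <- clade_sizes(config)
  tips <- list()
  frag <- list()
  for (cl in names(config$clade_ages)) {
    n <- sizes[[cl]]
    labels <- sprintf("%s_%03d", cl, seq_len(n))
    tips[[cl]] <- labels
    frag[[cl]] <- coalescent_fragment(
      n, config$demography, labels,
      crown_age = if (n >= 2L) config$clade_ages[[cl]] else NULL
    )
  }
  ages <- c(config$clade_ages, config$skeleton_ages)
  children_of <- split(names(config$skeleton_parents),
                       unname(config$skeleton_parents))
  build <- function(node) {
    if (node %in% names(config$clade_ages)) {
      list(newick = frag[[node]]$newick, height = frag[[node]]$height)
    } else {
      kids <- children_of[[node]]
      parts <- vapply(kids, function(k) {
        sub <- build(k)
        sprintf("%s:%.8f", sub$newick, ages[[node]] - sub$height)
      }, character(1))
      list(newick = sprintf("(%s)%s", paste(parts, collapse = ","), node),
           height = ages[[node]])
    }
  }
  top <- build("root")
  tree <- ape::read.tree(text = paste0(top$newick, ";"))
  tip_clade <- stats::setNames(
    rep(names(tips), vapply(tips, length, integer(1))),
    unlist(tips, use.names = FALSE)
  )
  list(tree = tree, tip_clade = tip_clade, ages = ages)
}

# HKY single-substitution sampler: given a current base index, pick the
# replacement with probability proportional to pi_j * (kappa for transitions).
hky_weights <- function(freqs, kappa) {
  bases <- c("A", "C", "G", "T")
  w <- matrix(0, 4L, 4L, dimnames = list(bases, bases))
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      ts <- (bases[i] %in% c("A", "G")) == (bases[j] %in% c("A", "G"))
      w[i, j] <- freqs[j] * if (ts) kappa else 1
    }
  }
  w
}

#' Simulate sequences along a dated genealogy
#'
#' Poisson mutation accumulation: on a branch of length dt the number of
#' events is Poisson(rate x dt x sum of site rates over the evolving region),
#' events land on sites with probability proportional to their gamma rate
#' multiplier and substitute bases with HKY bias. Only positions inside the
#' region scheme evolve; the rest of the emitted genome is held fixed (the
#' analysis never uses it). Outgroup sequences are evolved from a calibration
#' ancestor at the configured split time, so that the configured rate is
#' recoverable from the emitted divergence.
#'
#' @param genealogy Output of [simulate_genealogy()] (or any `phylo` with
#'   branch lengths in years whose tips are the samples).
#' @param config A [sim_config()].
#' @param seed Seed.
#' @return List with `sequences` (named, full genome length; outgroups named
#'   `outgroup1`, ...), `reference` (the ingroup-root sequence), `events`
#'   (data.frame parent, child, position_np, from, to for ingroup branches),
#'   `site_rates`, `truth` passthrough of the genealogy.
#' @export
simulate_sequences <- function(genealogy, config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  tree <- if (inherits(genealogy, "phylo")) genealogy else genealogy$tree
  positions <- region_positions(config$scheme)
  L <- length(positions)
  bases <- c("A", "C", "G", "T")
  freqs <- config$base_freqs
  genome <- sample(bases, config$genome_length, replace = TRUE, prob = freqs)
  ann <- config$annotation
  if (is.null(ann) && config$genome_length >= 18143L) {
    ann <- swallow_annotation()
  }
  if (!is.null(ann)) genome <- sanitize_genome(genome, ann, freqs)
  site_rates <- stats::rgamma(L, shape = config$alpha, rate = config$alpha)
  sum_rates <- sum(site_rates)
  W <- hky_weights(freqs, config$kappa)
  mu <- config$rate
  evolve <- function(seq_region, dt, record = FALSE) {
    n_mut <- stats::rpois(1L, mu * dt * sum_rates)
    ev <- NULL
    if (n_mut > 0L) {
      cols <- sample.int(L, n_mut, replace = TRUE, prob = site_rates)
      from <- character(n_mut)
      to <- character(n_mut)
      for (j in seq_len(n_mut)) {
        b <- seq_region[cols[j]]
        nb <- sample(bases, 1L, prob = W[b, ])
        from[j] <- b
        to[j] <- nb
        seq_region[cols[j]] <- nb
      }
      if (record) {
        ev <- data.frame(position_np = positions[cols], from = from, to = to,
                         stringsAsFactors = FALSE)
      }
    }
    list(seq = seq_region, events = ev)
  }
  # Calibration ancestor -> ingroup root and outgroups.
  anc_region <- genome[positions]
  root_height <- max(node_heights(tree))
  og <- config$outgroup
  stem <- og$split_time - root_height
  if (stem < 0) stop("outgroup split older than the ingroup root is required")
  root_region <- evolve(anc_region, stem)$seq
  if (!is.null(ann)) {
    # keep the ingroup-root reading frames stop-free after stem evolution
    g <- genome
    g[positions] <- root_region
    g <- sanitize_genome(g, ann, freqs)
    root_region <- g[positions]
  }
  og_seqs <- list()
  if (og$n >= 1L) {
    og_anc <- evolve(anc_region, og$split_time - og$og_split)$seq
    for (i in seq_len(og$n)) {
      og_seqs[[sprintf("outgroup%d", i)]] <- evolve(og_anc, og$og_split)$seq
    }
  }
  # Preorder traversal of the ingroup genealogy.
  post <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  heights <- node_heights(post)
  root <- post$edge[nrow(post$edge), 1L]
  node_region <- vector("list", ntip + tree$Nnode)
  node_region[[root]] <- root_region
  events <- vector("list", nrow(post$edge))
  for (i in rev(seq_len(nrow(post$edge)))) {
    p <- post$edge[i, 1L]
    ch <- post$edge[i, 2L]
    res <- evolve(node_region[[p]], post$edge.length[i], record = TRUE)
    node_region[[ch]] <- res$seq
    if (!is.null(res$events)) {
      res$events$parent <- p
      res$events$child <- ch
      events[[i]] <- res$events
    }
  }
  events <- do.call(rbind, events[!vapply(events, is.null, logical(1))])
  if (is.null(events)) {
    events <- data.frame(position_np = integer(0), from = character(0),
                         to = character(0), parent = integer(0),
                         child = integer(0))
  }
  to_genome <- function(region) {
    g <- genome
    g[positions] <- region
    paste(g, collapse = "")
  }
  seqs <- vapply(seq_len(ntip), function(i) to_genome(node_region[[i]]),
                 character(1))
  names(seqs) <- post$tip.label
  for (nm in names(og_seqs)) seqs[[nm]] <- to_genome(og_seqs[[nm]])
  list(
    sequences = seqs,
    reference = to_genome(root_region),
    events = events,
    site_rates = site_rates,
    tree = tree
  )
}

#' Simulate sample geography (metadata table)
#'
#' Assigns each sample to a population of its clade. In `ibd` mode samples
#' are laid out over populations ordered by latitude following the clade
#' genealogy's tip traversal order (genetic neighbours land in geographic
#' neighbours), then a fraction `mixing` is reassigned uniformly; in
#' `panmictic` mode assignment is uniform.
#'
#' @param config A [sim_config()].
#' @param genealogy Output of [simulate_genealogy()].
#' @param seed Seed.
#' @return Metadata data.frame (sample_id, subspecies, population, latitude,
#'   longitude, macro_group).
#' @export
simulate_geography <- function(config, genealogy, seed) {
  set.seed(seed)
  pops <- config$populations
  tree <- genealogy$tree
  rows <- list()
  for (cl in names(config$clade_ages)) {
    tips <- names(genealogy$tip_clade)[genealogy$tip_clade == cl]
    ppop <- pops[pops$clade == cl, , drop = FALSE]
    ppop <- ppop[order(ppop$latitude), , drop = FALSE]
    slots <- rep(ppop$population, ppop$size)
    if (length(slots) != length(tips)) {
      stop("population sizes do not sum to clade size for clade ", cl)
    }
    if (identical(config$ibd$mode, "ibd") && nrow(ppop) > 1L) {
      ord <- tree_traversal_order(tree, tips)
      assign <- stats::setNames(slots, ord)
      nmix <- round(config$ibd$mixing * length(tips))
      if (nmix > 0L) {
        who <- sample(ord, nmix)
        assign[who] <- sample(rep(ppop$population,
                                  length.out = length(who)))
      }
    } else {
      assign <- stats::setNames(sample(slots), tips)
    }
    idx <- match(assign, ppop$population)
    rows[[cl]] <- data.frame(
      sample_id = names(assign),
      subspecies = ppop$subspecies[idx],
      population = ppop$population[idx],
      latitude = ppop$latitude[idx],
      longitude = ppop$longitude[idx],
      stringsAsFactors = FALSE
    )
  }
  md <- do.call(rbind, rows)
  rownames(md) <- NULL
  validate_metadata(md)
}

# Tips of `subset` in the order they appear in the tree's tip sequence
# (genealogically adjacent tips are adjacent in the order).
tree_traversal_order <- function(tree, subset) {
  ord <- tree$tip.label[tree$tip.label %in% subset]
  ord
}

#' Simulate a per-site read-fraction table for one sample
#'
#' True substitutions get alt fractions near 1 (Beta(99, 1), floored at 0.75),
#' designated heteroplasmic sites get fractions uniform in [0.30, 0.70], and
#' Poisson-many noise sites get fractions below 0.30, so that
#' [call_variants()] recovers the profile exactly in the absence of
#' heteroplasmy.
#'
#' @param profile A `haplotype_profile`.
#' @param reference Reference sequence (for noise-site ref alleles).
#' @param het_sites Optional data.frame (position_np, ref, alt) of
#'   heteroplasmic sites to inject.
#' @param noise_rate Expected number of sub-threshold noise sites.
#' @param seed Seed.
#' @return data.frame (position_np, ref, alt, alt_fraction).
#' @export
simulate_read_fractions <- function(profile, reference, het_sites = NULL,
                                    noise_rate = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  subs <- profile$substitutions
  out <- list()
  if (nrow(subs) > 0L) {
    out[[1L]] <- data.frame(
      position_np = subs$position_np, ref = subs$ref, alt = subs$alt,
      alt_fraction = pmax(0.75, stats::rbeta(nrow(subs), 99, 1))
    )
  }
  if (!is.null(het_sites) && nrow(het_sites) > 0L) {
    out[[length(out) + 1L]] <- data.frame(
      position_np = het_sites$position_np, ref = het_sites$ref,
      alt = het_sites$alt,
      alt_fraction = stats::runif(nrow(het_sites), 0.30, 0.70)
    )
  }
  n_noise <- stats::rpois(1L, noise_rate)
  if (n_noise > 0L) {
    used <- unlist(lapply(out, `[[`, "position_np"))
    cand <- setdiff(sample.int(nchar(reference), n_noise + 10L), used)
    cand <- utils::head(cand, n_noise)
    if (length(cand) > 0L) {
      refb <- substring(reference, cand, cand)
      altb <- vapply(refb, function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
      out[[length(out) + 1L]] <- data.frame(
        position_np = cand, ref = unname(refb), alt = unname(altb),
        alt_fraction = stats::runif(length(cand), 0.01, 0.25)
      )
    }
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else {
    data.frame(position_np = integer(0), ref = character(0),
               alt = character(0), alt_fraction = numeric(0))
  }
  res <- res[order(res$position_np), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Simulate a complete synthetic dataset
#'
#' Runs [simulate_genealogy()], [simulate_sequences()] and
#' [simulate_geography()] under one seed and bundles the generating truth.
#'
#' @param config A [sim_config()].
#' @param seed Seed (mandatory).
#' @return List with `sequences` (ingroup + outgroups), `reference`,
#'   `metadata`, `truth` (list: tree, tip_clade, ages, events, site_rates,
#'   config, seed).
#' @export
simulate_dataset <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("seed is mandatory")
  gen <- simulate_genealogy(config, seed)
  sq <- simulate_sequences(gen, config, seed + 1L)
  md <- simulate_geography(config, gen, seed + 2L)
  list(
    sequences = sq$sequences,
    reference = sq$reference,
    metadata = md,
    truth = list(
      tree = gen$tree, tip_clade = gen$tip_clade, ages = gen$ages,
      events = sq$events, site_rates = sq$site_rates,
      config = config, seed = seed
    )
  )
}

#' Write a simulated dataset to disk
#'
#' FASTA (samples + outgroups + reference), metadata TSV, truth newick and a
#' JSON file of generating parameters and clade ages.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory.
#' @return Invisible character vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    fasta = file.path(dir, "sequences.fasta"),
    reference = file.path(dir, "reference.fasta"),
    metadata = file.path(dir, "metadata.tsv"),
    tree = file.path(dir, "truth_tree.nwk"),
    truth = file.path(dir, "truth.json")
  )
  write_fasta(dataset$sequences, files[["fasta"]])
  write_fasta(c(reference = dataset$reference), files[["reference"]])
  utils::write.table(dataset$metadata, files[["metadata"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(dataset$truth$tree, file = files[["tree"]])
  jsonlite::write_json(
    list(
      ages = as.list(dataset$truth$ages),
      tip_clade = as.list(dataset$truth$tip_clade),
      seed = dataset$truth$seed,
      rate = dataset$truth$config$rate
    ),
    files[["truth"]], auto_unbox = TRUE, digits = NA
  )
  invisible(files)
}
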