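# Molecular-clock machinery: calibration-derived substitution rates, rho-type
# node ages with genealogy-aware standard errors, and strict-clock ML node
# heights on a fixed topology under HKY+gamma.

#' Molecular clock model
#'
#' Bundles the per-site substitution rate, the analysed region length, the
#' derived years-per-mutation conversion, the calibration point and the
#' substitution-model settings used for likelihood dating.
#'
#' @param rate_per_site_per_year Substitution rate (default 2.45e-8 per site
#'   per year, the whole-mitogenome coding-region rate calibrated on the
#'   Progne-Hirundo split).
#' @param region_length Analysed region length in bp (default 15,601).
#' @param kappa HKY transition/transversion rate ratio.
#' @param alpha Gamma shape for among-site rate variation.
#' @param ncat Number of discrete gamma categories (default 32; use 4 for
#'   speed in exploratory fits).
#' @param prop_invariant Proportion of invariant sites.
#' @param calibration List with `split_time_years` (default 9.34e6) and
#'   `ci_years` (default c(5.8e6, 13.2e6)).
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(rate_per_site_per_year = 2.45e-8,
                        region_length = 15601L,
                        kappa = 10, alpha = 0.3, ncat = 32L,
                        prop_invariant = 0,
                        calibration = list(
                          split_time_years = 9.34e6,
                          ci_years = c(5.8e6, 13.2e6)
                        )) {
  stopifnot(rate_per_site_per_year > 0, region_length > 0)
  structure(
    list(
      rate_per_site_per_year = rate_per_site_per_year,
      region_length = as.integer(region_length),
      years_per_mutation = 1 / (rate_per_site_per_year * region_length),
      kappa = kappa, alpha = alpha, ncat = as.integer(ncat),
      prop_invariant = prop_invariant,
      calibration = calibration
    ),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "Clock model: %.3g subs/site/year on %d bp (one mutation every %d years)\n",
    x$rate_per_site_per_year, x$region_length,
    round(x$years_per_mutation)
  ))
  invisible(x)
}

#' Years per mutation implied by a rate and region length
#'
#' `1 / (rate x region_length)`; the default clock and coding region give one
#' mutation every 2,616 years.
#'
#' @param rate Substitution rate per site per year.
#' @param region_length Region length in bp.
#' @param rounded Round to the nearest integer year for reporting (default
#'   TRUE); the unrounded value is used internally everywhere.
#' @return Years per mutation.
#' @export
years_per_mutation <- function(rate, region_length, rounded = TRUE) {
  if (rate <= 0 || region_length <= 0) {
    stop("rate and region_length must be positive")
  }
  ypm <- 1 / (rate * region_length)
  if (rounded) round(ypm) else ypm
}

#' Calibrate a substitution rate from an outgroup split
#'
#' `rate = distance / split_time`, the standard point calibration that does not
#' fold the calibration uncertainty into the rate estimate; the rate interval
#' implied by the calibration CI is reported separately.
#'
#' @param distance Mean tip-to-split ML distance in substitutions per site.
#' @param split_time_years Calibration split time (default 9.34 My).
#' @param ci_years Calibration 95% CI (default 5.8-13.2 My).
#' @return List with `rate`, `rate_ci` (from the calibration CI only).
#' @export
calibrate_rate <- function(distance, split_time_years = 9.34e6,
                           ci_years = c(5.8e6, 13.2e6)) {
  stopifnot(distance >= 0, split_time_years > 0)
  if (distance == 0) {
    warning("zero distance: calibrated rate is 0")
    return(list(rate = 0, rate_ci = c(0, 0)))
  }
  list(
    rate = distance / split_time_years,
    rate_ci = sort(distance / ci_years)
  )
}

# Mutation count on each edge of an mp_tree (edge order of x$tree$edge).
edge_mutation_counts <- function(x) {
  counts <- integer(nrow(x$tree$edge))
  if (nrow(x$mutations) > 0L) {
    key <- paste(x$tree$edge[, 1L], x$tree$edge[, 2L])
    tab <- table(paste(x$mutations$parent, x$mutations$child))
    counts <- as.integer(tab[key])
    counts[is.na(counts)] <- 0L
  }
  counts
}

#' Rho age of a node on a mutation-annotated tree
#'
#' rho is the mean number of mutations from the node to each of its descendant
#' leaves; the age is `rho x years_per_mutation`. The standard error follows
#' the genealogy-aware propagation over the tree: treating each branch's
#' mutation count as Poisson, `var(rho) = sum_b (n_b / n)^2 m_b`, where `n_b`
#' is the number of descendant leaves below branch `b` and `m_b` its mutation
#' count.
#'
#' @param x An `mp_tree`.
#' @param node Node id (default: the ingroup ancestor).
#' @param clock A [clock_model()].
#' @return List with `node`, `rho`, `age_years`, `se_years`, `n_tips`,
#'   `method = "rho"`.
#' @export
rho_age <- function(x, node = x$ingroup_node, clock = clock_model()) {
  stopifnot(inherits(x, "mp_tree"), inherits(clock, "clock_model"))
  tree <- x$tree
  ntip <- length(tree$tip.label)
  og_tips <- which(tree$tip.label %in% x$outgroup)
  counts <- edge_mutation_counts(x)
  below <- c(node, descendant_nodes(tree, node))
  tips_below <- setdiff(intersect(below, seq_len(ntip)), og_tips)
  if (length(tips_below) == 0L) stop("node has no ingroup descendant leaves")
  edge_in <- tree$edge[, 1L] %in% below & tree$edge[, 2L] %in% below
  n <- length(tips_below)
  # Leaves below each edge's child.
  n_b <- vapply(which(edge_in), function(i) {
    ch <- tree$edge[i, 2L]
    if (ch <= ntip) {
      as.integer(ch %in% tips_below)
    } else {
      length(intersect(
        intersect(descendant_nodes(tree, ch), seq_len(ntip)),
        tips_below
      ))
    }
  }, integer(1))
  m_b <- counts[edge_in]
  rho <- sum(n_b * m_b) / n
  var_rho <- sum((n_b / n)^2 * m_b)
  ypm <- years_per_mutation(clock$rate_per_site_per_year,
                            clock$region_length, rounded = FALSE)
  list(
    node = node, rho = rho,
    age_years = rho * ypm,
    se_years = sqrt(var_rho) * ypm,
    n_tips = n, method = "rho"
  )
}

#' Rho ages of all internal nodes below the ingroup ancestor
#'
#' Parent-younger-than-child violations (possible for rho since each node is
#' estimated independently) are reported in the `violations` attribute, never
#' silently clipped.
#'
#' @param x An `mp_tree`.
#' @param clock A [clock_model()].
#' @return data.frame (node, rho, age_years, se_years, n_tips) with attribute
#'   `violations` (edge indices where child age exceeds parent age).
#' @export
rho_ages <- function(x, clock = clock_model()) {
  tree <- x$tree
  ntip <- length(tree$tip.label)
  nodes <- c(x$ingroup_node,
             setdiff(descendant_nodes(tree, x$ingroup_node),
                     seq_len(ntip)))
  rows <- lapply(nodes, function(nd) {
    as.data.frame(rho_age(x, nd, clock)[
      c("node", "rho", "age_years", "se_years", "n_tips")
    ])
  })
  out <- do.call(rbind, rows)
  age_of <- stats::setNames(out$age_years, out$node)
  viol <- integer(0)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    ch <- tree$edge[i, 2L]
    if (!is.na(age_of[as.character(p)]) && !is.na(age_of[as.character(ch)]) &&
        age_of[as.character(ch)] > age_of[as.character(p)] + 1e-9) {
      viol <- c(viol, i)
    }
  }
  attr(out, "violations") <- viol
  out
}

#' Date the ingroup genealogy with rho ages
#'
#' Builds an ultrametric tree of the ingroup haplotypes with node heights equal
#' to the rho ages in years (tips at 0). Monotonicity is enforced for the tree
#' construction by lifting any parent below its tallest child; the number of
#' lifted nodes is recorded in the `adjusted` attribute (the unadjusted ages
#' are available from [rho_ages()]).
#'
#' @param x An `mp_tree`.
#' @param clock A [clock_model()].
#' @return An ultrametric `phylo` with edge lengths in years; attribute
#'   `ages` holds the node ages used, `adjusted` the number of lifted nodes.
#' @export
date_tree_rho <- function(x, clock = clock_model()) {
  tree <- x$tree
  ntip <- length(tree$tip.label)
  ig_tips <- setdiff(seq_len(ntip), which(tree$tip.label %in% x$outgroup))
  if (length(ig_tips) < 2L) stop("need at least two ingroup haplotypes")
  ages_tab <- rho_ages(x, clock)
  age_of <- stats::setNames(ages_tab$age_years, ages_tab$node)
  clade <- ape::extract.clade(tree, x$ingroup_node)
  # extract.clade renumbers nodes; recompute ages by matching descendant sets
  map <- match_clade_nodes(tree, x$ingroup_node, clade)
  nn <- length(clade$tip.label) + clade$Nnode
  ages <- numeric(nn)
  for (nd in (length(clade$tip.label) + 1L):nn) {
    ages[nd] <- age_of[as.character(map[nd])]
  }
  adjusted <- 0L
  post <- stats::reorder(clade, "postorder")
  for (i in seq_len(nrow(post$edge))) {
    p <- post$edge[i, 1L]
    ch <- post$edge[i, 2L]
    if (ages[p] < ages[ch]) {
      ages[p] <- ages[ch]
      adjusted <- adjusted + 1L
    }
  }
  clade$edge.length <- ages[clade$edge[, 1L]] - ages[clade$edge[, 2L]]
  attr(clade, "ages") <- ages
  attr(clade, "adjusted") <- adjusted
  clade
}

# Map node ids of an extracted clade back to node ids of the full tree,
# matching by descendant tip-label sets.
match_clade_nodes <- function(tree, node, clade) {
  ntip_full <- length(tree$tip.label)
  full_nodes <- c(node, descendant_nodes(tree, node))
  full_sets <- lapply(full_nodes, function(nd) {
    if (nd <= ntip_full) {
      tree$tip.label[nd]
    } else {
      tips <- intersect(descendant_nodes(tree, nd), seq_len(ntip_full))
      sort(tree$tip.label[tips])
    }
  })
  keys_full <- vapply(full_sets, paste, character(1), collapse = "|")
  ntip_cl <- length(clade$tip.label)
  nn <- ntip_cl + clade$Nnode
  map <- integer(nn)
  for (nd in seq_len(nn)) {
    key <- if (nd <= ntip_cl) {
      clade$tip.label[nd]
    } else {
      tips <- intersect(descendant_nodes(clade, nd), seq_len(ntip_cl))
      paste(sort(clade$tip.label[tips]), collapse = "|")
    }
    map[nd] <- full_nodes[match(key, keys_full)]
  }
  map
}

#' Strict-clock ML node ages on a fixed rooted topology
#'
#' Maximises the HKY+gamma(+invariant) likelihood over ultrametric branch
#' lengths (all tips contemporaneous) on the given topology and converts node
#' heights from substitutions per site to years with the clock rate. The
#' topology is taken as given (e.g. from the parsimony step); multifurcations
#' are resolved deterministically into zero-height bifurcations first.
#'
#' @param tree Rooted `phylo` of the ingroup haplotypes.
#' @param seqs Named character vector of aligned sequences for the tips.
#' @param clock A [clock_model()]; `ncat` controls the gamma discretisation.
#' @param optimize_model Also optimise kappa, base frequencies and gamma shape
#'   (default TRUE).
#' @return List with `ages` (data.frame node, age_years, height_subs_per_site),
#'   `tree` (the fitted ultrametric tree, branch lengths in years),
#'   `loglik`, `converged`, `method = "ml"`.
#' @export
ml_clock_ages <- function(tree, seqs, clock = clock_model(),
                          optimize_model = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  rate <- clock$rate_per_site_per_year
  ntip <- length(tree$tip.label)
  enc <- encode_states(seqs[tree$tip.label])
  if (length(variable_columns(enc)) == 0L) {
    nn <- ntip + tree$Nnode
    ages <- data.frame(
      node = (ntip + 1L):nn,
      age_years = 0, height_subs_per_site = 0
    )
    tree$edge.length <- rep(0, nrow(tree$edge))
    return(list(ages = ages, tree = tree, loglik = NA_real_,
                converged = TRUE, method = "ml"))
  }
  if (ntip == 2L) {
    # Closed-form two-taxon case: the root height is half the ML distance.
    pd <- seqs_to_phyDat(seqs[tree$tip.label])
    d <- as.matrix(phangorn::dist.ml(pd))[1L, 2L]
    h <- d / 2
    tree$edge.length <- rep(h / rate, 2L)
    ages <- data.frame(node = 3L, age_years = h / rate,
                       height_subs_per_site = h)
    return(list(ages = ages, tree = tree, loglik = NA_real_,
                converged = TRUE, method = "ml"))
  }
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  pd <- seqs_to_phyDat(seqs[tree$tip.label])
  dm <- phangorn::dist.ml(pd)
  start <- tryCatch(
    phangorn::nnls.tree(dm, tree, method = "ultrametric"),
    error = function(e) NULL
  )
  if (is.null(start)) {
    start <- tree
    start$edge.length <- rep(mean(dm) / 2, nrow(tree$edge))
  }
  start$edge.length[start$edge.length < 1e-8] <- 1e-8
  converged <- TRUE
  fit <- tryCatch({
    f0 <- phangorn::pml(start, pd, model = "HKY", k = clock$ncat,
                        shape = clock$alpha, inv = clock$prop_invariant)
    phangorn::optim.pml(
      f0, model = "HKY",
      optEdge = TRUE, optRooted = TRUE,
      optGamma = optimize_model, optBf = optimize_model,
      optQ = optimize_model,
      optInv = optimize_model && clock$prop_invariant > 0,
      rearrangement = "none",
      control = phangorn::pml.control(trace = 0)
    )
  }, error = function(e) {
    converged <<- FALSE
    NULL
  })
  if (is.null(fit)) {
    ft <- start
    ll <- NA_real_
  } else {
    ft <- fit$tree
    ll <- fit$logLik
  }
  heights <- node_heights(ft)
  nn <- length(ft$tip.label) + ft$Nnode
  internal <- (length(ft$tip.label) + 1L):nn
  ages <- data.frame(
    node = internal,
    age_years = heights[internal] / rate,
    height_subs_per_site = heights[internal]
  )
  ft_years <- ft
  ft_years$edge.length <- ft$edge.length / rate
  list(ages = ages, tree = ft_years, loglik = ll, converged = converged,
       method = "ml")
}

# Height (distance to its tallest descendant tip) of every node.
node_heights <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  nn <- length(tree$tip.label) + tree$Nnode
  h <- numeric(nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    ch <- tree$edge[i, 2L]
    h[p] <- max(h[p], h[ch] + tree$edge.length[i])
  }
  h
}
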