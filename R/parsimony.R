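# Maximum-parsimony trees of mitogenome haplotypes with per-branch mutation
# annotation, in the style of mtDNA haplogroup trees: rooted through outgroups,
# zero-mutation internal branches collapsed to multifurcations, every branch
# carrying its reconstructed substitutions.

BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)
BIT_BASE <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T")
MISSING_BITS <- 15L

# Encode aligned sequences as a taxa x sites bitmask matrix
# (A=1, C=2, G=4, T=8; N/-/anything else = 15, the standard missing-data
# convention: an unconstrained state set).
encode_states <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  m <- matrix(
    unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE
  )
  enc <- matrix(MISSING_BITS, nrow = nrow(m), ncol = ncol(m))
  for (b in names(BASE_BITS)) enc[m == b] <- BASE_BITS[[b]]
  rownames(enc) <- names(seqs)
  enc
}

# Columns where at least two determinate states differ.
variable_columns <- function(enc) {
  det <- enc == 1L | enc == 2L | enc == 4L | enc == 8L
  n_states <- vapply(seq_len(ncol(enc)), function(j) {
    length(unique(enc[det[, j], j]))
  }, integer(1))
  which(n_states >= 2L)
}

# Compress site columns to unique patterns with weights.
compress_patterns <- function(enc) {
  key <- apply(enc, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[u])))
  list(states = enc[, u, drop = FALSE], weights = w)
}

#' Fitch parsimony score of a tree given aligned haplotype sequences
#'
#' Minimal number of state changes over all internal labelings; missing states
#' (`N`, `-`) are unconstrained. Multifurcating trees are scored with the
#' Fitch-Hartigan generalisation. The score is invariant under re-rooting of
#' the same unrooted topology.
#'
#' @param tree An `ape::phylo`; tip labels must name entries of `seqs`.
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Integer parsimony score.
#' @export
parsimony_score <- function(tree, seqs) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, names(seqs))
  if (length(miss) > 0L) {
    stop("leaf without sequence: ", paste(miss, collapse = ", "))
  }
  enc <- encode_states(seqs[tree$tip.label])
  vc <- variable_columns(enc)
  if (length(vc) == 0L) return(0L)
  cp <- compress_patterns(enc[, vc, drop = FALSE])
  tree <- stats::reorder(tree, "postorder")
  if (ape::is.binary(tree)) {
    as.integer(round(fitch_score_cpp(tree$edge, cp$states, cp$weights)))
  } else {
    as.integer(round(hartigan_down(tree, cp$states, cp$weights)$score))
  }
}

# Hartigan downpass on a (possibly multifurcating) postorder tree.
# Returns per-node candidate state sets and the parsimony score.
hartigan_down <- function(tree, states, weights) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- max(tree$edge)
  nsite <- ncol(states)
  S <- matrix(0L, nrow = nnode, ncol = nsite)
  S[seq_len(ntip), ] <- states
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  # postorder over internal nodes: order of last appearance as parent
  internal_order <- unique(tree$edge[, 1L])
  score <- 0
  for (nd in internal_order) {
    kids <- children[[as.character(nd)]]
    cnt_max <- rep(0L, nsite)
    cnt <- matrix(0L, nrow = 4L, ncol = nsite)
    for (bi in 1:4) {
      b <- BASE_BITS[[bi]]
      for (k in kids) cnt[bi, ] <- cnt[bi, ] + as.integer(bitwAnd(S[k, ], b) > 0L)
    }
    cnt_max <- apply(cnt, 2L, max)
    v <- rep(0L, nsite)
    for (bi in 1:4) {
      b <- BASE_BITS[[bi]]
      v <- bitwOr(v, ifelse(cnt[bi, ] == cnt_max, b, 0L))
    }
    S[nd, ] <- v
    score <- score + sum((length(kids) - cnt_max) * weights)
  }
  list(sets = S, score = score, order = internal_order, children = children)
}

# Deterministic most-parsimonious ancestral state assignment:
# root takes its candidate state (or a fixed root state), children take the
# parent state when compatible, else the alphabetically first candidate.
hartigan_up <- function(tree, down, root_state_bits = NULL) {
  tree <- stats::reorder(tree, "postorder")
  nnode <- max(tree$edge)
  nsite <- ncol(down$sets)
  root <- tree$edge[nrow(tree$edge), 1L]
  final <- matrix(0L, nrow = nnode, ncol = nsite)
  pick_min <- function(sets) {
    out <- rep(8L, length(sets))
    for (b in c(8L, 4L, 2L, 1L)) out[bitwAnd(sets, b) > 0L] <- b
    out
  }
  rs <- down$sets[root, ]
  if (is.null(root_state_bits)) {
    final[root, ] <- pick_min(rs)
  } else {
    keep <- bitwAnd(rs, root_state_bits) > 0L
    final[root, ] <- ifelse(keep, root_state_bits, root_state_bits)
  }
  # preorder = reverse postorder edge traversal
  for (i in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[i, 1L]
    ch <- tree$edge[i, 2L]
    sets <- down$sets[ch, ]
    par <- final[p, ]
    compat <- bitwAnd(sets, par) > 0L
    final[ch, ] <- ifelse(compat, par, pick_min(sets))
  }
  final
}

bits_to_seq <- function(bits) {
  paste(BIT_BASE[as.character(bits)], collapse = "")
}

seq_to_bits <- function(seq) {
  enc <- encode_states(stats::setNames(seq, "x"))
  as.integer(enc[1L, ])
}

#' Most-parsimonious per-branch mutation assignment on a fixed topology
#'
#' Reconstructs ancestral states by the Fitch-Hartigan procedure with a
#' deterministic tie-break (a child inherits the parental state whenever
#' compatible, otherwise takes the alphabetically first candidate) and lists
#' one substitution per branch and site where parent and child states differ.
#' Positions that mutate on more than one branch are flagged recurrent.
#'
#' @param tree Rooted `ape::phylo` (multifurcations allowed).
#' @param seqs Named character vector of aligned sequences for the tips.
#' @param root_state Optional root sequence (same length as the alignment)
#'   fixing the ancestral state at the root.
#' @param positions Optional integer vector mapping alignment columns to
#'   reference np positions (default `1:L`).
#' @return List with `mutations` (data.frame `parent`, `child`, `position_np`,
#'   `from`, `to`, `recurrent`), `node_states` (bitmask matrix over variable
#'   columns), `columns` (the variable columns used), `score`.
#' @export
annotate_mutations <- function(tree, seqs, root_state = NULL,
                               positions = NULL) {
  stopifnot(inherits(tree, "phylo"))
  miss <- setdiff(tree$tip.label, names(seqs))
  if (length(miss) > 0L) {
    stop("leaf without sequence: ", paste(miss, collapse = ", "))
  }
  enc <- encode_states(seqs[tree$tip.label])
  L <- ncol(enc)
  if (is.null(positions)) positions <- seq_len(L)
  if (length(positions) != L) stop("positions length must match alignment")
  root_bits_full <- NULL
  if (!is.null(root_state)) {
    if (nchar(root_state) != L) stop("inconsistent root state length")
    root_bits_full <- seq_to_bits(root_state)
    if (any(!root_bits_full %in% BASE_BITS)) {
      stop("root state must be fully determined (A/C/G/T)")
    }
  }
  # A column can mutate if it varies among tips, or if a fixed root state
  # disagrees with an otherwise constant column.
  vc <- variable_columns(enc)
  if (!is.null(root_bits_full)) {
    det_state <- apply(enc, 2L, function(col) {
      d <- col[col %in% BASE_BITS]
      if (length(d) > 0L) d[1L] else NA_integer_
    })
    extra <- which(!is.na(det_state) & det_state != root_bits_full)
    vc <- sort(union(vc, extra))
  }
  empty <- data.frame(
    parent = integer(0), child = integer(0), position_np = integer(0),
    from = character(0), to = character(0), recurrent = logical(0)
  )
  if (length(vc) == 0L) {
    return(list(mutations = empty, node_states = NULL, columns = integer(0),
                score = 0L))
  }
  sub <- enc[, vc, drop = FALSE]
  tree <- stats::reorder(tree, "postorder")
  down <- hartigan_down(tree, sub, rep(1, length(vc)))
  final <- hartigan_up(
    tree, down,
    if (is.null(root_bits_full)) NULL else root_bits_full[vc]
  )
  muts <- empty
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    ch <- tree$edge[i, 2L]
    d <- which(final[p, ] != final[ch, ])
    if (length(d) > 0L) {
      muts <- rbind(muts, data.frame(
        parent = p, child = ch,
        position_np = positions[vc[d]],
        from = unname(BIT_BASE[as.character(final[p, d])]),
        to = unname(BIT_BASE[as.character(final[ch, d])]),
        recurrent = FALSE
      ))
    }
  }
  if (nrow(muts) > 0L) {
    muts <- muts[order(muts$position_np, muts$parent, muts$child), ,
                 drop = FALSE]
    rownames(muts) <- NULL
    tab <- table(muts$position_np)
    muts$recurrent <- muts$position_np %in%
      as.integer(names(tab)[tab > 1L])
  }
  list(mutations = muts, node_states = final, columns = vc,
       score = nrow(muts))
}

# --- topology enumeration oracle ------------------------------------------

.topology_cache <- new.env(parent = emptyenv())

cached_topologies <- function(n) {
  key <- as.character(n)
  if (is.null(.topology_cache[[key]])) {
    trees <- phangorn::allTrees(n, rooted = FALSE)
    .topology_cache[[key]] <- lapply(trees, function(t) {
      stats::reorder(t, "postorder")$edge
    })
  }
  .topology_cache[[key]]
}

#' Exhaustive-search minimum parsimony score
#'
#' Scores every unrooted topology (feasible for up to ~10 taxa) and returns
#' the minimum, the first minimal topology in enumeration order and the number
#' of equally parsimonious topologies.
#'
#' @param seqs Named character vector of aligned sequences (>= 2 taxa).
#' @return List with `score`, `tree` (unrooted `phylo`), `n_ties`.
#' @export
exhaustive_mp <- function(seqs) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  if (n > 10L) stop("exhaustive search limited to 10 taxa")
  enc <- encode_states(seqs)
  vc <- variable_columns(enc)
  if (n <= 3L) {
    tree <- if (n == 2L) {
      ape::read.tree(text = paste0("(", names(seqs)[1L], ",",
                                   names(seqs)[2L], ");"))
    } else {
      ape::read.tree(text = paste0("(", paste(names(seqs), collapse = ","),
                                   ");"))
    }
    return(list(score = parsimony_score(tree, seqs), tree = tree, n_ties = 1L))
  }
  if (length(vc) == 0L) {
    edges <- cached_topologies(n)
    tree <- phangorn::allTrees(n, rooted = FALSE, tip.label = names(seqs))[[1L]]
    return(list(score = 0L, tree = tree, n_ties = length(edges)))
  }
  cp <- compress_patterns(enc[, vc, drop = FALSE])
  edges <- cached_topologies(n)
  scores <- fitch_score_many_cpp(edges, cp$states, cp$weights)
  best <- min(scores)
  idx <- which(scores == best)
  tree <- phangorn::allTrees(n, rooted = FALSE)[[idx[1L]]]
  tree$tip.label <- names(seqs)[as.integer(sub("^t", "", tree$tip.label))]
  list(score = as.integer(round(best)), tree = tree, n_ties = length(idx))
}

# --- tree building ---------------------------------------------------------

seqs_to_phyDat <- function(seqs) {
  m <- matrix(
    unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE,
    dimnames = list(names(seqs), NULL)
  )
  m[!m %in% c("A", "C", "G", "T")] <- "?"
  phangorn::phyDat(m, type = "DNA")
}

seqs_to_DNAbin <- function(seqs) {
  m <- matrix(
    unlist(strsplit(tolower(seqs), "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE,
    dimnames = list(names(seqs), NULL)
  )
  m[m == "-"] <- "n"
  ape::as.DNAbin(m)
}

# Heuristic MP search: neighbour-joining start plus SPR/NNI hill-climbing.
# Small inputs additionally run a fixed number of random-restart SPR climbs
# (high-homoplasy instances have many local optima); the restarts use an
# internal fixed seed and the caller's RNG state is left untouched, so the
# search is deterministic for a given input.
heuristic_search <- function(seqs, rearrangements = NULL, restarts = NULL) {
  n <- length(seqs)
  if (is.null(rearrangements)) {
    rearrangements <- if (n > 60L) "NNI" else "SPR"
  }
  if (is.null(restarts)) restarts <- if (n <= 25L) 8L else 0L
  pd <- seqs_to_phyDat(seqs)
  d <- ape::dist.dna(seqs_to_DNAbin(seqs), model = "raw",
                     pairwise.deletion = TRUE)
  d[is.na(d) | is.nan(d)] <- 0
  starts <- list(ape::unroot(ape::nj(d)))
  if (restarts > 0L) {
    seed_keep <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    set.seed(20260915L)
    for (r in seq_len(restarts)) {
      starts[[r + 1L]] <- ape::unroot(
        ape::rtree(n, tip.label = sample(names(seqs)))
      )
    }
    if (!is.null(seed_keep)) {
      assign(".Random.seed", seed_keep, envir = globalenv())
    }
  }
  best <- NULL
  best_score <- Inf
  for (st in starts) {
    fit <- phangorn::optim.parsimony(st, pd, method = "fitch",
                                     rearrangements = rearrangements,
                                     trace = 0)
    sc <- parsimony_score(fit, seqs)
    if (sc < best_score) {
      best_score <- sc
      best <- fit
    }
  }
  ape::unroot(best)
}

#' Build a rooted, mutation-annotated maximum-parsimony tree
#'
#' Searches for a maximum-parsimony topology of the ingroup haplotypes plus
#' outgroup(s) (neighbour-joining start followed by deterministic NNI/SPR
#' hill-climbing; or exhaustive enumeration for small inputs), roots the tree
#' on the branch to the outgroup(s), reconstructs ancestral states and
#' annotates every branch with its substitutions. Zero-mutation internal
#' branches below the ingroup ancestor are collapsed into multifurcations, the
#' usual convention for haplogroup trees. The state reconstructed at the
#' ingroup ancestor stands in for the ancestral mitogenome.
#'
#' @param haplotypes Named character vector of aligned ingroup haplotype
#'   sequences (distinct haplotypes; collapse samples first).
#' @param outgroups Named character vector of aligned outgroup sequences.
#' @param positions Optional np positions of the alignment columns.
#' @param method `"heuristic"` (default) or `"exhaustive"` (<= 10 taxa total).
#' @param rearrangements `"NNI"` or `"SPR"` for the heuristic search; default
#'   SPR up to 60 taxa, NNI above.
#' @param collapse Collapse zero-mutation internal branches (default TRUE).
#' @return An object of class `mp_tree`: list with the rooted annotated
#'   `tree` (edge lengths = mutation counts), `mutations` table,
#'   `ingroup_node`, `root_state` (sequence at the ingroup ancestor),
#'   `parsimony_score`, `n_ties` (exhaustive only), `positions`, `alignment`,
#'   `outgroup` labels.
#' @export
build_mp_tree <- function(haplotypes, outgroups, positions = NULL,
                          method = c("heuristic", "exhaustive"),
                          rearrangements = NULL, collapse = TRUE) {
  method <- match.arg(method)
  stopifnot(length(haplotypes) >= 1L, length(outgroups) >= 1L)
  if (is.null(names(haplotypes)) || is.null(names(outgroups))) {
    stop("haplotypes and outgroups must be named")
  }
  seqs <- c(haplotypes, outgroups)
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  enc <- encode_states(seqs)
  if (length(variable_columns(enc)) == 0L) {
    stop("degenerate input: no variable sites among haplotypes and outgroups")
  }
  L <- unique(nchar(seqs))
  if (is.null(positions)) positions <- seq_len(L)
  og <- names(outgroups)
  n_ties <- NA_integer_
  if (method == "exhaustive" || length(seqs) <= 3L) {
    ex <- exhaustive_mp(seqs)
    tree <- ex$tree
    n_ties <- ex$n_ties
  } else {
    tree <- heuristic_search(seqs, rearrangements)
  }
  # Root on the branch to the outgroup(s).
  tree <- root_on_outgroup(tree, og)
  score <- parsimony_score(tree, seqs)
  ann <- annotate_mutations(tree, seqs, positions = positions)
  ingroup_node <- ingroup_mrca(tree, setdiff(tree$tip.label, og))
  if (collapse) {
    tree2 <- collapse_zero_branches(tree, ann$mutations, ingroup_node)
    if (!identical(tree2, tree)) {
      tree <- tree2
      ann <- annotate_mutations(tree, seqs, positions = positions)
      ingroup_node <- ingroup_mrca(tree, setdiff(tree$tip.label, og))
    }
  }
  # Edge lengths = mutation counts.
  counts <- integer(nrow(tree$edge))
  if (nrow(ann$mutations) > 0L) {
    key <- paste(tree$edge[, 1L], tree$edge[, 2L])
    mkey <- paste(ann$mutations$parent, ann$mutations$child)
    tab <- table(mkey)
    counts <- as.integer(tab[key])
    counts[is.na(counts)] <- 0L
  }
  tree$edge.length <- as.numeric(counts)
  root_state <- node_sequence(tree, seqs, ann, ingroup_node, positions)
  structure(
    list(
      tree = tree,
      mutations = ann$mutations,
      ingroup_node = ingroup_node,
      root_state = root_state,
      parsimony_score = score,
      n_ties = n_ties,
      positions = positions,
      alignment = seqs,
      outgroup = og
    ),
    class = "mp_tree"
  )
}

root_on_outgroup <- function(tree, og) {
  if (length(tree$tip.label) <= 2L) return(tree)
  tree <- ape::unroot(tree)
  if (length(og) == 1L || ape::is.monophyletic(tree, og)) {
    rooted <- ape::root(tree, outgroup = og, resolve.root = TRUE)
  } else {
    warning("outgroups not monophyletic; rooting on first outgroup")
    rooted <- ape::root(tree, outgroup = og[1L], resolve.root = TRUE)
  }
  rooted
}

ingroup_mrca <- function(tree, ingroup_tips) {
  if (length(ingroup_tips) == 1L) {
    which(tree$tip.label == ingroup_tips)
  } else {
    ape::getMRCA(tree, ingroup_tips)
  }
}

# Collapse internal branches with zero mutations strictly below `node`.
collapse_zero_branches <- function(tree, mutations, node) {
  ntip <- length(tree$tip.label)
  counts <- integer(nrow(tree$edge))
  if (nrow(mutations) > 0L) {
    key <- paste(tree$edge[, 1L], tree$edge[, 2L])
    mkey <- paste(mutations$parent, mutations$child)
    tab <- table(mkey)
    counts <- as.integer(tab[key])
    counts[is.na(counts)] <- 0L
  }
  below <- descendant_nodes(tree, node)
  internal <- tree$edge[, 2L] > ntip
  collapsible <- internal & counts == 0L &
    tree$edge[, 1L] %in% c(node, below) & tree$edge[, 2L] %in% below
  if (!any(collapsible)) return(tree)
  tree$edge.length <- ifelse(collapsible, 0, 1)
  out <- ape::di2multi(tree, tol = 0.5)
  out$edge.length <- NULL
  out
}

# All nodes (internal and tips) strictly below `node`.
descendant_nodes <- function(tree, node) {
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  out <- integer(0)
  stack <- children[[as.character(node)]]
  while (length(stack) > 0L) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    out <- c(out, nd)
    kids <- children[[as.character(nd)]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  out
}

# Reconstructed full-length sequence at a node (reference-coordinate columns
# of the alignment; non-variable columns taken from the consensus/first
# determined tip state).
node_sequence <- function(tree, seqs, ann, node, positions) {
  enc <- encode_states(seqs[tree$tip.label])
  det_state <- apply(enc, 2L, function(col) {
    d <- col[col %in% BASE_BITS]
    if (length(d) > 0L) d[1L] else BASE_BITS[["A"]]
  })
  bits <- det_state
  if (!is.null(ann$node_states) && length(ann$columns) > 0L) {
    bits[ann$columns] <- ann$node_states[node, ]
  }
  bits_to_seq(bits)
}

#' @export
print.mp_tree <- function(x, ...) {
  cat(sprintf(
    "Mutation-annotated MP tree: %d tips (%d outgroup), score %d, %d branch mutations%s\n",
    length(x$tree$tip.label), length(x$outgroup), x$parsimony_score,
    nrow(x$mutations),
    if (!is.na(x$n_ties)) sprintf(", %d equally parsimonious topologies",
                                  x$n_ties) else ""
  ))
  invisible(x)
}

#' Replay branch mutations from the ingroup ancestor to each tip
#'
#' Internal consistency check: applying the annotated mutations along each
#' root-to-leaf path must reproduce every leaf's observed (determinate) state.
#'
#' @param x An `mp_tree`.
#' @return TRUE invisibly, or an error describing the first mismatch.
#' @export
replay_mutations <- function(x) {
  tree <- stats::reorder(x$tree, "postorder")
  enc <- encode_states(x$alignment[tree$tip.label])
  root <- tree$edge[nrow(tree$edge), 1L]
  root_bits <- seq_to_bits(node_sequence(tree, x$alignment,
                                         annotate_mutations(
                                           tree, x$alignment,
                                           positions = x$positions
                                         ), root, x$positions))
  pos_index <- stats::setNames(seq_along(x$positions), x$positions)
  state <- list()
  state[[as.character(root)]] <- root_bits
  for (i in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[i, 1L]
    ch <- tree$edge[i, 2L]
    s <- state[[as.character(p)]]
    m <- x$mutations[x$mutations$parent == p & x$mutations$child == ch, ,
                     drop = FALSE]
    if (nrow(m) > 0L) {
      s[pos_index[as.character(m$position_np)]] <-
        unname(BASE_BITS[m$to])
    }
    state[[as.character(ch)]] <- s
    if (ch <= length(tree$tip.label)) {
      obs <- enc[ch, ]
      det <- obs %in% BASE_BITS
      if (any(s[det] != obs[det])) {
        bad <- which(s[det] != obs[det])[1L]
        stop(sprintf("mutation replay mismatch at tip '%s'",
                     tree$tip.label[ch]))
      }
    }
  }
  invisible(TRUE)
}

# --- haplogroups -----------------------------------------------------------

int_to_letters <- function(i, upper = FALSE) {
  alph <- if (upper) LETTERS else letters
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      s <- paste0(alph[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[k] <- s
  }
  out
}

#' Define nested haplogroups on a mutation-annotated tree
#'
#' Deterministic nomenclature: the children of the ingroup ancestor get capital
#' letters in order of their first-listed leaf; deeper levels alternate number
#' and letter suffixes (A, A1, A1a, ...). A node is labelled only when its
#' subtending branch carries at least `min_defining_mutations` substitutions
#' and it subtends at least `min_clade_size` leaves; unlabelled nodes are
#' transparent (their children compete for the parent's suffixes).
#'
#' @param x An `mp_tree`.
#' @param min_clade_size Minimum number of descendant haplotypes.
#' @param min_defining_mutations Minimum substitutions on the subtending branch.
#' @return An object of class `haplogroup_definitions`: list with `table`
#'   (label, parent, node, n_tips, defining tokens), `paths` (cumulative
#'   defining mutations per label), `expected` (per-label expected substitution
#'   token set relative to the ingroup-ancestor state), `root_label`.
#' @export
define_haplogroups <- function(x, min_clade_size = 2L,
                               min_defining_mutations = 1L) {
  stopifnot(inherits(x, "mp_tree"))
  tree <- x$tree
  ntip <- length(tree$tip.label)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  og_tips <- which(tree$tip.label %in% x$outgroup)
  mut_by_edge <- split(
    seq_len(nrow(x$mutations)),
    paste(x$mutations$parent, x$mutations$child)
  )
  tip_order <- stats::setNames(seq_along(tree$tip.label), tree$tip.label)
  first_leaf <- function(nd) {
    if (nd <= ntip) return(nd)
    min(vapply(children[[as.character(nd)]], first_leaf, numeric(1)))
  }
  n_tips_below <- function(nd) {
    if (nd <= ntip) return(1L)
    sum(vapply(children[[as.character(nd)]], n_tips_below, integer(1)))
  }
  edge_tokens <- function(parent, child) {
    idx <- mut_by_edge[[paste(parent, child)]]
    if (is.null(idx)) return(character(0))
    m <- x$mutations[idx, , drop = FALSE]
    m <- m[order(m$position_np), , drop = FALSE]
    sprintf("%s%d%s", m$from, m$position_np, m$to)
  }
  rows <- list()
  # depth: 1 = letters (A, B, ...), 2 = numbers, 3 = letters (lowercase), ...
  suffix_for <- function(depth, k) {
    if (depth == 1L) {
      int_to_letters(k, upper = TRUE)
    } else if (depth %% 2L == 0L) {
      as.character(k)
    } else {
      int_to_letters(k, upper = FALSE)
    }
  }
  # Gather labelled candidates below `node`, treating non-qualifying internal
  # nodes as transparent.
  candidates_below <- function(node, carry_tokens = character(0)) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(list())
    out <- list()
    for (k in kids) {
      if (k %in% og_tips) next
      toks <- c(carry_tokens, edge_tokens(node, k))
      nt <- n_tips_below(k)
      qualifies <- k > ntip &&
        nt >= min_clade_size && length(toks) >= min_defining_mutations
      if (k <= ntip) {
        qualifies <- nt >= min_clade_size &&
          length(toks) >= min_defining_mutations
      }
      if (qualifies) {
        out[[length(out) + 1L]] <- list(node = k, tokens = toks,
                                        first = first_leaf(k), n_tips = nt)
      } else if (k > ntip) {
        out <- c(out, candidates_below(k, toks))
      }
    }
    out
  }
  assign_labels <- function(node, label, depth, tokens_so_far) {
    cands <- candidates_below(node)
    if (length(cands) == 0L) return(invisible(NULL))
    ord <- order(vapply(cands, function(cc) cc$first, numeric(1)))
    for (j in seq_along(ord)) {
      cc <- cands[[ord[j]]]
      lab <- if (depth == 1L) {
        suffix_for(1L, j)
      } else {
        paste0(label, suffix_for(depth, j))
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        label = lab,
        parent = label,
        node = cc$node,
        n_tips = cc$n_tips,
        defining = paste(cc$tokens, collapse = ";"),
        stringsAsFactors = FALSE
      )
      if (cc$node > ntip) {
        assign_labels(cc$node, lab, depth + 1L,
                      c(tokens_so_far, cc$tokens))
      }
    }
  }
  root_label <- "root"
  assign_labels(x$ingroup_node, root_label, 1L, character(0))
  tab <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(label = character(0), parent = character(0), node = integer(0),
               n_tips = integer(0), defining = character(0))
  }
  # Cumulative paths and expected substitution sets relative to the
  # ingroup-ancestor state (later mutations at a position override earlier).
  paths <- list()
  expected <- list()
  root_bits <- seq_to_bits(x$root_state)
  for (i in seq_len(nrow(tab))) {
    lab <- tab$label[i]
    par <- tab$parent[i]
    par_path <- if (par == root_label) character(0) else paths[[par]]
    own <- strsplit(tab$defining[i], ";", fixed = TRUE)[[1L]]
    own <- own[nzchar(own)]
    paths[[lab]] <- c(par_path, own)
    state <- if (par == root_label) {
      stats::setNames(integer(0), character(0))
    } else {
      expected_state <- expected[[par]]
      expected_state
    }
    cur <- state
    for (tok in own) {
      m <- regmatches(tok, regexec("^([ACGT])([0-9]+)([ACGT])$", tok))[[1L]]
      pos <- m[3L]
      to <- m[4L]
      ref_here <- BIT_BASE[as.character(
        root_bits[match(as.integer(pos), x$positions)]
      )]
      if (identical(unname(to), unname(ref_here))) {
        cur <- cur[names(cur) != pos]
      } else {
        cur[pos] <- BASE_BITS[[to]]
      }
    }
    expected[[lab]] <- cur
  }
  structure(
    list(table = tab, paths = paths, expected = expected,
         root_label = root_label, root_state = x$root_state,
         positions = x$positions),
    class = "haplogroup_definitions"
  )
}

#' @export
print.haplogroup_definitions <- function(x, ...) {
  cat(sprintf("Haplogroup definitions: %d labels under '%s'\n",
              nrow(x$table), x$root_label))
  if (nrow(x$table) > 0L) {
    top <- x$table[x$table$parent == x$root_label, ]
    cat("  top-level:", paste(top$label, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Assign a haplotype profile to a haplogroup
#'
#' Scores every label by matches minus mismatches of its cumulative defining
#' mutations (relative to the ingroup-ancestor state) against the profile's
#' substitution set; positions missing in the profile count neither way. Ties
#' go to the shallowest label.
#'
#' @param profile A `haplotype_profile` whose substitutions are relative to
#'   the same ancestral state used for the definitions (for synthetic data the
#'   reference equals the root haplotype; otherwise convert first).
#' @param definitions A `haplogroup_definitions`.
#' @return List with `label`, `score`, `matched`, `mismatched`.
#' @export
assign_haplogroup <- function(profile, definitions) {
  stopifnot(inherits(definitions, "haplogroup_definitions"))
  tab <- definitions$table
  prof <- profile$substitutions
  prof_state <- stats::setNames(
    unname(BASE_BITS[prof$alt]),
    as.character(prof$position_np)
  )
  missing <- as.character(profile$missing_sites)
  best <- list(label = definitions$root_label, score = 0,
               matched = character(0), mismatched = character(0), depth = 0L)
  if (nrow(tab) == 0L) return(best[c("label", "score", "matched", "mismatched")])
  for (i in seq_len(nrow(tab))) {
    lab <- tab$label[i]
    exp_state <- definitions$expected[[lab]]
    pos <- names(exp_state)
    usable <- !(pos %in% missing)
    pos <- pos[usable]
    exp_b <- exp_state[usable]
    got <- prof_state[pos]
    match_ok <- !is.na(got) & got == exp_b
    matched <- pos[match_ok]
    mismatched <- pos[!match_ok]
    score <- length(matched) - length(mismatched)
    depth <- length(definitions$paths[[lab]])
    if (score > best$score ||
        (score == best$score && depth < best$depth)) {
      best <- list(label = lab, score = score,
                   matched = sprintf("%s@%s",
                                     BIT_BASE[as.character(exp_b[match_ok])],
                                     matched),
                   mismatched = mismatched, depth = depth)
    }
  }
  best[c("label", "score", "matched", "mismatched")]
}

#' Bootstrap support for the clades of an MP tree
#'
#' Site resampling with replacement over the alignment columns; each replicate
#' rebuilds a maximum-parsimony tree and support is the percentage of
#' replicates containing each clade (as an unrooted bipartition).
#'
#' @param x An `mp_tree`.
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Random seed (required for reproducibility).
#' @param rearrangements Search intensity for replicate trees (default NNI).
#' @return Numeric vector of support percentages named by internal node id of
#'   `x$tree` (NA for the root).
#' @export
bootstrap_support <- function(x, n_replicates = 1000L, seed = NULL,
                              rearrangements = "NNI") {
  stopifnot(inherits(x, "mp_tree"), n_replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  seqs <- x$alignment
  L <- unique(nchar(seqs))
  mat <- matrix(
    unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
    nrow = length(seqs), byrow = TRUE, dimnames = list(names(seqs), NULL)
  )
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    bs <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    enc <- encode_states(bs)
    if (length(variable_columns(enc)) == 0L) {
      reps[[r]] <- NULL
      next
    }
    reps[[r]] <- heuristic_search(bs, rearrangements, restarts = 0L)
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  phy <- x$tree
  counts <- ape::prop.clades(phy, reps, rooted = FALSE)
  support <- 100 * counts / n_replicates
  ntip <- length(phy$tip.label)
  names(support) <- seq_len(phy$Nnode) + ntip
  support
}

#' Write an annotated tree and its companion tables
#'
#' Newick with branch lengths equal to mutation counts plus TSVs of branch
#' mutations and haplogroup definitions.
#'
#' @param x An `mp_tree`.
#' @param dir Output directory.
#' @param definitions Optional `haplogroup_definitions`.
#' @return Invisible character vector of files written.
#' @export
write_mp_tree <- function(x, dir, definitions = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  nwk <- file.path(dir, "mp_tree.nwk")
  ape::write.tree(x$tree, file = nwk)
  files <- c(files, nwk)
  mut <- file.path(dir, "branch_mutations.tsv")
  utils::write.table(x$mutations, mut, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, mut)
  if (!is.null(definitions)) {
    hg <- file.path(dir, "haplogroups.tsv")
    utils::write.table(definitions$table, hg, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, hg)
  }
  invisible(files)
}
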