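# Synonymous / non-synonymous classification of tree mutations under the
# vertebrate mitochondrial code, NG86-style site counting, and the
# time-partitioned dN/dS statistic with a Fisher exact test.

vertebrate_mito_code <- function() {
  Biostrings::getGeneticCode("2")
}

complement_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A")[b]
}

translate_codon <- function(codon, code = vertebrate_mito_code()) {
  aa <- code[codon]
  unname(aa)
}

#' Classify a substitution by its coding effect
#'
#' Looks the position up in the gene annotation, extracts the ancestral codon
#' (strand-aware), applies the single substitution and compares the encoded
#' amino acids under the vertebrate mitochondrial code. Positions covered by
#' more than one protein-coding gene are classified once per gene and flagged.
#' Positions outside protein-coding genes (or in an incomplete terminal codon)
#' are `noncoding`; changes that create or destroy a stop codon are
#' `stop_involved`.
#'
#' @param position_np 1-based reference position.
#' @param from,to Ancestral and derived base (reference strand).
#' @param annotation A `reference_annotation`.
#' @param ancestral Function `(np) -> base` returning the ancestral base on
#'   the reference strand at any np (used for the codon context), or a full
#'   character vector indexed by np.
#' @return data.frame with one row per overlapping protein-coding gene (or a
#'   single `noncoding` row): `position_np`, `gene`, `codon_index`,
#'   `codon_pos`, `effect`, `overlapping`.
#' @export
classify_mutation <- function(position_np, from, to, annotation, ancestral) {
  stopifnot(inherits(annotation, "reference_annotation"))
  getb <- if (is.function(ancestral)) {
    ancestral
  } else {
    function(np) ancestral[np]
  }
  genes <- annotation$genes
  hit <- genes$start_np <= position_np & genes$end_np >= position_np
  pcg <- genes[hit & genes$category == "protein_coding", , drop = FALSE]
  if (nrow(pcg) == 0L) {
    other <- genes$gene[hit]
    return(data.frame(
      position_np = position_np,
      gene = if (length(other) > 0L) other[1L] else NA_character_,
      codon_index = NA_integer_, codon_pos = NA_integer_,
      effect = "noncoding", overlapping = FALSE,
      stringsAsFactors = FALSE
    ))
  }
  code <- vertebrate_mito_code()
  rows <- lapply(seq_len(nrow(pcg)), function(i) {
    g <- pcg[i, ]
    if (g$strand == "+") {
      off <- position_np - g$start_np
      idx <- off %/% 3L
      cpos <- off %% 3L + 1L
      c1 <- g$start_np + idx * 3L
      if (c1 + 2L > g$end_np) {
        return(data.frame(
          position_np = position_np, gene = g$gene,
          codon_index = idx + 1L, codon_pos = cpos,
          effect = "noncoding", overlapping = nrow(pcg) > 1L,
          stringsAsFactors = FALSE
        ))
      }
      codon <- c(getb(c1), getb(c1 + 1L), getb(c1 + 2L))
      codon[cpos] <- from
      new <- codon
      new[cpos] <- to
    } else {
      off <- g$end_np - position_np
      idx <- off %/% 3L
      cpos <- off %% 3L + 1L
      p1 <- g$end_np - idx * 3L
      if (p1 - 2L < g$start_np) {
        return(data.frame(
          position_np = position_np, gene = g$gene,
          codon_index = idx + 1L, codon_pos = cpos,
          effect = "noncoding", overlapping = nrow(pcg) > 1L,
          stringsAsFactors = FALSE
        ))
      }
      codon <- unname(complement_base(c(getb(p1), getb(p1 - 1L),
                                        getb(p1 - 2L))))
      codon[cpos] <- unname(complement_base(from))
      new <- codon
      new[cpos] <- unname(complement_base(to))
    }
    aa_old <- translate_codon(paste(codon, collapse = ""), code)
    aa_new <- translate_codon(paste(new, collapse = ""), code)
    effect <- if (is.na(aa_old) || is.na(aa_new)) {
      "noncoding"
    } else if (aa_old == "*" || aa_new == "*") {
      "stop_involved"
    } else if (aa_old == aa_new) {
      "synonymous"
    } else {
      "nonsynonymous"
    }
    data.frame(
      position_np = position_np, gene = g$gene,
      codon_index = idx + 1L, codon_pos = cpos,
      effect = effect, overlapping = nrow(pcg) > 1L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' NG86 synonymous and non-synonymous site counts
#'
#' Per codon, each of the three positions contributes a fraction of a
#' synonymous site equal to (number of synonymous one-step changes at that
#' position)/3; the complement is non-synonymous. Changes that create a stop
#' codon count as non-synonymous, so the totals satisfy
#' `nonsyn_sites + syn_sites = sequence length`.
#'
#' @param cds In-frame coding sequence (length divisible by 3, no stop
#'   codons).
#' @param code Genetic code (default vertebrate mitochondrial).
#' @param on_stop `"error"` (default) rejects internal stop codons;
#'   `"skip"` excludes them from the site totals (useful when the input is a
#'   reconstructed ancestral sequence that may carry occasional
#'   reconstruction noise); skipped codons are reported in the
#'   `skipped_codons` attribute.
#' @return Named numeric vector `c(nonsyn_sites, syn_sites)`.
#' @export
count_sites <- function(cds, code = vertebrate_mito_code(),
                        on_stop = c("error", "skip")) {
  on_stop <- match.arg(on_stop)
  n <- nchar(cds)
  if (n == 0L) return(c(nonsyn_sites = 0, syn_sites = 0))
  if (n %% 3L != 0L) stop("coding sequence length must be divisible by 3")
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  bases <- c("A", "C", "G", "T")
  syn <- 0
  skipped <- integer(0)
  counted <- 0L
  for (ci in seq_along(codons)) {
    codon <- codons[ci]
    aa <- translate_codon(codon, code)
    if (is.na(aa) || aa == "*") {
      msg <- if (is.na(aa)) "codon with ambiguous base" else
        "internal stop codon"
      if (on_stop == "error") stop(msg, " at codon index ", ci)
      skipped <- c(skipped, ci)
      next
    }
    counted <- counted + 1L
    sp <- strsplit(codon, "", fixed = TRUE)[[1L]]
    for (p in 1:3) {
      for (b in setdiff(bases, sp[p])) {
        alt <- sp
        alt[p] <- b
        aa2 <- translate_codon(paste(alt, collapse = ""), code)
        if (aa2 == aa) syn <- syn + 1 / 3
        # changes to stop are non-synonymous by policy
      }
    }
  }
  out <- c(nonsyn_sites = 3 * counted - syn, syn_sites = syn)
  attr(out, "skipped_codons") <- skipped
  out
}

#' Extract the in-frame CDS of a gene from a reference-coordinate sequence
#'
#' Strand-aware; trims a trailing incomplete codon and drops a terminal stop
#' codon if present.
#'
#' @param sequence Sequence in reference coordinates (full length or a
#'   function `(np) -> base`).
#' @param gene One row of the annotation `genes` table.
#' @return The CDS string (coding strand, 5'->3').
#' @export
gene_cds <- function(sequence, gene) {
  getb <- if (is.function(sequence)) {
    sequence
  } else {
    function(np) substring(sequence, np, np)
  }
  nps <- if (gene$strand == "+") {
    gene$start_np:gene$end_np
  } else {
    gene$end_np:gene$start_np
  }
  b <- vapply(nps, getb, character(1))
  if (gene$strand == "-") b <- unname(complement_base(b))
  len <- (length(b) %/% 3L) * 3L
  b <- b[seq_len(len)]
  cds <- paste(b, collapse = "")
  if (len >= 3L) {
    last <- substring(cds, len - 2L, len)
    aa <- translate_codon(last)
    if (!is.na(aa) && aa == "*") cds <- substring(cds, 1L, len - 3L)
  }
  cds
}

#' Site counts summed over all protein-coding genes
#'
#' @param sequence Reference-coordinate sequence (string or `(np)->base`
#'   function).
#' @param annotation A `reference_annotation`.
#' @param on_stop Passed to [count_sites()]; the pipeline uses `"skip"`
#'   because its input is a reconstructed ancestral sequence.
#' @return List with `total` (named vector) and `per_gene` data.frame.
#' @export
count_sites_genes <- function(sequence, annotation,
                              on_stop = c("error", "skip")) {
  on_stop <- match.arg(on_stop)
  pcg <- annotation$genes[annotation$genes$category == "protein_coding", ,
                          drop = FALSE]
  per <- lapply(seq_len(nrow(pcg)), function(i) {
    g <- pcg[i, ]
    cs <- tryCatch(
      count_sites(gene_cds(sequence, g), on_stop = on_stop),
      error = function(e) stop("gene ", g$gene, ": ", conditionMessage(e))
    )
    data.frame(gene = g$gene, nonsyn_sites = cs[["nonsyn_sites"]],
               syn_sites = cs[["syn_sites"]], stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(
    total = c(nonsyn_sites = sum(per$nonsyn_sites),
              syn_sites = sum(per$syn_sites)),
    per_gene = per
  )
}

#' Classify every mutation on an annotated tree
#'
#' Reconstructs the ancestral sequence at each branch's parent node and
#' classifies each branch mutation in its ancestral codon context.
#'
#' @param x An `mp_tree` built on a region scheme covering the coding genes.
#' @param annotation A `reference_annotation`.
#' @return data.frame: the mutation table joined with `gene`, `codon_index`,
#'   `codon_pos`, `effect`, `overlapping`.
#' @export
classify_tree_mutations <- function(x, annotation) {
  stopifnot(inherits(x, "mp_tree"))
  if (nrow(x$mutations) == 0L) {
    return(cbind(x$mutations, data.frame(
      gene = character(0), codon_index = integer(0), codon_pos = integer(0),
      effect = character(0), overlapping = logical(0)
    )))
  }
  ann <- annotate_mutations(x$tree, x$alignment, positions = x$positions)
  pos_index <- stats::setNames(seq_along(x$positions), x$positions)
  # Base sequence (region columns) shared by all nodes; per-node overrides on
  # variable columns from the reconstruction.
  base_bits <- seq_to_bits(node_sequence(x$tree, x$alignment, ann,
                                         x$ingroup_node, x$positions))
  node_base <- function(node, np) {
    col <- pos_index[as.character(np)]
    if (is.na(col)) return(NA_character_)
    j <- match(col, ann$columns)
    bits <- if (!is.na(j)) ann$node_states[node, j] else base_bits[col]
    unname(BIT_BASE[as.character(bits)])
  }
  rows <- lapply(seq_len(nrow(x$mutations)), function(i) {
    m <- x$mutations[i, ]
    cls <- classify_mutation(
      m$position_np, m$from, m$to, annotation,
      ancestral = function(np) node_base(m$parent, np)
    )
    cbind(m[rep(1L, nrow(cls)), , drop = FALSE], cls[, -1L, drop = FALSE],
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p by summing hypergeometric probabilities no larger than that of the
#' observed table (with a small relative tolerance for floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  m1 <- sum(tab[1L, ])
  m2 <- sum(tab[2L, ])
  k <- sum(tab[, 1L])
  if (m1 == 0L || m2 == 0L || k == 0L || sum(tab[, 2L]) == 0L) {
    warning("zero margin: p = 1 by convention")
    return(1)
  }
  a <- tab[1L, 1L]
  support <- max(0L, k - m2):min(m1, k)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Time-partitioned dN/dS across a dated mutation-annotated tree
#'
#' Assigns every classified coding mutation to the young or old partition by
#' its branch midpoint age (young iff midpoint < cutoff), computes
#' site-normalised dN/dS per partition, and tests the N/S contrast with the
#' two-sided Fisher exact test. `stop_involved` mutations count as
#' non-synonymous; `noncoding` mutations are excluded.
#'
#' @param classified Output of [classify_tree_mutations()].
#' @param node_ages Named numeric vector node id -> age in years covering
#'   every parent and child in the table (tips may be omitted; they default
#'   to age 0).
#' @param site_counts Named vector `c(nonsyn_sites, syn_sites)`.
#' @param cutoff_age_years Partition cutoff (default 11,700, the end of the
#'   Younger Dryas).
#' @param n_tips Number of tips in the tree (node ids <= n_tips default to 0).
#' @return An object of class `partitioned_dnds`: list with `counts`
#'   (N_young, S_young, N_old, S_old), `dnds_young`, `dnds_old`, the
#'   unnormalised `ratio_young`/`ratio_old`, `fisher_p`, `cutoff_age_years`,
#'   `site_counts`.
#' @export
dnds_partitioned <- function(classified, node_ages, site_counts,
                             cutoff_age_years = 11700, n_tips = NULL) {
  cls <- classified[classified$effect %in%
                      c("synonymous", "nonsynonymous", "stop_involved"), ,
                    drop = FALSE]
  age_of <- function(node) {
    v <- node_ages[as.character(node)]
    v[is.na(v) & !is.null(n_tips) & node <= n_tips] <- 0
    v
  }
  pa <- age_of(cls$parent)
  ca <- age_of(cls$child)
  if (any(is.na(pa)) || any(is.na(ca))) {
    stop("undated branch: node ages missing for some parents/children")
  }
  midpoint <- (pa + ca) / 2
  young <- midpoint < cutoff_age_years
  is_n <- cls$effect %in% c("nonsynonymous", "stop_involved")
  counts <- c(
    N_young = sum(young & is_n), S_young = sum(young & !is_n),
    N_old = sum(!young & is_n), S_old = sum(!young & !is_n)
  )
  ns <- site_counts[["nonsyn_sites"]]
  ss <- site_counts[["syn_sites"]]
  dnds <- function(N, S) {
    if (S == 0) return(NA_real_)
    (N / ns) / (S / ss)
  }
  ratio <- function(N, S) if (S == 0) NA_real_ else N / S
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    fisher_exact_2x2(tab)
  } else {
    1
  }
  structure(
    list(
      counts = counts,
      dnds_young = dnds(counts[["N_young"]], counts[["S_young"]]),
      dnds_old = dnds(counts[["N_old"]], counts[["S_old"]]),
      ratio_young = ratio(counts[["N_young"]], counts[["S_young"]]),
      ratio_old = ratio(counts[["N_old"]], counts[["S_old"]]),
      fisher_p = p,
      cutoff_age_years = cutoff_age_years,
      site_counts = c(nonsyn_sites = ns, syn_sites = ss)
    ),
    class = "partitioned_dnds"
  )
}

#' @export
print.partitioned_dnds <- function(x, ...) {
  cat(sprintf(
    "Partitioned dN/dS (cutoff %.0f y): young %d N / %d S (dN/dS %.3g), old %d N / %d S (dN/dS %.3g), Fisher p = %.3g\n",
    x$cutoff_age_years,
    x$counts[["N_young"]], x$counts[["S_young"]], x$dnds_young,
    x$counts[["N_old"]], x$counts[["S_old"]], x$dnds_old,
    x$fisher_p
  ))
  invisible(x)
}
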