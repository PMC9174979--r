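# Scoring pipeline output against simulation truth: haplogroup recovery and
# clade-age recovery. The inferred nomenclature is deterministic but need not
# place the generating clades at fixed label strings (e.g. the four major
# clades may appear as A1/A2/B1/B2 when the basal split is labelled A/B), so
# truth clades are matched to inferred labels by sample content, not by name.

# Samples assigned to a label or any of its descendant labels.
label_groups <- function(assignments, definitions) {
  tab <- definitions$table
  kids <- split(tab$label, tab$parent)
  desc <- function(lab) {
    out <- lab
    stack <- kids[[lab]]
    while (length(stack) > 0L) {
      l <- stack[[1L]]
      stack <- stack[-1L]
      out <- c(out, l)
      if (!is.null(kids[[l]])) stack <- c(stack, kids[[l]])
    }
    out
  }
  labs <- tab$label
  stats::setNames(lapply(labs, function(l) {
    assignments$sample_id[assignments$haplogroup %in% desc(l)]
  }), labs)
}

#' Score haplogroup assignments against generating truth
#'
#' Finds the injective mapping from truth clades to inferred haplogroup labels
#' (a sample counts as recovered when it lies in the mapped label's group,
#' i.e. is assigned that label or a nested sub-label) that maximises the
#' number of correctly grouped samples, and reports the resulting accuracy.
#'
#' @param assignments Data frame with `sample_id` and `haplogroup` (the
#'   assigned label).
#' @param definitions The `haplogroup_definitions` used for assignment.
#' @param truth Named character vector sample_id -> generating clade.
#' @return List with `accuracy`, `mapping` (truth clade -> label) and `n`.
#' @export
haplogroup_recovery <- function(assignments, definitions, truth) {
  truth <- truth[assignments$sample_id]
  clades <- sort(unique(truth))
  groups <- label_groups(assignments, definitions)
  labs <- names(groups)
  overlap <- matrix(0L, nrow = length(clades), ncol = length(labs),
                    dimnames = list(clades, labs))
  for (ci in seq_along(clades)) {
    s_t <- assignments$sample_id[truth == clades[ci]]
    overlap[ci, ] <- vapply(groups, function(g) {
      length(intersect(g, s_t))
    }, integer(1))
  }
  # Exhaustive search over the top candidate labels per clade (injective);
  # equal-overlap ties prefer the most specific label (smallest group), so a
  # truth clade maps to its own clade rather than an enclosing one.
  sizes <- vapply(groups, length, integer(1))
  topk <- lapply(seq_along(clades), function(ci) {
    o <- order(overlap[ci, ], -sizes, decreasing = TRUE)
    utils::head(o, 6L)
  })
  best <- list(total = -1L, sizesum = Inf, map = NULL)
  search <- function(ci, used, total, sizesum, map) {
    if (ci > length(clades)) {
      if (total > best$total ||
          (total == best$total && sizesum < best$sizesum)) {
        best <<- list(total = total, sizesum = sizesum, map = map)
      }
      return(invisible(NULL))
    }
    for (j in topk[[ci]]) {
      if (j %in% used) next
      search(ci + 1L, c(used, j), total + overlap[ci, j],
             sizesum + sizes[j],
             c(map, stats::setNames(labs[j], clades[ci])))
    }
  }
  search(1L, integer(0), 0L, 0, character(0))
  list(
    accuracy = best$total / nrow(assignments),
    mapping = best$map,
    n = nrow(assignments)
  )
}

#' Rho ages of mapped truth clades with recovery check
#'
#' For each truth clade mapped by [haplogroup_recovery()], computes the rho
#' age of the mapped label's node and compares it with the generating age.
#'
#' @param x The `mp_tree`.
#' @param definitions The `haplogroup_definitions`.
#' @param mapping Truth clade -> label map (from [haplogroup_recovery()]).
#' @param true_ages Named numeric vector truth clade -> age in years.
#' @param clock A [clock_model()].
#' @return data.frame (clade, label, age_years, se_years, true_age, within_2se).
#' @export
clade_age_recovery <- function(x, definitions, mapping, true_ages,
                               clock = clock_model()) {
  rows <- lapply(names(mapping), function(cl) {
    lab <- mapping[[cl]]
    node <- definitions$table$node[definitions$table$label == lab]
    if (length(node) != 1L || node <= length(x$tree$tip.label)) {
      return(data.frame(clade = cl, label = lab, age_years = NA_real_,
                        se_years = NA_real_, true_age = true_ages[[cl]],
                        within_2se = NA))
    }
    ra <- rho_age(x, node, clock)
    data.frame(
      clade = cl, label = lab, age_years = ra$age_years,
      se_years = ra$se_years, true_age = true_ages[[cl]],
      within_2se = abs(ra$age_years - true_ages[[cl]]) <= 2 * ra$se_years
    )
  })
  do.call(rbind, rows)
}
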