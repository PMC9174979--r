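# Reference-relative variant calling and haplotype profiles.

PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Classify a substitution as transition or transversion
#'
#' @param ref,alt Single bases in `A, C, G, T`.
#' @return `"transition"` or `"transversion"`.
#' @export
substitution_kind <- function(ref, alt) {
  ifelse(
    (ref %in% PURINES) == (alt %in% PURINES),
    "transition", "transversion"
  )
}

#' Call substitutions from per-site allele fractions
#'
#' Implements the read-fraction rule used for mitogenome consensus calling: an
#' alternative allele is called when its read fraction reaches `min_fraction`
#' (default 30%), and a called variant is flagged heteroplasmic when the
#' fraction lies inside the closed interval `het_range` (default 30-70%).
#' Heteroplasmic calls are kept in profiles, carrying the flag as metadata.
#'
#' @param site_fractions Data frame with columns `position_np`, `ref`, `alt`,
#'   `alt_fraction`.
#' @param min_fraction Minimum alt-read fraction for a call.
#' @param het_range Closed interval of fractions flagged heteroplasmic.
#' @return A data.frame of called variants with columns `position_np`, `ref`,
#'   `alt`, `kind`, `heteroplasmic`.
#' @export
call_variants <- function(site_fractions, min_fraction = 0.30,
                          het_range = c(0.30, 0.70)) {
  need <- c("position_np", "ref", "alt", "alt_fraction")
  miss <- setdiff(need, names(site_fractions))
  if (length(miss) > 0L) {
    stop("site_fractions missing column(s): ", paste(miss, collapse = ", "))
  }
  f <- site_fractions$alt_fraction
  if (any(is.na(f)) || any(f < 0) || any(f > 1)) {
    stop("alt_fraction values must lie in [0, 1]")
  }
  called <- f >= min_fraction
  out <- site_fractions[called, need, drop = FALSE]
  out$kind <- substitution_kind(out$ref, out$alt)
  out$heteroplasmic <-
    out$alt_fraction >= het_range[1L] & out$alt_fraction <= het_range[2L]
  out$alt_fraction <- NULL
  rownames(out) <- NULL
  out
}

#' Haplotype profile of a sample relative to the reference
#'
#' Compares an aligned sample sequence to the reference over a region scheme.
#' Substitutions are recorded at every in-scheme position where both bases are
#' in `A, C, G, T` and differ; `N` positions are recorded as missing sites;
#' `-` is recorded as indel evidence only and never enters the substitution
#' set (indels are excluded from tree construction).
#'
#' @param sequence Sample sequence, same length as `reference`.
#' @param reference Reference sequence.
#' @param scheme A [region_scheme()].
#' @param sample_id Sample identifier.
#' @return An object of class `haplotype_profile`: list with `sample_id`,
#'   `scheme_label`, `substitutions` (data.frame `position_np`, `ref`, `alt`,
#'   `kind`), `missing_sites`, `indel_sites`.
#' @export
diff_to_reference <- function(sequence, reference, scheme,
                              sample_id = "sample") {
  stopifnot(inherits(scheme, "region_scheme"))
  if (nchar(sequence) != nchar(reference)) {
    stop(sprintf(
      "sequence length (%d) differs from reference length (%d)",
      nchar(sequence), nchar(reference)
    ))
  }
  pos <- region_positions(scheme)
  s <- strsplit(sequence, "", fixed = TRUE)[[1L]][pos]
  r <- strsplit(reference, "", fixed = TRUE)[[1L]][pos]
  missing_sites <- pos[s == "N"]
  indel_sites <- pos[s == "-" | r == "-"]
  ok <- s %in% c("A", "C", "G", "T") & r %in% c("A", "C", "G", "T")
  diff <- ok & s != r
  subs <- data.frame(
    position_np = pos[diff],
    ref = r[diff],
    alt = s[diff],
    stringsAsFactors = FALSE
  )
  subs$kind <- if (nrow(subs) > 0L) {
    substitution_kind(subs$ref, subs$alt)
  } else {
    character(0)
  }
  new_haplotype_profile(sample_id, scheme$label, subs,
                        missing_sites, indel_sites)
}

new_haplotype_profile <- function(sample_id, scheme_label, substitutions,
                                  missing_sites = integer(0),
                                  indel_sites = integer(0)) {
  if (anyDuplicated(substitutions$position_np)) {
    stop("at most one substitution per position in a profile")
  }
  structure(
    list(
      sample_id = sample_id,
      scheme_label = scheme_label,
      substitutions = substitutions,
      missing_sites = as.integer(missing_sites),
      indel_sites = as.integer(indel_sites)
    ),
    class = "haplotype_profile"
  )
}

#' @export
print.haplotype_profile <- function(x, ...) {
  cat(sprintf(
    "Haplotype profile '%s' on scheme '%s': %d substitutions, %d missing, %d indel sites\n",
    x$sample_id, x$scheme_label, nrow(x$substitutions),
    length(x$missing_sites), length(x$indel_sites)
  ))
  invisible(x)
}

#' Compact token form of a profile's substitution set ("A123G"-style)
#' @param profile A `haplotype_profile`.
#' @return Character vector of tokens, sorted by position.
#' @export
profile_tokens <- function(profile) {
  s <- profile$substitutions
  if (nrow(s) == 0L) return(character(0))
  s <- s[order(s$position_np), , drop = FALSE]
  sprintf("%s%d%s", s$ref, s$position_np, s$alt)
}

#' Collapse haplotype profiles to distinct haplotypes
#'
#' Profiles are identical iff their substitution sets are identical; missing
#' sites are ignored for identity (pairwise comparison over jointly non-missing
#' positions would make identity non-transitive).
#'
#' @param profiles List of `haplotype_profile` objects on a common scheme.
#' @return A list with `distinct_count`, `haplotypes` (named list mapping
#'   haplotype key -> sample ids) and `representative` (sample id of the first
#'   profile carrying each haplotype).
#' @export
collapse_haplotypes <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  labs <- vapply(profiles, function(p) p$scheme_label, character(1))
  if (length(unique(labs)) != 1L) {
    stop("profiles are on mixed region schemes: ",
         paste(unique(labs), collapse = ", "))
  }
  keys <- vapply(profiles, function(p) {
    paste(profile_tokens(p), collapse = ";")
  }, character(1))
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  haplos <- split(ids, factor(keys, levels = unique(keys)))
  list(
    distinct_count = length(haplos),
    haplotypes = haplos,
    representative = vapply(haplos, `[`, character(1), 1L)
  )
}

#' Variable sites across a set of profiles
#'
#' A site is variable when at least two distinct non-missing states are
#' observed across the samples, the reference allele counting as a state for
#' samples without a substitution there.
#'
#' @param profiles List of `haplotype_profile` objects on a common scheme.
#' @return List with `count` and sorted `sites`.
#' @export
variable_sites <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  labs <- vapply(profiles, function(p) p$scheme_label, character(1))
  if (length(unique(labs)) != 1L) stop("profiles are on mixed region schemes")
  sub_pos <- lapply(profiles, function(p) p$substitutions$position_np)
  sub_alt <- lapply(profiles, function(p) p$substitutions$alt)
  all_pos <- unique(unlist(sub_pos, use.names = FALSE))
  if (length(all_pos) == 0L) return(list(count = 0L, sites = integer(0)))
  n <- length(profiles)
  # State per candidate site per profile: alt allele, reference, or missing.
  states <- matrix("ref", nrow = n, ncol = length(all_pos))
  colnames(states) <- as.character(all_pos)
  for (i in seq_len(n)) {
    if (length(sub_pos[[i]]) > 0L) {
      states[i, as.character(sub_pos[[i]])] <- sub_alt[[i]]
    }
    ms <- intersect(profiles[[i]]$missing_sites, all_pos)
    if (length(ms) > 0L) states[i, as.character(ms)] <- NA_character_
    is_ <- intersect(profiles[[i]]$indel_sites, all_pos)
    if (length(is_) > 0L) states[i, as.character(is_)] <- NA_character_
  }
  variable <- apply(states, 2L, function(col) {
    length(unique(col[!is.na(col)])) >= 2L
  })
  sites <- sort(all_pos[variable])
  list(count = length(sites), sites = sites)
}

#' Write a variant table (TSV) for a set of profiles
#'
#' @param profiles List of `haplotype_profile` objects.
#' @param path Output TSV path.
#' @return The assembled data.frame, invisibly.
#' @export
write_variant_table <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    s <- p$substitutions
    if (nrow(s) == 0L) return(NULL)
    data.frame(
      sample_id = p$sample_id, position_np = s$position_np,
      ref = s$ref, alt = s$alt, kind = s$kind,
      heteroplasmic = if ("heteroplasmic" %in% names(s)) {
        s$heteroplasmic
      } else {
        FALSE
      },
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      sample_id = character(0), position_np = integer(0), ref = character(0),
      alt = character(0), kind = character(0), heteroplasmic = logical(0)
    )
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Apply a profile's substitutions to the reference
#'
#' Inverse of [diff_to_reference()] for gapless profiles; used in round-trip
#' checks and to reconstruct haplotype sequences.
#'
#' @param profile A `haplotype_profile`.
#' @param reference Reference sequence.
#' @return The reconstructed sample sequence (with `N` at missing sites).
#' @export
apply_profile <- function(profile, reference) {
  s <- strsplit(reference, "", fixed = TRUE)[[1L]]
  subs <- profile$substitutions
  if (nrow(subs) > 0L) s[subs$position_np] <- subs$alt
  if (length(profile$missing_sites) > 0L) s[profile$missing_sites] <- "N"
  paste(s, collapse = "")
}
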