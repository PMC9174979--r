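# Population-genetic summary statistics: nucleotide and haplotype diversity,
# haplogroup frequency tables and over-representation tests, AMOVA-based
# PhiST, geographic distances, Mantel isolation-by-distance testing and the
# diversity-versus-latitude regression.

#' Nucleotide diversity (pi)
#'
#' Mean pairwise proportion of differing sites. The default missing-data
#' policy is pairwise deletion: for each pair, sites with `N` (or a gap) in
#' either sequence are excluded and the difference count is divided by the
#' number of jointly determined sites; `complete_deletion = TRUE` instead
#' drops every site missing in any sequence first.
#'
#' @param seqs Named character vector of equal-length aligned sequences
#'   (n >= 2).
#' @param complete_deletion Use complete deletion instead of pairwise.
#' @return List with `pi` (per-site fraction), `mean_pairwise_diff`
#'   (mean absolute differences per pair), `n`, `sites_used` (mean jointly
#'   determined sites per pair).
#' @export
nucleotide_diversity <- function(seqs, complete_deletion = FALSE) {
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  enc <- encode_states(seqs)
  if (complete_deletion) {
    det <- enc == 1L | enc == 2L | enc == 4L | enc == 8L
    keep <- colSums(det) == n
    m <- matrix(
      unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
      nrow = n, byrow = TRUE
    )[, keep, drop = FALSE]
    seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""), names(seqs))
  }
  dna <- seqs_to_DNAbin(seqs)
  p <- ape::dist.dna(dna, model = "raw", pairwise.deletion = TRUE)
  d <- ape::dist.dna(dna, model = "N", pairwise.deletion = TRUE)
  p <- p[!is.na(p) & !is.nan(p)]
  L_pair <- as.numeric(d) / pmax(as.numeric(p), .Machine$double.eps)
  L_pair[as.numeric(p) == 0] <- NA
  list(
    pi = mean(p),
    mean_pairwise_diff = mean(as.numeric(d)),
    n = n,
    sites_used = if (all(is.na(L_pair))) nchar(seqs[[1L]]) else
      mean(L_pair, na.rm = TRUE)
  )
}

#' Haplotype diversity (HD)
#'
#' `HD = n/(n-1) * (1 - sum p_k^2)` over haplotype frequencies.
#'
#' @param counts Integer vector of haplotype counts (n = sum >= 2).
#' @return Haplotype diversity in [0, 1].
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2L) stop("need at least two samples")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Haplogroup frequency table by population
#'
#' @param assignments Data frame with columns `sample_id`, `population`,
#'   `haplogroup` (no NA haplogroups).
#' @return List with `counts` (populations x haplogroups matrix) and
#'   `frequencies` (row proportions).
#' @export
haplogroup_frequency_table <- function(assignments) {
  need <- c("sample_id", "population", "haplogroup")
  miss <- setdiff(need, names(assignments))
  if (length(miss) > 0L) {
    stop("assignments missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(assignments) == 0L) stop("empty assignment table")
  un <- is.na(assignments$haplogroup) | assignments$haplogroup == ""
  if (any(un)) {
    stop("unassigned sample(s): ",
         paste(assignments$sample_id[un], collapse = ", "))
  }
  counts <- table(assignments$population, assignments$haplogroup)
  counts <- unclass(counts)
  freqs <- counts / rowSums(counts)
  list(counts = counts, frequencies = freqs)
}

#' Over-representation chi-squared test of a clade in populations
#'
#' Pearson chi-squared (no continuity correction) on the presence/absence x
#' population table for a focal clade; degrees of freedom follow the table
#' shape and are printed alongside the statistic.
#'
#' @param counts Populations x haplogroups count matrix (from
#'   [haplogroup_frequency_table()]).
#' @param focal_clade Column name of the focal haplogroup.
#' @return List with `chi2`, `df`, `p`, `table`.
#' @export
overrepresentation_chi2 <- function(counts, focal_clade) {
  if (!focal_clade %in% colnames(counts)) {
    stop("focal clade not in table: ", focal_clade)
  }
  inc <- counts[, focal_clade]
  outc <- rowSums(counts) - inc
  tab <- cbind(in_clade = inc, out_clade = outc)
  if (sum(tab) == 0) stop("all-zero table")
  suppressWarnings(
    ct <- stats::chisq.test(tab, correct = FALSE)
  )
  list(
    chi2 = unname(ct$statistic),
    df = unname(ct$parameter),
    p = ct$p.value,
    table = tab
  )
}

# Pairwise absolute difference matrix between sequences (pairwise deletion).
pairwise_diff_matrix <- function(seqs) {
  d <- ape::dist.dna(seqs_to_DNAbin(seqs), model = "N",
                     pairwise.deletion = TRUE)
  as.matrix(d)
}

# AMOVA variance components for haploid sequences over populations, using
# pairwise differences as squared distances (the standard PhiST convention).
amova_components <- function(d2, pop) {
  pop <- as.character(pop)
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ssd_total <- sum(d2[upper.tri(d2)]) / N
  ssd_wp <- 0
  n_p <- integer(P)
  for (i in seq_along(pops)) {
    idx <- which(pop == pops[i])
    n_p[i] <- length(idx)
    if (length(idx) > 1L) {
      sub <- d2[idx, idx, drop = FALSE]
      ssd_wp <- ssd_wp + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ssd_ap <- ssd_total - ssd_wp
  df_ap <- P - 1L
  df_wp <- N - P
  msd_ap <- ssd_ap / df_ap
  msd_wp <- if (df_wp > 0L) ssd_wp / df_wp else 0
  n0 <- (N - sum(n_p^2) / N) / df_ap
  sigma_w <- msd_wp
  sigma_a <- (msd_ap - sigma_w) / n0
  list(sigma_a = sigma_a, sigma_w = sigma_w,
       phist = sigma_a / (sigma_a + sigma_w),
       ssd_total = ssd_total, ssd_among = ssd_ap, ssd_within = ssd_wp)
}

#' Pairwise PhiST matrix between populations
#'
#' AMOVA-based PhiST from the pairwise sequence-difference matrix: the among-
#' population fraction of the total molecular variance, computed for every
#' population pair. Populations with fewer than 2 samples are excluded with a
#' warning.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param populations Character vector of population labels, parallel to
#'   `seqs`.
#' @return Symmetric PhiST matrix with population dimnames.
#' @export
phist <- function(seqs, populations) {
  stopifnot(length(seqs) == length(populations))
  tab <- table(populations)
  small <- names(tab)[tab < 2L]
  if (length(small) > 0L) {
    warning("excluding population(s) with n < 2: ",
            paste(small, collapse = ", "))
    keep <- !populations %in% small
    seqs <- seqs[keep]
    populations <- populations[keep]
  }
  pops <- unique(populations)
  if (length(pops) < 2L) stop("need at least two populations with n >= 2")
  d2 <- pairwise_diff_matrix(seqs)
  P <- length(pops)
  out <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1L)) {
    for (j in (i + 1L):P) {
      idx <- which(populations %in% c(pops[i], pops[j]))
      comp <- amova_components(d2[idx, idx, drop = FALSE], populations[idx])
      out[i, j] <- out[j, i] <- comp$phist
    }
  }
  out
}

#' Great-circle distance matrix in km
#'
#' Haversine distances on the mean-radius sphere (R = 6371.0088 km), a
#' documented approximation to the ellipsoidal geodesic (discrepancy < 0.6%).
#' Pairs with missing coordinates get NA and are flagged.
#'
#' @param lat,lon Numeric vectors of decimal-degree coordinates.
#' @param labels Optional dimnames.
#' @return Symmetric distance matrix in km; attribute `missing` lists indices
#'   with missing coordinates.
#' @export
geographic_distance <- function(lat, lon, labels = NULL) {
  stopifnot(length(lat) == length(lon))
  ok_range <- (is.na(lat) | abs(lat) <= 90) & (is.na(lon) | abs(lon) <= 180)
  if (!all(ok_range)) stop("coordinates out of range")
  n <- length(lat)
  miss <- which(is.na(lat) | is.na(lon))
  pts <- cbind(lon, lat)
  m <- geosphere::distm(pts, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371008.8)
  }) / 1000
  if (length(miss) > 0L) {
    m[miss, ] <- NA
    m[, miss] <- NA
    diag(m) <- 0
  }
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  attr(m, "missing") <- miss
  m
}

#' Mantel test of matrix correlation (isolation by distance)
#'
#' Pearson correlation over the lower triangles, with significance from
#' simultaneous row/column permutations of one matrix:
#' `p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)`.
#'
#' @param genetic,geographic Symmetric matrices with matching dimensions and
#'   ordering.
#' @param n_perm Number of permutations (default 999).
#' @param seed Random seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(genetic, geographic, n_perm = 999L, seed = NULL) {
  genetic <- as.matrix(genetic)
  geographic <- as.matrix(geographic)
  if (!all(dim(genetic) == dim(geographic))) {
    stop("matrix dimensions differ")
  }
  if (nrow(genetic) < 3L) stop("need at least 3 populations")
  if (!is.null(seed)) set.seed(seed)
  res <- vegan::mantel(stats::as.dist(genetic), stats::as.dist(geographic),
                       method = "pearson", permutations = n_perm)
  list(r = unname(res$statistic), p = res$signif, n_perm = n_perm)
}

#' Diversity-versus-latitude regression
#'
#' Ordinary least squares of a per-population diversity index on the mean
#' latitude of its samples, with the two-sided slope test.
#'
#' @param diversity Numeric vector of per-population diversity values.
#' @param mean_latitude Numeric vector of mean latitudes, parallel to
#'   `diversity`.
#' @return List with `slope`, `intercept`, `r`, `p`, `n`.
#' @export
diversity_latitude_regression <- function(diversity, mean_latitude) {
  stopifnot(length(diversity) == length(mean_latitude))
  ok <- !is.na(diversity) & !is.na(mean_latitude)
  diversity <- diversity[ok]
  mean_latitude <- mean_latitude[ok]
  if (length(diversity) < 3L) stop("need at least three populations")
  if (stats::sd(mean_latitude) == 0) stop("zero latitude variance")
  fit <- stats::lm(diversity ~ mean_latitude)
  sm <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r = unname(stats::cor(diversity, mean_latitude)),
    p = sm$coefficients[2L, 4L],
    n = length(diversity)
  )
}
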