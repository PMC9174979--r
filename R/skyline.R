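# Classic / generalized skyline estimate of effective population size through
# time from a dated, ultrametric genealogy. This is the non-Bayesian
# counterpart of skyline plots from MCMC tree samples: per coalescent interval
# with k lineages and length dt, Ne = k(k-1)/2 * dt / generation_time.

#' Classic (or generalized) skyline trajectory
#'
#' @param dated_tree Ultrametric `phylo` with branch lengths in years and all
#'   tips at time 0.
#' @param generation_time Generation time in years (default 1).
#' @param epsilon Grouping parameter of the generalized skyline (0 = classic:
#'   one epoch per coalescent interval; larger values pool short adjacent
#'   intervals).
#' @return An object of class `skyline_trajectory`: data.frame with epochs
#'   `t_start` (recent bound, years before present), `t_end` (older bound) and
#'   `Ne`, ordered from the present backward; attributes `generation_time`,
#'   `n_tips`, `root_height`.
#' @export
classic_skyline <- function(dated_tree, generation_time = 1, epsilon = 0) {
  stopifnot(inherits(dated_tree, "phylo"))
  if (!ape::is.ultrametric(dated_tree, tol = 1e-6)) {
    stop("skyline requires an ultrametric dated tree (all tips at time 0)")
  }
  if (length(dated_tree$tip.label) == 2L) {
    # single coalescent interval; k(k-1)/2 = 1
    T_root <- max(node_heights(dated_tree))
    out <- data.frame(t_start = 0, t_end = T_root,
                      Ne = T_root / generation_time)
    return(structure(out,
                     class = c("skyline_trajectory", "data.frame"),
                     generation_time = generation_time, n_tips = 2L,
                     root_height = T_root))
  }
  if (!ape::is.binary(dated_tree)) {
    # multifurcations (e.g. collapsed haplogroup trees) become stacks of
    # zero-length intervals, which are dropped from the epoch table below
    dated_tree <- ape::multi2di(dated_tree, random = FALSE)
  }
  ci <- ape::coalescent.intervals(dated_tree)
  sk <- ape::skyline(ci, epsilon = epsilon)
  t_end <- cumsum(sk$interval.length)
  t_start <- c(0, t_end[-length(t_end)])
  out <- data.frame(
    t_start = t_start,
    t_end = t_end,
    Ne = sk$population.size / generation_time
  )
  keep <- (out$t_end - out$t_start) > 1e-9 * sum(sk$interval.length)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(
    out,
    class = c("skyline_trajectory", "data.frame"),
    generation_time = generation_time,
    n_tips = length(dated_tree$tip.label),
    root_height = sum(ci$interval.length)
  )
}

#' Harmonic mean of a skyline trajectory (time-weighted)
#'
#' A single-number summary of the trajectory; for a constant-size coalescent
#' this estimates Ne.
#'
#' @param trajectory A `skyline_trajectory`.
#' @return Harmonic mean Ne over time.
#' @export
skyline_harmonic_mean <- function(trajectory) {
  stopifnot(inherits(trajectory, "skyline_trajectory"))
  w <- trajectory$t_end - trajectory$t_start
  sum(w) / sum(w / trajectory$Ne)
}

#' @export
print.skyline_trajectory <- function(x, ...) {
  cat(sprintf(
    "Skyline trajectory: %d epoch(s) from %d tips, root height %.1f years\n",
    nrow(x), attr(x, "n_tips"), attr(x, "root_height")
  ))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

#' Step plot of a skyline trajectory
#'
#' @param x A `skyline_trajectory`.
#' @param max_time Optional cap on the time axis in years (older epochs are
#'   clipped from the display only).
#' @param log_ne Plot Ne on a log scale (default TRUE).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.skyline_trajectory <- function(x, max_time = NULL, log_ne = TRUE, ...) {
  df <- as.data.frame(x)
  if (!is.null(max_time)) {
    df <- df[df$t_start < max_time, , drop = FALSE]
    df$t_end <- pmin(df$t_end, max_time)
  }
  tx <- as.vector(rbind(df$t_start, df$t_end))
  ne <- as.vector(rbind(df$Ne, df$Ne))
  graphics::plot(tx, ne, type = "l",
                 log = if (log_ne) "y" else "",
                 xlab = "years before present",
                 ylab = "effective population size", ...)
  invisible(x)
}

#' Write a skyline trajectory to TSV
#'
#' @param trajectory A `skyline_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_skyline <- function(trajectory, path) {
  utils::write.table(as.data.frame(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
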