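# Config-driven orchestration: regions -> profiles -> tree -> dating ->
# skyline -> dN/dS -> population statistics, with a manifest and a summary
# JSON. Stages abort with the stage name on failure; partial outputs are kept
# with a .partial marker.

#' Pipeline configuration
#'
#' @param input Either a list of paths (`fasta`, `reference`, `metadata`,
#'   `annotation`) or an in-memory list (`sequences`, `reference`,
#'   `metadata`, `annotation`).
#' @param outgroups Names of outgroup sequences in the input FASTA.
#' @param scheme Region scheme (default: coding region).
#' @param clock A [clock_model()].
#' @param cutoff_age_years dN/dS partition cutoff (default 11,700).
#' @param bootstrap_replicates Bootstrap replicates for clade support
#'   (0 = skip).
#' @param mantel_permutations Permutations for the Mantel test.
#' @param run_ml Also run strict-clock ML dating (default FALSE; rho dating
#'   always runs).
#' @param min_clade_size,min_defining_mutations Haplogroup labelling control.
#' @param seed Seed governing every stochastic stage.
#' @param out_dir Output directory (NULL = no files written).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, outgroups,
                            scheme = coding_region_scheme(),
                            clock = clock_model(),
                            cutoff_age_years = 11700,
                            bootstrap_replicates = 0L,
                            mantel_permutations = 999L,
                            run_ml = FALSE,
                            min_clade_size = 2L,
                            min_defining_mutations = 1L,
                            seed = 1L,
                            out_dir = NULL) {
  structure(
    list(
      input = input, outgroups = outgroups, scheme = scheme, clock = clock,
      cutoff_age_years = cutoff_age_years,
      bootstrap_replicates = as.integer(bootstrap_replicates),
      mantel_permutations = as.integer(mantel_permutations),
      run_ml = isTRUE(run_ml),
      min_clade_size = as.integer(min_clade_size),
      min_defining_mutations = as.integer(min_defining_mutations),
      seed = as.integer(seed),
      out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips the path-based fields losslessly; in-memory inputs cannot be
#' serialised and are rejected.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  if (!is.null(config$input$sequences)) {
    stop("in-memory inputs cannot be written to YAML")
  }
  obj <- list(
    input = config$input,
    outgroups = config$outgroups,
    scheme = list(starts = config$scheme$starts, ends = config$scheme$ends,
                  label = config$scheme$label),
    clock = list(rate = config$clock$rate_per_site_per_year,
                 region_length = config$clock$region_length,
                 kappa = config$clock$kappa, alpha = config$clock$alpha,
                 ncat = config$clock$ncat),
    cutoff_age_years = config$cutoff_age_years,
    bootstrap_replicates = config$bootstrap_replicates,
    mantel_permutations = config$mantel_permutations,
    run_ml = config$run_ml,
    min_clade_size = config$min_clade_size,
    min_defining_mutations = config$min_defining_mutations,
    seed = config$seed,
    out_dir = config$out_dir
  )
  yaml::write_yaml(obj, path)
  path
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  pipeline_config(
    input = obj$input,
    outgroups = obj$outgroups,
    scheme = region_scheme(obj$scheme$starts, obj$scheme$ends,
                           obj$scheme$label),
    clock = clock_model(rate_per_site_per_year = obj$clock$rate,
                        region_length = obj$clock$region_length,
                        kappa = obj$clock$kappa, alpha = obj$clock$alpha,
                        ncat = obj$clock$ncat),
    cutoff_age_years = obj$cutoff_age_years,
    bootstrap_replicates = obj$bootstrap_replicates,
    mantel_permutations = obj$mantel_permutations,
    run_ml = obj$run_ml,
    min_clade_size = obj$min_clade_size,
    min_defining_mutations = obj$min_defining_mutations,
    seed = obj$seed,
    out_dir = obj$out_dir
  )
}

# Profile of a region string against a region-string baseline.
region_profile <- function(region_seq, baseline_region, positions,
                           sample_id = "sample", scheme_label = "region") {
  s <- strsplit(region_seq, "", fixed = TRUE)[[1L]]
  r <- strsplit(baseline_region, "", fixed = TRUE)[[1L]]
  missing_sites <- positions[s == "N"]
  indel_sites <- positions[s == "-" | r == "-"]
  ok <- s %in% c("A", "C", "G", "T") & r %in% c("A", "C", "G", "T")
  diff <- ok & s != r
  subs <- data.frame(
    position_np = positions[diff], ref = r[diff], alt = s[diff],
    stringsAsFactors = FALSE
  )
  subs$kind <- if (nrow(subs) > 0L) substitution_kind(subs$ref, subs$alt) else
    character(0)
  new_haplotype_profile(sample_id, scheme_label, subs, missing_sites,
                        indel_sites)
}

#' Short top-level haplogroup label (leading letters) of a nested label
#' @param label Haplogroup label (e.g. "A1a2").
#' @return The leading letter block ("A"), or the label itself for "root".
#' @export
major_haplogroup <- function(label) {
  ifelse(label == "root", "root", sub("^([A-Z]+).*$", "\\1", label))
}

#' Run the full analysis pipeline
#'
#' Stages in order: region extraction, reference-relative profiles, haplotype
#' collapsing, MP tree with mutation annotation, haplogroup definition and
#' per-sample assignment, rho (and optionally strict-clock ML) dating,
#' skyline demography on the dated genealogy, time-partitioned dN/dS, and
#' population statistics (diversity, haplogroup frequencies, PhiST, Mantel
#' IBD, diversity-latitude regression). Every stochastic stage is seeded from
#' `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @param annotation Optional `reference_annotation` (overrides
#'   `config$input$annotation`; default: the packaged annotation).
#' @return A list bundle with one element per stage plus `summary` and
#'   `manifest`.
#' @export
run_pipeline <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  bundle <- list()
  stage_times <- c()
  out_dir <- config$out_dir
  marker <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    marker <- file.path(out_dir, ".partial")
    file.create(marker)
  }
  run_stage <- function(name, fun) {
    ts <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), ts,
                                                units = "secs"))
    res
  }

  inputs <- run_stage("inputs", function() {
    inp <- config$input
    if (!is.null(inp$sequences)) {
      seqs <- inp$sequences
      reference <- inp$reference
      metadata <- validate_metadata(inp$metadata)
    } else {
      seqs <- read_fasta(inp$fasta)
      reference <- read_fasta(inp$reference)[[1L]]
      metadata <- read_metadata(inp$metadata)
    }
    ann <- annotation
    if (is.null(ann)) {
      ann <- if (!is.null(config$input$annotation) &&
                 is.character(config$input$annotation)) {
        read_annotation(config$input$annotation)
      } else if (inherits(config$input$annotation,
                          "reference_annotation")) {
        config$input$annotation
      } else {
        swallow_annotation()
      }
    }
    og <- intersect(config$outgroups, names(seqs))
    if (length(og) == 0L) stop("no outgroup sequences found in input")
    list(seqs = seqs, reference = reference, metadata = metadata,
         annotation = ann, outgroups = og)
  })

  scheme <- config$scheme
  positions <- region_positions(scheme)

  profiles <- run_stage("profiles", function() {
    samples <- setdiff(names(inputs$seqs), inputs$outgroups)
    lapply(stats::setNames(samples, samples), function(id) {
      diff_to_reference(inputs$seqs[[id]], inputs$reference, scheme,
                        sample_id = id)
    })
  })
  bundle$profiles <- profiles

  haplo <- run_stage("haplotypes", function() {
    cl <- collapse_haplotypes(profiles)
    vs <- variable_sites(profiles)
    list(collapse = cl, variable = vs)
  })
  bundle$haplotypes <- haplo

  tree <- run_stage("tree", function() {
    reps <- haplo$collapse$representative
    hap_seqs <- vapply(reps, function(id) {
      extract_region(inputs$seqs[[id]], scheme)
    }, character(1))
    names(hap_seqs) <- reps
    og_seqs <- vapply(inputs$outgroups, function(id) {
      extract_region(inputs$seqs[[id]], scheme)
    }, character(1))
    x <- build_mp_tree(hap_seqs, og_seqs, positions = positions)
    replay_mutations(x)
    x
  })
  bundle$tree <- tree

  haplogroups <- run_stage("haplogroups", function() {
    defs <- define_haplogroups(tree, config$min_clade_size,
                               config$min_defining_mutations)
    root_region <- extract_region(
      apply_profile(
        new_haplotype_profile("root", scheme$label,
                              data.frame(position_np = integer(0),
                                         ref = character(0),
                                         alt = character(0),
                                         kind = character(0))),
        inputs$reference
      ), scheme
    )
    assignments <- lapply(profiles, function(p) {
      # rebase the reference-relative profile onto the ingroup-ancestor state
      sample_region <- extract_region(apply_profile(p, inputs$reference),
                                      scheme)
      pr <- region_profile(sample_region, tree$root_state, positions,
                           p$sample_id, scheme$label)
      pr$missing_sites <- p$missing_sites
      assign_haplogroup(pr, defs)
    })
    lab <- vapply(assignments, `[[`, character(1), "label")
    tab <- data.frame(
      sample_id = names(assignments),
      haplogroup = unname(lab),
      major = major_haplogroup(unname(lab)),
      stringsAsFactors = FALSE
    )
    list(definitions = defs, assignments = tab)
  })
  bundle$haplogroups <- haplogroups

  support <- NULL
  if (config$bootstrap_replicates > 0L) {
    support <- run_stage("bootstrap", function() {
      bootstrap_support(tree, n_replicates = config$bootstrap_replicates,
                        seed = config$seed + 11L)
    })
  }
  bundle$bootstrap <- support

  dating <- run_stage("dating", function() {
    ages <- rho_ages(tree, config$clock)
    dated <- date_tree_rho(tree, config$clock)
    ml <- NULL
    if (config$run_ml) {
      clade <- ape::extract.clade(tree$tree, tree$ingroup_node)
      ml <- ml_clock_ages(clade, tree$alignment, config$clock)
    }
    list(rho = ages, dated_tree = dated, ml = ml)
  })
  bundle$dating <- dating

  sky <- run_stage("skyline", function() {
    classic_skyline(dating$dated_tree, generation_time = 1)
  })
  bundle$skyline <- sky

  dnds <- run_stage("dnds", function() {
    cls <- classify_tree_mutations(tree, inputs$annotation)
    ntip <- length(tree$tree$tip.label)
    age_of <- stats::setNames(dating$rho$age_years,
                              as.character(dating$rho$node))
    tips0 <- stats::setNames(rep(0, ntip), as.character(seq_len(ntip)))
    node_ages <- c(age_of, tips0)
    dated_nodes <- names(node_ages)
    keep <- as.character(cls$parent) %in% dated_nodes &
      as.character(cls$child) %in% dated_nodes
    cls_in <- cls[keep, , drop = FALSE]
    sites <- count_sites_genes(function(np) {
      col <- match(np, positions)
      if (is.na(col)) return("N")
      substring(tree$root_state, col, col)
    }, inputs$annotation, on_stop = "skip")
    stat <- dnds_partitioned(cls_in, node_ages, sites$total,
                             cutoff_age_years = config$cutoff_age_years,
                             n_tips = ntip)
    list(classified = cls, stat = stat, site_counts = sites)
  })
  bundle$dnds <- dnds

  popgen <- run_stage("popgen", function() {
    md <- inputs$metadata
    samples <- md$sample_id
    region_seqs <- vapply(samples, function(id) {
      extract_region(inputs$seqs[[id]], scheme)
    }, character(1))
    names(region_seqs) <- samples
    div_all <- nucleotide_diversity(region_seqs)
    pop_of <- stats::setNames(md$population, md$sample_id)
    pops <- unique(md$population)
    per_pop <- lapply(pops, function(pp) {
      ids <- md$sample_id[md$population == pp]
      if (length(ids) < 2L) return(NULL)
      dv <- nucleotide_diversity(region_seqs[ids])
      hap_keys <- vapply(profiles[ids], function(p) {
        paste(profile_tokens(p), collapse = ";")
      }, character(1))
      data.frame(
        population = pp, n = length(ids), pi = dv$pi,
        mean_pairwise_diff = dv$mean_pairwise_diff,
        hd = haplotype_diversity(as.integer(table(hap_keys))),
        mean_latitude = mean(md$latitude[md$population == pp]),
        stringsAsFactors = FALSE
      )
    })
    per_pop <- do.call(rbind, per_pop)
    assignments <- haplogroups$assignments
    assignments$population <- pop_of[assignments$sample_id]
    freq <- haplogroup_frequency_table(data.frame(
      sample_id = assignments$sample_id,
      population = assignments$population,
      haplogroup = assignments$major,
      stringsAsFactors = FALSE
    ))
    keep_pops <- names(which(table(md$population) >= 2L))
    keep_ids <- md$sample_id[md$population %in% keep_pops]
    ph <- suppressWarnings(
      phist(region_seqs[keep_ids], pop_of[keep_ids])
    )
    pop_coords <- do.call(rbind, lapply(rownames(ph), function(pp) {
      data.frame(lat = mean(md$latitude[md$population == pp]),
                 lon = mean(md$longitude[md$population == pp]))
    }))
    geo <- geographic_distance(pop_coords$lat, pop_coords$lon,
                               labels = rownames(ph))
    mt <- if (nrow(ph) >= 3L) {
      mantel_test(ph, geo, n_perm = config$mantel_permutations,
                  seed = config$seed + 23L)
    } else {
      NULL
    }
    reg <- if (!is.null(per_pop) && nrow(per_pop) >= 3L &&
               stats::sd(per_pop$mean_latitude) > 0) {
      diversity_latitude_regression(per_pop$pi, per_pop$mean_latitude)
    } else {
      NULL
    }
    list(diversity_all = div_all, diversity_by_population = per_pop,
         haplogroup_frequencies = freq, phist = ph, geographic_km = geo,
         mantel = mt, latitude_regression = reg)
  })
  bundle$popgen <- popgen

  bundle$summary <- list(
    n_samples = length(profiles),
    n_outgroups = length(inputs$outgroups),
    distinct_haplotypes = haplo$collapse$distinct_count,
    variable_sites = haplo$variable$count,
    parsimony_score = tree$parsimony_score,
    root_age_rho = dating$rho$age_years[
      dating$rho$node == tree$ingroup_node
    ],
    pi = popgen$diversity_all$pi,
    mean_pairwise_diff = popgen$diversity_all$mean_pairwise_diff,
    dnds_young = dnds$stat$dnds_young,
    dnds_old = dnds$stat$dnds_old,
    dnds_fisher_p = dnds$stat$fisher_p,
    mantel_r = if (!is.null(popgen$mantel)) popgen$mantel$r else NA,
    mantel_p = if (!is.null(popgen$mantel)) popgen$mantel$p else NA,
    seed = config$seed
  )
  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("mitophylo")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    stage_seconds = as.list(stage_times),
    started = format(t0), finished = format(Sys.time())
  )

  if (!is.null(out_dir)) {
    write_mp_tree(tree, out_dir, haplogroups$definitions)
    ape::write.tree(dating$dated_tree,
                    file = file.path(out_dir, "dated_tree.nwk"))
    utils::write.table(dating$rho, file.path(out_dir, "node_ages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_skyline(sky, file.path(out_dir, "skyline.tsv"))
    utils::write.table(dnds$classified,
                       file.path(out_dir, "mutation_classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(haplogroups$assignments,
                       file.path(out_dir, "haplogroup_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(popgen$diversity_by_population)) {
      utils::write.table(popgen$diversity_by_population,
                         file.path(out_dir, "diversity_by_population.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(as.data.frame(popgen$phist),
                       file.path(out_dir, "phist.tsv"),
                       sep = "\t", quote = FALSE, row.names = TRUE)
    jsonlite::write_json(bundle$summary,
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(bundle$manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(marker)) unlink(marker)
  }
  bundle
}
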