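# End-to-end orchestration: classify -> quantify -> curate -> place ->
# beta-statistics, with a manifest recording seeds and the sample-count
# funnel (input -> contamination-screened -> geographically merged ->
# minimum-nifD/K depth) at each stage.

#' Pipeline configuration
#'
#' Collects the per-module configurations, the placement and statistics
#' parameters, and the root seed from which all stage seeds derive.
#'
#' @param seed Root seed.
#' @param synth A [synth_config()].
#' @param classify A [classify_config()] (nucleotide prescreen enabled by
#'   default here; the pipeline's reads come from the bundled generator,
#'   whose divergence from the references is far below the prescreen's
#'   sensitivity limit).
#' @param curation A [curation_config()].
#' @param beta,tau,gamma Placement parameters (see [place_read()],
#'   [annotate_placement()]).
#' @param n_perm PERMANOVA label permutations (default 999).
#' @param nmds_restarts NMDS random restarts.
#' @param alpha Significance level for pairwise tests.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            synth = synth_config(),
                            classify = classify_config(nt_prefilter = TRUE),
                            curation = curation_config(),
                            beta = 0.5, tau = 0.8, gamma = 0.05,
                            n_perm = 999L, nmds_restarts = 10L,
                            alpha = 0.05) {
  structure(list(seed = as.integer(seed), synth = synth, classify = classify,
                 curation = curation, beta = beta, tau = tau, gamma = gamma,
                 n_perm = n_perm, nmds_restarts = nmds_restarts, alpha = alpha),
            class = "pipeline_config")
}

#' Simulate a complete multi-environment study
#'
#' Builds one reference set and simulates `n_aerobic` + `n_anaerobic`
#' samples spread over the three aerobic (cropland, forest, grassland) and
#' three anaerobic (paddy, sediment, tundra) categories, each at a distinct
#' sampling site (>= 10 km apart) with optional sub-kilometre replicates.
#'
#' @param config A [pipeline_config()].
#' @param n_aerobic,n_anaerobic Sample counts per oxygen group.
#' @param replicates_per_site Reads-bearing replicates per site (each
#'   replicate gets `n_reads` reads).
#' @param n_reads Reads per sample (default from the synth config).
#' @param lazy_reads When `TRUE`, each sample's `reads` field is a
#'   zero-argument function that simulates the reads on demand (same seeds,
#'   identical output); the pipeline then only ever holds one sample's
#'   reads in memory, which keeps full-scale studies well inside a few GB.
#' @return List: `refset`, `samples` (each with `reads`, `metadata`,
#'   `community`).
#' @export
simulate_study <- function(config = pipeline_config(), n_aerobic = 20L,
                           n_anaerobic = 20L, replicates_per_site = 1L,
                           n_reads = NULL, lazy_reads = FALSE) {
  seed <- config$seed
  refset <- simulate_reference_set(seed = derive_seed(seed, "refset"),
                                   config = config$synth)
  envs <- c(rep(c("cropland", "forest", "grassland"), length.out = n_aerobic),
            rep(c("paddy", "sediment", "tundra"), length.out = n_anaerobic))
  n_sites <- length(envs)
  meta <- simulate_geo_metadata(n_sites, replicates_per_site,
                                jitter_km = 0.4,
                                seed = derive_seed(seed, "geo"), envs = envs)
  samples <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    comm <- simulate_community(refset, meta$env[i], config$synth,
                               seed = derive_seed(seed, paste0("comm", meta$site[i])),
                               sample_id = sid)
    rseed <- derive_seed(seed, paste0("reads", sid))
    reads <- if (lazy_reads) {
      local({
        comm_i <- comm; seed_i <- rseed; n_i <- n_reads
        function() simulate_reads(refset, comm_i, n_reads = n_i, seed = seed_i)
      })
    } else simulate_reads(refset, comm, n_reads = n_reads, seed = rseed)
    samples[[i]] <- list(
      reads = reads,
      metadata = list(sample_id = sid, env = meta$env[i],
                      lat = meta$lat[i], lon = meta$lon[i]),
      community = comm)
  }
  list(refset = refset, samples = samples)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_diazo("pipeline stage '", name, "' failed: ", conditionMessage(e),
               class = "diazo_stage_error"))
}

#' Run the full analysis end to end
#'
#' Classifies every sample against the reference database, computes
#' nitrogenase dominance ratios, curates samples (contamination screen,
#' sub-kilometre merging, minimum nifD/K depth), places nifD and nifK
#' reads on their reference trees, and computes the beta-diversity and
#' group-comparison statistics. All randomness derives from the config's
#' root seed; a rerun with the same inputs and config is identical.
#'
#' @param refset A `diazo_refset` (or a list with `db` and refpkg inputs).
#' @param samples List of `list(reads, metadata)` as from
#'   [simulate_study()].
#' @param config A [pipeline_config()].
#' @return Object of class `diazo_results`.
#' @export
run_end_to_end <- function(refset, samples, config = pipeline_config()) {
  db <- refset$db
  idx <- run_stage("index", classifier_index(db, config$classify))

  profiles <- run_stage("classify", lapply(samples, function(s) {
    reads <- if (is.function(s$reads)) s$reads() else s$reads
    p <- profile_sample(reads, db, s$metadata, config$classify, idx)
    rm(reads)
    p
  }))
  n_input <- length(profiles)

  cf <- run_stage("contamination", contamination_filter(profiles, config$curation))
  n_clean <- length(cf$kept)

  mg <- run_stage("cluster", merge_by_location(cf$kept, config$curation))
  merged <- mg$profiles
  n_merged <- length(merged)

  ratios <- run_stage("quantify", nif_ratio_table(merged, db))
  ratios$group <- unname(env_groups()[ratios$env])

  grp <- split(ratios$ratio[ratios$usable], ratios$group[ratios$usable])
  bm_groups <- if (length(grp) == 2 && all(lengths(grp) >= 2)) {
    run_stage("bm", suppressWarnings(
      brunner_munzel(grp$aerobic, grp$anaerobic,
                     seed = derive_seed(config$seed, "bm"))))
  } else NULL
  fold <- if (length(grp) == 2 && all(lengths(grp) >= 1))
    mean(grp$anaerobic) / mean(grp$aerobic) else NA_real_
  env_split <- split(ratios$ratio[ratios$usable], ratios$env[ratios$usable])
  bm_pairwise <- if (sum(lengths(env_split) >= 2) >= 2) {
    run_stage("bm_pairwise", suppressWarnings(
      pairwise_bm_bonferroni(env_split[lengths(env_split) >= 2],
                             alpha = config$alpha,
                             seed = derive_seed(config$seed, "bmp"))))
  } else NULL

  deep <- run_stage("min_nifdk", min_nifdk_filter(merged, config$curation))
  n_deep <- length(deep)

  place_res <- list(); dms <- list(); avg_dm <- NULL
  ord <- NULL; pmv <- NULL; fam_tab <- NULL
  if (n_deep >= 2) {
    pkgs <- run_stage("refpkg", list(nifD = build_refpkg(refset, "nifD"),
                                     nifK = build_refpkg(refset, "nifK")))
    place_res <- run_stage("place", lapply(pkgs, function(pk)
      lapply(deep, place_sample, pkg = pk, beta = config$beta,
             tau = config$tau, gamma = config$gamma)))
    for (f in names(place_res))
      names(place_res[[f]]) <- vapply(deep, `[[`, "", "sample_id")
    usable_pl <- Reduce(intersect, lapply(place_res, function(pl)
      names(pl)[vapply(pl, function(p) p$n_reads > 0, NA)]))
    if (length(usable_pl) >= 2) {
      dms <- run_stage("unifrac", lapply(names(place_res), function(f)
        unifrac_matrix(place_res[[f]][usable_pl], pkgs[[f]]$tree)))
      names(dms) <- names(place_res)
      avg_dm <- average_marker_distance(dms$nifD, dms$nifK)
      ord <- run_stage("nmds", nmds(avg_dm, dims = 2,
                                    n_restarts = config$nmds_restarts,
                                    seed = derive_seed(config$seed, "nmds")))
      lab <- unname(env_groups()[vapply(deep, `[[`, "", "env")[
        match(usable_pl, vapply(deep, `[[`, "", "sample_id"))]])
      if (length(unique(lab)) >= 2)
        pmv <- run_stage("permanova",
                         permanova(avg_dm, lab, n_perm = config$n_perm,
                                   seed = derive_seed(config$seed, "permanova")))
      fam_tab <- do.call(rbind, lapply(usable_pl, function(sid) {
        fc <- family_composition(list(place_res$nifD[[sid]],
                                      place_res$nifK[[sid]]))
        if (!length(fc)) return(NULL)
        data.frame(sample_id = sid, family = names(fc), fraction = unname(fc),
                   stringsAsFactors = FALSE)
      }))
    }
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("diazoscope")),
    funnel = c(input = n_input, post_contamination = n_clean,
               post_clustering = n_merged, min_nifdk = n_deep))

  structure(list(profiles = profiles, excluded = cf$excluded,
                 clusters = mg$clusters, merged = merged,
                 ratios = ratios, fold_anaerobic_vs_aerobic = fold,
                 bm_groups = bm_groups, bm_pairwise = bm_pairwise,
                 deep = deep, placements = place_res, unifrac = dms,
                 avg_unifrac = avg_dm, nmds = ord, permanova = pmv,
                 family_table = fam_tab, manifest = manifest,
                 config = config), class = "diazo_results")
}

#' @export
print.diazo_results <- function(x, ...) {
  f <- x$manifest$funnel
  cat("diazoscope results\n")
  cat("  funnel:", paste(sprintf("%s=%d", names(f), f), collapse = " -> "), "\n")
  cat("  anaerobic/aerobic ratio fold:",
      format(x$fold_anaerobic_vs_aerobic, digits = 4), "\n")
  if (!is.null(x$bm_groups))
    cat("  aerobic vs anaerobic BM p:",
        format(x$bm_groups$p.value, digits = 4), "\n")
  if (!is.null(x$permanova))
    cat("  PERMANOVA R2:", format(x$permanova$R2, digits = 4),
        "p:", format(x$permanova$p.value, digits = 4), "\n")
  invisible(x)
}

#' Tidy tables for the figure-level summaries
#'
#' @param results A `diazo_results`.
#' @return List: `ratio_table` (sample, env, group, ratio, pseudo_flag) and
#'   `family_table` (sample, family, fraction; empty when no sample passed
#'   the depth filter).
#' @export
export_figure_tables <- function(results) {
  rt <- results$ratios[, c("sample_id", "env", "group", "ratio",
                           "pseudo_flag")]
  ft <- results$family_table %||%
    data.frame(sample_id = character(0), family = character(0),
               fraction = numeric(0))
  list(ratio_table = rt, family_table = ft)
}
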