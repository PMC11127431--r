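# Sample-level curation: 16S-based contamination exclusion, sub-kilometre
# geographic clustering and merging of redundant samples, and the minimum
# nifD/K read depth filter applied before taxonomic analyses.

#' Curation configuration
#'
#' @param ... Named overrides. Fields: `max_lactobacillales_frac` and
#'   `max_chloroplast_frac` (16S-fraction exclusion thresholds, default
#'   0.25 each), `cluster_radius_km` (samples strictly closer than this are
#'   clustered, default 1), `min_nifdk_reads` (combined nifD+nifK floor for
#'   taxonomic analyses, default 50, inclusive), `earth_radius_km` (mean
#'   Earth radius used by the haversine distance).
#' @return Named list.
#' @export
curation_config <- function(...) {
  cfg <- list(max_lactobacillales_frac = 0.25, max_chloroplast_frac = 0.25,
              cluster_radius_km = 1.0, min_nifdk_reads = 50L,
              earth_radius_km = 6371.0088)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  assert_that(length(bad) == 0, "unknown curation option(s): ",
              paste(bad, collapse = ", "), class = "diazo_config_error")
  cfg[names(ov)] <- ov
  assert_that(all(unlist(cfg) > 0) && is.finite(cfg$cluster_radius_km),
              "curation thresholds must be positive and finite",
              class = "diazo_config_error")
  cfg
}

ssu_fraction <- function(profile, what = c("lactobacillales", "chloroplast")) {
  what <- match.arg(what)
  if (!nrow(profile$ssu) || sum(profile$ssu$count) == 0) return(NA_real_)
  lin <- profile$ssu$lineage
  hit <- if (what == "lactobacillales") {
    lineage_at(lin, "order") %in% "Lactobacillales"
  } else {
    vapply(lineage_split(lin), function(p) any(p == "Chloroplast"), NA)
  }
  sum(profile$ssu$count[hit]) / sum(profile$ssu$count)
}

#' Exclude samples with 16S evidence of contamination
#'
#' Samples whose 16S composition exceeds the Lactobacillales fraction
#' threshold (fermentation/gut signal) or the chloroplast fraction
#' threshold (plant material) are excluded. Samples with no assigned 16S
#' reads are kept with a warning.
#'
#' @param profiles List of `sample_profile`.
#' @param config A [curation_config()].
#' @return List with `kept` (profiles) and `excluded` (data.frame:
#'   `sample_id`, `reason`, `fraction`).
#' @export
contamination_filter <- function(profiles, config = curation_config()) {
  excl <- data.frame(sample_id = character(0), reason = character(0),
                     fraction = numeric(0), stringsAsFactors = FALSE)
  keep <- logical(length(profiles))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    fl <- ssu_fraction(p, "lactobacillales")
    fc <- ssu_fraction(p, "chloroplast")
    if (is.na(fl)) {
      warning("sample ", p$sample_id, " has no 16S reads; kept unscreened",
              call. = FALSE)
      keep[i] <- TRUE
    } else if (fl > config$max_lactobacillales_frac) {
      excl <- rbind(excl, data.frame(sample_id = p$sample_id,
                                     reason = "lactobacillales", fraction = fl))
    } else if (fc > config$max_chloroplast_frac) {
      excl <- rbind(excl, data.frame(sample_id = p$sample_id,
                                     reason = "chloroplast", fraction = fc))
    } else keep[i] <- TRUE
  }
  list(kept = profiles[keep], excluded = excl)
}

#' Great-circle distance between coordinates
#'
#' Haversine formula on a sphere of mean Earth radius (6371.0088 km by
#' default). Vectorised over the second pair.
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees.
#' @param radius_km Sphere radius.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  assert_that(all(abs(c(lat1, lat2)) <= 90) && all(abs(c(lon1, lon2)) <= 180),
              "coordinates out of range", class = "diazo_coordinate_error")
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Cluster samples taken within a radius of each other
#'
#' Single linkage: clusters are the connected components of the graph whose
#' edges join samples strictly closer than `cluster_radius_km`.
#'
#' @param profiles List of `sample_profile` (coordinates required).
#' @param config A [curation_config()].
#' @return Integer cluster id per sample, named by `sample_id`; cluster ids
#'   are assigned in input order of each cluster's first member.
#' @export
cluster_samples <- function(profiles, config = curation_config()) {
  n <- length(profiles)
  ids <- vapply(profiles, `[[`, "", "sample_id")
  lat <- vapply(profiles, `[[`, 0, "lat")
  lon <- vapply(profiles, `[[`, 0, "lon")
  assert_that(!anyNA(lat) && !anyNA(lon), "all samples need coordinates",
              class = "diazo_coordinate_error")
  comp <- integer(n)
  nxt <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    nxt <- nxt + 1L
    queue <- i
    comp[i] <- nxt
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      d <- haversine_km(lat[j], lon[j], lat, lon, config$earth_radius_km)
      nb <- which(d < config$cluster_radius_km & comp == 0L)
      comp[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  stats::setNames(comp, ids)
}

#' Merge the member profiles of one geographic cluster
#'
#' Per-gene counts, 16S counts and QC totals are summed; coordinates become
#' the arithmetic centroid; the provenance list records the members. All
#' members must share one environment category.
#'
#' @param members List of `sample_profile` (>= 1).
#' @return A merged `sample_profile`.
#' @export
merge_cluster <- function(members) {
  assert_that(length(members) >= 1, "empty cluster")
  if (length(members) == 1) return(members[[1]])
  envs <- unique(vapply(members, `[[`, "", "env"))
  assert_that(length(envs) == 1,
              "cannot merge samples from different environments: ",
              paste(envs, collapse = " vs "), class = "diazo_merge_conflict_error")
  counts <- do.call(rbind, lapply(members, `[[`, "counts"))
  counts <- if (nrow(counts)) {
    agg <- stats::aggregate(count ~ family + gene_id, data = counts, FUN = sum)
    agg[order(agg$family, agg$gene_id), c("family", "gene_id", "count")]
  } else counts
  ssu <- do.call(rbind, lapply(members, `[[`, "ssu"))
  ssu <- if (nrow(ssu)) {
    agg <- stats::aggregate(count ~ lineage, data = ssu, FUN = sum)
    agg[order(agg$lineage), c("lineage", "count")]
  } else ssu
  asn <- lapply(members, `[[`, "assignments")
  asn <- if (all(vapply(asn, is.null, NA))) NULL else do.call(rbind, asn)
  structure(list(
    sample_id = paste(vapply(members, `[[`, "", "sample_id"), collapse = "+"),
    env = envs,
    lat = mean(vapply(members, `[[`, 0, "lat")),
    lon = mean(vapply(members, `[[`, 0, "lon")),
    total_reads_qc = sum(vapply(members, `[[`, 0, "total_reads_qc")),
    counts = counts, ssu = ssu, n_ssu_reads = sum(ssu$count),
    assignments = asn,
    provenance = unlist(lapply(members, `[[`, "provenance"))),
    class = "sample_profile")
}

#' Cluster and merge a list of profiles
#'
#' @inheritParams cluster_samples
#' @return List with `profiles` (merged, one per cluster) and `clusters`
#'   (the assignment vector).
#' @export
merge_by_location <- function(profiles, config = curation_config()) {
  cl <- cluster_samples(profiles, config)
  merged <- lapply(split(profiles, cl), merge_cluster)
  names(merged) <- vapply(merged, `[[`, "", "sample_id")
  list(profiles = unname(merged), clusters = cl)
}

#' Keep samples with enough nifD/K reads for taxonomic analysis
#'
#' The combined nifD + nifK read count must reach `min_nifdk_reads`
#' (inclusive).
#'
#' @inheritParams cluster_samples
#' @return The kept subset of `profiles`.
#' @export
min_nifdk_filter <- function(profiles, config = curation_config()) {
  keep <- vapply(profiles, function(p)
    family_count(p, c("nifD", "nifK")) >= config$min_nifdk_reads, NA)
  profiles[keep]
}
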