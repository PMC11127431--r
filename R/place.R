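# Placement-based taxonomic annotation of nifD/K reads. Translated reads
# are mapped onto the marker's reference alignment, scored against every
# reference leaf, and the scores are converted to a mass distribution over
# the reference-tree leaves (a score softmax). The annotation is the
# deepest taxonomy node holding at least `tau` of the mass
# (confidence-weighted LCA); reads without a sufficiently concentrated
# distribution are abandoned as unreliable, which is what makes placement
# preferable to a plain best-hit annotation for short fragments.

#' Build a reference package for one marker family
#'
#' @param msa Aligned protein sequences ([Biostrings::AAStringSet] or named
#'   character; `-` for gaps), one per reference leaf.
#' @param tree [ape::phylo] with branch lengths; tip labels must be a
#'   subset of the MSA names.
#' @param taxonomy Named character vector: leaf id -> semicolon lineage.
#' @param family Marker family name.
#' @param meta Optional list (e.g. clade restriction note).
#' @return Object of class `diazo_refpkg` (with precomputed alignment
#'   matrix and seed index).
#' @export
refpkg <- function(msa, tree, taxonomy, family, meta = list()) {
  if (!methods::is(msa, "AAStringSet")) msa <- Biostrings::AAStringSet(msa)
  assert_that(length(unique(Biostrings::width(msa))) == 1,
              "MSA sequences must have equal aligned length")
  assert_that(all(tree$tip.label %in% names(msa)),
              "tree leaves must be a subset of MSA sequence ids")
  leaves <- tree$tip.label
  assert_that(all(leaves %in% names(taxonomy)) && all(nzchar(taxonomy[leaves])),
              "lineage must be defined for every leaf")
  msa <- msa[leaves]
  chr <- as.character(msa)
  ncol <- nchar(chr[[1]])
  mat <- matrix(unlist(strsplit(chr, "", fixed = TRUE), use.names = FALSE),
                nrow = ncol)                      # columns = leaves
  # degapped leaf sequences and residue -> column maps
  degap <- gsub("-", "", chr, fixed = TRUE)
  col_map <- lapply(seq_along(leaves), function(i) which(mat[, i] != "-"))
  structure(list(family = family, msa = msa, tree = tree,
                 taxonomy = taxonomy[leaves], leaves = leaves,
                 mat = mat, degap = degap, col_map = col_map,
                 meta = meta), class = "diazo_refpkg")
}

#' @export
print.diazo_refpkg <- function(x, ...) {
  cat("diazo_refpkg", x$family, ":", length(x$leaves), "leaves,",
      nrow(x$mat), "alignment columns\n")
  invisible(x)
}

#' Build a reference package from a synthetic reference set
#'
#' Uses the reference-set proteins of one nitrogenase family (padded to a
#' common aligned length; the generator introduces no internal indels, so
#' terminal padding is a valid alignment) and a neighbour-joining tree from
#' pairwise amino-acid p-distances.
#'
#' @param refset A `diazo_refset`.
#' @param family Marker family (e.g. `"nifD"`).
#' @return A `diazo_refpkg` whose leaves are taxon ids.
#' @export
build_refpkg <- function(refset, family) {
  db <- refset$db
  sel <- db$genes$family == family
  assert_that(any(sel), "no reference genes for family ", family)
  ids <- db$genes$gene_id[sel]
  taxa <- db$genes$genome_id[sel]
  aa <- as.character(db$aa[ids])
  names(aa) <- taxa
  width <- max(nchar(aa))
  aligned <- vapply(aa, function(s)
    paste0(s, strrep("-", width - nchar(s))), "")
  # p-distance over shared (non-gap) columns
  n <- length(aligned)
  mat <- matrix(unlist(strsplit(aligned, "", fixed = TRUE)), nrow = width)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sh <- mat[, i] != "-" & mat[, j] != "-"
    D[i, j] <- D[j, i] <- mean(mat[sh, i] != mat[sh, j])
  }
  assert_that(n >= 2, "need at least 2 reference sequences for a tree")
  tree <- if (n == 2) {
    ape::read.tree(text = sprintf("(%s:%f,%s:%f);", taxa[1], D[1, 2] / 2,
                                  taxa[2], D[1, 2] / 2))
  } else ape::nj(stats::as.dist(D))
  tree$edge.length <- pmax(tree$edge.length, 1e-6)
  tax <- stats::setNames(unname(db$taxonomy[taxa]), taxa)
  refpkg(aligned, tree, tax, family)
}

#' Serialise / load a reference package directory
#'
#' Directory layout: `alignment.fasta`, `tree.nwk`, `taxonomy.tsv`,
#' `meta.json`.
#'
#' @param pkg A `diazo_refpkg`.
#' @param dir Directory path.
#' @return `dir` invisibly; `read_refpkg()` returns the `diazo_refpkg`.
#' @export
write_refpkg <- function(pkg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(pkg$msa, file.path(dir, "alignment.fasta"))
  ape::write.tree(pkg$tree, file.path(dir, "tree.nwk"))
  utils::write.table(
    data.frame(leaf = names(pkg$taxonomy), lineage = unname(pkg$taxonomy)),
    file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(c(list(family = pkg$family), pkg$meta),
                              auto_unbox = TRUE), file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_refpkg
#' @export
read_refpkg <- function(dir) {
  msa <- Biostrings::readAAStringSet(file.path(dir, "alignment.fasta"))
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  tx <- utils::read.delim(file.path(dir, "taxonomy.tsv"), stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  refpkg(msa, tree, stats::setNames(tx$lineage, tx$leaf),
         family = meta$family, meta = meta[setdiff(names(meta), "family")])
}

#' Align a translated read to the reference alignment and score each leaf
#'
#' Seeds exact amino-acid k-mers against the (degapped) leaf sequences to
#' locate the query's column offset, then scores the query against every
#' leaf over the covered columns with BLOSUM62 (half-bit matrix; leaf gap
#' columns score -4). Queries shorter than 20 aa carry too little signal
#' and are rejected.
#'
#' @param query_aa Amino-acid string (>= 20 residues).
#' @param pkg A `diazo_refpkg`.
#' @param k Seed width (default 5).
#' @return List: `scores` (named bits per leaf), `offset` (0-based column
#'   offset), `coverage` (number of scored columns).
#' @export
profile_align <- function(query_aa, pkg, k = 5L) {
  q <- gsub("-", "", query_aa, fixed = TRUE)
  L <- nchar(q)
  assert_that(L >= 20, "query shorter than 20 aa", class = "diazo_too_short_error")
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  st <- stepped_starts(L, k, k)
  qk <- substring(q, st, st + k - 1L)
  # candidate offsets: column of seed start in each leaf minus query pos
  offs <- integer(0)
  for (i in seq_along(pkg$degap)) {
    s <- pkg$degap[[i]]
    for (j in seq_along(qk)) {
      p <- gregexpr(qk[j], s, fixed = TRUE)[[1]]
      if (p[1] != -1L)
        offs <- c(offs, pkg$col_map[[i]][p] - st[j])
    }
  }
  offset <- if (length(offs)) {
    tb <- table(offs)
    as.integer(names(tb)[which.max(tb)])
  } else 0L
  cols <- (offset + 1L):(offset + L)
  inside <- cols >= 1L & cols <= nrow(pkg$mat)
  cols <- cols[inside]
  qv2 <- qv[inside]
  B <- blosum62()
  lv <- rownames(B)
  qi <- match(qv2, lv); qi[is.na(qi)] <- match("*", lv)
  sub <- pkg$mat[cols, , drop = FALSE]
  ri <- match(sub, lv)                  # NA for gaps
  scmat <- matrix(B[cbind(rep(qi, ncol(sub)),
                          ifelse(is.na(ri), 1L, ri))], nrow = length(cols))
  scmat[is.na(ri)] <- -4                # leaf gap
  scores <- colSums(scmat) / 2
  names(scores) <- pkg$leaves
  list(scores = scores, offset = offset, coverage = length(cols))
}

#' Convert leaf scores to a placement mass distribution
#'
#' Mass over pendant edges is the softmax of `beta` times the leaf scores
#' (bits). The default `beta = 0.5` per bit makes a 10-bit score gap
#' concentrate more than 99% of the mass on the better leaf; `beta -> 0`
#' tends to the uniform distribution.
#'
#' @param scores Named numeric leaf scores (bits).
#' @param beta Softmax inverse temperature per bit.
#' @return Named numeric weights summing to 1.
#' @export
place_read <- function(scores, beta = 0.5) {
  assert_that(all(is.finite(scores)), "scores must be finite")
  softmax(beta * scores)
}

#' Confidence-weighted LCA annotation of a placement
#'
#' The annotation is the deepest taxonomy node whose descendant leaves hold
#' cumulative placement mass of at least `tau`; its rank and the cumulative
#' mass (confidence) are recorded. If no node at or below the domain rank
#' reaches `tau`, the read is `unreliable`. Annotations above family rank
#' that lie within Deltaproteobacteria and whose confidently supported
#' descendant families are all Geobacteraceae or Anaeromyxobacteraceae are
#' assigned the `possibly_geo_anaeromyxo` category.
#'
#' @param weights Named placement weights (from [place_read()]).
#' @param pkg A `diazo_refpkg`.
#' @param tau Confidence threshold (default 0.8).
#' @param gamma Minimum within-clade mass fraction for a family to count as
#'   confidently present (default 0.05).
#' @return List: `lineage`, `rank`, `depth`, `confidence`, `category`,
#'   `best_leaf`.
#' @export
annotate_placement <- function(weights, pkg, tau = 0.8, gamma = 0.05) {
  lin <- pkg$taxonomy[names(weights)]
  best_leaf <- names(weights)[which.max(weights)]
  ranks <- lineage_rank_names()
  ann <- NULL
  for (depth in rev(seq_along(ranks))) {
    pre <- lineage_prefix(lin, depth)
    full <- lengths(lineage_split(lin)) >= depth
    w <- tapply(weights[full], pre[full], sum)
    if (!length(w)) next
    top <- which.max(w)
    if (w[[top]] >= tau) {
      ann <- list(lineage = names(w)[top], rank = ranks[depth], depth = depth,
                  confidence = unname(w[[top]]))
      break
    }
  }
  if (is.null(ann))
    return(list(lineage = NA_character_, rank = NA_character_, depth = 0L,
                confidence = max(0, max(tapply(weights, lineage_prefix(lin, 1), sum))),
                category = "unreliable", best_leaf = best_leaf))
  ann$category <- if (resolve_possibly_category(ann, weights, pkg, gamma))
    "possibly_geo_anaeromyxo" else "annotated"
  ann$best_leaf <- best_leaf
  ann
}

#' Detect the "possibly Geobacteraceae or Anaeromyxobacteraceae" category
#'
#' @param annotation List from [annotate_placement()] (fields `lineage`,
#'   `depth`).
#' @param weights Placement weights.
#' @param pkg A `diazo_refpkg`.
#' @param gamma Family-confidence floor within the annotated clade.
#' @return Logical.
#' @export
resolve_possibly_category <- function(annotation, weights, pkg, gamma = 0.05) {
  if (is.na(annotation$lineage) || annotation$depth >= 5L) return(FALSE)
  parts <- lineage_split(annotation$lineage)[[1]]
  if (length(parts) < 3 || parts[3] != "Deltaproteobacteria") return(FALSE)
  lin <- pkg$taxonomy[names(weights)]
  inside <- startsWith(paste0(lin, ";"), paste0(annotation$lineage, ";"))
  if (!any(inside)) return(FALSE)
  fam <- lineage_at(lin[inside], "family")
  wf <- tapply(weights[inside], fam, sum)
  wf <- wf / sum(wf)
  conf_fams <- names(wf)[wf >= gamma]
  length(conf_fams) > 0 &&
    all(conf_fams %in% c("Geobacteraceae", "Anaeromyxobacteraceae"))
}

#' Place all marker reads of one sample
#'
#' Runs align -> place -> annotate for every read of the sample assigned to
#' the package's marker family, and aggregates the per-read mass
#' distributions into the sample's leaf-mass vector (each read contributes
#' mass 1/n).
#'
#' @param profile A `sample_profile` built with `keep_assignments = TRUE`.
#' @param pkg A `diazo_refpkg`.
#' @param beta,tau,gamma See [place_read()] and [annotate_placement()].
#' @return Object of class `placement_set`: `per_read` data.frame, `mass`
#'   (named leaf masses summing to 1), `family`, `sample_id`, `n_reads`.
#' @export
place_sample <- function(profile, pkg, beta = 0.5, tau = 0.8, gamma = 0.05) {
  asn <- profile$assignments
  assert_that(!is.null(asn), "profile lacks per-read assignments")
  asn <- asn[asn$family == pkg$family & !is.na(asn$query_aa), , drop = FALSE]
  n <- nrow(asn)
  rows <- vector("list", n)
  mass <- stats::setNames(numeric(length(pkg$leaves)), pkg$leaves)
  for (i in seq_len(n)) {
    q <- gsub("[*-]", "", asn$query_aa[i])
    if (nchar(q) < 20) next
    al <- profile_align(q, pkg)
    w <- place_read(al$scores, beta)
    ann <- annotate_placement(w, pkg, tau, gamma)
    mass <- mass + w
    rows[[i]] <- data.frame(
      read_id = asn$read_id[i], best_leaf = ann$best_leaf,
      rank = ann$rank, lineage = ann$lineage,
      confidence = ann$confidence, category = ann$category,
      stringsAsFactors = FALSE)
  }
  per_read <- do.call(rbind, rows[!vapply(rows, is.null, NA)])
  if (is.null(per_read))
    per_read <- data.frame(read_id = character(0), best_leaf = character(0),
                           rank = character(0), lineage = character(0),
                           confidence = numeric(0), category = character(0))
  placed <- nrow(per_read)
  if (placed) mass <- mass / sum(mass)
  structure(list(family = pkg$family, sample_id = profile$sample_id,
                 per_read = per_read, mass = mass, n_reads = placed),
            class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat("placement_set", x$sample_id, "/", x$family, ":", x$n_reads,
      "placed reads\n")
  invisible(x)
}

#' Family-level composition of a sample's placements
#'
#' Fractions are computed over reads annotated at family rank or deeper
#' plus reads in the `possibly_geo_anaeromyxo` category; unreliable reads
#' and reads annotated above family outside that category are excluded.
#'
#' @param placements A `placement_set`, or a list of them (summed).
#' @return Named numeric fractions summing to 1 (empty, with attribute
#'   `no_annotated = TRUE`, when nothing qualifies).
#' @export
family_composition <- function(placements) {
  if (inherits(placements, "placement_set")) placements <- list(placements)
  pr <- do.call(rbind, lapply(placements, `[[`, "per_read"))
  if (!is.null(pr)) pr$lineage <- as.character(pr$lineage)
  if (is.null(pr) || !nrow(pr))
    return(structure(stats::setNames(numeric(0), character(0)),
                     no_annotated = TRUE))
  depth <- lengths(lineage_split(ifelse(is.na(pr$lineage), "", pr$lineage)))
  lab <- rep(NA_character_, nrow(pr))
  deep <- pr$category == "annotated" & depth >= 5
  lab[deep] <- lineage_at(pr$lineage[deep], "family")
  lab[pr$category == "possibly_geo_anaeromyxo"] <-
    "Possibly Geobacteraceae or Anaeromyxobacteraceae"
  keep <- !is.na(lab)
  if (!any(keep))
    return(structure(stats::setNames(numeric(0), character(0)),
                     no_annotated = TRUE))
  tb <- table(lab[keep])
  stats::setNames(as.numeric(tb) / sum(tb), names(tb))
}

#' Map annotated reads to the nearest reference isolate
#'
#' Computes the global (Needleman-Wunsch) alignment identity of each query
#' against every reference in the family, split into previously known
#' references and newly isolated strains, and classifies the query by the
#' partition holding its top hit; exact ties across partitions give class
#' `tie`.
#'
#' @param queries Named character vector / [Biostrings::AAStringSet] of
#'   query protein fragments.
#' @param known,new_isolate [Biostrings::AAStringSet] reference partitions
#'   (both non-empty).
#' @return List with `per_query` (data.frame: `query`, `class`,
#'   `best_known`, `best_new`) and `summary` (fraction per class).
#' @export
map_to_nearest_isolate <- function(queries, known, new_isolate) {
  assert_that(length(known) > 0 && length(new_isolate) > 0,
              "both reference partitions must be non-empty")
  if (!methods::is(queries, "AAStringSet"))
    queries <- Biostrings::AAStringSet(queries)
  if (!length(queries))
    return(list(per_query = data.frame(query = character(0), class = character(0),
                                       best_known = numeric(0), best_new = numeric(0)),
                summary = c(known = NaN, new_isolate = NaN, tie = NaN)))
  best_id <- function(refs) {
    m <- sapply(seq_along(refs), function(j)
      Biostrings::pid(Biostrings::pairwiseAlignment(
        queries, refs[[j]], type = "global",
        substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1),
        type = "PID1"))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(queries))
    apply(m, 1, max)
  }
  bk <- best_id(known)
  bn <- best_id(new_isolate)
  cls <- ifelse(bk > bn, "known", ifelse(bn > bk, "new_isolate", "tie"))
  per <- data.frame(query = names(queries) %||% as.character(seq_along(queries)),
                    class = cls, best_known = bk, best_new = bn,
                    stringsAsFactors = FALSE)
  summ <- vapply(c("known", "new_isolate", "tie"),
                 function(k) mean(cls == k), 0)
  list(per_query = per, summary = summ)
}
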