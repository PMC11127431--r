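# Read quality filtering and marker assignment. Protein markers
# (nitrogenase families + ribosomal proteins) are detected by translated
# six-frame search against the reference proteins; 16S rRNA by nucleotide
# best hit on either strand. The default search is seed-and-extend: exact
# amino-acid 8-mer seeds locate the diagonal, and a gapless BLOSUM62
# extension scores it (the read model is substitution-only, so gapless
# extension is exact there); `method = "full"` runs an exhaustive
# Smith-Waterman with affine gaps via Biostrings for small inputs and as an
# independent oracle.

#' Classifier configuration
#'
#' @param ... Named overrides. Fields: `id_min` (protein identity floor,
#'   0.6), `bits_min` (alignment score floor in bits, 50), `ssu_id_min`
#'   (16S nucleotide identity floor, 0.8), `min_len` (QC length floor, 100
#'   nt), `min_mean_q` (QC mean Phred floor, 20), `k_aa` (protein seed
#'   width, 8), `k_nt` (nucleotide seed width, 16), `nt_step` (spacing of
#'   nucleotide seed windows along a read, 30), `min_overlap_aa`
#'   (minimum scored overlap, 20 aa), `nt_prefilter` (skip translation of
#'   reads without any exact nucleotide seed against the database; valid
#'   only at low read-to-reference divergence), `method`
#'   (`"seed"`/`"full"`).
#' @return Named list.
#' @export
classify_config <- function(...) {
  cfg <- list(id_min = 0.6, bits_min = 50, ssu_id_min = 0.8,
              min_len = 100L, min_mean_q = 20, k_aa = 8L, k_nt = 16L,
              nt_step = 30L, min_overlap_aa = 20L, nt_prefilter = FALSE,
              method = "seed")
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  assert_that(length(bad) == 0, "unknown classify option(s): ",
              paste(bad, collapse = ", "), class = "diazo_config_error")
  cfg[names(ov)] <- ov
  cfg
}

blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

# dense k-mers of one string: positions 1..(n-k+1)
dense_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

#' Build the k-mer search index for a reference database
#'
#' Precomputes a dense amino-acid k-mer index over the reference proteins
#' and a dense nucleotide k-mer index over all genes (both strands; used by
#' the 16S classifier and the optional nucleotide prescreen). Build once,
#' reuse across samples.
#'
#' @param db A `diazo_refdb`.
#' @param config A [classify_config()].
#' @return Object of class `diazo_index`.
#' @export
classifier_index <- function(db, config = classify_config()) {
  k_aa <- config$k_aa; k_nt <- config$k_nt
  aa_ids <- names(db$aa)
  aa_chr <- as.character(db$aa)
  pk <- lapply(aa_chr, dense_kmers, k = k_aa)
  pl <- lengths(pk)
  prot <- list(
    gene = rep(seq_along(aa_ids), pl),
    pos = unlist(lapply(pl, seq_len), use.names = FALSE),
    kmer = unlist(pk, use.names = FALSE))
  pu <- unique(prot$kmer)
  prot_groups <- split(seq_along(prot$kmer),
                       factor(prot$kmer, levels = pu))
  prot_idx <- list(kmer_tab = pu, groups = unname(prot_groups),
                   gene = prot$gene, pos = prot$pos,
                   gene_ids = aa_ids, seqs = aa_chr,
                   family = db$genes$family[match(aa_ids, db$genes$gene_id)])

  nt_ids <- names(db$nt)
  fwd <- as.character(db$nt)
  rev <- as.character(Biostrings::reverseComplement(db$nt))
  nk_f <- lapply(fwd, dense_kmers, k = k_nt)
  nk_r <- lapply(rev, dense_kmers, k = k_nt)
  nt <- list(
    gene = c(rep(seq_along(nt_ids), lengths(nk_f)),
             rep(seq_along(nt_ids), lengths(nk_r))),
    pos = c(unlist(lapply(lengths(nk_f), seq_len), use.names = FALSE),
            unlist(lapply(lengths(nk_r), seq_len), use.names = FALSE)),
    strand = rep(c("+", "-"), c(sum(lengths(nk_f)), sum(lengths(nk_r)))),
    kmer = c(unlist(nk_f, use.names = FALSE), unlist(nk_r, use.names = FALSE)))
  nu <- unique(nt$kmer)
  nt_groups <- split(seq_along(nt$kmer), factor(nt$kmer, levels = nu))
  nt_idx <- list(kmer_tab = nu, groups = unname(nt_groups),
                 gene = nt$gene, pos = nt$pos, strand = nt$strand,
                 gene_ids = nt_ids, fwd = fwd, rev = rev,
                 family = db$genes$family[match(nt_ids, db$genes$gene_id)],
                 genome = db$genes$genome_id[match(nt_ids, db$genes$gene_id)])
  structure(list(prot = prot_idx, nt = nt_idx, k_aa = k_aa, k_nt = k_nt),
            class = "diazo_index")
}

#' Quality-filter reads
#'
#' Retains reads with length >= `min_len` and mean Phred quality >=
#' `min_mean_q`; input order is preserved.
#'
#' @param reads A `diazo_reads` object or FASTQ path.
#' @param min_len,min_mean_q Thresholds.
#' @return Filtered `diazo_reads`.
#' @export
quality_filter <- function(reads, min_len = 100L, min_mean_q = 20) {
  if (is.character(reads)) reads <- read_fastq(reads)
  len <- nchar(reads$seq)
  uq <- unique(reads$qual)
  meanq_u <- vapply(uq, function(q)
    if (nchar(q)) mean(utf8ToInt(q)) - 33 else 0, 0)
  meanq <- meanq_u[match(reads$qual, uq)]
  keep <- len >= min_len & meanq >= min_mean_q
  subset_reads(reads, keep)
}

subset_reads <- function(reads, keep) {
  out <- reads
  for (f in c("id", "seq", "qual", "taxon", "start", "strand"))
    if (!is.null(out[[f]])) out[[f]] <- out[[f]][keep]
  out
}

# Six-frame translation of read sequences; returns list of 6 character
# vectors (frames 1:3 forward, 4:6 reverse-complement).
six_frames <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  rc <- Biostrings::reverseComplement(x)
  one <- function(set, f) {
    w <- Biostrings::width(set)
    wid <- pmax(0L, ((w - f + 1L) %/% 3L) * 3L)
    as.character(suppressWarnings(Biostrings::translate(
      Biostrings::subseq(set, start = pmin(f, w + 1L), width = wid),
      genetic.code = Biostrings::getGeneticCode("11"),
      if.fuzzy.codon = "solve", no.init.codon = TRUE)))
  }
  c(lapply(1:3, function(f) one(x, f)), lapply(1:3, function(f) one(rc, f)))
}

# stepped k-mer starts covering a string of length L
stepped_starts <- function(L, k, step) {
  if (L < k) return(integer(0))
  unique(c(seq.int(1L, L - k + 1L, by = step), L - k + 1L))
}

# Vectorised gapless scoring of candidate pairs. q and r are equal-length
# character vectors of aligned (equal-nchar within pair) segments.
# Returns data.frame(identity, bits, overlap).
score_segments <- function(q, r) {
  n <- length(q)
  if (!n) return(data.frame(identity = numeric(0), bits = numeric(0),
                            overlap = integer(0)))
  L <- nchar(q)
  B <- blosum62()
  aa_levels <- rownames(B)
  identity <- numeric(n); bits <- numeric(n)
  for (len in unique(L)) {
    ii <- which(L == len)
    qm <- matrix(unlist(strsplit(q[ii], "", fixed = TRUE), use.names = FALSE),
                 nrow = len)
    rm_ <- matrix(unlist(strsplit(r[ii], "", fixed = TRUE), use.names = FALSE),
                  nrow = len)
    identity[ii] <- colMeans(qm == rm_)
    qi <- match(qm, aa_levels); ri <- match(rm_, aa_levels)
    qi[is.na(qi)] <- match("*", aa_levels)
    ri[is.na(ri)] <- match("*", aa_levels)
    sc <- matrix(B[cbind(qi, ri)], nrow = len)
    bits[ii] <- colSums(sc) / 2
  }
  data.frame(identity = identity, bits = bits, overlap = L)
}

# Seeded protein search of one frame against the protein index.
# Returns data.frame(read = index into seqs, gene, qlo, diag).
seed_frame_candidates <- function(frame_aa, idx, k, step) {
  lens <- nchar(frame_aa)
  cand <- list()
  for (L in unique(lens)) {
    st <- stepped_starts(L, k, step)
    if (!length(st)) next
    ri <- which(lens == L)
    qk <- substring(rep(frame_aa[ri], each = length(st)),
                    rep(st, times = length(ri)),
                    rep(st + k - 1L, times = length(ri)))
    qread <- rep(ri, each = length(st))
    qpos <- rep(st, times = length(ri))
    m <- match(qk, idx$kmer_tab)
    hit <- which(!is.na(m))
    if (!length(hit)) next
    entry_groups <- idx$groups[m[hit]]
    gl <- lengths(entry_groups)
    e <- unlist(entry_groups, use.names = FALSE)
    cand[[length(cand) + 1L]] <- data.frame(
      read = rep(qread[hit], gl),
      gene = idx$gene[e],
      diag = idx$pos[e] - rep(qpos[hit], gl))
  }
  if (!length(cand)) return(data.frame(read = integer(0), gene = integer(0),
                                       diag = integer(0)))
  out <- do.call(rbind, cand)
  key <- (as.numeric(out$read) * (max(idx$gene) + 1) + out$gene) * 1e5 +
    (out$diag + 5e4)
  out[!duplicated(key), , drop = FALSE]
}

#' Assign reads to protein-coding marker genes
#'
#' Best-scoring translated alignment of each read's six frames against the
#' reference proteins. A read is assigned to the top-scoring gene if the
#' score is at least `bits_min` bits and the identity at least `id_min`;
#' ties are broken by higher identity, then lexicographically smaller
#' `gene_id`. At most one assignment per read (best family wins).
#'
#' @param reads A `diazo_reads` object (post-QC).
#' @param db A `diazo_refdb`.
#' @param idx Optional prebuilt [classifier_index()].
#' @param config A [classify_config()].
#' @return data.frame: `read_id`, `gene_id` (NA when unassigned), `family`,
#'   `score` (bits), `identity`, `frame`, `query_aa` (translated segment
#'   used; NA when unassigned). One row per read, input order.
#' @export
assign_protein_marker <- function(reads, db, idx = NULL,
                                  config = classify_config()) {
  if (identical(config$method, "full"))
    return(assign_protein_full(reads, db, config))
  if (is.null(idx)) idx <- classifier_index(db, config)
  n <- length(reads$id)
  best <- data.frame(read_id = reads$id, gene_id = NA_character_,
                     family = NA_character_, score = NA_real_,
                     identity = NA_real_, frame = NA_integer_,
                     query_aa = NA_character_, stringsAsFactors = FALSE)
  if (!n) return(best)
  frames <- six_frames(reads$seq)
  pidx <- idx$prot
  ref_len <- nchar(pidx$seqs)
  all_sc <- list()
  for (f in seq_along(frames)) {
    fa <- frames[[f]]
    cand <- seed_frame_candidates(fa, pidx, idx$k_aa, step = idx$k_aa - 1L)
    if (!nrow(cand)) next
    Lq <- nchar(fa)[cand$read]
    Lr <- ref_len[cand$gene]
    qlo <- pmax(1L, 1L - cand$diag)
    qhi <- pmin(Lq, Lr - cand$diag)
    ok <- qhi - qlo + 1L >= config$min_overlap_aa
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    qlo <- qlo[ok]; qhi <- qhi[ok]
    qseg <- substring(fa[cand$read], qlo, qhi)
    rseg <- substring(pidx$seqs[cand$gene], qlo + cand$diag, qhi + cand$diag)
    sc <- score_segments(qseg, rseg)
    all_sc[[length(all_sc) + 1L]] <- data.frame(
      read = cand$read, gene = cand$gene, frame = f,
      identity = sc$identity, bits = sc$bits, query_aa = qseg,
      stringsAsFactors = FALSE)
  }
  if (!length(all_sc)) return(best)
  sc <- do.call(rbind, all_sc)
  sc <- sc[sc$bits >= config$bits_min & sc$identity >= config$id_min, , drop = FALSE]
  if (!nrow(sc)) return(best)
  gid <- pidx$gene_ids[sc$gene]
  o <- order(sc$read, -sc$bits, -sc$identity, gid)
  sc <- sc[o, , drop = FALSE]; gid <- gid[o]
  first <- !duplicated(sc$read)
  ri <- sc$read[first]
  best$gene_id[ri] <- gid[first]
  best$family[ri] <- pidx$family[sc$gene[first]]
  best$score[ri] <- sc$bits[first]
  best$identity[ri] <- sc$identity[first]
  best$frame[ri] <- sc$frame[first]
  best$query_aa[ri] <- sc$query_aa[first]
  best
}

# Exhaustive Smith-Waterman (affine gaps, BLOSUM62) over all frames and all
# reference proteins. Quadratic; intended for small inputs and as oracle.
assign_protein_full <- function(reads, db, config = classify_config()) {
  n <- length(reads$id)
  best <- data.frame(read_id = reads$id, gene_id = NA_character_,
                     family = NA_character_, score = NA_real_,
                     identity = NA_real_, frame = NA_integer_,
                     query_aa = NA_character_, stringsAsFactors = FALSE)
  if (!n) return(best)
  frames <- six_frames(reads$seq)
  B <- blosum62()
  fam <- db$genes$family[match(names(db$aa), db$genes$gene_id)]
  ord <- order(names(db$aa))
  for (g in ord) {
    subject <- db$aa[[g]]
    for (f in seq_along(frames)) {
      pat <- Biostrings::AAStringSet(gsub("*", "X", frames[[f]], fixed = TRUE))
      aln <- Biostrings::pairwiseAlignment(
        pat, subject, type = "local", substitutionMatrix = B,
        gapOpening = 10, gapExtension = 1)
      bits <- Biostrings::score(aln) / 2
      pid <- Biostrings::pid(aln, type = "PID1") / 100
      better <- bits >= config$bits_min & pid >= config$id_min &
        (is.na(best$score) | bits > best$score |
           (bits == best$score & pid > best$identity))
      if (any(better)) {
        i <- which(better)
        best$gene_id[i] <- names(db$aa)[g]
        best$family[i] <- fam[g]
        best$score[i] <- bits[i]
        best$identity[i] <- pid[i]
        best$frame[i] <- f
        best$query_aa[i] <- as.character(Biostrings::pattern(aln))[i]
      }
    }
  }
  best
}

# Match read k-mers against the nucleotide index, optionally restricted to
# a family subset. Returns candidates (read, gene, strand, diag).
nt_candidates <- function(seqs, nidx, k, step, families = NULL) {
  lens <- nchar(seqs)
  fam_of_entry <- nidx$family[nidx$gene]
  cand <- list()
  for (L in unique(lens)) {
    st <- stepped_starts(L, k, step)
    if (!length(st)) next
    ri <- which(lens == L)
    qk <- substring(rep(seqs[ri], each = length(st)),
                    rep(st, times = length(ri)),
                    rep(st + k - 1L, times = length(ri)))
    qread <- rep(ri, each = length(st))
    qpos <- rep(st, times = length(ri))
    m <- match(qk, nidx$kmer_tab)
    hit <- which(!is.na(m))
    if (!length(hit)) next
    entry_groups <- nidx$groups[m[hit]]
    gl <- lengths(entry_groups)
    e <- unlist(entry_groups, use.names = FALSE)
    d <- data.frame(read = rep(qread[hit], gl),
                    gene = nidx$gene[e], strand = nidx$strand[e],
                    diag = nidx$pos[e] - rep(qpos[hit], gl))
    if (!is.null(families)) d <- d[nidx$family[d$gene] %in% families, , drop = FALSE]
    if (nrow(d)) cand[[length(cand) + 1L]] <- d
  }
  if (!length(cand)) return(data.frame(read = integer(0), gene = integer(0),
                                       strand = character(0), diag = integer(0)))
  out <- do.call(rbind, cand)
  key <- ((as.numeric(out$read) * (max(nidx$gene) + 1) + out$gene) * 2 +
    (out$strand == "+")) * 1e5 + (out$diag + 5e4)
  out[!duplicated(key), , drop = FALSE]
}

#' Assign reads to 16S rRNA references
#'
#' Nucleotide best hit of each read (both strands) against the 16S
#' references; the hit lineage is returned when identity >= `id_min`.
#'
#' @inheritParams assign_protein_marker
#' @param id_min Identity floor (default from config `ssu_id_min`).
#' @return data.frame: `read_id`, `genome_id`, `identity`, `lineage` (NA
#'   when unassigned). One row per read.
#' @export
assign_16s <- function(reads, db, idx = NULL, config = classify_config(),
                       id_min = config$ssu_id_min) {
  if (is.null(idx)) idx <- classifier_index(db, config)
  n <- length(reads$id)
  out <- data.frame(read_id = reads$id, genome_id = NA_character_,
                    identity = NA_real_, lineage = NA_character_,
                    stringsAsFactors = FALSE)
  if (!n) return(out)
  nidx <- idx$nt
  cand <- nt_candidates(reads$seq, nidx, idx$k_nt, step = config$nt_step,
                        families = "SSU16S")
  if (!nrow(cand)) return(out)
  ref <- ifelse(cand$strand == "+", nidx$fwd[cand$gene], nidx$rev[cand$gene])
  Lq <- nchar(reads$seq)[cand$read]
  Lr <- nchar(ref)
  qlo <- pmax(1L, 1L - cand$diag)
  qhi <- pmin(Lq, Lr - cand$diag)
  ok <- qhi - qlo + 1L >= idx$k_nt
  cand <- cand[ok, , drop = FALSE]; ref <- ref[ok]
  if (!nrow(cand)) return(out)
  qlo <- qlo[ok]; qhi <- qhi[ok]
  qseg <- substring(reads$seq[cand$read], qlo, qhi)
  rseg <- substring(ref, qlo + cand$diag, qhi + cand$diag)
  eq <- numeric(nrow(cand))
  L <- nchar(qseg)
  for (len in unique(L)) {
    ii <- which(L == len)
    qm <- matrix(unlist(strsplit(qseg[ii], "", fixed = TRUE), use.names = FALSE),
                 nrow = len)
    rm_ <- matrix(unlist(strsplit(rseg[ii], "", fixed = TRUE), use.names = FALSE),
                  nrow = len)
    eq[ii] <- colMeans(qm == rm_)
  }
  gid <- nidx$gene_ids[cand$gene]
  o <- order(cand$read, -eq, gid)
  cand <- cand[o, , drop = FALSE]; eq <- eq[o]; gid <- gid[o]
  first <- !duplicated(cand$read)
  sel <- which(first)[eq[first] >= id_min]
  ri <- cand$read[sel]
  out$genome_id[ri] <- nidx$genome[cand$gene[sel]]
  out$identity[ri] <- eq[sel]
  out$lineage[ri] <- unname(db$taxonomy[out$genome_id[ri]])
  out
}

#' Classify all reads of a sample into a marker profile
#'
#' Quality-filters the reads, assigns protein markers and 16S, and
#' aggregates per-gene counts and the 16S community composition.
#'
#' @param reads A `diazo_reads` object or FASTQ path.
#' @param db A `diazo_refdb`.
#' @param metadata List or one-row data.frame with `sample_id`, `env`,
#'   `lat`, `lon`.
#' @param config A [classify_config()].
#' @param idx Optional prebuilt [classifier_index()].
#' @param keep_assignments Keep the per-read assignment tables (needed for
#'   downstream phylogenetic placement).
#' @return Object of class `sample_profile`.
#' @export
profile_sample <- function(reads, db, metadata, config = classify_config(),
                           idx = NULL, keep_assignments = TRUE) {
  md <- as.list(metadata)
  for (f in c("sample_id", "env", "lat", "lon"))
    assert_that(!is.null(md[[f]]) && !is.na(md[[f]]),
                "metadata field missing: ", f, class = "diazo_metadata_error")
  if (is.character(reads)) reads <- read_fastq(reads)
  if (is.null(idx)) idx <- classifier_index(db, config)
  qc <- quality_filter(reads, config$min_len, config$min_mean_q)
  total <- length(qc$id)

  if (isTRUE(config$nt_prefilter) && total) {
    cand <- nt_candidates(qc$seq, idx$nt, idx$k_nt, step = config$nt_step)
    fam <- idx$nt$family[cand$gene]
    prot_reads <- sort(unique(cand$read[fam != "SSU16S"]))
    ssu_reads <- sort(unique(cand$read[fam == "SSU16S"]))
    prot <- assign_protein_marker(subset_reads(qc, prot_reads), db, idx, config)
    assigned <- prot_reads[!is.na(prot$gene_id)]
    ssu <- assign_16s(subset_reads(qc, setdiff(ssu_reads, assigned)),
                      db, idx, config)
  } else {
    prot <- assign_protein_marker(qc, db, idx, config)
    ssu <- assign_16s(subset_reads(qc, is.na(prot$gene_id)), db, idx, config)
  }

  pa <- prot[!is.na(prot$gene_id), , drop = FALSE]
  counts <- if (nrow(pa)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(pa))),
                            by = list(family = pa$family, gene_id = pa$gene_id),
                            FUN = sum)
    agg[order(agg$family, agg$gene_id), , drop = FALSE]
  } else data.frame(family = character(0), gene_id = character(0),
                    count = integer(0))
  sa <- ssu[!is.na(ssu$lineage), , drop = FALSE]
  ssu_tab <- if (nrow(sa)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(sa))),
                            by = list(lineage = sa$lineage), FUN = sum)
    agg[order(agg$lineage), , drop = FALSE]
  } else data.frame(lineage = character(0), count = integer(0))

  structure(list(
    sample_id = md$sample_id, env = md$env,
    lat = as.numeric(md$lat), lon = as.numeric(md$lon),
    total_reads_qc = total,
    counts = counts, ssu = ssu_tab, n_ssu_reads = sum(ssu_tab$count),
    assignments = if (keep_assignments) pa else NULL,
    provenance = md$sample_id), class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat("sample_profile", x$sample_id, "(", x$env, "):",
      x$total_reads_qc, "QC reads;", sum(x$counts$count),
      "protein-marker reads;", x$n_ssu_reads, "16S reads\n")
  invisible(x)
}

family_count <- function(profile, family) {
  sum(profile$counts$count[profile$counts$family %in% family])
}

#' Taxonomic composition of a sample's 16S reads
#'
#' At `"phylum"` rank, proteobacterial reads are split out by class
#' (Alphaproteobacteria, Deltaproteobacteria, ...), matching common
#' soil-community reporting.
#'
#' @param profile A `sample_profile`.
#' @param rank `"phylum"` or `"order"`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
summarize_composition <- function(profile, rank = c("phylum", "order")) {
  rank <- match.arg(rank)
  assert_that(nrow(profile$ssu) > 0 && sum(profile$ssu$count) > 0,
              "sample ", profile$sample_id, " has no assigned 16S reads",
              class = "diazo_rank_error")
  lin <- profile$ssu$lineage
  lab <- if (rank == "phylum") {
    phy <- lineage_at(lin, "phylum")
    cls <- lineage_at(lin, "class")
    ifelse(phy == "Proteobacteria" & !is.na(cls), cls, phy)
  } else lineage_at(lin, rank)
  lab[is.na(lab)] <- "unclassified"
  tot <- tapply(profile$ssu$count, lab, sum)
  frac <- as.numeric(tot) / sum(profile$ssu$count)
  stats::setNames(frac, names(tot))
}
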