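# Synthetic reference sets, communities, reads and sampling metadata with
# known ground truth. The generator emulates the statistical structure the
# analysis assumes: multi-taxon soil communities with log-normal abundances,
# genomes carrying 0 or 1 copy of each marker with nifH:nifD:nifK lengths
# near 3:5:5, taxon-specific GC, pseudo-nifH carriers (nifH without nifD/K),
# Lactobacillales / chloroplast contaminants, an anaerobic:aerobic
# diazotroph-fraction effect, and sub-kilometre sampling replicates.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Environment categories and their oxygen grouping
#'
#' Cropland, forest and grassland soils are treated as aerobic; paddy soils,
#' sediments and tundra as anaerobic.
#'
#' @return Named character vector mapping category to `"aerobic"`/`"anaerobic"`.
#' @export
env_groups <- function() {
  c(cropland = "aerobic", forest = "aerobic", grassland = "aerobic",
    paddy = "anaerobic", sediment = "anaerobic", tundra = "anaerobic")
}

# Synthetic taxonomy pool. GC ranges are loosely modelled on the clades they
# name (Anaeromyxobacteraceae nif genes are distinctly GC-rich).
synth_family_pool <- function() {
  data.frame(
    lineage4 = c(
      "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Geobacteraceae",
      "Bacteria;Proteobacteria;Deltaproteobacteria;Myxococcales;Anaeromyxobacteraceae",
      "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Desulfuromonadaceae",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Nitrobacteraceae",
      "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Rhizobiaceae",
      "Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Azotobacteraceae",
      "Bacteria;Firmicutes;Clostridia;Eubacteriales;Clostridiaceae",
      "Bacteria;Cyanobacteria;Cyanophyceae;Nostocales;Nostocaceae",
      "Bacteria;Actinobacteria;Actinomycetia;Frankiales;Frankiaceae",
      "Bacteria;Acidobacteria;Acidobacteriia;Acidobacteriales;Acidobacteriaceae",
      "Bacteria;Actinobacteria;Actinomycetia;Streptomycetales;Streptomycetaceae",
      "Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Burkholderiaceae",
      "Bacteria;Bacteroidetes;Chitinophagia;Chitinophagales;Chitinophagaceae",
      "Bacteria;Verrucomicrobia;Verrucomicrobiae;Verrucomicrobiales;Verrucomicrobiaceae",
      "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae",
      "Bacteria;Cyanobacteria;Cyanophyceae;Chloroplast;Chloroplast"),
    diazo = c(rep(TRUE, 9), rep(FALSE, 7)),
    pref = c("anaerobic","anaerobic","anaerobic","aerobic","aerobic","aerobic",
             "anaerobic","either","aerobic", rep("either", 7)),
    gc_lo = c(0.55, 0.655, 0.50, 0.60, 0.58, 0.63, 0.30, 0.40, 0.68,
              0.55, 0.68, 0.62, 0.40, 0.55, 0.35, 0.35),
    gc_hi = c(0.62, 0.697, 0.60, 0.65, 0.63, 0.67, 0.40, 0.45, 0.72,
              0.62, 0.73, 0.68, 0.48, 0.62, 0.45, 0.42),
    contaminant = c(rep(FALSE, 14), TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Default configuration of the synthetic-data generator
#'
#' The defaults define the study conditions used throughout testing: 40
#' taxa per reference set (30% complete diazotrophs, 10% pseudo-nifH
#' carriers), marker base lengths 900/1500/1500 nt (nifH:nifD:nifK, the
#' 3:5:5 proportion) with +/-10% per-taxon jitter, a 10:1 spacer:marker
#' genome dilution, log-normal community abundances (sigma = 1), a 1%
#' aerobic mean diazotroph fraction amplified 17.6-fold in anaerobic
#' environments with log-normal between-sample scatter (sd 0.2 on the log
#' scale), 150-nt reads with 0.5% substitution errors and no GC bias.
#'
#' @param ... Named overrides of any default.
#' @return Named list of generator parameters.
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_taxa = 40L,
    frac_diazotroph = 0.30,
    frac_pseudo = 0.10,
    include_contaminants = TRUE,
    marker_base_len = c(nifH = 900L, nifD = 1500L, nifK = 1500L),
    length_jitter = 0.10,
    ssu_len = 1550L,
    rp_families = default_rp_families(),
    spacer_ratio = 10,
    div_family = 0.30,
    div_taxon = 0.12,
    lognormal_sigma = 1.0,
    aerobic_diazo_frac = 0.01,
    anaerobic_fold = 17.6,
    diazo_frac_sd_log = 0.2,
    env_family_bias = 4,
    contaminant_frac = 0,
    pseudo_frac = NULL,
    read_len = 150L,
    error_rate = 0.005,
    gc_bias_lambda = 0,
    n_reads = 2e5
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  assert_that(length(bad) == 0, "unknown config field(s): ",
              paste(bad, collapse = ", "), class = "diazo_config_error")
  cfg[names(ov)] <- ov
  assert_that(cfg$length_jitter >= 0 && cfg$length_jitter < 1 &&
              cfg$frac_diazotroph + cfg$frac_pseudo <= 1 &&
              cfg$spacer_ratio > 0 && cfg$error_rate >= 0 && cfg$error_rate < 1,
              "invalid generator configuration ranges", class = "diazo_config_error")
  cfg
}

rand_nt <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_protein <- function(n_aa) sample(AA20, n_aa, replace = TRUE)

mutate_protein <- function(aa, p) {
  hit <- which(stats::runif(length(aa)) < p)
  if (length(hit)) {
    repl <- sample(AA20, length(hit), replace = TRUE)
    # resample collisions so a "mutation" always changes the residue
    same <- repl == aa[hit]
    while (any(same)) {
      repl[same] <- sample(AA20, sum(same), replace = TRUE)
      same <- repl == aa[hit]
    }
    aa[hit] <- repl
  }
  aa
}

# codon table for the bacterial code, grouped by amino acid, with GC counts
codon_groups <- function() {
  code <- Biostrings::getGeneticCode("11")
  codons <- names(code)
  keep <- code != "*"
  split(data.frame(codon = codons[keep],
                   gc = vapply(strsplit(codons[keep], ""),
                               function(x) sum(x %in% c("G", "C")), 0L),
                   stringsAsFactors = FALSE),
        code[keep])
}

# Back-translate an amino-acid vector choosing synonymous codons with
# weights p^gc (1-p)^(3-gc), biasing realised GC toward the taxon target.
backtranslate <- function(aa, gc_target, groups = codon_groups()) {
  out <- character(length(aa))
  for (a in unique(aa)) {
    g <- groups[[a]]
    w <- gc_target^g$gc * (1 - gc_target)^(3 - g$gc)
    idx <- which(aa == a)
    out[idx] <- g$codon[sample.int(nrow(g), length(idx), replace = TRUE, prob = w)]
  }
  stops <- c("TAA", "TAG", "TGA")
  paste0(paste(out, collapse = ""), sample(stops, 1))
}

#' Simulate a marker reference set with known ground truth
#'
#' Generates `n_taxa` synthetic taxa assigned to a fixed pool of named
#' families (including Geobacteraceae and Anaeromyxobacteraceae within
#' Deltaproteobacteria), builds per-taxon marker genes (nitrogenase genes
#' evolved from shared family ancestors so that placement has signal;
#' independent single-copy ribosomal proteins and 16S rRNA), assembles each
#' genome as markers embedded in neutral spacer DNA at the taxon's GC, and
#' returns both the built reference database and the generating truth.
#'
#' @param n_taxa Number of non-contaminant taxa (>= 1).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param config A [synth_config()] list.
#' @return An object of class `diazo_refset` with elements `db`
#'   (`diazo_refdb`), `taxa` (truth table), `genomes`
#'   ([Biostrings::DNAStringSet]), `annotations`, `config`, `seed`.
#' @export
simulate_reference_set <- function(n_taxa = NULL, seed = 1L, config = synth_config()) {
  n_taxa <- as.integer(n_taxa %||% config$n_taxa)
  assert_that(n_taxa >= 1, "n_taxa must be >= 1", class = "diazo_config_error")
  with_seed(seed, {
    pool <- synth_family_pool()
    dpool <- pool[pool$diazo, ]
    npool <- pool[!pool$diazo & !pool$contaminant, ]

    n_dia <- max(1L, round(config$frac_diazotroph * n_taxa))
    n_pse <- round(config$frac_pseudo * n_taxa)
    n_oth <- n_taxa - n_dia - n_pse
    class_vec <- c(rep("diazotroph", n_dia), rep("pseudo_nifh", n_pse),
                   rep("non_diazotroph", max(0L, n_oth)))[seq_len(n_taxa)]
    fam_row <- integer(n_taxa)
    fam_row[class_vec == "diazotroph"] <-
      which(pool$diazo)[rep(seq_len(nrow(dpool)), length.out = n_dia)]
    fam_row[class_vec != "diazotroph"] <-
      which(!pool$diazo & !pool$contaminant)[
        rep(seq_len(nrow(npool)), length.out = n_taxa - n_dia)]

    taxa <- data.frame(
      taxon_id = sprintf("T%03d", seq_len(n_taxa)),
      class = class_vec,
      family_lineage = pool$lineage4[fam_row],
      pref = pool$pref[fam_row],
      contaminant = FALSE,
      gc = stats::runif(n_taxa, pool$gc_lo[fam_row], pool$gc_hi[fam_row]),
      stringsAsFactors = FALSE)
    if (config$include_contaminants) {
      cont <- pool[pool$contaminant, ]
      taxa <- rbind(taxa, data.frame(
        taxon_id = c("Tlacto", "Tchloro"),
        class = "non_diazotroph",
        family_lineage = cont$lineage4,
        pref = cont$pref,
        contaminant = TRUE,
        gc = stats::runif(2, cont$gc_lo, cont$gc_hi)))
    }
    taxa$lineage <- paste0(taxa$family_lineage, ";",
                           sub(".*;", "", taxa$family_lineage), "_g",
                           ";", taxa$taxon_id)

    # nitrogenase ancestors: one global per marker, one per taxonomic family
    groups <- codon_groups()
    nif_fams <- c("nifH", "nifD", "nifK")
    max_aa <- vapply(nif_fams, function(f)
      as.integer(ceiling((1 + config$length_jitter) * config$marker_base_len[[f]] / 3)), 0L)
    names(max_aa) <- nif_fams
    global_anc <- lapply(max_aa, random_protein)
    clade_anc <- list()
    anc_for <- function(marker, fam_lineage) {
      key <- paste(marker, fam_lineage, sep = "|")
      if (is.null(clade_anc[[key]]))
        clade_anc[[key]] <<- mutate_protein(global_anc[[marker]], config$div_family)
      clade_anc[[key]]
    }

    rp_fams <- config$rp_families
    rp_aa_len <- as.integer(round(seq(300, 700, length.out = length(rp_fams)) / 3))
    names(rp_aa_len) <- rp_fams

    genome_seq <- character(nrow(taxa))
    ann <- vector("list", nrow(taxa))
    prot_store <- list()  # taxon|family -> aa string (truth, pre-translation)

    for (i in seq_len(nrow(taxa))) {
      tx <- taxa$taxon_id[i]
      gc <- taxa$gc[i]
      markers <- character(0); seqs <- character(0)
      # ribosomal proteins
      for (f in rp_fams) {
        aa <- random_protein(rp_aa_len[[f]]); aa[1] <- "M"
        seqs <- c(seqs, backtranslate(aa, gc, groups)); markers <- c(markers, f)
        prot_store[[paste0(tx, "|", f)]] <- paste(aa, collapse = "")
      }
      # 16S
      seqs <- c(seqs, rand_nt(config$ssu_len, gc)); markers <- c(markers, "SSU16S")
      # nitrogenase complement
      nif_here <- switch(taxa$class[i], diazotroph = nif_fams,
                         pseudo_nifh = "nifH", character(0))
      for (f in nif_here) {
        target_aa <- as.integer(round(config$marker_base_len[[f]] / 3 *
                                stats::runif(1, 1 - config$length_jitter,
                                             1 + config$length_jitter)))
        target_aa <- min(target_aa, max_aa[[f]])
        aa <- mutate_protein(anc_for(f, taxa$family_lineage[i]),
                             config$div_taxon)[seq_len(target_aa)]
        aa[1] <- "M"
        seqs <- c(seqs, backtranslate(aa, gc, groups)); markers <- c(markers, f)
        prot_store[[paste0(tx, "|", f)]] <- paste(aa, collapse = "")
      }

      lens <- nchar(seqs)
      # spacers: total spacer_ratio x marker content, nif genes kept in one
      # neighbourhood separated by short spacers
      n_genes <- length(seqs)
      short <- markers %in% c("nifD", "nifK")   # spacer *before* these is short
      total_spacer <- round(config$spacer_ratio * sum(lens))
      n_slots <- n_genes + 1L
      w <- stats::runif(n_slots, 0.5, 1.5)
      w[which(short)] <- 0.001                  # keep nif operon tight
      spacer_len <- pmax(20L, as.integer(round(total_spacer * w / sum(w))))
      spacer_len[which(short)] <- sample(30:80, sum(short), replace = TRUE)

      pieces <- character(2 * n_genes + 1)
      starts <- integer(n_genes); strands <- character(n_genes)
      pos <- 0L
      for (j in seq_len(n_genes)) {
        sp <- rand_nt(spacer_len[j], gc)
        pieces[2 * j - 1] <- sp; pos <- pos + nchar(sp)
        starts[j] <- pos + 1L
        strands[j] <- sample(c("+", "-"), 1)
        gene_nt <- seqs[j]
        if (strands[j] == "-")
          gene_nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(gene_nt)))
        pieces[2 * j] <- gene_nt; pos <- pos + lens[j]
      }
      pieces[2 * n_genes + 1] <- rand_nt(spacer_len[n_slots], gc)
      genome_seq[i] <- paste(pieces, collapse = "")
      ann[[i]] <- data.frame(
        genome_id = tx, contig = tx, start = starts, end = starts + lens - 1L,
        strand = strands, family = markers,
        gene_id = paste0(tx, "_", markers), stringsAsFactors = FALSE)
    }

    genomes <- Biostrings::DNAStringSet(stats::setNames(genome_seq, taxa$taxon_id))
    annotations <- do.call(rbind, ann)
    taxonomy <- data.frame(genome_id = taxa$taxon_id, lineage = taxa$lineage,
                           stringsAsFactors = FALSE)
    db <- suppressMessages(build_db(genomes, annotations, taxonomy))
    structure(list(db = db, taxa = taxa, genomes = genomes,
                   annotations = annotations, config = config, seed = seed),
              class = "diazo_refset")
  })
}

#' @export
print.diazo_refset <- function(x, ...) {
  cat("diazo_refset:", nrow(x$taxa), "taxa (",
      sum(x$taxa$class == "diazotroph"), "diazotroph,",
      sum(x$taxa$class == "pseudo_nifh"), "pseudo-nifH,",
      sum(x$taxa$contaminant), "contaminant )\n")
  invisible(x)
}

#' Simulate a community abundance profile for one sample
#'
#' Taxon abundances are drawn log-normally and the diazotroph block is then
#' rescaled so that its total equals the sample's diazotroph fraction: the
#' environment-group mean (`aerobic_diazo_frac`, multiplied by
#' `anaerobic_fold` for anaerobic categories) times a log-normal
#' between-sample factor. Within the diazotroph block, taxa whose family
#' matches the environment's oxygen preference are up-weighted by
#' `env_family_bias`, which differentiates aerobic and anaerobic community
#' composition. Contaminant taxa receive `contaminant_frac` (default 0).
#'
#' @param refset A `diazo_refset`.
#' @param env Environment category (one of `names(env_groups())`).
#' @param config A [synth_config()] list (the refset's config by default).
#' @param seed Integer seed.
#' @param sample_id Optional id.
#' @return Object of class `synthetic_sample`: abundance vector over taxa
#'   (sums to 1) plus recomputable truth fields.
#' @export
simulate_community <- function(refset, env, config = refset$config, seed = 1L,
                               sample_id = NULL) {
  assert_that(env %in% names(env_groups()), "unknown environment: ", env)
  grp <- env_groups()[[env]]
  with_seed(seed, {
    taxa <- refset$taxa
    a <- stats::rlnorm(nrow(taxa), 0, config$lognormal_sigma)
    names(a) <- taxa$taxon_id
    dia <- taxa$class == "diazotroph"
    pse <- taxa$class == "pseudo_nifh"
    con <- taxa$contaminant
    # oxygen-preference bias inside the diazotroph block
    pref_hit <- dia & taxa$pref == grp
    a[pref_hit] <- a[pref_hit] * config$env_family_bias

    mean_frac <- config$aerobic_diazo_frac *
      if (grp == "anaerobic") config$anaerobic_fold else 1
    p_dia <- if (any(dia))
      mean_frac * stats::rlnorm(1, 0, config$diazo_frac_sd_log) else 0
    p_con <- if (any(con)) config$contaminant_frac else 0
    p_pse <- if (!is.null(config$pseudo_frac) && any(pse)) config$pseudo_frac else NA
    assert_that(p_dia + p_con + max(p_pse, 0, na.rm = TRUE) < 1,
                "target fractions exceed 1", class = "diazo_parameter_error")

    # fix diazotroph, contaminant and (optionally) pseudo blocks at their
    # target totals, spread the remainder over the free taxa

    fixed <- rep(NA_real_, nrow(taxa))
    if (any(dia)) fixed[dia] <- if (p_dia > 0) a[dia] / sum(a[dia]) * p_dia else 0
    if (any(con)) fixed[con] <- if (p_con > 0) a[con] / sum(a[con]) * p_con else 0
    if (!is.na(p_pse)) fixed[pse] <- if (p_pse > 0) a[pse] / sum(a[pse]) * p_pse else 0
    free <- is.na(fixed)
    rem <- 1 - sum(fixed, na.rm = TRUE)
    fixed[free] <- a[free] / sum(a[free]) * rem
    a <- stats::setNames(fixed, taxa$taxon_id)

    structure(list(
      sample_id = sample_id %||% paste0("S_", env, "_", seed),
      env = env, lat = NA_real_, lon = NA_real_,
      abundance = a,
      truth = list(diazotroph_fraction = sum(a[dia]),
                   pseudo_nifh_fraction = sum(a[pse]),
                   contaminant_fraction = sum(a[con]))),
      class = "synthetic_sample")
  })
}

#' Simulate shotgun reads from a community
#'
#' Fragments are drawn proportional to taxon abundance times genome length,
#' uniformly along the genome and from either strand. With
#' `gc_bias_lambda > 0`, fragments are accepted with probability
#' `plogis(-lambda * (fragGC - 0.5))`, emulating a sequencing bias against
#' GC-rich fragments. Per-base substitution errors are applied at
#' `error_rate` (no indels). Exactly `n_reads` reads are emitted with
#' constant Phred 37 qualities.
#'
#' @param refset A `diazo_refset`.
#' @param sample A `synthetic_sample`.
#' @param n_reads,read_len,error_rate,gc_bias_lambda Generator parameters
#'   (defaults from the refset's config).
#' @param seed Integer seed.
#' @return Object of class `diazo_reads`: parallel vectors `id`, `seq`,
#'   `qual` plus truth (`taxon`, `start`, `strand`).
#' @export
simulate_reads <- function(refset, sample, n_reads = NULL, read_len = NULL,
                           error_rate = NULL, gc_bias_lambda = NULL, seed = 1L) {
  cfg <- refset$config
  n_reads <- as.integer(n_reads %||% cfg$n_reads)
  read_len <- as.integer(read_len %||% cfg$read_len)
  error_rate <- error_rate %||% cfg$error_rate
  lambda <- gc_bias_lambda %||% cfg$gc_bias_lambda
  glen <- Biostrings::width(refset$genomes)
  names(glen) <- names(refset$genomes)
  assert_that(read_len <= min(glen), "read_len exceeds shortest genome")
  ab <- sample$abundance[names(glen)]
  w <- ab * glen
  if (n_reads == 0 || sum(w) == 0) {
    return(structure(list(id = character(0), seq = character(0),
                          qual = character(0), taxon = character(0),
                          start = integer(0), strand = character(0),
                          read_len = read_len), class = "diazo_reads"))
  }
  w <- w / sum(w)
  gchr <- as.character(refset$genomes)
  with_seed(seed, {
    taxon <- character(0); start <- integer(0); frag <- character(0)
    while (length(frag) < n_reads) {
      m <- ceiling((n_reads - length(frag)) * if (lambda > 0) 1.6 else 1)
      ti <- sample.int(length(glen), m, replace = TRUE, prob = w)
      st <- floor(stats::runif(m) * (glen[ti] - read_len + 1)) + 1L
      fr <- substring(gchr[ti], st, st + read_len - 1L)
      if (lambda > 0) {
        gc <- Biostrings::letterFrequency(Biostrings::DNAStringSet(fr),
                                          "GC", as.prob = TRUE)[, 1]
        keep <- stats::runif(m) < stats::plogis(-lambda * (gc - 0.5))
        ti <- ti[keep]; st <- st[keep]; fr <- fr[keep]
      }
      taxon <- c(taxon, names(glen)[ti]); start <- c(start, as.integer(st))
      frag <- c(frag, fr)
    }
    keep <- seq_len(n_reads)
    taxon <- unname(taxon[keep]); start <- unname(start[keep])
    frag <- unname(frag[keep])

    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    if (any(strand == "-")) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(frag[strand == "-"])))
      frag[strand == "-"] <- rc
    }
    # substitution errors: binomial count per read, positions drawn with
    # replacement, applied in vectorised rounds
    nerr <- stats::rbinom(n_reads, read_len, error_rate)
    if (any(nerr > 0)) {
      bases <- c("A", "C", "G", "T")
      # subst[b, k] = k-th alternative base for current base b
      subst <- rbind(c("C","G","T"), c("A","G","T"), c("A","C","T"), c("A","C","G"))
      rownames(subst) <- bases
      for (round in seq_len(max(nerr))) {
        ii <- which(nerr >= round)
        pos <- sample.int(read_len, length(ii), replace = TRUE)
        cur <- substr(frag[ii], pos, pos)
        new <- subst[cbind(match(cur, bases),
                           sample.int(3L, length(ii), replace = TRUE))]
        s <- frag[ii]
        substr(s, pos, pos) <- new
        frag[ii] <- s
      }
    }
    structure(list(
      id = paste0(sample$sample_id, "_r", seq_len(n_reads)),
      seq = frag,
      qual = rep(strrep("F", read_len), n_reads),   # Phred+33, Q37
      taxon = taxon, start = start, strand = strand,
      read_len = read_len), class = "diazo_reads")
  })
}

#' @export
print.diazo_reads <- function(x, ...) {
  cat("diazo_reads:", length(x$id), "reads of", x$read_len, "nt\n")
  invisible(x)
}

#' Write / read reads as FASTQ (Phred+33)
#'
#' @param reads A `diazo_reads` object.
#' @param path Output file.
#' @return `path` invisibly; `read_fastq()` returns a `diazo_reads` object
#'   (without simulation truth).
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads$id)
  out <- character(4 * n)
  if (n) {
    out[seq(1, 4 * n, 4)] <- paste0("@", reads$id)
    out[seq(2, 4 * n, 4)] <- reads$seq
    out[seq(3, 4 * n, 4)] <- "+"
    out[seq(4, 4 * n, 4)] <- reads$qual
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  ln <- readLines(path)
  assert_that(length(ln) %% 4 == 0, "truncated FASTQ: ", path,
              class = "diazo_parse_error")
  n <- length(ln) / 4
  ids <- ln[seq(1, length(ln), 4)]
  bad <- which(!startsWith(ids, "@"))
  assert_that(length(bad) == 0, "malformed FASTQ record at index ",
              if (length(bad)) bad[1] else "", class = "diazo_parse_error")
  structure(list(id = sub("^@", "", ids),
                 seq = ln[seq(2, length(ln), 4)],
                 qual = ln[seq(4, length(ln), 4)],
                 taxon = NULL, start = NULL, strand = NULL,
                 read_len = if (n) max(nchar(ln[seq(2, length(ln), 4)])) else 0L),
            class = "diazo_reads")
}

#' Simulate sampling-site metadata with sub-kilometre replicates
#'
#' Site centres are at least 10 km apart; replicate samples of a site are
#' jittered uniformly within `jitter_km` of the centre (great-circle).
#'
#' @param n_sites Number of distinct sites.
#' @param replicates_per_site Samples per site.
#' @param jitter_km Maximum replicate displacement (km, >= 0).
#' @param seed Integer seed.
#' @param envs Optional environment category per site (recycled).
#' @return data.frame: `sample_id`, `site`, `env`, `lat`, `lon`.
#' @export
simulate_geo_metadata <- function(n_sites, replicates_per_site = 1L,
                                  jitter_km = 0.4, seed = 1L, envs = NULL) {
  assert_that(jitter_km >= 0, "jitter_km must be >= 0")
  envs <- rep(envs %||% names(env_groups()), length.out = n_sites)
  with_seed(seed, {
    lat <- numeric(0); lon <- numeric(0)
    while (length(lat) < n_sites) {
      la <- stats::runif(1, -60, 70); lo <- stats::runif(1, -180, 180)
      if (!length(lat) || all(haversine_km(la, lo, lat, lon) >= 10)) {
        lat <- c(lat, la); lon <- c(lon, lo)
      }
    }
    rows <- lapply(seq_len(n_sites), function(s) {
      r <- jitter_km * sqrt(stats::runif(replicates_per_site))
      th <- stats::runif(replicates_per_site, 0, 2 * pi)
      km_per_deg <- pi / 180 * 6371.0088
      data.frame(
        sample_id = sprintf("site%02d_rep%d", s, seq_len(replicates_per_site)),
        site = s, env = envs[s],
        lat = lat[s] + r * sin(th) / km_per_deg,
        lon = lon[s] + r * cos(th) / (km_per_deg * cos(lat[s] * pi / 180)),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
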