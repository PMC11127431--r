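#' Marker gene families recognised by the reference database
#'
#' The quantification markers are the nitrogenase structural genes
#' `nifD`/`nifK` and their vanadium (`vnfD`/`vnfK`) and iron-only
#' (`anfD`/`anfK`) counterparts. `nifH` is tracked for pseudo-nifH
#' diagnostics and primer analyses but never enters the dominance ratio,
#' because short NifH fragments are easily confused with paralogous
#' reductases. Single-copy ribosomal proteins serve as the per-genome
#' normaliser, and `SSU16S` supports community profiling and contamination
#' screening.
#'
#' @return Character vector of the nitrogenase D/K-type family names.
#' @export
nitrogenase_dk_families <- function() c("nifD", "nifK", "vnfD", "vnfK", "anfD", "anfK")

#' @rdname nitrogenase_dk_families
#' @export
nitrogenase_families <- function() c("nifH", nitrogenase_dk_families())

#' Default universal single-copy ribosomal protein gene set
#'
#' A configurable stand-in for the curated single-copy ribosomal protein
#' panel used for read-depth normalisation: fifteen ribosomal protein genes
#' that are near-universally present in exactly one copy per prokaryotic
#' genome.
#'
#' @return Character vector of gene (family) names.
#' @export
default_rp_families <- function() {
  c("rplB", "rplC", "rplD", "rplE", "rplF", "rplN", "rplP", "rplR",
    "rplV", "rpsC", "rpsE", "rpsH", "rpsJ", "rpsQ", "rpsS")
}

marker_role <- function(family) {
  role <- rep("ribosomal_protein", length(family))
  role[family == "nifH"] <- "nitrogenase_H"
  role[family %in% nitrogenase_dk_families()] <- "nitrogenase_DK"
  role[family == "SSU16S"] <- "rRNA"
  role
}

is_protein_family <- function(family) family != "SSU16S"

#' Build the marker reference database
#'
#' Extracts annotated marker genes (nitrogenase families, single-copy
#' ribosomal proteins, 16S rRNA) from genome sequences, reverse-complements
#' minus-strand CDS, translates protein-coding families with the bacterial
#' genetic code, and attaches taxonomy. Nitrogenase annotations on archaeal
#' genomes are dropped: the profiling pipeline is restricted to bacterial
#' nitrogenases.
#'
#' @param genomes Named [Biostrings::DNAStringSet] (names are contig ids), a
#'   named character vector, or the path of a nucleotide FASTA file.
#' @param annotations data.frame with columns `genome_id`, `contig`,
#'   `start`, `end` (1-based inclusive), `strand` (`"+"`/`"-"`), `family`,
#'   `gene_id`. Any family not in [nitrogenase_families()] or `"SSU16S"` is
#'   treated as a single-copy ribosomal protein.
#' @param taxonomy data.frame with columns `genome_id` and `lineage`
#'   (semicolon-delimited, rooted at a domain), or a named character vector.
#' @return An object of class `diazo_refdb`: gene table, nucleotide and
#'   protein sequence sets, and per-genome lineages.
#' @export
build_db <- function(genomes, annotations, taxonomy) {
  if (is.character(genomes) && length(genomes) == 1 && file.exists(genomes))
    genomes <- Biostrings::readDNAStringSet(genomes)
  if (is.character(genomes)) genomes <- Biostrings::DNAStringSet(genomes)
  assert_that(!is.null(names(genomes)) && !anyNA(names(genomes)),
              "genome sequences must be named")
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  need <- c("genome_id", "contig", "start", "end", "strand", "family", "gene_id")
  assert_that(all(need %in% names(ann)),
              "annotation table must have columns: ", paste(need, collapse = ", "))
  assert_that(!anyDuplicated(ann$gene_id), "gene_id values must be unique")
  assert_that(all(ann$strand %in% c("+", "-")),
              "strand must be '+' or '-'", class = "diazo_annotation_error")

  if (is.data.frame(taxonomy)) {
    tax <- stats::setNames(as.character(taxonomy$lineage), taxonomy$genome_id)
  } else tax <- taxonomy
  assert_that(all(ann$genome_id %in% names(tax)),
              "every annotated genome needs a lineage")
  assert_that(all(nzchar(tax)), "lineages must be non-empty")

  widths <- stats::setNames(Biostrings::width(genomes), names(genomes))
  miss <- setdiff(ann$contig, names(genomes))
  assert_that(length(miss) == 0, "annotation references unknown contig(s): ",
              paste(miss, collapse = ", "), class = "diazo_coordinate_error")
  bad <- which(ann$start < 1 | ann$end > widths[ann$contig] | ann$start > ann$end)
  if (length(bad))
    stop_diazo("annotation coordinates out of bounds for row(s): ",
               paste(bad, collapse = ", "), " (gene ",
               paste(ann$gene_id[bad], collapse = ", "), ")",
               class = "diazo_coordinate_error")

  # Drop nitrogenase annotations from archaeal genomes.
  dom <- lineage_at(tax[ann$genome_id], "domain")
  arch_nif <- dom == "Archaea" & ann$family %in% nitrogenase_families()
  if (any(arch_nif)) {
    message("dropping ", sum(arch_nif), " nitrogenase annotation(s) on archaeal genomes")
    ann <- ann[!arch_nif, , drop = FALSE]
  }

  nt <- Biostrings::subseq(genomes[ann$contig], start = ann$start, end = ann$end)
  minus <- ann$strand == "-"
  if (any(minus)) nt[minus] <- Biostrings::reverseComplement(nt[minus])
  names(nt) <- ann$gene_id

  prot_i <- which(is_protein_family(ann$family))
  badlen <- prot_i[Biostrings::width(nt)[prot_i] %% 3 != 0]
  if (length(badlen))
    stop_diazo("CDS length not divisible by 3 for gene(s): ",
               paste(ann$gene_id[badlen], collapse = ", "),
               class = "diazo_annotation_error")
  aa <- Biostrings::AAStringSet()
  if (length(prot_i)) {
    aa <- Biostrings::translate(nt[prot_i],
                                genetic.code = Biostrings::getGeneticCode("11"),
                                if.fuzzy.codon = "solve")
    chr <- as.character(aa)
    chr <- sub("\\*$", "", chr)          # trailing stop codon
    internal <- grepl("*", chr, fixed = TRUE)
    if (any(internal)) {
      warning("internal stop codon(s) in: ",
              paste(ann$gene_id[prot_i][internal], collapse = ", "),
              "; stops stripped", call. = FALSE)
      chr <- gsub("*", "", chr, fixed = TRUE)
    }
    aa <- Biostrings::AAStringSet(chr)
    names(aa) <- ann$gene_id[prot_i]
  }

  genes <- data.frame(
    gene_id = ann$gene_id, genome_id = ann$genome_id, contig = ann$contig,
    start = as.integer(ann$start), end = as.integer(ann$end),
    strand = ann$strand, family = ann$family, role = marker_role(ann$family),
    length_nt = as.integer(Biostrings::width(nt)),
    stringsAsFactors = FALSE
  )
  db <- structure(list(genes = genes, nt = nt, aa = aa, taxonomy = tax),
                  class = "diazo_refdb")
  counts <- table(genes$family)
  message("reference database: ", nrow(genes), " genes in ",
          length(counts), " families (",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), ")")
  db
}

#' @export
print.diazo_refdb <- function(x, ...) {
  cat("diazo_refdb:", nrow(x$genes), "marker genes,",
      length(unique(x$genes$genome_id)), "genomes\n")
  print(table(x$genes$family))
  invisible(x)
}

db_lineage <- function(db, genome_id) unname(db$taxonomy[genome_id])

#' Screen genomes for complete molybdenum nitrogenase
#'
#' A genome is considered diazotrophic only if it carries at least one copy
#' of each structural gene `nifH`, `nifD` and `nifK`; genomes with `nifH`
#' alone are pseudo-nifH carriers. Archaeal genomes are always excluded.
#'
#' @param db A `diazo_refdb`.
#' @return Character vector of genome ids (possibly empty).
#' @export
screen_diazotroph_genomes <- function(db) {
  g <- db$genes[db$genes$family %in% c("nifH", "nifD", "nifK"), c("genome_id", "family")]
  if (!nrow(g)) return(character(0))
  tab <- table(g$genome_id, g$family)
  has <- vapply(c("nifH", "nifD", "nifK"), function(f)
    if (f %in% colnames(tab)) tab[, f] > 0 else rep(FALSE, nrow(tab)),
    logical(nrow(tab)))
  has <- matrix(has, nrow = nrow(tab))
  ok <- rownames(tab)[rowSums(has) == 3L]
  dom <- lineage_at(db$taxonomy[ok], "domain")
  sort(ok[dom != "Archaea"])
}

#' GC content of a marker family within one genome
#'
#' GC is computed over the concatenation of all qualifying copies of the
#' family in the genome; for 16S rRNA only copies of at least `min_ssu_len`
#' nucleotides qualify. Ambiguous (non-ACGT) bases are excluded from both
#' numerator and denominator.
#'
#' @param db A `diazo_refdb`.
#' @param genome_id Genome identifier.
#' @param family Marker family name.
#' @param min_ssu_len Minimum copy length for 16S rRNA (default 1000 nt).
#' @return Fraction in `[0, 1]`, or `NA_real_` when the genome has no
#'   qualifying copy.
#' @export
gc_content <- function(db, genome_id, family, min_ssu_len = 1000L) {
  sel <- db$genes$genome_id == genome_id & db$genes$family == family
  if (family == "SSU16S") sel <- sel & db$genes$length_nt >= min_ssu_len
  ids <- db$genes$gene_id[sel]
  if (!length(ids)) return(NA_real_)
  s <- paste(as.character(db$nt[ids]), collapse = "")
  f <- Biostrings::letterFrequency(Biostrings::DNAString(s), c("A", "C", "G", "T"))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  unname((f[["G"]] + f[["C"]]) / tot)
}

#' Select the genuine nifH copy of a genome
#'
#' When a genome carries multiple `nifH` copies, the copy whose genomic
#' distance to the nearest `nifD`/`nifK` annotation is minimal is selected
#' (pseudo-nifH copies are typically far from the nif operon); ties are
#' broken by the smaller start coordinate. Copies on contigs without any
#' `nifD`/`nifK` get infinite distance.
#'
#' @inheritParams gc_content
#' @return The selected `gene_id`.
#' @export
select_nifh_copy <- function(db, genome_id) {
  g <- db$genes
  h <- g[g$genome_id == genome_id & g$family == "nifH", , drop = FALSE]
  assert_that(nrow(h) > 0, "genome ", genome_id, " has no nifH copy",
              class = "diazo_absent_marker_error")
  if (nrow(h) == 1) return(h$gene_id)
  dk <- g[g$genome_id == genome_id & g$family %in% c("nifD", "nifK"), , drop = FALSE]
  dist_to_dk <- function(i) {
    same <- dk[dk$contig == h$contig[i], , drop = FALSE]
    if (!nrow(same)) return(Inf)
    # gap between intervals; overlapping/adjacent -> 0
    min(pmax(0, pmax(same$start - h$end[i], h$start[i] - same$end)))
  }
  d <- vapply(seq_len(nrow(h)), dist_to_dk, 0)
  h$gene_id[order(d, h$start)][1]
}

#' Per-family gene-length table
#'
#' Lossless projection of the database used for per-gene RPKM length
#' correction.
#'
#' @param db A `diazo_refdb`.
#' @return Named list (per family) of data.frames with `gene_id`, `length_nt`.
#' @export
marker_length_table <- function(db) {
  split(db$genes[, c("gene_id", "length_nt")], db$genes$family)
}

mean_family_length <- function(db, family) {
  sel <- db$genes$family == family
  if (!any(sel)) return(NA_real_)
  mean(db$genes$length_nt[sel])
}

#' Serialise / load a reference database directory
#'
#' Writes one protein FASTA per protein-coding family, a nucleotide FASTA of
#' all genes, a TSV gene index and a TSV taxonomy table.
#'
#' @param db A `diazo_refdb`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; `read_refdb()` returns the reconstructed
#'   `diazo_refdb`.
#' @export
write_refdb <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(db$genes, file.path(dir, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(db$nt, file.path(dir, "genes_nt.fasta"))
  for (fam in unique(db$genes$family[is_protein_family(db$genes$family)])) {
    ids <- db$genes$gene_id[db$genes$family == fam]
    Biostrings::writeXStringSet(db$aa[ids], file.path(dir, paste0(fam, "_aa.fasta")))
  }
  tx <- data.frame(genome_id = names(db$taxonomy), lineage = unname(db$taxonomy))
  utils::write.table(tx, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_refdb
#' @export
read_refdb <- function(dir) {
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), stringsAsFactors = FALSE)
  nt <- Biostrings::readDNAStringSet(file.path(dir, "genes_nt.fasta"))
  nt <- nt[genes$gene_id]
  prot <- genes$gene_id[is_protein_family(genes$family)]
  aa <- Biostrings::AAStringSet()
  for (fam in unique(genes$family[is_protein_family(genes$family)])) {
    aa <- c(aa, Biostrings::readAAStringSet(file.path(dir, paste0(fam, "_aa.fasta"))))
  }
  aa <- aa[prot]
  tx <- utils::read.delim(file.path(dir, "taxonomy.tsv"), stringsAsFactors = FALSE)
  structure(list(genes = genes, nt = nt, aa = aa,
                 taxonomy = stats::setNames(tx$lineage, tx$genome_id)),
            class = "diazo_refdb")
}
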