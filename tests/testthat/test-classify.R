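reads_obj <- function(seqs, quals = NULL, ids = NULL) {
  structure(list(
    id = ids %||% paste0("r", seq_along(seqs)), seq = seqs,
    qual = quals %||% vapply(nchar(seqs), function(n) strrep("I", n), ""),
    taxon = NULL, start = NULL, strand = NULL,
    read_len = max(nchar(seqs), 0L)), class = "diazo_reads")
}

excise <- function(rs, gene_id, from = 31L, len = 150L, revcomp = FALSE) {
  s <- substr(as.character(rs$db$nt[[gene_id]]), from, from + len - 1L)
  if (revcomp)
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

test_that("quality filter applies length and mean-quality floors in order", {
  rd <- reads_obj(c(strrep("A", 150), strrep("C", 150), strrep("G", 50)),
                  quals = c(strrep("I", 150), strrep("#", 150), strrep("I", 50)))
  kept <- quality_filter(rd, min_len = 100, min_mean_q = 20)
  expect_identical(kept$id, "r1")          # r2 low quality, r3 short
  all_ok <- quality_filter(reads_obj(rep(strrep("A", 150), 3)), 100, 20)
  expect_length(all_ok$id, 3)
  empty <- quality_filter(reads_obj(character(0)), 100, 20)
  expect_length(empty$id, 0)
})

test_that("error-free marker reads are assigned to their source gene on either strand", {
  rs <- small_refset()
  idx <- small_index()
  gid <- rs$db$genes$gene_id[rs$db$genes$family == "nifD"][1]
  rd <- reads_obj(c(excise(rs, gid), excise(rs, gid, revcomp = TRUE)))
  a <- assign_protein_marker(rd, rs$db, idx)
  expect_equal(a$gene_id, c(gid, gid))
  expect_equal(a$identity, c(1, 1))
  expect_equal(a$family, c("nifD", "nifD"))
})

test_that("random reads are almost never assigned", {
  rs <- small_refset()
  idx <- small_index()
  set.seed(99)
  seqs <- vapply(seq_len(4000), function(i)
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""), "")
  a <- assign_protein_marker(reads_obj(seqs), rs$db, idx)
  expect_lt(mean(!is.na(a$gene_id)), 0.001)
  s <- assign_16s(reads_obj(seqs[1:1000]), rs$db, idx)
  expect_lt(mean(!is.na(s$lineage)), 0.001)
})

test_that("exact score ties resolve to the lexicographically smaller gene id", {
  # two identical nifD copies on one genome
  cds <- strrep("GCTAAAGCTGCTAAAAAA", 30)    # 540 nt, stop-free
  genome <- paste0(cds, strrep("ACGT", 50), cds)
  ann <- data.frame(genome_id = "g", contig = "g",
                    start = c(1L, 741L), end = c(540L, 1280L), strand = "+",
                    family = "nifD", gene_id = c("g_b", "g_a"))
  db <- suppressMessages(build_db(c(g = genome), ann,
    data.frame(genome_id = "g", lineage = "Bacteria;P;C;O;F;G;g")))
  idx <- classifier_index(db)
  rd <- reads_obj(substr(genome, 31, 180))
  a <- assign_protein_marker(rd, db, idx)
  expect_equal(a$gene_id, "g_a")
})

test_that("16S assignment is strand-symmetric and identity-thresholded", {
  rs <- small_refset()
  idx <- small_index()
  g16 <- rs$db$genes$gene_id[rs$db$genes$family == "SSU16S" &
                               rs$db$genes$genome_id == "Tlacto"]
  fwd <- excise(rs, g16, from = 201)
  rev <- excise(rs, g16, from = 201, revcomp = TRUE)
  a <- assign_16s(reads_obj(c(fwd, rev)), rs$db, idx)
  expect_equal(a$lineage[1], a$lineage[2])
  expect_match(a$lineage[1], "Lactobacillales")
  # ~40% mutated read fails the 0.8 identity floor
  set.seed(7)
  v <- strsplit(fwd, "")[[1]]
  hit <- sample(150, 60)
  v[hit] <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  far <- paste(v, collapse = "")
  a2 <- assign_16s(reads_obj(far), rs$db, idx)
  expect_true(is.na(a2$lineage))
})

test_that("profiles aggregate counts per gene and composition per rank", {
  rs <- small_refset()
  idx <- small_index()
  tx <- screen_diazotroph_genomes(rs$db)[1]
  comm <- simulate_community(rs, "paddy", seed = 5)
  comm$abundance[] <- 0
  comm$abundance[tx] <- 1
  rd <- simulate_reads(rs, comm, n_reads = 8000, seed = 23)
  p <- profile_sample(rd, rs$db, list(sample_id = "one", env = "paddy",
                                      lat = 0, lon = 0),
                      classify_config(nt_prefilter = TRUE), idx)
  expect_true(all(startsWith(p$counts$gene_id, tx)))
  expect_equal(p$total_reads_qc, 8000)
  expect_lte(sum(p$counts$count), p$total_reads_qc)
  comp <- summarize_composition(p, "phylum")
  expect_equal(sum(comp), 1, tolerance = 1e-9)
  expect_length(comp, 1)   # single source taxon
})

test_that("composition splits proteobacterial classes and handles mocks", {
  ssu <- data.frame(
    lineage = c("Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Geobacteraceae;G_g;t1",
                "Bacteria;Firmicutes;Clostridia;Eubacteriales;Clostridiaceae;C_g;t2"),
    count = c(3L, 1L))
  p <- mock_profile("m", ssu = ssu)
  comp <- summarize_composition(p, "phylum")
  expect_equal(unname(comp[c("Deltaproteobacteria", "Firmicutes")]), c(0.75, 0.25))
  ord <- summarize_composition(p, "order")
  expect_equal(unname(ord["Desulfuromonadales"]), 0.75)
  empty <- mock_profile("e")
  expect_equal(empty$n_ssu_reads, 0L)
  expect_error(summarize_composition(empty), class = "diazo_rank_error")
})

test_that("halving the reads halves expected marker counts", {
  rs <- small_refset()
  idx <- small_index()
  cfg <- classify_config(nt_prefilter = TRUE)
  comm <- simulate_community(rs, "paddy", seed = 5)
  rd <- simulate_reads(rs, comm, n_reads = 40000, seed = 29)
  half <- rd
  for (f in c("id", "seq", "qual", "taxon", "start", "strand"))
    half[[f]] <- half[[f]][1:20000]
  md <- list(sample_id = "s", env = "paddy", lat = 0, lon = 0)
  pf <- profile_sample(rd, rs$db, md, cfg, idx)
  ph <- profile_sample(half, rs$db, md, cfg, idx)
  n_full <- sum(pf$counts$count)
  n_half <- sum(ph$counts$count)
  expect_lt(abs(n_half - n_full / 2), 3 * sqrt(n_full / 4))
})

test_that("seeded search agrees with the exhaustive Smith-Waterman oracle", {
  rs <- small_refset()
  # marker-only database keeps the exhaustive scan tractable
  db <- rs$db
  keep <- db$genes$family %in% c("nifH", "nifD", "nifK") &
    db$genes$genome_id %in% screen_diazotroph_genomes(db)[1:2]
  ids <- db$genes$gene_id[keep]
  db$genes <- db$genes[keep, ]
  db$nt <- db$nt[ids]; db$aa <- db$aa[ids]
  idx <- classifier_index(db)
  set.seed(41)
  n <- 250
  src <- sample(ids, n, replace = TRUE)
  seqs <- vapply(src, function(g) {
    L <- nchar(as.character(db$nt[[g]]))
    from <- sample(L - 150L, 1)
    s <- substr(as.character(db$nt[[g]]), from, from + 149L)
    v <- strsplit(s, "")[[1]]
    nm <- rbinom(1, 150, 0.01)
    if (nm > 0) {
      pos <- sample(150, nm)
      v[pos] <- sample(c("A", "C", "G", "T"), nm, replace = TRUE)
    }
    paste(v, collapse = "")
  }, "")
  rd <- reads_obj(unname(seqs))
  fast <- assign_protein_marker(rd, db, idx)
  full <- assign_protein_marker(rd, db, config = classify_config(method = "full"))
  agree <- mean((is.na(fast$gene_id) & is.na(full$gene_id)) |
                  (!is.na(fast$gene_id) & !is.na(full$gene_id) &
                     fast$gene_id == full$gene_id))
  expect_gte(agree, 0.99)
})

test_that("classification is deterministic and order-independent in scores", {
  rs <- small_refset()
  idx <- small_index()
  gid <- rs$db$genes$gene_id[rs$db$genes$family == "nifK"][1]
  rd <- reads_obj(c(excise(rs, gid), excise(rs, gid, from = 101)))
  a1 <- assign_protein_marker(rd, rs$db, idx)
  a2 <- assign_protein_marker(rd, rs$db, idx)
  expect_identical(a1, a2)
})
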