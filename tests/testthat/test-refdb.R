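test_that("build_db extracts annotated markers and handles strand", {
  db <- tiny_db()
  expect_s3_class(db, "diazo_refdb")
  expect_equal(nrow(db$genes), 2)
  # minus-strand CDS "CAT" is stored reverse-complemented and translated
  expect_equal(as.character(db$nt[["gA_nifH"]]), "ATG")
  expect_equal(as.character(db$aa[["gA_nifH"]]), "M")
  # trailing stop stripped from the protein
  expect_equal(as.character(db$aa[["gA_nifD"]]), "MAAK")
  expect_equal(db$genes$length_nt, c(15L, 3L))
})

test_that("build_db validates coordinates and CDS lengths", {
  bad_end <- data.frame(genome_id = "gB", contig = "gB", start = 100L,
                        end = 500L, strand = "+", family = "nifK",
                        gene_id = "gB_nifK")
  expect_error(tiny_db(bad_end), class = "diazo_coordinate_error")
  bad_len <- data.frame(genome_id = "gB", contig = "gB", start = 1L,
                        end = 4L, strand = "+", family = "nifK",
                        gene_id = "gB_nifK")
  expect_error(tiny_db(bad_len), class = "diazo_annotation_error")
})

test_that("build_db is deterministic", {
  d1 <- tiny_db(); d2 <- tiny_db()
  expect_identical(d1$genes, d2$genes)
  expect_identical(as.character(d1$nt), as.character(d2$nt))
  expect_identical(as.character(d1$aa), as.character(d2$aa))
})

test_that("diazotroph screening requires nifH, nifD and nifK and excludes archaea", {
  mk_db <- function(fams, domain = "Bacteria") {
    n <- length(fams)
    genome <- strrep("GCTAAA", 10 * n)
    starts <- seq(1L, by = 60L, length.out = n)
    ann <- data.frame(genome_id = "g", contig = "g", start = starts,
                      end = starts + 59L, strand = "+", family = fams,
                      gene_id = paste0("g_", fams, "_", seq_len(n)))
    suppressMessages(build_db(
      c(g = genome), ann,
      data.frame(genome_id = "g",
                 lineage = paste0(domain, ";P;C;O;F;G;g"))))
  }
  expect_equal(screen_diazotroph_genomes(mk_db(c("nifH", "nifD", "nifK"))), "g")
  expect_equal(screen_diazotroph_genomes(mk_db("nifH")), character(0))
  # archaeal nitrogenase annotations are dropped at build time
  db_a <- NULL
  msgs <- testthat::capture_messages(
    db_a <- build_db(
      c(g = strrep("GCTAAA", 30)),
      data.frame(genome_id = "g", contig = "g",
                 start = c(1L, 61L, 121L), end = c(60L, 120L, 180L),
                 strand = "+", family = c("nifH", "nifD", "nifK"),
                 gene_id = paste0("g_", c("nifH", "nifD", "nifK"))),
      data.frame(genome_id = "g", lineage = "Archaea;P;C;O;F;G;g")))
  expect_true(any(grepl("archaeal", msgs)))
  expect_equal(screen_diazotroph_genomes(db_a), character(0))
})

test_that("screening is unaffected by non-nitrogenase genes", {
  rs <- small_refset()
  base <- screen_diazotroph_genomes(rs$db)
  expect_true(all(base %in% rs$taxa$taxon_id[rs$taxa$class == "diazotroph"]))
  expect_setequal(base, rs$taxa$taxon_id[rs$taxa$class == "diazotroph"])
  # drop every ribosomal-protein gene: screen unchanged
  db2 <- rs$db
  keep <- db2$genes$role != "ribosomal_protein"
  ids <- db2$genes$gene_id[keep]
  db2$genes <- db2$genes[keep, ]
  db2$nt <- db2$nt[ids]
  expect_equal(screen_diazotroph_genomes(db2), base)
})

test_that("gc_content concatenates copies and excludes ambiguous bases", {
  mk_16s <- function(copies) {
    genome <- paste(copies, collapse = "")
    ends <- cumsum(nchar(copies))
    starts <- ends - nchar(copies) + 1L
    ann <- data.frame(genome_id = "g", contig = "g", start = starts,
                      end = ends, strand = "+", family = "SSU16S",
                      gene_id = paste0("g_16s_", seq_along(copies)))
    suppressMessages(build_db(c(g = genome), ann,
      data.frame(genome_id = "g", lineage = "Bacteria;P;C;O;F;G;g")))
  }
  expect_equal(gc_content(mk_16s("ATGC"), "g", "SSU16S", min_ssu_len = 1), 0.5)
  expect_equal(gc_content(mk_16s(c("AT", "GC")), "g", "SSU16S", min_ssu_len = 1), 0.5)
  expect_equal(gc_content(mk_16s("ATGN"), "g", "SSU16S", min_ssu_len = 1), 1 / 3)
  # 16S copies shorter than the length floor do not qualify
  expect_true(is.na(gc_content(mk_16s("ATGC"), "g", "SSU16S", min_ssu_len = 1000)))
  # no qualifying family at all -> undefined, not zero
  expect_true(is.na(gc_content(mk_16s("ATGC"), "g", "nifD")))
})

test_that("gc_content is invariant under copy duplication", {
  rs <- small_refset()
  tx <- rs$taxa$taxon_id[1]
  g1 <- gc_content(rs$db, tx, "SSU16S")
  expect_gte(g1, 0); expect_lte(g1, 1)
  # duplicate the 16S entry: concatenation of identical copies keeps GC
  db2 <- rs$db
  row <- db2$genes[db2$genes$genome_id == tx & db2$genes$family == "SSU16S", ]
  row$gene_id <- paste0(row$gene_id, "_dup")
  db2$genes <- rbind(db2$genes, row)
  dup <- db2$nt[paste0(tx, "_SSU16S")]
  names(dup) <- row$gene_id
  db2$nt <- c(db2$nt, dup)
  expect_equal(gc_content(db2, tx, "SSU16S"), g1)
})

test_that("select_nifh_copy prefers the copy nearest to nifD/K", {
  mk <- function(extra_nifh_start = NULL) {
    genome <- strrep("GCTAAA", 2000)   # 12 kb
    ann <- data.frame(genome_id = "g", contig = "g",
                      start = c(1L, 301L), end = c(60L, 360L),
                      strand = "+", family = c("nifH", "nifD"),
                      gene_id = c("h1", "d1"))
    if (!is.null(extra_nifh_start))
      ann <- rbind(ann, data.frame(genome_id = "g", contig = "g",
                                   start = extra_nifh_start,
                                   end = extra_nifh_start + 59L, strand = "+",
                                   family = "nifH", gene_id = "h2"))
    suppressMessages(build_db(c(g = genome), ann,
      data.frame(genome_id = "g", lineage = "Bacteria;P;C;O;F;G;g")))
  }
  expect_equal(select_nifh_copy(mk(), "g"), "h1")          # single copy
  expect_equal(select_nifh_copy(suppressWarnings(mk(9000L)), "g"), "h1")
  # equidistant copies: smaller start coordinate wins (h1 at 1, h2 at 601;
  # both 240 nt from the nifD interval 301..360)
  expect_equal(select_nifh_copy(mk(601L), "g"), "h1")
  db0 <- quant_db()
  expect_error(select_nifh_copy(db0, "missing"),
               class = "diazo_absent_marker_error")
})

test_that("marker_length_table is a lossless projection", {
  db <- quant_db()
  lt <- marker_length_table(db)
  expect_equal(lt$nifH$length_nt, 900L)
  expect_equal(lt$nifD$length_nt, 1500L)
  expect_equal(lt$nifK$length_nt, 1500L)
  expect_null(lt$vnfD)
  rs <- small_refset()
  lt2 <- marker_length_table(rs$db)
  expect_equal(sum(lengths(lapply(lt2, `[[`, "gene_id"))), nrow(rs$db$genes))
  # synthetic lengths honour the ~3:5:5 nifH:nifD:nifK proportion
  expect_equal(mean(lt2$nifH$length_nt) / mean(lt2$nifD$length_nt),
               3 / 5, tolerance = 0.15)
  expect_equal(mean(lt2$nifK$length_nt) / mean(lt2$nifD$length_nt),
               1, tolerance = 0.15)
})

test_that("reference database round-trips through its directory format", {
  rs <- small_refset()
  dir <- withr::local_tempdir()
  write_refdb(rs$db, dir)
  db2 <- read_refdb(dir)
  expect_equal(db2$genes, rs$db$genes, ignore_attr = TRUE)
  expect_identical(as.character(db2$nt), as.character(rs$db$nt))
  expect_identical(as.character(db2$aa), as.character(rs$db$aa))
  expect_identical(db2$taxonomy, rs$db$taxonomy)
})
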