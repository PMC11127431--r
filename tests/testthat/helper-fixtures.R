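# Shared fixtures, built in code and cached per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small synthetic reference set (8 taxa + 2 contaminants)
small_refset <- function() {
  cached("rs8", simulate_reference_set(
    n_taxa = 8L, seed = 42L, config = synth_config(n_taxa = 8L)))
}

small_index <- function() {
  cached("idx8", classifier_index(small_refset()$db, classify_config()))
}

# hand-built two-genome database exercising strand and taxonomy handling;
# codons chosen stop-free (GCT = Ala, AAA = Lys)
tiny_db <- function(extra_annotation = NULL) {
  genomes <- c(
    gA = paste0("TTTT", "ATGGCTGCTAAATAA", "TT", "CAT", "GGGG"),
    gB = strrep("ACGT", 30))
  ann <- data.frame(
    genome_id = c("gA", "gA"), contig = c("gA", "gA"),
    start = c(5L, 22L), end = c(19L, 24L),
    strand = c("+", "-"), family = c("nifD", "nifH"),
    gene_id = c("gA_nifD", "gA_nifH"), stringsAsFactors = FALSE)
  if (!is.null(extra_annotation)) ann <- rbind(ann, extra_annotation)
  tax <- data.frame(
    genome_id = c("gA", "gB"),
    lineage = c("Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Geobacteraceae;G_g;gA",
                "Bacteria;Firmicutes;Clostridia;Eubacteriales;Clostridiaceae;C_g;gB"),
    stringsAsFactors = FALSE)
  suppressMessages(build_db(genomes, ann, tax))
}

# minimal sample_profile constructor for quantify/curate tests
mock_profile <- function(sample_id, env = "paddy", lat = 0, lon = 0,
                         total = 1e6, counts = NULL, ssu = NULL) {
  structure(list(
    sample_id = sample_id, env = env, lat = lat, lon = lon,
    total_reads_qc = total,
    counts = counts %||% data.frame(family = character(0),
                                    gene_id = character(0),
                                    count = integer(0)),
    ssu = ssu %||% data.frame(lineage = character(0), count = integer(0)),
    n_ssu_reads = if (is.null(ssu)) 0L else sum(ssu$count),
    assignments = NULL, provenance = sample_id),
    class = "sample_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reference-quality database for quantification arithmetic: known lengths
quant_db <- function() {
  cached("quantdb", {
    mk <- function(n_codons) paste(rep("GCTAAA", n_codons / 2), collapse = "")
    genome <- paste0(mk(300), mk(500), mk(500), mk(334),
                     strrep("ACGT", 300))
    lens <- c(nifH = 900L, nifD = 1500L, nifK = 1500L, rplB = 1002L)
    starts <- cumsum(c(1L, unname(lens)))[1:4]
    ann <- data.frame(genome_id = "g1", contig = "g1",
                      start = starts, end = starts + lens - 1L,
                      strand = "+", family = names(lens),
                      gene_id = paste0("g1_", names(lens)),
                      stringsAsFactors = FALSE)
    suppressMessages(build_db(
      c(g1 = genome), ann,
      data.frame(genome_id = "g1",
                 lineage = "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Rhizobiaceae;R_g;g1")))
  })
}

# brute-force weighted UniFrac: enumerate each edge's descendant tips
unifrac_oracle <- function(mass_a, mass_b, tree) {
  ntip <- length(tree$tip.label)
  pa <- mass_a[tree$tip.label]; pa[is.na(pa)] <- 0; pa <- pa / sum(pa)
  pb <- mass_b[tree$tip.label]; pb[is.na(pb)] <- 0; pb <- pb / sum(pb)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= ntip) child else
      unlist(phangorn::Descendants(tree, child, "tips"))
    wa <- sum(pa[tips]); wb <- sum(pb[tips])
    num <- num + tree$edge.length[e] * abs(wa - wb)
    den <- den + tree$edge.length[e] * (wa + wb)
  }
  num / den
}

# union-find connected components for the clustering oracle
unionfind_clusters <- function(lat, lon, radius_km) {
  n <- length(lat)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (haversine_km(lat[i], lon[i], lat[j], lon[j]) < radius_km) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# random placement mass over a tree's tips
random_mass <- function(tree) {
  w <- stats::runif(length(tree$tip.label))
  stats::setNames(w / sum(w), tree$tip.label)
}
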