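# A hand-built reference package with controlled taxonomy.
demo_refpkg <- function() {
  cached("demopkg", {
    set.seed(77)
    aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    base <- sample(aa20, 60, replace = TRUE)
    mut <- function(x, p) {
      i <- which(stats::runif(length(x)) < p)
      x[i] <- sample(aa20, length(i), replace = TRUE)
      x
    }
    geo <- mut(base, 0.3)
    seqs <- c(
      G1 = paste(mut(geo, 0.08), collapse = ""),
      G2 = paste(mut(geo, 0.08), collapse = ""),
      D1 = paste(mut(mut(base, 0.3), 0.08), collapse = ""),
      A1 = paste(mut(mut(base, 0.35), 0.08), collapse = ""),
      R1 = paste(mut(mut(base, 0.5), 0.08), collapse = ""))
    tax <- c(
      G1 = "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Geobacteraceae;Geo_g;G1",
      G2 = "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Geobacteraceae;Geo_h;G2",
      D1 = "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Desulfuromonadaceae;Des_g;D1",
      A1 = "Bacteria;Proteobacteria;Deltaproteobacteria;Myxococcales;Anaeromyxobacteraceae;Ana_g;A1",
      R1 = "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Rhizobiaceae;Rhi_g;R1")
    tree <- ape::read.tree(
      text = "((G1:0.1,G2:0.1):0.2,(D1:0.25,(A1:0.3,R1:0.6):0.1):0.1);")
    refpkg(seqs, tree, tax, "nifD")
  })
}

test_that("profile alignment scores the source leaf highest", {
  pkg <- demo_refpkg()
  q <- substr(pkg$degap[["G1"]], 11, 50)
  al <- profile_align(q, pkg)
  expect_equal(names(which.max(al$scores)), "G1")
  expect_equal(al$offset, 10)
  expect_error(profile_align("SHORT", pkg), class = "diazo_too_short_error")
  # duplicated leaf sequences tie exactly
  dup <- refpkg(c(pkg$msa, Biostrings::AAStringSet(c(G1b = as.character(pkg$msa[["G1"]])))),
                ape::read.tree(text = "((G1:0.1,G1b:0.1):0.1,(G2:0.1,D1:0.1):0.1);"),
                c(pkg$taxonomy, G1b = unname(pkg$taxonomy["G1"])), "nifD")
  al2 <- profile_align(q, dup)
  expect_equal(al2$scores[["G1"]], al2$scores[["G1b"]])
})

test_that("placement mass behaves like a softmax over leaf scores", {
  s <- c(a = 20, b = 10, c = 0)
  w <- place_read(s, beta = 0.5)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_gt(w[["a"]], 0.99)          # 10-bit gap at beta 0.5
  w2 <- place_read(c(a = 5, b = 5), beta = 0.5)
  expect_equal(unname(w2), c(0.5, 0.5))
  w3 <- place_read(c(a = 7, b = 3, c = 1), beta = 1e-9)
  expect_equal(unname(w3), rep(1 / 3, 3), tolerance = 1e-6)
})

test_that("LCA annotation picks the deepest node reaching tau", {
  pkg <- demo_refpkg()
  # all mass in one family -> family-level or deeper
  w <- c(G1 = 0.55, G2 = 0.45, D1 = 0, A1 = 0, R1 = 0)
  a <- annotate_placement(w, pkg, tau = 0.8)
  expect_equal(a$rank, "family")
  expect_match(a$lineage, "Geobacteraceae$")
  expect_gte(a$confidence, 0.8)
  expect_equal(a$category, "annotated")
  # mass split across two families of one order -> order level
  w2 <- c(G1 = 0.3, G2 = 0.25, D1 = 0.45, A1 = 0, R1 = 0)
  a2 <- annotate_placement(w2, pkg, tau = 0.8)
  expect_equal(a2$rank, "order")
  expect_match(a2$lineage, "Desulfuromonadales$")
})

test_that("diffuse placements across domains are unreliable", {
  tax <- c(B1 = "Bacteria;P;C;O;F;G;B1", B2 = "Bacteria;P2;C2;O2;F2;G2;B2",
           A1 = "Archaea;PA;CA;OA;FA;GA;A1")
  set.seed(3)
  seqs <- vapply(1:3, function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 40,
                 replace = TRUE), collapse = ""), "")
  names(seqs) <- names(tax)
  pkg <- refpkg(seqs, ape::read.tree(text = "(B1:1,(B2:1,A1:1):0.5);"),
                tax, "nifD")
  a <- annotate_placement(c(B1 = 0.4, B2 = 0.35, A1 = 0.25), pkg, tau = 0.8)
  expect_equal(a$category, "unreliable")
  expect_true(is.na(a$lineage))
})

test_that("raising tau never deepens the annotation", {
  pkg <- demo_refpkg()
  w <- c(G1 = 0.5, G2 = 0.2, D1 = 0.2, A1 = 0.07, R1 = 0.03)
  depths <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.99), function(tau)
    annotate_placement(w, pkg, tau = tau)$depth, 0L)
  expect_true(all(diff(depths) <= 0))
})

test_that("the possibly-Geobacteraceae/Anaeromyxobacteraceae category follows its rule", {
  pkg <- demo_refpkg()
  # class-level Deltaproteobacteria, confident families = {Geo, Anaeromyxo}
  w <- c(G1 = 0.4, G2 = 0.15, D1 = 0.03, A1 = 0.32, R1 = 0.10)
  a <- annotate_placement(w, pkg, tau = 0.8)
  expect_equal(a$rank, "class")
  expect_equal(a$category, "possibly_geo_anaeromyxo")
  # same level but Desulfuromonadaceae confidently present -> plain annotation
  w2 <- c(G1 = 0.35, G2 = 0.15, D1 = 0.2, A1 = 0.2, R1 = 0.10)
  a2 <- annotate_placement(w2, pkg, tau = 0.8)
  expect_equal(a2$rank, "class")
  expect_equal(a2$category, "annotated")
  # family-level Geobacteraceae is a plain annotation, not "possibly"
  w3 <- c(G1 = 0.6, G2 = 0.3, D1 = 0.05, A1 = 0.03, R1 = 0.02)
  a3 <- annotate_placement(w3, pkg, tau = 0.8)
  expect_equal(a3$rank, "family")
  expect_equal(a3$category, "annotated")
})

mk_pset <- function(rows) {
  structure(list(family = "nifD", sample_id = "s", per_read = rows,
                 mass = NULL, n_reads = nrow(rows)), class = "placement_set")
}

test_that("family composition covers annotated plus possibly categories", {
  lin_geo <- "Bacteria;Proteobacteria;Deltaproteobacteria;Desulfuromonadales;Geobacteraceae"
  lin_rhi <- "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Rhizobiaceae;Rhi_g;R1"
  one <- mk_pset(data.frame(read_id = "r1", best_leaf = "G1", rank = "family",
                            lineage = lin_geo, confidence = 0.9,
                            category = "annotated"))
  expect_equal(unname(family_composition(one)), 1)
  mix <- mk_pset(data.frame(
    read_id = paste0("r", 1:5), best_leaf = "x", rank = c(rep("family", 3), "species", "class"),
    lineage = c(rep(lin_geo, 3), lin_rhi, NA),
    confidence = 0.9,
    category = c(rep("annotated", 3), "annotated", "possibly_geo_anaeromyxo")))
  fc <- family_composition(mix)
  expect_equal(sum(fc), 1)
  expect_equal(unname(fc["Geobacteraceae"]), 0.6)
  expect_equal(unname(fc["Rhizobiaceae"]), 0.2)
  expect_equal(unname(fc["Possibly Geobacteraceae or Anaeromyxobacteraceae"]), 0.2)
  none <- mk_pset(data.frame(read_id = "r1", best_leaf = "x", rank = NA,
                             lineage = NA, confidence = 0.2,
                             category = "unreliable"))
  fc0 <- family_composition(none)
  expect_length(fc0, 0)
  expect_true(attr(fc0, "no_annotated"))
})

test_that("error-free reads from reference leaves recover a containing rank", {
  rs <- small_refset()
  pkg <- build_refpkg(rs, "nifD")
  set.seed(83)
  n <- 60
  ok <- 0
  for (i in seq_len(n)) {
    leaf <- sample(pkg$leaves, 1)
    s <- pkg$degap[[leaf]]
    from <- sample(nchar(s) - 49, 1)
    q <- substr(s, from, from + 49)
    ann <- annotate_placement(place_read(profile_align(q, pkg)$scores), pkg)
    if (!is.na(ann$lineage) &&
        startsWith(paste0(pkg$taxonomy[[leaf]], ";"),
                   paste0(ann$lineage, ";"))) ok <- ok + 1
  }
  expect_gte(ok / n, 0.9)
})

test_that("nearest-isolate mapping classifies by top global-alignment hit", {
  set.seed(91)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mk <- function() paste(sample(aa20, 60, replace = TRUE), collapse = "")
  known <- Biostrings::AAStringSet(c(k1 = mk(), k2 = mk()))
  newiso <- Biostrings::AAStringSet(c(n1 = mk(), n2 = mk()))
  # query identical to a new-isolate sequence
  r <- map_to_nearest_isolate(c(q1 = as.character(newiso[["n1"]])),
                              known, newiso)
  expect_equal(r$per_query$class, "new_isolate")
  # identical best hit in both partitions -> tie
  shared <- mk()
  r2 <- map_to_nearest_isolate(
    c(q1 = shared),
    Biostrings::AAStringSet(c(k1 = shared)),
    Biostrings::AAStringSet(c(n1 = shared)))
  expect_equal(r2$per_query$class, "tie")
  # random queries match the exhaustive per-pair oracle
  queries <- stats::setNames(vapply(1:12, function(i) mk(), ""),
                             paste0("q", 1:12))
  r3 <- map_to_nearest_isolate(queries, known, newiso)
  oracle <- vapply(queries, function(q) {
    ids <- vapply(c(as.character(known), as.character(newiso)), function(s)
      Biostrings::pid(Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(s), type = "global",
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1),
        type = "PID1"), 0)
    bk <- max(ids[seq_along(known)])
    bn <- max(ids[length(known) + seq_along(newiso)])
    if (bk > bn) "known" else if (bn > bk) "new_isolate" else "tie"
  }, "")
  expect_equal(r3$per_query$class, unname(oracle))
  empty <- map_to_nearest_isolate(character(0), known, newiso)
  expect_equal(nrow(empty$per_query), 0)
})
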