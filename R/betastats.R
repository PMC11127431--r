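# Beta-diversity and group-comparison statistics operating on placement
# mass: normalized weighted UniFrac averaged over the NifD and NifK trees,
# two-dimensional NMDS, one-factor PERMANOVA with label permutations,
# Brunner-Munzel rank tests with Bonferroni correction and a compact
# letter display, and Spearman correlation.

#' Normalized weighted UniFrac between two placement mass distributions
#'
#' `d = sum_b l_b |P_A(b) - P_B(b)| / sum_b l_b (P_A(b) + P_B(b))`, where
#' `P_S(b)` is the fraction of sample S's placement mass descending through
#' branch `b`. Bounded in `[0, 1]`.
#'
#' @param mass_a,mass_b Named leaf-mass vectors (each summing to 1; names
#'   in `tree$tip.label`), or `placement_set` objects.
#' @param tree [ape::phylo] with branch lengths.
#' @return Distance in `[0, 1]`.
#' @export
weighted_unifrac <- function(mass_a, mass_b, tree) {
  if (inherits(mass_a, "placement_set")) mass_a <- mass_a$mass
  if (inherits(mass_b, "placement_set")) mass_b <- mass_b$mass
  pa <- branch_mass(mass_a, tree)
  pb <- branch_mass(mass_b, tree)
  el <- tree$edge.length
  denom <- sum(el * (pa + pb))
  assert_that(denom > 0, "zero placement mass in one of the samples",
              class = "diazo_undefined_distance_error")
  sum(el * abs(pa - pb)) / denom
}

# mass descending through each edge (postorder accumulation)
branch_mass <- function(mass, tree) {
  ntip <- length(tree$tip.label)
  total <- sum(mass)
  assert_that(total > 0, "zero total placement mass",
              class = "diazo_undefined_distance_error")
  node_mass <- numeric(ntip + tree$Nnode)
  m <- mass[tree$tip.label]
  m[is.na(m)] <- 0
  node_mass[seq_len(ntip)] <- m / total
  tr <- stats::reorder(tree, "postorder")
  for (e in seq_len(nrow(tr$edge))) {
    node_mass[tr$edge[e, 1]] <- node_mass[tr$edge[e, 1]] + node_mass[tr$edge[e, 2]]
  }
  # report in the original edge order
  node_mass[tree$edge[, 2]]
}

#' Pairwise weighted UniFrac matrix over samples
#'
#' @param placements Named list of `placement_set` (or mass vectors), one
#'   per sample.
#' @param tree Reference tree.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
unifrac_matrix <- function(placements, tree) {
  ids <- names(placements) %||%
    vapply(placements, function(p) p$sample_id, "")
  n <- length(placements)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- weighted_unifrac(placements[[i]], placements[[j]], tree)
  }
  D
}

#' Element-wise average of per-marker distance matrices
#'
#' The community distance is the average of the NifD- and NifK-based
#' UniFrac distances.
#'
#' @param d_nifD,d_nifK Distance matrices over the same sample set.
#' @return Averaged distance matrix.
#' @export
average_marker_distance <- function(d_nifD, d_nifK) {
  assert_that(all(dim(d_nifD) == dim(d_nifK)) &&
              setequal(rownames(d_nifD), rownames(d_nifK)),
              "distance matrices cover different sample sets",
              class = "diazo_alignment_error")
  d_nifK <- d_nifK[rownames(d_nifD), colnames(d_nifD)]
  (d_nifD + d_nifK) / 2
}

#' Brunner-Munzel rank test
#'
#' Tests the stochastic-superiority null `P(X < Y) + 0.5 P(X = Y) = 0.5`
#' with the Welch-type t approximation; robust to unequal variances and
#' ties. With complete separation (both rank variances zero) the t form is
#' undefined and a permutation p-value is reported instead (with a
#' warning).
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @param n_perm Permutations for the separation fallback.
#' @param seed Seed for the fallback permutations.
#' @return Object of class `bm_result`: `statistic` (W), `df`, `p.value`,
#'   `p_hat` (the estimate of `P(X<Y)+0.5 P(X=Y)`), `separation`.
#' @export
brunner_munzel <- function(x, y, n_perm = 2000L, seed = NULL) {
  nx <- length(x); ny <- length(y)
  assert_that(nx >= 2 && ny >= 2, "each group needs >= 2 values")
  R <- rank(c(x, y))
  Rx <- R[seq_len(nx)]; Ry <- R[nx + seq_len(ny)]
  rx <- rank(x); ry <- rank(y)
  mx <- mean(Rx); my <- mean(Ry)
  vx <- sum((Rx - rx - mx + (nx + 1) / 2)^2) / (nx - 1)
  vy <- sum((Ry - ry - my + (ny + 1) / 2)^2) / (ny - 1)
  p_hat <- (my - (ny + 1) / 2) / nx
  if (vx == 0 && vy == 0) {
    warning("complete separation: permutation p-value reported", call. = FALSE)
    obs <- abs(p_hat - 0.5)
    z <- c(x, y)
    perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nx + ny, nx)
      Rp <- rank(z)
      myp <- mean(Rp[-idx])
      abs((myp - (ny + 1) / 2) / nx - 0.5)
    }, 0))
    p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
    return(structure(list(statistic = NA_real_, df = NA_real_, p.value = p,
                          p_hat = p_hat, separation = TRUE), class = "bm_result"))
  }
  W <- nx * ny * (my - mx) / ((nx + ny) * sqrt(nx * vx + ny * vy))
  df <- (nx * vx + ny * vy)^2 /
    ((nx * vx)^2 / (nx - 1) + (ny * vy)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(W), df)
  structure(list(statistic = W, df = df, p.value = p, p_hat = p_hat,
                 separation = FALSE), class = "bm_result")
}

#' @export
print.bm_result <- function(x, ...) {
  cat("Brunner-Munzel: W =", format(x$statistic, digits = 4),
      "df =", format(x$df, digits = 4),
      "p =", format(x$p.value, digits = 4),
      "P(X<Y)+.5P(X=Y) =", format(x$p_hat, digits = 4),
      if (x$separation) "(separation fallback)" else "", "\n")
  invisible(x)
}

#' Pairwise Brunner-Munzel tests with Bonferroni correction
#'
#' All unordered group pairs are tested; adjusted p-values are
#' `min(1, C(g,2) * p)`. The compact letter display assigns letters so that
#' groups sharing a letter are not significantly different at `alpha`.
#'
#' @param groups Named list of numeric vectors (group -> values).
#' @param alpha Significance level (default 0.05).
#' @param seed Seed for separation fallbacks.
#' @return List: `pairs` (data.frame with per-pair results), `letters`
#'   (named character vector).
#' @export
pairwise_bm_bonferroni <- function(groups, alpha = 0.05, seed = NULL) {
  sizes <- lengths(groups)
  small <- sizes < 2
  if (any(small)) {
    warning("excluding group(s) with < 2 values: ",
            paste(names(groups)[small], collapse = ", "), call. = FALSE)
    groups <- groups[!small]
  }
  g <- length(groups)
  assert_that(g >= 2, "need >= 2 groups with >= 2 values")
  cmb <- utils::combn(names(groups), 2)
  k <- ncol(cmb)
  rows <- lapply(seq_len(k), function(i) {
    a <- cmb[1, i]; b <- cmb[2, i]
    r <- suppressWarnings(brunner_munzel(groups[[a]], groups[[b]],
                                         seed = if (is.null(seed)) NULL
                                                else derive_seed(seed, paste(a, b))))
    data.frame(group1 = a, group2 = b, W = r$statistic, df = r$df,
               p = r$p.value, p_adj = min(1, k * r$p.value), p_hat = r$p_hat,
               separation = r$separation, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  sig <- pairs[pairs$p_adj < alpha, c("group1", "group2"), drop = FALSE]
  list(pairs = pairs,
       letters = compact_letters(names(groups), sig))
}

# insert-and-absorb compact letter display
compact_letters <- function(groups, sig_pairs) {
  cols <- list(groups)
  if (nrow(sig_pairs)) for (i in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$group1[i]; b <- sig_pairs$group2[i]
    nxt <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        nxt <- c(nxt, list(setdiff(col, a)), list(setdiff(col, b)))
      } else nxt <- c(nxt, list(col))
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(nxt))
    for (u in seq_along(nxt)) for (v in seq_along(nxt)) {
      if (u != v && keep[u] && keep[v] &&
          all(nxt[[u]] %in% nxt[[v]]) &&
          (length(nxt[[u]]) < length(nxt[[v]]) || u > v)) keep[u] <- FALSE
    }
    cols <- nxt[keep]
  }
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    l <- letters[(i - 1) %% 26 + 1]
    for (gp in cols[[i]]) lab[gp] <- paste0(lab[gp], l)
  }
  lab
}

#' One-factor PERMANOVA by label permutation
#'
#' `SS_total = sum_{i<j} d_ij^2 / n`; `SS_within` sums the analogous
#' within-group terms; `F = (SS_between/(g-1)) / (SS_within/(n-g))`; the
#' p-value counts permuted statistics at least as large as the observed
#' one, with the add-one convention.
#'
#' @param dm Distance matrix (or `dist`).
#' @param labels Group label per sample (length n, >= 2 groups, all groups
#'   non-empty).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Seed for the permutations.
#' @return Object of class `permanova_result`: `F`, `R2`, `p.value`, `df`,
#'   `n_perm`.
#' @export
permanova <- function(dm, labels, n_perm = 999L, seed = NULL) {
  d2 <- as.matrix(dm)^2
  n <- nrow(d2)
  labels <- as.character(labels)
  assert_that(length(labels) == n, "labels must match the distance matrix")
  lev <- unique(labels)
  g <- length(lev)
  assert_that(g >= 2 && all(table(labels) >= 1), "need >= 2 non-empty groups",
              class = "diazo_label_error")
  ss_total <- sum(d2) / (2 * n)
  ss_within <- function(lab) {
    s <- 0
    for (l in lev) {
      idx <- which(lab == l)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  ssw <- ss_within(labels)
  ssb <- ss_total - ssw
  Fobs <- (ssb / (g - 1)) / (ssw / (n - g))
  R2 <- ssb / ss_total
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    lab <- labels[sample.int(n)]
    sswp <- ss_within(lab)
    ((ss_total - sswp) / (g - 1)) / (sswp / (n - g))
  }, 0))
  p <- (1 + sum(perm >= Fobs)) / (1 + n_perm)
  structure(list(F = Fobs, R2 = R2, p.value = p,
                 df = c(between = g - 1, within = n - g), n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", format(x$F, digits = 4),
      "R2 =", format(x$R2, digits = 4),
      "p =", format(x$p.value, digits = 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}

#' Two-dimensional NMDS of a distance matrix
#'
#' Kruskal's non-metric MDS (stress-1, monotone regression), initialised
#' from classical metric scaling of the distances and refined from
#' `n_restarts` additional random configurations; the configuration with
#' the lowest final stress is returned.
#'
#' @param dm Distance matrix (or `dist`).
#' @param dims Embedding dimension (default 2).
#' @param n_restarts Random restarts beyond the metric-scaling start.
#' @param max_iter Iterations per fit.
#' @param seed Seed for the random restarts.
#' @return Object of class `nmds_result`: `points` (n x dims), `stress`
#'   (Kruskal stress-1, fraction), `n_restarts`, `seed`.
#' @export
nmds <- function(dm, dims = 2L, n_restarts = 10L, max_iter = 200L, seed = NULL) {
  D <- as.matrix(dm)
  assert_that(all(is.finite(D)), "non-finite distances",
              class = "diazo_input_error")
  n <- nrow(D)
  ids <- rownames(D) %||% as.character(seq_len(n))
  if (n <= dims + 1) {
    pts <- stats::cmdscale(D, k = min(dims, max(1, n - 1)))
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
    rownames(pts) <- ids
    return(structure(list(points = pts, stress = 0,
                          n_restarts = 0L, seed = seed), class = "nmds_result"))
  }
  eps <- min(D[D > 0], 1) * 1e-9
  Dp <- pmax(D, eps); diag(Dp) <- 0
  dd <- stats::as.dist(Dp)
  fit_one <- function(y0) {
    f <- MASS::isoMDS(dd, y = y0, k = dims, maxit = max_iter, trace = FALSE)
    list(points = f$points, stress = f$stress / 100)
  }
  y0 <- stats::cmdscale(Dp, k = dims)
  if (ncol(y0) < dims) y0 <- cbind(y0, matrix(0, n, dims - ncol(y0)))
  best <- fit_one(y0)
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      yr <- matrix(stats::rnorm(n * dims, sd = stats::sd(Dp)), n, dims)
      fr <- tryCatch(fit_one(yr), error = function(e) NULL)
      if (!is.null(fr) && fr$stress < best$stress) best <- fr
    }
  })
  rownames(best$points) <- ids
  structure(list(points = best$points, stress = best$stress,
                 n_restarts = n_restarts, seed = seed), class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat("NMDS (", ncol(x$points), "dims ): stress-1 =",
      format(x$stress, digits = 4), "\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Midrank-based rho with the t approximation for the p-value.
#'
#' @param x,y Numeric vectors (length >= 3).
#' @return List: `rho`, `p.value`.
#' @export
spearman <- function(x, y) {
  assert_that(length(x) == length(y) && length(x) >= 3,
              "need paired vectors of length >= 3")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for constant input",
              class = "diazo_undefined_correlation_error")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}
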