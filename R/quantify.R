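# RPKM normalisation and the nitrogenase : ribosomal-protein dominance
# ratio. Using single-copy ribosomal proteins as the denominator makes the
# ratio a per-prokaryotic-genome dominance measure that is robust to
# plant/animal DNA in the sample, and per-gene length correction (RPKM)
# removes the ortholog length differences between marker families.

#' Reads per kilobase of reference per million sample reads
#'
#' `RPKM(f) = sum_g [ c_g / (L_g/1000) ] / (N_s / 1e6)` with the per-gene
#' length correction applied before summation.
#'
#' @param counts data.frame with `gene_id` and `count` for one family.
#' @param length_table data.frame with `gene_id`, `length_nt` (one family's
#'   entry of [marker_length_table()]).
#' @param total_reads Sample read count `N_s` (>= 1).
#' @return Numeric RPKM value (0 for zero counts).
#' @export
rpkm <- function(counts, length_table, total_reads) {
  assert_that(total_reads >= 1, "total_reads must be >= 1")
  if (is.null(counts) || !nrow(counts)) return(0)
  L <- length_table$length_nt[match(counts$gene_id, length_table$gene_id)]
  if (anyNA(L))
    stop_diazo("count present for gene(s) without a length entry: ",
               paste(counts$gene_id[is.na(L)], collapse = ", "),
               class = "diazo_consistency_error")
  sum(counts$count / (L / 1000)) / (total_reads / 1e6)
}

#' Nitrogenase dominance ratio of one sample
#'
#' Sums RPKM over the D/K-type nitrogenase families and divides by the
#' summed RPKM of the single-copy ribosomal protein families. Also computes
#' the pseudo-nifH diagnostic: the observed nifH read count against the
#' count expected from nifD/K under the reference length proportions.
#'
#' @param profile A `sample_profile`.
#' @param db A `diazo_refdb`.
#' @param pseudo_factor Flagging threshold on observed/expected nifH
#'   (default 1.5, inclusive).
#' @return One-row data.frame of class `ratio_result`: `sample_id`, `env`,
#'   `nif_rpkm`, `ribo_rpkm`, `ratio`, `observed_nifh`, `expected_nifh`,
#'   `pseudo_factor_observed`, `pseudo_flag`, `usable`.
#' @export
nif_ratio <- function(profile, db, pseudo_factor = 1.5) {
  lt <- marker_length_table(db)
  N <- max(1L, profile$total_reads_qc)
  fam_rpkm <- function(fams) {
    sum(vapply(fams, function(f) {
      ct <- profile$counts[profile$counts$family == f, , drop = FALSE]
      if (!nrow(ct) || is.null(lt[[f]])) 0 else rpkm(ct, lt[[f]], N)
    }, 0))
  }
  rp_fams <- unique(db$genes$family[db$genes$role == "ribosomal_protein"])
  nif <- fam_rpkm(intersect(nitrogenase_dk_families(), names(lt)))
  ribo <- fam_rpkm(rp_fams)
  usable <- !(ribo == 0 && nif > 0)
  ratio <- if (nif == 0) 0 else if (ribo > 0) nif / ribo else NA_real_

  c_H <- family_count(profile, "nifH")
  c_D <- family_count(profile, "nifD")
  c_K <- family_count(profile, "nifK")
  lens <- c(H = mean_family_length(db, "nifH"),
            D = mean_family_length(db, "nifD"),
            K = mean_family_length(db, "nifK"))
  e_H <- expected_nifh(c_D, c_K, lens)
  fac <- if (e_H > 0) c_H / e_H else if (c_H > 0) Inf else NA_real_
  structure(data.frame(
    sample_id = profile$sample_id, env = profile$env,
    nif_rpkm = nif, ribo_rpkm = ribo, ratio = ratio,
    observed_nifh = c_H, expected_nifh = e_H,
    pseudo_factor_observed = fac,
    pseudo_flag = pseudo_nifh_flag(c_H, e_H, pseudo_factor),
    usable = usable, stringsAsFactors = FALSE),
    class = c("ratio_result", "data.frame"))
}

#' Expected nifH read count from nifD/K counts
#'
#' The reference lengths of nifH:nifD:nifK are approximately 3:5:5, so read
#' counts sampled uniformly over gene length should follow the same
#' proportion. `E_H = L_H * (c_D/L_D + c_K/L_K) / 2`, with `L` the mean
#' reference length per family; at exact 3:5:5 this reduces to
#' `(3/5) * mean(c_D, c_K)`.
#'
#' @param c_D,c_K Observed nifD and nifK read counts.
#' @param lengths Numeric length-3 vector of mean reference lengths
#'   (nifH, nifD, nifK order).
#' @return Expected nifH count.
#' @export
expected_nifh <- function(c_D, c_K, lengths = c(900, 1500, 1500)) {
  assert_that(all(lengths > 0), "reference lengths must be positive")
  lengths[[1]] * (c_D / lengths[[2]] + c_K / lengths[[3]]) / 2
}

#' Pseudo-nifH excess flag
#'
#' A sample is flagged when it holds `factor` times or more nifH reads than
#' expected from its nifD/K reads (inclusive threshold), or any nifH reads
#' at all when none are expected. Samples so flagged carry substantial
#' pseudo-nifH signal (nifH-like genes on genomes lacking nifD/K) and would
#' inflate a nifH-based survey.
#'
#' @param observed Observed nifH count.
#' @param expected Expected nifH count from [expected_nifh()].
#' @param factor Threshold (> 0; default 1.5).
#' @return Logical.
#' @export
pseudo_nifh_flag <- function(observed, expected, factor = 1.5) {
  assert_that(factor > 0, "factor must be > 0")
  (expected > 0 & observed >= factor * expected) | (expected == 0 & observed > 0)
}

#' Dominance ratios for a list of profiles
#'
#' @param profiles List of `sample_profile`.
#' @inheritParams nif_ratio
#' @return data.frame, one `ratio_result` row per sample.
#' @export
nif_ratio_table <- function(profiles, db, pseudo_factor = 1.5) {
  do.call(rbind, lapply(profiles, nif_ratio, db = db,
                        pseudo_factor = pseudo_factor))
}
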