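# In-silico evaluation of nifH universal primers: IUPAC-aware mismatch
# counting at alignment-defined binding sites. Binding sites are explicit
# column ranges on the reference MSA (primer placement on the alignment is
# a curation step, not a search), and a gap in the template counts as a
# mismatch because a deleted position cannot anneal.

iupac_masks <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      map <- Biostrings::IUPAC_CODE_MAP
      bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
      m <- vapply(strsplit(unname(map), ""), function(b) sum(bit[b]), 0L)
      names(m) <- names(map)
      env$m <- m
    }
    env$m
  }
})

#' IUPAC-aware base match
#'
#' TRUE when the template base is within the primer code's expansion;
#' ambiguity codes on the template match when the expansions intersect.
#'
#' @param primer_base,template_base Single IUPAC characters (vectorised).
#' @return Logical vector.
#' @export
iupac_match <- function(primer_base, template_base) {
  m <- iupac_masks()
  pb <- m[toupper(primer_base)]
  tb <- m[toupper(template_base)]
  assert_that(!anyNA(pb) && !anyNA(tb), "invalid IUPAC code",
              class = "diazo_alphabet_error")
  bitwAnd(pb, tb) > 0L
}

revcomp_iupac <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Count primer-template mismatches at an MSA binding site
#'
#' The template region is the primer-length window of MSA columns; reverse
#' primers are reverse-complemented before comparison. Template gaps count
#' as mismatches.
#'
#' @param primer IUPAC primer sequence (5'->3').
#' @param template_region Template characters at the binding-site columns
#'   (may contain `-`).
#' @param orientation `"forward"` or `"reverse"`.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(primer, template_region,
                             orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  p <- if (orientation == "reverse") revcomp_iupac(primer) else toupper(primer)
  t_ <- toupper(template_region)
  assert_that(nchar(t_) == nchar(p),
              "binding site width (", nchar(t_), ") != primer length (",
              nchar(p), ")", class = "diazo_site_definition_error")
  pv <- strsplit(p, "")[[1]]
  tv <- strsplit(t_, "")[[1]]
  gap <- tv %in% c("-", ".")
  mm <- gap
  if (any(!gap)) mm[!gap] <- !iupac_match(pv[!gap], tv[!gap])
  sum(mm)
}

#' Primer-by-template mismatch matrix on a reference MSA
#'
#' @param msa Aligned nucleotide sequences ([Biostrings::DNAStringSet],
#'   named character vector, or FASTA path).
#' @param primers data.frame: `name`, `sequence`, `orientation`
#'   (`forward`/`reverse`), `msa_start_col`, `msa_end_col` (1-based
#'   inclusive; width must equal the primer length).
#' @return Integer matrix primers x templates.
#' @export
primer_mismatch_matrix <- function(msa, primers) {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa))
    msa <- Biostrings::readDNAStringSet(msa)
  nm <- names(msa)
  msa <- as.character(msa)
  names(msa) <- nm
  need <- c("name", "sequence", "orientation", "msa_start_col", "msa_end_col")
  assert_that(all(need %in% names(primers)),
              "primer table must have columns: ", paste(need, collapse = ", "))
  out <- matrix(NA_integer_, nrow(primers), length(msa),
                dimnames = list(primers$name, names(msa)))
  for (i in seq_len(nrow(primers))) {
    cols <- primers$msa_start_col[i]:primers$msa_end_col[i]
    assert_that(max(cols) <= min(nchar(msa)),
                "binding site outside MSA for primer ", primers$name[i],
                class = "diazo_site_definition_error")
    for (j in seq_along(msa)) {
      region <- substr(msa[[j]], min(cols), max(cols))
      out[i, j] <- count_mismatches(primers$sequence[i], region,
                                    primers$orientation[i])
    }
  }
  out
}

#' Read a primer table TSV
#'
#' Columns: `name`, `sequence`, `orientation`, `msa_start_col`,
#' `msa_end_col`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_primer_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
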