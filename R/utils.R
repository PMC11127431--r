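# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_diazo <- function(..., class) {
  stop(structure(
    class = c(class, "diazo_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_that <- function(ok, ..., class = "diazo_input_error") {
  if (!isTRUE(ok)) stop_diazo(..., class = class)
  invisible(TRUE)
}

#' @noRd
softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# Deterministic child seeds: fold a label into a root seed, keeping the
# result a valid 32-bit R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * (seq_along(utf8ToInt(as.character(label))) %% 7 + 1))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Ordered lineage utilities. Lineages are semicolon-delimited strings rooted
# at a domain, e.g. "Bacteria;Proteobacteria;Deltaproteobacteria;...".
lineage_split <- function(x) strsplit(x, ";", fixed = TRUE)

lineage_rank_names <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

lineage_at <- function(x, rank) {
  ranks <- lineage_rank_names()
  i <- match(rank, ranks)
  assert_that(!is.na(i), "unknown taxonomic rank: ", rank, class = "diazo_rank_error")
  vapply(lineage_split(x), function(p) if (length(p) >= i) p[[i]] else NA_character_, "")
}

lineage_prefix <- function(x, depth) {
  vapply(lineage_split(x), function(p) paste(p[seq_len(min(depth, length(p)))], collapse = ";"), "")
}
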