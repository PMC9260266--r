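#' Per-gene co-occurrence rates from a presence/absence matrix
#'
#' For each gene, the co-occurrence rate is the percentage of taxa in which
#' a homolog was found: `100 * n_present / n_taxa`. Rates are reported both
#' in full precision and rounded to one decimal, half away from zero (the
#' convention used when such tables are printed).
#'
#' @param occ Occurrence tibble from [read_occurrence_matrix()] (a `taxon`
#'   column followed by 0/1 gene columns).
#' @return A tibble with columns `gene`, `n_present`, `n_taxa`, `rate_pct`
#'   (exact) and `rate_pct_rounded`.
#' @export
#' @examples
#' occ <- tibble::tibble(taxon = c("a", "b", "c"), g1 = c(1L, 1L, 1L),
#'                       g2 = c(1L, 0L, 0L))
#' cooccurrence_rate(occ)
cooccurrence_rate <- function(occ) {
  occ <- check_occurrence(occ)
  genes <- names(occ)[-1]
  n_taxa <- nrow(occ)
  tibble::tibble(
    gene = genes,
    n_present = vapply(genes, function(g) sum(occ[[g]]), integer(1),
                       USE.NAMES = FALSE),
    n_taxa = n_taxa
  ) |>
    dplyr::mutate(
      rate_pct = 100 * .data$n_present / .data$n_taxa,
      rate_pct_rounded = round_half_away(.data$rate_pct, 1)
    )
}

#' Per-taxon matched-query counts
#'
#' Row sums of the occurrence matrix: how many of the query genes each
#' taxon matched.
#'
#' @inheritParams cooccurrence_rate
#' @return A tibble with columns `taxon` and `n_matched`, sorted by
#'   decreasing `n_matched` (input order within ties).
#' @export
queries_matched <- function(occ) {
  occ <- check_occurrence(occ)
  out <- tibble::tibble(
    taxon = occ$taxon,
    n_matched = as.integer(rowSums(occ[-1]))
  )
  out[order(-out$n_matched), ]
}

check_occurrence <- function(occ) {
  if (!is.data.frame(occ) || names(occ)[1] != "taxon" || ncol(occ) < 2 ||
      nrow(occ) < 1) {
    rlang::abort("Occurrence data must be a data frame with a leading 'taxon' column and at least one gene column.",
                 class = "msapr_error_format")
  }
  for (cc in names(occ)[-1]) {
    if (!all(occ[[cc]] %in% c(0L, 1L))) {
      rlang::abort(paste0("Occurrence column '", cc, "' contains non-binary values."),
                   class = "msapr_error_nonbinary")
    }
  }
  tibble::as_tibble(occ)
}

# round to `digits` decimals, ties away from zero (base round() rounds
# half to even, which would print 30.55 -> 30.5 instead of 30.6)
round_half_away <- function(x, digits = 1) {
  scale <- 10 ^ digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Gene co-occurrence matrix for iridoid glycoside synthase genes (packaged fixture)
#'
#' Loads the packaged 72-taxon x 5-gene presence/absence matrix for the
#' iridoid glycoside biosynthesis genes DXS, DXR, 10HGO, G10H and GPPS of
#' *Rehmannia glutinosa* across Viridiplantae.
#'
#' @return An occurrence tibble (`taxon` column plus five 0/1 gene
#'   columns), suitable for [cooccurrence_rate()] and [queries_matched()].
#' @export
iridoid_cooccurrence <- function() {
  path <- system.file("extdata", "iridoid_gene_cooccurrence.tsv",
                      package = "msapr")
  read_occurrence_matrix(path)
}
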