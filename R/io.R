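#' Read an MSAP band matrix and its sample metadata
#'
#' MSAP scoring produces, for every locus and sample, a pair of binary band
#' calls: one from the EcoRI/HpaII digest (H) and one from the EcoRI/MspI
#' digest (M). The band file is tab-separated with a mandatory header: the
#' first column is `locus_id`, followed by two columns per sample named
#' `<sample_id>.H` and `<sample_id>.M`, with cells that are literally `0`,
#' `1` or `NA`. The metadata file is tab-separated with columns
#' `sample_id`, `tissue`, `stage`, `dose_uM` and `replicate`.
#'
#' @param path Path to the band TSV.
#' @param meta_path Path to the sample-metadata TSV.
#'
#' @return A tibble in long form with one row per (locus, sample):
#'   columns `locus`, `sample_id`, `h`, `m` (integer 0/1, possibly `NA`),
#'   plus the metadata columns `tissue`, `stage`, `dose` (micromolar 5-azaC,
#'   0 for controls) and `replicate`.
#'
#' @details Validation is strict: a sample column lacking its `.H`/`.M`
#'   partner, a non-binary cell, a duplicated locus identifier, or a sample
#'   present in one file but not the other each raise a distinct error.
#'   Nothing is silently coerced; only the literal strings "0", "1" and
#'   "NA" are accepted as band calls.
#'
#' @seealso [write_band_matrix()], [classify_pattern()]
#' @export
#' @examples
#' bands <- system.file("extdata", "example_bands.tsv", package = "msapr")
#' meta <- system.file("extdata", "example_meta.tsv", package = "msapr")
#' read_band_matrix(bands, meta)
read_band_matrix <- function(path, meta_path) {
  meta <- read_sample_meta(meta_path)
  wide <- read_tsv_strict(path)
  if (names(wide)[1] != "locus_id") {
    rlang::abort(
      paste0("Band file must start with a 'locus_id' column, found '",
             names(wide)[1], "'."),
      class = "msapr_error_header"
    )
  }
  band_cols <- names(wide)[-1]
  ok <- grepl("\\.(H|M)$", band_cols)
  if (any(!ok)) {
    rlang::abort(
      paste0("Band columns must be named '<sample_id>.H' or '<sample_id>.M'; ",
             "offending column(s): ", toString(band_cols[!ok])),
      class = "msapr_error_header"
    )
  }
  samples <- unique(sub("\\.(H|M)$", "", band_cols))
  missing_pair <- samples[
    !(paste0(samples, ".H") %in% band_cols & paste0(samples, ".M") %in% band_cols)
  ]
  if (length(missing_pair) > 0) {
    rlang::abort(
      paste0("Sample(s) lacking a complete .H/.M column pair: ",
             toString(missing_pair)),
      class = "msapr_error_header"
    )
  }
  dup <- wide$locus_id[duplicated(wide$locus_id)]
  if (length(dup) > 0) {
    rlang::abort(
      paste0("Duplicate locus id(s): ", toString(unique(dup))),
      class = "msapr_error_duplicate_locus"
    )
  }
  for (cc in band_cols) {
    bad <- !(wide[[cc]] %in% c("0", "1") | is.na(wide[[cc]]))
    if (any(bad)) {
      rlang::abort(
        paste0("Non-binary band value '", wide[[cc]][which(bad)[1]],
               "' at locus '", wide$locus_id[which(bad)[1]],
               "', column '", cc, "'; cells must be 0, 1 or NA."),
        class = "msapr_error_nonbinary"
      )
    }
  }
  extra <- setdiff(samples, meta$sample_id)
  if (length(extra) > 0) {
    rlang::abort(
      paste0("Sample(s) in band file but missing from metadata: ",
             toString(extra)),
      class = "msapr_error_meta_mismatch"
    )
  }
  unused <- setdiff(meta$sample_id, samples)
  if (length(unused) > 0) {
    rlang::abort(
      paste0("Sample(s) in metadata but missing from band file: ",
             toString(unused)),
      class = "msapr_error_meta_mismatch"
    )
  }

  long <- wide |>
    tidyr::pivot_longer(-"locus_id", names_to = "column", values_to = "call") |>
    dplyr::mutate(
      sample_id = sub("\\.(H|M)$", "", .data$column),
      digest = sub("^.*\\.", "", .data$column),
      call = as.integer(.data$call)
    ) |>
    dplyr::select("locus_id", "sample_id", "digest", "call") |>
    tidyr::pivot_wider(names_from = "digest", values_from = "call") |>
    dplyr::rename(locus = "locus_id", h = "H", m = "M") |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::arrange(factor(.data$sample_id, levels = meta$sample_id),
                   factor(.data$locus, levels = wide$locus_id))
  tibble::as_tibble(long)
}

#' Read sample metadata
#'
#' @param meta_path TSV with columns `sample_id`, `tissue`, `stage`,
#'   `dose_uM`, `replicate`.
#' @return A tibble with columns `sample_id`, `tissue`, `stage`, `dose`,
#'   `replicate`.
#' @export
read_sample_meta <- function(meta_path) {
  meta <- read_tsv_strict(meta_path)
  required <- c("sample_id", "tissue", "stage", "dose_uM", "replicate")
  miss <- setdiff(required, names(meta))
  if (length(miss) > 0) {
    rlang::abort(
      paste0("Metadata is missing column(s): ", toString(miss)),
      class = "msapr_error_header"
    )
  }
  meta <- dplyr::mutate(
    meta,
    dose = as.numeric(.data$dose_uM),
    replicate = as.integer(.data$replicate)
  )
  validate_sample_meta(meta)
  tibble::as_tibble(meta[c("sample_id", "tissue", "stage", "dose", "replicate")])
}

validate_sample_meta <- function(meta) {
  dup <- meta$sample_id[duplicated(meta$sample_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("Duplicate sample_id(s) in metadata: ",
                        toString(unique(dup))),
                 class = "msapr_error_meta")
  }
  if (any(is.na(meta$dose)) || any(meta$dose < 0)) {
    rlang::abort("Metadata dose_uM must be a non-negative number.",
                 class = "msapr_error_meta")
  }
  if (any(is.na(meta$replicate)) || any(meta$replicate < 1)) {
    rlang::abort("Metadata replicate must be a positive integer.",
                 class = "msapr_error_meta")
  }
  invisible(meta)
}

#' Write an MSAP band matrix (and optionally its metadata) to TSV
#'
#' Inverse of [read_band_matrix()]: `read_band_matrix(write_band_matrix(x))`
#' reproduces `x` exactly.
#'
#' @param bands Long band tibble as returned by [read_band_matrix()] or
#'   [simulate_experiment()].
#' @param path Destination for the band TSV.
#' @param meta_path Optional destination for the sample-metadata TSV.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(bands, path, meta_path = NULL) {
  bands <- validate_bands(bands)
  loci <- unique(bands$locus)
  samples <- unique(bands$sample_id)
  wide <- bands |>
    dplyr::select("locus", "sample_id", "h", "m") |>
    tidyr::pivot_longer(c("h", "m"), names_to = "digest", values_to = "call") |>
    dplyr::mutate(
      column = paste0(.data$sample_id, ".", toupper(.data$digest))
    ) |>
    dplyr::select("locus", "column", "call") |>
    tidyr::pivot_wider(names_from = "column", values_from = "call")
  ord <- as.vector(rbind(paste0(samples, ".H"), paste0(samples, ".M")))
  wide <- wide[match(loci, wide$locus), c("locus", ord)]
  names(wide)[1] <- "locus_id"
  readr::write_tsv(wide, path, na = "NA")
  if (!is.null(meta_path)) {
    meta <- bands |>
      dplyr::distinct(.data$sample_id, .data$tissue, .data$stage,
                      .data$dose, .data$replicate) |>
      dplyr::rename(dose_uM = "dose")
    readr::write_tsv(meta, meta_path, na = "NA")
  }
  invisible(path)
}

#' Validate a long band tibble
#'
#' @param bands A data frame with columns `locus`, `sample_id`, `h`, `m`.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_bands <- function(bands) {
  required <- c("locus", "sample_id", "h", "m")
  miss <- setdiff(required, names(bands))
  if (length(miss) > 0) {
    rlang::abort(paste0("Band data is missing column(s): ", toString(miss)),
                 class = "msapr_error_format")
  }
  for (cc in c("h", "m")) {
    v <- bands[[cc]]
    if (!all(v %in% c(0L, 1L) | is.na(v))) {
      rlang::abort(paste0("Band flag '", cc, "' contains values other than 0/1/NA."),
                   class = "msapr_error_nonbinary")
    }
  }
  if (anyDuplicated(bands[c("locus", "sample_id")]) > 0) {
    rlang::abort("Duplicate (locus, sample_id) rows in band data.",
                 class = "msapr_error_duplicate_locus")
  }
  tibble::as_tibble(bands)
}

#' Read a gene x taxon occurrence matrix
#'
#' The file is tab-separated with taxa as rows: the first column is `taxon`,
#' remaining columns are genes, and cells are 0/1 presence flags.
#'
#' @param path Path to the TSV.
#' @return A tibble with a `taxon` column followed by one integer 0/1
#'   column per gene.
#' @seealso [cooccurrence_rate()], [queries_matched()]
#' @export
read_occurrence_matrix <- function(path) {
  occ <- read_tsv_strict(path)
  if (names(occ)[1] != "taxon") {
    rlang::abort("Occurrence matrix must start with a 'taxon' column.",
                 class = "msapr_error_header")
  }
  if (ncol(occ) < 2 || nrow(occ) < 1) {
    rlang::abort("Occurrence matrix needs at least one taxon and one gene.",
                 class = "msapr_error_format")
  }
  dup <- occ$taxon[duplicated(occ$taxon)]
  if (length(dup) > 0) {
    rlang::abort(paste0("Duplicate taxon/taxa: ", toString(unique(dup))),
                 class = "msapr_error_duplicate_taxon")
  }
  for (cc in names(occ)[-1]) {
    bad <- !(occ[[cc]] %in% c("0", "1"))
    if (any(bad)) {
      rlang::abort(
        paste0("Non-binary occurrence value '", occ[[cc]][which(bad)[1]],
               "' for taxon '", occ$taxon[which(bad)[1]], "', gene '", cc, "'."),
        class = "msapr_error_nonbinary"
      )
    }
    occ[[cc]] <- as.integer(occ[[cc]])
  }
  tibble::as_tibble(occ)
}

#' Read a Ct table for relative-expression analysis
#'
#' @param path CSV with columns `sample_id`, `group`, `gene`, `ct`.
#' @return A tibble with those columns; `ct` numeric.
#' @seealso [ddct_fold_change()]
#' @export
read_ct_table <- function(path) {
  ct <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  required <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(required, names(ct))
  if (length(miss) > 0) {
    rlang::abort(paste0("Ct table is missing column(s): ", toString(miss)),
                 class = "msapr_error_header")
  }
  ct$ct <- as.numeric(ct$ct)
  if (any(is.na(ct$ct)) || any(ct$ct <= 0)) {
    rlang::abort("Ct values must be positive numbers.",
                 class = "msapr_error_format")
  }
  tibble::as_tibble(ct[required])
}

# all band/meta/occurrence files are read as character so that validation,
# not readr's type guessing, decides what a legal cell is
read_tsv_strict <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path), class = "msapr_error_io")
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  na = "NA", comment = "#", progress = FALSE)
}
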