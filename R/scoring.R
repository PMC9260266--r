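#' Methylation pattern levels
#'
#' The four CCGG banding patterns, in display order.
#' @format Character vector of length four: `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
pattern_levels <- c("I", "II", "III", "IV")

#' Classify H/M band profiles into methylation patterns I-IV
#'
#' HpaII and MspI are isoschizomers recognizing CCGG but with different
#' methylation sensitivity, so the presence/absence of a band in the H
#' (EcoRI/HpaII) and M (EcoRI/MspI) digests encodes the methylation state of
#' the site:
#'
#' * band in both (1,1): unmethylated, pattern **I**;
#' * band only in H (1,0): hemi-methylated, pattern **II**;
#' * band only in M (0,1): fully methylated internal cytosine, pattern **III**;
#' * band in neither (0,0): hypermethylated, invisible to both digests,
#'   pattern **IV**.
#'
#' @param h,m Integer vectors of 0/1 band flags (recycled to common length).
#' @return A factor with levels [pattern_levels]; `NA` where either flag is
#'   `NA`.
#' @export
#' @examples
#' classify_pattern(c(1, 1, 0, 0), c(1, 0, 1, 0))
classify_pattern <- function(h, m) {
  if (!all(h %in% c(0L, 1L) | is.na(h)) || !all(m %in% c(0L, 1L) | is.na(m))) {
    rlang::abort("Band flags must be 0, 1 or NA.", class = "msapr_error_nonbinary")
  }
  code <- dplyr::case_when(
    h == 1 & m == 1 ~ 1L,
    h == 1 & m == 0 ~ 2L,
    h == 0 & m == 1 ~ 3L,
    h == 0 & m == 0 ~ 4L,
    TRUE ~ NA_integer_
  )
  factor(pattern_levels[code], levels = pattern_levels)
}

#' Add a methylation-pattern column to a band tibble
#'
#' @param bands Long band tibble (see [read_band_matrix()]).
#' @return `bands` with an extra factor column `pattern`.
#' @export
add_patterns <- function(bands) {
  bands <- validate_bands(bands)
  dplyr::mutate(bands, pattern = classify_pattern(.data$h, .data$m))
}

#' Tally methylation patterns per group
#'
#' Counts loci in each of the four patterns within groups defined by
#' metadata columns (e.g. tissue, stage, dose). Loci with a missing band
#' call are excluded from the tally (and reported via a message).
#'
#' @param bands Long band tibble.
#' @param ... Grouping columns, tidy-select style (e.g. `tissue, stage,
#'   dose`). With no grouping the whole dataset is one group.
#' @return A tibble with the grouping columns plus `n_I`, `n_II`, `n_III`,
#'   `n_IV` and `n_scored`.
#' @export
#' @examples
#' bands <- tibble::tibble(
#'   locus = paste0("L", 1:4), sample_id = "s1",
#'   h = c(1L, 1L, 0L, 0L), m = c(1L, 0L, 1L, 0L)
#' )
#' count_patterns(bands)
count_patterns <- function(bands, ...) {
  bands <- add_patterns(bands)
  group_vars <- rlang::enquos(...)
  n_na <- sum(is.na(bands$pattern))
  if (n_na > 0) {
    rlang::inform(paste0(n_na, " locus/sample cell(s) with missing band calls ",
                         "excluded from pattern counts."))
    bands <- dplyr::filter(bands, !is.na(.data$pattern))
  }
  counts <- bands |>
    dplyr::count(!!!group_vars, .data$pattern, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "pattern", values_from = "n",
                       names_prefix = "n_", values_fill = 0L)
  for (cc in paste0("n_", pattern_levels)) {
    if (!cc %in% names(counts)) counts[[cc]] <- 0L
  }
  counts <- counts |>
    dplyr::relocate(dplyr::all_of(paste0("n_", pattern_levels)),
                    .after = dplyr::last_col()) |>
    dplyr::mutate(n_scored = .data$n_I + .data$n_II + .data$n_III + .data$n_IV)
  if (any(counts$n_scored == 0)) {
    rlang::abort("Empty group in pattern counts.", class = "msapr_error_empty_group")
  }
  counts
}

#' Compute total, hemi- and full methylation levels from pattern counts
#'
#' Pattern IV sites are invisible to both digests, so they are tracked but
#' excluded from the denominator; the levels are
#' \deqn{total = 100 (n_{II}+n_{III})/(n_I+n_{II}+n_{III})}
#' \deqn{hemi  = 100\, n_{II}/(n_I+n_{II}+n_{III})}
#' \deqn{full  = 100\, n_{III}/(n_I+n_{II}+n_{III})}
#' so that `hemi_pct + full_pct == total_pct` always.
#'
#' @param counts A tibble with columns `n_I`, `n_II`, `n_III` (and usually
#'   `n_IV`), e.g. from [count_patterns()].
#' @return `counts` with added columns `total_pct`, `hemi_pct`, `full_pct`
#'   (percentages in full precision; round only for display).
#' @export
#' @examples
#' methylation_levels(tibble::tibble(n_I = 1, n_II = 1, n_III = 2, n_IV = 0))
methylation_levels <- function(counts) {
  required <- c("n_I", "n_II", "n_III")
  miss <- setdiff(required, names(counts))
  if (length(miss) > 0) {
    rlang::abort(paste0("Pattern counts missing column(s): ", toString(miss)),
                 class = "msapr_error_format")
  }
  denom <- counts$n_I + counts$n_II + counts$n_III
  if (any(denom <= 0)) {
    rlang::abort(
      "Methylation levels are undefined: no detectable (I/II/III) loci in a group.",
      class = "msapr_error_undefined_level"
    )
  }
  dplyr::mutate(
    tibble::as_tibble(counts),
    total_pct = 100 * (.data$n_II + .data$n_III) / denom,
    hemi_pct = 100 * .data$n_II / denom,
    full_pct = 100 * .data$n_III / denom
  )
}

#' Collapse replicate samples to one consensus profile per condition
#'
#' Merges the replicates within each (tissue, stage, dose) cell into a
#' single sample, combining the H and M flags independently under a
#' consensus policy:
#'
#' * `"majority"`: flag is 1 iff more than half the non-missing replicate
#'   calls are 1; exact ties resolve to 0 (a band call requires positive
#'   evidence) with a warning;
#' * `"any"`: 1 if any replicate shows the band;
#' * `"all"`: 1 only if every replicate shows the band.
#'
#' Cells where all replicate calls are missing yield `NA`.
#'
#' @param bands Long band tibble with metadata columns.
#' @param rule Consensus policy.
#' @return A band tibble with one sample per condition; `sample_id` is
#'   `<tissue>_<stage>_<dose>` and `replicate` is 1.
#' @export
aggregate_replicates <- function(bands, rule = c("majority", "any", "all")) {
  rule <- match.arg(rule)
  bands <- validate_bands(bands)
  for (cc in c("tissue", "stage", "dose")) {
    if (!cc %in% names(bands)) {
      rlang::abort(paste0("aggregate_replicates() needs metadata column '", cc, "'."),
                   class = "msapr_error_format")
    }
  }
  consensus <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_integer_)
    switch(rule,
      majority = as.integer(sum(v) * 2L > length(v)),
      any = as.integer(any(v == 1L)),
      all = as.integer(all(v == 1L))
    )
  }
  had_tie <- FALSE
  tie_check <- function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && sum(v) * 2L == length(v) && any(v == 1L)
  }
  out <- bands |>
    dplyr::group_by(.data$tissue, .data$stage, .data$dose, .data$locus) |>
    dplyr::summarise(
      tie = tie_check(.data$h) || tie_check(.data$m),
      h = consensus(.data$h),
      m = consensus(.data$m),
      .groups = "drop"
    )
  if (rule == "majority" && any(out$tie)) {
    rlang::warn(paste0(sum(out$tie),
                       " replicate tie(s) resolved to band-absent (0)."))
  }
  out |>
    dplyr::mutate(sample_id = paste(.data$tissue, .data$stage, .data$dose,
                                    sep = "_"),
                  replicate = 1L) |>
    dplyr::select("locus", "sample_id", "h", "m", "tissue", "stage",
                  "dose", "replicate")
}
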