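#' Transition type levels
#'
#' The ten types a control-to-treatment pattern change can take: four
#' methylation-gain band types (B1-B4), four demethylation band types
#' (C1-C4), `UNCHANGED` (same pattern in both) and `AMBIGUOUS` (the H band
#' is unchanged while the M band changes, so MSAP cannot tell whether
#' methylation rose or fell).
#' @format Character vector of length ten.
#' @export
transition_levels <- c("B1", "B2", "B3", "B4", "C1", "C2", "C3", "C4",
                       "UNCHANGED", "AMBIGUOUS")

# pattern pair -> type lookup; every one of the 16 pairs appears exactly once
transition_map <- c(
  "I>I" = "UNCHANGED", "I>II" = "AMBIGUOUS", "I>III" = "B1", "I>IV" = "B4",
  "II>I" = "AMBIGUOUS", "II>II" = "UNCHANGED", "II>III" = "B2", "II>IV" = "B3",
  "III>I" = "C1", "III>II" = "C2", "III>III" = "UNCHANGED", "III>IV" = "AMBIGUOUS",
  "IV>I" = "C4", "IV>II" = "C3", "IV>III" = "AMBIGUOUS", "IV>IV" = "UNCHANGED"
)

#' Classify a control-to-treatment pattern change
#'
#' Because the H (EcoRI/HpaII) digest cuts only unmethylated or
#' hemi-methylated CCGG sites, losing the H band means methylation was
#' gained (types B1-B4: I->III, II->III, II->IV, I->IV) and gaining the H
#' band means the site was demethylated (types C1-C4: III->I, III->II,
#' IV->II, IV->I). Changes that leave the H band intact while the M band
#' flips (I<->II, III<->IV) cannot be signed and are `AMBIGUOUS`; identical
#' patterns are `UNCHANGED`.
#'
#' @param ck,treated Factors or characters with values in [pattern_levels]
#'   (control and treated pattern, recycled to common length).
#' @return A factor with levels [transition_levels]; `NA` where either
#'   pattern is missing.
#' @export
#' @examples
#' classify_transition("I", "III")  # B1: methylation gain
#' classify_transition("IV", "II")  # C3: demethylation
classify_transition <- function(ck, treated) {
  ck <- as.character(ck)
  treated <- as.character(treated)
  ok <- function(x) x %in% pattern_levels | is.na(x)
  if (!all(ok(ck)) || !all(ok(treated))) {
    rlang::abort("Patterns must be one of I, II, III, IV.",
                 class = "msapr_error_format")
  }
  key <- paste0(ck, ">", treated)
  out <- unname(transition_map[key])
  out[is.na(ck) | is.na(treated)] <- NA_character_
  factor(out, levels = transition_levels)
}

#' Tabulate pattern transitions between a control and a treated band matrix
#'
#' Pairs the two matrices locus-by-locus (each must hold a single
#' consensus sample; see [aggregate_replicates()]), classifies every locus
#' with [classify_transition()], and tallies the ten transition types.
#' Loci with a missing call in either matrix are dropped from the
#' comparison.
#'
#' @param ck,treated Long band tibbles sharing an identical locus set.
#' @param label Optional comparison label (e.g. `"root CK-50uM"`) stored in
#'   the output.
#' @return A tibble with columns `label`, `type` (all ten levels), and `n`;
#'   attribute `n_loci_compared` carries the number of loci tallied.
#' @export
transition_table <- function(ck, treated, label = NA_character_) {
  ck <- validate_bands(ck)
  treated <- validate_bands(treated)
  one_sample <- function(x, what) {
    if (length(unique(x$sample_id)) != 1) {
      rlang::abort(paste0("The ", what, " matrix must contain a single ",
                          "(consensus) sample; see aggregate_replicates()."),
                   class = "msapr_error_format")
    }
  }
  one_sample(ck, "control")
  one_sample(treated, "treated")
  if (!setequal(ck$locus, treated$locus)) {
    rlang::abort("Control and treated matrices must share an identical locus set.",
                 class = "msapr_error_locus_mismatch")
  }
  pairs <- dplyr::inner_join(
    dplyr::select(add_patterns(ck), "locus", ck_pattern = "pattern"),
    dplyr::select(add_patterns(treated), "locus", treated_pattern = "pattern"),
    by = "locus"
  ) |>
    dplyr::filter(!is.na(.data$ck_pattern), !is.na(.data$treated_pattern)) |>
    dplyr::mutate(type = classify_transition(.data$ck_pattern,
                                             .data$treated_pattern))
  out <- pairs |>
    dplyr::count(.data$type, .drop = FALSE) |>
    dplyr::mutate(label = label, .before = 1)
  attr(out, "n_loci_compared") <- nrow(pairs)
  out
}

#' Summarize a transition table into gain/loss totals and dominant types
#'
#' @param table Transition-count tibble from [transition_table()] (or any
#'   tibble with `type` and `n` columns).
#' @return A one-row tibble: `methylation_total` (B1+B2+B3+B4),
#'   `demethylation_total` (C1+C2+C3+C4), `dominant_B` and `dominant_C`
#'   (the most frequent B and C type; ties joined with ","; empty string
#'   when all counts are zero), `n_unchanged`, `n_ambiguous` and
#'   `n_loci_compared`. Ambiguous transitions are excluded from both
#'   totals: MSAP cannot sign them.
#' @export
summarize_transitions <- function(table) {
  if (!all(c("type", "n") %in% names(table))) {
    rlang::abort("Need columns 'type' and 'n'.", class = "msapr_error_format")
  }
  n_of <- function(types) {
    sum(table$n[table$type %in% types])
  }
  dominant <- function(types) {
    sub <- table[table$type %in% types, ]
    sub <- sub[order(match(sub$type, transition_levels)), ]
    if (nrow(sub) == 0 || sum(sub$n) == 0) return("")
    paste(sub$type[sub$n == max(sub$n)], collapse = ",")
  }
  b_types <- paste0("B", 1:4)
  c_types <- paste0("C", 1:4)
  n_compared <- attr(table, "n_loci_compared")
  if (is.null(n_compared)) n_compared <- sum(table$n)
  tibble::tibble(
    label = if ("label" %in% names(table)) table$label[1] else NA_character_,
    methylation_total = n_of(b_types),
    demethylation_total = n_of(c_types),
    dominant_B = dominant(b_types),
    dominant_C = dominant(c_types),
    n_unchanged = n_of("UNCHANGED"),
    n_ambiguous = n_of("AMBIGUOUS"),
    n_loci_compared = n_compared
  )
}

#' Band-type definitions and per-comparison site counts (packaged fixture)
#'
#' Loads the packaged table of the eight band types (B1-B4 methylation
#' gain, C1-C4 demethylation) with their defining control/treated H and M
#' flags and the number of sites observed per tissue and 5-azaC dose in the
#' source study of *Rehmannia glutinosa*.
#'
#' @return A tibble with columns `type`, `ck_h`, `ck_m`, `treat_h`,
#'   `treat_m`, `tissue`, `dose` and `n_sites`, one row per band type per
#'   comparison column.
#' @seealso [expand_transition_counts()]
#' @export
band_type_counts <- function() {
  path <- system.file("extdata", "band_type_counts.tsv", package = "msapr")
  raw <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         progress = FALSE)
  raw |>
    tidyr::pivot_longer(-c("type", "ck_h", "ck_m", "treat_h", "treat_m"),
                        names_to = c("tissue", "dose"), names_sep = "_",
                        values_to = "n_sites") |>
    dplyr::mutate(dose = as.numeric(.data$dose),
                  dplyr::across(c("ck_h", "ck_m", "treat_h", "treat_m",
                                  "n_sites"), as.integer))
}

#' Expand per-type site counts into per-locus control/treated profiles
#'
#' Materializes one synthetic locus per counted site so that aggregated
#' band-type counts can be pushed through the full
#' [transition_table()]/[summarize_transitions()] pipeline.
#'
#' @param counts A tibble with columns `type`, `ck_h`, `ck_m`, `treat_h`,
#'   `treat_m` and `n_sites` for a single comparison (one tissue, one
#'   dose), e.g. one group of [band_type_counts()].
#' @param tissue,stage Metadata to stamp on the generated samples.
#' @param dose Treated-sample dose (micromolar).
#' @return A list with band tibbles `ck` and `treated`, each with one
#'   sample and `sum(n_sites)` loci.
#' @export
expand_transition_counts <- function(counts, tissue = "tissue", stage = "M",
                                     dose = NA_real_) {
  required <- c("type", "ck_h", "ck_m", "treat_h", "treat_m", "n_sites")
  miss <- setdiff(required, names(counts))
  if (length(miss) > 0) {
    rlang::abort(paste0("Count table missing column(s): ", toString(miss)),
                 class = "msapr_error_format")
  }
  expanded <- counts[rep(seq_len(nrow(counts)), counts$n_sites), ]
  expanded$locus <- sprintf("L%04d", seq_len(nrow(expanded)))
  make <- function(hcol, mcol, id, d) {
    tibble::tibble(
      locus = expanded$locus,
      sample_id = id,
      h = as.integer(expanded[[hcol]]),
      m = as.integer(expanded[[mcol]]),
      tissue = tissue, stage = stage, dose = d, replicate = 1L
    )
  }
  list(
    ck = make("ck_h", "ck_m", paste0(tissue, "_CK"), 0),
    treated = make("treat_h", "treat_m", paste0(tissue, "_T"), dose)
  )
}
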