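#' Relative expression by the 2^-ddCt method
#'
#' Livak's comparative-Ct estimator: per sample,
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}; per group,
#' \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_{group} -
#' \overline{\Delta Ct}_{control}}; fold change \eqn{2^{-\Delta\Delta Ct}}.
#' Group means of \eqn{\Delta Ct} are taken before exponentiation (the
#' standard Livak formulation), so the control group's fold change is 1 by
#' construction.
#'
#' @param records Ct tibble with columns `sample_id`, `group`, `gene`, `ct`
#'   (see [read_ct_table()]).
#' @param target_gene Gene whose expression is quantified.
#' @param reference_gene Internal reference gene (e.g. `TIP41`).
#' @param control_group Group used as the calibrator.
#' @return A tibble with one row per group: `group`, `n` (samples),
#'   `mean_dct`, `sd_dct`, `ddct`, `fold_change`.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = c("c1", "c1", "t1", "t1"),
#'   group = c("CK", "CK", "azaC", "azaC"),
#'   gene = c("DXS", "TIP41", "DXS", "TIP41"),
#'   ct = c(25, 20, 23, 20)
#' )
#' ddct_fold_change(ct, "DXS", "TIP41", "CK")
ddct_fold_change <- function(records, target_gene, reference_gene,
                             control_group) {
  required <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(required, names(records))
  if (length(miss) > 0) {
    rlang::abort(paste0("Ct records missing column(s): ", toString(miss)),
                 class = "msapr_error_format")
  }
  if (!control_group %in% records$group) {
    rlang::abort(paste0("Unknown control group '", control_group, "'."),
                 class = "msapr_error_format")
  }
  wide <- records |>
    dplyr::filter(.data$gene %in% c(target_gene, reference_gene)) |>
    dplyr::mutate(role = ifelse(.data$gene == target_gene, "target", "reference")) |>
    dplyr::group_by(.data$sample_id, .data$group, .data$role) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role", values_from = "ct")
  if (!all(c("target", "reference") %in% names(wide)) ||
      any(is.na(wide$target)) || any(is.na(wide$reference))) {
    bad <- if (!"reference" %in% names(wide)) wide$sample_id else
      wide$sample_id[is.na(wide$reference) | is.na(wide$target)]
    rlang::abort(paste0("Sample(s) lacking a target or reference Ct: ",
                        toString(bad)),
                 class = "msapr_error_missing_reference")
  }
  per_group <- wide |>
    dplyr::mutate(dct = .data$target - .data$reference) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean_dct = mean(.data$dct),
                     sd_dct = stats::sd(.data$dct), .groups = "drop")
  control_dct <- per_group$mean_dct[per_group$group == control_group]
  per_group |>
    dplyr::mutate(ddct = .data$mean_dct - control_dct,
                  fold_change = 2 ^ (-.data$ddct))
}

#' 5-methylcytosine percentage from chromatogram peak areas
#'
#' Genome-wide methylation measured by HPLC separation of hydrolyzed
#' genomic DNA: the 5mC content is the molar fraction of methylated
#' cytosine among all cytosines,
#' \deqn{100 \frac{A_{5mC}/f_{5mC}}{A_{5mC}/f_{5mC} + A_{C}/f_{C}}}
#' where the response factors \eqn{f} convert peak area to moles and
#' default to 1 (override them from calibration standards). The formula is
#' a convention, not a universal standard; report the factors used.
#'
#' @param area_5mC,area_C Non-negative peak areas (vectorized).
#' @param rf_5mC,rf_C Positive response factors.
#' @return Percentage(s) in `[0, 100]`.
#' @export
#' @examples
#' five_mc_percent(1, 3)            # 25
#' five_mc_percent(2, 2, rf_5mC = 2) # 33.33...
five_mc_percent <- function(area_5mC, area_C, rf_5mC = 1, rf_C = 1) {
  if (any(area_5mC < 0) || any(area_C < 0)) {
    rlang::abort("Peak areas must be non-negative.", class = "msapr_error_format")
  }
  if (any(rf_5mC <= 0) || any(rf_C <= 0)) {
    rlang::abort("Response factors must be positive.", class = "msapr_error_format")
  }
  num <- area_5mC / rf_5mC
  den <- num + area_C / rf_C
  if (any(den == 0)) {
    rlang::abort("Both corrected peak areas are zero; 5mC% is undefined.",
                 class = "msapr_error_undefined_level")
  }
  100 * num / den
}

#' One-way ANOVA followed by Duncan's multiple range test
#'
#' Fits a one-way ANOVA and compares all group means with Duncan's
#' multiple range test: means are sorted in decreasing order and two means
#' whose ranks span `p` positions differ significantly when their
#' difference exceeds the critical range
#' \deqn{R_p = q\!\left(1-\alpha_p;\, p,\, df_e\right)\sqrt{MS_e / n_h}}
#' with Duncan's protection level \eqn{\alpha_p = 1-(1-\alpha)^{p-1}}
#' applied to the studentized-range quantile, \eqn{n_h} the harmonic mean
#' of the group sizes, and \eqn{df_e}, \eqn{MS_e} from the ANOVA. Groups
#' are then labelled with a compact letter display (insert-and-absorb):
#' groups share a letter iff they are not significantly different, with
#' letter `a` starting at the largest mean.
#'
#' @param data A data frame of measurements.
#' @param value Column holding the measurement (tidy-eval).
#' @param group Column holding the group label (tidy-eval).
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return An object of class `duncan_fit`: use [tidy()][generics::tidy]
#'   for the per-group table (mean, sd, n, letters), [glance()][generics::glance]
#'   for the ANOVA summary, and [ggplot2::autoplot()] for a bar chart with
#'   letters.
#' @export
#' @examples
#' d <- data.frame(y = c(1, 1.1, 0.9, 5, 5.2, 4.8), g = rep(c("a", "b"), each = 3))
#' fit <- anova_duncan(d, y, g)
#' tidy(fit)
anova_duncan <- function(data, value, group, alpha = 0.05) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  df <- tibble::tibble(
    value = as.numeric(rlang::eval_tidy(value, data)),
    group = as.character(rlang::eval_tidy(group, data))
  )
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must be a single number in (0, 1).",
                 class = "msapr_error_format")
  }
  sizes <- table(df$group)
  if (length(sizes) < 2) {
    rlang::abort("Need at least two groups.", class = "msapr_error_format")
  }
  if (any(sizes < 2)) {
    rlang::abort(paste0("Every group needs at least two observations; too few in: ",
                        toString(names(sizes)[sizes < 2])),
                 class = "msapr_error_format")
  }
  # exact residual check before fitting: identical values within every
  # group leave MS_error = 0 and Duncan's ranges undefined
  rss <- sum(stats::ave(df$value, df$group) != df$value)
  if (rss == 0) {
    rlang::abort("Degenerate input: zero within-group variance leaves Duncan's ranges undefined.",
                 class = "msapr_error_degenerate")
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- suppressWarnings(stats::anova(fit))
  ms_error <- tab["Residuals", "Mean Sq"]
  df_error <- tab["Residuals", "Df"]
  if (!is.finite(ms_error) || ms_error <= 0) {
    rlang::abort("Degenerate input: zero within-group variance leaves Duncan's ranges undefined.",
                 class = "msapr_error_degenerate")
  }
  groups <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sd = stats::sd(.data$value), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean))
  sig <- duncan_pairwise(groups$mean, groups$n, ms_error, df_error, alpha)
  groups$letters <- compact_letters(sig)
  structure(
    list(
      groups = groups,
      f_statistic = tab["group", "F value"],
      p_value = tab["group", "Pr(>F)"],
      df_between = tab["group", "Df"],
      df_error = df_error,
      ms_error = ms_error,
      alpha = alpha,
      significant = sig
    ),
    class = "duncan_fit"
  )
}

# significance matrix for means already sorted in decreasing order:
# entry [i, j] TRUE when groups i and j differ under Duncan's range test
duncan_pairwise <- function(means, n, ms_error, df_error, alpha) {
  k <- length(means)
  n_h <- k / sum(1 / n)  # harmonic mean of group sizes
  se <- sqrt(ms_error / n_h)
  sig <- matrix(FALSE, k, k, dimnames = list(seq_len(k), seq_len(k)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- j - i + 1
      r_p <- stats::qtukey((1 - alpha) ^ (p - 1), p, df_error) * se
      sig[i, j] <- sig[j, i] <- (means[i] - means[j]) > r_p
    }
  }
  # protection: a pair inside a non-significant span is itself declared
  # non-significant (no pair can differ when a wider enclosing pair does not)
  for (span in rev(seq_len(k - 1))) {
    for (i in seq_len(k - span)) {
      j <- i + span
      if (!sig[i, j]) {
        for (a in i:j) for (b in i:j) sig[a, b] <- FALSE
      }
    }
  }
  sig
}

# insert-and-absorb compact letter display over a logical significance
# matrix (rows/cols ordered by decreasing mean); returns e.g. c("a","ab","b")
compact_letters <- function(sig) {
  k <- nrow(sig)
  cols <- list(rep(TRUE, k))  # each column is a set of groups sharing a letter
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          cols[[ci]] <- a
          cols[[length(cols) + 1]] <- b
        }
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(cols))
      for (ci in seq_along(cols)) {
        for (cj in seq_along(cols)) {
          if (ci != cj && keep[ci] && keep[cj] &&
              all(cols[[ci]] <= cols[[cj]]) && any(cols[[cj]] > cols[[ci]])) {
            keep[ci] <- FALSE
          }
        }
      }
      # drop exact duplicates too
      sig_keys <- vapply(cols, paste, character(1), collapse = "")
      keep <- keep & !duplicated(sig_keys)
      cols <- cols[keep]
    }
  }
  # order letters so 'a' appears at the largest mean
  first <- vapply(cols, function(col) which(col)[1], integer(1))
  cols <- cols[order(first)]
  letters_used <- letters[seq_along(cols)]
  vapply(seq_len(k), function(g) {
    paste(letters_used[vapply(cols, function(col) col[g], logical(1))],
          collapse = "")
  }, character(1))
}

#' @export
print.duncan_fit <- function(x, ...) {
  cat("One-way ANOVA + Duncan's multiple range test (alpha =", x$alpha, ")\n")
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g\n", x$df_between, x$df_error,
              x$f_statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' Tidy a Duncan fit: per-group means, dispersion and letters
#'
#' @param x A `duncan_fit` from [anova_duncan()].
#' @param ... Unused.
#' @return A tibble with columns `group`, `n`, `mean`, `sd`, `letters`,
#'   ordered by decreasing mean.
#' @method tidy duncan_fit
#' @export
tidy.duncan_fit <- function(x, ...) {
  x$groups
}

#' Glance at a Duncan fit: one-row ANOVA summary
#'
#' @inheritParams tidy.duncan_fit
#' @return A one-row tibble: `f_statistic`, `p_value`, `df_between`,
#'   `df_error`, `ms_error`, `alpha`, `n_groups`.
#' @method glance duncan_fit
#' @export
glance.duncan_fit <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic, p_value = x$p_value,
    df_between = x$df_between, df_error = x$df_error,
    ms_error = x$ms_error, alpha = x$alpha, n_groups = nrow(x$groups)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
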