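# shared fixture builders and independent oracles

make_bands <- function(h, m, sample_id = "s1", tissue = "root", stage = "M",
                       dose = 0, replicate = 1L,
                       locus = sprintf("L%d", seq_along(h))) {
  tibble::tibble(
    locus = locus, sample_id = sample_id,
    h = as.integer(h), m = as.integer(m),
    tissue = tissue, stage = stage, dose = dose, replicate = replicate
  )
}

write_band_fixture <- function(bands, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  bands_path <- file.path(dir, "bands.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  msapr::write_band_matrix(bands, bands_path, meta_path)
  list(bands = bands_path, meta = meta_path, dir = dir)
}

# analytic one-step treatment kernel: rows = control state, cols = treated
# state, p = demethylation probability, g = gain probability
one_step_kernel <- function(p, g) {
  k <- matrix(0, 4, 4, dimnames = list(msapr::state_levels, msapr::state_levels))
  k["UNMETHYLATED", ] <- c(1 - g, g / 2, g / 2, 0)
  k["HEMI", ] <- c(p, (1 - p) * (1 - g), 0, (1 - p) * g)
  k["INTERNAL_FULL", ] <- c(p, 0, 1 - p, 0)
  k["HYPER", ] <- c(0, p / 2, p / 2, 1 - p)
  k
}

# textbook Duncan multiple range test, stated directly from its definition:
# a pair of rank-ordered means differs iff EVERY range containing the pair
# exceeds its critical value R_p. Independent of the package's sequential
# zeroing implementation.
oracle_duncan_sig <- function(means, n, ms_error, df_error, alpha) {
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]
  k <- length(means)
  n_h <- k / sum(1 / n)
  exceeds <- function(i, j) {
    p <- j - i + 1
    r_p <- stats::qtukey((1 - alpha)^(p - 1), p, df_error) *
      sqrt(ms_error / n_h)
    (means[i] - means[j]) > r_p
  }
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      all_exceed <- TRUE
      for (a in seq_len(i)) {
        for (b in j:k) {
          if (!exceeds(a, b)) all_exceed <- FALSE
        }
      }
      sig[i, j] <- sig[j, i] <- all_exceed
    }
  }
  sig
}

# compact-letter-display contract: groups share a letter iff not
# significantly different
cld_valid <- function(letters_vec, sig) {
  k <- length(letters_vec)
  shares <- function(i, j) {
    length(intersect(strsplit(letters_vec[i], "")[[1]],
                     strsplit(letters_vec[j], "")[[1]])) > 0
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sig[i, j] && shares(i, j)) return(FALSE)
      if (!sig[i, j] && !shares(i, j)) return(FALSE)
    }
  }
  TRUE
}

# expand every packaged band-type count column through the full pipeline
table2_summaries <- function() {
  counts <- msapr::band_type_counts()
  purrr::map_dfr(
    dplyr::group_split(counts, tissue, dose),
    function(sub) {
      pair <- msapr::expand_transition_counts(
        sub, tissue = sub$tissue[1], dose = sub$dose[1])
      tab <- msapr::transition_table(
        pair$ck, pair$treated, label = paste0(sub$tissue[1], "_", sub$dose[1]))
      cbind(tissue = sub$tissue[1], dose = sub$dose[1],
            msapr::summarize_transitions(tab))
    }
  )
}
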