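test_that("fold change is 1 for the control and 2^-ddCt elsewhere", {
  ct <- tibble::tibble(
    sample_id = c("c1", "c1", "t1", "t1"),
    group = c("CK", "CK", "azaC", "azaC"),
    gene = c("DXS", "TIP41", "DXS", "TIP41"),
    ct = c(25, 20, 23, 20)
  )
  res <- ddct_fold_change(ct, "DXS", "TIP41", "CK")
  expect_equal(res$fold_change[res$group == "CK"], 1)
  expect_equal(res$fold_change[res$group == "azaC"], 4)  # ddCt = -2
})

test_that("fold changes match a sample-by-sample spreadsheet recomputation", {
  set.seed(21)
  groups <- rep(c("CK", "d15", "d50"), each = 3)
  samples <- paste0("s", seq_along(groups))
  target_ct <- round(rnorm(9, mean = c(26, 25, 24)[match(groups, c("CK", "d15", "d50"))],
                           sd = 0.3), 2)
  ref_ct <- round(rnorm(9, mean = 20, sd = 0.2), 2)
  ct <- dplyr::bind_rows(
    tibble::tibble(sample_id = samples, group = groups, gene = "G",
                   ct = target_ct),
    tibble::tibble(sample_id = samples, group = groups, gene = "R",
                   ct = ref_ct)
  )
  res <- ddct_fold_change(ct, "G", "R", "CK")

  # independent oracle: explicit loops, no dplyr
  dct <- target_ct - ref_ct
  ctrl_mean <- mean(dct[groups == "CK"])
  for (g in unique(groups)) {
    expected <- 2 ^ (-(mean(dct[groups == g]) - ctrl_mean))
    expect_equal(res$fold_change[res$group == g], expected, label = g)
  }
})

test_that("ddCt is invariant to shifts applied to both genes, not one", {
  ct <- tibble::tibble(
    sample_id = rep(paste0("s", 1:4), 2),
    group = rep(c("CK", "CK", "T", "T"), 2),
    gene = rep(c("G", "R"), each = 4),
    ct = c(25, 25.4, 23.1, 22.9, 20, 20.2, 19.8, 20.1)
  )
  base <- ddct_fold_change(ct, "G", "R", "CK")
  both <- dplyr::mutate(ct, ct = ct + 3)
  expect_equal(ddct_fold_change(both, "G", "R", "CK")$fold_change,
               base$fold_change)
  only_target <- dplyr::mutate(ct, ct = ct + ifelse(gene == "G", 3, 0))
  # a shift common to every sample's target cancels in ddCt too; shift one
  # group's target only to break it
  one_group <- dplyr::mutate(
    ct, ct = ct + ifelse(gene == "G" & group == "T", 1, 0))
  expect_false(isTRUE(all.equal(
    ddct_fold_change(one_group, "G", "R", "CK")$fold_change,
    base$fold_change)))
})

test_that("missing reference Cts and unknown control groups are errors", {
  ct <- tibble::tibble(sample_id = c("s1", "s2"), group = "CK",
                       gene = c("G", "G"), ct = c(25, 24))
  expect_error(ddct_fold_change(ct, "G", "R", "CK"),
               class = "msapr_error_missing_reference")
  ct2 <- tibble::tibble(sample_id = rep("s1", 2), group = "CK",
                        gene = c("G", "R"), ct = c(25, 20))
  expect_error(ddct_fold_change(ct2, "G", "R", "nope"),
               class = "msapr_error_format")
})

test_that("5mC percentage is a corrected molar fraction", {
  expect_equal(five_mc_percent(1, 3), 25)
  expect_equal(five_mc_percent(0, 3), 0)
  expect_equal(five_mc_percent(2, 2, rf_5mC = 2, rf_C = 1), 100 / 3)
  # invariant to common scaling of both areas
  expect_equal(five_mc_percent(0.2, 0.6), five_mc_percent(2000, 6000))
  expect_error(five_mc_percent(0, 0), class = "msapr_error_undefined_level")
  expect_error(five_mc_percent(1, 1, rf_5mC = 0), class = "msapr_error_format")
})

test_that("clearly separated groups get distinct Duncan letters", {
  set.seed(31)
  d <- data.frame(y = c(rnorm(3, 0, 0.1), rnorm(3, 100, 0.1)),
                  g = rep(c("lo", "hi"), each = 3))
  fit <- anova_duncan(d, y, g)
  td <- tidy(fit)
  expect_equal(td$letters, c("a", "b"))
  expect_equal(td$group, c("hi", "lo"))
  expect_lt(glance(fit)$p_value, 1e-6)
})

test_that("indistinguishable groups share one letter", {
  set.seed(32)
  d <- data.frame(y = 5 + rnorm(9, sd = 1e-9) +
                    rep(c(0, 1e-10, -1e-10), each = 3),
                  g = rep(c("a", "b", "c"), each = 3))
  fit <- anova_duncan(d, y, g)
  expect_true(all(tidy(fit)$letters == "a"))
})

test_that("letters match the textbook all-ranges oracle at <= 4 groups", {
  set.seed(33)
  scenarios <- list(
    list(means = c(10, 10.2, 15, 20), sd = 1, n = 4),
    list(means = c(0, 1, 2, 3), sd = 1.5, n = 3),
    list(means = c(5, 5, 5, 9), sd = 0.8, n = 4),
    list(means = c(2, 4), sd = 0.5, n = 5),
    list(means = c(1, 1.2, 1.4), sd = 0.1, n = 3)
  )
  for (sc in scenarios) {
    g <- rep(paste0("g", seq_along(sc$means)), each = sc$n)
    y <- rnorm(length(g), mean = rep(sc$means, each = sc$n), sd = sc$sd)
    d <- data.frame(y = y, g = g)
    fit <- anova_duncan(d, y, g, alpha = 0.05)
    td <- tidy(fit)
    oracle <- oracle_duncan_sig(td$mean, td$n, fit$ms_error, fit$df_error,
                                fit$alpha)
    expect_equal(unname(fit$significant), oracle)
    expect_true(cld_valid(td$letters, oracle))
  }
})

test_that("raising alpha never merges more groups", {
  set.seed(34)
  d <- data.frame(y = rnorm(12, mean = rep(c(0, 1.2, 2.4, 3.6), each = 3),
                            sd = 0.8),
                  g = rep(c("a", "b", "c", "d"), each = 3))
  strict <- anova_duncan(d, y, g, alpha = 0.01)$significant
  loose <- anova_duncan(d, y, g, alpha = 0.10)$significant
  # every pair significant at the stricter alpha stays significant
  expect_true(all(loose[strict]))
})

test_that("degenerate and undersized inputs are rejected", {
  flat <- data.frame(y = rep(5, 6), g = rep(c("a", "b"), each = 3))
  expect_error(anova_duncan(flat, y, g), class = "msapr_error_degenerate")
  tiny <- data.frame(y = c(1, 2, 3), g = c("a", "a", "b"))
  expect_error(anova_duncan(tiny, y, g), class = "msapr_error_format")
  expect_error(anova_duncan(data.frame(y = 1:4, g = rep("a", 4)), y, g),
               class = "msapr_error_format")
})

test_that("tidy/glance/autoplot expose the fit consistently", {
  set.seed(35)
  d <- data.frame(y = rnorm(9, rep(c(1, 5, 9), each = 3), 0.5),
                  g = rep(c("x", "y", "z"), each = 3))
  fit <- anova_duncan(d, y, g)
  td <- tidy(fit)
  gl <- glance(fit)
  expect_equal(nrow(td), gl$n_groups)
  expect_true(all(diff(td$mean) <= 0))  # sorted by decreasing mean
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
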