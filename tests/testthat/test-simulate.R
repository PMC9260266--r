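test_that("states render to band profiles by the fixed digestion table", {
  prof <- render_bands(c("UNMETHYLATED", "HEMI", "INTERNAL_FULL", "HYPER"))
  expect_equal(prof$h, c(1L, 1L, 0L, 0L))
  expect_equal(prof$m, c(1L, 0L, 1L, 0L))
  expect_error(render_bands("METH"), class = "msapr_error_format")
})

test_that("configuration validation catches out-of-range parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(state_probs = c(0.5, 0.5, 0.1, 0)),
               class = "msapr_error_config")
  expect_error(sim_config(call_error = 0.6), class = "msapr_error_config")
  expect_error(sim_config(gain_prob = 1), class = "msapr_error_config")
  expect_error(sim_config(kappa = -1), class = "msapr_error_config")
  expect_error(sim_config(n_loci = 0), class = "msapr_error_config")
})

test_that("dose zero with no gain leaves states untouched", {
  states <- rep(state_levels, 25)
  expect_equal(apply_dose(states, dose = 0, kappa = 1, gain_prob = 0,
                          seed = 1), states)
})

test_that("a saturating dose demethylates every hemi-methylated locus one step", {
  states <- rep("HEMI", 500)
  out <- apply_dose(states, dose = 1e9, kappa = 10, gain_prob = 0, seed = 2)
  expect_true(all(out == "UNMETHYLATED"))
  hyper <- apply_dose(rep("HYPER", 500), dose = 1e9, kappa = 10,
                      gain_prob = 0, seed = 3)
  expect_true(all(hyper %in% c("HEMI", "INTERNAL_FULL")))
})

test_that("the demethylation fraction follows its binomial law", {
  n <- 100000
  # kappa and dose chosen so p = 0.5
  out <- apply_dose(rep("HYPER", n), dose = 1, kappa = log(2), gain_prob = 0,
                    seed = 4)
  frac_remaining <- mean(out == "HYPER")
  sigma <- sqrt(0.25 / n)
  expect_lt(abs(frac_remaining - 0.5), 3 * sigma)
  # the two demethylation products are equally likely
  stepped <- out[out != "HYPER"]
  expect_lt(abs(mean(stepped == "HEMI") - 0.5), 3 * sqrt(0.25 / length(stepped)))
})

test_that("simulation is bit-identical under the same seed", {
  cfg <- sim_config(n_loci = 200, seed = 77)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$bands, b$bands)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_experiment(sim_config(n_loci = 200, seed = 78))
  expect_false(identical(a$bands, c2$bands))
})

test_that("noise-free scoring recovers the configured state distribution", {
  probs <- c(UNMETHYLATED = 0.45, HEMI = 0.2, INTERNAL_FULL = 0.15,
             HYPER = 0.2)
  sim <- simulate_experiment(sim_config(
    n_loci = 10000, state_probs = probs, doses = 0, call_error = 0,
    gain_prob = 0, n_replicates = 1, seed = 303
  ))
  counts <- count_patterns(sim$bands)
  observed <- unlist(counts[paste0("n_", pattern_levels)], use.names = FALSE)
  expected <- 10000 * unname(probs)
  sigma <- sqrt(10000 * unname(probs) * (1 - unname(probs)))
  expect_true(all(abs(observed - expected) <= 3 * sigma))
})

test_that("simulate -> score -> transitions matches the one-step kernel", {
  probs <- c(UNMETHYLATED = 0.3, HEMI = 0.25, INTERNAL_FULL = 0.2,
             HYPER = 0.25)
  kappa <- 0.02
  gain <- 0.03
  dose <- 50
  n <- 20000
  sim <- simulate_experiment(sim_config(
    n_loci = n, state_probs = probs, doses = c(0, dose), kappa = kappa,
    gain_prob = gain, call_error = 0, n_replicates = 1, seed = 404
  ))
  ck <- dplyr::filter(sim$bands, dose == 0)
  tr <- dplyr::filter(sim$bands, dose == !!dose)
  tab <- transition_table(ck, tr)

  # analytic joint law of (control pattern, treated pattern)
  p <- 1 - exp(-kappa * dose)
  kern <- one_step_kernel(p, gain)
  joint <- diag(unname(probs)) %*% kern
  dimnames(joint) <- list(pattern_levels, pattern_levels)
  expected_by_type <- sapply(transition_levels, function(ty) {
    total <- 0
    for (a in pattern_levels) for (b in pattern_levels) {
      if (as.character(classify_transition(a, b)) == ty) {
        total <- total + joint[a, b]
      }
    }
    n * total
  })
  observed <- setNames(tab$n, as.character(tab$type))[transition_levels]
  sigma <- sqrt(pmax(expected_by_type * (1 - expected_by_type / n), 1))
  expect_true(all(abs(observed - expected_by_type) <= 4 * sigma))
})

test_that("with hyper-methylated loci dominant, demethylation is mainly IV->II", {
  sim <- simulate_experiment(sim_config(
    n_loci = 5000,
    state_probs = c(UNMETHYLATED = 0.1, HEMI = 0.1, INTERNAL_FULL = 0.1,
                    HYPER = 0.7),
    doses = c(0, 100), kappa = 0.05, gain_prob = 0, call_error = 0,
    n_replicates = 1, seed = 505
  ))
  ck <- dplyr::filter(sim$bands, dose == 0)
  tr <- dplyr::filter(sim$bands, dose == 100)
  summ <- summarize_transitions(transition_table(ck, tr))
  expect_equal(summ$dominant_C, "C3")
})

test_that("kappa is recovered within 10% from one dose at n = 10,000", {
  kappa <- 0.01
  sim <- simulate_experiment(sim_config(
    n_loci = 10000, kappa = kappa, gain_prob = 0, call_error = 0,
    doses = c(0, 50), n_replicates = 1, seed = 606
  ))
  k_hat <- estimate_kappa(sim$truth$state[sim$truth$dose == 0],
                          sim$truth$state[sim$truth$dose == 50], 50)
  expect_lt(abs(k_hat - kappa) / kappa, 0.10)
})

test_that("expected total methylation level decreases with dose when gains are off", {
  sim <- simulate_experiment(sim_config(
    n_loci = 20000, doses = c(0, 15, 50, 100), kappa = 0.01, gain_prob = 0,
    call_error = 0, n_replicates = 1, seed = 707
  ))
  levels_by_dose <- sim$bands |>
    count_patterns(dose) |>
    methylation_levels() |>
    dplyr::arrange(dose)
  expect_true(all(diff(levels_by_dose$total_pct) <= 0))
})

test_that("band-call noise flips flags at the configured rate", {
  cfg <- sim_config(n_loci = 20000, doses = 0, call_error = 0.05,
                    gain_prob = 0, n_replicates = 1, seed = 808)
  sim <- simulate_experiment(cfg)
  clean <- render_bands(sim$truth$state)
  flips <- mean(sim$bands$h != clean$h) + mean(sim$bands$m != clean$m)
  expect_lt(abs(flips / 2 - 0.05), 3 * sqrt(0.05 * 0.95 / 40000))
})
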