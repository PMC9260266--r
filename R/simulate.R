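#' Methylation state levels used by the simulator
#'
#' Ground-truth CCGG methylation states: `UNMETHYLATED` (cut by both
#' digests, renders pattern I), `HEMI` (one strand methylated, pattern II),
#' `INTERNAL_FULL` (internal cytosine methylated on both strands, pattern
#' III) and `HYPER` (methylation blocking both enzymes, pattern IV,
#' invisible to MSAP).
#' @format Character vector of length four.
#' @export
state_levels <- c("UNMETHYLATED", "HEMI", "INTERNAL_FULL", "HYPER")

state_to_pattern <- c(UNMETHYLATED = "I", HEMI = "II",
                      INTERNAL_FULL = "III", HYPER = "IV")

#' Simulation configuration for synthetic MSAP experiments
#'
#' Bundles and validates the parameters of the generative model. Defaults
#' emulate a plant MSAP study design: three 5-azaC doses plus an untreated
#' control, three replicates, and a control state distribution in which
#' hemi-methylation exceeds full methylation (as typically observed at
#' CCGG sites in plant genomes).
#'
#' @param n_loci Number of CCGG loci.
#' @param state_probs Length-4 probability vector over [state_levels]
#'   (control state distribution); must sum to 1.
#' @param doses 5-azaC doses in micromolar; dose 0 is the untreated
#'   control and is always included.
#' @param kappa Demethylation rate constant per micromolar: the
#'   probability that a methylated locus takes one demethylation step at
#'   dose d is `1 - exp(-kappa * d)`.
#' @param gain_prob Small per-locus probability of a one-step methylation
#'   gain under treatment (produces the rare B-type transitions).
#' @param call_error Probability of miscalling each band flag
#'   independently; in `[0, 0.5)`.
#' @param n_replicates Replicate samples per dose.
#' @param seed Integer seed; every random draw in
#'   [simulate_experiment()] descends from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 500,
                       state_probs = c(UNMETHYLATED = 0.45, HEMI = 0.20,
                                       INTERNAL_FULL = 0.15, HYPER = 0.20),
                       doses = c(0, 15, 50, 100),
                       kappa = 0.01,
                       gain_prob = 0.02,
                       call_error = 0.02,
                       n_replicates = 3,
                       seed = 1L) {
  stop_cfg <- function(msg) rlang::abort(msg, class = "msapr_error_config")
  if (!is.numeric(n_loci) || n_loci < 1) stop_cfg("n_loci must be a positive integer.")
  if (length(state_probs) != 4 || any(state_probs < 0) ||
      abs(sum(state_probs) - 1) > 1e-12) {
    stop_cfg("state_probs must be 4 non-negative numbers summing to 1.")
  }
  if (is.null(names(state_probs))) names(state_probs) <- state_levels
  if (!identical(names(state_probs), state_levels)) {
    stop_cfg(paste0("state_probs must be named ", toString(state_levels), "."))
  }
  if (any(doses < 0)) stop_cfg("doses must be non-negative.")
  if (!is.numeric(kappa) || kappa < 0) stop_cfg("kappa must be >= 0.")
  if (gain_prob < 0 || gain_prob >= 1) stop_cfg("gain_prob must be in [0, 1).")
  if (call_error < 0 || call_error >= 0.5) stop_cfg("call_error must be in [0, 0.5).")
  if (n_replicates < 1) stop_cfg("n_replicates must be >= 1.")
  structure(
    list(n_loci = as.integer(n_loci), state_probs = state_probs,
         doses = sort(unique(c(0, doses))), kappa = kappa,
         gain_prob = gain_prob, call_error = call_error,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Render methylation states as H/M band profiles
#'
#' The deterministic digestion rule: `UNMETHYLATED` -> (1,1), `HEMI` ->
#' (1,0), `INTERNAL_FULL` -> (0,1), `HYPER` -> (0,0). Composing this with
#' [classify_pattern()] maps each state to its pattern (I-IV) exactly.
#'
#' @param states Character or factor vector with values in [state_levels].
#' @return A tibble with integer columns `h` and `m`.
#' @export
#' @examples
#' render_bands(c("UNMETHYLATED", "HYPER"))
render_bands <- function(states) {
  states <- as.character(states)
  if (!all(states %in% state_levels)) {
    rlang::abort(paste0("States must be one of ", toString(state_levels), "."),
                 class = "msapr_error_format")
  }
  tibble::tibble(
    h = as.integer(states %in% c("UNMETHYLATED", "HEMI")),
    m = as.integer(states %in% c("UNMETHYLATED", "INTERNAL_FULL"))
  )
}

#' Apply one treatment round of the dose-dependent demethylation model
#'
#' Each locus independently takes at most one demethylation step with
#' probability `p = 1 - exp(-kappa * dose)`: `HYPER` steps to `HEMI` or
#' `INTERNAL_FULL` with equal odds, `INTERNAL_FULL` and `HEMI` step to
#' `UNMETHYLATED`. Independently, a locus that can still gain methylation
#' does so with probability `gain_prob` (`UNMETHYLATED` to `HEMI` or
#' `INTERNAL_FULL` with equal odds, `HEMI` to `HYPER`), so methylation-gain
#' transitions occur at low frequency alongside the dominant demethylation.
#'
#' @param states Character vector of control states ([state_levels]).
#' @param dose 5-azaC dose in micromolar.
#' @param kappa Demethylation rate constant per micromolar.
#' @param gain_prob Per-locus methylation-gain probability.
#' @param seed Optional integer; when given, draws come from a local RNG
#'   seeded with it, otherwise the current RNG stream is used.
#' @return Character vector of post-treatment states.
#' @export
apply_dose <- function(states, dose, kappa, gain_prob = 0, seed = NULL) {
  states <- as.character(states)
  if (!all(states %in% state_levels)) {
    rlang::abort(paste0("States must be one of ", toString(state_levels), "."),
                 class = "msapr_error_format")
  }
  if (kappa < 0 || dose < 0 || gain_prob < 0 || gain_prob >= 1) {
    rlang::abort("Invalid kappa, dose or gain_prob.", class = "msapr_error_config")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- length(states)
  p <- 1 - exp(-kappa * dose)
  out <- states
  step <- stats::runif(n) < p
  branch <- stats::runif(n) < 0.5  # HYPER's two demethylation products
  out[step & states == "HYPER" & branch] <- "HEMI"
  out[step & states == "HYPER" & !branch] <- "INTERNAL_FULL"
  out[step & states == "INTERNAL_FULL"] <- "UNMETHYLATED"
  out[step & states == "HEMI"] <- "UNMETHYLATED"
  gain <- stats::runif(n) < gain_prob
  gbranch <- stats::runif(n) < 0.5
  out[gain & states == "UNMETHYLATED" & gbranch] <- "HEMI"
  out[gain & states == "UNMETHYLATED" & !gbranch] <- "INTERNAL_FULL"
  out[gain & states == "HEMI" & !step] <- "HYPER"
  out
}

#' Simulate a complete MSAP dose-response experiment
#'
#' Draws per-locus control states from `state_probs`, applies the
#' demethylation model of [apply_dose()] once per treated dose, renders
#' the isoschizomer band profiles with [render_bands()], and emits
#' `n_replicates` samples per dose with each band flag independently
#' flipped with probability `call_error`. Dose 0 is the untreated control
#' and carries the base states unchanged. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param tissue,stage Metadata stamped on the generated samples.
#' @return A list of class `msap_sim` with elements `bands` (one long band
#'   tibble covering all doses and replicates), `truth` (tibble `locus`,
#'   `dose`, `state`) and `config`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_loci = 50, seed = 42))
#' dplyr::count(sim$truth, dose, state)
simulate_experiment <- function(config = sim_config(), tissue = "root",
                                stage = "M") {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  # generator splitting: one sub-seed per (dose) for the state process and
  # one per (dose, replicate) for band-call noise, all drawn up front from
  # the master seed so adding doses/replicates never reshuffles earlier draws
  n_doses <- length(config$doses)
  sub_seeds <- sample.int(.Machine$integer.max - 1L,
                          n_doses * (1L + config$n_replicates))
  seed_mat <- matrix(sub_seeds, nrow = n_doses)

  loci <- sprintf("L%05d", seq_len(config$n_loci))
  set.seed(seed_mat[1, 1])
  base_states <- sample(state_levels, config$n_loci, replace = TRUE,
                        prob = config$state_probs)

  truth <- list()
  bands <- list()
  for (di in seq_along(config$doses)) {
    dose <- config$doses[di]
    states <- if (dose == 0) base_states else
      apply_dose(base_states, dose, config$kappa, config$gain_prob,
                 seed = seed_mat[di, 1])
    truth[[di]] <- tibble::tibble(locus = loci, dose = dose, state = states)
    clean <- render_bands(states)
    for (rep_i in seq_len(config$n_replicates)) {
      set.seed(seed_mat[di, 1 + rep_i])
      flip_h <- stats::runif(config$n_loci) < config$call_error
      flip_m <- stats::runif(config$n_loci) < config$call_error
      bands[[length(bands) + 1]] <- tibble::tibble(
        locus = loci,
        sample_id = paste0(tissue, "_", stage, "_d", dose, "_r", rep_i),
        h = as.integer(xor(clean$h == 1L, flip_h)),
        m = as.integer(xor(clean$m == 1L, flip_m)),
        tissue = tissue, stage = stage, dose = dose, replicate = rep_i
      )
    }
  }
  structure(
    list(bands = dplyr::bind_rows(bands), truth = dplyr::bind_rows(truth),
         config = config),
    class = "msap_sim"
  )
}

#' Estimate the demethylation rate constant from simulator ground truth
#'
#' Inverts the one-step model: among loci that were methylated in the
#' control (and so eligible to demethylate), the fraction observed to have
#' stepped down at dose `d` estimates `p = 1 - exp(-kappa d)`, giving
#' `kappa_hat = -log(1 - p_hat) / d`. Valid when `gain_prob = 0`; gains
#' bias the eligible set slightly.
#'
#' @param control_states,treated_states Character vectors of per-locus
#'   states before and after treatment.
#' @param dose The treated dose (micromolar, > 0).
#' @return The estimate `kappa_hat`.
#' @export
estimate_kappa <- function(control_states, treated_states, dose) {
  if (dose <= 0) {
    rlang::abort("kappa is only identifiable at a positive dose.",
                 class = "msapr_error_config")
  }
  eligible <- control_states != "UNMETHYLATED"
  if (!any(eligible)) {
    rlang::abort("No methylated control loci; kappa is not identifiable.",
                 class = "msapr_error_config")
  }
  stepped <- eligible & (
    (control_states == "HYPER" & treated_states %in% c("HEMI", "INTERNAL_FULL")) |
    (control_states %in% c("HEMI", "INTERNAL_FULL") &
       treated_states == "UNMETHYLATED")
  )
  p_hat <- sum(stepped) / sum(eligible)
  if (p_hat >= 1) {
    rlang::abort("All eligible loci demethylated; kappa estimate diverges.",
                 class = "msapr_error_config")
  }
  -log(1 - p_hat) / dose
}

#' @export
print.msap_sim <- function(x, ...) {
  cat("Simulated MSAP experiment:", x$config$n_loci, "loci,",
      length(x$config$doses), "doses,", x$config$n_replicates,
      "replicates (seed", x$config$seed, ")\n")
  invisible(x)
}
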