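#' Deterministic child seeds
#'
#' Every stage of the pipeline derives its own seed from the master seed by
#' a counter-based linear-congruential split:
#' `child = (master * 48271 + 7919 * counter) mod (2^31 - 1)`, kept strictly
#' inside 32-bit integer range. Recorded in run manifests so any stage can
#' be re-run in isolation.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stage counter.
#' @return Integer seed.
#' @export
child_seed <- function(master, counter) {
  s <- (as.double(master) * 48271 + 7919 * as.double(counter)) %% 2147483647
  as.integer(max(s, 1))
}

# Calibration anchors: group-level generating values and reference 95% CIs
# for each pooled feedback environment of the two sharing experiments.
# Spreads are the package's stated subject-level heterogeneity (see the
# methods vignette); they are not part of the anchors.
GEN_SIGMA <- c(v = 0.2, a = 0.3, z = 0.15, t0 = 0.2)

GROUP_ANCHORS <- list(
  exp2 = list(
    baseline = list(
      mu = list(v = 0.098, a = 2.153, z = 0.497, t0 = 7.025),
      ci = list(v = c(0.039, 0.158), a = c(2.09, 2.214),
                z = c(0.486, 0.508), t0 = c(6.898, 7.154))),
    dislike_like = list(
      mu = list(v = 0.10, a = 2.373, z = 0.491, t0 = 6.936),
      ci = list(v = c(0.056, 0.145), a = c(2.281, 2.466),
                z = c(0.483, 0.50), t0 = c(6.802, 7.071))),
    trust_distrust = list(
      mu = list(v = 0.216, a = 2.403, z = 0.48, t0 = 6.681),
      ci = list(v = c(0.17, 0.262), a = c(2.280, 2.529),
                z = c(0.471, 0.49), t0 = c(6.425, 6.94)))),
  exp3 = list(
    baseline = list(
      mu = list(v = 0.006, a = 2.238, z = 0.5, t0 = 6.9),
      ci = list(v = c(-0.027, 0.037), a = c(2.153, 2.328),
                z = c(0.49, 0.51), t0 = c(6.762, 7.04))),
    dislike_like = list(
      mu = list(v = 0.037, a = 2.207, z = 0.5, t0 = 7.051),
      ci = list(v = c(0.002, 0.069), a = c(2.132, 2.286),
                z = c(0.49, 0.511), t0 = c(6.918, 7.186))),
    trust_distrust = list(
      mu = list(v = 0.12, a = 2.209, z = 0.489, t0 = 7.076),
      ci = list(v = c(0.086, 0.155), a = c(2.134, 2.286),
                z = c(0.476, 0.5), t0 = c(6.944, 7.208)))))

#' Group-level generating parameters for a pooled feedback environment
#'
#' The package's calibration anchors: group means (with reference 95% CIs)
#' for the Baseline, pooled (Dis)Like and pooled (Dis)Trust environments of
#' the two sharing experiments, plus the stated subject-level spreads.
#'
#' @param experiment `"exp2"` or `"exp3"`.
#' @param group `"baseline"`, `"dislike_like"` or `"trust_distrust"`.
#' @return List with `mu` (named group means), `sigma` (named spreads;
#'   `z` on the logit scale), `ci` (reference intervals per parameter).
#' @export
default_group_params <- function(experiment = c("exp2", "exp3"),
                                 group = c("trust_distrust", "dislike_like",
                                           "baseline")) {
  experiment <- match.arg(experiment)
  group <- match.arg(group)
  anchor <- GROUP_ANCHORS[[experiment]][[group]]
  list(mu = anchor$mu, sigma = GEN_SIGMA, ci = anchor$ci)
}

# environment -> pooled fit group
POOLING <- c(baseline = "baseline", like = "dislike_like",
             dislike = "dislike_like", trust = "trust_distrust",
             distrust = "trust_distrust", like_dislike = "dislike_like",
             trust_distrust = "trust_distrust")

#' Experiment configuration
#'
#' Assembles everything a pipeline run needs: the experiment template and
#' its feedback environments with cohort sizes, the post pool, the reaction
#' profile, per-group generating diffusion parameters, the MCMC protocols
#' and the master seed. Defaults reproduce the studies the generator
#' emulates: the single-button sharing experiment (five environments,
#' N = 59/89/45/46/49, 100 posts) and the paired-button experiment (three
#' environments, N = 126/128/137, 40 posts).
#'
#' @param template `"exp1"`, `"exp2"` or `"exp3"`.
#' @param cohorts named integer vector of cohort sizes per environment
#'   (template default used when `NULL`).
#' @param n_true,n_false post counts (template default when `NULL`).
#' @param profile a [reaction_profile()].
#' @param mcmc an [mcmc_config()] for headline fits.
#' @param mcmc_recovery an [mcmc_config()] for recovery/posterior-predictive
#'   fits.
#' @param n_trials_fit trials per subject entering the fits (defaults to the
#'   post count).
#' @param seed master seed.
#' @param fast logical; scales the MCMC protocols down (10x fewer draws) for
#'   smoke runs.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(template = c("exp2", "exp3", "exp1"),
                              cohorts = NULL, n_true = NULL, n_false = NULL,
                              profile = default_reaction_profile(),
                              mcmc = NULL, mcmc_recovery = NULL,
                              n_trials_fit = NULL, seed = 1L, fast = FALSE) {
  template <- match.arg(template)
  defaults <- list(
    exp1 = list(cohorts = c(reaction = 106L), n_true = 50L, n_false = 50L),
    exp2 = list(cohorts = c(baseline = 59L, like = 89L, dislike = 45L,
                            trust = 46L, distrust = 49L),
                n_true = 50L, n_false = 50L),
    exp3 = list(cohorts = c(baseline = 126L, like_dislike = 128L,
                            trust_distrust = 137L),
                n_true = 20L, n_false = 20L))[[template]]
  if (is.null(cohorts)) cohorts <- defaults$cohorts
  if (is.null(n_true)) n_true <- defaults$n_true
  if (is.null(n_false)) n_false <- defaults$n_false
  if (any(cohorts < 1)) stop("experiment_config: cohort sizes must be >= 1",
                             call. = FALSE)
  cohorts <- stats::setNames(as.integer(cohorts), names(cohorts))
  if (template == "exp2" &&
      !setequal(names(cohorts), c("baseline", "like", "dislike", "trust",
                                  "distrust")))
    stop("experiment_config: exp2 needs the five single-button environments",
         call. = FALSE)
  if (template == "exp3" &&
      !setequal(names(cohorts), c("baseline", "like_dislike",
                                  "trust_distrust")))
    stop("experiment_config: exp3 needs the three paired environments",
         call. = FALSE)
  if (is.null(mcmc)) mcmc <- mcmc_config(20000L, 5000L, 5L, 5L, seed)
  if (is.null(mcmc_recovery)) mcmc_recovery <- mcmc_config(2000L, 500L, 1L, 1L, seed)
  if (fast) {
    mcmc <- mcmc_config(max(mcmc$n_samples %/% 10L, 200L),
                        max(mcmc$burn_in %/% 10L, 50L), mcmc$thin,
                        mcmc$n_chains, seed)
    mcmc_recovery <- mcmc_config(max(mcmc_recovery$n_samples %/% 10L, 200L),
                                 max(mcmc_recovery$burn_in %/% 10L, 50L),
                                 mcmc_recovery$thin, mcmc_recovery$n_chains,
                                 seed)
  }
  if (is.null(n_trials_fit)) n_trials_fit <- n_true + n_false
  experiment <- if (template == "exp1") NULL else template
  groups <- if (is.null(experiment)) NULL else {
    gs <- unique(unname(POOLING[names(cohorts)]))
    stats::setNames(lapply(gs, function(g) default_group_params(experiment, g)), gs)
  }
  structure(list(template = template, cohorts = cohorts, n_true = n_true,
                 n_false = n_false, profile = profile,
                 group_params = groups, mcmc = mcmc,
                 mcmc_recovery = mcmc_recovery,
                 n_trials_fit = n_trials_fit, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from a JSON file
#'
#' Plain-text config support for the command-line interface. Recognized
#' top-level keys: `template`, `seed`, `fast`, `cohorts` (named object),
#' `n_true`, `n_false`, `mcmc` / `mcmc_recovery` (objects with `n_samples`,
#' `burn_in`, `thin`, `n_chains`), `profile` (object with `usage`,
#' `discernment`, `skip` passed to [calibrate_reaction_profile()]).
#' Missing keys fall back to [experiment_config()] defaults.
#'
#' @param path JSON file path.
#' @param seed optional master-seed override.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(seed)) seed <- if (!is.null(raw$seed)) raw$seed else 1L
  args <- list(template = if (!is.null(raw$template)) raw$template else "exp2",
               seed = as.integer(seed))
  if (!is.null(raw$fast)) args$fast <- isTRUE(raw$fast)
  if (!is.null(raw$cohorts)) args$cohorts <- unlist(raw$cohorts)
  for (k in c("n_true", "n_false", "n_trials_fit"))
    if (!is.null(raw[[k]])) args[[k]] <- as.integer(raw[[k]])
  for (k in c("mcmc", "mcmc_recovery"))
    if (!is.null(raw[[k]])) {
      m <- raw[[k]]
      args[[k]] <- mcmc_config(m$n_samples, m$burn_in,
                               if (is.null(m$thin)) 1L else m$thin,
                               if (is.null(m$n_chains)) 1L else m$n_chains,
                               as.integer(seed))
    }
  if (!is.null(raw$profile))
    args$profile <- calibrate_reaction_profile(
      usage = unlist(raw$profile$usage),
      discernment = unlist(raw$profile$discernment),
      skip = if (is.null(raw$profile$skip)) 0.2 else raw$profile$skip)
  do.call(experiment_config, args)
}
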