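#' Simulate a veracity-coded trial cohort from group-level parameters
#'
#' Draws `n_subj` subjects from the group distribution (see
#' [make_participants()]) and `n_trials` diffusion trials per subject,
#' returning the veracity-coded table the hierarchical fit consumes.
#'
#' @param group_params list with `mu` and `sigma` as returned by
#'   [default_group_params()].
#' @param n_subj subjects; `n_trials` trials per subject.
#' @param n_trials trials per subject.
#' @param seed integer seed.
#' @param environment label stored on the rows.
#' @param id_prefix participant id prefix.
#' @return Data frame with `participant_id`, `environment`, `response`,
#'   `rt`, `promoting`.
#' @export
simulate_cohort_trials <- function(group_params, n_subj, n_trials, seed = 1L,
                                   environment = "cohort", id_prefix = "s") {
  parts <- make_participants(n_subj, environment = "baseline",
                             group_params = group_params, seed = seed,
                             id_prefix = id_prefix)
  set.seed(child_seed(seed, 1L))
  rows <- lapply(seq_len(n_subj), function(i) {
    p <- parts[i, ]
    sim <- simulate_trials(ddm_params(p$v, p$a, p$z, p$t0), n_trials)
    data.frame(participant_id = p$participant_id, environment = environment,
               response = sim$boundary, rt = sim$rt,
               promoting = sim$boundary == "upper", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery analysis
#'
#' For every pooled feedback environment in the configuration: simulate a
#' cohort from the generating group parameters (the environment's pooled
#' cohort size, `n_trials_fit` trials each), refit the hierarchical model
#' with the recovery protocol, and tabulate generating value vs posterior
#' mean, posterior SD, 95% HDI and whether the posterior mean falls inside
#' the reference CI. A behavioral block compares veracity-coded discernment
#' across environments with a one-way ANOVA, and drift rates across pooled
#' groups with HDI difference comparisons.
#'
#' @param config an [experiment_config()] with a sharing template.
#' @param verbose print per-group progress.
#' @return List of class `recovery_report`: `table` (one row per group x
#'   parameter), `fits`, `comparisons` (pairwise `mu_v` HDI differences),
#'   `behavior` (discernment ANOVA), `config`.
#' @export
run_recovery <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(config$group_params))
    stop("run_recovery: config template has no sharing environments",
         call. = FALSE)
  check_mcmc_feasible(config$mcmc_recovery)
  groups <- names(config$group_params)
  pooled_n <- vapply(groups, function(g)
    sum(config$cohorts[POOLING[names(config$cohorts)] == g]), integer(1))
  fits <- list(); trials_all <- list(); rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    gp <- config$group_params[[g]]
    trials <- simulate_cohort_trials(gp, pooled_n[gi], config$n_trials_fit,
                                     seed = child_seed(config$seed, 100 + gi),
                                     environment = g,
                                     id_prefix = paste0(substr(g, 1, 2), "_"))
    cfg <- config$mcmc_recovery
    cfg$seed <- child_seed(config$seed, 200 + gi)
    fit <- fit_hierarchical_ddm(trials, cfg)
    fits[[g]] <- fit; trials_all[[g]] <- trials
    summ <- group_summary(fit)
    for (par in c("v", "a", "z", "t0")) {
      mu_par <- paste0("mu_", par)
      post_mean <- summ[mu_par, "mean"]
      ci <- gp$ci[[par]]
      rows[[length(rows) + 1]] <- data.frame(
        group = g, parameter = par, generating = gp$mu[[par]],
        post_mean = post_mean, post_sd = summ[mu_par, "sd"],
        hdi_lower = summ[mu_par, "hdi_lower"],
        hdi_upper = summ[mu_par, "hdi_upper"],
        inside_ref_ci = !is.null(ci) && post_mean >= ci[1] & post_mean <= ci[2],
        stringsAsFactors = FALSE)
    }
    if (verbose) message("recovered group ", g)
  }
  comparisons <- list()
  if (length(groups) > 1) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    comparisons <- lapply(pairs, function(pr) {
      cmp <- compare_groups(fits[[pr[1]]], fits[[pr[2]]], "mu_v")
      c(list(a = pr[1], b = pr[2]), cmp)
    })
  }
  disc <- do.call(rbind, lapply(groups, function(g) {
    d <- veracity_coded_discernment(trials_all[[g]])
    d$group <- g
    d
  }))
  behavior <- oneway_anova(disc$value, disc$group)
  structure(list(table = do.call(rbind, rows), fits = fits,
                 comparisons = comparisons, behavior = behavior,
                 discernment = disc, config = config),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' Posterior-predictive simulation
#'
#' Simulates the exact design (subjects x trials per environment) from
#' fitted or supplied group parameters, then compares environments on
#' veracity-coded discernment with a one-way ANOVA.
#'
#' @param group_params named list (per environment) of lists with `mu` and
#'   `sigma`, e.g. posterior group means from fits or
#'   [default_group_params()] anchors.
#' @param design data frame with columns `environment`, `n_subjects`,
#'   `n_trials`; every environment must appear in `group_params`.
#' @param seed integer seed.
#' @return List with `trials`, per-environment `discernment`, and `anova`.
#' @export
posterior_predictive <- function(group_params, design, seed = 1L) {
  need <- c("environment", "n_subjects", "n_trials")
  if (!all(need %in% names(design)))
    stop("posterior_predictive: design needs environment, n_subjects, n_trials",
         call. = FALSE)
  missing_env <- setdiff(design$environment, names(group_params))
  if (length(missing_env) > 0)
    stop("posterior_predictive: no parameters for environment(s) ",
         paste(missing_env, collapse = ", "), call. = FALSE)
  trials <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    simulate_cohort_trials(group_params[[design$environment[i]]],
                           design$n_subjects[i], design$n_trials[i],
                           seed = child_seed(seed, i),
                           environment = design$environment[i],
                           id_prefix = sprintf("pp%d_", i))
  }))
  disc <- veracity_coded_discernment(trials)
  disc$environment <- trials$environment[match(disc$participant_id,
                                               trials$participant_id)]
  av <- if (nrow(design) > 1) oneway_anova(disc$value, disc$environment) else NULL
  list(trials = trials, discernment = disc, anova = av)
}

check_mcmc_feasible <- function(cfg) {
  if ((cfg$n_samples - cfg$burn_in) %/% cfg$thin < 10)
    stop("MCMC config infeasible: fewer than 10 retained draws", call. = FALSE)
  invisible(TRUE)
}

#' Run the full pipeline
#'
#' End-to-end run: simulate the reaction study and derive per-post feedback,
#' (for the paired-button template) select non-partisan posts, simulate the
#' sharing cohorts, compute behavioral metrics, fit the hierarchical model
#' per pooled environment, compare groups, and write all tables, posterior
#' summaries and a JSON manifest (config, child seeds, content hashes) to
#' `out_dir`. Identical (config, seed) runs produce byte-identical
#' manifests. Refuses to touch a non-empty directory unless
#' `overwrite = TRUE`.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @param fit run the (slow) hierarchical fits; disable for
#'   simulation/metrics-only runs.
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_full_pipeline <- function(config, out_dir, overwrite = FALSE, fit = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("run_full_pipeline: output directory not empty (use overwrite = TRUE)",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (fit) check_mcmc_feasible(config$mcmc)
  seed <- config$seed
  res <- list(config = config)

  # reaction stage: posts + reaction study + feedback counts
  posts <- generate_posts(config$n_true, config$n_false,
                          seed = child_seed(seed, 1))
  rx_cohort <- make_participants(106L, "baseline",
                                 seed = child_seed(seed, 2), id_prefix = "rx")
  rx_cohort <- exclude_failed_checks(rx_cohort)
  reactions <- simulate_reaction_study(posts, rx_cohort, config$profile,
                                       seed = child_seed(seed, 3))
  posts <- derive_feedback(reactions, posts)
  res$posts <- posts; res$reactions <- reactions

  if (config$template == "exp1") {
    scores <- do.call(rbind, lapply(BUTTONS, function(b)
      reaction_discernment(reactions, posts, b)))
    res$reaction_discernment <- scores
    write_table(reactions, file.path(out_dir, "reactions.csv"))
    write_table(scores, file.path(out_dir, "reaction_discernment.csv"))
  } else {
    if (config$template == "exp3")
      posts <- select_nonpartisan_posts(reactions, rx_cohort, posts = posts)
    # sharing cohorts per environment, drawn from the pooled group anchors
    trials <- do.call(rbind, lapply(seq_along(config$cohorts), function(i) {
      env <- names(config$cohorts)[i]
      gp <- config$group_params[[POOLING[[env]]]]
      parts <- make_participants(config$cohorts[[i]], env, gp,
                                 seed = child_seed(seed, 10 + i),
                                 id_prefix = paste0(env, "_"))
      parts <- exclude_failed_checks(parts)
      simulate_sharing_study(posts, parts, seed = child_seed(seed, 30 + i))
    }))
    res$trials <- trials
    disc <- sharing_discernment(trials)
    disc$environment <- trials$environment[match(disc$participant_id,
                                                 trials$participant_id)]
    res$sharing_discernment <- disc
    res$engagement <- engagement_rate(trials)
    res$discernment_anova <- oneway_anova(disc$value,
                                          POOLING[disc$environment])
    write_table(trials, file.path(out_dir, "trials.csv"))
    write_table(disc, file.path(out_dir, "sharing_discernment.csv"))

    if (fit) {
      groups <- names(config$group_params)
      fits <- list()
      for (gi in seq_along(groups)) {
        g <- groups[gi]
        sub <- trials[POOLING[trials$environment] == g, ]
        cfg <- config$mcmc
        cfg$seed <- child_seed(seed, 50 + gi)
        fits[[g]] <- fit_hierarchical_ddm(sub, cfg)
        write_posterior_csv(fits[[g]],
                            file.path(out_dir, paste0("posterior_", g, ".csv")))
      }
      res$fits <- fits
      pairs <- utils::combn(groups, 2, simplify = FALSE)
      res$comparisons <- lapply(pairs, function(pr) {
        cmp <- compare_groups(fits[[pr[1]]], fits[[pr[2]]], "mu_v")
        c(list(a = pr[1], b = pr[2]), cmp)
      })
      cmp_df <- do.call(rbind, lapply(res$comparisons, function(cc)
        data.frame(a = cc$a, b = cc$b, parameter = cc$parameter,
                   mean_diff = cc$mean_diff, hdi_lower = cc$hdi$lower,
                   hdi_upper = cc$hdi$upper, credible = cc$credible)))
      write_table(cmp_df, file.path(out_dir, "comparisons.csv"))
    }
  }

  files <- sort(dir(out_dir))
  manifest <- list(
    package = "shareddm",
    template = config$template,
    seed = seed,
    child_seed_rule = "child = (master * 48271 + 7919 * counter) mod 2^31-1",
    mcmc = unclass(config$mcmc),
    files = lapply(stats::setNames(files, files), function(f)
      fnv1a_hash(readBin(file.path(out_dir, f), "raw",
                         file.size(file.path(out_dir, f))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
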