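# Shared fixtures: all data built in code at test time.

tiny_posts <- function(n_true = 5, n_false = 5, seed = 1) {
  generate_posts(n_true, n_false, seed = seed)
}

# hand-built reaction table: participant q1 likes 3 of 5 true and 1 of 5
# false posts, never presses anything else
handmade_reactions <- function(posts) {
  rx <- expand.grid(participant_id = "q1", post_id = posts$post_id,
                    stringsAsFactors = FALSE)
  rx$like <- rx$dislike <- rx$trust <- rx$distrust <- 0L
  true_ids <- posts$post_id[posts$veracity][1:3]
  false_ids <- posts$post_id[!posts$veracity][1]
  rx$like[rx$post_id %in% c(true_ids, false_ids)] <- 1L
  rx$skipped <- FALSE
  class(rx) <- c("reaction_table", "data.frame")
  rx
}

# minimal ddm_posterior stub with given pooled draws of one parameter
fake_posterior <- function(draws, parameter = "mu_v", n_chains = 2) {
  pars <- c("mu_v", "sigma_v", "mu_a", "sigma_a", "mu_z", "sigma_z",
            "mu_t0", "sigma_t0")
  n <- length(draws) / n_chains
  g <- array(0.5, c(n, n_chains, 8), dimnames = list(NULL, NULL, pars))
  g[, , parameter] <- matrix(draws, n, n_chains)
  structure(list(group = g, subject = NULL, subject_ids = "s1",
                 config = mcmc_config(20, 10, 1, n_chains)),
            class = "ddm_posterior")
}

# standard test cohort for sampler checks (kept small; acceptance tests run
# the full-size protocol)
small_cohort <- function(n_subj = 20, n_trials = 60, seed = 42,
                         mu = list(v = 0.3, a = 2.2, z = 0.5, t0 = 6.8)) {
  simulate_cohort_trials(list(mu = mu,
                              sigma = c(v = 0.2, a = 0.3, z = 0.15, t0 = 0.2)),
                         n_subj, n_trials, seed = seed)
}
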