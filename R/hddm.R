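#' MCMC configuration
#'
#' Sampling protocol for the hierarchical fit. The headline protocol is
#' 20,000 draws with 5,000 burn-in, thinning 5 and 5 chains; the short
#' protocol used for recovery and posterior-predictive fits is 2,000 draws
#' with 500 burn-in and no thinning.
#'
#' @param n_samples total MCMC iterations per chain.
#' @param burn_in iterations discarded, `< n_samples`.
#' @param thin retain every `thin`-th post-burn-in draw, >= 1.
#' @param n_chains number of chains, >= 1.
#' @param seed integer master seed; chain `c` runs under child seed
#'   [child_seed()]`(seed, c)`.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_samples = 2000L, burn_in = 500L, thin = 1L,
                        n_chains = 1L, seed = 1L) {
  if (burn_in >= n_samples)
    stop("mcmc_config: burn_in must be < n_samples", call. = FALSE)
  if (thin < 1 || n_chains < 1)
    stop("mcmc_config: thin and n_chains must be >= 1", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
mcmc_config_headline <- function(seed = 1L)
  mcmc_config(20000L, 5000L, 5L, 5L, seed)

GROUP_PARS <- c("mu_v", "sigma_v", "mu_a", "sigma_a",
                "mu_z", "sigma_z", "mu_t0", "sigma_t0")

#' Fit the hierarchical diffusion model
#'
#' Hierarchical Bayesian estimation of group- and subject-level diffusion
#' parameters from veracity-coded trials by adaptive Metropolis-within-Gibbs
#' MCMC (see the methods vignette for the model, priors and sampler). Group
#' distributions: normal for `v`, normal for `a` and `t0` respecting their
#' domains, logit-normal for `z`; hyperpriors are bounded uniforms assigning
#' equal probability to all admissible values. Trials whose `rt` falls at or
#' below a proposed subject `t0` contribute `-Inf` likelihood, which the
#' sampler treats as a rejection; no data are removed.
#'
#' @param trials data frame with columns `participant_id`, `rt` (model time
#'   axis) and either `response` (`"upper"`/`"lower"`) or `promoting`
#'   (logical). At least 2 subjects with at least 10 trials each.
#' @param config an [mcmc_config()].
#' @param init_jitter SD of the per-chain jitter applied to the shared
#'   starting values (overdispersed starts make Gelman-Rubin meaningful).
#' @param verbose print a one-line log per chain.
#' @return Object of class `ddm_posterior`: `group` is a draws x chains x 8
#'   array over mu_v, sigma_v, mu_a, sigma_a, mu_z, sigma_z, mu_t0, sigma_t0
#'   (z reported on the probability scale, its spread on the logit scale),
#'   `subject` a draws x 4 x subjects x chains array, plus `subject_ids`,
#'   `config`, `acceptance`, `data_hash`.
#' @export
fit_hierarchical_ddm <- function(trials, config = mcmc_config(),
                                 init_jitter = 0.05, verbose = FALSE) {
  stopifnot(inherits(config, "mcmc_config"))
  if (!is.null(trials$response)) {
    up <- trials$response == "upper"
  } else if (!is.null(trials$promoting)) {
    up <- as.logical(trials$promoting)
  } else stop("fit_hierarchical_ddm: trials need a response/promoting column",
              call. = FALSE)
  rt <- trials$rt
  if (any(!is.finite(rt)) || any(rt <= 0))
    stop("fit_hierarchical_ddm: rt must be finite and > 0 on the model axis",
         call. = FALSE)
  id <- factor(trials$participant_id)
  n_subj <- nlevels(id)
  if (n_subj < 2) stop("fit_hierarchical_ddm: need >= 2 subjects", call. = FALSE)
  if (min(table(id)) < 10)
    stop("fit_hierarchical_ddm: need >= 10 trials per subject", call. = FALSE)

  ord <- order(as.integer(id))
  rt_s <- as.numeric(rt[ord]); up_s <- as.integer(up[ord])
  id_s <- as.integer(id)[ord]
  offset <- as.integer(c(0, cumsum(tabulate(id_s, n_subj))))

  # moment-based starting values per subject
  init <- t(vapply(seq_len(n_subj), function(i) {
    r <- rt_s[(offset[i] + 1):offset[i + 1]]
    u <- up_s[(offset[i] + 1):offset[i + 1]]
    t0_0 <- max(min(r) - 0.3, 0)
    a_0 <- 2
    p <- min(max(mean(u), 0.1), 0.9)
    c(v = qlogis(p) / a_0, a = a_0, zl = 0, t0 = t0_0)
  }, numeric(4)))
  g_init <- c(mean(init[, 1]), max(sd(init[, 1]), 0.1),
              mean(init[, 2]), 0.3,
              0, 0.2,
              mean(init[, 4]), max(sd(init[, 4]), 0.1))

  n_keep <- (config$n_samples - config$burn_in) %/% config$thin
  group <- array(NA_real_, c(n_keep, config$n_chains, 8),
                 dimnames = list(NULL, NULL, GROUP_PARS))
  subject <- array(NA_real_, c(n_keep, 4, n_subj, config$n_chains),
                   dimnames = list(NULL, c("v", "a", "z", "t0"), NULL, NULL))
  acc <- numeric(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(child_seed(config$seed, ch))
    sj <- init + matrix(rnorm(length(init), 0, init_jitter), nrow(init))
    sj[, 2] <- pmax(sj[, 2], 0.2)          # a > 0
    sj[, 4] <- pmax(pmin(sj[, 4], init[, 4]), 0) # keep t0 below each min rt
    gi <- g_init * exp(rnorm(8, 0, init_jitter))
    gi[c(1, 5)] <- g_init[c(1, 5)] + rnorm(2, 0, init_jitter)
    fit <- hddm_mcmc_cpp(rt_s, up_s, offset, sj, gi,
                         config$n_samples, config$burn_in, config$thin, 50L)
    g <- fit$group
    g[, 5] <- plogis(g[, 5]) # eta_z -> mu_z on the probability scale
    group[, ch, ] <- g
    sdraws <- fit$subject                 # n_keep x 4 x n_subj
    sdraws[, 3, ] <- plogis(sdraws[, 3, ])
    subject[, , , ch] <- sdraws
    acc[ch] <- fit$acceptance
    if (verbose)
      message(sprintf("chain %d: seed %d, subject acceptance %.2f",
                      ch, child_seed(config$seed, ch), acc[ch]))
  }
  structure(list(group = group, subject = subject,
                 subject_ids = levels(id), config = config,
                 acceptance = acc,
                 data_hash = fnv1a_hash(list(rt_s, up_s, id_s))),
            class = "ddm_posterior")
}

#' @export
print.ddm_posterior <- function(x, ...) {
  cat(sprintf("ddm_posterior: %d subjects, %d chains x %d draws\n",
              length(x$subject_ids), dim(x$group)[2], dim(x$group)[1]))
  print(round(group_summary(x), 4))
  invisible(x)
}

#' Posterior summary of group-level parameters
#'
#' @param fit a `ddm_posterior`.
#' @return Matrix with posterior mean, sd and central 95% HDI per
#'   group-level parameter (draws pooled across chains).
#' @export
group_summary <- function(fit) {
  t(vapply(GROUP_PARS, function(p) {
    d <- pooled_draws(fit, p)
    h <- hdi(d, 0.95)
    c(mean = mean(d), sd = sd(d), hdi_lower = h$lower, hdi_upper = h$upper)
  }, numeric(4)))
}

# pooled post-burn-in draws of one group parameter, chains concatenated in
# index order
pooled_draws <- function(fit, parameter) {
  if (!parameter %in% GROUP_PARS)
    stop("unknown group parameter '", parameter, "'", call. = FALSE)
  as.numeric(fit$group[, , parameter])
}

# Polynomial rolling hash over the serialized object; cheap content
# fingerprint for manifests (not cryptographic).
fnv1a_hash <- function(x) {
  raw <- if (is.raw(x)) x else serialize(x, NULL, version = 2)
  b <- as.double(raw)
  h <- 5381
  # block-wise Horner scheme keeps the loop short for large objects
  block <- 4096L
  for (i in seq_len(ceiling(length(b) / block))) {
    idx <- ((i - 1L) * block + 1L):min(i * block, length(b))
    seg <- b[idx]
    pw <- 31^((length(seg) - 1):0 %% 8) # bounded powers, folded mod 2^31-1
    h <- (h * 131 + sum(seg * pw)) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
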