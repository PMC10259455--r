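#' Generate a set of news posts
#'
#' Creates a pool of simulated news posts with a veracity label, a topic tag
#' and zeroed feedback counters. The default study pool is 100 posts, half
#' true and half false, covering politics, science, health, environment and
#' society.
#'
#' @param n_true number of true posts (>= 0).
#' @param n_false number of false posts (>= 0).
#' @param topic_weights named non-negative weights over topics; normalized
#'   internally. Defaults to uniform over the six standard topics.
#' @param seed integer seed (topic assignment is the only randomness).
#' @return A data frame of class `post_set` with columns `post_id`,
#'   `veracity` (logical), `topic`, and per-button feedback counts
#'   `n_like`, `n_dislike`, `n_trust`, `n_distrust`.
#' @examples
#' posts <- generate_posts(50, 50, seed = 1)
#' table(posts$veracity)
#' @export
generate_posts <- function(n_true, n_false, topic_weights = NULL, seed = 1L) {
  if (n_true < 0 || n_false < 0)
    stop("generate_posts: post counts must be >= 0", call. = FALSE)
  topics <- c("politics", "science", "health", "environment", "society", "other")
  if (is.null(topic_weights))
    topic_weights <- stats::setNames(rep(1, length(topics)), topics)
  if (any(topic_weights < 0) || sum(topic_weights) <= 0)
    stop("generate_posts: topic_weights must be normalizable", call. = FALSE)
  n <- n_true + n_false
  if (n == 0) {
    out <- data.frame(post_id = character(), veracity = logical(),
                      topic = character(), n_like = integer(),
                      n_dislike = integer(), n_trust = integer(),
                      n_distrust = integer(), stringsAsFactors = FALSE)
    class(out) <- c("post_set", "data.frame")
    return(out)
  }
  set.seed(seed)
  out <- data.frame(
    post_id = sprintf("post%03d", seq_len(n)),
    veracity = rep(c(TRUE, FALSE), c(n_true, n_false)),
    topic = sample(names(topic_weights), n, replace = TRUE,
                   prob = topic_weights / sum(topic_weights)),
    n_like = 0L, n_dislike = 0L, n_trust = 0L, n_distrust = 0L,
    stringsAsFactors = FALSE)
  class(out) <- c("post_set", "data.frame")
  out
}

BUTTONS <- c("like", "dislike", "trust", "distrust")

#' Simulated participant cohorts
#'
#' Builds a cohort of participant profiles: an identifier, a political party,
#' a feedback environment, individual diffusion-model parameters (drawn from
#' the environment's group-level distribution) and a memory-check failure
#' count (Binomial over 5 checks). Party labels alternate so cohorts are
#' politically balanced, as in the studies being emulated.
#'
#' @param n cohort size.
#' @param environment feedback environment label for the whole cohort, one of
#'   `"baseline"`, `"like"`, `"dislike"`, `"trust"`, `"distrust"`,
#'   `"like_dislike"`, `"trust_distrust"`.
#' @param group_params optional list with elements `mu` ([ddm_params()]-like
#'   named list of group means) and `sigma` (named spreads `v`, `a`, `z`
#'   (logit scale), `t0`); when supplied, individual parameters are drawn
#'   `v_i ~ N(mu_v, sd_v)`, `a_i ~ N(mu_a, sd_a)` (truncated > 0),
#'   `logit(z_i) ~ N(logit(mu_z), sd_z)`, `t0_i ~ N(mu_t0, sd_t0)` (>= 0).
#' @param p_fail_check per-check failure probability; the default 0.17 makes
#'   roughly 3-4% of participants fail more than two of five checks.
#' @param seed integer seed.
#' @param id_prefix prefix for participant identifiers.
#' @return A data frame of class `participant_set` with columns
#'   `participant_id`, `party`, `environment`, `v`, `a`, `z`, `t0`,
#'   `memory_checks_failed`.
#' @export
make_participants <- function(n, environment = "baseline", group_params = NULL,
                              p_fail_check = 0.17, seed = 1L,
                              id_prefix = "p") {
  envs <- c("baseline", "like", "dislike", "trust", "distrust",
            "like_dislike", "trust_distrust")
  if (!environment %in% envs)
    stop("make_participants: unknown environment '", environment, "'",
         call. = FALSE)
  stopifnot(n >= 1)
  set.seed(seed)
  party <- rep(c("Democrat", "Republican"), length.out = n)
  if (is.null(group_params)) {
    v <- a <- z <- t0 <- rep(NA_real_, n)
  } else {
    mu <- group_params$mu; sg <- group_params$sigma
    v <- rnorm(n, mu$v, sg["v"])
    a <- pmax(rnorm(n, mu$a, sg["a"]), 0.1)
    z <- plogis(rnorm(n, qlogis(mu$z), sg["z"]))
    t0 <- pmax(rnorm(n, mu$t0, sg["t0"]), 0)
  }
  out <- data.frame(
    participant_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    party = party, environment = environment,
    v = v, a = a, z = z, t0 = t0,
    memory_checks_failed = rbinom(n, 5L, p_fail_check),
    stringsAsFactors = FALSE)
  class(out) <- c("participant_set", "data.frame")
  out
}

#' Apply the memory-check exclusion rule
#'
#' Retains participants who failed at most two of the five end-of-task
#' memory checks; those failing more than two are excluded. Order is
#' preserved.
#'
#' @param participants a `participant_set` data frame with a populated
#'   `memory_checks_failed` column.
#' @return The filtered participant set.
#' @export
exclude_failed_checks <- function(participants) {
  mcf <- participants$memory_checks_failed
  if (is.null(mcf) || any(!is.finite(mcf)) || any(mcf < 0) || any(mcf > 5))
    stop("exclude_failed_checks: memory_checks_failed must be in [0, 5]",
         call. = FALSE)
  out <- participants[mcf <= 2, , drop = FALSE]
  rownames(out) <- NULL
  out
}
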