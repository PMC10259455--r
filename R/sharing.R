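#' Simulate a sharing study from individual diffusion parameters
#'
#' For every (participant, post) pair a diffusion trial is drawn with that
#' participant's individual parameters ([simulate_trials()]). The diffusion
#' process is veracity-coded: the upper boundary is the veracity-promoting
#' response, so the observable choice is share when (upper and true) or
#' (lower and false), skip otherwise. In feedback environments the feedback
#' count for the environment's button(s) is attached on share trials
#' (the summed count when two buttons are shown); it is `NA` elsewhere --
#' feedback is display-only and does not enter the decision process, whose
#' environment dependence is entirely through the group-level parameters the
#' cohort was drawn from.
#'
#' @param posts a `post_set`, with feedback counts populated when the
#'   environment displays them (see [derive_feedback()]).
#' @param participants a `participant_set` whose `v`, `a`, `z`, `t0` columns
#'   are populated.
#' @param seed integer seed.
#' @param dt simulator step, passed to [simulate_trials()].
#' @return A data frame of class `sharing_table` with columns
#'   `participant_id`, `post_id`, `environment`, `veracity`, `choice`
#'   (`"share"`/`"skip"`), `response` (`"upper"`/`"lower"`), `rt` (model
#'   axis), `feedback_shown`.
#' @export
simulate_sharing_study <- function(posts, participants, seed = 1L, dt = 1e-3) {
  need <- c("v", "a", "z", "t0")
  if (any(!need %in% names(participants)) ||
      any(!is.finite(as.matrix(participants[need]))))
    stop("simulate_sharing_study: participants need individual v, a, z, t0",
         call. = FALSE)
  set.seed(seed)
  n_s <- nrow(posts)
  env_buttons <- list(baseline = character(), like = "like",
                      dislike = "dislike", trust = "trust",
                      distrust = "distrust",
                      like_dislike = c("like", "dislike"),
                      trust_distrust = c("trust", "distrust"))
  rows <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    sim <- simulate_trials(ddm_params(p$v, p$a, p$z, p$t0), n_s, dt)
    upper <- sim$boundary == "upper"
    share <- upper == posts$veracity
    env <- p$environment
    fb <- rep(NA_integer_, n_s)
    btns <- env_buttons[[env]]
    if (length(btns) > 0) {
      shown <- rowSums(as.matrix(posts[paste0("n_", btns)]))
      fb[share] <- as.integer(shown[share])
    }
    rows[[i]] <- data.frame(participant_id = p$participant_id,
                            post_id = posts$post_id,
                            environment = env,
                            veracity = posts$veracity,
                            choice = ifelse(share, "share", "skip"),
                            response = sim$boundary,
                            rt = sim$rt,
                            feedback_shown = fb,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sharing_table", "data.frame")
  out
}

#' Simulate post-hoc belief-accuracy ratings
#'
#' Each rating is a clipped mixture of a veracity signal (100 for true
#' posts, 0 for false) and an uninformative midpoint, plus Gaussian noise:
#' `rating = clip(w * signal + (1 - w) * 50 + noise, 0, 100)`. Mean belief
#' error decreases in the accuracy weight `w`; `w = 0` gives noise around
#' 50 (expected mean error 50), `w = 1` with vanishing noise gives perfect
#' knowledge.
#'
#' @param posts a `post_set`.
#' @param participants a `participant_set`.
#' @param accuracy_weight mixing weight in `[0, 1]`.
#' @param noise_sd rating noise standard deviation, > 0.
#' @param seed integer seed.
#' @return A data frame of class `rating_table` with columns
#'   `participant_id`, `post_id`, `rating` in `[0, 100]`.
#' @export
simulate_belief_ratings <- function(posts, participants, accuracy_weight = 0.1,
                                    noise_sd = 25, seed = 1L) {
  if (accuracy_weight < 0 || accuracy_weight > 1)
    stop("simulate_belief_ratings: accuracy_weight must be in [0, 1]",
         call. = FALSE)
  if (noise_sd <= 0)
    stop("simulate_belief_ratings: noise_sd must be > 0", call. = FALSE)
  set.seed(seed)
  grid <- expand.grid(pi = seq_len(nrow(participants)),
                      si = seq_len(nrow(posts)))
  signal <- ifelse(posts$veracity[grid$si], 100, 0)
  rating <- accuracy_weight * signal + (1 - accuracy_weight) * 50 +
    rnorm(nrow(grid), 0, noise_sd)
  out <- data.frame(participant_id = participants$participant_id[grid$pi],
                    post_id = posts$post_id[grid$si],
                    rating = pmin(pmax(rating, 0), 100),
                    stringsAsFactors = FALSE)
  class(out) <- c("rating_table", "data.frame")
  out
}
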