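#' Reaction profile for the reaction-study generator
#'
#' Describes how a cohort uses the four reaction buttons. A trial first draws
#' a skip (which excludes all buttons); otherwise each button is selected
#' independently with its veracity-conditional probability (multi-select is
#' allowed, matching the task where any number of buttons could be pressed).
#'
#' Optional structure beyond the marginals:
#' * `party_mult` scales each party's true/false probability gap around its
#'   midpoint (1 = symmetric parties, the default);
#' * `partisan_fraction`/`partisan_shift` make a random subset of posts
#'   partisan: for those posts a post-specific alignment of `partisan_shift`
#'   logit units is added for one party and subtracted for the other
#'   (positive buttons shifted up when aligned, negative buttons down).
#'
#' @param p_true,p_false named probabilities (like, dislike, trust, distrust)
#'   of selecting each button given a non-skipped true/false post.
#' @param skip probability of skipping, length-2 named vector
#'   (`true`, `false`) or a scalar used for both.
#' @param party_mult named multipliers (`Democrat`, `Republican`) on the
#'   true/false probability gap.
#' @param partisan_fraction fraction of posts given a partisan alignment.
#' @param partisan_shift logit-scale magnitude of the alignment.
#' @return An object of class `reaction_profile`.
#' @seealso [default_reaction_profile()], [calibrate_reaction_profile()]
#' @export
reaction_profile <- function(p_true, p_false, skip = 0.2,
                             party_mult = c(Democrat = 1, Republican = 1),
                             partisan_fraction = 0, partisan_shift = 0) {
  p_true <- p_true[BUTTONS]; p_false <- p_false[BUTTONS]
  if (length(skip) == 1) skip <- c(true = unname(skip), false = unname(skip))
  probs <- c(p_true, p_false, skip)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("reaction_profile: probabilities must be in [0, 1]", call. = FALSE)
  if (partisan_fraction < 0 || partisan_fraction > 1)
    stop("reaction_profile: partisan_fraction must be in [0, 1]", call. = FALSE)
  structure(list(p_true = p_true, p_false = p_false,
                 skip = skip[c("true", "false")],
                 party_mult = party_mult,
                 partisan_fraction = partisan_fraction,
                 partisan_shift = partisan_shift),
            class = "reaction_profile")
}

#' Closed-form calibration of a reaction profile
#'
#' Builds the profile whose expected per-button usage rates and discernment
#' scores equal the supplied targets, by probability differences alone (no
#' optimization). With overall usage `u_b` (proportion of all trials on
#' which button `b` is pressed) and discernment `d_b`, the marginal
#' veracity-conditional probabilities are `u_b + d_b/2` on the favoured
#' veracity and `u_b - d_b/2` on the other (favoured = true for the positive
#' buttons like/trust, false for the negative buttons dislike/distrust);
#' division by `1 - skip` converts marginals to skip-gated conditionals.
#'
#' @param usage named per-button usage rates (proportions of all trials).
#' @param discernment named per-button discernment targets.
#' @param skip skip probability (scalar or `true`/`false` pair).
#' @param ... passed to [reaction_profile()].
#' @return A `reaction_profile`.
#' @export
calibrate_reaction_profile <- function(usage, discernment, skip = 0.2, ...) {
  usage <- usage[BUTTONS]; discernment <- discernment[BUTTONS]
  sgn <- c(like = 1, dislike = -1, trust = 1, distrust = -1)
  m_true <- usage + sgn * discernment / 2
  m_false <- usage - sgn * discernment / 2
  s <- if (length(skip) == 1) rep(skip, 2) else skip[c("true", "false")]
  reaction_profile(p_true = m_true / (1 - s[[1]]),
                   p_false = m_false / (1 - s[[2]]), skip = skip, ...)
}

#' Default calibrated reaction profile
#'
#' The package's stated-world calibration: expected usage rates of
#' like/dislike/trust/distrust are 18.604%, 23.745%, 28.057%, 34.085% of all
#' trials, expected discernment scores 0.06, 0.034, 0.099, 0.156, with a 20%
#' skip rate. These are the group-level reaction statistics of the
#' 106-participant reaction study the generator emulates.
#'
#' @param ... overrides passed to [calibrate_reaction_profile()].
#' @return A `reaction_profile`.
#' @export
default_reaction_profile <- function(...) {
  calibrate_reaction_profile(
    usage = c(like = 0.18604, dislike = 0.23745,
              trust = 0.28057, distrust = 0.34085),
    discernment = c(like = 0.06, dislike = 0.034,
                    trust = 0.099, distrust = 0.156),
    skip = 0.2, ...)
}

#' Simulate a reaction study
#'
#' Generates one multi-select reaction row per (participant, post) pair under
#' a [reaction_profile()]: a skip gate first, then independent Bernoulli
#' draws per button with probabilities conditioned on post veracity (and,
#' optionally, party and per-post partisan alignment).
#'
#' @param posts a `post_set` from [generate_posts()].
#' @param participants a `participant_set` with party labels.
#' @param profile a `reaction_profile`.
#' @param seed integer seed.
#' @return A data frame of class `reaction_table` with columns
#'   `participant_id`, `post_id`, `like`, `dislike`, `trust`, `distrust`
#'   (0/1) and `skipped` (logical).
#' @export
simulate_reaction_study <- function(posts, participants,
                                    profile = default_reaction_profile(),
                                    seed = 1L) {
  stopifnot(inherits(profile, "reaction_profile"))
  if (is.null(participants$party) || any(is.na(participants$party)))
    stop("simulate_reaction_study: participants need party labels", call. = FALSE)
  set.seed(seed)
  n_p <- nrow(participants); n_s <- nrow(posts)
  # per-post partisan alignment sign: 0 for non-partisan posts
  align <- numeric(n_s)
  if (profile$partisan_fraction > 0 && profile$partisan_shift != 0) {
    partisan <- runif(n_s) < profile$partisan_fraction
    align[partisan] <- sample(c(-1, 1), sum(partisan), replace = TRUE) *
      profile$partisan_shift
  }
  grid <- expand.grid(pi = seq_len(n_p), si = seq_len(n_s))
  veracity <- posts$veracity[grid$si]
  party <- participants$party[grid$pi]
  party_sign <- ifelse(party == "Democrat", 1, -1)
  mult <- profile$party_mult[party]
  skipped <- runif(nrow(grid)) <
    ifelse(veracity, profile$skip[["true"]], profile$skip[["false"]])
  out <- data.frame(participant_id = participants$participant_id[grid$pi],
                    post_id = posts$post_id[grid$si],
                    stringsAsFactors = FALSE)
  sgn <- c(like = 1, dislike = -1, trust = 1, distrust = -1)
  for (b in BUTTONS) {
    pT <- profile$p_true[[b]]; pF <- profile$p_false[[b]]
    pbar <- (pT + pF) / 2
    p <- ifelse(veracity, pbar + mult * (pT - pbar), pbar + mult * (pF - pbar))
    shift <- align[grid$si] * party_sign * sgn[[b]]
    nz <- shift != 0 & p > 0 & p < 1
    p[nz] <- plogis(qlogis(p[nz]) + shift[nz])
    p <- pmin(pmax(p, 0), 1)
    out[[b]] <- as.integer(!skipped & runif(nrow(grid)) < p)
  }
  out$skipped <- skipped
  class(out) <- c("reaction_table", "data.frame")
  out
}

#' Aggregate reactions into per-post feedback counts
#'
#' Sets each post's per-button feedback count to the number of participants
#' who selected that button for the post, emulating the design in which the
#' feedback later shown to sharers was taken from an earlier reaction study
#' rather than collected live.
#'
#' @param reactions a `reaction_table`.
#' @param posts a `post_set`; every `post_id` in `reactions` must be present.
#' @return The `post_set` with `n_like`, `n_dislike`, `n_trust`,
#'   `n_distrust` filled in.
#' @export
derive_feedback <- function(reactions, posts) {
  if (!all(reactions$post_id %in% posts$post_id))
    stop("derive_feedback: reaction table references unknown post_id",
         call. = FALSE)
  for (b in BUTTONS) {
    counts <- tapply(reactions[[b]], reactions$post_id, sum)
    col <- paste0("n_", b)
    posts[[col]] <- 0L
    idx <- match(names(counts), posts$post_id)
    posts[[col]][idx] <- as.integer(counts)
  }
  posts
}
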