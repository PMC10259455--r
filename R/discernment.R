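#' Per-participant reaction discernment
#'
#' Difference of veracity-conditional selection proportions for one reaction
#' button, signed so that higher always means more truth-aligned: for the
#' positive buttons (like, trust) `Prop(button | true) - Prop(button |
#' false)`, for the negative buttons (dislike, distrust) the reverse.
#' Denominators are the numbers of true and of false posts *seen* (skipped
#' trials count in the denominator). A participant who saw no true or no
#' false posts gets `NA`.
#'
#' @param reactions a `reaction_table`.
#' @param posts a `post_set` supplying veracity labels.
#' @param button one of `"like"`, `"dislike"`, `"trust"`, `"distrust"`.
#' @return Data frame with `participant_id`, `context`, `value` in `[-1, 1]`.
#' @export
reaction_discernment <- function(reactions, posts, button) {
  if (!button %in% BUTTONS)
    stop("reaction_discernment: unknown button '", button, "'", call. = FALSE)
  ver <- posts$veracity[match(reactions$post_id, posts$post_id)]
  if (any(is.na(ver)))
    stop("reaction_discernment: reactions reference unknown posts", call. = FALSE)
  sel <- reactions[[button]]
  ids <- unique(reactions$participant_id)
  p_true <- tapply(sel[ver], reactions$participant_id[ver], mean)[ids]
  p_false <- tapply(sel[!ver], reactions$participant_id[!ver], mean)[ids]
  sgn <- if (button %in% c("like", "trust")) 1 else -1
  data.frame(participant_id = ids, context = button,
             value = as.numeric(sgn * (p_true - p_false)),
             stringsAsFactors = FALSE)
}

#' Per-participant sharing discernment
#'
#' Proportion of true posts shared minus proportion of false posts shared.
#'
#' @param trials a `sharing_table` with `veracity` and `choice` columns.
#' @return Data frame with `participant_id`, `context = "sharing"`, `value`.
#' @export
sharing_discernment <- function(trials) {
  share <- trials$choice == "share"
  ids <- unique(trials$participant_id)
  p_true <- tapply(share[trials$veracity],
                   trials$participant_id[trials$veracity], mean)[ids]
  p_false <- tapply(share[!trials$veracity],
                    trials$participant_id[!trials$veracity], mean)[ids]
  data.frame(participant_id = ids, context = "sharing",
             value = as.numeric(p_true - p_false), stringsAsFactors = FALSE)
}

#' Per-participant veracity-coded discernment
#'
#' Proportion of veracity-promoting responses (true shared or false skipped)
#' minus proportion of veracity-obstructing responses. Because the two
#' proportions sum to one this is identically `2 * Prop(promoting) - 1`.
#'
#' @param trials a `sharing_table`; the promoting/obstructing coding is read
#'   from the `response` column (`"upper"` = promoting) when present,
#'   otherwise derived from `choice` and `veracity`.
#' @return Data frame with `participant_id`, `context = "veracity_coded"`,
#'   `value`.
#' @export
veracity_coded_discernment <- function(trials) {
  promoting <- if (!is.null(trials$response)) trials$response == "upper"
  else (trials$choice == "share") == trials$veracity
  p <- tapply(promoting, trials$participant_id, mean)
  data.frame(participant_id = names(p), context = "veracity_coded",
             value = as.numeric(2 * p - 1), stringsAsFactors = FALSE)
}

#' Per-participant belief error
#'
#' Error of an accuracy rating against the post's label: for false posts the
#' error is the rating itself, for true posts it is 100 minus the rating.
#' Returns each participant's mean error on the 0-100 scale.
#'
#' @param ratings a `rating_table`.
#' @param posts a `post_set`.
#' @return Data frame with `participant_id`, `mean_error`.
#' @export
belief_error <- function(ratings, posts) {
  if (any(!is.finite(ratings$rating)) || any(ratings$rating < 0) ||
      any(ratings$rating > 100))
    stop("belief_error: ratings must lie in [0, 100]", call. = FALSE)
  ver <- posts$veracity[match(ratings$post_id, posts$post_id)]
  if (any(is.na(ver)))
    stop("belief_error: ratings reference unknown posts", call. = FALSE)
  err <- ifelse(ver, 100 - ratings$rating, ratings$rating)
  m <- tapply(err, ratings$participant_id, mean)
  data.frame(participant_id = names(m), mean_error = as.numeric(m),
             stringsAsFactors = FALSE)
}

#' Per-participant engagement rates
#'
#' For a sharing table: percentage of trials on which the participant
#' shared. For a reaction table: percentage use of each reaction button out
#' of all trials (plus the skip percentage).
#'
#' @param x a `sharing_table` or `reaction_table`.
#' @return Data frame with `participant_id` and percentage column(s).
#' @export
engagement_rate <- function(x) {
  if (nrow(x) == 0)
    stop("engagement_rate: empty input", call. = FALSE)
  if (inherits(x, "sharing_table") || !is.null(x$choice)) {
    r <- tapply(x$choice == "share", x$participant_id, mean)
    return(data.frame(participant_id = names(r),
                      share_pct = as.numeric(100 * r),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(participant_id = names(tapply(x$like, x$participant_id, mean)),
                    stringsAsFactors = FALSE)
  for (b in BUTTONS)
    out[[paste0(b, "_pct")]] <-
      as.numeric(100 * tapply(x[[b]], x$participant_id, mean)[out$participant_id])
  out$skip_pct <-
    as.numeric(100 * tapply(x$skipped, x$participant_id, mean)[out$participant_id])
  out
}

#' Select posts reacted to similarly across parties
#'
#' Reproduces the non-partisan stimulus selection: per post, participants'
#' trust selections (0/1) are tabulated against party and tested with an
#' uncorrected 2x2 Pearson chi-square; posts whose p-value is at least
#' `alpha` (no detectable partisan difference in trust use) are retained.
#' Degenerate tables (a button never or always used) have statistic 0 and
#' are retained.
#'
#' @param reactions a `reaction_table`.
#' @param participants a `participant_set` supplying party labels; both
#'   parties must be represented.
#' @param alpha significance level, default 0.05.
#' @param posts optional `post_set` to subset (otherwise post ids returned).
#' @return The retained subset of `posts` (or a vector of post ids).
#' @export
select_nonpartisan_posts <- function(reactions, participants, alpha = 0.05,
                                     posts = NULL) {
  party <- participants$party[match(reactions$participant_id,
                                    participants$participant_id)]
  keep_party <- party %in% c("Democrat", "Republican")
  if (length(unique(party[keep_party])) < 2)
    stop("select_nonpartisan_posts: both parties must be present", call. = FALSE)
  rx <- reactions[keep_party, ]; party <- party[keep_party]
  pvals <- vapply(split(seq_len(nrow(rx)), rx$post_id), function(idx) {
    tab <- table(factor(party[idx], c("Democrat", "Republican")),
                 factor(rx$trust[idx], c(0, 1)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1.0)
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
  keep_ids <- names(pvals)[pvals >= alpha]
  if (is.null(posts)) return(keep_ids)
  out <- posts[posts$post_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
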