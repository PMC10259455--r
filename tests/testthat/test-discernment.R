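test_that("reaction discernment follows the signed proportion-difference formula", {
  posts <- tiny_posts()
  rx <- handmade_reactions(posts) # likes 3/5 true, 1/5 false
  expect_equal(reaction_discernment(rx, posts, "like")$value, 0.6 - 0.2)
  # negative button with equal proportions on both veracities scores zero
  rx$distrust[match(c(posts$post_id[posts$veracity][1:2],
                      posts$post_id[!posts$veracity][1:2]), rx$post_id)] <- 1L
  expect_equal(reaction_discernment(rx, posts, "distrust")$value, 0)
  expect_error(reaction_discernment(rx, posts, "share"), "unknown button")
})

test_that("reaction discernment negates under veracity relabelling", {
  posts <- tiny_posts(6, 4)
  parts <- make_participants(15, seed = 31)
  rx <- simulate_reaction_study(posts, parts, seed = 32)
  flipped <- posts; flipped$veracity <- !flipped$veracity
  for (b in c("like", "distrust")) {
    d1 <- reaction_discernment(rx, posts, b)$value
    d2 <- reaction_discernment(rx, flipped, b)$value
    expect_equal(d1, -d2)
    expect_true(all(abs(d1) <= 1, na.rm = TRUE))
  }
})

test_that("participants without both veracities are flagged missing", {
  posts <- tiny_posts(3, 0)
  rx <- handmade_reactions(tiny_posts())[1:3, ]
  rx$post_id <- posts$post_id
  expect_true(is.na(reaction_discernment(rx, posts, "like")$value))
})

test_that("sharing discernment spans the trivial anchor cases", {
  tab <- data.frame(participant_id = "s", veracity = rep(c(TRUE, FALSE), 5),
                    choice = "share", stringsAsFactors = FALSE)
  expect_equal(sharing_discernment(tab)$value, 0) # shares everything
  tab$choice <- ifelse(tab$veracity, "share", "skip")
  expect_equal(sharing_discernment(tab)$value, 1) # perfect discernment
})

test_that("veracity-coded discernment equals 2 * Prop(promoting) - 1 exactly", {
  set.seed(33)
  tab <- data.frame(participant_id = rep(c("a", "b"), each = 50),
                    veracity = sample(c(TRUE, FALSE), 100, TRUE),
                    choice = sample(c("share", "skip"), 100, TRUE),
                    stringsAsFactors = FALSE)
  d <- veracity_coded_discernment(tab)
  prop <- tapply((tab$choice == "share") == tab$veracity, tab$participant_id,
                 mean)
  expect_identical(d$value, as.numeric(2 * prop[d$participant_id] - 1))
  tab$choice <- ifelse(tab$veracity, "share", "skip")
  expect_true(all(veracity_coded_discernment(tab)$value == 1))
})

test_that("belief error implements the rating transformation", {
  posts <- tiny_posts(1, 1)
  r <- data.frame(participant_id = "p", post_id = posts$post_id,
                  rating = c(100, 100))
  # true post rated 100 -> error 0; false post rated 100 -> error 100
  expect_equal(belief_error(r, posts)$mean_error, 50)
  r$rating <- c(100, 0)
  expect_equal(belief_error(r, posts)$mean_error, 0)
  r$rating <- c(50, 50)
  expect_equal(belief_error(r, posts)$mean_error, 50)
  r$rating <- c(101, 0)
  expect_error(belief_error(r, posts), "\\[0, 100\\]")
})

test_that("engagement rates are percentages of all trials", {
  tab <- data.frame(participant_id = "e",
                    choice = rep(c("share", "skip"), c(27, 73)))
  class(tab) <- c("sharing_table", "data.frame")
  expect_equal(engagement_rate(tab)$share_pct, 27)
  tab$choice <- "skip"
  expect_equal(engagement_rate(tab)$share_pct, 0)
  expect_error(engagement_rate(tab[0, ]), "empty")
})

test_that("non-partisan post selection applies per-post chi-square", {
  posts <- tiny_posts(2, 2)
  # 50 per party; post 1 trusted 40/50 D vs 2/50 R, post 2 identical use
  parts <- make_participants(100, seed = 41)
  parts$party <- rep(c("Democrat", "Republican"), each = 50)
  rx <- expand.grid(participant_id = parts$participant_id,
                    post_id = posts$post_id, stringsAsFactors = FALSE)
  rx$like <- rx$dislike <- rx$distrust <- 0L
  rx$trust <- 0L
  dems <- parts$participant_id[parts$party == "Democrat"]
  reps <- parts$participant_id[parts$party == "Republican"]
  p1 <- rx$post_id == posts$post_id[1]
  rx$trust[p1 & rx$participant_id %in% dems[1:40]] <- 1L
  rx$trust[p1 & rx$participant_id %in% reps[1:2]] <- 1L
  p2 <- rx$post_id == posts$post_id[2]
  rx$trust[p2 & rx$participant_id %in% c(dems[1:10], reps[1:10])] <- 1L
  rx$skipped <- FALSE
  kept <- select_nonpartisan_posts(rx, parts, alpha = 0.05)
  expect_false(posts$post_id[1] %in% kept) # partisan post excluded
  expect_true(posts$post_id[2] %in% kept)  # balanced post retained
  # alpha -> 0 retains everything
  expect_setequal(select_nonpartisan_posts(rx, parts, alpha = 0), posts$post_id)
  parts$party <- "Democrat"
  expect_error(select_nonpartisan_posts(rx, parts), "both parties")
})

test_that("partisan-mixture calibration retains roughly 40 of 100 posts", {
  posts <- generate_posts(50, 50, seed = 51)
  parts <- make_participants(106, seed = 52)
  prof <- default_reaction_profile(partisan_fraction = 0.6, partisan_shift = 2)
  rx <- simulate_reaction_study(posts, parts, prof, seed = 53)
  kept <- select_nonpartisan_posts(rx, parts, alpha = 0.05, posts = posts)
  expect_gt(nrow(kept), 25)
  expect_lt(nrow(kept), 55)
})

test_that("one-sample t matches the hand formula and flags zero variance", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  res <- one_sample_t(x)
  # manual: mean .25, sd sqrt(1/60), t = .25 / (sd/2)
  expect_equal(res$statistic, 0.25 / (sqrt(1 / 60) / 2))
  expect_equal(res$df, 3)
  oracle <- stats::t.test(x)
  expect_equal(res$statistic, unname(oracle$statistic))
  expect_equal(res$p, oracle$p.value)
  flagged <- one_sample_t(rep(0.2, 5))
  expect_true(flagged$flagged)
  expect_error(one_sample_t(0.3), "at least 2")
})

test_that("one-way ANOVA matches the aov oracle", {
  set.seed(55)
  g <- rep(c("x", "y", "z"), each = 20)
  v <- rnorm(60) + (g == "z") * 0.8
  res <- oneway_anova(v, g)
  oracle <- summary(stats::aov(v ~ g))[[1]]
  expect_equal(res$statistic, oracle[["F value"]][1])
  expect_equal(res$p, oracle[["Pr(>F)"]][1])
  expect_equal(res$df1, 2); expect_equal(res$df2, 57)
  expect_error(oneway_anova(v, rep("x", 60)), "2 groups")
})

test_that("2x2 within-subject ANOVA matches the aov error-stratum oracle", {
  set.seed(56)
  n <- 16
  d <- expand.grid(subject = factor(1:n), f1 = c("lo", "hi"),
                   f2 = c("neg", "pos"))
  d$value <- rnorm(nrow(d)) + (d$f1 == "hi") * 0.5 +
    (d$f1 == "hi" & d$f2 == "pos") * 0.3 + rep(rnorm(n), 4)
  res <- within_anova_2x2(d$value, d$subject, d$f1, d$f2)
  oracle <- summary(stats::aov(value ~ f1 * f2 + Error(subject / (f1 * f2)),
                               data = d))
  getF <- function(stratum) {
    tab <- oracle[[stratum]][[1]]
    tab[["F value"]][1]
  }
  expect_equal(res$f1$statistic, getF("Error: subject:f1"))
  expect_equal(res$f2$statistic, getF("Error: subject:f2"))
  expect_equal(res$interaction$statistic, getF("Error: subject:f1:f2"))
  expect_error(within_anova_2x2(d$value[-1], d$subject[-1], d$f1[-1],
                                d$f2[-1]), "one observation")
})

test_that("group_tests dispatches designs", {
  scores <- data.frame(value = rnorm(30, 0.1, 0.05),
                       group = rep(c("a", "b", "c"), 10))
  expect_equal(group_tests(scores, "one_sample")$design, "one_sample")
  expect_equal(group_tests(scores, "oneway")$design, "oneway")
})
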