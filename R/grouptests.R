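#' One-sample t-test against zero
#'
#' Hand-computed one-sample t (two-sided) with Cohen's d, used to test
#' whether a cohort's mean discernment differs from zero. Zero-variance
#' input is flagged (`flagged = TRUE`, statistics `NA`) rather than raised.
#'
#' @param x numeric vector, length >= 2.
#' @return List with `statistic`, `df`, `p`, `cohens_d`, `mean`, `flagged`.
#' @export
one_sample_t <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2)
    stop("one_sample_t: need at least 2 observations", call. = FALSE)
  s <- sd(x)
  if (s == 0)
    return(list(statistic = NA_real_, df = length(x) - 1, p = NA_real_,
                cohens_d = NA_real_, mean = mean(x), flagged = TRUE))
  tt <- mean(x) / (s / sqrt(length(x)))
  list(statistic = tt, df = length(x) - 1,
       p = 2 * pt(-abs(tt), length(x) - 1),
       cohens_d = mean(x) / s, mean = mean(x), flagged = FALSE)
}

#' One-way fixed-effects ANOVA from explicit sums of squares
#'
#' Between/within decomposition computed directly: `SS_b = sum n_g (m_g -
#' m)^2`, `SS_w = sum (x - m_g)^2`, `F = (SS_b / df_b) / (SS_w / df_w)`,
#' with partial eta^2 = `SS_b / (SS_b + SS_w)`.
#'
#' @param value numeric response.
#' @param group grouping factor (>= 2 levels).
#' @return List with `statistic`, `df1`, `df2`, `p`, `partial_eta2`,
#'   `group_means`.
#' @export
oneway_anova <- function(value, group) {
  keep <- is.finite(value)
  value <- value[keep]; group <- factor(group[keep])
  if (nlevels(group) < 2)
    stop("oneway_anova: need at least 2 groups", call. = FALSE)
  m <- mean(value)
  mg <- tapply(value, group, mean)
  ng <- tapply(value, group, length)
  ss_b <- sum(ng * (mg - m)^2)
  ss_w <- sum((value - mg[group])^2)
  df1 <- nlevels(group) - 1
  df2 <- length(value) - nlevels(group)
  f <- (ss_b / df1) / (ss_w / df2)
  list(statistic = f, df1 = df1, df2 = df2, p = pf(f, df1, df2, lower.tail = FALSE),
       partial_eta2 = ss_b / (ss_b + ss_w), group_means = mg)
}

#' Balanced 2x2 within-subject ANOVA
#'
#' Fixed-effects analysis of a balanced two-factor within-subject design
#' (one observation per subject per cell), computed from explicit sums of
#' squares with each effect tested against its own effect-by-subject error
#' stratum. This covers the reaction-type by valence design the reaction
#' study produces; unbalanced designs are out of scope.
#'
#' @param value numeric response.
#' @param subject subject identifier.
#' @param f1,f2 two-level within-subject factors.
#' @return List of per-effect results (`f1`, `f2`, `interaction`), each with
#'   `statistic`, `df1`, `df2`, `p`, `partial_eta2`.
#' @export
within_anova_2x2 <- function(value, subject, f1, f2) {
  subject <- factor(subject); f1 <- factor(f1); f2 <- factor(f2)
  if (nlevels(f1) != 2 || nlevels(f2) != 2)
    stop("within_anova_2x2: both factors must have exactly 2 levels", call. = FALSE)
  n <- nlevels(subject)
  if (length(value) != n * 4 || any(table(subject, f1, f2) != 1))
    stop("within_anova_2x2: need one observation per subject per cell", call. = FALSE)
  gm <- mean(value)
  m_s <- tapply(value, subject, mean)
  eff <- function(fac) tapply(value, fac, mean) - gm
  one <- function(fac_main, name) {
    a <- eff(fac_main)
    ss_eff <- 2 * n * sum(a^2)
    # effect-by-subject interaction error
    cell <- tapply(value, list(subject, fac_main), mean)
    resid <- cell - outer(m_s - gm, a, "+") - gm
    ss_err <- 2 * sum(resid^2)
    df1 <- 1; df2 <- n - 1
    f <- (ss_eff / df1) / (ss_err / df2)
    list(statistic = f, df1 = df1, df2 = df2,
         p = pf(f, df1, df2, lower.tail = FALSE),
         partial_eta2 = ss_eff / (ss_eff + ss_err))
  }
  inter <- {
    a <- eff(f1); b <- eff(f2)
    cellm <- tapply(value, list(f1, f2), mean)
    ab <- cellm - outer(a, b, "+") - gm
    ss_eff <- n * sum(ab^2)
    # interaction error = total SS minus every other stratum
    ss_tot <- sum((value - gm)^2)
    m_sf1 <- tapply(value, list(subject, f1), mean)
    m_sf2 <- tapply(value, list(subject, f2), mean)
    ss_sf1 <- 2 * sum((m_sf1 - outer(m_s - gm, a, "+") - gm)^2)
    ss_sf2 <- 2 * sum((m_sf2 - outer(m_s - gm, b, "+") - gm)^2)
    ss_s <- 4 * sum((m_s - gm)^2)
    ss_f1 <- 2 * n * sum(a^2); ss_f2 <- 2 * n * sum(b^2)
    ss_err <- ss_tot - ss_s - ss_f1 - ss_f2 - ss_eff - ss_sf1 - ss_sf2
    ss_err <- max(ss_err, 0)
    df1 <- 1; df2 <- n - 1
    f <- (ss_eff / df1) / (ss_err / df2)
    list(statistic = f, df1 = df1, df2 = df2,
         p = pf(f, df1, df2, lower.tail = FALSE),
         partial_eta2 = ss_eff / (ss_eff + ss_err))
  }
  list(f1 = one(f1), f2 = one(f2), interaction = inter)
}

#' Group tests over discernment scores
#'
#' Dispatcher for the standard tests used to compare feedback environments:
#' `design = "one_sample"` runs a one-sample t against zero on `value`;
#' `design = "oneway"` runs a one-way between-subject ANOVA of `value` on
#' `group`; `design = "within2x2"` runs the balanced within-subject two-way
#' ANOVA (requires `subject`, `f1`, `f2`).
#'
#' @param scores data frame with a `value` column (e.g. from
#'   [sharing_discernment()]) plus design columns.
#' @param design one of `"one_sample"`, `"oneway"`, `"within2x2"`.
#' @param group,subject,f1,f2 column names in `scores` for the chosen design.
#' @return The corresponding test summary list, plus `design`.
#' @export
group_tests <- function(scores, design = c("one_sample", "oneway", "within2x2"),
                        group = "group", subject = "participant_id",
                        f1 = "f1", f2 = "f2") {
  design <- match.arg(design)
  out <- switch(design,
    one_sample = one_sample_t(scores$value),
    oneway = oneway_anova(scores$value, scores[[group]]),
    within2x2 = within_anova_2x2(scores$value, scores[[subject]],
                                 scores[[f1]], scores[[f2]]))
  out$design <- design
  out
}
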