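#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor computed from between- and within-chain
#' variances: with `W` the mean within-chain variance and `B_n` the variance
#' of the chain means, `R-hat = sqrt((W + B_n) / W)`. This form is exactly 1
#' for identical chains and never below 1; it differs from the classical
#' pooled estimator by `W/n`, negligible at the chain lengths used here.
#' Values near 1 (conventionally < 1.1) indicate convergence.
#'
#' @param fit a `ddm_posterior` (all group-level parameters are monitored)
#'   or a draws x chains matrix.
#' @return Named vector of R-hat values.
#' @export
gelman_rubin <- function(fit) {
  if (inherits(fit, "ddm_posterior")) {
    if (dim(fit$group)[2] < 2)
      stop("gelman_rubin: need at least 2 chains", call. = FALSE)
    return(vapply(GROUP_PARS, function(p) gelman_rubin(fit$group[, , p]),
                  numeric(1)))
  }
  x <- as.matrix(fit)
  if (ncol(x) < 2) stop("gelman_rubin: need at least 2 chains", call. = FALSE)
  w <- mean(apply(x, 2, var))
  b_n <- var(colMeans(x))
  if (w == 0) return(if (b_n == 0) 1.0 else Inf)
  sqrt((w + b_n) / w)
}

#' Highest-density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the sorted
#' draws (ties broken toward the earliest such window).
#'
#' @param draws numeric vector, >= 10 draws.
#' @param mass interval mass in (0, 1), default 0.95.
#' @return List of class `hdinterval` with `lower`, `upper`, `mass`.
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0) stop("hdi: empty input", call. = FALSE)
  if (length(draws) < 10) stop("hdi: need at least 10 draws", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("hdi: mass must be in (0, 1)", call. = FALSE)
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) k <- n
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  structure(list(lower = x[i], upper = x[i + k - 1], mass = mass),
            class = "hdinterval")
}

#' @export
print.hdinterval <- function(x, ...) {
  cat(sprintf("%.0f%% HDI [%.4g; %.4g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Compare a group-level parameter across two fitted environments
#'
#' Forms the posterior distribution of the difference `parameter_a -
#' parameter_b` by pairing pooled post-burn-in draws (chains concatenated in
#' index order, truncated to the shorter vector), and reports its HDI. The
#' difference is called credible when the HDI excludes zero.
#'
#' @param post_a,post_b `ddm_posterior` objects.
#' @param parameter a group-level parameter name (e.g. `"mu_v"`).
#' @param mass HDI mass, default 0.95.
#' @return List with `hdi` (an `hdinterval` of the difference), `credible`,
#'   `mean_diff`, `parameter`.
#' @export
compare_groups <- function(post_a, post_b, parameter = "mu_v", mass = 0.95) {
  da <- pooled_draws(post_a, parameter)
  db <- pooled_draws(post_b, parameter)
  n <- min(length(da), length(db))
  d <- da[seq_len(n)] - db[seq_len(n)]
  h <- hdi(d, mass)
  list(hdi = h, credible = (h$lower > 0 || h$upper < 0),
       mean_diff = mean(d), parameter = parameter)
}
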