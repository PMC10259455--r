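#' Four-parameter diffusion model parameters
#'
#' Bundles the four parameters of the Wiener diffusion model used throughout
#' the package: drift rate `v` (signed evidence per unit decision time toward
#' the veracity-promoting boundary), boundary separation `a` (> 0), relative
#' starting point `z` in (0, 1) (fraction of `a`), and non-decision time `t0`
#' (>= 0, on the same axis as response times). The model's time axis follows
#' the log-millisecond response-time convention, so `t0` values near 7
#' correspond to roughly a second of encoding/motor time. The diffusion
#' coefficient is fixed at 1.
#'
#' @param v drift rate (finite).
#' @param a boundary separation, > 0.
#' @param z relative starting point, in (0, 1).
#' @param t0 non-decision time, >= 0.
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(v = 0.216, a = 2.403, z = 0.48, t0 = 6.681)
#' @export
ddm_params <- function(v, a, z, t0) {
  vals <- c(v = v, a = a, z = z, t0 = t0)
  if (!all(is.finite(vals)))
    stop("ddm_params: all parameters must be finite", call. = FALSE)
  if (a <= 0) stop("ddm_params: boundary separation a must be > 0", call. = FALSE)
  if (z <= 0 || z >= 1) stop("ddm_params: starting point z must be in (0, 1)", call. = FALSE)
  if (t0 < 0) stop("ddm_params: non-decision time t0 must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("ddm_params: v = %.4g, a = %.4g, z = %.4g, t0 = %.4g\n",
              x$v, x$a, x$z, x$t0))
  invisible(x)
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  ddm_params(x[["v"]], x[["a"]], x[["z"]], x[["t0"]])
}

#' Defective first-passage-time density of the diffusion model
#'
#' Density of absorption at the named boundary at decision time `t_dec`
#' (decision time excludes `t0`). The two defective densities jointly
#' integrate to 1. Evaluation uses the standard dual small-time/large-time
#' series with an automatic switch to whichever expansion needs fewer terms
#' (truncation tolerance 1e-7).
#'
#' @param t_dec vector of decision times, > 0.
#' @param params a [ddm_params()] object (or named list with v, a, z, t0).
#' @param boundary `"upper"` (veracity-promoting) or `"lower"`.
#' @param log if `TRUE` return the log density.
#' @return Numeric vector of (log) densities.
#' @examples
#' p <- ddm_params(0.216, 2.403, 0.48, 6.681)
#' wfpt_density(c(0.5, 1, 2), p, "upper")
#' @export
wfpt_density <- function(t_dec, params, boundary = c("upper", "lower"),
                         log = FALSE) {
  boundary <- match.arg(boundary)
  params <- as_ddm_params(params)
  if (!all(is.finite(t_dec)) || any(t_dec <= 0))
    stop("wfpt_density: t_dec must be finite and > 0", call. = FALSE)
  wfpt_density_cpp(as.numeric(t_dec), params$v, params$a, params$z,
                   boundary == "upper", log)
}

#' Closed-form probability of absorption at the upper boundary
#'
#' For a diffusion with drift `v`, boundaries 0 and `a`, and start `z * a`,
#' the probability of absorbing at the upper (veracity-promoting) boundary
#' is the classical gambler's-ruin expression
#' `(1 - exp(-2 v z a)) / (1 - exp(-2 v a))`; it reduces to `z` exactly when
#' `v = 0` and is strictly increasing in `v`. Used as an analytic
#' cross-check on both the simulator and the density.
#'
#' @param params a [ddm_params()] object.
#' @return Probability in `[0, 1]`.
#' @examples
#' choice_probability(ddm_params(0, 2, 0.3, 0)) # 0.3
#' @export
choice_probability <- function(params) {
  params <- as_ddm_params(params)
  v <- params$v; a <- params$a; z <- params$z
  if (abs(v) < 1e-9) return(z)
  # P(upper) = (1 - exp(-2 v z a)) / (1 - exp(-2 v a)), stable via expm1
  expm1(-2 * v * z * a) / expm1(-2 * v * a)
}

#' Simulate diffusion-model trials
#'
#' Draws boundary/decision-time outcomes by Euler-Maruyama integration of the
#' diffusion path (step `dt` on the decision-time axis) with a
#' Brownian-bridge correction for between-step boundary crossings, which
#' removes the first-passage bias of the naive scheme. Uses R's RNG: seed
#' with [set.seed()].
#'
#' @param params a [ddm_params()] object.
#' @param n number of trials.
#' @param dt integration step, default `1e-3`.
#' @return A data frame with columns `boundary` (`"upper"`/`"lower"`),
#'   `decision_time` and `rt` (`decision_time + t0`).
#' @examples
#' set.seed(1)
#' simulate_trials(ddm_params(0.2, 2.4, 0.5, 6.7), n = 5)
#' @export
simulate_trials <- function(params, n = 1L, dt = 1e-3) {
  params <- as_ddm_params(params)
  stopifnot(n >= 0, dt > 0)
  if (n == 0)
    return(data.frame(boundary = character(), decision_time = numeric(),
                      rt = numeric()))
  sim <- rddm_cpp(as.integer(n), params$v, params$a, params$z, params$t0, dt)
  data.frame(boundary = ifelse(sim$upper == 1L, "upper", "lower"),
             decision_time = sim$rt - params$t0,
             rt = sim$rt)
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(params, dt = 1e-3) simulate_trials(params, 1L, dt)

#' Trial log-likelihood under the diffusion model
#'
#' Log of the defective first-passage density at the observed boundary,
#' evaluated at `rt - t0`. Response times at or below `t0` have zero density
#' and yield `-Inf` (returned, not raised: the hierarchical sampler treats
#' such proposals as rejections rather than deleting data).
#'
#' @param choice `"upper"`/`"lower"` vector (or logical, `TRUE` = upper).
#' @param rt response-time vector on the model's time axis.
#' @param params a [ddm_params()] object.
#' @return Vector of log densities (`-Inf` where `rt <= t0`).
#' @export
trial_loglik <- function(choice, rt, params) {
  params <- as_ddm_params(params)
  if (!all(is.finite(rt)))
    stop("trial_loglik: rt must be finite", call. = FALSE)
  if (is.logical(choice)) {
    up <- as.integer(choice)
  } else {
    if (!all(choice %in% c("upper", "lower")))
      stop("trial_loglik: choice must be 'upper' or 'lower'", call. = FALSE)
    up <- as.integer(choice == "upper")
  }
  if (length(up) != length(rt))
    stop("trial_loglik: choice and rt lengths differ", call. = FALSE)
  trial_loglik_cpp(as.numeric(rt), up, params$v, params$a, params$z, params$t0)
}

# Conditional CDF of decision time given absorption at `boundary`,
# as a vectorized function built by integrating the defective density on a
# fine grid. Used by the simulator-vs-density KS oracle.
wfpt_cdf_fun <- function(params, boundary = "upper", t_max = NULL,
                         n_grid = 4096L) {
  params <- as_ddm_params(params)
  p_bound <- if (boundary == "upper") choice_probability(params) else
    1 - choice_probability(params)
  if (is.null(t_max)) {
    # extend until the defective density has decayed to numerical zero
    t_max <- params$a^2 * 4
    while (wfpt_density(t_max, params, boundary) > 1e-12 && t_max < 1e4)
      t_max <- t_max * 2
  }
  grid <- seq(0, t_max, length.out = n_grid)
  dens <- c(0, wfpt_density(grid[-1], params, boundary))
  cdf <- cumsum((dens[-1] + dens[-n_grid]) / 2 * diff(grid))
  cdf <- c(0, cdf) / p_bound
  cdf <- pmin(cummax(cdf), 1)
  function(q) {
    out <- approx(grid, cdf, xout = q, yleft = 0, yright = 1)$y
    out
  }
}

#' Convert between millisecond and model-axis response times
#'
#' The model's time axis is log-milliseconds; these helpers convert raw
#' millisecond RTs to the model axis and back.
#'
#' @param rt_ms response times in milliseconds (> 0).
#' @param rt_log response times on the log-millisecond axis.
#' @return Numeric vector.
#' @export
rt_to_model_axis <- function(rt_ms) {
  if (any(rt_ms <= 0)) stop("rt_to_model_axis: rt_ms must be > 0", call. = FALSE)
  log(rt_ms)
}

#' @rdname rt_to_model_axis
#' @export
rt_from_model_axis <- function(rt_log) exp(rt_log)
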