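# Noise schedule for the variance-preserving diffusion process.
#
# The process is parameterized by gamma(t) = -log SNR(t), with
# SNR(t) = alpha_t^2 / sigma_t^2 and alpha_t^2 + sigma_t^2 = 1, so that
# alpha_t^2 = sigmoid(-gamma(t)) and sigma_t^2 = sigmoid(gamma(t)).
# All quantities are evaluated in log/sigmoid space; near t = 0 the noise
# variance is ~ exp(gamma_min) and naive 1 - alpha^2 arithmetic would lose
# every significant digit.

#' Construct a variance-preserving noise schedule
#'
#' The schedule is defined by `gamma(t) = -log SNR(t)`, a smooth, strictly
#' increasing function on `[0, 1]`. Signal and noise scales follow as
#' `alpha_t^2 = sigmoid(-gamma(t))` and `sigma_t^2 = sigmoid(gamma(t))`, which
#' enforces `alpha_t^2 + sigma_t^2 = 1` identically. The endpoints must give an
#' almost-clean latent at `t = 0` (`sigma_0^2 < 1e-4`) and an almost-pure-noise
#' latent at `t = 1` (`alpha_1^2 < 1e-2`), so that the terminal marginal can be
#' modeled as a standard (subspace) Gaussian.
#'
#' @param gamma_min Value of `gamma` at `t = 0` (log inverse SNR; dimensionless).
#' @param gamma_max Value of `gamma` at `t = 1`.
#' @param form Interpolation shape between the endpoints; only `"linear"` is
#'   implemented.
#' @return An object of class `noise_schedule`.
#' @examples
#' sch <- noise_schedule()
#' schedule_gamma(sch, 0.5)
#' schedule_alpha_sigma(sch, 0.5)
#' @export
noise_schedule <- function(gamma_min = -13.3, gamma_max = 5.0, form = "linear") {
  stopifnot(is.numeric(gamma_min), is.numeric(gamma_max), length(gamma_min) == 1L,
            length(gamma_max) == 1L)
  form <- match.arg(form, "linear")
  if (gamma_max <= gamma_min)
    stop("gamma_max must exceed gamma_min (gamma must be strictly increasing)")
  s0_sq <- stats::plogis(gamma_min)
  a1_sq <- stats::plogis(-gamma_max)
  if (s0_sq >= 1e-4)
    stop("endpoint contract violated: sigma_0^2 = sigmoid(gamma_min) must be < 1e-4")
  if (a1_sq >= 1e-2)
    stop("endpoint contract violated: alpha_1^2 = sigmoid(-gamma_max) must be < 1e-2")
  structure(list(gamma_min = gamma_min, gamma_max = gamma_max, form = form),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule form=%s gamma: [%g, %g]>\n", x$form,
              x$gamma_min, x$gamma_max))
  invisible(x)
}

check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0) || any(t > 1))
    stop("diffusion time t must lie in [0, 1]")
  t
}

#' Evaluate gamma(t) = -log SNR(t)
#'
#' @param schedule A [noise_schedule()].
#' @param t Diffusion time(s) in `[0, 1]`; vectorized.
#' @return `gamma(t)`, same length as `t`.
#' @export
schedule_gamma <- function(schedule, t) {
  check_time(t)
  schedule$gamma_min + (schedule$gamma_max - schedule$gamma_min) * t
}

#' Derivative of gamma with respect to t
#'
#' For the linear form this is the constant `gamma_max - gamma_min`; it is the
#' weight of the continuous-time diffusion loss.
#' @inheritParams schedule_gamma
#' @return `gamma'(t)`, same length as `t`.
#' @export
schedule_gamma_prime <- function(schedule, t) {
  check_time(t)
  rep_len(schedule$gamma_max - schedule$gamma_min, length(t))
}

#' Signal and noise scales at time t
#'
#' @inheritParams schedule_gamma
#' @return A list with vectors `alpha`, `sigma`, `alpha_sq`, `sigma_sq`
#'   satisfying `alpha^2 + sigma^2 = 1`.
#' @export
schedule_alpha_sigma <- function(schedule, t) {
  g <- schedule_gamma(schedule, t)
  a_sq <- stats::plogis(-g)
  s_sq <- stats::plogis(g)
  list(alpha = sqrt(a_sq), sigma = sqrt(s_sq), alpha_sq = a_sq, sigma_sq = s_sq)
}

#' Signal-to-noise ratio at time t
#'
#' `SNR(t) = alpha_t^2 / sigma_t^2 = exp(-gamma(t))`; strictly decreasing.
#' @inheritParams schedule_gamma
#' @return SNR values, same length as `t`.
#' @export
schedule_snr <- function(schedule, t) {
  exp(-schedule_gamma(schedule, t))
}

#' Transition parameters of the forward process from time s to t
#'
#' The forward process is Markov, with `q(z_t | z_s)` Gaussian with mean scale
#' `alpha_{t|s} = alpha_t / alpha_s` and variance
#' `sigma_{t|s}^2 = sigma_t^2 - alpha_{t|s}^2 sigma_s^2`. The variance is
#' computed as `sigma_t^2 * (-expm1(gamma(s) - gamma(t)))`, an algebraically
#' equal form that stays accurate when s and t are close.
#'
#' @param schedule A [noise_schedule()].
#' @param s,t Times with `0 <= s <= t <= 1`; vectorized in parallel.
#' @return A list with `alpha_ts` and `sigma2_ts` (both `>= 0`).
#' @export
schedule_transition <- function(schedule, s, t) {
  check_time(s); check_time(t)
  if (any(s > t)) stop("transition requires s <= t")
  gs <- schedule_gamma(schedule, s)
  gt <- schedule_gamma(schedule, t)
  as_ <- schedule_alpha_sigma(schedule, s)
  at_ <- schedule_alpha_sigma(schedule, t)
  alpha_ts <- at_$alpha / as_$alpha
  # sigma_t^2 - alpha_ts^2 sigma_s^2 = sigma_t^2 (1 - exp(gamma_s - gamma_t))
  sigma2_ts <- at_$sigma_sq * (-expm1(gs - gt))
  list(alpha_ts = alpha_ts, sigma2_ts = pmax(sigma2_ts, 0))
}

#' Posterior q(z_s | z_t, x) of the forward process
#'
#' By Bayes' rule the conditional of the earlier latent given the later latent
#' and the clean coordinates is Gaussian on the zero-centroid subspace with
#' mean `mu = (alpha_{t|s} sigma_s^2 / sigma_t^2) z_t +
#' (alpha_s sigma_{t|s}^2 / sigma_t^2) x` and scalar standard deviation
#' `sigma_{t->s} = sigma_{t|s} sigma_s / sigma_t`.
#'
#' @param schedule A [noise_schedule()].
#' @param z_t Latent coordinates, an `N x 3` matrix (zero centroid).
#' @param x Clean coordinates, same shape as `z_t`.
#' @param s,t Scalar times with `s < t`.
#' @return A list with `mu` (`N x 3`) and `sigma_post` (scalar).
#' @export
schedule_posterior <- function(schedule, z_t, x, s, t) {
  if (!identical(dim(z_t), dim(x)))
    stop("z_t and x must have the same shape")
  if (length(s) != 1L || length(t) != 1L || s >= t)
    stop("posterior requires scalar times with s < t")
  as_ <- schedule_alpha_sigma(schedule, s)
  at_ <- schedule_alpha_sigma(schedule, t)
  tr <- schedule_transition(schedule, s, t)
  w_z <- tr$alpha_ts * as_$sigma_sq / at_$sigma_sq
  w_x <- as_$alpha * tr$sigma2_ts / at_$sigma_sq
  mu <- w_z * z_t + w_x * x
  sigma_post <- sqrt(tr$sigma2_ts) * as_$sigma / at_$sigma
  list(mu = mu, sigma_post = sigma_post)
}
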