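#' Build a diffusion noise schedule
#'
#' The schedule is kept in the cumulative (DDIM) convention: `alpha_bar[t]`
#' is the fraction of signal variance retained at step t, strictly
#' decreasing in (0, 1). Per-step `beta` values are retained for the
#' stochastic ancestral sampler.
#'
#' @param T_steps number of diffusion steps (>= 2); default 1000.
#' @param kind `"linear_beta"` (betas linearly spaced, the standard DDPM
#'   default) or `"cosine"` (squared-cosine alpha-bar).
#' @param beta_min,beta_max linear-beta endpoints, `0 < beta_min < beta_max
#'   < 1`; defaults 1e-4 and 0.02.
#' @return object of class `noise_schedule` with fields `T`, `kind`, `beta`,
#'   `alpha_bar`.
#' @export
make_schedule <- function(T_steps = 1000L, kind = c("linear_beta", "cosine"),
                          beta_min = 1e-4, beta_max = 0.02) {
  kind <- match.arg(kind)
  T_steps <- as.integer(T_steps)
  if (T_steps < 2) stop("T_steps must be >= 2")
  if (kind == "linear_beta") {
    if (!(beta_min > 0 && beta_min < beta_max && beta_max < 1))
      stop("need 0 < beta_min < beta_max < 1")
    beta <- seq(beta_min, beta_max, length.out = T_steps)
    alpha_bar <- cumprod(1 - beta)
  } else {
    # squared-cosine cumulative schedule; betas derived and capped at 0.999
    s <- 0.008
    f <- function(t) cos((t / T_steps + s) / (1 + s) * pi / 2)^2
    ab <- f(seq_len(T_steps)) / f(0)
    beta <- pmin(1 - ab / c(1, ab[-T_steps]), 0.999)
    alpha_bar <- cumprod(1 - beta)
  }
  structure(list(T = T_steps, kind = kind, beta = beta,
                 alpha_bar = alpha_bar),
            class = "noise_schedule")
}

# alpha_bar with the t = 0 convention alpha_bar[0] = 1 (no noise)
.abar <- function(schedule, t) {
  if (any(t < 0 | t > schedule$T)) stop("t out of range [0, T]")
  ifelse(t == 0, 1, schedule$alpha_bar[pmax(t, 1)])
}

#' Forward diffusion: closed-form marginal sample
#'
#' `x_t = sqrt(abar_t) * x0 + sqrt(1 - abar_t) * eps`, applied row-wise with
#' each row's own timestep.
#'
#' @param x0 matrix (rows = samples) in \[-1, 1\].
#' @param t integer vector of timesteps in \[1, T\] (or 0 for "no noise"),
#'   one per row (recycled if length 1).
#' @param eps matrix of standard-normal noise, same shape as `x0`.
#' @param schedule a [make_schedule()] object.
#' @return matrix `x_t`, same shape as `x0`.
#' @export
q_sample <- function(x0, t, eps, schedule) {
  x0 <- as.matrix(x0); eps <- as.matrix(eps)
  stopifnot(all(dim(x0) == dim(eps)))
  t <- rep_len(as.integer(t), nrow(x0))
  ab <- .abar(schedule, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Predict x0 from a noisy sample and predicted noise
#'
#' Algebraic inverse of the forward marginal:
#' `x0_hat = (x_t - sqrt(1 - abar_t) * eps_hat) / sqrt(abar_t)`.
#'
#' @param x_t noisy matrix at step `t`.
#' @param eps_hat predicted noise, same shape.
#' @param t integer timestep(s), one per row (recycled).
#' @param schedule a `noise_schedule`.
#' @return matrix `x0_hat`.
#' @export
predict_x0 <- function(x_t, eps_hat, t, schedule) {
  x_t <- as.matrix(x_t); eps_hat <- as.matrix(eps_hat)
  stopifnot(all(dim(x_t) == dim(eps_hat)))
  t <- rep_len(as.integer(t), nrow(x_t))
  ab <- .abar(schedule, t)
  (x_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
}

#' One implicit (DDIM) reverse step
#'
#' `x_{t_prev} = sqrt(abar_prev) * x0_hat + sqrt(1 - abar_prev - sigma^2) *
#' eps_hat + sigma * noise`. With `sigma_t = 0` the step is deterministic
#' and iterating it integrates the probability-flow ODE.
#'
#' @param x_t matrix at step `t`.
#' @param eps_hat predicted noise.
#' @param t,t_prev integer timesteps with `t_prev < t` (`t_prev = 0` means
#'   a full jump to the data manifold).
#' @param sigma_t non-negative noise scale; must satisfy
#'   `sigma_t^2 <= 1 - abar_{t_prev}`.
#' @param schedule a `noise_schedule`.
#' @param noise optional standard-normal matrix (required if `sigma_t > 0`).
#' @return matrix at step `t_prev`.
#' @export
ddim_step <- function(x_t, eps_hat, t, t_prev, sigma_t = 0, schedule,
                      noise = NULL) {
  if (any(t_prev >= t)) stop("t_prev must be < t")
  if (sigma_t < 0) stop("sigma_t must be >= 0")
  x_t <- as.matrix(x_t)
  t <- rep_len(as.integer(t), nrow(x_t))
  t_prev <- rep_len(as.integer(t_prev), nrow(x_t))
  ab_prev <- .abar(schedule, t_prev)
  if (any(sigma_t^2 > 1 - ab_prev + 1e-12))
    stop("sigma_t^2 exceeds 1 - alpha_bar at t_prev")
  x0_hat <- predict_x0(x_t, eps_hat, t, schedule)
  out <- sqrt(ab_prev) * x0_hat +
    sqrt(pmax(1 - ab_prev - sigma_t^2, 0)) * as.matrix(eps_hat)
  if (sigma_t > 0) {
    if (is.null(noise)) stop("noise matrix required when sigma_t > 0")
    out <- out + sigma_t * as.matrix(noise)
  }
  out
}

#' Noise-prediction training loss
#'
#' Mean squared error between the true injected noise and the denoiser's
#' prediction on the corresponding noisy batch.
#'
#' @param denoiser function `(x_t, t, condition) -> eps_hat` (shape
#'   preserving); typically [denoiser_fun()] around a trained model.
#' @param batch list with `x0`, `t`, `eps`, `condition` (see
#'   [make_batch()]).
#' @param schedule a `noise_schedule`.
#' @return non-negative scalar.
#' @export
loss_simple <- function(denoiser, batch, schedule) {
  x_t <- q_sample(batch$x0, batch$t, batch$eps, schedule)
  eps_hat <- denoiser(x_t, batch$t, batch$condition)
  mean((batch$eps - eps_hat)^2)
}

#' Assemble a diffusion training batch
#'
#' @param x0 matrix of clean rows in \[-1, 1\].
#' @param t integer timesteps in \[1, T\], one per row.
#' @param eps standard-normal matrix, same shape as `x0`.
#' @param condition integer class index per row (1-based).
#' @param schedule a `noise_schedule` used for range validation.
#' @return list of the validated components.
#' @export
make_batch <- function(x0, t, eps, condition, schedule) {
  x0 <- as.matrix(x0); eps <- as.matrix(eps)
  t <- as.integer(t); condition <- as.integer(condition)
  if (!all(dim(x0) == dim(eps))) stop("x0 and eps shapes differ")
  if (length(t) != nrow(x0) || length(condition) != nrow(x0))
    stop("t and condition need one entry per row")
  if (any(t < 1 | t > schedule$T)) stop("t out of [1, T]")
  list(x0 = x0, t = t, eps = eps, condition = condition)
}

#' Stochastic ancestral (DDPM) sampling
#'
#' Starts from standard Gaussian noise at step T and iterates the learned
#' reverse chain down to the data manifold, using the posterior variance of
#' the forward process at each step. The final samples are clipped to the
#' normalized data domain \[-1, 1\].
#'
#' @param denoiser function `(x_t, t, condition) -> eps_hat`.
#' @param n number of samples to draw.
#' @param n_genes feature dimension.
#' @param condition integer class index (scalar or length n).
#' @param schedule a `noise_schedule`.
#' @param seed integer RNG seed.
#' @return `n x n_genes` matrix in \[-1, 1\].
#' @export
ancestral_sample <- function(denoiser, n, n_genes, condition, schedule,
                             seed = 1L) {
  condition <- rep_len(as.integer(condition), n)
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * n_genes), n, n_genes)
    ab <- schedule$alpha_bar
    ab_prev <- c(1, ab[-schedule$T])
    for (t in schedule$T:1) {
      eps_hat <- denoiser(x, rep(t, n), condition)
      beta_t <- schedule$beta[t]
      alpha_t <- 1 - beta_t
      mean_t <- (x - beta_t / sqrt(1 - ab[t]) * eps_hat) / sqrt(alpha_t)
      if (t > 1) {
        var_t <- beta_t * (1 - ab_prev[t]) / (1 - ab[t])
        x <- mean_t + sqrt(var_t) * matrix(stats::rnorm(n * n_genes), n, n_genes)
      } else {
        x <- mean_t
      }
    }
    pmin(pmax(x, -1), 1)
  })
}

# Evenly spaced timestep ladder 0 = tau_0 < tau_1 < ... < tau_K = T
.ode_taus <- function(schedule, n_ode_steps) {
  n_ode_steps <- as.integer(n_ode_steps)
  if (n_ode_steps < 1) stop("n_ode_steps must be >= 1")
  if (n_ode_steps > schedule$T) stop("n_ode_steps must be <= T")
  unique(round(seq(0, schedule$T, length.out = n_ode_steps + 1)))
}

#' Deterministic ODE encoding (data -> latent)
#'
#' Integrates the sigma = 0 implicit-diffusion recursion forward (t: 0 -> T)
#' over an evenly spaced subsequence of timesteps, conditioning the denoiser
#' on the source phenotype. The step-T latent is the bridge point between
#' phenotype states: decoding it under a different condition transports the
#' sample to the other state while preserving row pairing.
#'
#' @param denoiser function `(x_t, t, condition) -> eps_hat`.
#' @param x0 matrix of rows in \[-1, 1\].
#' @param condition integer class index (scalar or per row).
#' @param schedule a `noise_schedule`.
#' @param n_ode_steps number of integration steps (<= T, default 100).
#' @return latent matrix, same shape as `x0`, with attributes `condition`
#'   and `n_ode_steps`.
#' @export
ode_encode <- function(denoiser, x0, condition, schedule, n_ode_steps = 100L) {
  x <- as.matrix(x0)
  n <- nrow(x)
  condition <- rep_len(as.integer(condition), n)
  taus <- .ode_taus(schedule, n_ode_steps)
  for (i in seq_len(length(taus) - 1)) {
    t_lo <- taus[i]; t_hi <- taus[i + 1]
    # evaluate the model at the current (lower) noise level, then jump up
    eps_hat <- denoiser(x, rep(max(t_lo, 1L), n), condition)
    x0_hat <- predict_x0(x, eps_hat, t_lo, schedule)
    ab_hi <- .abar(schedule, t_hi)
    x <- sqrt(ab_hi) * x0_hat + sqrt(1 - ab_hi) * eps_hat
  }
  attr(x, "condition") <- condition
  attr(x, "n_ode_steps") <- n_ode_steps
  x
}

#' Deterministic ODE decoding (latent -> data)
#'
#' Integrates the sigma = 0 recursion in reverse (t: T -> 0) under the
#' target phenotype condition. Output rows are paired with input rows.
#'
#' @param denoiser function `(x_t, t, condition) -> eps_hat`.
#' @param latent matrix from [ode_encode()] (or Gaussian noise).
#' @param condition integer target class index.
#' @param schedule a `noise_schedule`.
#' @param n_ode_steps number of integration steps (<= T, default 100).
#' @return matrix in \[-1, 1\], same shape as `latent`.
#' @export
ode_decode <- function(denoiser, latent, condition, schedule,
                       n_ode_steps = 100L) {
  x <- as.matrix(latent)
  n <- nrow(x)
  condition <- rep_len(as.integer(condition), n)
  taus <- rev(.ode_taus(schedule, n_ode_steps))
  for (i in seq_len(length(taus) - 1)) {
    t_hi <- taus[i]; t_lo <- taus[i + 1]
    eps_hat <- denoiser(x, rep(t_hi, n), condition)
    x <- ddim_step(x, eps_hat, t_hi, t_lo, sigma_t = 0, schedule = schedule)
  }
  pmin(pmax(x, -1), 1)
}
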