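#' Sigmoid coupling function
#'
#' Logistic gate through which each site reads the other site's
#' activation before inhibiting it: `1 / (1 + exp(-beta * u))`.
#' Strictly increasing, with value 0.5 at `u = 0` and saturating at 0
#' and 1, so inhibition is effectively off while a site sits near the
#' resting level and fully on once it is active.
#'
#' @param u Activation value(s).
#' @param beta Steepness (> 0).
#' @return Values in (0, 1), same shape as `u`.
#' @examples
#' sigmoid(0, 2)      # 0.5
#' sigmoid(1, 2)      # 0.880797
#' @export
sigmoid <- function(u, beta = 2) {
  stopifnot("beta must be > 0" = beta > 0)
  1 / (1 + exp(-beta * u))
}

#' Deterministic drift of the two-site system
#'
#' The coupled rates
#' \deqn{\tau \dot u_P = -u_P + h - c_P \sigma(u_{NP}) + I_P}
#' \deqn{\tau \dot u_{NP} = -u_{NP} + h - c_{NP} \sigma(u_P) + I_{NP}}
#' evaluated at one state, without the noise term. Each site decays to
#' the resting level `h`, is pushed up by its total input and pulled
#' down by the sigmoid-gated activation of the other site.
#'
#' @param state Numeric vector `c(u_p, u_np)` (names optional).
#' @param params A [model_params()] object.
#' @param drive_p,drive_np Total input (sensory + memory) to each site.
#' @return Named numeric vector `c(du_p, du_np)` of time derivatives.
#' @export
drift <- function(state, params, drive_p, drive_np) {
  u_p <- state[[1]]; u_np <- state[[2]]
  c(du_p = (-u_p + params$h - params$c_p * sigmoid(u_np, params$beta) +
              drive_p) / params$tau,
    du_np = (-u_np + params$h - params$c_np * sigmoid(u_p, params$beta) +
               drive_np) / params$tau)
}

# Noise amplitude applied to the standard-normal deviate at each Euler
# step, per dialect. "per-step" reads the printed equation literally
# (noise is part of the rate); "sqrt-dt" is Euler-Maruyama.
.noise_amp <- function(params) {
  a <- params$dt / params$tau
  switch(params$noise_dialect,
         "per-step" = a * params$noise_strength,
         "sqrt-dt"  = params$noise_strength * sqrt(params$dt) / params$tau)
}

# Vectorized stochastic Euler integration of one trial for a batch of
# independent participants. u_p0/u_np0: length-N start states;
# noise_p/noise_np: N x n_steps matrices of standard normals (may be
# zero-row-free when noise_strength = 0). Returns list of final
# activations. Errors if any activation leaves the finite range.
.integrate_trial <- function(u_p0, u_np0, drive_p, drive_np, params,
                             noise_p = NULL, noise_np = NULL,
                             keep_path = FALSE) {
  n <- length(u_p0)
  a <- params$dt / params$tau
  amp <- .noise_amp(params)
  noisy <- params$noise_strength > 0
  u_p <- u_p0; u_np <- u_np0
  if (keep_path) {
    path_p <- matrix(NA_real_, n, params$n_steps + 1L)
    path_np <- path_p
    path_p[, 1L] <- u_p; path_np[, 1L] <- u_np
  }
  for (s in seq_len(params$n_steps)) {
    sig_np <- 1 / (1 + exp(-params$beta * u_np))
    sig_p <- 1 / (1 + exp(-params$beta * u_p))
    new_p <- u_p + a * (-u_p + params$h - params$c_p * sig_np + drive_p)
    new_np <- u_np + a * (-u_np + params$h - params$c_np * sig_p + drive_np)
    if (noisy) {
      new_p <- new_p + amp * noise_p[, s]
      new_np <- new_np + amp * noise_np[, s]
    }
    u_p <- new_p; u_np <- new_np
    if (any(!is.finite(u_p)) || any(!is.finite(u_np)))
      stop("integration diverged (non-finite activation) at step ", s)
    if (keep_path) {
      path_p[, s + 1L] <- u_p; path_np[, s + 1L] <- u_np
    }
  }
  out <- list(u_p = u_p, u_np = u_np)
  if (keep_path) {
    out$path_p <- path_p
    out$path_np <- path_np
  }
  out
}

#' Read out the selected limb from a final activation state
#'
#' The limb whose site has the strictly greater final activation is
#' selected; an exact tie is broken by a fair coin flip (one draw from
#' the current RNG stream) and flagged.
#'
#' @param u_p,u_np Final activations of the preferred and nonpreferred
#'   site (finite scalars).
#' @return List with `selected` (`"P"` or `"NP"`) and `tie_broken`.
#' @export
select_limb <- function(u_p, u_np) {
  stopifnot(is.finite(u_p), is.finite(u_np))
  if (u_p == u_np) {
    list(selected = if (stats::runif(1) < 0.5) "P" else "NP",
         tie_broken = TRUE)
  } else {
    list(selected = if (u_p > u_np) "P" else "NP", tie_broken = FALSE)
  }
}

#' Simulate a single trial
#'
#' Integrates the two coupled stochastic equations over one trial with
#' constant drives, starting from the resting level `u_p = u_np = h`,
#' and reads out the selected limb from the final state. Noise is an
#' independent standard-normal deviate per site per step, scaled
#' according to `params$noise_dialect`, drawn from R's current RNG
#' stream (seed with [set.seed()] for reproducibility).
#'
#' @param params A [model_params()] object.
#' @param drive_p,drive_np Total input to each site, constant over the
#'   trial.
#' @return List with `outcome` (list `selected`, `final_state`,
#'   `tie_broken`) and `trajectory` (data frame `step`, `time`, `u_p`,
#'   `u_np` with `n_steps + 1` rows including the initial state).
#' @examples
#' p <- age_preset("24mo", noise_strength = 0)
#' simulate_trial(p, drive_p = 6, drive_np = 6)$outcome$selected # "P"
#' @export
simulate_trial <- function(params, drive_p, drive_np) {
  validate_params(params)
  noisy <- params$noise_strength > 0
  noise_p <- noise_np <- NULL
  if (noisy) {
    noise_p <- matrix(stats::rnorm(params$n_steps), 1L)
    noise_np <- matrix(stats::rnorm(params$n_steps), 1L)
  }
  res <- .integrate_trial(params$h, params$h, drive_p, drive_np, params,
                          noise_p, noise_np, keep_path = TRUE)
  sel <- select_limb(res$u_p, res$u_np)
  traj <- data.frame(step = 0:params$n_steps,
                     time = (0:params$n_steps) * params$dt,
                     u_p = drop(res$path_p), u_np = drop(res$path_np))
  list(outcome = list(selected = sel$selected,
                      final_state = c(u_p = res$u_p, u_np = res$u_np),
                      tie_broken = sel$tie_broken),
       trajectory = traj)
}
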