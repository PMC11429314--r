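#' PPO hyperparameters
#'
#' Defaults are the controller's training configuration: rollouts of 288
#' steps (one simulated day) per update, minibatches of 64, discount 0.99,
#' GAE lambda 0.95, surrogate clip 0.2, no entropy bonus, value-loss weight
#' 0.5, gradient-norm clip 0.5, no state-dependent exploration and no KL
#' early stopping. The full-scale training budget is 5e7 environment steps
#' with checkpointing on the trailing mean reward of the last 100 episodes;
#' scale `total_steps` down for desk-scale runs.
#'
#' @param learning_rate Adam step size.
#' @param n_steps environment steps per rollout/update.
#' @param batch_size minibatch size.
#' @param gamma discount factor.
#' @param gae_lambda generalized advantage estimation lambda.
#' @param clip_range PPO probability-ratio clip.
#' @param ent_coef entropy bonus coefficient.
#' @param vf_coef value-loss coefficient.
#' @param max_grad_norm global gradient-norm clip.
#' @param use_sde state-dependent exploration (not implemented; must stay
#'   `FALSE`).
#' @param target_kl optional KL early-stopping threshold (`NULL` disables).
#' @param total_steps total environment steps of training.
#' @param checkpoint_window trailing-episode window for the best-model rule.
#' @param n_epochs optimisation epochs per rollout.
#' @param normalize_advantage normalise advantages within each minibatch.
#' @export
ppo_config <- function(learning_rate = 3e-4, n_steps = 288L, batch_size = 64L,
                       gamma = 0.99, gae_lambda = 0.95, clip_range = 0.2,
                       ent_coef = 0, vf_coef = 0.5, max_grad_norm = 0.5,
                       use_sde = FALSE, target_kl = NULL,
                       total_steps = 5e7, checkpoint_window = 100L,
                       n_epochs = 10L, normalize_advantage = TRUE) {
  if (isTRUE(use_sde)) stop("state-dependent exploration is not supported")
  structure(list(learning_rate = learning_rate, n_steps = as.integer(n_steps),
                 batch_size = as.integer(batch_size), gamma = gamma,
                 gae_lambda = gae_lambda, clip_range = clip_range,
                 ent_coef = ent_coef, vf_coef = vf_coef,
                 max_grad_norm = max_grad_norm, use_sde = FALSE,
                 target_kl = target_kl, total_steps = total_steps,
                 checkpoint_window = as.integer(checkpoint_window),
                 n_epochs = as.integer(n_epochs),
                 normalize_advantage = isTRUE(normalize_advantage)),
            class = "ppo_config")
}

gaussian_logp <- function(a, mu, log_sigma) {
  sigma <- exp(log_sigma)
  -0.5 * ((a - mu) / sigma)^2 - log_sigma - 0.5 * log(2 * pi)
}

#' PPO loss and analytic gradient on one minibatch
#'
#' The objective is the clipped surrogate plus the weighted value loss,
#' \deqn{L = -\mathrm{mean}\left(\min(r A, \mathrm{clip}(r, 1-\epsilon,
#'   1+\epsilon) A)\right) + c_v\, \mathrm{mean}\left((V - \hat R)^2\right),}
#' with probability ratio \eqn{r = \exp(\log\pi(a) - \log\pi_{old}(a))}
#' under the Gaussian policy head (entropy coefficient 0 by default).
#' Returns the loss, gradients for every trainable parameter and
#' diagnostics (approximate KL, clip fraction).
#'
#' @param nets networks from [build_networks()].
#' @param batch list with matrix `X` (n x 2) and vectors `a`, `logp_old`,
#'   `adv`, `ret`.
#' @param cfg a [ppo_config()].
#' @keywords internal
ppo_loss_grad <- function(nets, batch, cfg) {
  n <- nrow(batch$X)
  fp <- mlp_forward(nets$policy, batch$X, cache = TRUE)
  fv <- mlp_forward(nets$value, batch$X, cache = TRUE)
  mu <- fp$out[, 1]
  V <- fv$out[, 1]
  sigma2 <- exp(2 * nets$log_sigma)
  logp <- gaussian_logp(batch$a, mu, nets$log_sigma)
  # clamp the log-ratio: far-off-policy samples otherwise overflow exp()
  ratio <- exp(pmin(pmax(logp - batch$logp_old, -20), 20))
  s1 <- ratio * batch$adv
  s2 <- pmin(pmax(ratio, 1 - cfg$clip_range), 1 + cfg$clip_range) * batch$adv
  policy_loss <- -mean(pmin(s1, s2))
  value_loss <- mean((V - batch$ret)^2)
  loss <- policy_loss + cfg$vf_coef * value_loss
  if (!is.finite(loss)) {
    stop("non-finite PPO loss (policy ", signif(policy_loss, 4),
         ", value ", signif(value_loss, 4), ")")
  }

  # gradient flows through the unclipped branch where it attains the min
  # (ties included: inside the clip interval both branches coincide)
  mask <- as.numeric(s1 <= s2)
  dlogp <- -(1 / n) * batch$adv * ratio * mask
  dmu <- dlogp * (batch$a - mu) / sigma2
  dlog_sigma <- sum(dlogp * (((batch$a - mu)^2) / sigma2 - 1))
  dV <- cfg$vf_coef * 2 * (V - batch$ret) / n

  gp <- mlp_backward(nets$policy, fp, matrix(dmu, ncol = 1))
  gv <- mlp_backward(nets$value, fv, matrix(dV, ncol = 1))
  list(loss = loss, policy_loss = policy_loss, value_loss = value_loss,
       grads = list(pW = gp$W, pb = gp$b, vW = gv$W, vb = gv$b,
                    log_sigma = dlog_sigma),
       approx_kl = mean(batch$logp_old - logp),
       clip_frac = mean(abs(ratio - 1) > cfg$clip_range))
}

trainable_params <- function(nets) {
  list(pW = nets$policy$W, pb = nets$policy$b,
       vW = nets$value$W, vb = nets$value$b, log_sigma = nets$log_sigma)
}

set_trainable_params <- function(nets, params) {
  nets$policy$W <- params$pW; nets$policy$b <- params$pb
  nets$value$W <- params$vW; nets$value$b <- params$vb
  nets$log_sigma <- params$log_sigma
  nets
}

#' One PPO update from a rollout buffer
#'
#' Runs `n_epochs` passes of shuffled minibatches over the rollout,
#' normalising advantages per minibatch, clipping the global gradient norm
#' and applying Adam. Optionally stops early when the approximate KL
#' exceeds `target_kl`.
#'
#' @param nets networks from [build_networks()].
#' @param rollout list with `X`, `a`, `logp`, `adv`, `ret` over `n_steps`.
#' @param cfg a [ppo_config()].
#' @param opt Adam state (from a previous call), or `NULL` to start fresh.
#' @return list with updated `nets`, `opt` and `diagnostics`.
#' @export
ppo_update <- function(nets, rollout, cfg, opt = NULL) {
  params <- trainable_params(nets)
  if (is.null(opt)) opt <- adam_init(params)
  n <- nrow(rollout$X)
  diags <- list(loss = numeric(0), approx_kl = numeric(0), clip_frac = numeric(0))
  for (epoch in seq_len(cfg$n_epochs)) {
    idx <- sample.int(n)
    start <- 1L
    stop_epochs <- FALSE
    while (start <= n) {
      take <- idx[start:min(start + cfg$batch_size - 1L, n)]
      start <- start + cfg$batch_size
      adv <- rollout$adv[take]
      if (cfg$normalize_advantage && length(take) > 1) {
        s <- stats::sd(adv)
        if (s > 1e-8) adv <- (adv - mean(adv)) / s else adv <- adv - mean(adv)
      }
      batch <- list(X = rollout$X[take, , drop = FALSE], a = rollout$a[take],
                    logp_old = rollout$logp[take], adv = adv,
                    ret = rollout$ret[take])
      nets <- set_trainable_params(nets, params)
      lg <- ppo_loss_grad(nets, batch, cfg)
      gnorm <- grad_global_norm(lg$grads)
      grads <- if (gnorm > cfg$max_grad_norm) {
        scale_grads(lg$grads, cfg$max_grad_norm / gnorm)
      } else lg$grads
      st <- adam_step(params, grads, opt, cfg$learning_rate)
      params <- st$params; opt <- st$state
      # keep the exploration scale in a sane numerical range
      params$log_sigma <- min(max(params$log_sigma, -5), 2)
      diags$loss <- c(diags$loss, lg$loss)
      diags$approx_kl <- c(diags$approx_kl, lg$approx_kl)
      diags$clip_frac <- c(diags$clip_frac, lg$clip_frac)
      if (!is.null(cfg$target_kl) && lg$approx_kl > 1.5 * cfg$target_kl) {
        stop_epochs <- TRUE
        break
      }
    }
    if (stop_epochs) break
  }
  list(nets = set_trainable_params(nets, params), opt = opt,
       diagnostics = lapply(diags, mean))
}

# Generalized advantage estimation over one rollout. `values` has length
# n + 1 (bootstrap value of the state after the last step); `dones` marks
# steps that ended an episode. Time-limit truncations are pre-compensated in
# `rewards` by the caller (reward += gamma * V(terminal state)).
compute_gae <- function(rewards, values, dones, gamma, lam) {
  n <- length(rewards)
  adv <- numeric(n)
  last <- 0
  for (t in n:1) {
    nonterm <- 1 - dones[t]
    delta <- rewards[t] + gamma * values[t + 1] * nonterm - values[t]
    last <- delta + gamma * lam * nonterm * last
    adv[t] <- last
  }
  list(adv = adv, ret = adv + values[seq_len(n)])
}

#' Train a PPO insulin controller
#'
#' Runs the rollout/update loop on a closed-loop environment. Meal schedules
#' are redrawn at every episode (the controller never sees the same day
#' twice). After each completed episode the mean per-step reward of the
#' trailing `checkpoint_window` episodes is computed; whenever this trailing
#' mean improves, the current weights are saved as the best checkpoint.
#'
#' Uses R's global RNG throughout; call [set.seed()] (or pass `seed`) for a
#' reproducible run.
#'
#' @param env a [glyco_env()].
#' @param cfg a [ppo_config()]; `cfg$total_steps` controls the budget.
#' @param arch a [ppo_arch()].
#' @param seed optional seed applied before network init and the first reset.
#' @param verbose print progress every 50 updates.
#' @return an object of class `ppo_agent`: final and best network weights,
#'   the per-episode reward curve and the trailing-mean curve.
#' @export
ppo_train <- function(env, cfg = ppo_config(), arch = ppo_arch(), seed = NULL,
                      verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  nets <- build_networks(arch)
  opt <- NULL
  n_updates <- ceiling(cfg$total_steps / cfg$n_steps)
  episode_rewards <- numeric(0)
  trailing_mean <- numeric(0)
  best <- list(params = trainable_params(nets), trailing = -Inf, episode = 0L)
  obs <- env_reset(env)
  ep_sum <- 0; ep_len <- 0L
  steps_done <- 0

  for (upd in seq_len(n_updates)) {
    ns <- cfg$n_steps
    X <- matrix(0, ns, 2)
    a_v <- numeric(ns); logp_v <- numeric(ns); rew <- numeric(ns)
    val <- numeric(ns + 1); done <- numeric(ns)
    sigma <- exp(nets$log_sigma)
    for (t in seq_len(ns)) {
      mu <- mlp_forward1(nets$policy, obs)
      v <- mlp_forward1(nets$value, obs)
      # squashed-Gaussian head: sample in pre-squash space, execute
      # tanh(z). The tanh Jacobian term of the density is parameter-free
      # and cancels in the PPO probability ratio, so the surrogate works
      # directly on the pre-squash Gaussian
      z <- stats::rnorm(1, mu, sigma)
      X[t, ] <- obs
      a_v[t] <- z
      logp_v[t] <- gaussian_logp(z, mu, nets$log_sigma)
      val[t] <- v
      res <- env_step(env, tanh(z))
      rew[t] <- res$reward
      ep_sum <- ep_sum + res$reward; ep_len <- ep_len + 1L
      if (res$terminated || res$truncated) {
        done[t] <- 1
        if (res$truncated && !res$terminated) {
          # bootstrap through the time limit: the episode ends by the clock,
          # not because the state is absorbing
          rew[t] <- rew[t] +
            cfg$gamma * mlp_forward1(nets$value, res$observation)
        }
        episode_rewards <- c(episode_rewards, ep_sum / ep_len)
        w <- min(cfg$checkpoint_window, length(episode_rewards))
        tm <- mean(utils::tail(episode_rewards, w))
        trailing_mean <- c(trailing_mean, tm)
        if (tm > best$trailing) {
          best <- list(params = trainable_params(nets), trailing = tm,
                       episode = length(episode_rewards))
        }
        ep_sum <- 0; ep_len <- 0L
        obs <- env_reset(env)
      } else {
        obs <- res$observation
      }
    }
    val[ns + 1] <- mlp_forward1(nets$value, obs)
    gae <- compute_gae(rew, val, done, cfg$gamma, cfg$gae_lambda)
    rollout <- list(X = X, a = a_v, logp = logp_v, adv = gae$adv, ret = gae$ret)
    up <- ppo_update(nets, rollout, cfg, opt)
    nets <- up$nets; opt <- up$opt
    steps_done <- steps_done + ns
    if (verbose && upd %% 50 == 0) {
      message(sprintf("update %d/%d (%d steps), episodes %d, trailing mean %.4f",
                      upd, n_updates, steps_done, length(episode_rewards),
                      if (length(trailing_mean)) utils::tail(trailing_mean, 1) else NA))
    }
    if (steps_done >= cfg$total_steps) break
  }
  structure(list(nets = nets, best = best, episode_rewards = episode_rewards,
                 trailing_mean = trailing_mean, config = cfg, arch = arch,
                 steps_done = steps_done),
            class = "ppo_agent")
}

# Gauss-Hermite rule (Golub-Welsch), cached: nodes/weights for
# E[f(Z)] with Z standard normal via sum(w * f(sqrt(2) x)) / sqrt(pi)
.gh_cache <- new.env(parent = emptyenv())
gauss_hermite <- function(n = 33L) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    k <- seq_len(n - 1L)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1L)] <- sqrt(k / 2)
    J[cbind(k + 1L, k)] <- sqrt(k / 2)
    e <- eigen(J, symmetric = TRUE)
    .gh_cache[[key]] <- list(x = e$values, w = e$vectors[1, ]^2 * sqrt(pi))
  }
  .gh_cache[[key]]
}

# mean executed action E[tanh(z)], z ~ N(mu, sigma)
squashed_mean_action <- function(mu, sigma) {
  if (sigma < 1e-6) return(tanh(mu))
  q <- gauss_hermite()
  sum(q$w * tanh(mu + sigma * sqrt(2) * q$x)) / sqrt(pi)
}

#' Deterministic policy action
#'
#' Evaluation-time action: the *mean executed action* of the squashed
#' Gaussian head, `E[tanh(z)]` with `z ~ N(mu, sigma)`, computed by
#' Gauss-Hermite quadrature — strictly inside `(-1, 1)`, with no sampling.
#' This is the deterministic controller equivalent to the trained
#' stochastic policy: it delivers the average dose the agent delivered in
#' training, rather than the median dose `tanh(mu)` (the two differ
#' materially while the exploration scale is still large).
#'
#' @param agent a `ppo_agent` (uses the best checkpoint by default), or the
#'   raw `nets` list.
#' @param obs length-2 observation.
#' @param use_best use the best-trailing-mean checkpoint rather than the
#'   final weights.
#' @export
policy_action <- function(agent, obs, use_best = TRUE) {
  nets <- agent_nets(agent, use_best)
  squashed_mean_action(mlp_forward1(nets$policy, obs), exp(nets$log_sigma))
}

agent_nets <- function(agent, use_best = TRUE) {
  if (inherits(agent, "ppo_agent")) {
    nets <- agent$nets
    if (use_best) nets <- set_trainable_params(nets, agent$best$params)
    nets
  } else {
    agent
  }
}

#' Save / load a trained agent
#'
#' Checkpoints are portable JSON: an architecture manifest plus flat weight
#' arrays (full double precision).
#'
#' @param agent a `ppo_agent`.
#' @param path file path (`.json`).
#' @export
save_ppo_agent <- function(agent, path) {
  nets <- agent_nets(agent, use_best = TRUE)
  ser_net <- function(net) list(sizes = net$sizes,
                                out_activation = net$out_activation,
                                W = lapply(net$W, as.vector),
                                b = net$b)
  obj <- list(arch = unclass(agent$arch),
              policy = ser_net(nets$policy),
              value = ser_net(nets$value),
              log_sigma = nets$log_sigma)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_ppo_agent
#' @export
load_ppo_agent <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_net <- function(x) {
    sizes <- as.integer(x$sizes)
    L <- length(sizes) - 1L
    W <- lapply(seq_len(L), function(l) {
      matrix(x$W[[l]], sizes[l], sizes[l + 1])
    })
    structure(list(W = W, b = lapply(x$b, as.numeric), sizes = sizes,
                   out_activation = x$out_activation %||% "identity"),
              class = "glyco_mlp")
  }
  arch <- do.call(ppo_arch, obj$arch[c("width", "policy_blocks",
                                       "value_blocks", "block_out")])
  list(policy = de_net(obj$policy), value = de_net(obj$value),
       log_sigma = obj$log_sigma, arch = arch)
}

#' @export
print.ppo_agent <- function(x, ...) {
  cat("PPO insulin controller\n")
  cat(sprintf("  trained for %g env steps, %d episodes\n",
              x$steps_done, length(x$episode_rewards)))
  cat(sprintf("  best trailing-%d mean reward %.4f at episode %d\n",
              x$config$checkpoint_window, x$best$trailing, x$best$episode))
  invisible(x)
}
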