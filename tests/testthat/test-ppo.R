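# flatten trainable parameters to a vector and back, for the
# finite-difference gradient oracle
flatten_params <- function(params) {
  unlist(rapply(params, as.vector, how = "unlist"), use.names = FALSE)
}
unflatten_like <- function(vec, template) {
  i <- 0
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vec[(i + 1):(i + n)]
    i <<- i + n
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  walk(template)
}

toy_batch <- function(nets, n = 3, seed = 5) {
  set.seed(seed)
  X <- matrix(stats::runif(2 * n), n, 2)
  mu <- glyco:::mlp_forward(nets$policy, X)[, 1]
  a <- mu + stats::rnorm(n, 0, 0.7)
  # old log-probs from a slightly different (earlier) policy so ratios != 1
  logp_old <- glyco:::gaussian_logp(a, mu + stats::rnorm(n, 0, 0.2),
                                    nets$log_sigma + 0.1)
  list(X = X, a = a, logp_old = logp_old,
       adv = stats::rnorm(n), ret = stats::rnorm(n))
}

test_that("networks have the block shape: deeper policy, scalar outputs", {
  set.seed(1)
  nets <- build_networks(ppo_arch(width = 32))
  expect_length(nets$policy$W, 8L)  # 7 ELU blocks + terminal linear
  expect_length(nets$value$W, 6L)   # 5 ELU blocks + terminal linear
  expect_equal(nets$policy$sizes[1], 2L)
  expect_equal(utils::tail(nets$policy$sizes, 2), c(64L, 1L))
  out_p <- glyco:::mlp_forward1(nets$policy, c(0.12, 0.5))
  out_v <- glyco:::mlp_forward1(nets$value, c(0.12, 0.5))
  expect_length(out_p, 1L)
  expect_true(is.finite(out_p) && is.finite(out_v))
  expect_gt(glyco:::nn_num_params(nets$policy), glyco:::nn_num_params(nets$value))
  # deterministic rebuild under the same seed
  set.seed(1)
  nets2 <- build_networks(ppo_arch(width = 32))
  expect_identical(nets$policy$W, nets2$policy$W)
})

test_that("batched and single-observation forward passes agree", {
  set.seed(2)
  nets <- build_networks(ppo_arch(width = 16))
  X <- matrix(stats::runif(10), 5, 2)
  batch <- glyco:::mlp_forward(nets$policy, X)[, 1]
  single <- apply(X, 1, function(x) glyco:::mlp_forward1(nets$policy, x))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("the analytic PPO gradient matches finite differences", {
  set.seed(3)
  nets <- build_networks(ppo_arch(width = 6, policy_blocks = 3, value_blocks = 2,
                                  block_out = 4))
  cfg <- ppo_config()
  batch <- toy_batch(nets, n = 3)
  lg <- glyco:::ppo_loss_grad(nets, batch, cfg)
  params <- glyco:::trainable_params(nets)
  theta <- flatten_params(params)
  ga <- flatten_params(lg$grads)
  loss_at <- function(v) {
    nets2 <- glyco:::set_trainable_params(nets, unflatten_like(v, params))
    glyco:::ppo_loss_grad(nets2, batch, cfg)$loss
  }
  h <- 1e-6
  idx <- seq_along(theta)
  gn <- vapply(idx, function(j) {
    e <- numeric(length(theta)); e[j] <- h
    (loss_at(theta + e) - loss_at(theta - e)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga - gn)) / max(1, max(abs(ga))), 1e-4)
})

test_that("zero advantages silence the policy gradient but not the critic", {
  set.seed(4)
  nets <- build_networks(ppo_arch(width = 8, policy_blocks = 3, value_blocks = 2))
  batch <- toy_batch(nets, n = 4)
  batch$adv <- rep(0, 4)
  lg <- glyco:::ppo_loss_grad(nets, batch, ppo_config())
  expect_equal(max(abs(flatten_params(lg$grads[c("pW", "pb")]))), 0)
  expect_equal(lg$grads$log_sigma, 0)
  expect_gt(max(abs(flatten_params(lg$grads[c("vW", "vb")]))), 0)
})

test_that("GAE with lambda = 1 reduces to discounted Monte-Carlo advantages", {
  set.seed(6)
  n <- 12
  rew <- stats::rnorm(n)
  val <- stats::rnorm(n + 1)
  gamma <- 0.97
  out <- glyco:::compute_gae(rew, val, rep(0, n), gamma, 1)
  # oracle: direct discounted sums including the bootstrap value
  mc <- vapply(seq_len(n), function(t) {
    sum(gamma^(0:(n - t)) * rew[t:n]) + gamma^(n - t + 1) * val[n + 1]
  }, numeric(1))
  expect_equal(out$adv, mc - val[seq_len(n)], tolerance = 1e-12)
  expect_equal(out$ret, mc, tolerance = 1e-12)
  # an episode boundary stops the recursion
  dones <- rep(0, n); dones[5] <- 1
  out2 <- glyco:::compute_gae(rew, val, dones, gamma, 1)
  mc5 <- sum(gamma^(0:4) * rew[1:5])
  expect_equal(out2$ret[1], mc5, tolerance = 1e-12)
})

test_that("the published hyperparameter defaults are wired into the configuration", {
  cfg <- ppo_config()
  expect_equal(cfg$learning_rate, 3e-4)
  expect_equal(cfg$n_steps, 288L)
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$gamma, 0.99)
  expect_equal(cfg$gae_lambda, 0.95)
  expect_equal(cfg$clip_range, 0.2)
  expect_equal(cfg$ent_coef, 0)
  expect_equal(cfg$vf_coef, 0.5)
  expect_equal(cfg$max_grad_norm, 0.5)
  expect_false(cfg$use_sde)
  expect_null(cfg$target_kl)
  expect_equal(cfg$total_steps, 5e7)
  expect_equal(cfg$checkpoint_window, 100L)
  expect_error(ppo_config(use_sde = TRUE), "not supported")
})

test_that("a zero-step budget returns the initial weights and empty curve", {
  env <- glyco_env(ivp_patient(10), episode_days = 1)
  agent <- ppo_train(env, ppo_config(total_steps = 0),
                     arch = ppo_arch(width = 8, policy_blocks = 3,
                                     value_blocks = 2), seed = 9)
  expect_length(agent$episode_rewards, 0L)
  set.seed(9)
  nets0 <- build_networks(ppo_arch(width = 8, policy_blocks = 3, value_blocks = 2))
  expect_identical(agent$nets$policy$W, nets0$policy$W)
})

test_that("short training runs are reproducible end to end", {
  run <- function() {
    env <- glyco_env(ivp_patient(10), reward = "piecewise", episode_days = 1)
    agent <- ppo_train(env, ppo_config(total_steps = 2 * 288),
                       arch = ppo_arch(width = 8, policy_blocks = 3,
                                       value_blocks = 2), seed = 17)
    list(rewards = agent$episode_rewards,
         theta = flatten_params(glyco:::trainable_params(agent$nets)))
  }
  a <- run(); b <- run()
  expect_identical(a$rewards, b$rewards)
  expect_identical(a$theta, b$theta)
  expect_length(a$rewards, 2L)
})

test_that("agents save to JSON and reload with identical behaviour", {
  env <- glyco_env(ivp_patient(10), reward = "piecewise", episode_days = 1)
  agent <- ppo_train(env, ppo_config(total_steps = 288),
                     arch = ppo_arch(width = 8, policy_blocks = 3,
                                     value_blocks = 2), seed = 23)
  f <- tempfile(fileext = ".json")
  save_ppo_agent(agent, f)
  back <- load_ppo_agent(f)
  obs <- c(0.12, 0.5)
  expect_equal(policy_action(back, obs), policy_action(agent, obs),
               tolerance = 1e-12)
  unlink(f)
})

test_that("deterministic evaluation actions are the mean executed action", {
  set.seed(31)
  nets <- build_networks(ppo_arch(width = 8, policy_blocks = 3, value_blocks = 2))
  obs <- c(0.2, 0.4)
  mu <- glyco:::mlp_forward1(nets$policy, obs)
  sigma <- exp(nets$log_sigma)
  # independent oracle: adaptive quadrature of E[tanh(z)], z ~ N(mu, sigma)
  oracle <- stats::integrate(function(z) tanh(z) * stats::dnorm(z, mu, sigma),
                             mu - 10 * sigma, mu + 10 * sigma,
                             rel.tol = 1e-10)$value
  # 33-node Gauss-Hermite truncation leaves ~1e-8 absolute error
  expect_lt(abs(policy_action(nets, obs) - oracle), 1e-7)
  expect_true(abs(policy_action(nets, obs)) < 1)
  fn <- glyco:::as_policy_fn(nets)
  expect_equal(fn(obs), policy_action(nets, obs))
  # with a vanishing exploration scale the mean action tends to tanh(mu)
  nets$log_sigma <- -20
  expect_equal(policy_action(nets, obs), tanh(mu), tolerance = 1e-9)
})
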