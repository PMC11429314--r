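#' Actor-critic network architecture
#'
#' Both networks are stacks of fully connected blocks (Linear + ELU). The
#' policy tower is deeper than the value tower: by default seven blocks of
#' 2048 units against five, the rationale being that the critic should learn
#' fast while the actor needs more capacity for the control strategy. The
#' first block maps the 2-feature observation up to the block width, the
#' last block maps down to 64 units, and a terminal linear layer (identity
#' activation) produces the scalar output: the action mean for the policy,
#' the state value for the critic.
#'
#' `width` scales every hidden block; reduced widths give a faithful
#' small-scale replica of the same topology for desk-scale experiments.
#'
#' @param width hidden block width (default 2048).
#' @param policy_blocks,value_blocks number of Linear+ELU blocks.
#' @param block_out output width of the last block (default 64).
#' @return an object of class `ppo_arch`.
#' @export
ppo_arch <- function(width = 2048, policy_blocks = 7, value_blocks = 5,
                     block_out = 64) {
  stopifnot(width >= 1, policy_blocks >= 2, value_blocks >= 2, block_out >= 1)
  structure(list(width = width, policy_blocks = policy_blocks,
                 value_blocks = value_blocks, block_out = block_out,
                 n_inputs = 2L),
            class = "ppo_arch")
}

arch_sizes <- function(arch, blocks) {
  c(arch$n_inputs, rep(arch$width, blocks - 1), arch$block_out, 1L)
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

# Fully connected net: hidden layers Linear+ELU, terminal layer linear or,
# for the policy head, tanh (`out_activation`), which bounds the action
# mean inside (-1, 1) by construction. Weights W[[l]] are (in x out);
# scaled-Gaussian init with gain sqrt(2), terminal layer scaled by
# `final_gain`.
mlp_init <- function(sizes, final_gain = 1, out_activation = c("identity", "tanh")) {
  out_activation <- match.arg(out_activation)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    gain <- if (l == L) final_gain else sqrt(2)
    sd <- gain / sqrt(sizes[l])
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sd),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(W = W, b = b, sizes = sizes, out_activation = out_activation),
            class = "glyco_mlp")
}

# Forward pass on a batch X (n x d). With cache = TRUE also returns the
# pre-activations needed by mlp_backward.
mlp_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  A <- X
  Zs <- if (cache) vector("list", L) else NULL
  As <- if (cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    if (cache) As[[l]] <- A
    Z <- A %*% net$W[[l]]
    Z <- sweep(Z, 2, net$b[[l]], `+`)
    if (l < L) {
      if (cache) Zs[[l]] <- Z
      A <- elu(Z)
    } else {
      A <- if (identical(net$out_activation, "tanh")) tanh(Z) else Z
    }
  }
  if (cache) list(out = A, Zs = Zs, As = As) else A
}

# Single-observation forward pass (no cache), kept lean for rollouts.
mlp_forward1 <- function(net, x) {
  L <- length(net$W)
  h <- x
  for (l in seq_len(L)) {
    h <- c(h %*% net$W[[l]]) + net$b[[l]]
    if (l < L) h <- elu(h)
  }
  if (identical(net$out_activation, "tanh")) h <- tanh(h)
  h
}

# Backpropagate dOut (n x out, gradient wrt the net output after any
# output activation) through a cached forward pass; returns gradients with
# the same shapes as net$W / net$b.
mlp_backward <- function(net, fw, dOut) {
  L <- length(net$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- if (identical(net$out_activation, "tanh")) {
    dOut * (1 - fw$out^2)
  } else {
    dOut
  }
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$As[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- tcrossprod(delta, net$W[[l]]) * elu_grad(fw$Zs[[l - 1]])
    }
  }
  list(W = gW, b = gb)
}

nn_num_params <- function(net) {
  sum(vapply(net$W, length, numeric(1))) + sum(vapply(net$b, length, numeric(1)))
}

#' Build the policy and value networks
#'
#' Initialises both towers from the architecture description using R's
#' global RNG (seed with [set.seed()] for reproducible builds). The policy
#' output parameterises a squashed-Gaussian action head: the network emits
#' the pre-squash mean, exploration samples
#' `z ~ N(mean, exp(log_sigma))` in that space, and the executed action is
#' `tanh(z)` — strictly inside (-1, 1), so the controller's output is
#' always a valid insulin fraction of the pump range. `log_sigma` is a
#' learned state-independent scalar initialised at 0. The terminal layers
#' are initialised small so the initial action mean is near 0.
#'
#' @param arch a [ppo_arch()].
#' @return list with `policy` (net + `log_sigma`), `value` (net) and `arch`.
#' @export
build_networks <- function(arch = ppo_arch()) {
  policy <- mlp_init(arch_sizes(arch, arch$policy_blocks), final_gain = 0.01)
  value <- mlp_init(arch_sizes(arch, arch$value_blocks), final_gain = 1)
  list(policy = policy, value = value, log_sigma = 0, arch = arch)
}

# ---- Adam optimiser over a list-structured parameter set -------------------

adam_init <- function(params) {
  zeros <- rapply(params, function(x) x * 0, how = "replace")
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  out <- walk(params, grads, state$m, state$v)
  list(params = out$p, state = list(m = out$m, v = out$v, t = t))
}

grad_global_norm <- function(grads) {
  sqrt(sum(unlist(rapply(grads, function(g) sum(g^2), how = "unlist"))))
}

scale_grads <- function(grads, factor) {
  rapply(grads, function(g) g * factor, how = "replace")
}
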