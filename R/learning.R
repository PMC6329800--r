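#' Ideal-observer learning trial of a block
#'
#' Estimates the latent probability-correct of a block's binary outcome
#' sequence with a binomial state-space smoother: the latent probability
#' follows a reflected Gaussian random walk (sd `sigma` per trial) over a
#' probability grid with a uniform prior, outcomes are Bernoulli emissions,
#' and the posterior at each trial is obtained by forward-backward smoothing.
#' The learning trial is the earliest trial at which the lower bound of the
#' one-sided `conf` credible interval exceeds `chance` and remains above
#' chance for the remainder of the block.
#'
#' @param outcomes Binary outcome sequence of one block (1 = correct).
#' @param chance Chance performance level (0.5 for a binary choice).
#' @param sigma Random-walk standard deviation per trial on the probability
#'   scale.
#' @param conf One-sided credible level for the lower bound.
#' @param grid_n Number of grid points for the latent probability.
#' @return 1-based index of the learning trial, or `NA_integer_` if the block
#'   was never learned. Sequences shorter than 5 trials return `NA_integer_`.
#' @examples
#' learning_trial(rep(1, 30)) # learned almost immediately
#' learning_trial(rep(0, 30)) # never learned
#' @export
learning_trial <- function(outcomes, chance = 0.5, sigma = 0.1,
                           conf = 0.95, grid_n = 99L) {
  stopifnot(all(outcomes %in% c(0, 1)))
  n <- length(outcomes)
  if (n < 5) {
    return(NA_integer_)
  }
  post <- state_space_posterior(outcomes, sigma, grid_n)
  lower <- apply(post$posterior, 2, function(p) {
    post$grid[which(cumsum(p) >= 1 - conf)[1]]
  })
  above <- lower > chance
  # earliest trial above chance with all later trials above as well
  ok <- rev(cumprod(rev(above))) == 1
  if (!any(ok)) {
    return(NA_integer_)
  }
  as.integer(which(ok)[1])
}

# Forward-backward smoothing of a Bernoulli sequence under a Gaussian
# random-walk prior on the success probability (grid approximation).
state_space_posterior <- function(outcomes, sigma = 0.1, grid_n = 99L) {
  grid <- seq(1 / (2 * grid_n), 1 - 1 / (2 * grid_n), length.out = grid_n)
  n <- length(outcomes)
  # transition kernel: Gaussian in p, renormalized (mass reflected into [0,1])
  K <- outer(grid, grid, function(from, to) {
    exp(-(to - from)^2 / (2 * sigma^2))
  })
  K <- K / rowSums(K)
  lik <- vapply(outcomes, function(y) if (y == 1) grid else 1 - grid,
    numeric(grid_n)
  )
  fwd <- matrix(0, grid_n, n)
  f <- rep(1 / grid_n, grid_n) * lik[, 1]
  fwd[, 1] <- f / sum(f)
  for (t in seq_len(n)[-1]) {
    f <- as.vector(crossprod(K, fwd[, t - 1])) * lik[, t]
    fwd[, t] <- f / sum(f)
  }
  bwd <- matrix(0, grid_n, n)
  bwd[, n] <- 1
  for (t in rev(seq_len(n - 1))) {
    b <- K %*% (bwd[, t + 1] * lik[, t + 1])
    bwd[, t] <- b / sum(b)
  }
  post <- fwd * bwd
  post <- sweep(post, 2, colSums(post), "/")
  list(grid = grid, posterior = post)
}
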