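#' Inverse-logit and logit helpers
#'
#' Numerically safe logistic transforms used throughout the samplers.
#'
#' @param x Real number(s) (for `ilogit`) or probabilities in (0, 1)
#'   (for `logit`).
#' @return Numeric vector of the same length.
#' @examples
#' ilogit(0)      # 0.5
#' logit(0.5)     # 0
#' @export
ilogit <- function(x) stats::plogis(x)

#' @rdname ilogit
#' @export
logit <- function(x) stats::qlogis(x)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' One-step transition probability of the latent occupancy chain
#'
#' The probability that a site is occupied in season t+1 given its state in
#' season t: an occupied site persists with probability `phi`, an empty one
#' is colonized with probability `gamma`, i.e.
#' \eqn{\pi_t = \phi z_t + \gamma (1 - z_t)}.
#'
#' @param z Occupancy state at season t, 0 or 1 (vectorised).
#' @param phi Persistence probability in \[0, 1\].
#' @param gamma Colonization probability in \[0, 1\].
#' @return Probability that the site is occupied at season t+1.
#' @export
transition_prob <- function(z, phi, gamma) {
  if (any(!z %in% c(0, 1))) stop("`z` must be 0 or 1", call. = FALSE)
  check_prob(phi, "phi")
  check_prob(gamma, "gamma")
  phi * z + gamma * (1 - z)
}

#' Marginal occupancy recursion
#'
#' Propagates the marginal occupancy probability one season forward under
#' the first-order Markov dynamics:
#' \eqn{\psi_{t+1} = \psi_t \phi + (1 - \psi_t) \gamma}.
#' For constant rates with \eqn{\phi < 1} the recursion converges to the
#' equilibrium occupancy \eqn{\gamma / (\gamma + 1 - \phi)}.
#'
#' @param psi Occupancy probability at season t.
#' @param phi Persistence probability.
#' @param gamma Colonization probability.
#' @return Occupancy probability at season t+1, guaranteed in \[0, 1\].
#' @export
occupancy_recursion <- function(psi, phi, gamma) {
  check_prob(psi, "psi")
  check_prob(phi, "phi")
  check_prob(gamma, "gamma")
  psi * phi + (1 - psi) * gamma
}

#' Binomial detection log-likelihood conditional on occupancy
#'
#' Log-probability of observing `y` detection occasions out of `k` given
#' per-occasion detection probability `p` and latent occupancy `z`. An
#' unoccupied site cannot yield detections: when `z = 0` the value is 0 for
#' `y = 0` and `-Inf` otherwise.
#'
#' @param y Number of occasions with a detection (0..k).
#' @param k Number of occasions surveyed.
#' @param p Per-occasion detection probability.
#' @param z Latent occupancy state, 0 or 1.
#' @return Log-probability (scalar or vector).
#' @export
detection_loglik <- function(y, k, p, z) {
  if (any(y < 0) || any(y > k)) stop("`y` must satisfy 0 <= y <= k", call. = FALSE)
  if (any(!z %in% c(0, 1))) stop("`z` must be 0 or 1", call. = FALSE)
  check_prob(p, "p")
  out <- ifelse(z == 1,
    stats::dbinom(y, k, p, log = TRUE),
    ifelse(y == 0, 0, -Inf)
  )
  out
}

#' Marginal probability of a multi-season detection history
#'
#' Sums the latent occupancy chain out of the joint likelihood by the
#' forward algorithm over the two-state Markov chain: initial occupancy
#' `psi1`, per-transition persistence `phi` and colonization `gamma`, and
#' per-season binomial detection with probability `p[t]` over `k[t]`
#' occasions.
#'
#' @param y Integer vector of detections per season (length T).
#' @param k Integer vector of occasions per season (length T).
#' @param psi1 Initial occupancy probability.
#' @param phi Persistence probabilities, length T-1.
#' @param gamma Colonization probabilities, length T-1.
#' @param p Detection probabilities, length T (or scalar, recycled).
#' @param log Return the log-probability?
#' @return The marginal probability P(y) (or its log).
#' @export
forward_history_prob <- function(y, k, psi1, phi, gamma, p, log = FALSE) {
  T <- length(y)
  stopifnot(length(k) == T)
  p <- rep_len(p, T)
  if (T > 1) {
    phi <- rep_len(phi, T - 1)
    gamma <- rep_len(gamma, T - 1)
  }
  # alpha[s] = P(y_1..t, z_t = s), s in {0 = empty, 1 = occupied}
  e0 <- ifelse(y == 0, 1, 0)                      # emission given z = 0
  e1 <- stats::dbinom(y, k, p)                    # emission given z = 1
  alpha <- c(`0` = (1 - psi1) * e0[1], `1` = psi1 * e1[1])
  if (T > 1) {
    for (t in 2:T) {
      a1 <- alpha[1] * gamma[t - 1] + alpha[2] * phi[t - 1]
      a0 <- alpha[1] * (1 - gamma[t - 1]) + alpha[2] * (1 - phi[t - 1])
      alpha <- c(a0 * e0[t], a1 * e1[t])
    }
  }
  out <- sum(alpha)
  if (log) base::log(out) else out
}

#' Sample a latent occupancy history from its exact full conditional
#'
#' Forward-filtering backward-sampling (FFBS) for the two-state occupancy
#' chain: draws z\[1..T\] jointly from P(z | y, parameters). Seasons with at
#' least one detection always come back occupied.
#'
#' @inheritParams forward_history_prob
#' @return Integer vector z of length T with entries in \{0, 1\}.
#' @export
ffbs_sample_states <- function(y, k, psi1, phi, gamma, p) {
  T <- length(y)
  p <- rep_len(p, T)
  if (T > 1) {
    phi <- rep_len(phi, T - 1)
    gamma <- rep_len(gamma, T - 1)
  }
  e0 <- ifelse(y == 0, 1, 0)
  e1 <- stats::dbinom(y, k, p)
  a0 <- numeric(T); a1 <- numeric(T)
  a0[1] <- (1 - psi1) * e0[1]
  a1[1] <- psi1 * e1[1]
  if (T > 1) {
    for (t in 2:T) {
      a1[t] <- (a0[t - 1] * gamma[t - 1] + a1[t - 1] * phi[t - 1]) * e1[t]
      a0[t] <- (a0[t - 1] * (1 - gamma[t - 1]) + a1[t - 1] * (1 - phi[t - 1])) * e0[t]
    }
  }
  z <- integer(T)
  tot <- a0[T] + a1[T]
  if (tot <= 0) stop("detection history has probability zero under the supplied parameters")
  z[T] <- stats::rbinom(1L, 1L, a1[T] / tot)
  if (T > 1) {
    for (t in (T - 1):1) {
      if (z[t + 1] == 1) {
        w1 <- a1[t] * phi[t]
        w0 <- a0[t] * gamma[t]
      } else {
        w1 <- a1[t] * (1 - phi[t])
        w0 <- a0[t] * (1 - gamma[t])
      }
      z[t] <- stats::rbinom(1L, 1L, w1 / (w1 + w0))
    }
  }
  z
}

#' Metropolis random-walk update for a logit-scale parameter
#'
#' One Metropolis step targeting `loglik_fn(x) + log N(x | prior_mean,
#' prior_sd^2)` with a Gaussian random-walk proposal. Used for all
#' logit-scale intercept updates in the samplers.
#'
#' @param current Current parameter value.
#' @param loglik_fn Function of the parameter returning a log-likelihood.
#' @param prior_mean,prior_sd Gaussian prior on the parameter.
#' @param proposal_sd Random-walk proposal standard deviation.
#' @return List with `value` (new state) and `accepted` (logical).
#' @export
mh_update_logit <- function(current, loglik_fn, prior_mean, prior_sd, proposal_sd) {
  stopifnot(proposal_sd > 0, prior_sd > 0)
  prop <- current + stats::rnorm(1L, 0, proposal_sd)
  log_ratio <- (loglik_fn(prop) + stats::dnorm(prop, prior_mean, prior_sd, log = TRUE)) -
    (loglik_fn(current) + stats::dnorm(current, prior_mean, prior_sd, log = TRUE))
  if (is.finite(log_ratio) && log(stats::runif(1L)) < log_ratio) {
    list(value = prop, accepted = TRUE)
  } else {
    list(value = current, accepted = FALSE)
  }
}

# Stepping-out + shrinkage slice sampler on a bounded interval (Neal 2003).
slice_sample_bounded <- function(current, logpost_fn, lower, upper, w = 0.5) {
  ly <- logpost_fn(current) + log(stats::runif(1L))
  l <- max(lower, current - stats::runif(1L) * w)
  r <- min(upper, l + w)
  # step out
  while (l > lower && logpost_fn(l) > ly) l <- max(lower, l - w)
  while (r < upper && logpost_fn(r) > ly) r <- min(upper, r + w)
  repeat {
    x <- stats::runif(1L, l, r)
    if (logpost_fn(x) > ly) return(x)
    if (x < current) l <- x else r <- x
  }
}

#' Gibbs update of logit-normal hyperparameters
#'
#' Given the current species-level logit-scale effects, draws the
#' hyper-mean from its conjugate Normal full conditional (hyperprior
#' Normal(0, `mu_prior_sd`^2)) and the hyper-SD by slice sampling its full
#' conditional under a Uniform(0, `sigma_max`) hyperprior.
#'
#' @param effects Numeric vector of logit-scale effects (length >= 1).
#' @param sigma Current hyper-SD (used as the slice starting state).
#' @param mu_prior_sd SD of the Normal(0, .) hyperprior on the mean.
#' @param sigma_max Upper bound of the uniform hyperprior on the SD.
#' @return List with elements `mu` and `sigma`.
#' @export
update_hyperparams <- function(effects, sigma = stats::sd(effects),
                               mu_prior_sd = 10, sigma_max = 5) {
  n <- length(effects)
  stopifnot(n >= 1)
  if (!is.finite(sigma) || sigma <= 0 || sigma >= sigma_max) sigma <- sigma_max / 2
  post_var <- 1 / (n / sigma^2 + 1 / mu_prior_sd^2)
  post_mean <- post_var * sum(effects) / sigma^2
  mu <- stats::rnorm(1L, post_mean, sqrt(post_var))
  lp <- function(s) {
    if (s <= 0 || s >= sigma_max) return(-Inf)
    sum(stats::dnorm(effects, mu, s, log = TRUE))
  }
  sigma_new <- slice_sample_bounded(sigma, lp, 0, sigma_max)
  list(mu = mu, sigma = sigma_new)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Plain between/within-chain variance form of the convergence diagnostic:
#' \eqn{\hat R = \sqrt{\hat{var}^+ / W}} with
#' \eqn{\hat{var}^+ = (n-1)/n \, W + B/n}.
#'
#' @param chains Matrix of draws, iterations in rows, one column per chain
#'   (at least 2 chains of equal length >= 10).
#' @return The scalar \eqn{\hat R}.
#' @export
gelman_rubin <- function(chains) {
  chains <- as.matrix(chains)
  m <- ncol(chains)
  n <- nrow(chains)
  if (m < 2) stop("gelman_rubin() needs at least 2 chains", call. = FALSE)
  if (n < 10) stop("chains must have length >= 10", call. = FALSE)
  means <- colMeans(chains)
  W <- mean(apply(chains, 2, stats::var))
  B <- n * stats::var(means)
  if (W == 0) return(1)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Posterior summary of MCMC draws
#'
#' Mean, median and central 95% credible interval (2.5/97.5 percentiles,
#' type-7 linear interpolation), plus the Gelman-Rubin \eqn{\hat R} when
#' more than one chain is supplied.
#'
#' @param draws Numeric vector of pooled draws, or an iterations x chains
#'   matrix.
#' @return A one-row tibble with columns `mean`, `median`, `q2.5`, `q97.5`
#'   and `rhat` (NA for a single chain).
#' @export
summarise_draws <- function(draws) {
  rhat <- NA_real_
  if (is.matrix(draws) && ncol(draws) > 1) {
    rhat <- gelman_rubin(draws)
  }
  x <- as.numeric(draws)
  if (length(x) == 0) stop("no draws to summarise", call. = FALSE)
  q <- stats::quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
  tibble::tibble(
    mean = mean(x), median = q[2], q2.5 = q[1], q97.5 = q[3], rhat = rhat
  )
}

#' Do two 95% credible intervals overlap?
#'
#' Closed-interval overlap test used as the significance rule throughout:
#' a difference is called significant when the two 95% BCIs do not overlap.
#' Touching endpoints count as overlapping.
#'
#' @param a,b Either one-row data frames with columns `q2.5` and `q97.5`
#'   (as returned by [summarise_draws()]) or length-2 numeric vectors
#'   `c(lower, upper)`.
#' @return Logical: `TRUE` if the intervals overlap.
#' @export
bci_overlap <- function(a, b) {
  iv <- function(x) {
    if (is.data.frame(x)) c(x$q2.5[1], x$q97.5[1]) else as.numeric(x[1:2])
  }
  a <- iv(a); b <- iv(b)
  stopifnot(a[1] <= a[2], b[1] <= b[2])
  a[1] <= b[2] && b[1] <= a[2]
}
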