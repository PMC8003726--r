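test_that("transition_prob selects persistence or colonization by state", {
  expect_equal(transition_prob(1, 0.55, 0.09), 0.55)
  expect_equal(transition_prob(0, 0.55, 0.09), 0.09)
  # symmetric case: identical rates make the state irrelevant
  expect_equal(transition_prob(0, 0.3, 0.3), transition_prob(1, 0.3, 0.3))
  expect_error(transition_prob(2, 0.5, 0.5), "0 or 1")
  expect_error(transition_prob(1, 1.5, 0.5), "\\[0, 1\\]")
})

test_that("occupancy recursion has the mixture form and its fixed point", {
  expect_equal(occupancy_recursion(0.5, 1, 0), 0.5)   # absorbing persistence
  expect_equal(occupancy_recursion(0, 0.9, 0.2), 0.2) # pure colonization
  # iterating converges to gamma / (gamma + 1 - phi) for any start
  for (seed in 1:20) {
    set.seed(seed)
    phi <- runif(1, 0, 0.99); gamma <- runif(1); psi <- runif(1)
    for (i in 1:500) psi <- occupancy_recursion(psi, phi, gamma)
    expect_equal(psi, gamma / (gamma + 1 - phi), tolerance = 1e-6)
    expect_gte(psi, 0); expect_lte(psi, 1)
  }
})

test_that("detection log-likelihood matches binomial arithmetic and the z = 0 convention", {
  expect_equal(detection_loglik(0, 11, 0.3, 0), 0)
  expect_equal(detection_loglik(1, 11, 0.3, 0), -Inf)
  expect_equal(detection_loglik(2, 5, 0.3, 1), log(choose(5, 2) * 0.3^2 * 0.7^3))
  expect_error(detection_loglik(6, 5, 0.3, 1), "y <= k")
})

test_that("forward history probability equals exhaustive path enumeration", {
  enumerate_prob <- function(y, k, psi1, phi, gamma, p) {
    T <- length(y)
    paths <- as.matrix(expand.grid(rep(list(0:1), T)))
    sum(apply(paths, 1, function(z) {
      pr <- if (z[1] == 1) psi1 else 1 - psi1
      if (T > 1) for (t in 2:T) {
        pi_t <- if (z[t - 1] == 1) phi[t - 1] else gamma[t - 1]
        pr <- pr * (if (z[t] == 1) pi_t else 1 - pi_t)
      }
      for (t in 1:T) {
        pr <- pr * (if (z[t] == 1) dbinom(y[t], k[t], p[t]) else as.numeric(y[t] == 0))
      }
      pr
    }))
  }
  # T = 1 closed form
  expect_equal(forward_history_prob(2, 5, 0.4, numeric(0), numeric(0), 0.3),
               0.4 * dbinom(2, 5, 0.3))
  expect_equal(forward_history_prob(0, 5, 0.4, numeric(0), numeric(0), 0.3),
               0.4 * dbinom(0, 5, 0.3) + 0.6)
  # certain detection makes an all-zero history impossible
  expect_equal(forward_history_prob(0, 1, 1, 1, 0, 1), 0)
  # exhaustive grid: all y-configurations with T <= 3, k <= 3
  set.seed(42)
  for (rep in 1:10) {
    T <- sample(2:3, 1); k <- sample(1:3, T, replace = TRUE)
    psi1 <- runif(1); p <- runif(T)
    phi <- runif(T - 1); gamma <- runif(T - 1)
    grid <- expand.grid(lapply(k, function(kk) 0:kk))
    tot <- 0
    for (r in seq_len(nrow(grid))) {
      y <- as.integer(grid[r, ])
      fp <- forward_history_prob(y, k, psi1, phi, gamma, p)
      expect_equal(fp, enumerate_prob(y, k, psi1, phi, gamma, p),
                   tolerance = 1e-12)
      tot <- tot + fp
    }
    expect_equal(tot, 1, tolerance = 1e-12) # probabilities sum to one
  }
})

test_that("FFBS draws match the enumerated full-conditional state distribution", {
  y <- c(0L, 0L, 1L); k <- c(2L, 2L, 2L)
  psi1 <- 0.35; phi <- c(0.7, 0.6); gamma <- c(0.15, 0.25); p <- c(0.4, 0.4, 0.4)
  # exact joint over the 2^3 paths
  paths <- as.matrix(expand.grid(rep(list(0:1), 3)))
  w <- apply(paths, 1, function(z) {
    pr <- if (z[1] == 1) psi1 else 1 - psi1
    for (t in 2:3) {
      pi_t <- if (z[t - 1] == 1) phi[t - 1] else gamma[t - 1]
      pr <- pr * (if (z[t] == 1) pi_t else 1 - pi_t)
    }
    for (t in 1:3) pr <- pr * (if (z[t] == 1) dbinom(y[t], k[t], p[t]) else as.numeric(y[t] == 0))
    pr
  })
  exact <- colSums(paths * w) / sum(w)
  set.seed(99)
  n <- 20000
  draws <- t(replicate(n, ffbs_sample_states(y, k, psi1, phi, gamma, p)))
  expect_true(all(draws[, 3] == 1)) # detection forces occupancy
  freq <- colMeans(draws)
  se <- sqrt(exact * (1 - exact) / n)
  expect_true(all(abs(freq - exact) < 3 * se + 1e-8))
})

test_that("FFBS reproduces prior chain marginals when data are uninformative", {
  set.seed(5)
  psi1 <- 0.4; phi <- 0.8; gamma <- 0.1
  n <- 20000
  draws <- t(replicate(n, ffbs_sample_states(c(0L, 0L), c(3L, 3L), psi1, phi, gamma, 0)))
  prior2 <- psi1 * phi + (1 - psi1) * gamma
  expect_lt(abs(mean(draws[, 1]) - psi1), 3 * sqrt(psi1 * (1 - psi1) / n))
  expect_lt(abs(mean(draws[, 2]) - prior2), 3 * sqrt(prior2 * (1 - prior2) / n))
})

test_that("Metropolis logit update targets the correct posterior", {
  # flat likelihood: long-run mean equals the prior mean
  set.seed(1)
  x <- 0; acc <- 0; xs <- numeric(4000)
  for (i in seq_along(xs)) {
    st <- mh_update_logit(x, function(v) 0, prior_mean = 1.5, prior_sd = 0.8,
                          proposal_sd = 1)
    x <- st$value; acc <- acc + st$accepted; xs[i] <- x
  }
  expect_lt(abs(mean(xs[-(1:500)]) - 1.5), 0.1)
  # conjugate Normal x Normal target: posterior moments match closed form
  set.seed(2)
  obs_mean <- 2; obs_sd <- 0.5; pr_mean <- 0; pr_sd <- 1
  post_var <- 1 / (1 / obs_sd^2 + 1 / pr_sd^2)
  post_mean <- post_var * obs_mean / obs_sd^2
  x <- 0; xs <- numeric(30000)
  for (i in seq_along(xs)) {
    st <- mh_update_logit(x, function(v) dnorm(v, obs_mean, obs_sd, log = TRUE),
                          pr_mean, pr_sd, proposal_sd = 0.8)
    x <- st$value; xs[i] <- x
  }
  xs <- xs[-(1:2000)]
  expect_lt(abs(mean(xs) - post_mean), 3 * sd(xs) / sqrt(length(xs) / 10))
  expect_equal(var(xs), post_var, tolerance = 0.1)
  # vanishing proposal freezes the chain with near-certain acceptance
  set.seed(3)
  frozen <- vapply(1:200, function(i) {
    mh_update_logit(0.7, function(v) 0, 0, 1, proposal_sd = 1e-8)$accepted
  }, logical(1))
  expect_gt(mean(frozen), 0.99)
})

test_that("hyperparameter Gibbs update recovers simulated truth", {
  set.seed(4)
  effects <- rnorm(10000, 1.2, 0.7)
  mus <- numeric(200); sigmas <- numeric(200); sg <- 1
  for (i in 1:200) {
    up <- update_hyperparams(effects, sigma = sg)
    mus[i] <- up$mu; sg <- up$sigma; sigmas[i] <- sg
  }
  expect_equal(mean(mus), 1.2, tolerance = 0.05)
  expect_equal(mean(sigmas), 0.7, tolerance = 0.05)
  # single effect: conjugate mean shrinks by sigma^2/(sigma^2 + tau^2)
  set.seed(6)
  one <- replicate(3000, update_hyperparams(3, sigma = 1)$mu)
  expect_equal(mean(one), 3 * 100 / 101, tolerance = 3 * 1 / sqrt(3000) + 0.02)
})

test_that("Gelman-Rubin diagnostic behaves at its limits and matches coda", {
  set.seed(7)
  same <- matrix(rnorm(4000), 2000, 2)
  expect_lt(gelman_rubin(same), 1.05)
  ident <- cbind(1:2000, 1:2000)
  expect_equal(gelman_rubin(ident), 1, tolerance = 1e-3)
  apart <- cbind(rnorm(500), rnorm(500) + 10)
  expect_gt(gelman_rubin(apart), 1.1)
  expect_error(gelman_rubin(matrix(1:10, ncol = 1)), "2 chains")
  skip_if_not_installed("coda")
  ml <- coda::mcmc.list(coda::mcmc(same[, 1]), coda::mcmc(same[, 2]))
  cd <- unname(coda::gelman.diag(ml, autoburnin = FALSE)$psrf[1, 1])
  expect_equal(gelman_rubin(same), cd, tolerance = 0.01)
})

test_that("draw summaries report mean, median, central 95% interval", {
  expect_equal(summarise_draws(c(1, 2, 3))$median, 2)
  s <- summarise_draws(rep(4.2, 50))
  expect_equal(unlist(s[c("mean", "median", "q2.5", "q97.5")]),
               c(mean = 4.2, median = 4.2, q2.5 = 4.2, q97.5 = 4.2))
  set.seed(8)
  u <- runif(1e6)
  su <- summarise_draws(u)
  expect_lt(abs(su$q2.5 - 0.025), 0.001)
  expect_lt(abs(su$q97.5 - 0.975), 0.001)
  # quantiles commute with monotone transforms (odd length: exact order stat)
  x <- rnorm(1001)
  expect_equal(summarise_draws(exp(x))$median, exp(summarise_draws(x)$median))
})

test_that("credible-interval overlap implements the closed-interval rule", {
  # the community colonization vs persistence intervals are disjoint
  expect_false(bci_overlap(c(0.03, 0.24), c(0.36, 0.72)))
  expect_true(bci_overlap(c(0.1, 0.5), c(0.1, 0.5)))
  expect_true(bci_overlap(c(0.1, 0.3), c(0.3, 0.6))) # touching endpoints
  a <- summarise_draws(runif(100)); expect_true(bci_overlap(a, a))
})
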