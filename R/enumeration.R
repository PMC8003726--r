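# Exact posterior computation for tiny augmented-community instances by
# brute-force enumeration. Independent of the MCMC code path: latent-state
# marginals come from explicit sums over all 2^T occupancy paths, and the
# membership posterior integrates Omega analytically under its Uniform
# prior. Feasible only for a handful of species, cameras and seasons; used
# as the oracle the sampler is checked against.

# P(y_1..T) and P(z_t = 1 | y) for one site by summing over all 2^T paths.
enumerate_site <- function(y, k, psi1, phi, gamma, p) {
  T <- length(y)
  p <- rep_len(p, T)
  if (T > 1) {
    phi <- rep_len(phi, T - 1)
    gamma <- rep_len(gamma, T - 1)
  }
  paths <- as.matrix(expand.grid(rep(list(0:1), T)))
  w <- apply(paths, 1, function(z) {
    pr <- if (z[1] == 1) psi1 else 1 - psi1
    if (T > 1) {
      for (t in 2:T) {
        pi_t <- transition_prob(z[t - 1], phi[t - 1], gamma[t - 1])
        pr <- pr * (if (z[t] == 1) pi_t else 1 - pi_t)
      }
    }
    for (t in seq_len(T)) {
      pr <- pr * if (z[t] == 1) stats::dbinom(y[t], k[t], p[t]) else (y[t] == 0)
    }
    pr
  })
  list(prob = sum(w),
       z_marg = vapply(seq_len(T), function(t) sum(w[paths[, t] == 1]) / sum(w),
                       numeric(1)))
}

#' Exact posterior for a tiny augmented community by enumeration
#'
#' Computes, with species effects held fixed, the exact joint posterior
#' over membership indicators and latent occupancy states for an augmented
#' detection tensor, integrating the membership probability Omega
#' analytically under its Uniform(0,1) prior. Enumerates all membership
#' vectors (detected species are forced members) and all occupancy paths,
#' so it is feasible only for a few species slots and seasons.
#'
#' @param tensor An augmented `occu_tensor` (a handful of species slots).
#' @param params List of species-level probability-scale parameters:
#'   `psi1` (length M), `p` (M x T), `phi`, `gamma` (M x T-1).
#' @return List: `p_member` (exact P(omega_i = 1)), `e_Omega`, `e_N`,
#'   `z_marginal` (M x J x T array of P(z = 1)), and `p_richness_year`
#'   (exact expected per-season richness).
#' @export
enumerate_community_posterior <- function(tensor, params) {
  Y <- tensor$Y
  K <- tensor$K
  M <- dim(Y)[1]; J <- dim(Y)[2]; T <- dim(Y)[3]
  if (M > 12) stop("enumeration is exponential in M; use fewer species slots")
  detected <- apply(Y, 1, sum) > 0

  # per species: marginal likelihood given membership, and z smoothing
  L1 <- numeric(M)
  zmarg <- array(0, c(M, J, T))
  # per-season P(species present at >= 1 camera | member): needs the joint
  # over cameras, but cameras are independent given membership.
  pr_any <- matrix(0, M, T)
  for (i in seq_len(M)) {
    li <- 1
    absent_all <- rep(1, T)
    for (j in seq_len(J)) {
      es <- enumerate_site(Y[i, j, ], K[j, ], params$psi1[i],
                           params$phi[i, ], params$gamma[i, ], params$p[i, ])
      li <- li * es$prob
      zmarg[i, j, ] <- es$z_marg
      absent_all <- absent_all * (1 - es$z_marg)
    }
    L1[i] <- li
    pr_any[i, ] <- 1 - absent_all
  }
  L0 <- ifelse(detected, 0, 1)  # all-zero history is certain for a non-member

  free <- which(!detected)
  n_free <- length(free)
  subsets <- if (n_free > 0) {
    as.matrix(expand.grid(rep(list(0:1), n_free)))
  } else {
    matrix(0L, 1, 0)
  }
  weights <- numeric(nrow(subsets))
  s_base <- sum(detected)
  lik_base <- prod(L1[detected])
  for (r in seq_len(nrow(subsets))) {
    om <- subsets[r, ]
    s <- s_base + sum(om)
    lik <- lik_base
    for (q in seq_len(n_free)) {
      lik <- lik * if (om[q] == 1) L1[free[q]] else L0[free[q]]
    }
    # integral of Omega^s (1-Omega)^(M-s) dOmega under Uniform prior
    weights[r] <- lik * beta(1 + s, 1 + M - s)
  }
  wsum <- sum(weights)
  p_member <- as.numeric(detected)
  for (q in seq_len(n_free)) {
    p_member[free[q]] <- sum(weights[subsets[, q] == 1]) / wsum
  }
  s_vec <- s_base + if (n_free > 0) rowSums(subsets) else 0
  e_Omega <- sum(weights * (1 + s_vec) / (2 + M)) / wsum
  e_N <- sum(weights * s_vec) / wsum
  # z is independent of the other species given omega_i
  z_post <- zmarg * array(rep(p_member, J * T), c(M, J, T))
  e_rich <- colSums(pr_any * p_member)
  list(p_member = p_member, e_Omega = e_Omega, e_N = e_N,
       z_marginal = z_post, e_richness_year = e_rich)
}
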