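#' MCMC configuration
#'
#' Settings for the Metropolis-within-Gibbs samplers. The defaults mirror
#' the full analysis schedule (3 chains, 50,000 iterations retained after
#' 5,000 burn-in, thinning every 10 draws); tests and examples use much
#' shorter schedules.
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Post-burn-in iterations per chain (before thinning).
#' @param n_burnin Burn-in iterations discarded (proposal SDs adapt only
#'   during burn-in).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Base RNG seed; chain c uses `seed + c - 1`.
#' @param proposal_sd Initial random-walk proposal SD for logit updates.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 50000, n_burnin = 5000,
                        thin = 10, seed = 1, proposal_sd = 0.5) {
  stopifnot(n_chains >= 1, n_iter >= 1, n_burnin >= 0, thin >= 1,
            proposal_sd > 0)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), proposal_sd = proposal_sd),
            class = "mcmc_config")
}

hyper_param_names <- function(n_years, year_specific) {
  nTr <- n_years - 1
  pn <- if (year_specific) sprintf("p[%d]", seq_len(n_years)) else "p"
  gn <- if (n_years > 1) {
    if (year_specific) sprintf("gamma[%d]", seq_len(nTr)) else "gamma"
  } else character()
  fn <- if (n_years > 1) {
    if (year_specific) sprintf("phi[%d]", seq_len(nTr)) else "phi"
  } else character()
  c("mu_psi1", "sigma_psi1",
    as.vector(rbind(paste0("mu_", pn), paste0("sigma_", pn))),
    as.vector(rbind(paste0("mu_", gn), paste0("sigma_", gn))),
    as.vector(rbind(paste0("mu_", fn), paste0("sigma_", fn))))
}

#' Fit the data-augmented multi-species multi-season occupancy model
#'
#' Full MCMC over latent occupancy states z (exact FFBS per species and
#' camera), community-membership indicators, the membership probability
#' Omega (conjugate Beta under a Uniform(0,1) prior), species-level logit
#' intercepts (random-walk Metropolis) and the logit-normal hyperparameters
#' (conjugate mean, slice-sampled SD under Uniform(0, `sigma_max`)).
#' Detections force occupancy and membership in every retained draw.
#'
#' @param tensor An augmented `occu_tensor` (see [augment_tensor()]).
#' @param config An [mcmc_config()].
#' @param year_specific Use season-specific hyper-means/SDs for detection
#'   and transition-specific ones for colonization and persistence
#'   (default); `FALSE` pools each family across seasons.
#' @param mu_prior_sd SD of the Normal(0, .) hyperprior on hyper-means.
#' @param sigma_max Upper bound of the Uniform hyperprior on hyper-SDs.
#' @param fix_effects Optional list with elements `b0` (length M), `a`
#'   (M x T), `c`, `d` (M x T-1) of logit-scale species effects to hold
#'   fixed (effect and hyper updates are skipped). Used to validate the
#'   latent-state machinery against exact enumeration.
#' @param save_effects Keep species-effect draws (needed for species-level
#'   rate summaries).
#' @param save_z Keep full latent-state draws (memory-heavy; tiny
#'   instances only).
#' @return An object of class `community_fit`.
#' @export
fit_community <- function(tensor, config = mcmc_config(),
                          year_specific = TRUE, mu_prior_sd = 10,
                          sigma_max = 5, fix_effects = NULL,
                          save_effects = TRUE, save_z = FALSE) {
  stopifnot(inherits(tensor, "occu_tensor"), inherits(config, "mcmc_config"))
  M <- length(tensor$species)
  J <- length(tensor$cameras)
  T <- length(tensor$years)
  Y <- tensor$Y
  storage.mode(Y) <- "integer"
  K <- tensor$K
  storage.mode(K) <- "integer"
  fixed <- fix_effects
  if (is.null(fixed)) {
    fixed <- list(b0 = numeric(M), a = matrix(0, M, T),
                  c = matrix(0, M, max(T - 1, 1)),
                  d = matrix(0, M, max(T - 1, 1)))
  }
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    chains[[ch]] <- community_mcmc_cpp(
      Y, K, M - tensor$n_aug,
      config$n_iter + config$n_burnin, config$n_burnin, config$thin,
      year_specific, mu_prior_sd, sigma_max, config$proposal_sd,
      !is.null(fix_effects), fixed, save_effects, save_z
    )
    colnames(chains[[ch]]$hyper) <- hyper_param_names(T, year_specific)
  }
  structure(
    list(chains = chains, config = config, year_specific = year_specific,
         species = tensor$species, n_aug = tensor$n_aug,
         n_obs = M - tensor$n_aug, cameras = tensor$cameras,
         years = tensor$years,
         observed_by_year = apply(tensor$Y > 0, 3, function(m) sum(rowSums(m) > 0)),
         observed_total = sum(apply(tensor$Y, 1, sum) > 0),
         fixed_effects = !is.null(fix_effects),
         save_effects = save_effects, save_z = save_z),
    class = "community_fit"
  )
}

# iterations x chains matrix for a scalar quantity of the fit
chain_matrix <- function(fit, extract) {
  do.call(cbind, lapply(fit$chains, extract))
}

#' Posterior summary of total community richness
#'
#' Total (superpopulation) richness per draw is the number of species slots
#' flagged as community members, N = sum of the membership indicators.
#'
#' @param fit A `community_fit`.
#' @return One-row tibble (mean, median, 95% BCI, rhat).
#' @export
derive_total_richness <- function(fit) {
  m <- chain_matrix(fit, function(ch) ch$N)
  out <- summarise_draws(m)
  out$observed <- fit$observed_total
  out
}

#' Posterior summary of per-season species richness
#'
#' Richness in season t for one draw counts the species that are community
#' members and occupy at least one analysed camera in that season. Every
#' draw is bounded below by the number of species actually detected that
#' season.
#'
#' @param fit A `community_fit`.
#' @return Tibble with one row per season.
#' @export
derive_yearly_richness <- function(fit) {
  T <- length(fit$years)
  purrr::map_dfr(seq_len(T), function(t) {
    m <- chain_matrix(fit, function(ch) ch$richness[, t])
    out <- summarise_draws(m)
    out$year <- fit$years[t]
    out$observed <- fit$observed_by_year[t]
    dplyr::relocate(out, "year")
  })
}

#' Posterior summary of the membership probability Omega
#' @param fit A `community_fit`.
#' @return One-row tibble.
#' @export
derive_omega <- function(fit) {
  summarise_draws(chain_matrix(fit, function(ch) ch$Omega))
}

#' Community colonization and persistence rates per transition
#'
#' The community rate for a transition is the inverse-logit of the
#' colonization (or persistence) hyper-mean, summarised over draws
#' (`type = "hypermean"`, the headline summary). Alternatively
#' (`type = "species_mean"`) the per-draw average of the species-level
#' rates over current community members. A significance flag marks
#' transitions where the colonization and persistence 95% BCIs do not
#' overlap.
#'
#' @param fit A `community_fit`.
#' @param type `"hypermean"` or `"species_mean"`.
#' @return Tibble with one row per parameter x transition, plus a
#'   `significant` flag (colonization vs persistence non-overlap).
#' @export
derive_community_rates <- function(fit, type = c("hypermean", "species_mean")) {
  type <- match.arg(type)
  T <- length(fit$years)
  if (T < 2) stop("rates need at least two seasons", call. = FALSE)
  nTr <- T - 1
  M <- length(fit$species)
  one <- function(param, tr) {
    if (type == "hypermean") {
      nm <- if (fit$year_specific) sprintf("mu_%s[%d]", param, tr) else paste0("mu_", param)
      m <- ilogit(chain_matrix(fit, function(ch) ch$hyper[, nm]))
    } else {
      if (!fit$save_effects) stop("fit was run with save_effects = FALSE", call. = FALSE)
      el <- if (param == "gamma") "c" else "d"
      m <- chain_matrix(fit, function(ch) {
        eff <- ilogit(ch[[el]][, (tr - 1) * M + seq_len(M), drop = FALSE])
        rowSums(eff * ch$omega) / rowSums(ch$omega)
      })
    }
    out <- summarise_draws(m)
    out$parameter <- if (param == "gamma") "colonization" else "persistence"
    out$transition <- tr
    dplyr::relocate(out, "parameter", "transition")
  }
  res <- purrr::map_dfr(seq_len(nTr), function(tr) {
    dplyr::bind_rows(one("gamma", tr), one("phi", tr))
  })
  res$significant <- purrr::map_lgl(seq_len(nrow(res)), function(r) {
    pair <- res[res$transition == res$transition[r], ]
    !bci_overlap(pair[pair$parameter == "colonization", ],
                 pair[pair$parameter == "persistence", ])
  })
  res
}

#' Posterior membership probability per species slot
#' @param fit A `community_fit`.
#' @return Tibble: species, P(member), detected flag.
#' @export
membership_probabilities <- function(fit) {
  m <- do.call(rbind, lapply(fit$chains, function(ch) ch$omega))
  tibble::tibble(
    species = fit$species,
    p_member = colMeans(m),
    augmented = seq_along(fit$species) > fit$n_obs
  )
}

#' @export
print.community_fit <- function(x, ...) {
  cat("<community_fit> ", x$n_obs, " observed species + ", x$n_aug,
      " augmented, ", length(x$cameras), " cameras, ", length(x$years),
      " seasons\n", sep = "")
  cat(x$config$n_chains, " chains x ",
      nrow(x$chains[[1]]$hyper), " retained draws\n", sep = "")
  tr <- derive_total_richness(x)
  cat(sprintf("total richness: median %g (95%% BCI %g-%g)\n",
              tr$median, tr$q2.5, tr$q97.5))
  invisible(x)
}

#' Tidy posterior summaries of a community fit
#'
#' Broom-style one-row-per-parameter summary: richness per season, total
#' richness, Omega, and colonization/persistence rates per transition.
#'
#' @param x A `community_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (posterior median),
#'   `mean`, `conf.low`, `conf.high` (95% BCI) and `rhat`.
#' @export
tidy.community_fit <- function(x, ...) {
  yr <- derive_yearly_richness(x)
  rates <- if (length(x$years) > 1) derive_community_rates(x) else NULL
  rows <- dplyr::bind_rows(
    dplyr::mutate(yr, term = paste0("richness[", .data$year, "]")),
    dplyr::mutate(derive_total_richness(x), term = "richness_total"),
    dplyr::mutate(derive_omega(x), term = "Omega"),
    if (!is.null(rates)) {
      dplyr::mutate(rates, term = paste0(.data$parameter, "[", .data$transition, "]"))
    }
  )
  tibble::tibble(term = rows$term, estimate = rows$median, mean = rows$mean,
                 conf.low = rows$q2.5, conf.high = rows$q97.5,
                 rhat = rows$rhat)
}

#' One-line model summary
#' @param x A `community_fit`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, draw counts, richness median,
#'   worst rhat.
#' @export
glance.community_fit <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_species_observed = x$n_obs, n_aug = x$n_aug,
    n_cameras = length(x$cameras), n_seasons = length(x$years),
    n_chains = x$config$n_chains,
    n_draws = nrow(x$chains[[1]]$hyper) * x$config$n_chains,
    richness_total = td$estimate[td$term == "richness_total"],
    max_rhat = max(td$rhat, na.rm = TRUE)
  )
}

#' Plot posterior species richness per season
#'
#' @param object A `community_fit`.
#' @param ... Unused.
#' @return A ggplot: posterior median and 95% BCI per season, with the
#'   observed species count overlaid.
#' @export
autoplot.community_fit <- function(object, ...) {
  yr <- derive_yearly_richness(object)
  yr$year <- factor(yr$year)
  ggplot2::ggplot(yr, ggplot2::aes(x = .data$year, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), shape = 4, size = 3) +
    ggplot2::labs(x = "season", y = "species richness",
                  caption = "point-interval: posterior median and 95% BCI; x: observed") +
    ggplot2::theme_minimal()
}
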