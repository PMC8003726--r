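#' Species eligible for single-species modelling
#'
#' A species qualifies when its total detection count reaches `min_det` in
#' BOTH areas (the threshold below which dynamic occupancy fits are not
#' considered reliable). Detections are counted at the occasion level (sum
#' of Y over cameras and seasons); pass pre-computed totals (e.g. raw
#' video counts) through `totals_a` / `totals_b` to use a different
#' counting rule.
#'
#' @param tensor_a,tensor_b `occu_tensor` objects for the two areas.
#' @param min_det Minimum detections required in each area (default 10).
#' @param totals_a,totals_b Optional named vectors of per-species totals
#'   overriding the occasion-level counts.
#' @return Character vector of qualifying species (sorted).
#' @export
eligible_species <- function(tensor_a, tensor_b, min_det = 10,
                             totals_a = NULL, totals_b = NULL) {
  ta <- totals_a %||% species_detection_totals(tensor_a)
  tb <- totals_b %||% species_detection_totals(tensor_b)
  universe <- union(names(ta), names(tb))
  ca <- ifelse(universe %in% names(ta), ta[universe], 0)
  cb <- ifelse(universe %in% names(tb), tb[universe], 0)
  sort(universe[ca >= min_det & cb >= min_det])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a single-species multi-season occupancy model
#'
#' Dynamic (multi-season) occupancy for one species: scalar initial
#' occupancy psi1 and per-transition persistence/colonization with
#' Uniform(0,1) priors (conjugate Beta updates given the latent states),
#' and detection with site-level random logit intercepts
#' (logit p_j = a_j0 ~ N(alpha0, sigma_a0^2)). Latent states are sampled
#' exactly by FFBS; reported detection is the inverse-logit of the
#' detection hyper-mean, and season-2/3 occupancy follows the recursion
#' psi_{t+1} = psi_t phi_t + (1 - psi_t) gamma_t applied draw by draw.
#' (Site random intercepts on initial occupancy are deliberately not
#' fitted: one Bernoulli realization per site cannot identify their SD,
#' which then drifts over its prior and biases the reported occupancy.)
#'
#' The tensor must have equal effort across seasons within each camera;
#' if not it is truncated with [truncate_to_common_occasions()] first.
#'
#' @param tensor An `occu_tensor` containing the species (typically the
#'   full-series, common-occasion tensor for one area).
#' @param species Species name to fit (must have at least one detection).
#' @param config An [mcmc_config()].
#' @param mu_prior_sd SD of the Normal(0, .) priors on hyper-means and on
#'   the transition logits.
#' @param sigma_max Upper bound of the Uniform prior on the site-effect
#'   SDs.
#' @return An object of class `species_fit`.
#' @export
fit_species <- function(tensor, species, config = mcmc_config(),
                        mu_prior_sd = 10, sigma_max = 5) {
  stopifnot(inherits(tensor, "occu_tensor"), inherits(config, "mcmc_config"))
  i <- match(species, tensor$species)
  if (is.na(i)) stop("species not present in the tensor: ", species, call. = FALSE)
  if (any(apply(tensor$K, 1, function(k) length(unique(k)) > 1))) {
    tensor <- truncate_to_common_occasions(tensor)
  }
  y <- tensor$Y[i, , , drop = TRUE]
  if (length(tensor$years) == 1) y <- matrix(y, ncol = 1)
  if (sum(y) == 0) {
    stop("insufficient detections: species has an all-zero history", call. = FALSE)
  }
  K <- tensor$K
  storage.mode(y) <- "integer"; storage.mode(K) <- "integer"
  T <- ncol(y); nTr <- T - 1
  par_names <- c("psi1", "alpha0", "sigma_a0",
                 if (nTr > 0) sprintf("gamma[%d]", seq_len(nTr)),
                 if (nTr > 0) sprintf("phi[%d]", seq_len(nTr)))
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    res <- species_mcmc_cpp(y, K, config$n_iter + config$n_burnin,
                            config$n_burnin, config$thin,
                            mu_prior_sd, sigma_max, config$proposal_sd)
    colnames(res$draws) <- par_names
    chains[[ch]] <- res
  }
  structure(
    list(species = species, chains = chains, config = config,
         years = tensor$years, n_sites = nrow(y),
         n_detections = sum(y)),
    class = "species_fit"
  )
}

# derived probability-scale draws for one chain: psi per season, p,
# gamma/phi per transition
species_derived_draws <- function(draws, T) {
  nTr <- T - 1
  out <- list(p = ilogit(draws[, "alpha0"]))
  psi <- list(draws[, "psi1"])
  gam <- phi <- list()
  for (t in seq_len(nTr)) {
    gam[[t]] <- draws[, sprintf("gamma[%d]", t)]
    phi[[t]] <- draws[, sprintf("phi[%d]", t)]
    psi[[t + 1]] <- psi[[t]] * phi[[t]] + (1 - psi[[t]]) * gam[[t]]
  }
  out$psi <- psi; out$gamma <- gam; out$phi <- phi
  out
}

#' Tidy posterior summaries of a single-species fit
#'
#' @param x A `species_fit`.
#' @param ... Unused.
#' @return Tibble: `species`, `parameter` (`psi`, `p`, `colonization`,
#'   `persistence`), `year` (season or transition index, NA for `p`),
#'   posterior `mean`, `estimate` (median), `conf.low`, `conf.high`,
#'   `rhat`.
#' @export
tidy.species_fit <- function(x, ...) {
  T <- length(x$years)
  der <- lapply(x$chains, function(ch) species_derived_draws(ch$draws, T))
  row_for <- function(parameter, year, extract) {
    m <- do.call(cbind, lapply(der, extract))
    s <- summarise_draws(m)
    tibble::tibble(species = x$species, parameter = parameter, year = year,
                   mean = s$mean, estimate = s$median,
                   conf.low = s$q2.5, conf.high = s$q97.5, rhat = s$rhat)
  }
  dplyr::bind_rows(
    purrr::map_dfr(seq_len(T), function(t) {
      row_for("psi", t, function(d) d$psi[[t]])
    }),
    row_for("p", NA_integer_, function(d) d$p),
    purrr::map_dfr(seq_len(T - 1), function(t) {
      dplyr::bind_rows(
        row_for("colonization", t, function(d) d$gamma[[t]]),
        row_for("persistence", t, function(d) d$phi[[t]])
      )
    })
  )
}

#' One-line summary of a single-species fit
#' @param x A `species_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit dimensions, first-season occupancy and
#'   worst rhat (fits with rhat > 1.1 should be treated as unreliable).
#' @export
glance.species_fit <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    species = x$species, n_sites = x$n_sites, n_seasons = length(x$years),
    n_detections = x$n_detections,
    n_draws = nrow(x$chains[[1]]$draws) * x$config$n_chains,
    psi1 = td$estimate[td$parameter == "psi"][1],
    p = td$estimate[td$parameter == "p"],
    max_rhat = max(td$rhat, na.rm = TRUE),
    converged = max(td$rhat, na.rm = TRUE) <= 1.1
  )
}

#' @export
print.species_fit <- function(x, ...) {
  g <- glance(x)
  cat("<species_fit> ", x$species, ": ", x$n_sites, " sites, ",
      length(x$years), " seasons, ", x$n_detections, " detections\n", sep = "")
  cat(sprintf("psi1 median %.2f, p median %.2f, max rhat %.3f\n",
              g$psi1, g$p, g$max_rhat))
  invisible(x)
}

#' Plot per-season occupancy for a single-species fit
#' @param object A `species_fit`.
#' @param ... Unused.
#' @return A ggplot of the posterior occupancy trajectory with 95% BCIs.
#' @export
autoplot.species_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$parameter == "psi", ]
  ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$year), y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "season", y = "occupancy", title = object$species) +
    ggplot2::theme_minimal()
}

#' Compare a species' parameters between two areas
#'
#' Joins the tidy summaries of two single-species fits and flags
#' parameters whose 95% BCIs do not overlap between areas (the
#' significance rule used throughout).
#'
#' @param fit_a,fit_b `species_fit` objects for the same species in two
#'   areas.
#' @param labels Length-2 character vector of area labels.
#' @return Tibble: parameter, year, per-area median and BCI columns, and a
#'   `significant` flag.
#' @export
compare_species_between_areas <- function(fit_a, fit_b,
                                          labels = c("A", "B")) {
  ta <- tidy(fit_a); tb <- tidy(fit_b)
  j <- dplyr::inner_join(ta, tb, by = c("parameter", "year"),
                         suffix = c("_a", "_b"))
  tibble::tibble(
    species = fit_a$species,
    parameter = j$parameter, year = j$year,
    !!paste0("median_", labels[1]) := j$estimate_a,
    !!paste0("bci_", labels[1]) := sprintf("%s-%s", fmt2(j$conf.low_a), fmt2(j$conf.high_a)),
    !!paste0("median_", labels[2]) := j$estimate_b,
    !!paste0("bci_", labels[2]) := sprintf("%s-%s", fmt2(j$conf.low_b), fmt2(j$conf.high_b)),
    significant = !purrr::map_lgl(seq_len(nrow(j)), function(r) {
      bci_overlap(c(j$conf.low_a[r], j$conf.high_a[r]),
                  c(j$conf.low_b[r], j$conf.high_b[r]))
    })
  )
}

# two decimals, half away from zero (the printed-precision convention)
fmt2 <- function(x) sprintf("%.2f", round_half_up(x, 2))

#' Round half away from zero
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values; exact halves move away from zero (so 0.5 -> 1),
#'   unlike base [round()]'s round-half-even.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
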