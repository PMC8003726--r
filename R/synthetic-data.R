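#' Preset survey scenarios echoing the two-area Myanmar design
#'
#' Generative configurations matching the scale of the two real surveys:
#' "HWS-like" (108 cameras, 3 seasons, 11 five-day occasions, 31 true
#' species) and "RYER-like" (107 cameras, 13 occasions, 26 true species).
#' Hyper-means put detection around 0.13 per occasion, initial occupancy
#' around 0.3, persistence around 0.6 and colonization around 0.1 --
#' modest-detection camera-trap conditions of the kind the surveys report.
#'
#' @param area `"HWS-like"` or `"RYER-like"`.
#' @return A truth-configuration list: `n_species_true`, `J`, `T`, `K`,
#'   `occasion_days`, `n_aug`, `area` and `hyper` (logit-scale means and
#'   SDs for psi1, p, gamma, phi).
#' @export
survey_scenario <- function(area = c("HWS-like", "RYER-like")) {
  area <- match.arg(area)
  hws <- area == "HWS-like"
  list(
    area = area,
    n_species_true = if (hws) 31L else 26L,
    J = if (hws) 108L else 107L,
    T = 3L,
    K = if (hws) 11L else 13L,
    occasion_days = 5L,
    n_aug = 100L,
    hyper = list(
      mu_psi1 = logit(0.3), sigma_psi1 = 1,
      mu_p = logit(0.13), sigma_p = 0.5,
      mu_gamma = logit(0.1), sigma_gamma = 0.5,
      mu_phi = logit(0.6), sigma_phi = 0.5
    )
  )
}

validate_scenario <- function(cfg) {
  stopifnot(cfg$J >= 1, cfg$T >= 1, all(cfg$K >= 1), cfg$occasion_days >= 1,
            cfg$n_species_true >= 1)
  h <- cfg$hyper
  stopifnot(h$sigma_psi1 >= 0, h$sigma_p >= 0, h$sigma_gamma >= 0,
            h$sigma_phi >= 0)
  probs <- ilogit(c(h$mu_psi1, h$mu_p, h$mu_gamma, h$mu_phi))
  stopifnot(all(probs > 0), all(probs < 1))
  invisible(cfg)
}

#' Draw species-level parameters from the logit-normal hyper-distributions
#'
#' Each species gets an initial-occupancy logit, season-specific detection
#' logits, and transition-specific colonization and persistence logits,
#' all Normal around the hyper-means; probability-scale values are their
#' inverse-logits.
#'
#' @param n_species Number of species to draw.
#' @param hyper Hyperparameter list (see [survey_scenario()]).
#' @param n_years Number of seasons T.
#' @return Tibble with one row per species: `species`, `psi1`, `p_1..T`,
#'   `gamma_1..T-1`, `phi_1..T-1`.
#' @export
draw_species_params <- function(n_species, hyper, n_years) {
  n <- n_species; T <- n_years
  out <- tibble::tibble(
    species = sprintf("sp_%03d", seq_len(n)),
    psi1 = ilogit(stats::rnorm(n, hyper$mu_psi1, hyper$sigma_psi1))
  )
  for (t in seq_len(T)) {
    out[[paste0("p_", t)]] <- ilogit(stats::rnorm(n, hyper$mu_p, hyper$sigma_p))
  }
  for (t in seq_len(max(T - 1, 0))) {
    out[[paste0("gamma_", t)]] <- ilogit(stats::rnorm(n, hyper$mu_gamma, hyper$sigma_gamma))
    out[[paste0("phi_", t)]] <- ilogit(stats::rnorm(n, hyper$mu_phi, hyper$sigma_phi))
  }
  out
}

params_matrices <- function(params, T) {
  list(
    psi1 = params$psi1,
    p = as.matrix(params[paste0("p_", seq_len(T))]),
    gamma = if (T > 1) as.matrix(params[paste0("gamma_", seq_len(T - 1))]) else matrix(0, nrow(params), 0),
    phi = if (T > 1) as.matrix(params[paste0("phi_", seq_len(T - 1))]) else matrix(0, nrow(params), 0)
  )
}

#' Simulate latent occupancy states
#'
#' First-season occupancy is Bernoulli(psi1); later seasons follow the
#' Markov dynamics through [transition_prob()], independently per camera.
#'
#' @param params Species-parameter tibble from [draw_species_params()].
#' @param J Number of cameras.
#' @param n_years Number of seasons.
#' @return Integer array z\[species, camera, season\].
#' @export
simulate_latent_states <- function(params, J, n_years) {
  pm <- params_matrices(params, n_years)
  n <- nrow(params)
  z <- array(0L, c(n, J, n_years))
  z[, , 1] <- stats::rbinom(n * J, 1L, rep(pm$psi1, J))
  if (n_years > 1) {
    for (t in 2:n_years) {
      pr <- transition_prob(z[, , t - 1],
                            matrix(pm$phi[, t - 1], n, J),
                            matrix(pm$gamma[, t - 1], n, J))
      z[, , t] <- array(stats::rbinom(n * J, 1L, pr), c(n, J))
    }
  }
  z
}

#' Simulate occasion-level detections and emit a record table
#'
#' Per occupied species-camera-season, each occasion registers a
#' detection independently with the species' seasonal detection
#' probability. One record (video) is emitted per occasion-hit, dated on
#' the first day of its five-day occasion window, so rebuilding the
#' tensor from the records recovers the hits exactly.
#'
#' @param z Latent state array from [simulate_latent_states()].
#' @param params Species-parameter tibble.
#' @param deployments Deployment tibble (one row per camera-season with
#'   `camera_id`, `year`, `start_date`).
#' @param K Occasions per camera-season (scalar).
#' @param occasion_days Days per occasion.
#' @param area Area label stamped on the records.
#' @return List: `records` tibble (species, camera_id, area, date) and the
#'   binary `hits` array \[species, camera, season, occasion\].
#' @export
simulate_detections <- function(z, params, deployments, K, occasion_days = 5,
                                area = "SIM") {
  d <- dim(z)
  n <- d[1]; J <- d[2]; T <- d[3]
  pm <- params_matrices(params, T)
  hits <- array(FALSE, c(n, J, T, K))
  for (t in seq_len(T)) {
    p_occ <- matrix(pm$p[, t], n, J) * z[, , t]
    for (o in seq_len(K)) {
      hits[, , t, o] <- array(stats::rbinom(n * J, 1L, p_occ), c(n, J)) == 1L
    }
  }
  idx <- which(hits, arr.ind = TRUE)
  cam_ids <- sort(unique(deployments$camera_id))
  dep_start <- matrix(deployments$start_date[
    match(paste(rep(cam_ids, T), rep(seq_len(T), each = J)),
          paste(deployments$camera_id, deployments$year))], J, T)
  records <- tibble::tibble(
    species = params$species[idx[, 1]],
    camera_id = cam_ids[idx[, 2]],
    area = area,
    date = as.Date(dep_start[cbind(idx[, 2], idx[, 3])], origin = "1970-01-01") +
      (idx[, 4] - 1L) * occasion_days
  )
  records <- records[order(records$date, records$camera_id, records$species), ]
  list(records = records, hits = hits)
}

#' Simulate a complete camera-trap survey with exported ground truth
#'
#' Draws species parameters from the configured hyper-distributions,
#' simulates latent occupancy and occasion-level detections, and emits
#' the detection-record and deployment tables the ingestion layer
#' consumes, together with the full generative truth.
#'
#' @param config A scenario list from [survey_scenario()] (or a hand-built
#'   one with the same fields).
#' @param seed Optional RNG seed for a reproducible survey.
#' @return List of class `sim_survey`: `records`, `deployments`, `truth`
#'   (species `params`, latent `z`, `hits`, `richness_by_year`,
#'   `total_richness`) and the scenario `config`.
#' @export
simulate_survey <- function(config = survey_scenario("HWS-like"), seed = NULL) {
  validate_scenario(config)
  if (!is.null(seed)) set.seed(seed)
  J <- config$J; T <- config$T; K <- config$K
  params <- draw_species_params(config$n_species_true, config$hyper, T)
  z <- simulate_latent_states(params, J, T)

  cam_ids <- sprintf("cam_%03d", seq_len(J))
  season_starts <- as.Date("2016-11-01") + (seq_len(T) - 1) * 365
  deployments <- tidyr::expand_grid(camera_id = cam_ids, year = seq_len(T))
  deployments$area <- config$area
  deployments$site <- paste0("site_", 1L + (match(deployments$camera_id, cam_ids) - 1L) %/% 30L)
  deployments$start_date <- season_starts[deployments$year]
  deployments$end_date <- deployments$start_date + K * config$occasion_days - 1L
  deployments$active_days <- as.integer(deployments$end_date - deployments$start_date) + 1L

  det <- simulate_detections(z, params, deployments, K, config$occasion_days,
                             config$area)
  truth <- list(
    params = params, z = z, hits = det$hits,
    richness_by_year = apply(z, 3, function(m) sum(rowSums(m) > 0)),
    total_richness = config$n_species_true,
    occasion_hit_totals = apply(det$hits, 1, sum)
  )
  structure(list(records = det$records, deployments = deployments,
                 truth = truth, config = config),
            class = "sim_survey")
}

#' @export
print.sim_survey <- function(x, ...) {
  cat("<sim_survey> ", x$config$area, ": ", x$config$n_species_true,
      " species, ", x$config$J, " cameras, ", x$config$T, " seasons x ",
      x$config$K, " occasions\n", sep = "")
  cat(nrow(x$records), " detection records, ",
      length(unique(x$records$species)), " species detected\n", sep = "")
  invisible(x)
}

#' Write a simulated survey to disk
#'
#' @param survey A `sim_survey`.
#' @param dir Output directory (created if needed): writes
#'   `detections.csv`, `deployments.csv` and `truth.json`.
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "sim_survey"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(survey$records, file.path(dir, "detections.csv"))
  readr::write_csv(survey$deployments[, c("camera_id", "area", "site", "year",
                                          "start_date", "end_date")],
                   file.path(dir, "deployments.csv"))
  jsonlite::write_json(
    list(config = survey$config[setdiff(names(survey$config), "hyper")],
         hyper = survey$config$hyper,
         params = survey$truth$params,
         richness_by_year = survey$truth$richness_by_year,
         total_richness = survey$truth$total_richness),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
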