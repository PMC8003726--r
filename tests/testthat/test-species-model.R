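# simulate one species with constant parameters across sites by zeroing the
# hyper-SDs of a preset scenario
one_species_survey <- function(psi1, p, phi, gamma, J = 100, K = 11, T = 3,
                               seed = 1) {
  cfg <- survey_scenario("HWS-like")
  cfg$J <- as.integer(J); cfg$K <- as.integer(K); cfg$T <- as.integer(T)
  cfg$n_species_true <- 1L
  cfg$hyper <- list(mu_psi1 = logit(psi1), sigma_psi1 = 0,
                    mu_p = logit(p), sigma_p = 0,
                    mu_gamma = logit(gamma), sigma_gamma = 0,
                    mu_phi = logit(phi), sigma_phi = 0)
  simulate_survey(cfg, seed = seed)
}

species_tensor <- function(s) {
  build_detection_tensor(s$records, s$deployments) |>
    restrict_to_full_series() |>
    truncate_to_common_occasions()
}

test_that("eligibility requires the detection threshold in both areas", {
  recA <- make_records(c(rep("x", 10), rep("y", 10), rep("z", 2)),
                       sprintf("c%02d", 1:22), 1, 1)
  recB <- make_records(c(rep("x", 9), rep("y", 10), rep("w", 10)),
                       sprintf("c%02d", 1:29), 1, 1)
  ta <- tensor_from_hits(recA, sprintf("c%02d", 1:30), years = 1, k = 11)
  tb <- tensor_from_hits(recB, sprintf("c%02d", 1:30), years = 1, k = 11)
  # x: 10 in A but 9 in B -> excluded; y: 10 and 10 -> included
  expect_equal(eligible_species(ta, tb, min_det = 10), "y")
  # a zero threshold degenerates to the union of both species lists
  expect_equal(eligible_species(ta, tb, 0), sort(c("w", "x", "y", "z")))
  # species present in only one area never qualify at a positive threshold
  expect_false("w" %in% eligible_species(ta, tb, 1))
  expect_false("z" %in% eligible_species(ta, tb, 1))
  # monotone: raising the threshold never adds species
  for (m in c(0, 2, 5, 9, 10, 11)) {
    expect_true(all(eligible_species(ta, tb, m + 1) %in%
                    eligible_species(ta, tb, m)))
  }
})

test_that("single-species fits are reproducible and refuse empty histories", {
  s <- one_species_survey(0.5, 0.3, 0.7, 0.1, J = 30, seed = 5)
  tens <- species_tensor(s)
  cfg <- mcmc_config(n_chains = 2, n_iter = 500, n_burnin = 200, thin = 2,
                     seed = 9)
  f1 <- fit_species(tens, tens$species[1], cfg)
  f2 <- fit_species(tens, tens$species[1], cfg)
  expect_identical(f1$chains[[1]]$draws, f2$chains[[1]]$draws)
  expect_identical(tidy(f1), tidy(f2))
  expect_error(fit_species(tens, "nope", cfg), "not present")
  # an all-zero species history is refused
  aug <- augment_tensor(tens, 1)
  expect_error(fit_species(aug, "aug_001", cfg), "insufficient detections")
})

test_that("perfect detection pins occupancy at the occupied fraction", {
  s <- one_species_survey(0.6, 0.999, 0.8, 0.1, J = 100, seed = 6)
  tens <- species_tensor(s)
  frac <- mean(s$truth$z[1, , 1])
  fit <- fit_species(tens, tens$species[1],
                     mcmc_config(n_chains = 2, n_iter = 1500, n_burnin = 500,
                                 thin = 2, seed = 10))
  td <- tidy(fit)
  psi1 <- td[td$parameter == "psi" & td$year == 1, ]
  expect_lt(abs(psi1$estimate - frac), 0.12)
  expect_gt(td$estimate[td$parameter == "p"], 0.95)
})

test_that("later-season occupancy equals the recursion applied draw by draw", {
  s <- one_species_survey(0.7, 0.4, 0.8, 0.1, J = 60, seed = 7)
  tens <- species_tensor(s)
  fit <- fit_species(tens, tens$species[1],
                     mcmc_config(n_chains = 2, n_iter = 600, n_burnin = 200,
                                 thin = 2, seed = 11))
  d <- fit$chains[[1]]$draws
  psi1 <- d[, "psi1"]
  psi2 <- occupancy_recursion(psi1, d[, "phi[1]"], d[, "gamma[1]"])
  psi3 <- occupancy_recursion(psi2, d[, "phi[2]"], d[, "gamma[2]"])
  der <- occomm:::species_derived_draws(d, 3)
  expect_equal(der$psi[[2]], psi2)
  expect_equal(der$psi[[3]], psi3)
  td <- tidy(fit)
  expect_true(all(td$estimate >= 0 & td$estimate <= 1))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("between-area comparison flags exactly the non-overlapping parameters", {
  sA <- one_species_survey(0.75, 0.5, 0.8, 0.1, J = 80, seed = 8)
  sB <- one_species_survey(0.15, 0.5, 0.8, 0.1, J = 80, seed = 9)
  cfg <- mcmc_config(n_chains = 2, n_iter = 1000, n_burnin = 300, thin = 2,
                     seed = 12)
  tA <- species_tensor(sA); tB <- species_tensor(sB)
  fA <- fit_species(tA, tA$species[1], cfg)
  fB <- fit_species(tB, tB$species[1], cfg)
  cmp <- compare_species_between_areas(fA, fB, labels = c("HWS", "RYER"))
  expect_true(all(c("median_HWS", "median_RYER", "significant") %in% names(cmp)))
  # strongly separated first-season occupancy must be flagged
  expect_true(cmp$significant[cmp$parameter == "psi" & cmp$year == 1])
  # a fit compared with itself is never significant
  self <- compare_species_between_areas(fA, fA)
  expect_false(any(self$significant))
  # manual overlap check matches the table's flag for every row
  ta <- tidy(fA); tb <- tidy(fB)
  j <- dplyr::inner_join(ta, tb, by = c("parameter", "year"), suffix = c("_a", "_b"))
  manual <- !mapply(function(l1, u1, l2, u2) bci_overlap(c(l1, u1), c(l2, u2)),
                    j$conf.low_a, j$conf.high_a, j$conf.low_b, j$conf.high_b)
  expect_equal(cmp$significant, unname(manual))
})

test_that("humans run through the identical single-species machinery", {
  s <- one_species_survey(0.5, 0.35, 0.7, 0.2, J = 40, seed = 13)
  rec <- dplyr::mutate(s$records, species = "Homo sapiens")
  tens <- build_detection_tensor(rec, s$deployments) |>
    truncate_to_common_occasions()
  fit <- fit_species(tens, "Homo sapiens",
                     mcmc_config(n_chains = 2, n_iter = 400, n_burnin = 200,
                                 thin = 2, seed = 14))
  expect_s3_class(fit, "species_fit")
  expect_equal(glance(fit)$species, "Homo sapiens")
})
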