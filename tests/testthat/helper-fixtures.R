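# Small builders used across tests. Deployments are dated so that
# bin_occasions() yields the requested number of occasions.

make_deployments <- function(cameras, years = 1:3, k = 11, area = "A",
                             occasion_days = 5) {
  k <- matrix(k, length(cameras), length(years))
  tidyr::expand_grid(camera_id = cameras, year = years) |>
    dplyr::mutate(
      area = area, site = "s1",
      start_date = as.Date("2016-11-01") + (.data$year - min(years)) * 365,
      end_date = .data$start_date +
        k[cbind(match(.data$camera_id, cameras), match(.data$year, years))] *
          occasion_days - 1,
      active_days = as.integer(.data$end_date - .data$start_date) + 1L
    )
}

# records placed by (camera, year, occasion) using the binned schema
make_records <- function(species, camera_id, year, occasion, area = "A") {
  tibble::tibble(species = species, camera_id = camera_id, area = area,
                 year = year, occasion = occasion)
}

# a tensor with prescribed per-cell detection counts is easiest to build
# from one record per desired occasion-hit
tensor_from_hits <- function(hit_df, cameras, years = 1:3, k = 11,
                             species = NULL) {
  deps <- make_deployments(cameras, years, k)
  build_detection_tensor(hit_df, deps, occasion_days = 5, species = species)
}

chain_matrix_for_tests <- function(fit, extract) {
  do.call(cbind, lapply(fit$chains, extract))
}

# batch-means Monte Carlo standard error of the grand mean of an
# iterations x chains draw matrix
mcse <- function(m) {
  m <- as.matrix(m)
  per_chain <- apply(m, 2, function(x) {
    nb <- max(10, floor(sqrt(length(x))))
    bs <- floor(length(x) / nb)
    bm <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
                 numeric(1))
    stats::var(bm) / nb
  })
  sqrt(sum(per_chain)) / ncol(m)
}

expect_within_3se <- function(est, exact, se, floor_se = 1e-4) {
  expect_lt(abs(est - exact), 3 * max(se, floor_se) + 1e-8)
}
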