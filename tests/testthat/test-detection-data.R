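test_that("detection records round-trip through CSV and flag exclusions", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "det.csv")
  df <- tibble::tibble(
    species = c("Muntiacus vaginalis", "Homo sapiens", "Sus scrofa"),
    camera_id = c("c1", "c1", "c2"), area = "A",
    date = as.Date("2016-11-03") + 0:2
  )
  readr::write_csv(df, f)
  rec <- read_detections(f, exclude = "Homo sapiens")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$excluded, c(FALSE, TRUE, FALSE))
  expect_equal(nrow(filter_community(rec)), 2)
  expect_equal(rec$species, df$species)
  expect_equal(rec$date, df$date)
  # schema and date errors are precise
  readr::write_csv(df[, -1], f)
  expect_error(read_detections(f), "missing column")
  df2 <- df; df2$date <- c("2016-11-03", "not-a-date", "2016-11-05")
  readr::write_csv(df2, f)
  expect_error(read_detections(f), "row.*2")
})

test_that("a simulated survey round-trips through write_survey and read_detections", {
  tmp <- withr::local_tempdir()
  cfg <- survey_scenario("RYER-like"); cfg$J <- 12L; cfg$n_species_true <- 5L
  s <- simulate_survey(cfg, seed = 21)
  write_survey(s, tmp)
  rec <- read_detections(file.path(tmp, "detections.csv"))
  dep <- read_deployments(file.path(tmp, "deployments.csv"))
  expect_equal(nrow(rec), nrow(s$records))
  expect_equal(rec$species, s$records$species)
  expect_equal(rec$date, s$records$date)
  expect_equal(nrow(dep), nrow(s$deployments))
  expect_true(all(dep$active_days == cfg$K * cfg$occasion_days))
})

test_that("community filtering drops exactly the excluded taxa, keeping order", {
  rec <- make_records(c("a", "Homo sapiens", "b", "Homo sapiens"),
                      "c1", 1, 1:4)
  out <- filter_community(rec, "Homo sapiens")
  expect_equal(out$species, c("a", "b"))
  expect_equal(out$occasion, c(1L, 3L))
  expect_equal(filter_community(rec, character()), rec) # empty exclusion set
  expect_equal(nrow(filter_community(rec, c("a", "b", "Homo sapiens"))), 0)
})

test_that("occasion binning floors at five-day blocks", {
  # the two real deployments: 55 and 66 mean active days -> 11 and 13
  expect_equal(bin_occasions(55), 11L)
  expect_equal(bin_occasions(66), 13L)
  expect_warning(out <- bin_occasions(4), "0 occasions")
  expect_equal(out, 0L)
  expect_equal(bin_occasions(10, occasion_days = 5), 2L)
})

test_that("tensor building collapses videos to occasion-level detections", {
  # three records of one species in the same occasion count once
  rec <- make_records("sp", c("c1", "c1", "c1"), 1, c(2, 2, 2))
  tens <- tensor_from_hits(rec, c("c1", "c2"), years = 1:2, k = 5)
  expect_equal(tens$Y["sp", "c1", "1"], 1L)
  expect_equal(sum(tens$Y), 1L)
  expect_true(all(tens$K == 5L))
  # duplication idempotence: repeating every record never changes Y
  tens2 <- tensor_from_hits(dplyr::bind_rows(rec, rec), c("c1", "c2"),
                            years = 1:2, k = 5)
  expect_identical(tens$Y, tens2$Y)
  # a never-detected species appears only via a master list
  tens3 <- tensor_from_hits(rec, c("c1", "c2"), years = 1:2, k = 5,
                            species = c("sp", "ghost"))
  expect_equal(species_detection_totals(tens3)[["ghost"]], 0L)
  expect_false("ghost" %in% tensor_from_hits(rec, c("c1", "c2"), 1:2, 5)$species)
})

test_that("date-schema records land in the right occasion and bad dates error", {
  deps <- make_deployments("c1", years = 1:2, k = 3)
  # day 6 of the season is occasion 2
  rec <- tibble::tibble(species = "sp", camera_id = "c1", area = "A",
                        date = deps$start_date[1] + 5)
  tens <- build_detection_tensor(rec, deps)
  expect_equal(unname(tens$Y[1, 1, ]), c(1L, 0L))
  # a record outside every deployment window is an error with row numbers
  bad <- tibble::tibble(species = "sp", camera_id = "c1", area = "A",
                        date = deps$start_date[1] - 30)
  expect_error(build_detection_tensor(bad, deps), "outside any deployment")
  # unknown camera
  expect_error(
    build_detection_tensor(dplyr::mutate(rec, camera_id = "cX"), deps),
    "absent from deployments"
  )
})

test_that("Y never exceeds K through the whole transformation chain", {
  cfg <- survey_scenario("HWS-like"); cfg$J <- 15L; cfg$n_species_true <- 6L
  s <- simulate_survey(cfg, seed = 31)
  tens <- build_detection_tensor(s$records, s$deployments)
  for (tr in list(tens, restrict_to_full_series(tens),
                  truncate_to_common_occasions(tens),
                  augment_tensor(tens, 10))) {
    Kexp <- aperm(array(tr$K, c(dim(tr$K), length(tr$species))), c(3, 1, 2))
    expect_true(all(tr$Y >= 0 & tr$Y <= Kexp))
  }
})

test_that("simulated occasion hits are recovered exactly by the tensor builder", {
  cfg <- survey_scenario("HWS-like"); cfg$J <- 10L; cfg$n_species_true <- 6L
  s <- simulate_survey(cfg, seed = 41)
  tens <- build_detection_tensor(s$records, s$deployments)
  det <- which(apply(s$truth$hits, 1, sum) > 0)
  Ysim <- apply(s$truth$hits[det, , , , drop = FALSE], c(1, 2, 3), sum)
  ord <- order(s$truth$params$species[det])
  expect_equal(unname(tens$Y), unname(Ysim[ord, , , drop = FALSE]))
  # per-species totals match the simulator's occasion-hit bookkeeping
  expect_equal(unname(species_detection_totals(tens)),
               unname(s$truth$occasion_hit_totals[det][ord]))
})

test_that("full-series restriction keeps exactly the cameras active every season", {
  full <- make_deployments(sprintf("f%03d", 1:108), years = 1:3, k = 11)
  partial <- make_deployments(sprintf("p%02d", 1:12), years = 1:3, k = 11) |>
    dplyr::mutate(end_date = dplyr::if_else(.data$year == 2, .data$start_date + 2, .data$end_date),
                  active_days = as.integer(.data$end_date - .data$start_date) + 1L)
  deps <- dplyr::bind_rows(full, partial)
  rec <- make_records("sp", "f001", 1, 1)
  tens <- suppressWarnings(build_detection_tensor(rec, deps))
  expect_equal(length(tens$cameras), 120)
  kept <- restrict_to_full_series(tens)
  expect_equal(length(kept$cameras), 108)
  expect_true(all(startsWith(kept$cameras, "f")))
  # all cameras active: identity
  tens2 <- build_detection_tensor(rec, full)
  expect_equal(restrict_to_full_series(tens2)$cameras, tens2$cameras)
  # no qualifying camera
  allpart <- dplyr::mutate(full, end_date = .data$start_date + 1,
                           active_days = 2L)
  expect_error(restrict_to_full_series(
    suppressWarnings(build_detection_tensor(rec[0, ], allpart, species = "sp"))),
    "no camera")
})

test_that("common-occasion truncation recomputes Y from retained occasions", {
  deps <- make_deployments("c1", years = 1:3, k = c(13, 11, 12))
  # detections: occasion 12 of year 1 (beyond the common 11) and occasion 3
  rec <- make_records(c("sp", "sp"), "c1", c(1, 3), c(12, 3))
  tens <- build_detection_tensor(rec, deps)
  expect_equal(unname(tens$K[1, ]), c(13L, 11L, 12L))
  tr <- truncate_to_common_occasions(tens)
  expect_true(all(tr$K == 11L))
  expect_equal(unname(tr$Y[1, 1, ]), c(0L, 0L, 1L)) # year-1 hit fell away
  # equal effort: identity
  deps2 <- make_deployments("c1", years = 1:3, k = 11)
  tens2 <- build_detection_tensor(make_records("sp", "c1", 1, 1), deps2)
  tr2 <- truncate_to_common_occasions(tens2)
  expect_identical(tr2$Y, tens2$Y)
  expect_identical(tr2$K, tens2$K)
})

test_that("augmentation appends all-zero slots and is reversible", {
  rec <- make_records(sprintf("s%02d", 1:32), "c1", 1, 1)
  tens <- tensor_from_hits(rec, "c1", years = 1, k = 4)
  aug <- augment_tensor(tens, 100)
  expect_equal(length(aug$species), 132) # 32 observed + 100
  expect_equal(aug$n_aug, 100L)
  expect_true(all(aug$Y[33:132, , ] == 0))
  expect_identical(drop_augmentation(aug)$Y, tens$Y)
  rec25 <- make_records(sprintf("s%02d", 1:25), "c1", 1, 1)
  expect_equal(length(augment_tensor(tensor_from_hits(rec25, "c1", 1, 4), 100)$species), 125)
  aug0 <- augment_tensor(tens, 0)
  expect_identical(aug0$Y, tens$Y)
})

test_that("long-format and design summaries describe the tensor faithfully", {
  deps <- make_deployments(c("c1", "c2"), years = 1:2, k = 3)
  rec <- make_records("sp", "c1", 1, 2)
  tens <- build_detection_tensor(rec, deps)
  long <- as_tibble(tens)
  expect_equal(nrow(long), 1 * 2 * 2)
  expect_equal(sum(long$y), 1)
  expect_true(all(long$k == 3))
  ds <- design_summary(tens)
  expect_equal(ds$n_species, 1)
  expect_equal(ds$n_cameras, 2)
  expect_equal(nrow(ds$occasions), 4)
})
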