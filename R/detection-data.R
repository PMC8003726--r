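#' Read camera-trap detection records
#'
#' Reads a delimited file of detection records (one row per video /
#' detection event). Two schemas are accepted: calendar dates
#' (`species, camera_id, area, date`) or pre-binned occasions
#' (`species, camera_id, area, year, occasion`). Species named in
#' `exclude` (humans, non-target taxa) are flagged in an `excluded`
#' column, never silently dropped.
#'
#' @param path Path to a delimited text file with a header row.
#' @param exclude Character vector of taxon names to flag as excluded.
#' @param delim Field delimiter (default comma).
#' @return A tibble of detection records with an `excluded` logical column.
#' @export
read_detections <- function(path, exclude = character(), delim = ",") {
  stopifnot(file.exists(path))
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("species", "camera_id", "area")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("detections file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  has_date <- "date" %in% names(df)
  has_binned <- all(c("year", "occasion") %in% names(df))
  if (!has_date && !has_binned) {
    stop("detections file needs either a `date` column or `year` + `occasion`",
         call. = FALSE)
  }
  if (any(is.na(df$species) | df$species == "")) {
    bad <- which(is.na(df$species) | df$species == "")
    stop("empty species name on row(s): ", paste(utils::head(bad, 10), collapse = ", "),
         call. = FALSE)
  }
  if (has_date) {
    d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    bad <- which(is.na(d))
    if (length(bad) > 0) {
      stop("unparseable date(s) on row(s): ", paste(utils::head(bad, 10), collapse = ", "),
           call. = FALSE)
    }
    df$date <- d
  }
  df$excluded <- df$species %in% exclude
  tibble::as_tibble(df)
}

#' Read a camera-deployment table
#'
#' One row per camera per survey season (`camera_id, area, site, year,
#' start_date, end_date`). A season ("year") is a campaign label supplied
#' in the data, not a calendar year: campaigns may span the new year.
#'
#' @param path Path to a delimited text file with a header row.
#' @param delim Field delimiter.
#' @return A tibble with parsed dates and an `active_days` column.
#' @export
read_deployments <- function(path, delim = ",") {
  stopifnot(file.exists(path))
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("camera_id", "area", "site", "year", "start_date", "end_date")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("deployments file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$start_date <- as.Date(as.character(df$start_date))
  df$end_date <- as.Date(as.character(df$end_date))
  if (any(is.na(df$start_date)) || any(is.na(df$end_date))) {
    stop("unparseable deployment dates", call. = FALSE)
  }
  if (any(df$end_date < df$start_date)) {
    stop("deployment end date before start date", call. = FALSE)
  }
  df$active_days <- as.integer(df$end_date - df$start_date) + 1L
  tibble::as_tibble(df)
}

#' Drop excluded taxa from a record table
#'
#' Removes records whose species is in `exclusions` (for the community
#' analysis humans are excluded; they are analysed separately with the
#' single-species model). Row order of retained records is preserved.
#'
#' @param records Detection-record tibble.
#' @param exclusions Character vector of taxon names (may be empty).
#' @return The filtered tibble.
#' @export
filter_community <- function(records, exclusions = character()) {
  keep <- !(records$species %in% exclusions)
  if ("excluded" %in% names(records)) keep <- keep & !records$excluded
  records[keep, , drop = FALSE]
}

#' Number of complete sampling occasions in a deployment
#'
#' Consecutive non-overlapping blocks of `occasion_days` trap-days counted
#' from the camera's own deployment start; a trailing partial block is
#' discarded. A camera active for fewer days than one occasion yields 0
#' occasions and should be excluded by the caller.
#'
#' @param active_days Integer number of days the camera was active.
#' @param occasion_days Days per occasion (default 5).
#' @return Integer occasion count, `floor(active_days / occasion_days)`.
#' @export
bin_occasions <- function(active_days, occasion_days = 5) {
  stopifnot(occasion_days >= 1, all(active_days >= 0))
  out <- as.integer(active_days %/% occasion_days)
  if (any(out == 0)) {
    warning(sum(out == 0),
            " deployment(s) shorter than one occasion yield 0 occasions",
            call. = FALSE)
  }
  out
}

new_occu_tensor <- function(hits, K, species, cameras, years, n_aug = 0L) {
  structure(
    list(
      hits = hits,                       # [species, camera, year, occasion]
      Y = occasion_counts(hits, K),      # [species, camera, year]
      K = K,                             # [camera, year]
      species = species, cameras = cameras, years = years,
      n_aug = as.integer(n_aug)
    ),
    class = "occu_tensor"
  )
}

# Reduce the occasion-resolved hit array to Y[i, j, t], masking occasions
# beyond each camera-year's effort.
occasion_counts <- function(hits, K) {
  d <- dim(hits)
  Y <- array(0L, d[1:3], dimnames = dimnames(hits)[1:3])
  for (t in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      kk <- K[j, t]
      if (kk > 0) Y[, j, t] <- as.integer(rowSums(hits[, j, t, seq_len(kk), drop = FALSE]))
    }
  }
  Y
}

#' Build an occasion-binned detection tensor
#'
#' Collapses detection records into the 3D detection array Y\[species,
#' camera, year\] of occasions-with-detection together with the effort
#' matrix K\[camera, year\] of occasion counts. Multiple videos of a
#' species within one occasion count once: the binomial observation model
#' Bin(K, p z) consumes occasion-level detection/non-detection outcomes.
#' The occasion-resolved hit array is kept internally so later
#' transformations (common-occasion truncation) can recompute Y exactly.
#'
#' @param records Detection tibble from [read_detections()] (already
#'   filtered with [filter_community()] as needed). Either a `date` column
#'   or `year` + `occasion` columns.
#' @param deployments Deployment tibble from [read_deployments()].
#' @param occasion_days Days per sampling occasion (default 5).
#' @param species Optional master species list; defaults to the species
#'   observed in `records` (sorted). Species in the list but never
#'   detected get all-zero rows.
#' @return An object of class `occu_tensor`.
#' @export
build_detection_tensor <- function(records, deployments, occasion_days = 5,
                                   species = NULL) {
  unknown <- setdiff(unique(records$camera_id), deployments$camera_id)
  if (length(unknown) > 0) {
    stop("record camera(s) absent from deployments: ",
         paste(utils::head(unknown, 10), collapse = ", "), call. = FALSE)
  }
  cameras <- sort(unique(deployments$camera_id))
  years <- sort(unique(deployments$year))
  J <- length(cameras); T <- length(years)

  K <- matrix(0L, J, T, dimnames = list(cameras, years))
  dep_key <- paste(deployments$camera_id, deployments$year)
  if (anyDuplicated(dep_key)) {
    stop("multiple deployment rows for the same camera and year", call. = FALSE)
  }
  K[cbind(match(deployments$camera_id, cameras),
          match(deployments$year, years))] <-
    suppressWarnings(bin_occasions(deployments$active_days, occasion_days))

  # locate each record: (camera, year, occasion)
  if ("date" %in% names(records)) {
    di <- match(
      paste(records$camera_id,
            purrr::map_chr(seq_len(nrow(records)), function(r) {
              hit <- which(deployments$camera_id == records$camera_id[r] &
                             deployments$start_date <= records$date[r] &
                             deployments$end_date >= records$date[r])
              if (length(hit) == 0) NA_character_ else as.character(deployments$year[hit[1]])
            })),
      paste(deployments$camera_id, deployments$year)
    )
    bad <- which(is.na(di))
    if (length(bad) > 0) {
      stop("record(s) dated outside any deployment window, rows: ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
    rec_year <- deployments$year[di]
    rec_occ <- as.integer(records$date - deployments$start_date[di]) %/%
      occasion_days + 1L
  } else {
    stopifnot(all(c("year", "occasion") %in% names(records)))
    rec_year <- records$year
    rec_occ <- as.integer(records$occasion)
  }
  rec_k <- K[cbind(match(records$camera_id, cameras), match(rec_year, years))]
  in_partial <- rec_occ > rec_k
  if (any(in_partial)) {
    warning(sum(in_partial),
            " record(s) fell in a discarded trailing partial occasion and were dropped",
            call. = FALSE)
  }
  records <- records[!in_partial, , drop = FALSE]
  rec_year <- rec_year[!in_partial]; rec_occ <- rec_occ[!in_partial]

  if (is.null(species)) species <- sort(unique(records$species))
  miss <- setdiff(unique(records$species), species)
  if (length(miss) > 0) {
    stop("record species missing from the supplied master list: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  }

  Kmax <- max(K, 1L)
  hits <- array(FALSE, c(length(species), J, T, Kmax),
                dimnames = list(species, cameras, years, NULL))
  if (nrow(records) > 0) {
    idx <- cbind(match(records$species, species),
                 match(records$camera_id, cameras),
                 match(rec_year, years),
                 rec_occ)
    hits[idx] <- TRUE
  }
  new_occu_tensor(hits, K, species, cameras, years)
}

#' Keep only cameras that worked in every season
#'
#' Restricts a detection tensor to cameras with at least one complete
#' occasion in every survey year, the design rule used before fitting the
#' community model.
#'
#' @param tensor An `occu_tensor`.
#' @return The restricted `occu_tensor`.
#' @export
restrict_to_full_series <- function(tensor) {
  stopifnot(inherits(tensor, "occu_tensor"))
  keep <- apply(tensor$K >= 1L, 1, all)
  if (!any(keep)) stop("no camera was active in all seasons", call. = FALSE)
  new_occu_tensor(
    tensor$hits[, keep, , , drop = FALSE],
    tensor$K[keep, , drop = FALSE],
    tensor$species, tensor$cameras[keep], tensor$years, tensor$n_aug
  )
}

#' Truncate every season to a camera's smallest occasion count
#'
#' Per camera, the season with the fewest occasions determines how many
#' occasions are retained from the other seasons; Y is recomputed from the
#' retained occasions only. This equalises effort across seasons for the
#' single-species analysis.
#'
#' @param tensor An `occu_tensor`.
#' @return The truncated `occu_tensor` (per camera, K is constant over
#'   years).
#' @export
truncate_to_common_occasions <- function(tensor) {
  stopifnot(inherits(tensor, "occu_tensor"))
  kmin <- apply(tensor$K, 1, min)
  K <- matrix(as.integer(kmin), nrow = nrow(tensor$K), ncol = ncol(tensor$K),
              dimnames = dimnames(tensor$K))
  hits <- tensor$hits
  # zero out occasions beyond the common count so Y is recomputed from the
  # retained occasions only
  for (j in seq_along(kmin)) {
    if (kmin[j] < dim(hits)[4]) {
      hits[, j, , setdiff(seq_len(dim(hits)[4]), seq_len(kmin[j]))] <- FALSE
    }
  }
  new_occu_tensor(hits, K, tensor$species, tensor$cameras, tensor$years,
                  tensor$n_aug)
}

#' Augment a detection tensor with all-zero pseudo-species
#'
#' Appends `n_aug` all-zero species rows so the unknown total community
#' size becomes estimable by data augmentation (total slots
#' M = observed + n_aug).
#'
#' @param tensor An `occu_tensor` of observed species.
#' @param n_aug Number of pseudo-species to append (default 100).
#' @return An `occu_tensor` with `n_aug` recorded; pseudo-species are named
#'   `aug_001`, `aug_002`, ...
#' @export
augment_tensor <- function(tensor, n_aug = 100) {
  stopifnot(inherits(tensor, "occu_tensor"), n_aug >= 0)
  n_aug <- as.integer(n_aug)
  if (n_aug == 0) {
    return(new_occu_tensor(tensor$hits, tensor$K, tensor$species,
                           tensor$cameras, tensor$years, 0L))
  }
  d <- dim(tensor$hits)
  aug_names <- sprintf("aug_%03d", seq_len(n_aug))
  hits <- array(FALSE, c(d[1] + n_aug, d[2], d[3], d[4]),
                dimnames = list(c(tensor$species, aug_names),
                                tensor$cameras, tensor$years, NULL))
  hits[seq_len(d[1]), , , ] <- tensor$hits
  new_occu_tensor(hits, tensor$K, c(tensor$species, aug_names),
                  tensor$cameras, tensor$years, n_aug)
}

#' Drop augmentation rows, recovering the observed-species tensor
#' @param tensor An augmented `occu_tensor`.
#' @return The `occu_tensor` without pseudo-species rows.
#' @export
drop_augmentation <- function(tensor) {
  stopifnot(inherits(tensor, "occu_tensor"))
  if (tensor$n_aug == 0) return(tensor)
  n_obs <- length(tensor$species) - tensor$n_aug
  new_occu_tensor(tensor$hits[seq_len(n_obs), , , , drop = FALSE], tensor$K,
                  tensor$species[seq_len(n_obs)], tensor$cameras,
                  tensor$years, 0L)
}

#' @export
print.occu_tensor <- function(x, ...) {
  cat("<occu_tensor> ", length(x$species) - x$n_aug, " species",
      if (x$n_aug > 0) paste0(" (+", x$n_aug, " augmented)"),
      ", ", length(x$cameras), " cameras, ", length(x$years), " seasons\n",
      sep = "")
  cat("occasions per camera-season: ", min(x$K), "-", max(x$K), "\n", sep = "")
  invisible(x)
}

#' Long-format view of a detection tensor
#'
#' @param x An `occu_tensor`.
#' @param ... Unused.
#' @return A tibble with columns `species`, `camera`, `year`, `y`, `k`.
#' @export
as_tibble.occu_tensor <- function(x, ...) {
  df <- expand.grid(species = x$species, camera = x$cameras, year = x$years,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$y <- as.vector(x$Y)
  df$k <- as.vector(x$K[cbind(match(df$camera, x$cameras),
                              match(df$year, x$years))])
  tibble::as_tibble(df)
}

#' Design summary of a detection tensor
#'
#' @param tensor An `occu_tensor`.
#' @return A list: species/camera/season counts, augmentation size, and the
#'   per-camera-season occasion table (suitable for [jsonlite::write_json]).
#' @export
design_summary <- function(tensor) {
  stopifnot(inherits(tensor, "occu_tensor"))
  list(
    n_species = length(tensor$species) - tensor$n_aug,
    n_aug = tensor$n_aug,
    n_cameras = length(tensor$cameras),
    years = tensor$years,
    occasions = as.data.frame.table(tensor$K, responseName = "k",
                                    stringsAsFactors = FALSE) |>
      stats::setNames(c("camera", "year", "k"))
  )
}

#' Total occasion-level detections per species
#'
#' @param tensor An `occu_tensor`.
#' @return Named integer vector: sum of Y over cameras and years per
#'   species.
#' @export
species_detection_totals <- function(tensor) {
  out <- apply(tensor$Y, 1, sum)
  names(out) <- tensor$species
  out
}
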