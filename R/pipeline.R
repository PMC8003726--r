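#' Format "median (q2.5-q97.5)" rate strings with significance asterisks
#'
#' Renders per-transition community colonization and persistence summaries
#' the way the study tables print them: two decimals (half away from
#' zero), the 95% BCI in parentheses, and an asterisk on persistence when
#' its BCI does not overlap the paired colonization BCI.
#'
#' @param rates Tibble from [derive_community_rates()], optionally with an
#'   `area` column when several areas are bound together.
#' @return Tibble: one row per area x transition with `colonization` and
#'   `persistence` cell strings.
#' @export
render_rate_table <- function(rates) {
  if (!"area" %in% names(rates)) rates$area <- "area"
  cell <- function(r, star = FALSE) {
    sprintf("%s (%s-%s)%s", fmt2(r$median), fmt2(r$q2.5), fmt2(r$q97.5),
            if (star) " *" else "")
  }
  purrr::map_dfr(split(rates, list(rates$area, rates$transition), drop = TRUE),
    function(pair) {
      col <- pair[pair$parameter == "colonization", ]
      per <- pair[pair$parameter == "persistence", ]
      tibble::tibble(
        area = pair$area[1], transition = pair$transition[1],
        colonization = cell(col),
        persistence = cell(per, star = per$significant[1])
      )
    }) |> dplyr::arrange(.data$area, .data$transition)
}

#' Run the full community analysis for one or more areas
#'
#' End-to-end composition of the pipeline stages on already-read record
#' and deployment tables: exclusion filtering, occasion binning,
#' full-series camera restriction, augmentation, the community model per
#' area, derived richness/rates, trait composition, and (optionally)
#' single-species fits with a between-area comparison when exactly two
#' areas are analysed. Stages are reproducible from the seed in `config`.
#'
#' @param records Detection tibble (see [read_detections()]).
#' @param deployments Deployment tibble (see [read_deployments()]).
#' @param traits Optional trait tibble; composition is skipped when
#'   `NULL`.
#' @param config An [mcmc_config()] shared by all model runs.
#' @param occasion_days Days per sampling occasion.
#' @param n_aug Pseudo-species for community augmentation.
#' @param min_det Detection threshold for single-species eligibility.
#' @param exclude Taxa excluded from the community model (humans by
#'   default); excluded taxa are still eligible for single-species fits.
#' @param fit_species_models Fit eligible single species (needs two
#'   areas)?
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   the long-format tensors and the rate table.
#' @return A list of class `occomm_report`: per-area `tensors`, `fits`,
#'   `richness`, `rates`, `rate_table`, `composition`, `shared`,
#'   `species_comparison`.
#' @export
run_full_analysis <- function(records, deployments, traits = NULL,
                              config = mcmc_config(), occasion_days = 5,
                              n_aug = 100, min_det = 10,
                              exclude = "Homo sapiens",
                              fit_species_models = TRUE, out_dir = NULL) {
  areas <- sort(unique(deployments$area))
  community_records <- filter_community(records, exclude)

  tensors <- fits <- richness <- list()
  rates <- list()
  for (ar in areas) {
    tensor <- build_detection_tensor(
      community_records[community_records$area == ar, ],
      deployments[deployments$area == ar, ], occasion_days
    ) |> restrict_to_full_series()
    tensors[[ar]] <- tensor
    fit <- fit_community(augment_tensor(tensor, n_aug), config)
    fits[[ar]] <- fit
    richness[[ar]] <- dplyr::bind_rows(
      dplyr::mutate(derive_yearly_richness(fit), scope = "year"),
      dplyr::mutate(derive_total_richness(fit), scope = "total")
    )
    if (length(tensor$years) > 1) {
      rates[[ar]] <- dplyr::mutate(derive_community_rates(fit), area = ar)
    }
  }
  rates <- dplyr::bind_rows(rates)
  rate_table <- if (nrow(rates) > 0) render_rate_table(rates) else NULL

  composition <- shared <- NULL
  if (!is.null(traits)) {
    composition <- purrr::map_dfr(areas, function(ar) {
      detected <- tensors[[ar]]$species[species_detection_totals(tensors[[ar]]) > 0]
      dplyr::bind_rows(
        dplyr::mutate(composition_proportions(detected, traits, "guild"),
                      by = "guild"),
        dplyr::mutate(composition_proportions(detected, traits, "mass"),
                      by = "mass")
      ) |> dplyr::mutate(area = ar)
    })
    if (length(areas) == 2) {
      shared <- shared_species(tensors[[areas[1]]]$species,
                               tensors[[areas[2]]]$species)
    }
  }

  species_comparison <- NULL
  if (fit_species_models && length(areas) == 2) {
    # humans and other excluded taxa run through the same machinery here
    full_tensors <- lapply(areas, function(ar) {
      build_detection_tensor(records[records$area == ar, ],
                             deployments[deployments$area == ar, ],
                             occasion_days) |>
        restrict_to_full_series() |>
        truncate_to_common_occasions()
    })
    names(full_tensors) <- areas
    elig <- eligible_species(full_tensors[[1]], full_tensors[[2]], min_det)
    species_comparison <- purrr::map_dfr(elig, function(sp) {
      fa <- fit_species(full_tensors[[1]], sp, config)
      fb <- fit_species(full_tensors[[2]], sp, config)
      compare_species_between_areas(fa, fb, labels = areas)
    })
  }

  report <- structure(
    list(areas = areas, tensors = tensors, fits = fits, richness = richness,
         rates = rates, rate_table = rate_table, composition = composition,
         shared = shared, species_comparison = species_comparison,
         config = config),
    class = "occomm_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report bundle to disk
#'
#' @param report An `occomm_report` from [run_full_analysis()].
#' @param dir Output directory; writes `report.json` plus CSV tables.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ar in report$areas) {
    readr::write_csv(as_tibble(report$tensors[[ar]]),
                     file.path(dir, paste0("tensor_", ar, ".csv")))
  }
  if (!is.null(report$rate_table)) {
    readr::write_csv(report$rate_table, file.path(dir, "rate_table.csv"))
  }
  if (!is.null(report$species_comparison) && nrow(report$species_comparison) > 0) {
    readr::write_csv(report$species_comparison,
                     file.path(dir, "species_comparison.csv"))
  }
  json <- list(
    seed = report$config$seed,
    areas = report$areas,
    design = lapply(report$tensors, design_summary),
    richness = report$richness,
    rates = if (nrow(report$rates) > 0) report$rates else NULL,
    composition = report$composition,
    shared = report$shared
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.occomm_report <- function(x, ...) {
  cat("<occomm_report> areas:", paste(x$areas, collapse = ", "), "\n")
  for (ar in x$areas) {
    tot <- x$richness[[ar]][x$richness[[ar]]$scope == "total", ]
    cat(sprintf("  %s: total richness %g (%g-%g), %d species observed\n",
                ar, tot$median, tot$q2.5, tot$q97.5, tot$observed))
  }
  if (!is.null(x$shared)) cat("  shared species:", x$shared$n_shared, "\n")
  invisible(x)
}
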