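#' Read a species-trait table
#'
#' Expects columns `species`, `guild` (one of herbivore, carnivore,
#' omnivore, insectivore) and either `body_mass_kg` or a pre-assigned
#' `mass_class`; numeric masses are classed with [mass_class()]. Extra
#' columns (e.g. `area`) are kept.
#'
#' @param path Delimited text file with a header row.
#' @param delim Field delimiter.
#' @return A tibble with at least `species`, `guild`, `mass_class`.
#' @export
read_traits <- function(path, delim = ",") {
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("species", "guild")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("trait file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$guild), trophic_guilds())
  if (length(bad) > 0) {
    stop("unknown trophic guild(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!"mass_class" %in% names(df)) {
    if (!"body_mass_kg" %in% names(df)) {
      stop("trait file needs `mass_class` or `body_mass_kg`", call. = FALSE)
    }
    df$mass_class <- mass_class(df$body_mass_kg)
  }
  bad <- setdiff(unique(df$mass_class), mass_classes())
  if (length(bad) > 0) {
    stop("unknown mass class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' @rdname read_traits
#' @export
trophic_guilds <- function() c("herbivore", "carnivore", "omnivore", "insectivore")

#' @rdname read_traits
#' @export
mass_classes <- function() c("medium", "medium-large", "large")

#' The packaged two-area Myanmar community trait table
#'
#' Species lists with trophic guild and body-mass class for the two
#' surveyed Myanmar reserves (RYER: 25 species; HWS: 32), shipped as the
#' worked example for the composition layer.
#'
#' @return A tibble with columns `area`, `species`, `guild`, `mass_class`.
#' @export
myanmar_traits <- function() {
  read_traits(system.file("extdata", "myanmar_community_traits.csv",
                          package = "occomm"))
}

#' Body-mass class of a medium-large mammal
#'
#' The survey targets mammals above 1 kg: medium (1-10 kg), medium-large
#' (10-100 kg), large (>100 kg). Boundary masses of exactly 10 or 100 kg
#' go to the heavier class.
#'
#' @param body_mass_kg Positive mass in kilograms (> 1 kg; vectorised).
#' @return Character vector of classes.
#' @export
mass_class <- function(body_mass_kg) {
  if (any(body_mass_kg <= 1)) {
    stop("body mass <= 1 kg is below the target size range", call. = FALSE)
  }
  dplyr::case_when(
    body_mass_kg < 10 ~ "medium",
    body_mass_kg < 100 ~ "medium-large",
    TRUE ~ "large"
  )
}

#' Community composition by trophic guild or body-mass class
#'
#' Counts and integer percentages (rounded half away from zero) of an
#' observed species list across trait groups.
#'
#' @param species Character vector (or set) of species names.
#' @param traits Trait tibble (see [read_traits()]); any `area` duplicates
#'   are collapsed to one row per species.
#' @param by `"guild"` or `"mass"`.
#' @return Tibble with columns `group`, `n`, `pct`, covering every level
#'   of the classification (zero rows included).
#' @export
composition_proportions <- function(species, traits, by = c("guild", "mass")) {
  by <- match.arg(by)
  species <- unique(species)
  traits <- dplyr::distinct(traits, .data$species, .keep_all = TRUE)
  missing_sp <- setdiff(species, traits$species)
  if (length(missing_sp) > 0) {
    stop("species missing from the trait table: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  col <- if (by == "guild") "guild" else "mass_class"
  levels <- if (by == "guild") trophic_guilds() else mass_classes()
  tr <- traits[match(species, traits$species), ]
  counts <- table(factor(tr[[col]], levels = levels))
  tibble::tibble(
    group = levels,
    n = as.integer(counts),
    pct = round_half_up(100 * as.integer(counts) / length(species))
  )
}

#' Species shared between two areas
#'
#' @param list_a,list_b Character vectors of species names.
#' @return List: `shared` (sorted intersection), `only_a`, `only_b`,
#'   `n_shared`.
#' @export
shared_species <- function(list_a, list_b) {
  list_a <- unique(list_a); list_b <- unique(list_b)
  sh <- sort(intersect(list_a, list_b))
  list(shared = sh, only_a = sort(setdiff(list_a, list_b)),
       only_b = sort(setdiff(list_b, list_a)), n_shared = length(sh))
}

#' Restrict a detection tensor to a subset of species
#' @param tensor An `occu_tensor` (unaugmented).
#' @param species Species names to keep.
#' @return The restricted `occu_tensor`.
#' @export
subset_species <- function(tensor, species) {
  stopifnot(inherits(tensor, "occu_tensor"))
  idx <- match(species, tensor$species)
  if (anyNA(idx)) {
    stop("species not in tensor: ",
         paste(species[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  new_occu_tensor(tensor$hits[idx, , , , drop = FALSE], tensor$K,
                  tensor$species[idx], tensor$cameras, tensor$years, 0L)
}

#' Community richness model for one trophic guild
#'
#' Restricts the detection tensor to the observed species of a guild,
#' augments it, and runs the community model to estimate guild richness.
#' Guilds with fewer than two observed species are refused: such runs do
#' not converge (in the surveyed RYER community the single observed
#' insectivore made the guild model unusable).
#'
#' @param tensor An unaugmented `occu_tensor` of observed species.
#' @param traits Trait tibble covering the tensor's species.
#' @param guild One of [trophic_guilds()].
#' @param n_aug Pseudo-species appended for the guild run (default 20).
#' @param config An [mcmc_config()].
#' @param ... Passed to [fit_community()].
#' @return List: `fit` (`community_fit`), `yearly` and `total` richness
#'   summaries.
#' @export
guild_subset_richness <- function(tensor, traits, guild, n_aug = 20,
                                  config = mcmc_config(), ...) {
  stopifnot(guild %in% trophic_guilds())
  traits <- dplyr::distinct(traits, .data$species, .keep_all = TRUE)
  members <- intersect(tensor$species, traits$species[traits$guild == guild])
  detected <- members[species_detection_totals(tensor)[members] > 0]
  if (length(detected) < 2) {
    stop("insufficient species for convergence: guild '", guild, "' has ",
         length(detected), " observed species", call. = FALSE)
  }
  sub <- augment_tensor(subset_species(tensor, detected), n_aug)
  fit <- fit_community(sub, config, ...)
  list(fit = fit, yearly = derive_yearly_richness(fit),
       total = derive_total_richness(fit))
}
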