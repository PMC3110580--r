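#' Build an occurrence table from community and plant-trait records
#'
#' The central data container of the package: a plot-by-species abundance
#' table (abundance = fraction of quadrats in which the species was recorded,
#' in `(0, 1]`) together with individual-plant trait measurements and plot
#' metadata. Trait values are log10-transformed once at ingest; all downstream
#' statistics operate on the log scale.
#'
#' @param community A data frame with columns `plot`, `species`, `abundance`.
#'   Abundances may be given as percentages (values > 1 are divided by 100).
#'   Absences are simply unlisted; listed abundances must be positive.
#' @param plants Optional data frame of individual-plant records with columns
#'   `species`, `plot`, optionally `plant_id`, and one numeric column per
#'   trait. Each record must refer to a (species, plot) pair present in
#'   `community` (others are dropped with a warning).
#' @param plots Optional plot metadata (`plot`, optionally `site`, `habitat`).
#'   Plots default to a single site and unknown habitat.
#' @param species_constants Optional data frame (`species`, one column per
#'   trait) of species-level constant traits, e.g. maximum height taken from a
#'   flora. These participate in gradient partitions and comparative tests but
#'   carry no within-species information.
#' @param log10_traits Logical; log10-transform all trait columns (default
#'   `TRUE`). Non-positive trait values are an error when transforming.
#' @return An object of class `"occurrence_table"`: a list with tibbles
#'   `community`, `plants`, `plots`, `constants`, `imputed`, plus the trait
#'   name vector `traits` and `constant_traits`.
#' @export
occurrence_table <- function(community, plants = NULL, plots = NULL,
                             species_constants = NULL, log10_traits = TRUE) {
  community <- as_tibble(community)
  req <- c("plot", "species", "abundance")
  if (!all(req %in% names(community)))
    abort("`community` needs columns plot, species, abundance.")
  community <- community |>
    mutate(plot = as.character(.data$plot), species = as.character(.data$species))
  if (any(!is.finite(community$abundance)) || any(community$abundance <= 0))
    abort("Abundances must be positive and finite (omit absences).")
  if (any(community$abundance > 1)) {
    if (any(community$abundance > 100)) abort("Abundances exceed 100%.")
    community$abundance <- community$abundance / 100
  }
  if (anyDuplicated(community[c("species", "plot")]))
    abort("Duplicate (species, plot) pairs in `community`.")

  plots <- if (is.null(plots)) tibble(plot = unique(community$plot)) else as_tibble(plots)
  plots$plot <- as.character(plots$plot)
  if (!"site" %in% names(plots)) plots$site <- "site1"
  if (!"habitat" %in% names(plots)) plots$habitat <- NA_character_
  missing_plots <- setdiff(community$plot, plots$plot)
  if (length(missing_plots))
    abort(paste0("Plots missing from `plots` metadata: ", paste(missing_plots, collapse = ", ")))

  traits <- character(0)
  if (!is.null(plants)) {
    plants <- as_tibble(plants)
    if (!all(c("species", "plot") %in% names(plants)))
      abort("`plants` needs columns species and plot.")
    plants <- plants |>
      mutate(plot = as.character(.data$plot), species = as.character(.data$species))
    if (!"plant_id" %in% names(plants))
      plants$plant_id <- sprintf("plant%05d", seq_len(nrow(plants)))
    traits <- setdiff(names(plants)[vapply(plants, is.numeric, logical(1))],
                      c("plant_id"))
    orphan <- anti_join(plants, community, by = c("species", "plot"))
    if (nrow(orphan)) {
      warn(paste0(nrow(orphan), " plant record(s) refer to (species, plot) pairs ",
                  "absent from `community`; dropped."))
      plants <- inner_join(plants, community[c("species", "plot")],
                           by = c("species", "plot"))
    }
    plants <- select(plants, "plant_id", "species", "plot", dplyr::all_of(traits))
  } else {
    plants <- tibble(plant_id = character(), species = character(), plot = character())
  }

  constant_traits <- character(0)
  if (!is.null(species_constants)) {
    species_constants <- as_tibble(species_constants)
    if (!"species" %in% names(species_constants))
      abort("`species_constants` needs a `species` column.")
    species_constants$species <- as.character(species_constants$species)
    constant_traits <- setdiff(
      names(species_constants)[vapply(species_constants, is.numeric, logical(1))],
      "species")
  } else {
    species_constants <- tibble(species = character())
  }
  if (length(intersect(traits, constant_traits)))
    abort("A trait cannot be both plant-level and a species constant.")

  logged <- character(0)
  if (isTRUE(log10_traits)) {
    for (tr in traits) {
      v <- plants[[tr]]
      if (any(v[!is.na(v)] <= 0))
        abort(paste0("Trait `", tr, "` has non-positive values; cannot log10-transform."))
      plants[[tr]] <- log10(v)
    }
    for (tr in constant_traits) {
      v <- species_constants[[tr]]
      if (any(v[!is.na(v)] <= 0))
        abort(paste0("Trait `", tr, "` has non-positive values; cannot log10-transform."))
      species_constants[[tr]] <- log10(v)
    }
    logged <- c(traits, constant_traits)
  }

  structure(
    list(
      community = arrange(community, .data$plot, .data$species),
      plants = arrange(plants, .data$species, .data$plot, .data$plant_id),
      plots = arrange(plots, .data$plot),
      constants = species_constants,
      imputed = tibble(species = character(), plot = character(),
                       trait = character(), value = double(),
                       n_donor_plots = integer(), note = character()),
      traits = traits,
      constant_traits = constant_traits,
      log10_traits = logged
    ),
    class = "occurrence_table"
  )
}

#' @export
print.occurrence_table <- function(x, ...) {
  cat("<occurrence_table>\n")
  cat("  ", length(unique(x$community$species)), "species x",
      length(unique(x$community$plot)), "plots;",
      nrow(x$community), "occurrences\n")
  cat("  ", nrow(x$plants), "plant records;",
      length(x$traits), "plant-level trait(s);",
      length(x$constant_traits), "species-constant trait(s)\n")
  if (nrow(x$imputed)) cat("  ", nrow(x$imputed), "imputed trait cell(s)\n")
  invisible(x)
}

#' Derive leaf and root functional traits from raw measurements
#'
#' Computes the standard derived traits from per-plant raw leaf and root
#' measures: specific leaf area (SLA = area/mass, cm2/g), leaf tissue density
#' (mass per leaf volume, mg/mm3, with leaf volume = area x thickness), specific
#' root length (SRL = length/mass, m/g) and root tissue density (mg/mm3).
#' Direct measures (leaf size, leaf thickness, root diameter) are passed
#' through.
#'
#' Expected input columns (any subset; only the derivable traits are
#' returned): `leaf_area_cm2`, `leaf_mass_g`, `leaf_thickness_mm`,
#' `root_length_m`, `root_volume_mm3`, `root_mass_g`, `root_diameter_mm`.
#'
#' @param raw Data frame of per-plant raw measures; identifier columns
#'   (`plant_id`, `species`, `plot`, `site`) are carried through.
#' @return A tibble of derived traits on the original (linear) scale. Records
#'   with non-positive masses or volumes are excluded; the exclusion log is in
#'   `attr(, "dropped")`.
#' @export
derive_traits <- function(raw) {
  raw <- as_tibble(raw)
  id_cols <- intersect(c("plant_id", "species", "plot", "site"), names(raw))

  bad <- rep(FALSE, nrow(raw))
  why <- rep(NA_character_, nrow(raw))
  flag <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    why[cond & !bad] <<- msg
    bad <<- bad | cond
  }
  if ("leaf_mass_g" %in% names(raw)) flag(raw$leaf_mass_g <= 0, "non-positive leaf mass")
  if ("root_mass_g" %in% names(raw)) flag(raw$root_mass_g <= 0, "non-positive root mass")
  if ("root_volume_mm3" %in% names(raw)) flag(raw$root_volume_mm3 <= 0, "non-positive root volume")
  if (all(c("leaf_area_cm2", "leaf_thickness_mm") %in% names(raw)))
    flag(raw$leaf_area_cm2 * raw$leaf_thickness_mm <= 0, "non-positive leaf volume")

  dropped <- tibble(row = which(bad), reason = why[bad])
  if (nrow(dropped))
    warn(paste0(nrow(dropped), " record(s) with non-positive mass/volume excluded."))
  ok <- raw[!bad, , drop = FALSE]

  out <- ok[id_cols]
  has <- function(...) all(c(...) %in% names(ok))
  if (has("leaf_area_cm2")) out$leaf_size <- ok$leaf_area_cm2
  if (has("leaf_thickness_mm")) out$leaf_thickness <- ok$leaf_thickness_mm
  if (has("leaf_area_cm2", "leaf_mass_g"))
    out$sla <- ok$leaf_area_cm2 / ok$leaf_mass_g
  if (has("leaf_area_cm2", "leaf_thickness_mm", "leaf_mass_g")) {
    leaf_volume_mm3 <- ok$leaf_area_cm2 * 100 * ok$leaf_thickness_mm # cm2 -> mm2
    out$leaf_density <- ok$leaf_mass_g * 1000 / leaf_volume_mm3      # g -> mg
  }
  if (has("root_length_m", "root_mass_g"))
    out$srl <- ok$root_length_m / ok$root_mass_g
  if (has("root_mass_g", "root_volume_mm3"))
    out$root_density <- ok$root_mass_g * 1000 / ok$root_volume_mm3
  if (has("root_diameter_mm")) out$root_diameter <- ok$root_diameter_mm

  attr(out, "dropped") <- dropped
  out
}

#' Impute missing species-by-plot trait values
#'
#' A species can occur in a plot without a usable trait measurement there
#' (local rarity, failed collection). Such occurrences receive the mean of the
#' species' measured values from other plots at the same site; when the
#' species was never measured at that site, its global mean is used and the
#' log entry is flagged `"cross_site"`. Species never measured for a trait
#' keep that trait missing (and are dropped, with a message, by
#' [trait_gradient()] for that trait).
#'
#' @param occ An [occurrence_table()].
#' @param traits Trait names to impute (default: all plant-level traits).
#' @return The occurrence table with its `imputed` tibble filled in; retrieve
#'   it with [imputation_log()].
#' @export
impute_missing_traits <- function(occ, traits = NULL) {
  stopifnot(inherits(occ, "occurrence_table"))
  traits <- traits %||% occ$traits
  site_of <- setNames(occ$plots$site, occ$plots$plot)

  logs <- list()
  for (tr in traits) {
    meas <- occ$plants |>
      filter(!is.na(.data[[tr]])) |>
      mutate(site = site_of[.data$plot])
    measured_pairs <- distinct(meas, .data$species, .data$plot)
    todo <- anti_join(occ$community, measured_pairs, by = c("species", "plot")) |>
      mutate(site = site_of[.data$plot])
    if (!nrow(todo)) next
    never <- setdiff(todo$species, meas$species)
    if (length(never)) {
      warn(paste0("Species never measured for `", tr, "`: ",
                  paste(never, collapse = ", "), "; left missing."))
      todo <- filter(todo, !(.data$species %in% never))
    }
    if (!nrow(todo)) next
    site_means <- meas |>
      group_by(.data$species, .data$site) |>
      summarise(value = mean(.data[[tr]]), n_donor_plots = dplyr::n_distinct(.data$plot),
                .groups = "drop")
    global_means <- meas |>
      group_by(.data$species) |>
      summarise(gvalue = mean(.data[[tr]]), gn = dplyr::n_distinct(.data$plot),
                .groups = "drop")
    filled <- todo |>
      left_join(site_means, by = c("species", "site")) |>
      left_join(global_means, by = "species") |>
      mutate(
        note = ifelse(is.na(.data$value), "cross_site", "same_site"),
        n_donor_plots = ifelse(is.na(.data$value), .data$gn, .data$n_donor_plots),
        value = ifelse(is.na(.data$value), .data$gvalue, .data$value),
        trait = tr
      ) |>
      select("species", "plot", "trait", "value", "n_donor_plots", "note")
    logs[[tr]] <- filled
  }
  new_log <- bind_rows(logs)
  if (nrow(new_log)) {
    occ$imputed <- bind_rows(occ$imputed, new_log) |>
      distinct(.data$species, .data$plot, .data$trait, .keep_all = TRUE) |>
      arrange(.data$trait, .data$species, .data$plot)
  }
  occ
}

#' Retrieve the imputation log of an occurrence table
#'
#' @param occ An [occurrence_table()].
#' @return A tibble with one row per imputed (species, plot, trait) cell.
#' @export
imputation_log <- function(occ) {
  stopifnot(inherits(occ, "occurrence_table"))
  occ$imputed
}
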