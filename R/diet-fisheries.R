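#' Standardize a raw diet source
#'
#' Drops unidentified material and renormalizes the remaining prey amounts
#' (prey weight or percent frequency of occurrence are treated identically
#' after this normalization) so the identified-prey proportions sum to 1.
#'
#' @param src A tibble with columns `prey` and `amount` (nonnegative), and
#'   optionally `n` (predator sample size) and `basis`.
#' @param unidentified_labels Prey labels treated as unidentified (matched
#'   case-insensitively; default any label containing "unid").
#' @return The source tibble with a normalized `proportion` column (the
#'   `amount` column is dropped).
#' @export
standardize_diet <- function(src, unidentified_labels = NULL) {
  src <- tibble::as_tibble(src)
  if (any(src$amount < 0)) abort("amounts must be nonnegative",
                                 class = "shelfweb_domain_error")
  unid <- if (is.null(unidentified_labels)) {
    grepl("unid", src$prey, ignore.case = TRUE)
  } else {
    tolower(src$prey) %in% tolower(unidentified_labels)
  }
  keep <- src[!unid, ]
  tot <- sum(keep$amount)
  if (tot <= 0) abort("no identified prey in source", class = "shelfweb_empty_diet")
  keep$proportion <- keep$amount / tot
  keep$amount <- NULL
  keep
}

#' Merge diet sources for one predator
#'
#' Sample-size-weighted average of standardized diets: each source's prey
#' proportions receive weight `n_k / sum(n)` where `n_k` is the number of
#' predator individuals behind source `k`. Order of sources is irrelevant.
#'
#' @param sources A list of standardized sources (tibbles with `prey`,
#'   `proportion`, `n`), or a single tibble with a `source` column.
#' @return A tibble `(prey, proportion)` summing to 1.
#' @export
merge_sources <- function(sources) {
  if (is.data.frame(sources)) {
    sources <- split(tibble::as_tibble(sources), sources$source)
  }
  df <- purrr::map_dfr(sources, function(s) {
    n <- if ("n" %in% names(s)) s$n[1] else 1
    tibble::tibble(prey = s$prey, proportion = s$proportion, w = n)
  })
  total_w <- sum(purrr::map_dbl(sources, ~ if ("n" %in% names(.x)) .x$n[1] else 1))
  out <- df |>
    dplyr::group_by(.data$prey) |>
    dplyr::summarise(proportion = sum(.data$proportion * .data$w) / total_w,
                     .groups = "drop")
  out$proportion <- out$proportion / sum(out$proportion)
  out
}

#' Combine predator species into a functional-group diet
#'
#' Biomass-share-weighted sum of member-species diets: each species
#' contributes its diet proportions times the share of the functional
#' group's biomass it accounts for.
#'
#' @param diets Named list of per-species diet tibbles (`prey`, `proportion`).
#' @param shares Named numeric vector of biomass shares (same names; should
#'   sum to 1 -- renormalized if not).
#' @return A tibble `(prey, proportion)` summing to 1.
#' @export
species_to_group <- function(diets, shares) {
  shares <- shares[names(diets)]
  if (anyNA(shares)) abort("every diet needs a biomass share",
                           class = "shelfweb_domain_error")
  shares <- shares / sum(shares)
  df <- purrr::imap_dfr(diets, function(d, nm) {
    tibble::tibble(prey = d$prey, proportion = d$proportion * shares[[nm]])
  })
  df |>
    dplyr::group_by(.data$prey) |>
    dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop")
}

#' Disaggregate broad prey labels into model groups
#'
#' Splits a broad prey label (e.g. "cephalopod") across its member
#' functional groups in proportion to group biomass, restricted to members
#' observed at least once in this predator's diet; if no member was
#' observed, the split covers all members (with a warning).
#'
#' @param diet A tibble `(prey, proportion)` possibly containing broad labels.
#' @param broad_map A tibble `(broad, member)` listing the member groups of
#'   each broad label.
#' @param biomasses Named numeric vector of member-group biomasses.
#' @param observed Character vector of prey groups observed in this
#'   predator's diet (used to restrict the split).
#' @return A tibble `(prey, proportion)` over model groups, summing to 1.
#' @export
disaggregate_broad_prey <- function(diet, broad_map, biomasses,
                                    observed = character(0)) {
  diet <- tibble::as_tibble(diet)
  broad_map <- tibble::as_tibble(broad_map)
  rows <- purrr::pmap_dfr(diet, function(prey, proportion, ...) {
    if (!prey %in% broad_map$broad) {
      return(tibble::tibble(prey = prey, proportion = proportion))
    }
    members <- broad_map$member[broad_map$broad == prey]
    use <- intersect(members, observed)
    if (length(use) == 0) {
      warn(paste0("broad label '", prey,
                  "' has no observed member group; splitting across all members"))
      use <- members
    }
    b <- biomasses[use]
    if (anyNA(b) || sum(b) <= 0) abort(paste0("missing biomass for members of '",
                                              prey, "'"),
                                       class = "shelfweb_domain_error")
    tibble::tibble(prey = use, proportion = proportion * b / sum(b))
  })
  rows |>
    dplyr::group_by(.data$prey) |>
    dplyr::summarise(proportion = sum(.data$proportion), .groups = "drop")
}

#' Rescale one prey's share and renormalize the rest
#'
#' Sets the target prey to `new_value` and rescales the remaining prey
#' proportionally so the column still sums to 1 (relative ratios of
#' untouched prey are preserved).
#'
#' @param diet A tibble `(prey, proportion)`.
#' @param prey The prey label to pin.
#' @param new_value Its new proportion in `[0, 1)`.
#' @return The adjusted diet tibble.
#' @export
rescale_prey <- function(diet, prey, new_value) {
  diet <- tibble::as_tibble(diet)
  i <- match(prey, diet$prey)
  if (is.na(i)) abort(paste0("prey '", prey, "' not in diet"),
                      class = "shelfweb_domain_error")
  others <- sum(diet$proportion[-i])
  if (others <= 0 && new_value < 1) {
    abort("cannot renormalize: no other prey", class = "shelfweb_domain_error")
  }
  diet$proportion[-i] <- diet$proportion[-i] * (1 - new_value) / others
  diet$proportion[i] <- new_value
  diet
}

#' Average a new diet with a legacy diet
#'
#' Unweighted arithmetic mean of two diet columns (prey union; absent prey
#' count as 0), renormalized to sum to 1.
#'
#' @param new_diet,legacy_diet Tibbles `(prey, proportion)`.
#' @return A tibble `(prey, proportion)`.
#' @export
legacy_average <- function(new_diet, legacy_diet) {
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(new_diet), src = "new"),
    dplyr::mutate(tibble::as_tibble(legacy_diet), src = "legacy")
  ) |>
    tidyr::pivot_wider(names_from = "src", values_from = "proportion",
                       values_fill = 0, values_fn = sum) |>
    dplyr::mutate(proportion = (.data$new + .data$legacy) / 2)
  out <- df[, c("prey", "proportion")]
  out$proportion <- out$proportion / sum(out$proportion)
  out
}

#' Latitude interval overlap fraction
#' @noRd
lat_overlap <- function(zone_min, zone_max, bin_min, bin_max) {
  pmax(0, pmin(zone_max, bin_max) - pmax(zone_min, bin_min)) /
    (zone_max - zone_min)
}

#' Reallocate fisheries landings to model subregions and fleets
#'
#' Redistributes landings reported on coarse latitude zones onto the model's
#' latitude bins by the proportion of latitudinal overlap, spreads each bin's
#' landings across the shelf by per-group cross-shelf occurrence proportions,
#' maps gear categories to model fleets, and adds discards from per-fleet
#' per-group discard rates. Total landed weight is conserved exactly when
#' the model bins cover each source zone.
#'
#' @param zones A tibble `(lat_min, lat_max, group_id, gear, landed)` of
#'   source records (weights >= 0, `lat_min < lat_max`).
#' @param lat_bins A tibble `(bin, lat_min, lat_max)` of model latitude bins.
#' @param shelf_props A tibble `(group_id, shelf_zone, proportion)` giving
#'   each group's cross-shelf occurrence split (proportions sum to 1 per
#'   group); optional -- omitted means no cross-shelf split.
#' @param gear_map A tibble `(gear, fleet_id)`; every gear category in
#'   `zones` must be mapped.
#' @param discard_rates Optional tibble `(group_id, fleet_id, rate)`;
#'   discards = rate * landings.
#' @return A tibble `(bin, shelf_zone, group_id, fleet_id, landed, discarded)`.
#' @export
reallocate_landings <- function(zones, lat_bins, shelf_props = NULL,
                                gear_map, discard_rates = NULL) {
  zones <- tibble::as_tibble(zones)
  if (any(zones$lat_min >= zones$lat_max)) {
    abort("zone lat_min must be < lat_max", class = "shelfweb_domain_error")
  }
  unmapped <- setdiff(unique(zones$gear), gear_map$gear)
  if (length(unmapped) > 0) {
    abort(paste0("unmapped gear categor", if (length(unmapped) > 1) "ies: " else "y: ",
                 paste(unmapped, collapse = ", ")),
          class = "shelfweb_domain_error")
  }
  lb <- dplyr::rename(tibble::as_tibble(lat_bins),
                      bin_lat_min = "lat_min", bin_lat_max = "lat_max")
  out <- tidyr::crossing(zones, lb) |>
    dplyr::mutate(frac = lat_overlap(.data$lat_min, .data$lat_max,
                                     .data$bin_lat_min, .data$bin_lat_max)) |>
    dplyr::filter(.data$frac > 0) |>
    dplyr::mutate(landed = .data$landed * .data$frac)

  if (!is.null(shelf_props)) {
    out <- dplyr::inner_join(out, tibble::as_tibble(shelf_props),
                             by = "group_id",
                             relationship = "many-to-many") |>
      dplyr::mutate(landed = .data$landed * .data$proportion)
  } else {
    out$shelf_zone <- "all"
  }

  out <- dplyr::left_join(out, tibble::as_tibble(gear_map), by = "gear") |>
    dplyr::group_by(.data$bin, .data$shelf_zone, .data$group_id,
                    .data$fleet_id) |>
    dplyr::summarise(landed = sum(.data$landed), .groups = "drop")

  if (!is.null(discard_rates)) {
    out <- dplyr::left_join(out, tibble::as_tibble(discard_rates),
                            by = c("group_id", "fleet_id")) |>
      dplyr::mutate(discarded = .data$landed * dplyr::coalesce(.data$rate, 0)) |>
      dplyr::select(-"rate")
  } else {
    out$discarded <- 0
  }
  out
}
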