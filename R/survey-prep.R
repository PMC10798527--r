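#' Delta-lognormal (Pennington) mean density
#'
#' Minimum-variance unbiased estimator of the mean for catch data that mix
#' exact zeros with lognormally distributed positives. With `m` positive
#' values out of `n`, and `ybar`/`s2` the mean and variance of the logs of
#' the positives, the estimate is `(m/n) * exp(ybar) * G_m(s2/2)`, where
#' `G_m` is Pennington's Bessel-type series. Degenerate cases: all zeros
#' return 0, a single positive `x1` returns `x1/n`.
#'
#' @param values Nonnegative numeric vector of per-haul densities.
#' @return The estimated mean density (same units as `values`).
#' @export
delta_lognormal_mean <- function(values) {
  if (length(values) < 1) abort("need at least one value", class = "shelfweb_domain_error")
  if (any(values < 0)) abort("values must be nonnegative", class = "shelfweb_domain_error")
  n <- length(values)
  pos <- values[values > 0]
  m <- length(pos)
  if (m == 0) return(0)
  if (m == 1) return(pos / n)
  y <- log(pos)
  ybar <- mean(y)
  s2 <- stats::var(y)
  (m / n) * exp(ybar) * pennington_g(m, s2 / 2)
}

# Pennington's G_m(t) = 1 + ((m-1)/m) t +
#   sum_{j>=2} (m-1)^(2j-1) t^j / (m^j (m+1)(m+3)...(m+2j-3) j!)
# truncated when terms fall below 1e-12 relative.
pennington_g <- function(m, t) {
  if (t == 0) return(1)
  total <- 1 + (m - 1) / m * t
  term_num <- (m - 1)  # (m-1)^(2j-1) built incrementally
  denom_prod <- 1      # (m+1)(m+3)...(m+2j-3)
  for (j in 2:200) {
    term_num <- term_num * (m - 1)^2
    denom_prod <- denom_prod * (m + 2 * j - 3)
    term <- term_num * t^j / (m^j * denom_prod * factorial(j))
    total <- total + term
    if (abs(term) < 1e-12 * abs(total)) break
  }
  total
}

#' Arithmetic mean density
#'
#' The plain mean including zeros: appropriate for acoustic-trawl and
#' mid-water tow data whose water-column distribution is roughly uniform.
#'
#' @param values Numeric vector of densities (zeros included).
#' @return The mean.
#' @export
arithmetic_mean_density <- function(values) {
  if (length(values) == 0) abort("empty input", class = "shelfweb_domain_error")
  mean(values)
}

#' Counts and mean length to biomass
#'
#' Converts a count plus a mean length to biomass through a power-law
#' length-weight relationship `W = a * L^b`.
#'
#' @param count Number of individuals (>= 0).
#' @param mean_length Mean length (units matching the `a`, `b` fit).
#' @param lw Length-weight coefficients `c(a, b)`, both > 0.
#' @return `count * a * mean_length^b`.
#' @export
counts_to_biomass <- function(count, mean_length, lw) {
  a <- lw[[1]]; b <- lw[[2]]
  if (a <= 0 || b <= 0) abort("length-weight coefficients must be > 0",
                              class = "shelfweb_domain_error")
  count * a * mean_length^b
}

#' Volumetric to areal density
#'
#' Vertical integration: multiplies a volumetric density (mt km^-3) by the
#' assumed occupied depth range to give an areal density (mt km^-2).
#'
#' @param density Volumetric density, mt km^-3.
#' @param depth_range_m Occupied vertical extent, m.
#' @return Areal density, mt km^-2.
#' @export
volumetric_to_areal <- function(density, depth_range_m) {
  density * depth_range_m / 1000
}

#' Gelatinous water-content biomass scaling
#'
#' Rescales gelatinous-group wet weight so one unit of gelatinous biomass
#' carries the same organic content as the reference prey it displaces:
#' multiply by `(1 - wc_gel) / (1 - wc_ref)`. The same scaler should be
#' applied to the group's contributions as prey in consumer diets.
#'
#' @param biomass Wet-weight biomass.
#' @param wc_gel Water-content fraction of the gelatinous group.
#' @param wc_ref Water-content fraction of the reference group
#'   (crustacean zooplankton or pelagic fish).
#' @return Scaled biomass.
#' @export
gelatinous_scaling <- function(biomass, wc_gel = 0.96, wc_ref = 0.80) {
  if (wc_gel < 0 || wc_gel >= 1 || wc_ref < 0 || wc_ref >= 1) {
    abort("water contents must lie in [0, 1)", class = "shelfweb_domain_error")
  }
  biomass * (1 - wc_gel) / (1 - wc_ref)
}

#' Annual mean from seasonal observations
#'
#' Periodic linear interpolation of day-of-year observations over a 365-day
#' year, then the mean of the interpolated daily series. A single
#' observation yields itself.
#'
#' @param doy Integer day-of-year values (1-365).
#' @param value Observed values at those days.
#' @return The annual mean.
#' @export
seasonal_annual_mean <- function(doy, value) {
  if (length(doy) != length(value) || length(doy) < 1) {
    abort("doy and value must be equal-length, nonempty", class = "shelfweb_domain_error")
  }
  if (length(doy) == 1) return(value)
  o <- order(doy)
  doy <- doy[o]; value <- value[o]
  # wrap: repeat the series one period to the left and right of the year
  x <- c(doy - 365, doy, doy + 365)
  y <- rep(value, 3)
  daily <- approx(x, y, xout = 1:365)$y
  mean(daily)
}

#' Production-model output to phytoplankton biomass
#'
#' Converts a monthly net-primary-production series (mg C m^-2 d^-1) to an
#' areal wet-weight biomass density by averaging the productive-season
#' months, converting carbon production to an annual wet-weight rate, and
#' dividing by the phytoplankton biomass-specific production rate.
#'
#' @param pp Numeric vector of monthly production values, mg C m^-2 d^-1,
#'   named or ordered January..December (length 12), or already-subset
#'   months.
#' @param pb Phytoplankton P/B, yr^-1 (> 0).
#' @param months Indices of the months averaged (default April-September).
#' @param c_to_ww Wet weight per unit carbon (default 10 g ww / g C).
#' @return Biomass density, mt km^-2.
#' @export
vgpm_to_phyto_biomass <- function(pp, pb, months = 4:9, c_to_ww = 10) {
  if (pb <= 0) abort("pb must be > 0", class = "shelfweb_domain_error")
  pp_season <- if (length(pp) == 12) pp[months] else pp
  mean_pp <- mean(pp_season)                  # mg C m^-2 d^-1
  # mg C m^-2 d^-1 -> g ww m^-2 yr^-1 == mt km^-2 yr^-1
  annual_ww <- mean_pp / 1000 * c_to_ww * 365
  annual_ww / pb
}

#' Phytoplankton size partition from chlorophyll
#'
#' Fraction of total phytoplankton in the small (flagellate, <= 10 um) size
#' class as a function of total chlorophyll a:
#' `P_small = 0.30821 * chl^-0.82351`, clamped to at most 1 (the power law
#' exceeds 1 at low chlorophyll). The large fraction is the complement.
#'
#' @param chl Chlorophyll a concentration, mg m^-3 (> 0).
#' @return A tibble `(chl, small_fraction, large_fraction)`.
#' @export
phyto_size_partition <- function(chl) {
  if (any(chl <= 0)) abort("chl must be > 0", class = "shelfweb_domain_error")
  small <- pmin(1, 0.30821 * chl^(-0.82351))
  tibble::tibble(chl = chl, small_fraction = small, large_fraction = 1 - small)
}

#' Subregional biomass densities from survey records
#'
#' The full per-group biomass pipeline: within each subregion, apply the
#' per-group estimator (delta-lognormal or arithmetic) to each species'
#' per-haul records from each survey; convert volumetric densities to areal
#' by the assumed depth range; apply the catchability scaler; average across
#' surveys where they overlap spatially; then sum member species into
#' functional groups.
#'
#' @param records A tibble with columns `station_id`, `subregion`, `survey`,
#'   `species`, `value`, `value_kind` (`"volumetric"` = mt km^-3 or
#'   `"areal"` = mt km^-2). Absence records (explicit zeros) must be present
#'   for sampled stations.
#' @param conversions A tibble keyed by `species` with columns `group_id`
#'   (target functional group), `estimator` (`"delta"` or `"arithmetic"`),
#'   `depth_range_m` (vertical integration for volumetric records) and
#'   `scaler` (catchability multiplier, default 1).
#' @return A tibble `(subregion, group_id, biomass)` in mt km^-2, plus a
#'   `"shelfweb_unmapped"` attribute listing species without a group (also
#'   raised as a warning).
#' @export
subregional_biomass <- function(records, conversions) {
  records <- tibble::as_tibble(records)
  conversions <- tibble::as_tibble(conversions)
  if (!"scaler" %in% names(conversions)) conversions$scaler <- 1
  unmapped <- setdiff(unique(records$species), conversions$species)
  if (length(unmapped) > 0) {
    warn(paste0("species with no functional-group mapping dropped: ",
                paste(unmapped, collapse = ", ")))
    records <- records[!records$species %in% unmapped, ]
  }
  df <- dplyr::left_join(records, conversions, by = "species")
  if (nrow(df) == 0) {
    out <- tibble::tibble(subregion = records$subregion[0],
                          group_id = integer(0), biomass = numeric(0))
    attr(out, "shelfweb_unmapped") <- unmapped
    return(out)
  }

  per_survey <- df |>
    dplyr::group_by(.data$subregion, .data$group_id, .data$species,
                    .data$survey) |>
    dplyr::summarise(
      est = if (dplyr::first(.data$estimator) == "delta") {
        delta_lognormal_mean(.data$value)
      } else {
        arithmetic_mean_density(.data$value)
      },
      est = if (dplyr::first(.data$value_kind) == "volumetric") {
        volumetric_to_areal(.data$est, dplyr::first(.data$depth_range_m))
      } else .data$est,
      est = .data$est * dplyr::first(.data$scaler),
      .groups = "drop"
    )

  per_species <- per_survey |>
    dplyr::group_by(.data$subregion, .data$group_id, .data$species) |>
    dplyr::summarise(biomass = mean(.data$est), .groups = "drop")

  out <- per_species |>
    dplyr::group_by(.data$subregion, .data$group_id) |>
    dplyr::summarise(biomass = sum(.data$biomass), .groups = "drop")
  attr(out, "shelfweb_unmapped") <- unmapped
  out
}
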