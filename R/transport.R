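#' Five-box cross-shelf geometry
#'
#' The physical scaffold is five boxes spanning the shelf: box I is the
#' vertically-integrated inner-shelf upwelling zone; boxes II/III are the
#' middle-shelf surface/sub-surface layers and IV/V the outer-shelf
#' surface/sub-surface layers, split at the annual-mean mixed layer depth
#' (default 15 m). Default areas and thicknesses describe a generic
#' several-hundred-kilometre upwelling shelf (inner 1-100 m, middle
#' 101-200 m, outer 201-1280 m isobath bands); supply your own for a
#' specific domain.
#'
#' @param alongshore_km Alongshore length of the domain, km.
#' @param mld_m Mixed layer depth separating surface from sub-surface, m.
#' @param widths_km Cross-shelf widths of the inner, middle and outer zones, km.
#' @param mean_depths_m Mean water-column depth of the three zones, m.
#' @return An object of class `shelf_geometry`: list with a `boxes` tibble
#'   (`box`, `zone`, `layer`, `area_km2`, `thickness_m`, `volume_km3`),
#'   `alongshore_km` and `mld_m`.
#' @export
shelf_geometry <- function(alongshore_km = 830, mld_m = 15,
                           widths_km = c(inner = 15, middle = 15, outer = 30),
                           mean_depths_m = c(inner = 50, middle = 150, outer = 500)) {
  if (mld_m <= 0) abort("mld_m must be > 0", class = "shelfweb_config_error")
  areas <- alongshore_km * widths_km
  boxes <- tibble::tibble(
    box = c("I", "II", "III", "IV", "V"),
    zone = c("inner", "middle", "middle", "outer", "outer"),
    layer = c("whole", "surface", "subsurface", "surface", "subsurface"),
    area_km2 = c(areas[["inner"]], areas[["middle"]], areas[["middle"]],
                 areas[["outer"]], areas[["outer"]]),
    thickness_m = c(mean_depths_m[["inner"]], mld_m,
                    mean_depths_m[["middle"]] - mld_m, mld_m,
                    mean_depths_m[["outer"]] - mld_m)
  )
  if (any(boxes$thickness_m <= 0)) {
    abort("mixed layer depth must be shallower than zone depths",
          class = "shelfweb_config_error")
  }
  boxes$volume_km3 <- boxes$area_km2 * boxes$thickness_m / 1000
  structure(list(boxes = boxes, alongshore_km = alongshore_km, mld_m = mld_m),
            class = "shelf_geometry")
}

#' @export
print.shelf_geometry <- function(x, ...) {
  cat("<shelf_geometry> alongshore ", x$alongshore_km, " km, MLD ",
      x$mld_m, " m\n", sep = "")
  print(x$boxes)
  invisible(x)
}

#' Upwelling forcing series
#'
#' A daily coastal upwelling transport index series: cross-shore transport in
#' m^2 s^-1 per metre of coastline, positive = upwelling (deep onshore flow),
#' negative = downwelling.
#'
#' @param dates Date vector, daily spacing.
#' @param cuti Numeric vector of the same length, finite.
#' @return A tibble of class `upwelling_series` with columns `date`, `cuti`.
#' @export
upwelling_series <- function(dates, cuti) {
  if (length(dates) != length(cuti)) abort("dates and cuti lengths differ",
                                           class = "shelfweb_config_error")
  if (any(!is.finite(cuti))) abort("cuti must be finite",
                                   class = "shelfweb_config_error")
  if (length(dates) > 1 && any(as.integer(diff(as.Date(dates))) != 1L)) {
    abort("upwelling series must have daily spacing", class = "shelfweb_config_error")
  }
  structure(tibble::tibble(date = as.Date(dates), cuti = cuti),
            class = c("upwelling_series", "tbl_df", "tbl", "data.frame"))
}

#' Monthly boundary nutrient climatology
#'
#' Climatological nitrate and ammonium concentrations (mmol N m^-3) at the
#' surface and deep oceanic boundaries, one row per month. Lookups are
#' periodic: any date maps to its month of year.
#'
#' @param no3_surface,no3_deep,nh4_surface,nh4_deep Length-12 nonnegative
#'   vectors (January..December).
#' @return A tibble of class `nutrient_climatology`.
#' @export
nutrient_climatology <- function(no3_surface, no3_deep, nh4_surface, nh4_deep) {
  vals <- list(no3_surface = no3_surface, no3_deep = no3_deep,
               nh4_surface = nh4_surface, nh4_deep = nh4_deep)
  for (nm in names(vals)) {
    if (length(vals[[nm]]) != 12) abort(paste0(nm, " must have 12 monthly values"),
                                        class = "shelfweb_config_error")
    if (any(vals[[nm]] < 0)) abort(paste0(nm, " must be nonnegative"),
                                   class = "shelfweb_config_error")
  }
  structure(tibble::tibble(month = 1:12, !!!vals),
            class = c("nutrient_climatology", "tbl_df", "tbl", "data.frame"))
}

# Interfaces along the upwelling circuit, in positive-CUTI flow order.
CIRCUIT <- matrix(c("ocean_deep", "V",
                    "V", "III",
                    "III", "I",
                    "I", "II",
                    "II", "IV",
                    "IV", "ocean_surface"),
                  ncol = 2, byrow = TRUE,
                  dimnames = list(NULL, c("from", "to")))

#' Upwelling-driven advection fluxes
#'
#' Converts a daily upwelling-index value into volume fluxes along the
#' cross-shelf circuit. Positive values drive deep onshore flow
#' ocean -> V -> III -> I with compensating surface offshore flow
#' I -> II -> IV -> ocean; negative values reverse every arrow. The
#' volumetric flux is `cuti` (m^2 s^-1 per m coastline) times the alongshore
#' length, converted to km^3 d^-1; continuity (inflow = outflow) holds at
#' every box by construction.
#'
#' @param cuti_value Upwelling index, m^2 s^-1 (any finite value).
#' @param geom A [shelf_geometry()].
#' @return A tibble `(from, to, flux_km3_d)` with nonnegative fluxes in the
#'   direction of flow.
#' @export
advection_fluxes <- function(cuti_value, geom) {
  stopifnot(inherits(geom, "shelf_geometry"))
  q <- cuti_value * geom$alongshore_km * 1000 * 86400 / 1e9  # km^3 d^-1
  circ <- CIRCUIT
  if (q < 0) {
    circ <- circ[rev(seq_len(nrow(circ))), c("to", "from")]
    colnames(circ) <- c("from", "to")
    q <- -q
  }
  tibble::tibble(from = circ[, "from"], to = circ[, "to"], flux_km3_d = q)
}

#' Boundary nutrient inputs
#'
#' Nutrient mass entering the domain through the oceanic boundary: inbound
#' volume flux times the climatological boundary concentration for the month
#' of `date`. Upwelling brings deep-boundary water into box V; downwelling
#' brings surface-boundary water into box IV.
#'
#' @param date A Date (any year; the climatology is periodic).
#' @param clim A [nutrient_climatology()].
#' @param fluxes Output of [advection_fluxes()].
#' @return A tibble `(box, no3_mmol_d, nh4_mmol_d)` for boxes receiving
#'   ocean inflow (possibly zero rows).
#' @export
boundary_input <- function(date, clim, fluxes) {
  mo <- as.integer(format(as.Date(date), "%m"))
  row <- clim[clim$month == mo, ]
  inbound <- fluxes[fluxes$from %in% c("ocean_deep", "ocean_surface") &
                      fluxes$flux_km3_d > 0, ]
  if (nrow(inbound) == 0) {
    return(tibble::tibble(box = character(0), no3_mmol_d = numeric(0),
                          nh4_mmol_d = numeric(0)))
  }
  conc_no3 <- ifelse(inbound$from == "ocean_deep", row$no3_deep, row$no3_surface)
  conc_nh4 <- ifelse(inbound$from == "ocean_deep", row$nh4_deep, row$nh4_surface)
  tibble::tibble(box = inbound$to,
                 no3_mmol_d = inbound$flux_km3_d * 1e9 * conc_no3,
                 nh4_mmol_d = inbound$flux_km3_d * 1e9 * conc_nh4)
}

#' Advect one day of state across the shelf
#'
#' Moves nutrient, plankton and detritus concentrations between boxes along
#' the daily flux circuit. A group's susceptibility to advection is
#' `1 - retention` (retention 1 = resists advection fully, 0 = passively
#' driven); nutrients always move. Non-nutrient groups see reflective ocean
#' boundaries: under `boundary = "reflective"` ocean inflow mirrors the
#' receiving box (no net import, no dilution) while offshore outflow exports
#' mass; under `"closed"` the ocean boundary exchanges no non-nutrient mass
#' at all. Detritus (and any variable with a positive `sinking` rate) also
#' sinks from surface boxes II and IV into III and V.
#'
#' @param state Numeric matrix, rows = boxes I..V, columns = state variables
#'   (must include `"NO3"`, `"NH4"`), units mmol N m^-3.
#' @param fluxes Output of [advection_fluxes()].
#' @param retention Named vector of retention fractions in `[0, 1]` for the
#'   non-nutrient columns of `state` (missing names default to 1).
#' @param geom A [shelf_geometry()].
#' @param boundary_conc Optional named vector `c(NO3 = ..., NH4 = ...)` of
#'   boundary concentrations used for nutrient inflow (mmol N m^-3); if
#'   `NULL` no boundary nutrient mass enters (use [boundary_input()]
#'   externally, or supply it here).
#' @param boundary `"reflective"` or `"closed"` (non-nutrient groups).
#' @param sinking Named vector of daily sinking fractions (fraction of the
#'   surface-box standing stock moved to the box below per day).
#' @param vertical_mixing Mixing velocity across the mixed-layer base
#'   (m d^-1): drives Fickian exchange between II and III and between IV and
#'   V in proportion to the concentration difference. 0 disables mixing.
#' @param dt Time step in days (default 1).
#' @return A list: `state` (updated matrix) and `exported` (named vector of
#'   mass, mmol, exported through the ocean boundary per variable).
#' @export
transport_step <- function(state, fluxes, retention = NULL, geom,
                           boundary_conc = NULL,
                           boundary = c("reflective", "closed"),
                           sinking = NULL, vertical_mixing = 0, dt = 1) {
  boundary <- match.arg(boundary)
  if (any(state < 0)) abort("state must be nonnegative", class = "shelfweb_step_error")
  vars <- colnames(state)
  ret <- setNames(rep(1, length(vars)), vars)
  if (!is.null(retention)) ret[names(retention)] <- retention
  ret[c("NO3", "NH4")] <- 0
  sink_vec <- setNames(rep(0, length(vars)), vars)
  if (!is.null(sinking)) sink_vec[names(sinking)] <- sinking
  q <- fluxes$flux_km3_d[1] * 1e9 * dt
  # direction is encoded by the first interface of the circuit
  positive <- fluxes$from[1] == "ocean_deep"
  bconc <- c(NO3 = 0, NH4 = 0)
  if (!is.null(boundary_conc)) bconc[names(boundary_conc)] <- boundary_conc
  mix_m3 <- vertical_mixing * geom$boxes$area_km2[c(2, 4)] * 1e6 * dt
  transport_core(state, q, positive, ret, bconc, boundary,
                 sink_vec, geom$boxes$volume_km3 * 1e9, mix_m3 = mix_m3)
}

# Shared advection/mixing/sinking core. state: 5 x vars concentration matrix
# (rows I..V); q: volume moved per step, m^3 (>= 0); positive: upwelling
# direction; mix_m3: exchange volumes for the II<->III and IV<->V mixed-layer
# interfaces. Returns list(state, exported).
transport_core <- function(state, q, positive, ret, bconc, boundary,
                           sink_vec, vol_m3, mix_m3 = c(0, 0)) {
  vars <- colnames(state)
  nn <- !(vars %in% c("NO3", "NH4"))
  mass <- state * vol_m3
  dmass <- mass * 0
  exported <- setNames(rep(0, length(vars)), vars)
  mob <- 1 - ret

  if (q > 0) {
    # interior interfaces (from_box -> to_box), in flow order
    path <- if (positive) rbind(c(5, 3), c(3, 1), c(1, 2), c(2, 4)) else
      rbind(c(4, 2), c(2, 1), c(1, 3), c(3, 5))
    in_box <- if (positive) 5L else 4L       # ocean inflow target
    out_box <- if (positive) 4L else 5L      # offshore outflow source
    for (k in seq_len(nrow(path))) {
      i <- path[k, 1]; j <- path[k, 2]
      move <- q * state[i, ] * mob
      dmass[i, ] <- dmass[i, ] - move
      dmass[j, ] <- dmass[j, ] + move
    }
    # ocean inflow: nutrients at boundary concentration; non-nutrients mirror
    # the receiving box (reflective: no net import, no dilution)
    dmass[in_box, "NO3"] <- dmass[in_box, "NO3"] + q * bconc[["NO3"]]
    dmass[in_box, "NH4"] <- dmass[in_box, "NH4"] + q * bconc[["NH4"]]
    if (boundary == "reflective") {
      mirror <- q * state[in_box, nn] * mob[nn]
      dmass[in_box, nn] <- dmass[in_box, nn] + mirror
      # the mirror inflow offsets export in the ledger: reflective boundaries
      # report net (outflow minus mirrored inflow) non-nutrient export
      exported[nn] <- exported[nn] - mirror
    }
    # offshore outflow: export (non-nutrients retained under "closed")
    move <- q * state[out_box, ] * mob
    if (boundary == "closed") move[nn] <- 0
    dmass[out_box, ] <- dmass[out_box, ] - move
    exported <- exported + move
  }

  if (any(mix_m3 > 0)) {
    # Fickian exchange across the mixed-layer base; preserves uniform fields
    pairs <- list(c(2L, 3L), c(4L, 5L))
    for (k in 1:2) {
      i <- pairs[[k]][1]; j <- pairs[[k]][2]
      ex <- mix_m3[k] * (state[i, ] - state[j, ]) * mob
      dmass[i, ] <- dmass[i, ] - ex
      dmass[j, ] <- dmass[j, ] + ex
    }
  }

  if (any(sink_vec > 0)) {
    sv <- which(sink_vec > 0)
    for (p in list(c(2L, 3L), c(4L, 5L))) {
      mv <- sink_vec[sv] * mass[p[1], sv]
      dmass[p[1], sv] <- dmass[p[1], sv] - mv
      dmass[p[2], sv] <- dmass[p[2], sv] + mv
    }
  }

  new_mass <- mass + dmass
  if (any(new_mass < -1e-6 * max(mass, 1))) {
    abort("negative state after transport step; reduce dt",
          class = "shelfweb_step_error")
  }
  new_mass[new_mass < 0] <- 0
  list(state = new_mass / vol_m3, exported = exported)
}

#' Day-of-year periodic helper: month of a simulation day
#' @noRd
month_of_doy <- function(doy) {
  cum <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  findInterval(((doy - 1) %% 365) + 1, c(0, head(cum, -1)) + 1)
}
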