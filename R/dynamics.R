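#' Simulation configuration
#'
#' Collects the tunable parameters of the daily nitrogen-currency simulation.
#' Fractions are per daily time step.
#'
#' @param years Simulated years (365-day years).
#' @param pelagic_remineralization Fraction of the pelagic-detritus (and egg)
#'   pools remineralized to ammonium per day.
#' @param benthic_remineralization Fraction of the benthic-detritus (and
#'   offal) pools remineralized to ammonium per day.
#' @param benthic_sequestration Fraction of the benthic-detritus pool
#'   permanently removed (buried) per day.
#' @param nitrification_rate Daily fraction of ammonium nitrified to nitrate
#'   in the sub-surface boxes III and V.
#' @param ammonium_preference Relative preference weight for ammonium over
#'   nitrate in producer uptake (>= 0; 1 = neutral).
#' @param uptake_surge Ratio of the producers' maximum uptake rate to their
#'   balanced production rate (>= 1). Values above 1 let producer biomass
#'   grow when nutrients allow, so the web equilibrates where nutrient
#'   supply, not the initial condition, limits primary production.
#' @param init_no3,init_nh4 Initial nutrient concentrations, mmol N m^-3.
#' @param ww_to_c Wet weight to carbon mass fraction used to convert areal
#'   biomass (mt km^-2, i.e. g ww m^-2) to nitrogen currency through the
#'   Redfield C:N of 106:16.
#' @param detritus_sinking Daily fraction of surface-box pelagic detritus
#'   sinking into the sub-surface box beneath.
#' @param vertical_mixing_m_d Mixing velocity across the mixed-layer base,
#'   m d^-1 (see [transport_step()]); supplies sub-surface nitrate to the
#'   mid- and outer-shelf surface boxes.
#' @param subsurface_senescence Daily fraction of sub-surface phytoplankton
#'   standing stock transferred to pelagic detritus (boxes III and V host no
#'   grazing; senescence, detritus metabolism and nitrification only).
#' @param boundary Ocean-boundary convention for non-nutrient groups
#'   (see [transport_step()]).
#' @param extinction_threshold Production (biomass) fraction of the initial
#'   value below which a group is flagged as going extinct (default 1%).
#' @param save_daily If `TRUE`, keep daily per-group total-mass trajectories
#'   (memory scales with years); annual means are always kept.
#' @param seed Optional integer seed recorded with the run (the integration
#'   itself is deterministic).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(years = 10,
                              pelagic_remineralization = 0.1,
                              benthic_remineralization = 0.1,
                              benthic_sequestration = 0.1,
                              nitrification_rate = 0.1,
                              ammonium_preference = 2,
                              uptake_surge = 2,
                              init_no3 = 15, init_nh4 = 1,
                              ww_to_c = 0.1,
                              detritus_sinking = 0.2,
                              vertical_mixing_m_d = 1,
                              subsurface_senescence = 0.05,
                              boundary = c("reflective", "closed"),
                              extinction_threshold = 0.01,
                              save_daily = FALSE,
                              seed = NULL) {
  boundary <- match.arg(boundary)
  fr <- c(pelagic_remineralization, benthic_remineralization,
          benthic_sequestration, nitrification_rate, detritus_sinking,
          subsurface_senescence)
  if (any(fr < 0 | fr > 1)) abort("daily fractions must lie in [0, 1]",
                                  class = "shelfweb_config_error")
  if (years < 1) abort("years must be >= 1", class = "shelfweb_config_error")
  if (ammonium_preference < 0) abort("ammonium_preference must be >= 0",
                                     class = "shelfweb_config_error")
  if (uptake_surge < 1) abort("uptake_surge must be >= 1",
                              class = "shelfweb_config_error")
  structure(as.list(environment()), class = "simulation_config")
}

mmoln_per_gww <- function(ww_to_c) ww_to_c * 1000 * (16 / 106) / 12.011

FOODWEB_BOXES <- c("I", "II", "IV")
SUBSURFACE_BOXES <- c("III", "V")

#' Run the daily nitrogen-currency simulation
#'
#' Integrates the expanded trophic network on the five-box shelf under daily
#' upwelling forcing. Each day, per box: (1) cross-shelf advection, boundary
#' nutrient input, and detritus sinking; (2) nutrient-limited producer uptake
#' of NO3/NH4 weighted by the ammonium preference; (3) donor-controlled flow
#' of every living group's daily production along the network (consumption,
#' landings out, discards to offal, senescence to pools); (4) consumer intake
#' split into growth (P/Q), feces (1-AE, routed per the fate table) and
#' excretion to NH4; detritus pools grazed at their balanced turnover; (5)
#' remineralization of detritus to NH4 and sequestration of benthic detritus;
#' (6) nitrification of NH4 to NO3 in the sub-surface boxes. The Ecopath
#' balance point is a fixed point of these dynamics.
#'
#' @param net A [expand_fates()] trophic network.
#' @param geom A [shelf_geometry()].
#' @param forcing A list with `upwelling` (an [upwelling_series()], tiled
#'   year-wise if shorter than the run) and `climatology`
#'   (a [nutrient_climatology()]).
#' @param cfg A [simulation_config()].
#' @return An object of class `shelfweb_sim`: annual mean per-group total
#'   mass (`annual`, years x variables, mmol N), per-year per-box NO3/NH4
#'   uptake ledgers, extinction flags, landings/export/sequestration ledgers,
#'   the final state, clip counter, and (optionally) daily trajectories.
#' @export
run_simulation <- function(net, geom, forcing, cfg = simulation_config()) {
  g <- net$groups
  liv <- as.character(net$living)
  det <- as.character(net$detritus)
  vars <- c("NO3", "NH4", liv, det)
  boxes <- geom$boxes$box
  nb <- length(boxes)
  vol_m3 <- geom$boxes$volume_km3 * 1e9
  thick <- geom$boxes$thickness_m

  up <- forcing$upwelling
  clim <- forcing$climatology
  if (is.null(up) || is.null(clim)) {
    abort("forcing must supply $upwelling and $climatology",
          class = "shelfweb_config_error")
  }
  if (any(!is.finite(up$cuti))) abort("forcing gap: non-finite cuti",
                                      class = "shelfweb_config_error")
  steps_per_year <- 365L
  ndays <- cfg$years * steps_per_year
  cuti <- rep_len(up$cuti, ndays)     # short series are tiled

  # --- precomputed network pieces -----------------------------------------
  il <- match(liv, g$id); idet <- match(det, g$id)
  nl <- length(liv); nd <- length(det)
  pb_d <- ifelse(is.na(g$pb[il]), 0, g$pb[il]) / 365
  producers <- g$category[il] == "producer"
  A_LL <- net$A[liv, liv, drop = FALSE]                   # living -> living
  A_DL <- net$A[det, liv, drop = FALSE]                   # living -> pools
  a_land <- net$A["landings", liv]
  a_exp <- net$A["export", liv]
  # feces: pools x consumers -> pools x living (zeros for producers)
  F_DL <- matrix(0, nd, nl, dimnames = list(det, liv))
  f_exp <- setNames(numeric(nl), liv)
  cons_cols <- intersect(colnames(net$feces), liv)
  F_DL[, cons_cols] <- net$feces[det, cons_cols, drop = FALSE]
  f_exp[cons_cols] <- net$feces["export", cons_cols]
  exc <- setNames(numeric(nl), liv); grw <- setNames(numeric(nl), liv)
  exc[names(net$excretion)] <- net$excretion
  grw[names(net$growth)] <- net$growth
  A_det <- net$A_detritus[liv, det, drop = FALSE]         # pools -> living
  q_det <- net$detritus_turnover[det] / 365               # daily grazing rate
  q_det[!is.finite(q_det)] <- 0
  pool_lab <- net$pool_labels[det]
  remin_rate <- ifelse(pool_lab %in% c("pelagic_detritus", "invertebrate_eggs",
                                       "fish_eggs"),
                       cfg$pelagic_remineralization,
                       cfg$benthic_remineralization)
  seq_rate <- ifelse(pool_lab == "benthic_detritus", cfg$benthic_sequestration, 0)

  retention <- setNames(c(0, 0, g$retention[il], g$retention[idet]), vars)
  sink_vars <- det[pool_lab == "pelagic_detritus"]
  sinking <- if (cfg$detritus_sinking > 0 && length(sink_vars) > 0) {
    setNames(rep(cfg$detritus_sinking, length(sink_vars)), sink_vars)
  } else NULL

  # --- initial state -------------------------------------------------------
  conv <- mmoln_per_gww(cfg$ww_to_c)
  state <- matrix(0, nb, length(vars), dimnames = list(boxes, vars))
  state[, "NO3"] <- cfg$init_no3
  state[, "NH4"] <- cfg$init_nh4
  b_areal <- g$biomass[c(il, idet)]
  conc0 <- outer(1 / thick, b_areal * conv)               # boxes x (liv+det)
  colnames(conc0) <- c(liv, det)
  fb <- boxes %in% FOODWEB_BOXES
  state[fb, c(liv, det)] <- conc0[fb, ]
  sub_vars <- c(liv[producers], det)                      # sub-surface carries these
  state[!fb, sub_vars] <- conc0[!fb, sub_vars]

  init_mass <- colSums(state[, c(liv, det), drop = FALSE] * vol_m3)
  initial_nitrogen <- sum(state * vol_m3)

  # --- ledgers -------------------------------------------------------------
  years <- cfg$years
  annual <- matrix(0, years, length(vars), dimnames = list(NULL, vars))
  upt_no3 <- matrix(0, years, nb, dimnames = list(NULL, boxes))
  upt_nh4 <- matrix(0, years, nb, dimnames = list(NULL, boxes))
  landings_ledger <- 0; export_ledger <- 0; seq_ledger <- 0; input_ledger <- 0
  clip_count <- 0L; clip_mass <- 0
  min_ratio <- setNames(rep(Inf, nl), liv)
  daily <- if (cfg$save_daily) matrix(NA_real_, ndays, nl + nd,
                                      dimnames = list(NULL, c(liv, det))) else NULL

  pref <- cfg$ammonium_preference
  fbi <- which(fb); sbi <- which(!fb)

  # precomputed per-day physics and hot-loop constants
  q_day <- cuti * geom$alongshore_km * 1000 * 86400      # m^3 d^-1
  mo_day <- month_of_doy(seq_len(ndays))
  clim_no3 <- ifelse(q_day >= 0, clim$no3_deep[mo_day], clim$no3_surface[mo_day])
  clim_nh4 <- ifelse(q_day >= 0, clim$nh4_deep[mo_day], clim$nh4_surface[mo_day])
  ret_vec <- retention
  sink_vec <- setNames(rep(0, length(vars)), vars)
  if (!is.null(sinking)) sink_vec[names(sinking)] <- sinking
  mix_m3 <- cfg$vertical_mixing_m_d * geom$boxes$area_km2[c(2, 4)] * 1e6
  nfb <- length(fbi)
  PBD <- matrix(pb_d, nfb, nl, byrow = TRUE)
  QDET <- matrix(q_det, nfb, nd, byrow = TRUE)
  GRW <- matrix(grw, nfb, nl, byrow = TRUE)
  REM <- matrix(remin_rate, nfb, nd, byrow = TRUE)
  SEQ <- matrix(seq_rate, nfb, nd, byrow = TRUE)
  REM2 <- matrix(remin_rate, length(sbi), nd, byrow = TRUE)
  SEQ2 <- matrix(seq_rate, length(sbi), nd, byrow = TRUE)
  tA_LL <- t(A_LL); tA_det <- t(A_det); tA_DL <- t(A_DL); tF_DL <- t(F_DL)
  surge <- cfg$uptake_surge
  liv_det <- c(liv, det)

  for (day in seq_len(ndays)) {
    yr <- ((day - 1) %/% 365) + 1
    # (1) physics
    q <- abs(q_day[day])
    bconc <- c(NO3 = clim_no3[day], NH4 = clim_nh4[day])
    if (q > 0) input_ledger <- input_ledger + q * sum(bconc)
    ts <- transport_core(state, q, positive = q_day[day] >= 0, ret = ret_vec,
                         bconc = bconc, boundary = cfg$boundary,
                         sink_vec = sink_vec, vol_m3 = vol_m3, mix_m3 = mix_m3)
    state <- ts$state
    export_ledger <- export_ledger + sum(ts$exported)

    # (2)-(5) biology in food-web boxes, vectorized across boxes
    S <- state[fbi, , drop = FALSE]
    P_pot <- S[, liv, drop = FALSE] * PBD
    base_demand <- rowSums(P_pot[, producers, drop = FALSE])
    demand <- surge * base_demand
    no3 <- S[, "NO3"]; nh4 <- S[, "NH4"]
    U_tot <- pmin(demand, no3 + nh4)
    wden <- pref * nh4 + no3
    wnh4 <- ifelse(wden > 0, pref * nh4 / wden, 0)
    nh4_up <- pmin(wnh4 * U_tot, nh4)
    no3_up <- pmin(U_tot - nh4_up, no3)
    U <- nh4_up + no3_up

    # donor flows scale with standing-stock production capacity (P_pot);
    # realized uptake U is the producers' growth, split by their share of demand
    P <- P_pot
    det_graze <- S[, det, drop = FALSE] * QDET

    intake <- P %*% tA_LL + det_graze %*% tA_det          # boxes x living
    growth <- intake * GRW
    u_share <- ifelse(base_demand > 0, U / base_demand, 0)
    growth[, producers] <- P_pot[, producers, drop = FALSE] * u_share

    pool_in <- P %*% tA_DL + intake %*% tF_DL             # boxes x pools
    nh4_gain <- intake %*% exc                            # excretion
    land_out <- P %*% a_land
    exp_out <- P %*% a_exp + intake %*% f_exp

    S[, liv] <- S[, liv, drop = FALSE] + growth - P
    remin <- S[, det, drop = FALSE] * REM
    seqs <- S[, det, drop = FALSE] * SEQ
    S[, det] <- S[, det, drop = FALSE] + pool_in - det_graze - remin - seqs
    S[, "NO3"] <- no3 - no3_up
    S[, "NH4"] <- nh4 - nh4_up + as.numeric(nh4_gain) + rowSums(remin)

    upt_no3[yr, fbi] <- upt_no3[yr, fbi] + no3_up * vol_m3[fbi]
    upt_nh4[yr, fbi] <- upt_nh4[yr, fbi] + nh4_up * vol_m3[fbi]
    landings_ledger <- landings_ledger + sum(land_out * vol_m3[fbi])
    export_ledger <- export_ledger + sum(exp_out * vol_m3[fbi])
    seq_ledger <- seq_ledger + sum(seqs * vol_m3[fbi])
    state[fbi, ] <- S

    # sub-surface boxes: senescence, detritus metabolism, nitrification
    S2 <- state[sbi, , drop = FALSE]
    if (any(producers) && nd > 0) {
      sen <- S2[, liv[producers], drop = FALSE] * cfg$subsurface_senescence
      S2[, liv[producers]] <- S2[, liv[producers], drop = FALSE] - sen
      pel <- det[pool_lab == "pelagic_detritus"]
      sink_to <- if (length(pel) > 0) pel[1] else det[1]
      S2[, sink_to] <- S2[, sink_to] + rowSums(sen)
    }
    remin2 <- S2[, det, drop = FALSE] * REM2
    seqs2 <- S2[, det, drop = FALSE] * SEQ2
    S2[, det] <- S2[, det, drop = FALSE] - remin2 - seqs2
    S2[, "NH4"] <- S2[, "NH4"] + rowSums(remin2)
    nitr <- cfg$nitrification_rate * S2[, "NH4"]
    S2[, "NH4"] <- S2[, "NH4"] - nitr
    S2[, "NO3"] <- S2[, "NO3"] + nitr
    seq_ledger <- seq_ledger + sum(seqs2 * vol_m3[sbi])
    state[sbi, ] <- S2

    if (any(!is.finite(state))) {
      abort(paste0("integration failure (non-finite state) at day ", day),
            class = "shelfweb_integration_error")
    }
    neg <- state < 0
    if (any(neg)) {
      clip_count <- clip_count + sum(neg)
      clip_mass <- clip_mass + sum(pmax(-state, 0) * vol_m3)
      state[neg] <- 0
    }

    tot <- colSums(state[, c(liv, det), drop = FALSE] * vol_m3)
    annual[yr, c(liv, det)] <- annual[yr, c(liv, det)] + tot / 365
    annual[yr, c("NO3", "NH4")] <- annual[yr, c("NO3", "NH4")] +
      colSums(state[, c("NO3", "NH4"), drop = FALSE] * vol_m3) / 365
    ratio <- ifelse(init_mass[liv] > 0, tot[liv] / init_mass[liv], 1)
    min_ratio <- pmin(min_ratio, ratio)
    if (cfg$save_daily) daily[day, ] <- tot
  }

  extinct <- names(min_ratio)[min_ratio < cfg$extinction_threshold]
  structure(list(
    annual = annual, uptake_no3 = upt_no3, uptake_nh4 = upt_nh4,
    extinct = extinct, min_ratio = min_ratio,
    ledgers = c(landings = landings_ledger, export = export_ledger,
                sequestration = seq_ledger, boundary_input = input_ledger,
                clipped = clip_mass),
    initial_nitrogen = initial_nitrogen,
    final_state = state, clip_count = clip_count,
    daily = daily, geom = geom, cfg = cfg,
    living = liv, detritus = det, producers = liv[producers],
    group_names = setNames(g$name[c(il, idet)], c(liv, det))
  ), class = "shelfweb_sim")
}

#' @export
print.shelfweb_sim <- function(x, ...) {
  cat("<shelfweb_sim> ", x$cfg$years, " years, ", length(x$living),
      " living groups; extinctions: ", length(x$extinct),
      "; clipped updates: ", x$clip_count, "\n", sep = "")
  invisible(x)
}

#' Last-window stability of simulated groups
#'
#' Per-group relative change between the annual mean at the start of the
#' final window and the final year:
#' `|mean(final year) - mean(year end-window)| / mean(year end-window)`.
#' Groups whose reference mean is zero are reported extinct rather than
#' divided.
#'
#' @param out A `shelfweb_sim`, or a numeric matrix of trajectories
#'   (rows = time, columns = groups).
#' @param window_years Width of the assessment window (default 20).
#' @param threshold Pass threshold on the relative change (default 0.05).
#' @param steps_per_year Rows per year when `out` is a daily matrix
#'   (use 1 for an annual matrix).
#' @return A tibble `(group, reference, final, change, pass, extinct)`.
#' @export
stability_metric <- function(out, window_years = 20, threshold = 0.05,
                             steps_per_year = 365) {
  if (inherits(out, "shelfweb_sim")) {
    traj <- out$annual[, c(out$living, out$detritus), drop = FALSE]
    steps_per_year <- 1
  } else {
    traj <- as.matrix(out)
  }
  ny <- nrow(traj) %/% steps_per_year
  if (ny < window_years + 1) {
    abort("run shorter than the assessment window", class = "shelfweb_config_error")
  }
  yr_mean <- function(y) {
    rows <- ((y - 1) * steps_per_year + 1):(y * steps_per_year)
    colMeans(traj[rows, , drop = FALSE])
  }
  ref <- yr_mean(ny - window_years)
  fin <- yr_mean(ny)
  change <- ifelse(ref > 0, abs(fin - ref) / ref, NA_real_)
  tibble::tibble(
    group = colnames(traj) %||% as.character(seq_along(ref)),
    reference = unname(ref), final = unname(fin), change = unname(change),
    pass = !is.na(change) & change <= threshold,
    extinct = ref == 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' f-ratio (new production share) by shelf zone
#'
#' Nitrate uptake divided by total (nitrate + ammonium) uptake over the
#' evaluation window (default: final simulated year), per cross-shelf zone:
#' inner = box I, mid = boxes II + III, outer = boxes IV + V.
#'
#' @param out A `shelfweb_sim`.
#' @param zone `"inner"`, `"mid"`, `"outer"` or `"all"`; default all three.
#' @param window_years Number of final years to aggregate (default 1).
#' @return A tibble `(zone, no3_uptake, nh4_uptake, f_ratio)`; `f_ratio` is
#'   `NA` where total uptake is zero.
#' @export
f_ratio <- function(out, zone = c("all", "inner", "mid", "outer"),
                    window_years = 1) {
  zone <- match.arg(zone)
  zones <- list(inner = "I", mid = c("II", "III"), outer = c("IV", "V"))
  if (zone != "all") zones <- zones[zone]
  ny <- nrow(out$uptake_no3)
  rows <- (ny - window_years + 1):ny
  purrr::map_dfr(names(zones), function(z) {
    bx <- zones[[z]]
    no3 <- sum(out$uptake_no3[rows, bx])
    nh4 <- sum(out$uptake_nh4[rows, bx])
    tibble::tibble(zone = z, no3_uptake = no3, nh4_uptake = nh4,
                   f_ratio = if (no3 + nh4 > 0) no3 / (no3 + nh4) else NA_real_)
  })
}

#' Ecosystem-average total primary production
#'
#' Volume-weighted mean daily uptake-driven production over the evaluation
#' window, mmol N m^-3 d^-1.
#'
#' @param out A `shelfweb_sim`.
#' @param window_years Number of final years to average (default 1).
#' @return A single number.
#' @export
total_primary_production <- function(out, window_years = 1) {
  ny <- nrow(out$uptake_no3)
  rows <- (ny - window_years + 1):ny
  total_uptake <- sum(out$uptake_no3[rows, ]) + sum(out$uptake_nh4[rows, ])
  vol_m3 <- sum(out$geom$boxes$volume_km3) * 1e9
  total_uptake / (length(rows) * 365 * vol_m3)
}

#' Tidy simulated annual trajectories
#'
#' @param x A `shelfweb_sim`.
#' @param ... Unused.
#' @return A long tibble `(year, group, name, mass_mmol)` of annual mean
#'   total mass per group.
#' @method tidy shelfweb_sim
#' @export
tidy.shelfweb_sim <- function(x, ...) {
  ann <- x$annual[, c(x$living, x$detritus), drop = FALSE]
  df <- tibble::as_tibble(ann)
  df$year <- seq_len(nrow(ann))
  out <- tidyr::pivot_longer(df, -"year", names_to = "group",
                             values_to = "mass_mmol")
  out$name <- unname(x$group_names[out$group])
  out[, c("year", "group", "name", "mass_mmol")]
}

#' Glance at a simulation
#'
#' @param x A `shelfweb_sim`.
#' @param ... Unused.
#' @return One-row tibble: years, extinctions, f-ratios by zone, total
#'   primary production, clip count.
#' @method glance shelfweb_sim
#' @export
glance.shelfweb_sim <- function(x, ...) {
  fr <- f_ratio(x)
  tibble::tibble(
    years = x$cfg$years,
    n_extinct = length(x$extinct),
    f_ratio_inner = fr$f_ratio[fr$zone == "inner"],
    f_ratio_mid = fr$f_ratio[fr$zone == "mid"],
    f_ratio_outer = fr$f_ratio[fr$zone == "outer"],
    total_pp = total_primary_production(x),
    clip_count = x$clip_count
  )
}
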