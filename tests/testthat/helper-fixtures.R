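# Three-group chain with a benthic detritus pool and hand-checkable balance:
# producer P (B=10, P/B=10) <- herbivore H (B=2, C/B=25, P/B=5)
#                           <- carnivore C (B=0.5, C/B=8, P/B=2)
# EE_P = 2*25/100 = 0.5 ; EE_H = 0.5*8/10 = 0.4 ; EE_C = 0.
toy_chain <- function(h_biomass = 2, h_ee = NULL, p_biomass = 10,
                      with_fleet = FALSE) {
  n_fleet <- if (with_fleet) 1 else 0
  groups <- tibble::tibble(
    id = seq_len(4 + n_fleet),
    name = c("producer", "herbivore", "carnivore", "benthic_detritus",
             if (with_fleet) "fleet_1"),
    category = c("producer", "consumer", "consumer", "detritus",
                 if (with_fleet) "fleet"),
    biomass = c(p_biomass, h_biomass, 0.5, 10, if (with_fleet) NA),
    pb = c(10, 5, 2, 0, if (with_fleet) NA),
    cb = c(NA, 25, 8, 0, if (with_fleet) NA),
    ae = c(NA, 0.8, 0.8, NA, if (with_fleet) NA),
    ee = c(NA, h_ee %||% NA, NA, NA, if (with_fleet) NA),
    ee_fixed = c(FALSE, !is.null(h_ee), FALSE, FALSE, if (with_fleet) FALSE),
    retention = c(0, 0.5, 1, 0, if (with_fleet) 1),
    pool = c(NA, NA, NA, "benthic_detritus", if (with_fleet) NA)
  )
  n <- nrow(groups)
  D <- matrix(0, n, n)
  D[1, 2] <- 1   # herbivore eats producer
  D[2, 3] <- 1   # carnivore eats herbivore
  fates <- make_default_fates(groups)
  # route everything to the single pool present
  fates$destination[fates$destination == "pelagic_detritus"] <- "benthic_detritus"
  fates <- dplyr::distinct(dplyr::summarise(
    dplyr::group_by(fates, group_id, flow_class, destination),
    fraction = sum(fraction), .groups = "drop"))
  catch <- if (with_fleet) {
    l <- matrix(0, n, 1, dimnames = list(groups$id, n))
    list(landings = l, discards = l)
  } else NULL
  ecopath_model(groups, D, catch = catch, fates = fates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

living_consumer_col <- function(m) {
  m$groups$id[m$groups$category == "consumer"][1]
}

# Direct per-group evaluation of the master equation: the independent oracle
# for the Ecopath solver. Returns EE for every living group of a model whose
# biomasses are all known.
ee_by_hand <- function(m) {
  g <- m$groups
  liv <- which(g$category %in% c("producer", "consumer"))
  cons <- which(g$category == "consumer" & !is.na(g$cb) & g$cb > 0)
  f_tot <- rep(0, nrow(g))
  if (!is.null(m$catch) && ncol(m$catch$landings) > 0) {
    f_tot <- rowSums(m$catch$landings) + rowSums(m$catch$discards)
  }
  sapply(liv, function(i) {
    pred <- sum(sapply(cons, function(j) g$biomass[j] * g$cb[j] * m$diet[i, j]))
    (pred + g$emigration[i] + f_tot[i] - g$immigration[i] - g$ba[i]) /
      (g$biomass[i] * g$pb[i])
  })
}

# Minimal simulation-shaped object for the uptake-ratio metrics.
fake_sim <- function(no3, nh4, geom = shelf_geometry()) {
  structure(list(
    uptake_no3 = matrix(no3, 1, 5, dimnames = list(NULL, geom$boxes$box)),
    uptake_nh4 = matrix(nh4, 1, 5, dimnames = list(NULL, geom$boxes$box)),
    geom = geom
  ), class = "shelfweb_sim")
}

default_forcing <- function(seed = 1, n_years = 1, annual_mean = 0.5) {
  list(
    upwelling = make_upwelling(n_years = n_years, annual_mean = annual_mean,
                               seed = seed),
    climatology = nutrient_climatology(rep(20, 12), rep(30, 12),
                                       rep(1, 12), rep(2, 12))
  )
}
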