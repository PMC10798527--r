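test_that("delta-lognormal estimator handles the degenerate cases", {
  expect_equal(delta_lognormal_mean(c(0, 0, 0)), 0)
  expect_equal(delta_lognormal_mean(rep(4.2, 6)), 4.2, tolerance = 1e-12)
  expect_equal(delta_lognormal_mean(c(0, 0, exp(1), exp(1))),
               0.5 * exp(1), tolerance = 1e-12)          # G_2(0) = 1
  expect_equal(delta_lognormal_mean(c(0, 0, 0, 7)), 7 / 4)  # single positive
  expect_error(delta_lognormal_mean(c(1, -2)), class = "shelfweb_domain_error")
  expect_error(delta_lognormal_mean(numeric(0)), class = "shelfweb_domain_error")
})

test_that("Pennington estimator is unbiased on synthetic delta samples", {
  p_zero <- 0.4; mu <- 0.5; sg <- 1
  truth <- (1 - p_zero) * exp(mu + sg^2 / 2)
  set.seed(42)
  reps <- replicate(500, {
    svy <- make_survey(n_hauls = 1000, p_zero = p_zero, meanlog = mu,
                       sdlog = sg, seed = sample.int(1e6, 1))
    delta_lognormal_mean(svy$value)
  })
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - truth), 4 * se + 0.01 * truth)
})

test_that("delta estimator beats the arithmetic mean on heavy-tailed data", {
  set.seed(7)
  ests <- replicate(400, {
    svy <- make_survey(n_hauls = 60, p_zero = 0.5, meanlog = 0, sdlog = 1.8,
                       seed = sample.int(1e6, 1))
    c(delta = delta_lognormal_mean(svy$value),
      arith = arithmetic_mean_density(svy$value))
  })
  expect_lt(stats::var(ests["delta", ]), stats::var(ests["arith", ]))
})

test_that("arithmetic mean includes zeros", {
  expect_equal(arithmetic_mean_density(c(0, 0, 4)), 4 / 3)
  expect_equal(arithmetic_mean_density(rep(2.5, 9)), 2.5)
  expect_error(arithmetic_mean_density(numeric(0)),
               class = "shelfweb_domain_error")
})

test_that("unit conversions are exact and homogeneous of degree one", {
  expect_equal(counts_to_biomass(5, 10, c(0.01, 3)), 5 * 10)
  expect_equal(counts_to_biomass(0, 10, c(0.01, 3)), 0)
  expect_equal(counts_to_biomass(10, 10, c(0.01, 3)),
               2 * counts_to_biomass(5, 10, c(0.01, 3)))

  expect_equal(volumetric_to_areal(1000, 100), 100)
  expect_equal(volumetric_to_areal(3, 0), 0)
  expect_equal(volumetric_to_areal(7, 1000), 7)

  expect_equal(gelatinous_scaling(10, 0.96, 0.80), 2)   # factor 0.2
  expect_equal(gelatinous_scaling(10, 0.8, 0.8), 10)    # equal water content
  for (x in c(0.5, 3, 11)) {
    expect_equal(gelatinous_scaling(2 * x), 2 * gelatinous_scaling(x))
  }
})

test_that("seasonal annual mean interpolates periodically", {
  expect_equal(seasonal_annual_mean(100, 7), 7)
  expect_equal(seasonal_annual_mean(c(50, 200, 300), c(3, 3, 3)), 3)
  # two antipodal observations average to their midpoint
  expect_equal(seasonal_annual_mean(c(90, 272), c(2, 8)), 5, tolerance = 0.01)
})

test_that("production-model output converts to biomass via P/B", {
  # a series whose seasonal mean gives 2150 mt km^-2 yr^-1 of wet weight
  mean_pp <- 2150 / (10 * 365) * 1000
  expect_equal(vgpm_to_phyto_biomass(rep(mean_pp, 6), pb = 215), 10,
               tolerance = 1e-12)
  expect_equal(vgpm_to_phyto_biomass(rep(0, 12), pb = 215), 0)
  # month subsetting: only April-September enter the seasonal mean
  full_year <- c(rep(1e6, 3), rep(mean_pp, 6), rep(1e6, 3))
  expect_equal(vgpm_to_phyto_biomass(full_year, pb = 215), 10)
  expect_error(vgpm_to_phyto_biomass(rep(1, 12), pb = 0),
               class = "shelfweb_domain_error")
})

test_that("phytoplankton size partition follows the printed power law", {
  expect_equal(phyto_size_partition(1)$small_fraction, 0.30821)
  expect_equal(phyto_size_partition(10)$small_fraction,
               0.30821 * 10^(-0.82351), tolerance = 1e-12)
  expect_equal(phyto_size_partition(10)$small_fraction, 0.0463,
               tolerance = 1e-3)
  # clamped to a proper fraction at low chlorophyll
  expect_equal(phyto_size_partition(0.1)$small_fraction, 1)
  expect_equal(phyto_size_partition(0.1)$large_fraction, 0)
  expect_error(phyto_size_partition(0), class = "shelfweb_domain_error")
})

test_that("subregional pipeline composes estimator, conversion, and merging", {
  conv <- tibble::tibble(
    species = c("spA", "spB"), group_id = c(1L, 1L),
    estimator = "arithmetic", depth_range_m = c(100, 100), scaler = 1
  )
  # overlapping surveys reporting 2 and 4 contribute their average, 3
  rec <- tibble::tibble(
    station_id = 1:2, subregion = 1, survey = c("s1", "s2"),
    species = "spA", value = c(2, 4), value_kind = "areal"
  )
  out <- subregional_biomass(rec, conv)
  expect_equal(out$biomass, 3)

  # volumetric records are vertically integrated then summed across species
  rec2 <- tibble::tibble(
    station_id = 1:4, subregion = 1, survey = "s1",
    species = rep(c("spA", "spB"), each = 2),
    value = c(1000, 1000, 500, 500), value_kind = "volumetric"
  )
  out2 <- subregional_biomass(rec2, conv)
  expect_equal(out2$biomass, 100 + 50)

  expect_warning(subregional_biomass(
    dplyr::mutate(rec, species = "mystery"), conv), "no functional-group")
})

test_that("pooled krill biomass splits by observed species proportions", {
  total <- 42.528
  props <- c(0.7594, 0.2406)
  split <- disaggregate_broad_prey(
    tibble::tibble(prey = "krill", proportion = 1),
    tibble::tibble(broad = "krill", member = c("E. pacifica", "T. spinifera")),
    biomasses = setNames(props, c("E. pacifica", "T. spinifera")),
    observed = c("E. pacifica", "T. spinifera")
  )
  apportioned <- total * split$proportion[match(c("E. pacifica", "T. spinifera"),
                                                split$prey)]
  expect_equal(apportioned, c(32.30, 10.23), tolerance = 1e-3)
})
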