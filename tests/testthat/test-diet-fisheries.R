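test_that("standardization drops unidentified prey and renormalizes", {
  src <- tibble::tibble(prey = c("A", "unidentified fish"), amount = c(30, 70))
  expect_equal(standardize_diet(src)$proportion, 1)
  src2 <- tibble::tibble(prey = c("A", "B"), amount = c(2, 2))
  expect_equal(standardize_diet(src2)$proportion, c(0.5, 0.5))
  # percent-frequency-of-occurrence amounts are treated identically
  src3 <- tibble::tibble(prey = c("A", "B"), amount = c(40, 60),
                         basis = "frequency-of-occurrence")
  expect_equal(standardize_diet(src3)$proportion, c(0.4, 0.6))
  expect_error(standardize_diet(tibble::tibble(prey = "unid", amount = 1)),
               class = "shelfweb_empty_diet")
})

test_that("source merging weights by predator sample size", {
  s1 <- tibble::tibble(prey = c("X", "Y"), proportion = c(0.6, 0.4), n = 30)
  s2 <- tibble::tibble(prey = c("X", "Y"), proportion = c(0.2, 0.8), n = 10)
  merged <- merge_sources(list(s1, s2))
  expect_equal(merged$proportion[match(c("X", "Y"), merged$prey)], c(0.5, 0.5))
  expect_equal(merge_sources(list(s1))$proportion, c(0.6, 0.4))
  # equal diets are unchanged regardless of n
  s3 <- dplyr::mutate(s1, n = 500)
  expect_equal(merge_sources(list(s1, s3))$proportion, c(0.6, 0.4))
  # order invariance
  expect_equal(merge_sources(list(s2, s1)), merge_sources(list(s1, s2)))
})

test_that("species combine into groups by biomass share", {
  harbor <- tibble::tibble(prey = c("salmon", "smelt"), proportion = c(0.3, 0.7))
  fur <- tibble::tibble(prey = c("squid", "smelt"), proportion = c(0.9, 0.1))
  d <- species_to_group(list(harbor = harbor, fur = fur),
                        c(harbor = 0.989, fur = 0.011))
  expect_equal(sum(d$proportion), 1, tolerance = 1e-12)
  expect_equal(d$proportion[d$prey == "salmon"], 0.3 * 0.989)
  expect_equal(d$proportion[d$prey == "squid"], 0.9 * 0.011)
  expect_equal(species_to_group(list(a = harbor), c(a = 1)),
               dplyr::arrange(harbor, prey))
})

test_that("broad prey disaggregate proportionally to observed biomass", {
  diet <- tibble::tibble(prey = c("cephalopod", "fish"), proportion = c(0.2, 0.8))
  map <- tibble::tibble(broad = "cephalopod", member = c("squid", "octopus"))
  b <- c(squid = 3, octopus = 1)
  out <- disaggregate_broad_prey(diet, map, b,
                                 observed = c("squid", "octopus", "fish"))
  expect_equal(out$proportion[out$prey == "squid"], 0.15)
  expect_equal(out$proportion[out$prey == "octopus"], 0.05)
  expect_equal(sum(out$proportion), 1)
  # unobserved members are excluded from the split
  out2 <- disaggregate_broad_prey(diet, map, b, observed = c("squid", "fish"))
  expect_equal(out2$proportion[out2$prey == "squid"], 0.2)
  expect_false("octopus" %in% out2$prey)
  # no observed member: warn and split across all members
  expect_warning(
    out3 <- disaggregate_broad_prey(diet, map, b, observed = "fish"),
    "no observed member")
  expect_equal(out3$proportion[out3$prey == "squid"], 0.15)
})

test_that("prey rescaling pins the target and renormalizes the rest", {
  diet <- tibble::tibble(prey = c("salmon", "other"), proportion = c(0.36, 0.64))
  out <- rescale_prey(diet, "salmon", 0.20)
  expect_equal(out$proportion, c(0.20, 0.80))
  expect_equal(rescale_prey(diet, "salmon", 0.36)$proportion, diet$proportion)
  # relative ratios of untouched prey are preserved
  d3 <- tibble::tibble(prey = c("a", "b", "c"), proportion = c(0.5, 0.3, 0.2))
  out3 <- rescale_prey(d3, "a", 0.1)
  expect_equal(out3$proportion[2] / out3$proportion[3], 0.3 / 0.2)
  expect_equal(sum(out3$proportion), 1)
})

test_that("legacy averaging is an unweighted renormalized mean", {
  a <- tibble::tibble(prey = "A", proportion = 1)
  b <- tibble::tibble(prey = "B", proportion = 1)
  out <- legacy_average(a, b)
  expect_equal(sort(out$proportion), c(0.5, 0.5))
  same <- tibble::tibble(prey = c("A", "B"), proportion = c(0.7, 0.3))
  expect_equal(legacy_average(same, same)$proportion, c(0.7, 0.3))
  mixed <- legacy_average(same, tibble::tibble(prey = c("B", "C"),
                                               proportion = c(0.5, 0.5)))
  expect_equal(sum(mixed$proportion), 1, tolerance = 1e-12)
})

test_that("landings reallocate by latitude overlap and conserve weight", {
  zones <- tibble::tibble(lat_min = 42, lat_max = 46, group_id = 1L,
                          gear = "trawl", landed = 100)
  bins <- tibble::tibble(bin = c("sOR", "nOR"),
                         lat_min = c(42, 44.4), lat_max = c(44.4, 46))
  gear_map <- tibble::tibble(gear = "trawl", fleet_id = 97L)
  out <- reallocate_landings(zones, bins, gear_map = gear_map)
  expect_equal(out$landed[out$bin == "nOR"], 100 * 1.6 / 4)   # overlap 0.4
  expect_equal(sum(out$landed), 100)                          # conservation

  # a zone inside one bin keeps everything there
  z2 <- dplyr::mutate(zones, lat_min = 44.5, lat_max = 45.5)
  out2 <- reallocate_landings(z2, bins, gear_map = gear_map)
  expect_equal(out2$bin, "nOR")
  expect_equal(out2$landed, 100)

  # cross-shelf proportions and discard rates compose
  props <- tibble::tibble(group_id = 1L, shelf_zone = c("inner", "outer"),
                          proportion = c(0.25, 0.75))
  rates <- tibble::tibble(group_id = 1L, fleet_id = 97L, rate = 0.1)
  out3 <- reallocate_landings(zones, bins, shelf_props = props,
                              gear_map = gear_map, discard_rates = rates)
  expect_equal(sum(out3$landed), 100, tolerance = 1e-9)
  expect_equal(out3$discarded, out3$landed * 0.1)

  expect_error(reallocate_landings(
    dplyr::mutate(zones, gear = "ghost"), bins, gear_map = gear_map),
    regexp = "ghost", class = "shelfweb_domain_error")
})

test_that("multi-zone reallocation conserves weight per group and gear", {
  set.seed(31)
  zones <- tidyr::expand_grid(z = 1:3, group_id = 1:2, gear = c("trawl", "net"))
  zones$lat_min <- 40 + 2 * zones$z
  zones$lat_max <- zones$lat_min + 2
  zones$landed <- runif(nrow(zones), 1, 10)
  bins <- tibble::tibble(bin = paste0("b", 1:4),
                         lat_min = seq(42, 48, 2) - 0, lat_max = seq(44, 50, 2))
  gm <- tibble::tibble(gear = c("trawl", "net"), fleet_id = c(97L, 94L))
  out <- reallocate_landings(zones[, -1], bins, gear_map = gm)
  by_group <- dplyr::summarise(dplyr::group_by(out, group_id, fleet_id),
                               landed = sum(landed), .groups = "drop")
  src <- dplyr::summarise(dplyr::group_by(zones, group_id, gear),
                          landed = sum(landed), .groups = "drop")
  expect_equal(sum(by_group$landed), sum(src$landed), tolerance = 1e-9)
  expect_equal(sort(by_group$landed), sort(src$landed), tolerance = 1e-9)
})
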