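test_that("single-consumer link gets the whole donor-normalized fraction", {
  bw <- solve_ecopath(toy_chain())
  A <- transpose_consumers(bw)
  expect_equal(A["2", "1"], 1)   # herbivore takes all consumed producer output
  expect_equal(A["3", "2"], 1)
  expect_equal(sum(A[, "3"]), 0) # nobody eats the carnivore
})

test_that("donor normalization splits prey by consumption rate", {
  # consumer 1: c = 10, 100% on P ; consumer 2: c = 30, 50% on P
  groups <- tibble::tibble(
    id = 1:4, name = c("P", "c1", "c2", "benthic_detritus"),
    category = c("producer", "consumer", "consumer", "detritus"),
    biomass = c(100, 1, 3, 1), pb = c(10, 2, 2, 0),
    cb = c(NA, 10, 10, 0), ae = c(NA, 0.8, 0.8, NA),
    pool = c(NA, NA, NA, "benthic_detritus")
  )
  D <- matrix(0, 4, 4)
  D[1, 2] <- 1
  D[1, 3] <- 0.5; D[4, 3] <- 0.5
  fates <- make_default_fates(groups)
  fates$destination[fates$destination == "pelagic_detritus"] <- "benthic_detritus"
  fates <- dplyr::summarise(
    dplyr::group_by(fates, group_id, flow_class, destination),
    fraction = sum(fraction), .groups = "drop")
  m <- ecopath_model(groups, D, fates = fates)
  A <- transpose_consumers(solve_ecopath(m))
  expect_equal(A["2", "1"], 10 / 25)
  expect_equal(A["3", "1"], 15 / 25)
})

test_that("permuting group order permutes the flow matrix identically", {
  m <- make_toy_web(7, seed = 9)
  A <- transpose_consumers(solve_ecopath(m))
  perm <- sample(nrow(m$groups))
  g2 <- m$groups[perm, ]
  g2$id <- seq_len(nrow(g2))                  # new contiguous ids
  D2 <- m$diet[perm, perm]
  catch2 <- list(landings = m$catch$landings[perm, , drop = FALSE],
                 discards = m$catch$discards[perm, , drop = FALSE])
  rownames(catch2$landings) <- rownames(catch2$discards) <- g2$id
  f2 <- m$fates
  f2$group_id <- match(f2$group_id, m$groups$id[perm])
  m2 <- ecopath_model(g2, D2, catch = catch2, fates = f2)
  A2 <- transpose_consumers(solve_ecopath(m2))
  expect_equal(unname(A2), unname(A[perm, perm]), tolerance = 1e-12)
})

test_that("expanded columns allocate all production and close to 1", {
  for (seed in c(1, 4, 12)) {
    m <- make_toy_web(3 + 2 * seed, depth = 1 + seed %% 3, seed = seed)
    net <- expand_fates(solve_ecopath(m))
    sums <- colSums(net$A)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("expansion rescales consumer shares by EE and routes the rest", {
  # production 100, consumers take 25 split 0.4/0.6, remainder senesces
  groups <- tibble::tibble(
    id = 1:4, name = c("P", "c1", "c2", "benthic_detritus"),
    category = c("producer", "consumer", "consumer", "detritus"),
    biomass = c(10, 1, 1.5, 1), pb = c(10, 2, 2, 0),
    cb = c(NA, 10, 10, 0), ae = c(NA, 0.8, 0.8, NA),
    pool = c(NA, NA, NA, "benthic_detritus")
  )
  D <- matrix(0, 4, 4); D[1, 2] <- 1; D[1, 3] <- 1
  fates <- tibble::tibble(
    group_id = c(1, 2, 2, 3, 3),
    flow_class = c("senescence", "senescence", "feces", "senescence", "feces"),
    destination = "benthic_detritus", fraction = 1
  )
  m <- ecopath_model(groups, D, fates = fates)
  bw <- solve_ecopath(m)
  expect_equal(bw$model$groups$ee[1], 0.25)
  net <- expand_fates(bw)
  expect_equal(net$A["2", "1"], 0.10, tolerance = 1e-12)
  expect_equal(net$A["3", "1"], 0.15, tolerance = 1e-12)
  expect_equal(net$A["4", "1"], 0.75, tolerance = 1e-12)
  # consumer intake fate: AE 0.8 means 20% feces to detritus pools
  expect_equal(sum(net$feces[, "2"]), 0.2, tolerance = 1e-12)
  # growth + feces + excretion account for the whole intake
  expect_equal(unname(net$growth + net$excretion + colSums(net$feces)),
               rep(1, 2), tolerance = 1e-12)
})

test_that("consumer entries equal donor-normalized fractions times EE", {
  m <- make_toy_web(10, depth = 3, seed = 21)
  bw <- solve_ecopath(m)
  A1 <- transpose_consumers(bw)
  net <- expand_fates(bw)
  g <- bw$model$groups
  liv <- as.character(g$id[g$category %in% c("producer", "consumer")])
  prod <- g$biomass * g$pb
  pred_share <- rowSums(bw$Q) / ifelse(prod > 0, prod, 1)
  for (i in liv) {
    expect_equal(unname(net$A[liv, i]),
                 unname(A1[liv, i] * pred_share[match(i, as.character(g$id))]),
                 tolerance = 1e-10)
  }
})

test_that("a fully consumed group (EE = 1) has no senescence flow", {
  m <- toy_chain()
  m$groups$biomass[1] <- 5    # production 50 = predation 50 -> EE 1
  bw <- solve_ecopath(m)
  expect_equal(bw$model$groups$ee[1], 1, tolerance = 1e-12)
  net <- expand_fates(bw)
  expect_equal(net$A["4", "1"], 0, tolerance = 1e-9)
})

test_that("detritus pools dominate network inflow", {
  m <- make_toy_web(12, depth = 3, seed = 6)
  bw <- solve_ecopath(m)
  net <- expand_fates(bw)
  g <- bw$model$groups
  prod <- g$biomass * g$pb
  liv <- as.character(g$id[g$category %in% c("producer", "consumer")])
  det <- as.character(g$id[g$category == "detritus"])
  flow_to <- function(rows) {
    sum(sapply(liv, function(i) {
      sum(net$A[rows, i, drop = FALSE]) * prod[match(i, as.character(g$id))]
    }))
  }
  # senescence/discard inflow plus feces (20% of all intake) into the pools
  det_in <- flow_to(det) + sum(colSums(bw$Q)) * 0.2
  strongest_living <- max(sapply(liv, function(j) flow_to(j)))
  expect_gt(det_in, strongest_living)
})

test_that("missing fate rows are a configuration error", {
  m <- toy_chain()
  f <- m$fates[m$fates$group_id != 1, ]
  bw <- solve_ecopath(m)
  expect_error(expand_fates(bw, fates = f), class = "shelfweb_config_error")
})
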