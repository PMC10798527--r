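#' @importFrom rlang .data abort warn .env
#' @importFrom stats setNames lm coef approx rnorm runif rlnorm rbinom
#' @importFrom utils head tail
NULL

# Canonical pool labels used by fate tables and the expanded trophic network.
POOL_LABELS <- c("invertebrate_eggs", "fish_eggs", "pelagic_detritus",
                 "fishery_offal", "benthic_detritus", "export")
FLOW_CLASSES <- c("feces", "senescence", "excretion")
GROUP_CATEGORIES <- c("producer", "consumer", "detritus", "fleet")

#' Construct a shelf food-web model
#'
#' Bundles the per-group parameter table, diet matrix, fleet catch matrices and
#' detritus-fate table into a single validated model object. Groups are indexed
#' by a single 1-based id space shared by every matrix; fleets are stored as
#' groups with `category = "fleet"` and no rate parameters so that
#' trophic-level and network code can treat them uniformly.
#'
#' @param groups Data frame with columns `id`, `name`, `category` (one of
#'   producer, consumer, detritus, fleet), `biomass` (wet weight, mt km^-2),
#'   `pb` (production/biomass, yr^-1), `cb` (consumption/biomass, yr^-1),
#'   `ae` (assimilation efficiency), `ee` (ecotrophic efficiency), and
#'   optionally `ee_fixed`, `ba`, `immigration`, `emigration`,
#'   `is_homeotherm`, `retention`, `pool`. Missing optional columns are filled
#'   with defaults (`ae = 0.8` for living consumers, rates 0, retention 1).
#' @param diet Square numeric matrix, rows = prey id, columns = consumer id,
#'   entries = diet fractions. Living-consumer columns must sum to 1 within
#'   `tol`; they are renormalized to exactly 1 internally.
#' @param catch Optional list with `landings` and `discards` matrices
#'   (rows = group id, columns = fleet id, mt km^-2 yr^-1). Defaults to zeros.
#' @param fates Optional long-format data frame `(group_id, flow_class,
#'   destination, fraction)` routing feces, senescence and excretion flows to
#'   the pools `r paste(POOL_LABELS, collapse = ", ")`. Each
#'   (group, flow class) row set must sum to 1.
#' @param subregion Optional subregion label (default `"aggregated"`).
#' @param tol Read tolerance for diet column sums (default `1e-6`).
#'
#' @return An object of class `ecopath_model`: a list with elements `groups`
#'   (tibble), `diet` (matrix), `catch` (list of two matrices), `fates`
#'   (tibble or `NULL`) and `subregion`.
#' @export
ecopath_model <- function(groups, diet, catch = NULL, fates = NULL,
                          subregion = "aggregated", tol = 1e-6) {
  groups <- tibble::as_tibble(groups)
  required <- c("id", "name", "category")
  missing_cols <- setdiff(required, names(groups))
  if (length(missing_cols) > 0) {
    abort(paste0("groups table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "shelfweb_load_error")
  }
  if (anyDuplicated(groups$id) > 0) {
    abort(paste0("duplicate group id(s): ",
                 paste(unique(groups$id[duplicated(groups$id)]), collapse = ", ")),
          class = "shelfweb_load_error")
  }
  groups <- groups[order(groups$id), ]

  defaults <- list(biomass = NA_real_, pb = NA_real_, cb = NA_real_,
                   ae = NA_real_, ee = NA_real_, ee_fixed = FALSE,
                   ba = 0, immigration = 0, emigration = 0,
                   is_homeotherm = FALSE, retention = 1, pool = NA_character_)
  for (nm in names(defaults)) {
    if (!nm %in% names(groups)) groups[[nm]] <- defaults[[nm]]
    else groups[[nm]][is.na(groups[[nm]]) & !nm %in% c("biomass", "pb", "cb", "ae", "ee", "pool")] <-
        defaults[[nm]]
  }
  living <- groups$category %in% c("producer", "consumer")
  groups$ae[living & groups$category == "consumer" & is.na(groups$ae)] <- 0.8
  groups$pool[groups$category == "detritus" & is.na(groups$pool)] <-
    infer_pool_label(groups$name[groups$category == "detritus" & is.na(groups$pool)])

  n <- nrow(groups)
  diet <- as.matrix(diet)
  if (!all(dim(diet) == c(n, n))) {
    abort(sprintf("diet matrix must be %d x %d to conform to the group index", n, n),
          class = "shelfweb_validation_error")
  }
  dimnames(diet) <- list(groups$id, groups$id)

  fleet_idx <- which(groups$category == "fleet")
  if (is.null(catch)) {
    catch <- list(
      landings = matrix(0, n, length(fleet_idx),
                        dimnames = list(groups$id, groups$id[fleet_idx])),
      discards = matrix(0, n, length(fleet_idx),
                        dimnames = list(groups$id, groups$id[fleet_idx]))
    )
  } else {
    catch$landings <- as.matrix(catch$landings)
    catch$discards <- as.matrix(catch$discards)
  }
  if (!is.null(fates)) fates <- tibble::as_tibble(fates)

  m <- structure(list(groups = groups, diet = diet, catch = catch,
                      fates = fates, subregion = subregion),
                 class = "ecopath_model")
  validate_ecopath_model(m, tol = tol)
  # renormalize living-consumer diet columns to exactly 1
  cons <- living_consumer_ids(m)
  for (j in match(cons, groups$id)) {
    s <- sum(m$diet[, j])
    if (s > 0) m$diet[, j] <- m$diet[, j] / s
  }
  m
}

infer_pool_label <- function(nms) {
  if (length(nms) == 0) return(character(0))
  slug <- gsub("[^a-z]+", "_", tolower(nms))
  out <- rep(NA_character_, length(nms))
  for (lab in setdiff(POOL_LABELS, "export")) {
    hit <- grepl(sub("_", ".?", lab), slug)
    out[hit & is.na(out)] <- lab
  }
  out
}

living_ids <- function(m) m$groups$id[m$groups$category %in% c("producer", "consumer")]
living_consumer_ids <- function(m) {
  m$groups$id[m$groups$category == "consumer" & !is.na(m$groups$cb) & m$groups$cb > 0]
}
detritus_ids <- function(m) m$groups$id[m$groups$category == "detritus"]
fleet_ids <- function(m) m$groups$id[m$groups$category == "fleet"]

#' Validate a food-web model against its structural invariants
#'
#' Checks parameter signs and ranges, diet column sums, the one-unknown-per-
#' group rule (exactly one of biomass / EE may be unset for a living group),
#' fate-row closure and matrix conformance. Called by [ecopath_model()]; also
#' useful after manual edits.
#'
#' @param m An `ecopath_model`.
#' @param tol Diet column-sum tolerance.
#' @return `m`, invisibly. Throws a classed condition on violation.
#' @export
validate_ecopath_model <- function(m, tol = 1e-6) {
  g <- m$groups
  living <- g$category %in% c("producer", "consumer")
  bad <- !is.na(g$biomass) & g$biomass < 0
  if (any(bad)) abort(paste0("negative biomass for group(s): ",
                             paste(g$id[bad], collapse = ", ")),
                      class = "shelfweb_validation_error")
  bad <- !is.na(g$pb) & g$pb < 0
  if (any(bad)) abort("pb must be >= 0", class = "shelfweb_validation_error")
  bad <- !is.na(g$cb) & g$cb < 0
  if (any(bad)) abort("cb must be >= 0", class = "shelfweb_validation_error")
  bad <- living & g$category == "consumer" & (is.na(g$cb) | g$cb <= 0)
  if (any(bad)) abort(paste0("living consumers must have cb > 0: groups ",
                             paste(g$id[bad], collapse = ", ")),
                      class = "shelfweb_validation_error")
  bad <- !is.na(g$ae) & (g$ae < 0 | g$ae > 1)
  if (any(bad)) abort("ae must lie in [0, 1]", class = "shelfweb_validation_error")
  bad <- !is.na(g$ee) & g$ee < 0
  if (any(bad)) abort("ee must be >= 0 when set", class = "shelfweb_validation_error")
  both_unset <- living & is.na(g$biomass) & is.na(g$ee)
  if (any(both_unset)) {
    abort(paste0("both biomass and ee unset for living group(s): ",
                 paste(g$id[both_unset], collapse = ", ")),
          class = "shelfweb_validation_error")
  }

  d <- m$diet
  if (any(d < -tol) || any(d > 1 + tol)) {
    abort("diet fractions must lie in [0, 1]", class = "shelfweb_validation_error")
  }
  cons <- living_consumer_ids(m)
  jj <- match(cons, g$id)
  sums <- colSums(d)[jj]
  off <- abs(sums - 1) > tol
  if (any(off)) {
    abort(paste0("diet column does not sum to 1 for consumer(s): ",
                 paste(cons[off], collapse = ", "),
                 " (sums: ", paste(signif(sums[off], 6), collapse = ", "), ")"),
          class = "shelfweb_validation_error")
  }
  nonfeeding <- match(g$id[g$category %in% c("producer", "detritus")], g$id)
  if (any(colSums(d)[nonfeeding] > tol)) {
    abort("producers and detritus groups must have all-zero diet columns",
          class = "shelfweb_validation_error")
  }

  if (any(m$catch$landings < 0) || any(m$catch$discards < 0)) {
    abort("catch matrices must be nonnegative", class = "shelfweb_validation_error")
  }

  if (!is.null(m$fates)) {
    f <- m$fates
    if (any(f$fraction < -tol | f$fraction > 1 + tol)) {
      abort("fate fractions must lie in [0, 1]", class = "shelfweb_validation_error")
    }
    bad_dest <- setdiff(unique(f$destination), POOL_LABELS)
    if (length(bad_dest) > 0) {
      abort(paste0("unknown fate destination(s): ", paste(bad_dest, collapse = ", ")),
            class = "shelfweb_validation_error")
    }
    sums <- dplyr::summarise(dplyr::group_by(f, .data$group_id, .data$flow_class),
                             s = sum(.data$fraction), .groups = "drop")
    off <- abs(sums$s - 1) > 1e-9
    if (any(off)) {
      abort(paste0("fate rows must sum to 1; offending (group, class): ",
                   paste(sums$group_id[off], sums$flow_class[off],
                         sep = "/", collapse = ", ")),
            class = "shelfweb_validation_error")
    }
  }
  invisible(m)
}

#' Read a food-web model from a directory of CSV tables
#'
#' Expects `groups.csv`, `diet.csv` and optionally `fates.csv`, `landings.csv`
#' and `discards.csv` in `dir` (UTF-8, `.` decimal, header row; empty cell =
#' unset). `diet.csv` is a square matrix with a leading prey-id column;
#' landings/discards have a leading group-id column and one column per fleet
#' id; `fates.csv` is long format `(group_id, flow_class, destination,
#' fraction)`.
#'
#' @param dir Directory containing the tables.
#' @param tol Diet column-sum read tolerance.
#' @return A validated [ecopath_model()].
#' @export
read_ecopath_model <- function(dir, tol = 1e-6) {
  path <- function(f) file.path(dir, f)
  if (!file.exists(path("groups.csv"))) {
    abort(paste0("missing groups.csv in ", dir), class = "shelfweb_load_error")
  }
  groups <- readr::read_csv(path("groups.csv"), show_col_types = FALSE,
                            progress = FALSE)
  need <- c("id", "name", "category")
  miss <- setdiff(need, names(groups))
  if (length(miss) > 0) {
    abort(paste0("groups.csv missing column(s): ", paste(miss, collapse = ", ")),
          class = "shelfweb_load_error")
  }
  if (!file.exists(path("diet.csv"))) {
    abort(paste0("missing diet.csv in ", dir), class = "shelfweb_load_error")
  }
  diet_df <- readr::read_csv(path("diet.csv"), show_col_types = FALSE,
                             progress = FALSE)
  diet <- as.matrix(diet_df[, -1, drop = FALSE])
  rownames(diet) <- diet_df[[1]]

  read_catch <- function(f) {
    if (!file.exists(path(f))) return(NULL)
    df <- readr::read_csv(path(f), show_col_types = FALSE, progress = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df[[1]]
    mat
  }
  landings <- read_catch("landings.csv")
  discards <- read_catch("discards.csv")
  catch <- if (is.null(landings) && is.null(discards)) NULL else {
    if (is.null(landings)) landings <- discards * 0
    if (is.null(discards)) discards <- landings * 0
    list(landings = landings, discards = discards)
  }
  fates <- if (file.exists(path("fates.csv"))) {
    readr::read_csv(path("fates.csv"), show_col_types = FALSE, progress = FALSE)
  } else NULL

  ecopath_model(groups, diet, catch = catch, fates = fates, tol = tol)
}

#' Write a food-web model to a directory of CSV tables
#'
#' Inverse of [read_ecopath_model()]: numeric cells round-trip exactly.
#'
#' @param m An `ecopath_model`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ecopath_model <- function(m, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(m$groups, file.path(dir, "groups.csv"))
  diet_df <- tibble::as_tibble(m$diet, .name_repair = "minimal")
  names(diet_df) <- as.character(m$groups$id)
  diet_df <- dplyr::bind_cols(tibble::tibble(prey_id = m$groups$id), diet_df)
  readr::write_csv(diet_df, file.path(dir, "diet.csv"))
  if (!is.null(m$catch) && ncol(m$catch$landings) > 0) {
    for (what in c("landings", "discards")) {
      mat <- m$catch[[what]]
      df <- dplyr::bind_cols(tibble::tibble(group_id = m$groups$id),
                             tibble::as_tibble(mat, .name_repair = "minimal"))
      readr::write_csv(df, file.path(dir, paste0(what, ".csv")))
    }
  }
  if (!is.null(m$fates)) readr::write_csv(m$fates, file.path(dir, "fates.csv"))
  invisible(dir)
}

#' @export
print.ecopath_model <- function(x, ...) {
  g <- x$groups
  cat("<ecopath_model> ", sum(g$category %in% c("producer", "consumer", "detritus")),
      " functional groups (", sum(g$category == "producer"), " producers, ",
      sum(g$category == "consumer"), " consumers, ",
      sum(g$category == "detritus"), " detritus), ",
      sum(g$category == "fleet"), " fleets; subregion: ", x$subregion, "\n", sep = "")
  invisible(x)
}

#' Per-group production rate
#'
#' Production is biomass times the biomass-specific production rate
#' (`biomass * pb`, mt km^-2 yr^-1).
#'
#' @param groups A groups data frame (as in [ecopath_model()]) or an
#'   `ecopath_model`.
#' @return A tibble with `id`, `name` and `production`.
#' @export
production_rate <- function(groups) {
  if (inherits(groups, "ecopath_model")) groups <- groups$groups
  groups <- tibble::as_tibble(groups)
  living <- groups$category %in% c("producer", "consumer")
  if (any(living & is.na(groups$biomass))) {
    abort(paste0("biomass unset for group(s): ",
                 paste(groups$id[living & is.na(groups$biomass)], collapse = ", ")),
          class = "shelfweb_unset_parameter")
  }
  dplyr::transmute(groups[living, ], id = .data$id, name = .data$name,
                   production = .data$biomass * .data$pb)
}

#' Production efficiency (P/Q)
#'
#' The ratio of biomass-specific production to biomass-specific consumption,
#' `pb / cb`. Defined only for feeding groups (`cb > 0`).
#'
#' @inheritParams production_rate
#' @return A tibble with `id`, `name` and `pq` for groups with `cb > 0`.
#' @param strict If `TRUE` (default) groups with `cb = 0` among consumers
#'   raise an error; producers/detritus/fleets are always skipped silently.
#' @export
pq_ratio <- function(groups, strict = TRUE) {
  if (inherits(groups, "ecopath_model")) groups <- groups$groups
  groups <- tibble::as_tibble(groups)
  cons <- groups$category == "consumer"
  if (strict && any(cons & (is.na(groups$cb) | groups$cb == 0))) {
    abort("pq_ratio undefined: consumer with cb = 0",
          class = "shelfweb_undefined_ratio")
  }
  keep <- !is.na(groups$cb) & groups$cb > 0 & !is.na(groups$pb)
  dplyr::transmute(groups[keep, ], id = .data$id, name = .data$name,
                   pq = .data$pb / .data$cb)
}

#' Load the bundled Northern California Current parameter table
#'
#' Returns the transcribed 90-group + 9-fleet Ecopath parameter table for the
#' Northern California Current shelf (trophic level, biomass density in
#' mt km^-2, P/B, C/B, EE, fixed-EE flags and homeotherm flags).
#'
#' @return A tibble with one row per group/fleet.
#' @export
ncc_parameters <- function() {
  f <- system.file("extdata", "ncc_table1.csv", package = "shelfweb")
  readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
}
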