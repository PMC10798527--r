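#' Enumerate the detritus-recycling parameter grid
#'
#' All combinations of pelagic remineralization, benthic remineralization and
#' benthic sequestration from 0 to 1 in `step` increments, in deterministic
#' lexicographic order. With the default step 0.1 the grid has 11^3 = 1331
#' cells.
#'
#' @param step Grid increment (default 0.1).
#' @return A tibble `(pelagic_remin, benthic_remin, sequestration)`.
#' @export
tuning_grid <- function(step = 0.1) {
  v <- seq(0, 1, by = step)
  tidyr::expand_grid(pelagic_remin = v, benthic_remin = v, sequestration = v)
}

#' Grid search over detritus recycling parameters
#'
#' Runs a short simulation for every grid cell with the three recycling
#' parameters substituted into the base configuration, recording the f-ratio
#' by shelf zone, ecosystem-average total primary production, and the number
#' of groups whose biomass fell below the extinction threshold. Cell
#' failures are recorded per cell, not fatal.
#'
#' @param net A [expand_fates()] network.
#' @param geom A [shelf_geometry()].
#' @param forcing Forcing list as in [run_simulation()].
#' @param base_cfg A [simulation_config()]; `years` there sets the per-cell
#'   run length (the reference protocol uses 20-year runs).
#' @param grid Optional grid tibble (default [tuning_grid()]).
#' @param subsample Optional integer: evaluate only every `subsample`-th cell
#'   (desk-scale runs); unevaluated cells keep `NA` metrics.
#' @return An object of class `tuning_result`: the grid with per-cell
#'   `f_inner`, `f_mid`, `f_outer`, `total_pp`, `n_extinct`, `failed`.
#' @export
run_grid <- function(net, geom, forcing, base_cfg = simulation_config(years = 20),
                     grid = tuning_grid(), subsample = NULL) {
  grid <- tibble::as_tibble(grid)
  n <- nrow(grid)
  res <- dplyr::mutate(grid, f_inner = NA_real_, f_mid = NA_real_,
                       f_outer = NA_real_, total_pp = NA_real_,
                       n_extinct = NA_integer_, failed = FALSE)
  eval_rows <- if (is.null(subsample)) seq_len(n) else seq(1, n, by = subsample)
  for (k in eval_rows) {
    cfg <- base_cfg
    cfg$pelagic_remineralization <- grid$pelagic_remin[k]
    cfg$benthic_remineralization <- grid$benthic_remin[k]
    cfg$benthic_sequestration <- grid$sequestration[k]
    out <- tryCatch(run_simulation(net, geom, forcing, cfg),
                    error = function(e) e)
    if (inherits(out, "error")) {
      res$failed[k] <- TRUE
      next
    }
    fr <- f_ratio(out)
    res$f_inner[k] <- fr$f_ratio[fr$zone == "inner"]
    res$f_mid[k] <- fr$f_ratio[fr$zone == "mid"]
    res$f_outer[k] <- fr$f_ratio[fr$zone == "outer"]
    res$total_pp[k] <- total_primary_production(out)
    res$n_extinct[k] <- length(out$extinct)
  }
  structure(list(grid = res, step = NULL), class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("<tuning_result> ", nrow(x$grid), " cells, ",
      sum(!is.na(x$grid$n_extinct)), " evaluated\n", sep = "")
  invisible(x)
}

#' Select recycling parameters from a tuning grid
#'
#' Among zero-extinction cells, picks the cell minimizing the documented
#' score: the sum over shelf zones of the squared distance of the f-ratio
#' from the nearest point of `f_target_range`, plus the squared relative
#' deviation of total primary production from `pp_benchmark`, equally
#' weighted. Ties break to the lexicographically smallest
#' (pelagic, benthic, sequestration) triple. If no evaluated cell is
#' extinction-free, the minimal-extinction cell is returned with a warning.
#'
#' @param res A `tuning_result` (or its grid tibble).
#' @param f_target_range Acceptable f-ratio interval (default `c(0.3, 0.8)`).
#' @param pp_benchmark Benchmark total primary production (same units as the
#'   grid's `total_pp`).
#' @return A one-row tibble: the selected triple with its metrics and score.
#' @export
select_parameters <- function(res, f_target_range = c(0.3, 0.8), pp_benchmark) {
  grid <- if (inherits(res, "tuning_result")) res$grid else tibble::as_tibble(res)
  ev <- grid[!is.na(grid$n_extinct) & !isTRUE_vec(grid$failed), ]
  if (nrow(ev) == 0) abort("no evaluated cells", class = "shelfweb_config_error")
  pool <- ev[ev$n_extinct == 0, ]
  if (nrow(pool) == 0) {
    warn("no zero-extinction cell; returning the minimal-extinction cell")
    pool <- ev[ev$n_extinct == min(ev$n_extinct), ]
  }
  band_dist <- function(f) {
    ifelse(is.na(f), 0,
           pmax(f_target_range[1] - f, 0, f - f_target_range[2]))
  }
  score <- band_dist(pool$f_inner)^2 + band_dist(pool$f_mid)^2 +
    band_dist(pool$f_outer)^2 +
    ((pool$total_pp - pp_benchmark) / pp_benchmark)^2
  pool$score <- score
  pool <- pool[order(pool$score, pool$pelagic_remin, pool$benthic_remin,
                     pool$sequestration), ]
  pool[1, ]
}
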