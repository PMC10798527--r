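#' Solve the Ecopath master equation for mixed unknowns
#'
#' For every living group the master equation
#' \deqn{B_i (P/B)_i EE_i + I_i + BA_i = \sum_j B_j (C/B)_j D_{ij} + E_i + F_i}
#' must hold: production used within the system (left) balances predation,
#' emigration, and fishery removals (right). Each living group supplies
#' exactly one unknown — either its ecotrophic efficiency `EE` (biomass
#' surveyed) or its biomass `B` (EE fixed on the usual 0.85-0.9 assumption).
#' The unknown biomasses are obtained in a single linear solve over the
#' fixed-EE subset (the equation is linear in the unknown B's once known-B
#' predation is folded into the constant side); EE for the remaining groups
#' then follows directly. EE values above 1 are not errors: they are the
#' thermodynamic-imbalance diagnostic, collected in `imbalance`.
#'
#' @param m An [ecopath_model()] in which, for each living group, exactly one
#'   of `biomass` / `ee` is `NA`.
#' @param ba_convention `"as_printed"` places the biomass-accumulation term BA
#'   (and immigration) on the production side; `"canonical"` treats BA as a
#'   right-hand-side loss. With the default BA = I = 0 the two agree.
#' @return An object of class `balanced_web`: the input model with all `B`
#'   and `EE` populated, the predation matrix `Q` (`Q[i, j] = B_j (C/B)_j
#'   D_ij`, mt km^-2 yr^-1), fishing removals `F`, a tibble `imbalance` of
#'   groups with EE > 1, and detritus-budget EE values.
#' @export
solve_ecopath <- function(m, ba_convention = c("as_printed", "canonical")) {
  ba_convention <- match.arg(ba_convention)
  g <- m$groups
  n <- nrow(g)
  liv <- which(g$category %in% c("producer", "consumer"))
  cons <- which(g$category == "consumer" & !is.na(g$cb) & g$cb > 0)

  f_total <- fishing_removals(m)

  b <- g$biomass
  ee <- g$ee
  unknown_b <- intersect(liv, which(is.na(b)))
  if (any(is.na(ee[unknown_b]))) {
    abort("groups with unset biomass must have ee fixed",
          class = "shelfweb_validation_error")
  }
  # constant side per prey i (everything except predation by unknown-B groups)
  rhs_const <- function(bvec) {
    pred <- rep(0, n)
    for (j in cons) {
      if (!is.na(bvec[j])) {
        pred <- pred + bvec[j] * g$cb[j] * m$diet[, j]
      }
    }
    pred
  }

  # as_printed: ... = pred + E + F - I - BA ; canonical: BA is a loss term
  loss_extra <- g$emigration + f_total - g$immigration +
    (if (ba_convention == "as_printed") -g$ba else g$ba)

  if (length(unknown_b) > 0) {
    k <- length(unknown_b)
    M <- matrix(0, k, k)
    rhs <- numeric(k)
    pred_known <- rhs_const(b)
    for (a in seq_len(k)) {
      i <- unknown_b[a]
      M[a, a] <- g$pb[i] * ee[i]
      for (bb in seq_len(k)) {
        j <- unknown_b[bb]
        if (j %in% cons) {
          M[a, bb] <- M[a, bb] - g$cb[j] * m$diet[i, j]
        }
      }
      rhs[a] <- pred_known[i] + loss_extra[i]
    }
    cnum <- tryCatch(kappa(M, exact = TRUE), error = function(e) Inf)
    if (!is.finite(cnum) || cnum > 1e12) {
      abort(paste0("non-identifiable biomass solve; coupled groups: ",
                   paste(g$id[unknown_b], collapse = ", ")),
            class = "shelfweb_nonidentifiable")
    }
    sol <- solve(M, rhs)
    if (any(sol < 0)) {
      abort(paste0("infeasible: negative estimated biomass for group(s): ",
                   paste(g$id[unknown_b[sol < 0]], collapse = ", ")),
            class = "shelfweb_infeasible")
    }
    b[unknown_b] <- sol
  }

  # predation matrix with all biomasses known
  Q <- matrix(0, n, n, dimnames = list(g$id, g$id))
  for (j in cons) Q[, j] <- b[j] * g$cb[j] * m$diet[, j]
  pred_tot <- rowSums(Q)

  solve_ee <- setdiff(liv, unknown_b)
  prod <- b * g$pb
  ee_new <- ee
  for (i in solve_ee) {
    if (prod[i] <= 0) {
      ee_new[i] <- if (pred_tot[i] + loss_extra[i] <= 0) 0 else Inf
    } else {
      ee_new[i] <- (pred_tot[i] + loss_extra[i]) / prod[i]
    }
  }

  out <- m
  out$groups$biomass <- b
  out$groups$ee <- ee_new

  det <- which(g$category == "detritus")
  det_ee <- rep(NA_real_, length(det))
  if (length(det) > 0 && !is.null(m$fates)) {
    inflow <- detritus_inflows(out, Q)
    for (a in seq_along(det)) {
      i <- det[a]
      consumed <- pred_tot[i]
      det_ee[a] <- if (inflow[a] > 0) consumed / inflow[a] else NA_real_
    }
    out$groups$ee[det] <- det_ee
  }

  live_tbl <- out$groups[liv, ]
  imb <- live_tbl[!is.na(live_tbl$ee) & live_tbl$ee > 1,
                  c("id", "name", "ee")]

  structure(list(model = out, Q = Q, fishing = f_total,
                 imbalance = tibble::as_tibble(imb),
                 ba_convention = ba_convention,
                 biomass_estimated = g$id[unknown_b]),
            class = "balanced_web")
}

fishing_removals <- function(m) {
  n <- nrow(m$groups)
  if (is.null(m$catch) || ncol(m$catch$landings) == 0) return(rep(0, n))
  rowSums(m$catch$landings) + rowSums(m$catch$discards)
}

# Yearly inflow to each detritus pool: feces from consumers, senescence
# (unused production) from living groups, and fishery discards to offal.
detritus_inflows <- function(m, Q) {
  g <- m$groups
  det <- which(g$category == "detritus")
  labs <- g$pool[det]
  inflow <- setNames(rep(0, length(det)), labs)
  fate_frac <- function(gid, class, dest) {
    f <- m$fates
    s <- f$fraction[f$group_id == gid & f$flow_class == class & f$destination == dest]
    if (length(s) == 0) 0 else sum(s)
  }
  liv <- which(g$category %in% c("producer", "consumer"))
  cons_tot <- colSums(Q)
  prod <- g$biomass * g$pb
  pred_tot <- rowSums(Q)
  f_total <- fishing_removals(m)
  used <- pred_tot + g$emigration + f_total
  senescence <- pmax(prod - used, 0)
  for (lab in labs) {
    for (i in liv) {
      gid <- g$id[i]
      if (cons_tot[i] > 0 && !is.na(g$ae[i])) {
        inflow[lab] <- inflow[lab] +
          cons_tot[i] * (1 - g$ae[i]) * fate_frac(gid, "feces", lab)
      }
      inflow[lab] <- inflow[lab] + senescence[i] * fate_frac(gid, "senescence", lab)
    }
  }
  if ("fishery_offal" %in% labs && !is.null(m$catch) &&
      ncol(m$catch$discards) > 0) {
    inflow["fishery_offal"] <- inflow["fishery_offal"] + sum(m$catch$discards)
  }
  inflow
}

#' Rescale survey biomasses before re-balancing
#'
#' Applies per-group multiplicative scalers to biomass, the standard remedy
#' when a solved EE exceeds 1 (survey biomass under-catches are common for
#' small or net-avoiding animals). Returns a copy; re-run [solve_ecopath()]
#' afterwards.
#'
#' @param m An [ecopath_model()].
#' @param scalers Named numeric vector (names = group ids) or a data frame
#'   with columns `id` and `scaler`. All scalers must be > 0 and must target
#'   groups whose biomass is set.
#' @return The rescaled `ecopath_model`.
#' @export
rebalance_by_scaling <- function(m, scalers) {
  if (is.data.frame(scalers)) {
    scalers <- setNames(scalers$scaler, scalers$id)
  }
  if (any(scalers <= 0)) abort("scalers must be > 0", class = "shelfweb_validation_error")
  idx <- match(as.integer(names(scalers)), m$groups$id)
  if (anyNA(idx)) abort("scaler names must be group ids", class = "shelfweb_validation_error")
  if (any(is.na(m$groups$biomass[idx]))) {
    abort("cannot scale a group whose biomass is model-estimated (unset)",
          class = "shelfweb_validation_error")
  }
  m$groups$biomass[idx] <- m$groups$biomass[idx] * scalers
  m
}

#' @export
print.balanced_web <- function(x, ...) {
  cat("<balanced_web> ", nrow(x$model$groups), " groups; ",
      nrow(x$imbalance), " group(s) with EE > 1\n", sep = "")
  invisible(x)
}

#' Tidy a balanced food web
#'
#' One row per functional group with the solved parameterization: biomass,
#' production, total predation loss, fishing removal and ecotrophic
#' efficiency, plus whether biomass was model-estimated.
#'
#' @param x A `balanced_web` from [solve_ecopath()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy balanced_web
#' @export
tidy.balanced_web <- function(x, ...) {
  g <- x$model$groups
  keep <- g$category %in% c("producer", "consumer", "detritus")
  tibble::tibble(
    id = g$id[keep], name = g$name[keep], category = g$category[keep],
    biomass = g$biomass[keep], pb = g$pb[keep], cb = g$cb[keep],
    ee = g$ee[keep],
    production = g$biomass[keep] * dplyr::coalesce(g$pb[keep], 0),
    predation = rowSums(x$Q)[keep],
    fishing = x$fishing[keep],
    biomass_estimated = g$id[keep] %in% x$biomass_estimated
  )
}

#' Glance at a balanced food web
#'
#' @inheritParams tidy.balanced_web
#' @return A one-row tibble: group counts, number of EE > 1 imbalances, the
#'   maximum living-group EE, and total system predation throughput.
#' @method glance balanced_web
#' @export
glance.balanced_web <- function(x, ...) {
  g <- x$model$groups
  liv <- g$category %in% c("producer", "consumer")
  tibble::tibble(
    n_groups = sum(g$category %in% c("producer", "consumer", "detritus")),
    n_fleets = sum(g$category == "fleet"),
    n_imbalanced = nrow(x$imbalance),
    max_ee = max(g$ee[liv], na.rm = TRUE),
    total_predation = sum(x$Q),
    total_fishing = sum(x$fishing)
  )
}

#' Verify the master equation residuals of a balanced web
#'
#' Direct per-group evaluation of the balance residual (production-side minus
#' loss-side), used as an independent check on the solver.
#'
#' @param bw A `balanced_web`.
#' @return A tibble with `id` and `residual` (relative to production where
#'   production > 0).
#' @export
balance_residuals <- function(bw) {
  g <- bw$model$groups
  liv <- which(g$category %in% c("producer", "consumer"))
  f_total <- bw$fishing
  pred <- rowSums(bw$Q)
  lhs <- g$biomass * g$pb * g$ee + g$immigration +
    (if (bw$ba_convention == "as_printed") g$ba else -g$ba)
  rhs <- pred + g$emigration + f_total
  res <- (lhs - rhs)[liv]
  scale <- pmax(g$biomass[liv] * g$pb[liv], 1)
  tibble::tibble(id = g$id[liv], residual = res / scale)
}
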