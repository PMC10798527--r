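#' Donor-normalized consumer flow fractions
#'
#' Re-expresses the balanced consumption matrix as a donor-normalized network:
#' the entry for (consumer j, prey i) is
#' \deqn{A_{ji} = D_{ij} c_j / \sum_j D_{ij} c_j}
#' with \eqn{c_j = B_j (C/B)_j} the consumption rate of consumer j, i.e. the
#' fraction of the *consumed* share of prey i's production that goes to each
#' consumer. Columns of consumed prey sum to 1 over consumers; a prey nobody
#' eats keeps an all-zero column.
#'
#' @param bw A `balanced_web` from [solve_ecopath()].
#' @return A matrix with rows = consumer ids, columns = prey ids.
#' @export
transpose_consumers <- function(bw) {
  m <- bw$model
  g <- m$groups
  n <- nrow(g)
  A <- t(bw$Q)                       # rows consumer j, cols prey i
  tot <- rowSums(bw$Q)               # total consumption of each prey
  keep <- tot > 0
  A[, keep] <- sweep(A[, keep, drop = FALSE], 2, tot[keep], "/")
  A[, !keep] <- 0
  dimnames(A) <- list(g$id, g$id)
  A
}

#' Expand the consumer network with detritus and nutrient pools
#'
#' Builds the full energy-flow network: each living group's column allocates
#' its entire annual production among living consumers (the donor-normalized
#' fractions of [transpose_consumers()] rescaled by the consumed share),
#' fishery landings (leaving the system), discards (to the fishery-offal
#' pool), emigration (export, taken off the top), and senescence of the
#' unconsumed remainder routed to egg/detritus pools per the group's
#' senescence fate row. Columns sum to 1 exactly. Alongside the production
#' fates, each consumer's intake split is recorded: a fraction `1 - AE` is
#' feces (routed per the feces fate row), a fraction `P/Q` becomes growth and
#' the assimilated remainder `AE - P/Q` is excreted to the ammonium pool.
#'
#' @param bw A `balanced_web` whose model carries a fate table.
#' @param fates Optional fate table overriding `bw$model$fates`.
#' @return An object of class `trophic_network`: list with the production-fate
#'   matrix `A` (rows = living groups, detritus pools, `"NH4"`, `"NO3"`,
#'   `"landings"`, `"export"`; columns = living groups), detritus-prey
#'   fractions `A_detritus`, the feces routing matrix `feces` (pools x
#'   consumers, fractions of intake), `excretion` and `growth` fractions per
#'   consumer, per-pool balance EE, and the group table.
#' @export
expand_fates <- function(bw, fates = NULL) {
  m <- bw$model
  if (!is.null(fates)) m$fates <- tibble::as_tibble(fates)
  if (is.null(m$fates)) {
    abort("expand_fates requires a detritus fate table", class = "shelfweb_config_error")
  }
  g <- m$groups
  liv <- which(g$category %in% c("producer", "consumer"))
  det <- which(g$category == "detritus")
  if (any(is.na(g$ae[g$category == "consumer"]))) {
    abort("AE must be set for all consumers", class = "shelfweb_config_error")
  }
  missing_fates <- setdiff(g$id[liv], unique(m$fates$group_id))
  if (length(missing_fates) > 0) {
    abort(paste0("fate rows missing for group(s): ",
                 paste(missing_fates, collapse = ", ")),
          class = "shelfweb_config_error")
  }

  det_lab <- g$pool[det]
  A1 <- transpose_consumers(bw)

  row_ids <- c(as.character(g$id[liv]), as.character(g$id[det]),
               "NH4", "NO3", "landings", "export")
  ncol_A <- length(liv)
  A <- matrix(0, length(row_ids), ncol_A,
              dimnames = list(row_ids, as.character(g$id[liv])))

  prod <- g$biomass * g$pb
  pred_tot <- rowSums(bw$Q)
  land_tot <- if (ncol(m$catch$landings) > 0) rowSums(m$catch$landings) else rep(0, nrow(g))
  disc_tot <- if (ncol(m$catch$discards) > 0) rowSums(m$catch$discards) else rep(0, nrow(g))

  fate_row <- function(gid, class) {
    f <- m$fates[m$fates$group_id == gid & m$fates$flow_class == class, ]
    setNames(f$fraction, f$destination)
  }
  dest_row <- function(lab) {
    if (lab == "export") "export"
    else as.character(g$id[det][match(lab, det_lab)])
  }

  for (a in seq_along(liv)) {
    i <- liv[a]
    col <- as.character(g$id[i])
    if (prod[i] <= 0) next
    q_share <- pred_tot[i] / prod[i]
    A[as.character(g$id[liv]), col] <-
      A1[as.character(g$id[liv]), as.character(g$id[i])] * q_share
    A["landings", col] <- land_tot[i] / prod[i]
    if (disc_tot[i] > 0) {
      off <- dest_row("fishery_offal")
      if (is.na(off)) off <- "export"
      A[off, col] <- A[off, col] + disc_tot[i] / prod[i]
    }
    A["export", col] <- A["export", col] + g$emigration[i] / prod[i]
    sen <- 1 - sum(A[, col])          # unconsumed remainder closes the column
    if (sen > 1e-12) {
      fr <- fate_row(g$id[i], "senescence")
      if (length(fr) == 0 || abs(sum(fr) - 1) > 1e-6) {
        abort(paste0("senescence fate row missing/invalid for group ", g$id[i]),
              class = "shelfweb_config_error")
      }
      for (lab in names(fr)) {
        r <- dest_row(lab)
        if (is.na(r)) r <- "export"
        A[r, col] <- A[r, col] + sen * fr[[lab]]
      }
    } else if (sen < -1e-8) {
      # production over-allocated (EE > 1): leave as-is; column sum reported
      warn(paste0("group ", g$id[i], " allocates more than its production ",
                  "(EE > 1); expanded column sum exceeds 1"))
    }
  }

  # consumer intake split: feces to pools, excretion to NH4, growth retained
  cons <- which(g$category == "consumer" & !is.na(g$cb) & g$cb > 0)
  feces <- matrix(0, length(det) + 1, length(cons),
                  dimnames = list(c(as.character(g$id[det]), "export"),
                                  as.character(g$id[cons])))
  excretion <- setNames(numeric(length(cons)), as.character(g$id[cons]))
  growth <- setNames(numeric(length(cons)), as.character(g$id[cons]))
  for (a in seq_along(cons)) {
    j <- cons[a]
    pq <- g$pb[j] / g$cb[j]
    fr <- fate_row(g$id[j], "feces")
    fec <- 1 - g$ae[j]
    for (lab in names(fr)) {
      r <- dest_row(lab)
      if (is.na(r)) r <- "export"
      feces[r, a] <- feces[r, a] + fec * fr[[lab]]
    }
    growth[a] <- pq
    excretion[a] <- max(g$ae[j] - pq, 0)
  }

  # donor-normalized fractions for detritus prey (who eats each pool)
  A_det <- A1[as.character(g$id[liv]), as.character(g$id[det]), drop = FALSE]

  # annual grazing turnover of each pool: consumption / standing stock
  pred_det <- rowSums(bw$Q)[det]
  det_turn <- ifelse(!is.na(g$biomass[det]) & g$biomass[det] > 0,
                     pred_det / g$biomass[det], 0)
  det_turn <- setNames(det_turn, as.character(g$id[det]))

  structure(list(
    A = A, A_detritus = A_det, feces = feces,
    excretion = excretion, growth = growth,
    detritus_turnover = det_turn,
    pool_ee = setNames(g$ee[det], g$pool[det]),
    groups = g, living = g$id[liv], detritus = g$id[det],
    pool_labels = setNames(g$pool[det], as.character(g$id[det]))
  ), class = "trophic_network")
}

#' @export
print.trophic_network <- function(x, ...) {
  cat("<trophic_network> ", length(x$living), " living groups, ",
      length(x$detritus), " detritus/egg pools + NH4/NO3/export\n", sep = "")
  invisible(x)
}

#' Tidy a trophic network into an edge list
#'
#' @param x A `trophic_network`.
#' @param ... Unused.
#' @return A long tibble `(from_id, to_id, fraction)` with one row per
#'   nonzero production-fate edge (to_id may be a pool label).
#' @method tidy trophic_network
#' @export
tidy.trophic_network <- function(x, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(x$A), stringsAsFactors = FALSE))
  names(df) <- c("to_id", "from_id", "fraction")
  df <- df[df$fraction != 0, c("from_id", "to_id", "fraction")]
  tibble::as_tibble(df)
}
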