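#' Trophic levels from the diet matrix
#'
#' Producers and detritus pools sit at trophic level 1. Consumers satisfy
#' \eqn{TL_j = 1 + \sum_i D_{ij} TL_i}, solved as one linear system (cyclic
#' diets are fine). Fishing fleets are assigned `1 +` the catch-share-weighted
#' mean trophic level of the groups they remove (landings + discards).
#'
#' @param m An [ecopath_model()] (the diet matrix and catch matrices are
#'   taken from it), or a `balanced_web`.
#' @return A tibble with `id`, `name`, `category` and `tl`.
#' @export
trophic_levels <- function(m) {
  if (inherits(m, "balanced_web")) m <- m$model
  g <- m$groups
  n <- nrow(g)
  tl <- rep(NA_real_, n)
  base <- g$category %in% c("producer", "detritus")
  tl[base] <- 1

  cons <- which(g$category == "consumer")
  if (length(cons) > 0) {
    zero_col <- colSums(m$diet)[cons] == 0
    if (any(zero_col)) {
      abort(paste0("consumer(s) with all-zero diet column: ",
                   paste(g$id[cons[zero_col]], collapse = ", ")),
            class = "shelfweb_validation_error")
    }
    D <- m$diet
    k <- length(cons)
    M <- diag(k) - t(D[cons, cons, drop = FALSE])
    rhs <- 1 + as.numeric(t(D[base, cons, drop = FALSE]) %*% tl[base])
    tl[cons] <- solve(M, rhs)
  }

  fl <- which(g$category == "fleet")
  if (length(fl) > 0 && !is.null(m$catch) && ncol(m$catch$landings) > 0) {
    removal <- m$catch$landings + m$catch$discards
    for (f in fl) {
      col <- match(as.character(g$id[f]), colnames(removal))
      if (is.na(col)) next
      w <- removal[, col]
      pos <- w > 0
      if (any(pos)) tl[f] <- 1 + sum(w[pos] * tl[pos]) / sum(w[pos])
    }
  }
  tibble::tibble(id = g$id, name = g$name, category = g$category, tl = tl)
}

#' Pre-balance (PREBAL) diagnostics
#'
#' Screens a food-web parameterization against the standard pre-balance
#' criteria: (i) biomass densities should span roughly 5-7 orders of
#' magnitude, (ii) log10 biomass should decline about 5-10% per unit trophic
#' level, (iii) P/B should never exceed C/B, and (iv) every EE should be
#' below 1. Homeotherms (birds, mammals) are expected exceptions to rate
#' orderings and are flagged rather than failed.
#'
#' @param m An [ecopath_model()] with biomasses populated, a `balanced_web`,
#'   or a bare groups data frame (with a `tl` column or `tls` supplied).
#' @param tls Optional trophic-level tibble from [trophic_levels()]; computed
#'   if omitted and a diet matrix is available, else the `tl` column of
#'   `m$groups` is used.
#' @param slope_subset Optional vector of group ids used for the
#'   log10(biomass) ~ TL regression. Default: all living (non-detritus)
#'   groups with biomass > 0. Detritus is always excluded from the fit but
#'   included in the span.
#' @return An object of class `prebal_report`: list with `span_orders`
#'   (floor of the log10 biomass range over all functional groups),
#'   `slope`, `intercept`, `slope_subset`, `pb_cb_violations`,
#'   `ee_violations`, `homeotherm_flags` and the assembled per-group table.
#' @export
prebal <- function(m, tls = NULL, slope_subset = NULL) {
  g <- if (inherits(m, "balanced_web")) m$model$groups
       else if (inherits(m, "ecopath_model")) m$groups
       else tibble::as_tibble(m)
  fg <- g[g$category %in% c("producer", "consumer", "detritus"), ]
  if (any(is.na(fg$biomass))) {
    abort("prebal requires all biomasses populated", class = "shelfweb_validation_error")
  }
  if (is.null(tls)) {
    tls <- if ("tl" %in% names(g)) {
      tibble::tibble(id = g$id, tl = g$tl)
    } else if (inherits(m, c("ecopath_model", "balanced_web"))) {
      trophic_levels(m)[, c("id", "tl")]
    } else {
      abort("a bare groups table needs a tl column or the tls argument",
            class = "shelfweb_validation_error")
    }
  }
  fg$tl <- tls$tl[match(fg$id, tls$id)]

  pos <- fg$biomass > 0
  span_orders <- floor(log10(max(fg$biomass[pos]) / min(fg$biomass[pos])))

  if (is.null(slope_subset)) {
    slope_subset <- fg$id[fg$category %in% c("producer", "consumer") & pos]
  }
  sub <- fg[fg$id %in% slope_subset & pos & !is.na(fg$tl), ]
  if (nrow(sub) < 3) {
    abort("fewer than 3 points available for the biomass ~ TL fit",
          class = "shelfweb_fit_error")
  }
  fit <- lm(log10(biomass) ~ tl, data = sub)

  if (!"ee" %in% names(fg)) fg$ee <- NA_real_
  if (!"is_homeotherm" %in% names(fg)) fg$is_homeotherm <- FALSE
  feeding <- !is.na(fg$cb) & fg$cb > 0 & !is.na(fg$pb)
  pb_cb <- fg[feeding & fg$pb > fg$cb, c("id", "name", "pb", "cb")]
  ee_v <- fg[!is.na(fg$ee) & fg$ee > 1, c("id", "name", "ee")]
  homeo <- fg[isTRUE_vec(fg$is_homeotherm), c("id", "name", "pb", "cb")]

  structure(list(
    span_orders = span_orders,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    slope_subset = sub$id,
    pb_cb_violations = tibble::as_tibble(pb_cb),
    ee_violations = tibble::as_tibble(ee_v),
    homeotherm_flags = tibble::as_tibble(homeo),
    table = tibble::as_tibble(fg)
  ), class = "prebal_report")
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.prebal_report <- function(x, ...) {
  cat("<prebal_report>\n",
      "  biomass span: ", x$span_orders, " orders of magnitude\n",
      "  log10(B) ~ TL slope: ", signif(x$slope, 4), "\n",
      "  P/B > C/B violations: ", nrow(x$pb_cb_violations), "\n",
      "  EE > 1 violations: ", nrow(x$ee_violations), "\n", sep = "")
  invisible(x)
}

#' @method glance prebal_report
#' @export
glance.prebal_report <- function(x, ...) {
  tibble::tibble(span_orders = x$span_orders, slope = x$slope,
                 intercept = x$intercept,
                 n_pb_cb_violations = nrow(x$pb_cb_violations),
                 n_ee_violations = nrow(x$ee_violations))
}
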