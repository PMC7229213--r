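# Reference flux estimation: FBA with ratio constraints, the parsimonious
# variant, flux variability at the optimum, and the genotype biomass maximum.

.biomass_obj <- function(model) {
  obj <- numeric(length(model$reaction_ids))
  obj[model$biomass_index] <- 1
  obj
}

.lp_constraints <- function(model, ratios, ratio_eps = 0, extra = NULL) {
  ss <- list(Aeq = model$S, beq = numeric(nrow(model$S)))
  .stack_rows(ss, .ratio_rows(model, ratios, eps = ratio_eps), extra)
}

#' Reference flux distribution by FBA with ratio constraints
#'
#' Maximizes the biomass flux subject to steady state, flux bounds and fixed
#' ratios between the tagged carboxylation/oxygenation and starch/sucrose
#' synthesis reactions (defaults 2.88 and 2.58, measured for the reference
#' genotype under optimal nitrogen).
#'
#' @param model a `metabolic_model` with tagged ratio reactions. If a tag
#'   pair is absent the corresponding ratio constraint is skipped with a
#'   warning.
#' @param ratios a fixed-mode [ratio_constraints()].
#' @return a `flux_distribution` with the biomass optimum in `$objective`.
#' @export
solve_reference_fba <- function(model, ratios = ratio_constraints()) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!is.null(ratios) && ratios$mode != "fixed")
    stop("reference FBA uses fixed-value ratio constraints", call. = FALSE)
  .warn_missing_tags(model, ratios)
  cons <- .lp_constraints(model, ratios)
  res <- .solve_lp(.biomass_obj(model), Aeq = cons$Aeq, beq = cons$beq,
                   G = cons$G, h = cons$h, lb = model$lb, ub = model$ub,
                   maximize = TRUE)
  if (res$status == "infeasible")
    stop("reference FBA infeasible: steady-state + bounds + ratio constraints ",
         "admit no flux distribution", call. = FALSE)
  if (res$status != "optimal")
    stop("reference FBA unbounded; check exchange reaction bounds", call. = FALSE)
  flux_distribution(res$v, model, label = "reference", objective = res$value)
}

.warn_missing_tags <- function(model, ratios) {
  if (is.null(ratios)) return(invisible())
  have <- names(model$tags)
  for (pair in list(c("carboxylation", "oxygenation"),
                    c("starch_synthesis", "sucrose_synthesis")))
    if (!all(pair %in% have))
      warning("tags ", paste(pair, collapse = "/"),
              " absent; skipping that ratio constraint", call. = FALSE)
  invisible()
}

#' Parsimonious reference flux distribution
#'
#' Fixes the biomass flux at the FBA optimum of [solve_reference_fba()] and,
#' among all such optima, minimizes the total absolute flux `sum(|v|)`.
#' Implemented as an LP on split positive/negative flux parts.
#'
#' @inheritParams solve_reference_fba
#' @return a `flux_distribution`; `$objective` holds the biomass flux (equal
#'   to the FBA optimum), `attr(, "total_flux")` the minimized `sum(|v|)`.
#' @export
solve_reference_pfba <- function(model, ratios = ratio_constraints()) {
  ref <- solve_reference_fba(model, ratios)
  n <- length(model$reaction_ids)
  cons <- .lp_constraints(model, ratios,
                          extra = .pin_rows(n, model$biomass_index, ref$objective))
  # variables x = c(p, q), v = p - q, p,q >= 0
  split <- function(A) if (is.null(A)) NULL else cbind(A, -A)
  G2 <- split(cons$G); h2 <- cons$h
  # bounds lb <= p - q <= ub as inequality rows
  I <- diag(n)
  G2 <- rbind(G2, cbind(I, -I), cbind(-I, I))
  h2 <- c(h2, model$lb, -model$ub)
  pq_ub <- pmax(abs(model$lb), abs(model$ub))
  res <- .solve_lp(rep(1, 2 * n), Aeq = split(cons$Aeq), beq = cons$beq,
                   G = G2, h = h2, lb = rep(0, 2 * n), ub = rep(pq_ub, 2),
                   maximize = FALSE)
  if (res$status != "optimal")
    stop("pFBA step failed (", res$status, ")", call. = FALSE)
  v <- res$v[seq_len(n)] - res$v[n + seq_len(n)]
  out <- flux_distribution(v, model, label = "reference_pfba",
                           objective = v[model$biomass_index])
  attr(out, "total_flux") <- sum(abs(v))
  out
}

.pin_rows <- function(n, i, value) {
  row <- numeric(n); row[i] <- 1
  list(Aeq = rbind(row), beq = value)
}

#' Flux variability at the reference optimum
#'
#' For every reaction, the minimum and maximum flux over the reference
#' constraint set with the biomass flux pinned to the value attained by
#' `v_ref`. Negligible ranges indicate that the FBA solution is effectively
#' unique for that reaction.
#'
#' @inheritParams solve_reference_fba
#' @param v_ref a `flux_distribution` from [solve_reference_fba()].
#' @param reactions optional subset of reaction ids (default all).
#' @return data.frame with columns `reaction_id`, `min`, `max`, `range`.
#' @export
flux_variability_at_optimum <- function(model, ratios = ratio_constraints(),
                                        v_ref, reactions = NULL) {
  stopifnot(inherits(v_ref, "flux_distribution"))
  if (is.null(reactions)) reactions <- model$reaction_ids
  n <- length(model$reaction_ids)
  vbio <- v_ref$values[model$biomass_index]
  cons <- .lp_constraints(model, ratios,
                          extra = .pin_rows(n, model$biomass_index, vbio))
  res <- lapply(reactions, function(id) {
    i <- match(id, model$reaction_ids)
    obj <- numeric(n); obj[i] <- 1
    lo <- .solve_lp(obj, cons$Aeq, cons$beq, cons$G, cons$h,
                    model$lb, model$ub, maximize = FALSE)
    hi <- .solve_lp(obj, cons$Aeq, cons$beq, cons$G, cons$h,
                    model$lb, model$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA infeasible with biomass pinned at ", vbio, call. = FALSE)
    c(lo$value, hi$value)
  })
  mn <- vapply(res, `[`, numeric(1), 1)
  mx <- vapply(res, `[`, numeric(1), 2)
  data.frame(reaction_id = reactions, min = mn, max = mx, range = mx - mn,
             row.names = NULL)
}

#' Maximum biomass flux of a genotype-specific model
#'
#' Maximizes the flux through the genotype-specific biomass reaction subject
#' to steady state, bounds, interval ratio constraints and non-negative
#' carboxylation flux.
#'
#' @param model_Z `metabolic_model` carrying the genotype biomass column
#'   (see [set_biomass()]).
#' @param ratios interval-mode [ratio_constraints()]; default
#'   [ratio_constraints_interval()].
#' @return the maximal biomass flux (numeric scalar).
#' @export
max_genotype_biomass <- function(model_Z, ratios = ratio_constraints_interval()) {
  stopifnot(inherits(model_Z, "metabolic_model"))
  if (!is.null(ratios) && ratios$mode != "interval")
    stop("genotype programs use interval ratio constraints", call. = FALSE)
  n <- length(model_Z$reaction_ids)
  extra <- NULL
  icarb <- .tag_index(model_Z, "carboxylation")
  if (!is.na(icarb)) {
    row <- numeric(n); row[icarb] <- 1
    extra <- list(G = rbind(row), h = 0)        # v_carb >= 0
  }
  cons <- .lp_constraints(model_Z, ratios, extra = extra)
  res <- .solve_lp(.biomass_obj(model_Z), cons$Aeq, cons$beq, cons$G, cons$h,
                   model_Z$lb, model_Z$ub, maximize = TRUE)
  if (res$status != "optimal")
    stop("genotype biomass maximization failed (", res$status, ")", call. = FALSE)
  res$value
}

#' Fraction of reactions carrying non-zero flux
#'
#' @param flux a `flux_distribution`.
#' @param tol zero-flux tolerance.
#' @return fraction in \[0, 1\].
#' @export
nonzero_flux_fraction <- function(flux, tol = 1e-9) {
  mean(abs(flux$values) > tol)
}

#' Reactions with non-zero flux in a reference distribution
#'
#' The support set over which the reciprocal-weighted projections operate.
#'
#' @param flux a `flux_distribution`.
#' @param tol zero-flux tolerance (default 1e-9; reciprocal weights blow up
#'   numerically below this).
#' @return character vector of reaction ids.
#' @export
nonzero_reactions <- function(flux, tol = 1e-9) {
  flux$reaction_ids[abs(flux$values) > tol]
}

#' Write / read flux distribution tables
#'
#' TSV with columns `reaction_id`, `flux`, `lb_active`, `ub_active`
#' (whether the flux sits on a bound within 1e-6), full double precision.
#'
#' @param flux a `flux_distribution`; `model` its `metabolic_model`.
#' @param path TSV file.
#' @export
write_flux_tsv <- function(flux, model, path) {
  v <- flux$values
  df <- data.frame(reaction_id = names(v),
                   flux = format(v, digits = 17, trim = TRUE),
                   lb_active = abs(v - model$lb) < 1e-6,
                   ub_active = abs(v - model$ub) < 1e-6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_tsv
#' @export
read_flux_tsv <- function(path, model) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  v <- stats::setNames(as.numeric(df$flux), df$reaction_id)
  flux_distribution(v[model$reaction_ids], model)
}
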