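# Cross-environment transfer: only the reference genotype has a model for
# the unseen environment E2. Its exchange-flux ratios between E2 and E1 are
# imposed on the GEBV projection, carrying the environmental shift onto every
# genotype's prediction.

#' Reference flux distribution in a second environment
#'
#' Projects the E1 reference distribution onto the constraint set of the
#' second environment: steady state with the reference E2 biomass column,
#' bounds, interval ratio constraints, and the biomass flux held within a
#' relative band around `biomass_ratio * v_bio_E1` (the measured-biomass
#' ratio between the environments).
#'
#' @param model_E2 `metabolic_model` carrying the reference biomass column
#'   measured in E2.
#' @param v_ref_E1 reference `flux_distribution` in E1.
#' @param biomass_ratio `M_ref_E2 / M_ref_E1 > 0`.
#' @param ratios interval-mode [ratio_constraints()].
#' @param eps_band relative band half-width (default 0.05).
#' @param max_widen band widenings allowed on infeasibility.
#' @return a `flux_distribution` for the reference genotype in E2.
#' @export
reference_in_env2 <- function(model_E2, v_ref_E1, biomass_ratio,
                              ratios = ratio_constraints_interval(),
                              eps_band = 0.05, max_widen = 3L) {
  if (!is.numeric(biomass_ratio) || biomass_ratio <= 0)
    stop("biomass_ratio must be positive", call. = FALSE)
  target <- biomass_ratio * v_ref_E1$values[model_E2$biomass_index]
  out <- estimate_genotype_flux(model_E2, v_ref_E1, target, ratios = ratios,
                                eps_band = eps_band, max_widen = max_widen)
  out$label <- "reference_E2"
  out
}

#' Exchange-flux ratios between two environments
#'
#' `ratio_j = v_E2_j / v_E1_j` for each exchange reaction in `P`. Reactions
#' with near-zero E1 flux are dropped from `P` with a warning.
#'
#' @param v_E1,v_E2 `flux_distribution`s of the reference genotype in the
#'   two environments (same model).
#' @param P character vector of exchange reaction ids.
#' @param eps relative slack stored for the transfer constraints
#'   (default 0.05).
#' @param tol zero-flux tolerance on the denominator.
#' @return object of class `exchange_ratio_set` with fields `ratios`
#'   (named vector), `P`, `eps`.
#' @export
exchange_ratios <- function(v_E1, v_E2, P, eps = 0.05, tol = 1e-9) {
  if (!setequal(v_E1$reaction_ids, v_E2$reaction_ids))
    stop("flux distributions come from different models", call. = FALSE)
  missing <- setdiff(P, v_E1$reaction_ids)
  if (length(missing))
    stop("unknown exchange reactions: ", paste(missing, collapse = ", "),
         call. = FALSE)
  denom <- v_E1$values[P]
  ok <- abs(denom) > tol
  if (any(!ok))
    warning("exchange reaction(s) with near-zero E1 flux dropped from P: ",
            paste(P[!ok], collapse = ", "), call. = FALSE)
  P <- P[ok]
  if (!length(P)) stop("P is empty after dropping zero-flux exchanges", call. = FALSE)
  structure(list(ratios = v_E2$values[P] / v_E1$values[P], P = P, eps = eps),
            class = "exchange_ratio_set")
}

#' Project flux GEBVs into an unseen environment
#'
#' The within-environment projection ([project_gebv_to_steady_state()])
#' augmented with one constraint per exchange reaction `j` in `P`: the flux
#' must lie within a relative band around `ratio_j * g_j`, where `g_j` is
#' the E1-trained GEBV and `ratio_j` the reference-genotype exchange-flux
#' ratio between the environments. The genotype-specific biomass column is
#' the one measured in E1; the biomass entry of the result is the E2 growth
#' prediction.
#'
#' @param model_Z_E1 `metabolic_model` with the genotype's E1 biomass column.
#' @param gebv named vector of E1-trained flux GEBVs; must cover every
#'   reaction in `xr$P`.
#' @param xr an [exchange_ratios()] object.
#' @param ratios interval-mode [ratio_constraints()].
#' @return a `projection_result`; `growth_gebv` is the E2 prediction.
#' @export
project_cross_env <- function(model_Z_E1, gebv, xr,
                              ratios = ratio_constraints_interval()) {
  stopifnot(inherits(xr, "exchange_ratio_set"))
  missing <- setdiff(xr$P, names(gebv))
  if (length(missing))
    stop("GEBVs missing for exchange reactions: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- length(model_Z_E1$reaction_ids)
  bands <- lapply(xr$P, function(j) {
    i <- match(j, model_Z_E1$reaction_ids)
    .band_rows(n, i, xr$ratios[[j]] * gebv[[j]], xr$eps)
  })
  extra <- do.call(.stack_rows, bands)
  out <- project_gebv_to_steady_state(model_Z_E1, gebv, ratios = ratios,
                                      extra = extra)
  out$w$label <- "gebv_projection_E2"
  out
}

#' Predict growth GEBVs in an unseen environment
#'
#' Cross-environment analogue of [predict_growth()]: evaluates the E1
#' flux models and projects with the exchange-ratio constraints of
#' [project_cross_env()].
#'
#' @inheritParams predict_growth
#' @param xr an [exchange_ratios()] object.
#' @return named numeric vector of E2 growth GEBVs; `attr(, "failed")`
#'   lists failed accessions.
#' @export
predict_growth_cross_env <- function(set, G_test, model_by_accession, xr,
                                     retained = names(set$models),
                                     ratios = ratio_constraints_interval(),
                                     covariates = NULL) {
  gebvs <- predict_flux_gebvs(set, G_test, covariates = covariates)
  avail <- intersect(retained, colnames(gebvs))
  # exchange constraints always use g_j, independent of threshold selection
  avail <- union(avail, intersect(xr$P, colnames(gebvs)))
  shared <- inherits(model_by_accession, "metabolic_model")
  out <- stats::setNames(rep(NA_real_, nrow(gebvs)), rownames(gebvs))
  failed <- character(0)
  for (acc in rownames(gebvs)) {
    mz <- if (shared) model_by_accession else model_by_accession[[acc]]
    if (is.null(mz)) stop("no metabolic model for accession ", acc, call. = FALSE)
    pr <- tryCatch(
      suppressWarnings(project_cross_env(mz, gebvs[acc, avail], xr,
                                         ratios = ratios)),
      error = function(e) e)
    if (inherits(pr, "error")) failed <- c(failed, acc)
    else out[acc] <- pr$growth_gebv
  }
  if (length(failed))
    warning("cross-environment projection failed for ", length(failed),
            " accession(s)", call. = FALSE)
  attr(out, "failed") <- failed
  out
}
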