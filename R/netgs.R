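# The netGS step: project predicted flux GEBVs onto the steady-state
# polytope; the biomass entry of the projection is the growth GEBV.

#' Select flux models by cross-validated accuracy
#'
#' Retains the reactions whose flux-model accuracy exceeds a threshold;
#' conventionally the threshold is the classical-GS accuracy for fresh
#' weight, so that only fluxes predicted better than growth itself inform
#' the projection.
#'
#' @param set a `flux_model_set` with populated `cv_accuracy`.
#' @param threshold numeric accuracy threshold.
#' @return character vector of retained reaction ids.
#' @export
select_flux_models <- function(set, threshold) {
  acc <- vapply(set$models, `[[`, numeric(1), "cv_accuracy")
  if (all(is.na(acc)))
    stop("cv_accuracy is not populated; fit with a cv_plan", call. = FALSE)
  keep <- names(acc)[!is.na(acc) & acc > threshold]
  if (!length(keep))
    stop("no flux model exceeds accuracy ", threshold,
         "; reduce the threshold", call. = FALSE)
  keep
}

#' Project flux GEBVs onto the steady-state polytope
#'
#' Finds the steady-state flux distribution `w` closest to the predicted
#' flux GEBVs in the reciprocal-weighted distance
#' `sum_i ((w_i - g_i)/g_i)^2` over the retained reactions, subject to flux
#' bounds, interval ratio constraints, the genotype-specific biomass column
#' and a non-negative biomass flux. The biomass entry of `w` is the growth
#' GEBV; the biomass flux carries no objective weight.
#'
#' @param model_Z `metabolic_model` with the genotype biomass column.
#' @param gebv named vector of predicted fluxes over the retained reactions;
#'   entries below the zero tolerance are dropped from the objective with a
#'   warning.
#' @param ratios interval-mode [ratio_constraints()].
#' @param extra internal: additional constraint fragments (used by the
#'   cross-environment program).
#' @return object of class `projection_result`: `w` (a
#'   `flux_distribution`), `growth_gebv`, `objective`, `retained_reactions`,
#'   `solver_status`.
#' @export
project_gebv_to_steady_state <- function(model_Z, gebv,
                                         ratios = ratio_constraints_interval(),
                                         extra = NULL) {
  n <- length(model_Z$reaction_ids)
  ibio <- model_Z$biomass_index
  gebv <- gebv[setdiff(names(gebv), model_Z$reaction_ids[ibio])]
  if (any(!is.finite(gebv))) stop("non-finite GEBV", call. = FALSE)
  row <- numeric(n); row[ibio] <- 1
  pos_bio <- list(G = rbind(row), h = 0)         # w_biomass >= 0
  res <- .project_reciprocal(model_Z, gebv, ratios = ratios,
                             extra = .stack_rows(pos_bio, extra))
  if (res$status != "optimal")
    stop("GEBV projection failed (", res$status, "): ", res$message,
         call. = FALSE)
  w <- flux_distribution(res$v, model_Z, label = "gebv_projection",
                         objective = res$objective)
  structure(list(w = w, growth_gebv = unname(res$v[ibio]),
                 objective = res$objective,
                 retained_reactions = names(gebv),
                 solver_status = res$status),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat("projection_result: growth GEBV ", format(x$growth_gebv),
      " (objective ", format(x$objective), ", ",
      length(x$retained_reactions), " retained reactions)\n", sep = "")
  invisible(x)
}

#' Predict growth GEBVs for test accessions
#'
#' For each test accession: evaluate the retained reaction models on its
#' genotype, then project the predicted fluxes onto the steady-state
#' polytope of its metabolic model. Per-accession projection failures are
#' recorded as NA and flagged; the other accessions proceed.
#'
#' @param set a `flux_model_set`.
#' @param G_test `genotype_matrix` of the test accessions.
#' @param model_by_accession either one shared `metabolic_model` (the
#'   reference-biomass ablation mode) or a named list with one model per
#'   test accession.
#' @param retained reaction ids to keep in the objective (default: all
#'   modelled reactions; see [select_flux_models()]).
#' @param ratios interval-mode [ratio_constraints()].
#' @param covariates optional covariates for [predict_gebv()].
#' @return named numeric vector of growth GEBVs per accession;
#'   `attr(, "failed")` lists failed accessions.
#' @export
predict_growth <- function(set, G_test, model_by_accession,
                           retained = names(set$models),
                           ratios = ratio_constraints_interval(),
                           covariates = NULL) {
  gebvs <- predict_flux_gebvs(set, G_test, covariates = covariates)
  avail <- intersect(retained, colnames(gebvs))
  if (!length(avail)) stop("no retained reaction has a model", call. = FALSE)
  shared <- inherits(model_by_accession, "metabolic_model")
  out <- stats::setNames(rep(NA_real_, nrow(gebvs)), rownames(gebvs))
  failed <- character(0)
  for (acc in rownames(gebvs)) {
    mz <- if (shared) model_by_accession else model_by_accession[[acc]]
    if (is.null(mz)) stop("no metabolic model for accession ", acc, call. = FALSE)
    pr <- tryCatch(
      suppressWarnings(
        project_gebv_to_steady_state(mz, gebvs[acc, avail], ratios = ratios)),
      error = function(e) e)
    if (inherits(pr, "error")) failed <- c(failed, acc)
    else out[acc] <- pr$growth_gebv
  }
  if (length(failed))
    warning("projection failed for ", length(failed), " accession(s)",
            call. = FALSE)
  attr(out, "failed") <- failed
  out
}
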