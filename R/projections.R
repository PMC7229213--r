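# Reciprocal-weighted quadratic projections onto the steady-state polytope:
# genotype flux estimation, the biomass scaling scheme that makes it
# feasible, and robustness resampling of the reference distribution.

# Shared engine: minimize sum_i [ (target_i - v_i) / target_i ]^2 over the
# weighted set, subject to steady state, bounds and the supplied constraint
# fragments. `targets` is a named vector over the weighted reactions.
.project_reciprocal <- function(model, targets, ratios = NULL, ratio_eps = 0,
                                extra = NULL, pin_zero = FALSE,
                                zero_tol = 1e-9) {
  n <- length(model$reaction_ids)
  idx <- match(names(targets), model$reaction_ids)
  if (anyNA(idx)) stop("target reactions absent from model", call. = FALSE)
  small <- abs(targets) <= zero_tol
  if (any(small)) {
    warning(sum(small), " target flux(es) below the zero tolerance dropped ",
            "from the objective", call. = FALSE)
    targets <- targets[!small]; idx <- idx[!small]
  }
  if (!length(targets)) stop("no usable target fluxes", call. = FALSE)
  w <- numeric(n); g <- numeric(n)
  w[idx] <- 1 / targets^2
  g[idx] <- targets
  cons <- .stack_rows(list(Aeq = model$S, beq = numeric(nrow(model$S))),
                      .ratio_rows(model, ratios, eps = ratio_eps), extra)
  if (pin_zero) {
    out <- setdiff(seq_len(n), idx)
    if (length(out)) {
      P <- matrix(0, length(out), n); P[cbind(seq_along(out), out)] <- 1
      cons <- .stack_rows(cons, list(Aeq = P, beq = numeric(length(out))))
    }
  }
  .solve_qp(w, g, cons$Aeq, cons$beq, cons$G, cons$h, model$lb, model$ub)
}

#' Biomass scaling scheme for genotype flux estimation
#'
#' Maps measured fresh weights onto the range of biomass fluxes the model can
#' attain. `s_model` is the mean of the genotype-specific biomass maxima
#' (see [max_genotype_biomass()]); each genotype's ratio-scaled biomass is
#' `(M_Z / M_ref) * v_bio_ref`; `s_measurement` is the maximum of these over
#' all genotypes; the scaled target for genotype Z is
#' `((s_model - delta) / s_measurement) * (M_Z / M_ref) * v_bio_ref`.
#'
#' @param maxima named vector, genotype -> biomass maximum of its model.
#' @param measured named vector, genotype -> measured fresh weight (same
#'   genotype set; all positive).
#' @param M_ref measured fresh weight of the reference genotype.
#' @param v_bio_ref biomass flux of the reference flux distribution.
#' @param delta safety margin keeping targets strictly inside the feasible
#'   range; default 1.1e-4.
#' @return object of class `scaling_scheme` with fields `s_model`,
#'   `s_measurement`, `delta` and `targets` (named vector of scaled biomass
#'   targets per genotype).
#' @export
build_scaling <- function(maxima, measured, M_ref, v_bio_ref, delta = 1.1e-4) {
  gts <- names(maxima)
  if (is.null(gts) || !setequal(gts, names(measured)) || !length(gts))
    stop("maxima and measured must be named over the same non-empty genotype set",
         call. = FALSE)
  measured <- measured[gts]
  if (any(measured <= 0) || M_ref <= 0)
    stop("fresh weights must be positive", call. = FALSE)
  s_model <- mean(maxima)
  if (s_model <= delta) stop("mean biomass maximum does not exceed delta", call. = FALSE)
  ratio_scaled <- (measured / M_ref) * v_bio_ref
  s_measurement <- max(ratio_scaled)
  targets <- (s_model - delta) / s_measurement * ratio_scaled
  structure(list(s_model = s_model, s_measurement = s_measurement,
                 delta = delta, targets = targets),
            class = "scaling_scheme")
}

#' Estimate the flux distribution of a genotype
#'
#' Finds the steady-state flux distribution of genotype Z closest to the
#' reference distribution, with per-reaction distances scaled by the
#' reciprocal of the reference flux (so only reactions with non-zero
#' reference flux contribute). Constraints: steady state with the
#' genotype-specific biomass column, flux bounds, interval ratio constraints,
#' and the biomass flux held within a relative band around `scaled_target`.
#'
#' If the program is infeasible the band is widened (x2, at most
#' `max_widen` times, each widening emitting a warning) before failing.
#'
#' @param model_Z `metabolic_model` with the genotype biomass column.
#' @param v_ref reference `flux_distribution`.
#' @param scaled_target target biomass flux for Z (see [build_scaling()]).
#' @param ratios interval-mode [ratio_constraints()].
#' @param eps_band relative half-width of the biomass equality band
#'   (default 0.05).
#' @param pin_zero fix reactions outside the reference support to zero
#'   instead of leaving them free (default `FALSE`).
#' @param max_widen maximum number of band widenings on infeasibility.
#' @return a `flux_distribution` for genotype Z; `$objective` holds the
#'   attained weighted distance.
#' @export
estimate_genotype_flux <- function(model_Z, v_ref, scaled_target,
                                   ratios = ratio_constraints_interval(),
                                   eps_band = 0.05, pin_zero = FALSE,
                                   max_widen = 3L) {
  stopifnot(inherits(v_ref, "flux_distribution"))
  nz <- nonzero_reactions(v_ref)
  n <- length(model_Z$reaction_ids)
  eb <- eps_band
  for (k in 0:max_widen) {
    band <- .band_rows(n, model_Z$biomass_index, scaled_target, eb)
    res <- .project_reciprocal(model_Z, v_ref$values[nz], ratios = ratios,
                               extra = band, pin_zero = pin_zero)
    if (res$status == "optimal") {
      out <- flux_distribution(res$v, model_Z, label = v_ref$label,
                               objective = res$objective)
      attr(out, "eps_band_used") <- eb
      return(out)
    }
    if (k < max_widen) {
      eb <- eb * 2
      warning("genotype flux QP infeasible; widening biomass band to +/-",
              format(eb), call. = FALSE)
    }
  }
  stop("genotype flux estimation infeasible after ", max_widen,
       " band widenings (", res$message, ")", call. = FALSE)
}

#' Estimate flux distributions for a panel of accessions
#'
#' Convenience wrapper running [max_genotype_biomass()], [build_scaling()]
#' and [estimate_genotype_flux()] over a set of accessions.
#'
#' @param model base `metabolic_model` (reference biomass column).
#' @param v_ref reference `flux_distribution`.
#' @param compositions named list, accession -> `biomass_composition`.
#' @param measured named vector of fresh weights per accession.
#' @param M_ref reference fresh weight.
#' @param ratios interval [ratio_constraints()].
#' @param eps_band,delta,pin_zero passed through.
#' @return list with `fluxes` (accession x reaction matrix), `scaling`
#'   (the `scaling_scheme`), `maxima`.
#' @export
estimate_panel_fluxes <- function(model, v_ref, compositions, measured, M_ref,
                                  ratios = ratio_constraints_interval(),
                                  eps_band = 0.05, delta = 1.1e-4,
                                  pin_zero = FALSE) {
  acc <- names(compositions)
  if (!setequal(acc, names(measured)))
    stop("compositions and measured weights must cover the same accessions",
         call. = FALSE)
  models <- lapply(compositions, function(cp) set_biomass(model, cp))
  maxima <- vapply(models, max_genotype_biomass, numeric(1), ratios = ratios)
  sc <- build_scaling(maxima, measured[acc],
                      M_ref, v_ref$values[model$biomass_index], delta)
  fluxes <- t(vapply(acc, function(a) {
    estimate_genotype_flux(models[[a]], v_ref, sc$targets[[a]], ratios,
                           eps_band = eps_band, pin_zero = pin_zero)$values
  }, numeric(length(model$reaction_ids))))
  rownames(fluxes) <- acc
  list(fluxes = fluxes, scaling = sc, maxima = maxima)
}

#' Robustness resampling of the reference flux distribution
#'
#' Draws `n_samples` perturbed copies of the reference: each non-zero flux is
#' sampled uniformly from `[v * (1 - e), v * (1 + e)]`, then projected back
#' onto the constraint set (steady state, bounds, fixed ratios with a
#' two-sided slack `eps`, biomass flux pinned to the reference value) by the
#' reciprocal-weighted program. The element-wise mean of the projections is a
#' robustified reference distribution.
#'
#' @param model the reference `metabolic_model`.
#' @param v_ref reference `flux_distribution` from [solve_reference_fba()].
#' @param e relative half-width of the sampling interval (variance
#'   percentage, e.g. 0.05 for 5 percent).
#' @param n_samples number of resampled references (default 50).
#' @param eps two-sided slack on the ratio equalities (default 1e-4).
#' @param seed mandatory RNG seed.
#' @param ratios fixed-mode [ratio_constraints()] used for the slackened
#'   ratio equalities.
#' @return list with `mean` (a `flux_distribution`) and `samples`
#'   (list of per-sample `flux_distribution`).
#' @export
robust_reference <- function(model, v_ref, e, n_samples = 50L, eps = 1e-4,
                             seed, ratios = ratio_constraints()) {
  stopifnot(e >= 0, n_samples >= 1L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  nz <- nonzero_reactions(v_ref)
  vnz <- v_ref$values[nz]
  n <- length(model$reaction_ids)
  vbio <- v_ref$values[model$biomass_index]
  pin <- .pin_rows(n, model$biomass_index, vbio)
  samples <- vector("list", n_samples)
  for (r in seq_len(n_samples)) {
    vr <- vnz * stats::runif(length(vnz), 1 - e, 1 + e)
    res <- .project_reciprocal(model, vr, ratios = ratios, ratio_eps = eps,
                               extra = pin)
    if (res$status != "optimal")
      stop("robustness projection failed at sample ", r, " (", res$message, ")",
           call. = FALSE)
    samples[[r]] <- flux_distribution(res$v, model,
                                      label = sprintf("robust_%03d", r),
                                      objective = res$objective)
  }
  mean_v <- Reduce(`+`, lapply(samples, `[[`, "values")) / n_samples
  list(mean = flux_distribution(mean_v, model, label = "robust_mean"),
       samples = samples)
}
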