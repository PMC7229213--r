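# End-to-end orchestration: simulate -> reference-flux -> genotype-flux ->
# fit-models -> predict -> cross-env -> evaluate, with a reproducibility
# manifest per stage. The CLI at inst/cli/netgs.R is a thin wrapper over
# run_pipeline().

#' Assemble a run configuration
#'
#' Either programmatically or from a YAML file. All seeds are explicit; no
#' wall-clock defaults.
#'
#' @param output_dir directory for stage artifacts (created).
#' @param seed integer seed used for every stochastic stage.
#' @param size toy-network size for the simulate stage.
#' @param n_accessions,n_markers,n_qtl,h2_biomass,h2_composition panel
#'   parameters (see [sim_config()]).
#' @param eps_band biomass-band half width for flux estimation.
#' @param exchange_set exchange reaction ids for the cross-environment
#'   transfer; default the CO2 exchange (carbon-transfer configuration).
#' @param n_folds,n_repeats cross-validation plan.
#' @param leakage `"paper"` or `"strict"` (see [run_cv()]).
#' @return a `run_config` list.
#' @export
run_config <- function(output_dir, seed, size = "minimal",
                       n_accessions = 60L, n_markers = 200L, n_qtl = 30L,
                       h2_biomass = 0.8, h2_composition = 0.6,
                       eps_band = 0.05, exchange_set = NULL,
                       n_folds = 3L, n_repeats = 5L,
                       leakage = "paper") {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 size = size, n_accessions = as.integer(n_accessions),
                 n_markers = as.integer(n_markers), n_qtl = as.integer(n_qtl),
                 h2_biomass = h2_biomass, h2_composition = h2_composition,
                 eps_band = eps_band, exchange_set = exchange_set,
                 n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), leakage = leakage),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with the fields of `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Run the growth-prediction pipeline
#'
#' Executes the requested stages in order on a simulated study, writing
#' versioned artifacts and a manifest (parameters, seeds, file checksums) to
#' `config$output_dir`. Rerunning with an identical configuration reproduces
#' identical artifacts for the deterministic stages.
#'
#' Stages: `simulate` (toy network + accession panel), `reference_flux`
#' (FBA reference + FVA), `genotype_flux` (per-accession flux estimation),
#' `fit_models` (per-reaction rrBLUP models), `predict` (within-environment
#' growth GEBVs), `cross_env` (E2 reference, exchange ratios, E2 growth
#' GEBVs), `evaluate` (repeated CV of classical GS vs netGS).
#'
#' @param config a [run_config()].
#' @param stages ordered subset of the stage names (default all).
#' @return invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "reference_flux",
                                    "genotype_flux", "fit_models", "predict",
                                    "cross_env", "evaluate")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(config = config)
  manifest <- list(config = unclass(config), stages = list())
  art <- function(...) file.path(config$output_dir, ...)

  if ("simulate" %in% stages) {
    fx <- make_toy_model(config$size,
                         seed = if (config$size == "standard") config$seed)
    cfg <- sim_config(config$n_accessions, config$n_markers, config$n_qtl,
                      config$h2_biomass, config$h2_composition,
                      seed = config$seed)
    panel <- simulate_panel(fx, cfg, compute_fluxes = character(0))
    write_model(fx$model, art("model"), dialect = "tsv")
    utils::write.csv(data.frame(accession = rownames(panel$fresh_weight),
                                panel$fresh_weight),
                     art("fresh_weight.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(cbind(accession = panel$genotypes$accession_ids,
                           as.data.frame(panel$genotypes$dosages)),
                     art("genotypes.csv"), row.names = FALSE, quote = FALSE)
    for (env in names(panel$compositions))
      write_biomass_csv(panel$compositions[[env]],
                        art(paste0("biomass_", env, ".csv")))
    state$fixtures <- fx; state$panel <- panel
    manifest$stages$simulate <- list(seed = config$seed,
                                     n_accessions = config$n_accessions)
  }
  .need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop("stage '", stage, "' requires an earlier stage providing '", what,
           "'; run the pipeline from 'simulate'", call. = FALSE)
    state[[what]]
  }

  if ("reference_flux" %in% stages) {
    fx <- .need("fixtures", "reference_flux")
    model_E1 <- set_biomass(fx$model, fx$compositions$E1)
    ref <- solve_reference_fba(model_E1)
    fva <- flux_variability_at_optimum(model_E1, v_ref = ref)
    write_flux_tsv(ref, model_E1, art("reference_flux.tsv"))
    utils::write.table(fva, art("fva.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    state$model_E1 <- model_E1; state$reference <- ref
    manifest$stages$reference_flux <-
      list(biomass_optimum = ref$objective,
           nonzero_fraction = nonzero_flux_fraction(ref))
  }

  if ("genotype_flux" %in% stages) {
    panel <- .need("panel", "genotype_flux")
    ref <- .need("reference", "genotype_flux")
    fx <- state$fixtures
    est <- estimate_panel_fluxes(
      fx$model, ref, panel$compositions$E1,
      stats::setNames(panel$fresh_weight[, "E1"],
                      rownames(panel$fresh_weight)),
      fx$ref_weight[["E1"]], eps_band = config$eps_band)
    utils::write.table(
      cbind(accession = rownames(est$fluxes), as.data.frame(est$fluxes)),
      art("genotype_fluxes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    state$flux_matrix <- est$fluxes
    manifest$stages$genotype_flux <- list(s_model = est$scaling$s_model,
                                          s_measurement = est$scaling$s_measurement)
  }

  if ("fit_models" %in% stages) {
    panel <- .need("panel", "fit_models")
    fm <- .need("flux_matrix", "fit_models")
    nz <- nonzero_reactions(state$reference)
    set <- suppressWarnings(
      fit_flux_models(panel$genotypes, fm[, nz, drop = FALSE]))
    eff <- do.call(rbind, lapply(names(set$models), function(r)
      data.frame(reaction_id = r, marker = names(set$models[[r]]$marker_effects),
                 effect = set$models[[r]]$marker_effects)))
    utils::write.table(eff, art("marker_effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    state$model_set <- set
    manifest$stages$fit_models <- list(n_models = length(set$models),
                                       n_constant = length(set$dropped))
  }

  if ("predict" %in% stages) {
    set <- .need("model_set", "predict")
    panel <- state$panel
    models_by_acc <- lapply(panel$compositions$E1, function(cp)
      set_biomass(state$fixtures$model, cp))
    growth <- suppressWarnings(
      predict_growth(set, panel$genotypes, models_by_acc))
    utils::write.csv(data.frame(accession = names(growth),
                                growth_gebv = as.numeric(growth)),
                     art("growth_gebv.csv"), row.names = FALSE, quote = FALSE)
    state$growth <- growth
    manifest$stages$predict <- list(n_predicted = sum(!is.na(growth)))
  }

  if ("cross_env" %in% stages) {
    fx <- .need("fixtures", "cross_env")
    ref <- .need("reference", "cross_env")
    model_E2 <- set_biomass(fx$model, fx$compositions$E2)
    ref_E2 <- reference_in_env2(model_E2, ref,
                                fx$ref_weight[["E2"]] / fx$ref_weight[["E1"]],
                                eps_band = config$eps_band)
    P <- config$exchange_set
    if (is.null(P)) {
      # carbon-transfer default: constrain the CO2 exchange only; a fully
      # coupled toy network cannot satisfy several exchange bands with
      # different fold-changes at once
      P <- intersect("EX_co2", fx$model$exchange_ids)
      if (!length(P)) {
        nzx <- intersect(fx$model$exchange_ids, nonzero_reactions(ref))
        P <- nzx[which.max(abs(ref$values[nzx]))]
      }
    }
    xr <- exchange_ratios(ref, ref_E2, P)
    write_flux_tsv(ref_E2, model_E2, art("reference_flux_E2.tsv"))
    utils::write.csv(data.frame(reaction_id = xr$P, ratio = xr$ratios),
                     art("exchange_ratios.csv"), row.names = FALSE,
                     quote = FALSE)
    set <- .need("model_set", "cross_env")
    panel <- state$panel
    models_by_acc <- lapply(panel$compositions$E1, function(cp)
      set_biomass(fx$model, cp))
    growth_E2 <- suppressWarnings(
      predict_growth_cross_env(set, panel$genotypes, models_by_acc, xr))
    utils::write.csv(data.frame(accession = names(growth_E2),
                                growth_gebv_E2 = as.numeric(growth_E2)),
                     art("growth_gebv_E2.csv"), row.names = FALSE,
                     quote = FALSE)
    state$xr <- xr; state$growth_E2 <- growth_E2; state$reference_E2 <- ref_E2
    manifest$stages$cross_env <-
      list(mean_exchange_ratio = mean(xr$ratios),
           biomass_ratio = fx$ref_weight[["E2"]] / fx$ref_weight[["E1"]])
  }

  if ("evaluate" %in% stages) {
    panel <- .need("panel", "evaluate")
    fm <- .need("flux_matrix", "evaluate")
    fx <- state$fixtures
    plan <- make_cv_plan(panel$genotypes$accession_ids, config$n_folds,
                         config$n_repeats, seed = config$seed + 1L)
    models_by_acc <- lapply(panel$compositions$E1, function(cp)
      set_biomass(fx$model, cp))
    y_E1 <- stats::setNames(panel$fresh_weight[, "E1"],
                            rownames(panel$fresh_weight))
    bundle <- list(genotypes = panel$genotypes, phenotype = y_E1,
                   flux_matrix = fm[, nonzero_reactions(state$reference),
                                    drop = FALSE],
                   models_by_accession = models_by_acc,
                   ratios = ratio_constraints_interval(),
                   model = fx$model, reference = state$reference,
                   compositions = panel$compositions$E1,
                   weights_E1 = y_E1, M_ref = fx$ref_weight[["E1"]])
    rec_gs <- run_cv(plan, "classical_gs", bundle, leakage = config$leakage)
    rec_net <- run_cv(plan, "netgs", bundle, leakage = config$leakage)
    res <- rbind(
      data.frame(method = "classical_gs", repeat_id = rec_gs$repeat_id,
                 fold = rec_gs$fold_id, r = rec_gs$r),
      data.frame(method = "netgs", repeat_id = rec_net$repeat_id,
                 fold = rec_net$fold_id, r = rec_net$r))
    utils::write.csv(res, art("cv_accuracy.csv"), row.names = FALSE,
                     quote = FALSE)
    cmp <- compare_accuracy(rec_net, rec_gs)
    jsonlite::write_json(list(classical_gs = rec_gs$mean, netgs = rec_net$mean,
                              difference = cmp$difference, t = cmp$t, p = cmp$p,
                              leakage = config$leakage),
                         art("cv_summary.json"), auto_unbox = TRUE, digits = NA)
    state$cv <- list(classical = rec_gs, netgs = rec_net, compare = cmp)
    manifest$stages$evaluate <- list(classical_mean = rec_gs$mean,
                                     netgs_mean = rec_net$mean)
  }

  files <- list.files(config$output_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, art("manifest.json"))
  manifest$artifacts <- lapply(stats::setNames(files, basename(files)),
                               function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  state$manifest <- manifest
  invisible(state)
}
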