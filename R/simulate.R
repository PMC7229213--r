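# Generators for toy stoichiometric networks and simulated accession panels
# with the statistical structure the method assumes: additive marker effects
# driving fresh weight and biomass composition in two environments.

#' Simulation configuration for an accession panel
#'
#' @param n_accessions panel size.
#' @param n_markers biallelic markers (allele frequencies uniform on
#'   \[0.1, 0.9\]).
#' @param n_qtl markers with non-zero effect (split between the
#'   fresh-weight trait and two composition-tilt traits).
#' @param h2_biomass narrow-sense heritability of fresh weight in (0, 1\].
#' @param h2_composition heritability of the biomass-composition tilts.
#' @param env_effects named list per environment:
#'   `list(biomass_scale =, composition_shift =)`. The shift scales the
#'   nitrogen coefficient of the biomass reaction (low-N environments have
#'   nitrogen-poorer biomass).
#' @param cv_weight coefficient of variation of fresh weight around the
#'   reference (default 0.15).
#' @param tilt_amplitude relative composition change per tilt standard
#'   deviation (default 0.04, keeping starch:sucrose inside \[0.79, 3.37\]).
#' @param seed mandatory RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_accessions, n_markers = 200L, n_qtl = 30L,
                       h2_biomass = 0.8, h2_composition = 0.6,
                       env_effects = list(
                         E1 = list(biomass_scale = 1.0, composition_shift = 0),
                         E2 = list(biomass_scale = 0.7, composition_shift = -0.3)),
                       cv_weight = 0.15, tilt_amplitude = 0.04, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_qtl <= n_markers, h2_biomass > 0, h2_biomass <= 1,
            h2_composition >= 0, h2_composition <= 1)
  structure(list(n_accessions = as.integer(n_accessions),
                 n_markers = as.integer(n_markers), n_qtl = as.integer(n_qtl),
                 h2_biomass = h2_biomass, h2_composition = h2_composition,
                 env_effects = env_effects, cv_weight = cv_weight,
                 tilt_amplitude = tilt_amplitude, seed = seed),
            class = "sim_config")
}

# Hand-checkable 8-reaction photosynthesis cartoon. Carbon enters through
# RuBisCO carboxylation/oxygenation (co-limited by photon and CO2 uptake),
# is partitioned between starch and sucrose synthesis, and is consumed
# together with nitrate by the biomass reaction.
.minimal_fixture <- function() {
  mets <- c("photon", "co2", "no3", "triose", "starch", "sucrose")
  rxns <- c("EX_photon", "EX_co2", "EX_no3", "carb", "oxy",
            "starch_syn", "suc_syn", "biomass")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["photon", "EX_photon"] <- 1
  S["co2", "EX_co2"] <- 1
  S["no3", "EX_no3"] <- 1
  S[c("photon", "co2", "triose"), "carb"] <- c(-1, -1, 2)
  S[c("photon", "co2", "triose"), "oxy"] <- c(-1, -1, 1)
  S[c("triose", "starch"), "starch_syn"] <- c(-1, 1)
  S[c("triose", "sucrose"), "suc_syn"] <- c(-1, 1)
  comp_E1 <- c(starch = 2.58, sucrose = 1, no3 = 0.5)
  S[names(comp_E1), "biomass"] <- -comp_E1
  lb <- rep(0, length(rxns))
  ub <- c(100, 60, 1000, 1000, 1000, 1000, 1000, 1000)
  model <- metabolic_model(mets, rxns, S, lb, ub, "biomass",
                           tags = c(carboxylation = "carb",
                                    oxygenation = "oxy",
                                    starch_synthesis = "starch_syn",
                                    sucrose_synthesis = "suc_syn"))
  # CO2 uptake (<= 60) limits carbon: carb + oxy = 60 with carb = 2.88 oxy,
  # triose = 2 carb + oxy, biomass = triose / (2.58 + 1).
  vbio <- 60 * (2 * 2.88 + 1) / (2.88 + 1) / (2.58 + 1)
  list(model = model,
       compositions = list(
         E1 = biomass_composition(comp_E1, "reference", "E1"),
         E2 = biomass_composition(c(starch = 2.40, sucrose = 1.05, no3 = 0.35),
                                  "reference", "E2")),
       ref_weight = c(E1 = 1.0, E2 = 0.7),
       ground_truth = list(biomass_optimum = vbio),
       size = "minimal")
}

#' Generate a toy stoichiometric network with tagged reactions
#'
#' `"minimal"` is a deterministic, fully hand-checkable 8-reaction network
#' (photon/CO2/nitrate exchanges, RuBisCO carboxylation and oxygenation,
#' starch and sucrose synthesis, biomass). `"standard"` decorates the same
#' backbone with randomized mass-consistent structure (intermediate chains,
#' parallel routes, amino-acid synthesis and export, a water exchange
#' consumed by biomass) until it has 20-40 reactions, guaranteeing a
#' feasible non-zero biomass optimum.
#'
#' @param size `"minimal"` or `"standard"`.
#' @param seed RNG seed (required for `"standard"`).
#' @return list with `model` (a `metabolic_model`, reference biomass column
#'   installed), `compositions` (reference `biomass_composition` per
#'   environment E1/E2), `ref_weight` (reference fresh weight per
#'   environment), `ground_truth` (`biomass_optimum` for the minimal model),
#'   `size`.
#' @export
make_toy_model <- function(size = c("minimal", "standard"), seed = NULL) {
  size <- match.arg(size)
  if (size == "minimal") return(.minimal_fixture())
  if (is.null(seed)) stop("seed is required for the standard generator", call. = FALSE)
  for (attempt in seq_len(20L)) {
    set.seed(seed + 1000L * (attempt - 1L))
    fx <- .standard_fixture()
    ok <- tryCatch({
      ref <- solve_reference_fba(fx$model)
      ref$objective > 1e-3 &&
        !inherits(tryCatch(reference_in_env2(
          set_biomass(fx$model, fx$compositions$E2), ref,
          fx$ref_weight[["E2"]] / fx$ref_weight[["E1"]]),
          error = function(e) e), "error")
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (ok) return(fx)
  }
  stop("could not generate a feasible standard network", call. = FALSE)
}

.standard_fixture <- function() {
  base <- .minimal_fixture()
  mets <- base$model$metabolite_ids
  # rebuild as editable tables
  cols <- lapply(seq_along(base$model$reaction_ids), function(i) {
    col <- base$model$S[, i]; col[col != 0]
  })
  names(cols) <- base$model$reaction_ids
  lb <- base$model$lb; ub <- base$model$ub
  # water exchange consumed by biomass
  mets <- c(mets, "h2o", "aa")
  cols$EX_h2o <- c(h2o = 1); lb["EX_h2o"] <- 0; ub["EX_h2o"] <- 1000
  cols$aa_syn <- c(triose = -1, no3 = -1, aa = 1)
  lb["aa_syn"] <- 0; ub["aa_syn"] <- 1000
  cols$EX_aa <- c(aa = -1)                       # export
  lb["EX_aa"] <- 0; ub["EX_aa"] <- stats::runif(1, 0.5, 3)
  comp_E1 <- c(starch = 2.58, sucrose = 1, no3 = 0.35, h2o = 0.8, aa = 0.15)
  comp_E2 <- c(starch = 2.40, sucrose = 1.05, no3 = 0.25, h2o = 0.8, aa = 0.10)
  cols$biomass <- -comp_E1
  # random decorations
  n_target <- sample(20:40, 1)
  counter <- 0L
  while (length(cols) < n_target && counter < 200L) {
    counter <- counter + 1L
    kind <- sample(c("chain", "parallel", "overflow"), 1,
                   prob = c(0.5, 0.3, 0.2))
    if (kind == "chain") {
      # split an internal conversion A -> ... into A -> new -> ...
      cand <- setdiff(names(cols), c("biomass", grep("^EX_", names(cols),
                                                     value = TRUE)))
      rid <- sample(cand, 1)
      col <- cols[[rid]]
      prods <- names(col)[col > 0]
      if (!length(prods)) next
      pmet <- sample(prods, 1)
      newm <- sprintf("m%02d", counter); mets <- c(mets, newm)
      amount <- col[[pmet]]
      col[pmet] <- 0; col[newm] <- amount
      cols[[rid]] <- col[col != 0]
      newr <- sprintf("conv%02d", counter)
      cols[[newr]] <- stats::setNames(c(-amount, amount), c(newm, pmet))
      lb[newr] <- 0; ub[newr] <- 1000
    } else if (kind == "parallel") {
      cand <- setdiff(names(cols), c("biomass", "carb", "oxy", "starch_syn",
                                     "suc_syn",
                                     grep("^EX_", names(cols), value = TRUE)))
      if (!length(cand)) next
      rid <- sample(cand, 1)
      newr <- sprintf("par%02d", counter)
      cols[[newr]] <- cols[[rid]]
      lb[newr] <- 0; ub[newr] <- stats::runif(1, 1, 50)
    } else {
      # optional overflow: internal metabolite -> exported byproduct
      src <- sample(c("triose", "sucrose"), 1)
      newm <- sprintf("byp%02d", counter); mets <- c(mets, newm)
      r1 <- sprintf("ovf%02d", counter); r2 <- sprintf("EX_byp%02d", counter)
      cols[[r1]] <- stats::setNames(c(-1, 1), c(src, newm))
      lb[r1] <- 0; ub[r1] <- 1000
      cols[[r2]] <- stats::setNames(-1, newm)
      lb[r2] <- 0; ub[r2] <- stats::runif(1, 0, 2)
    }
  }
  rxns <- names(cols)
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  for (i in seq_along(cols)) S[names(cols[[i]]), i] <- cols[[i]]
  # randomized uptake capacities
  ub["EX_photon"] <- stats::runif(1, 80, 120)
  ub["EX_co2"] <- stats::runif(1, 50, 70)
  model <- metabolic_model(mets, rxns, S, lb[rxns], ub[rxns], "biomass",
                           tags = base$model$tags)
  list(model = model,
       compositions = list(
         E1 = biomass_composition(comp_E1, "reference", "E1"),
         E2 = biomass_composition(comp_E2, "reference", "E2")),
       ref_weight = c(E1 = 1.0, E2 = 0.7),
       ground_truth = list(biomass_optimum = NA_real_),
       size = "standard")
}

#' Simulate an accession panel on a toy network
#'
#' Draws a biallelic marker panel, additive QTL effects for fresh weight and
#' for two biomass-composition tilts (starch-vs-sucrose partitioning and the
#' nitrogen coefficient), fresh weights per environment at the configured
#' heritability, accession-specific biomass compositions, and (optionally)
#' ground-truth flux distributions obtained by running the genotype flux
#' estimation against the generated compositions and weights.
#'
#' @param fixtures output of [make_toy_model()].
#' @param cfg a [sim_config()].
#' @param compute_fluxes environments for which to compute ground-truth flux
#'   matrices: `"E1"`, `c("E1","E2")`, or `character(0)` to skip.
#' @return list with `genotypes` (`genotype_matrix`), `compositions`
#'   (env -> named list of `biomass_composition`), `fresh_weight`
#'   (accession x environment matrix), `genetic_values` (true additive
#'   values), `fluxes` (env -> accession x reaction matrix),
#'   `reference` (env -> reference `flux_distribution`), `scaling`
#'   (env -> `scaling_scheme`), `config`.
#' @export
simulate_panel <- function(fixtures, cfg, compute_fluxes = "E1") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_accessions; p <- cfg$n_markers
  acc <- sprintf("ACC%03d", seq_len(n))
  mrk <- sprintf("M%04d", seq_len(p))
  freq <- stats::runif(p, 0.1, 0.9)
  dos <- vapply(freq, function(f) stats::rbinom(n, 2, f), numeric(n))
  dimnames(dos) <- list(acc, mrk)
  G <- genotype_matrix(dos)

  std <- function(x) {
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else x * 0
  }
  mix <- function(g, h2) {
    if (h2 >= 1) return(std(g))
    sqrt(h2) * std(g) + sqrt(1 - h2) * stats::rnorm(length(g))
  }
  qtl <- sample(p, cfg$n_qtl)
  thirds <- split(qtl, rep_len(1:3, length(qtl)))
  gv <- lapply(thirds, function(ix)
    std(as.numeric(dos[, ix, drop = FALSE] %*% stats::rnorm(length(ix)))))
  g_size <- gv[[1]]; g_tilt <- gv[[2]]; g_nitro <- gv[[3]]

  envs <- names(cfg$env_effects)
  clamp <- function(x, lim = 3) pmin(pmax(x, -lim), lim)
  tilt <- clamp(mix(g_tilt, cfg$h2_composition))
  nitro <- clamp(mix(g_nitro, cfg$h2_composition))

  fresh_weight <- matrix(NA_real_, n, length(envs), dimnames = list(acc, envs))
  compositions <- list()
  a <- cfg$tilt_amplitude
  for (env in envs) {
    ee <- cfg$env_effects[[env]]
    liab <- cfg$cv_weight * clamp(mix(g_size, cfg$h2_biomass))
    M_ref <- fixtures$ref_weight[[env]]
    fresh_weight[, env] <- pmax(M_ref * ee$biomass_scale * (1 + liab),
                                0.05 * M_ref)
    base_comp <- fixtures$compositions[[env]]$coefficients
    compositions[[env]] <- stats::setNames(lapply(seq_len(n), function(i) {
      cc <- base_comp
      cc["starch"] <- cc["starch"] * (1 + a * tilt[i])
      cc["sucrose"] <- cc["sucrose"] * (1 - a * tilt[i])
      cc["no3"] <- cc["no3"] * (1 + a * nitro[i])
      biomass_composition(cc, acc[i], env)
    }), acc)
  }

  out <- list(genotypes = G, compositions = compositions,
              fresh_weight = fresh_weight,
              genetic_values = cbind(size = g_size, tilt = tilt,
                                     nitro = nitro),
              fluxes = list(), reference = list(), scaling = list(),
              config = cfg)

  if (length(compute_fluxes)) {
    model_E1 <- set_biomass(fixtures$model, fixtures$compositions$E1)
    ref_E1 <- solve_reference_fba(model_E1)
    out$reference$E1 <- ref_E1
    for (env in compute_fluxes) {
      ref_env <- if (env == "E1") ref_E1 else {
        model_env <- set_biomass(fixtures$model, fixtures$compositions[[env]])
        reference_in_env2(model_env, ref_E1,
                          fixtures$ref_weight[[env]] / fixtures$ref_weight[["E1"]])
      }
      out$reference[[env]] <- ref_env
      est <- estimate_panel_fluxes(
        fixtures$model, ref_env, compositions[[env]],
        stats::setNames(fresh_weight[, env], acc),
        fixtures$ref_weight[[env]])
      out$fluxes[[env]] <- est$fluxes
      out$scaling[[env]] <- est$scaling
    }
  }
  out
}
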