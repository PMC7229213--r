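test_that("reference FBA solves hand-checkable networks", {
  # chain limited by the uptake bound; no tagged ratio pairs -> warned + skip
  w <- capture_warnings(ref <- solve_reference_fba(chain_model(cap = 10)))
  expect_match(w, "tags", all = TRUE)
  expect_length(w, 2L)                           # one warning per absent pair
  expect_equal(ref$objective, 10, tolerance = 1e-9)
  expect_equal(unname(ref$values), c(10, 10, 10), tolerance = 1e-9)

  # branch with carb = 2.88 oxy draining uptake <= 10
  suppressWarnings(ref2 <- solve_reference_fba(branch_model(cap = 10),
                                               ratio_constraints(2.88, 2.58)))
  expect_equal(unname(ref2$values["carb"]), 10 * 2.88 / 3.88, tolerance = 1e-9)
  expect_equal(unname(ref2$values["oxy"]), 10 / 3.88, tolerance = 1e-9)

  # zero uptake: everything irreversible collapses to zero
  m0 <- chain_model(cap = 0)
  suppressWarnings(ref0 <- solve_reference_fba(m0))
  expect_equal(max(abs(ref0$values)), 0, tolerance = 1e-9)
})

test_that("minimal toy model FBA reproduces the stored hand optimum", {
  fx <- make_toy_model("minimal")
  ref <- solve_reference_fba(fx$model)
  expect_equal(ref$objective, fx$ground_truth$biomass_optimum,
               tolerance = 1e-8)
  # CO2-limited: carb + oxy = 60 at carb = 2.88 oxy
  expect_equal(unname(ref$values["carb"] + ref$values["oxy"]), 60,
               tolerance = 1e-8)
  expect_equal(unname(ref$values["carb"] / ref$values["oxy"]), 2.88,
               tolerance = 1e-8)
  expect_equal(unname(ref$values["starch_syn"] / ref$values["suc_syn"]), 2.58,
               tolerance = 1e-8)
})

test_that("LP solutions match vertex enumeration on random small networks", {
  n_opt <- 0L
  for (s in 1:12) {
    mod <- random_small_model(3, 5, seed = 400 + s)
    obj <- numeric(5); obj[mod$biomass_index] <- 1
    cons <- oracle_constraints(mod)
    o <- oracle_lp(obj, cons, maximize = TRUE)
    r <- netgs:::.solve_lp(obj, mod$S, numeric(3), NULL, NULL,
                           mod$lb, mod$ub, maximize = TRUE)
    expect_identical(r$status, o$status, label = paste("seed", s))
    if (o$status == "optimal") {
      n_opt <- n_opt + 1L
      expect_equal(r$value, o$value, tolerance = 1e-6,
                   label = paste("seed", s))
    }
  }
  expect_gte(n_opt, 6L)
})

test_that("pFBA keeps the biomass optimum and minimizes total flux", {
  # chain: unique flux pattern, pFBA equals FBA
  suppressWarnings({
    ref <- solve_reference_fba(chain_model())
    pf <- solve_reference_pfba(chain_model())
  })
  expect_equal(pf$values, ref$values, tolerance = 1e-8)

  # futile cycle runs at zero in the parsimonious solution
  suppressWarnings(pfc <- solve_reference_pfba(cycle_model()))
  expect_equal(unname(pfc$values["f1"]), 0, tolerance = 1e-8)
  expect_equal(unname(pfc$values["f2"]), 0, tolerance = 1e-8)
  expect_equal(unname(pfc$values["biomass"]), 10, tolerance = 1e-8)

  # dominance on the minimal model
  fx <- make_toy_model("minimal")
  ref <- solve_reference_fba(fx$model)
  pf <- solve_reference_pfba(fx$model)
  expect_equal(pf$objective, ref$objective, tolerance = 1e-8)
  expect_lte(attr(pf, "total_flux"), sum(abs(ref$values)) + 1e-8)
})

test_that("FVA ranges are tight on chains and open on parallel routes", {
  suppressWarnings({
    ref <- solve_reference_fba(chain_model())
    fva <- flux_variability_at_optimum(chain_model(), v_ref = ref)
  })
  expect_equal(fva$min, unname(ref$values), tolerance = 1e-8)
  expect_equal(fva$max, unname(ref$values), tolerance = 1e-8)

  mod2 <- two_route_model(cap = 10)
  suppressWarnings({
    ref2 <- solve_reference_fba(mod2)
    fva2 <- flux_variability_at_optimum(mod2, v_ref = ref2)
  })
  expect_equal(fva2[fva2$reaction_id == "r1", c("min", "max")],
               data.frame(min = 0, max = 10),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(fva2[fva2$reaction_id == "r2", c("min", "max")],
               data.frame(min = 0, max = 10),
               ignore_attr = TRUE, tolerance = 1e-8)
  # the pinned biomass reaction is degenerate by construction
  bio <- fva2[fva2$reaction_id == "biomass", ]
  expect_equal(bio$min, bio$max, tolerance = 1e-9)
  expect_equal(bio$min, unname(ref2$values["biomass"]), tolerance = 1e-9)
})

test_that("genotype biomass maximum scales inversely with composition", {
  suppressWarnings(expect_equal(max_genotype_biomass(chain_model(), NULL), 10,
                                tolerance = 1e-9))
  fx <- make_toy_model("minimal")
  mx <- max_genotype_biomass(fx$model)
  comp <- model_biomass_composition(fx$model)
  comp$coefficients <- 2 * comp$coefficients
  mx2 <- max_genotype_biomass(set_biomass(fx$model, comp))
  expect_equal(mx2, mx / 2, tolerance = 1e-8)
  # interval ratios relax the fixed-ratio optimum
  ref <- solve_reference_fba(fx$model)
  expect_gte(mx, ref$objective - 1e-9)
})

test_that("the scaling scheme follows its defining arithmetic", {
  sc <- build_scaling(c(A = 10, B = 20), c(A = 1, B = 1), M_ref = 1,
                      v_bio_ref = 5, delta = 1.1e-4)
  expect_equal(sc$s_model, 15)
  # all weights equal to M_ref: ratio-scaled biomass collapses to v_bio_ref
  expect_equal(sc$s_measurement, 5)
  expect_equal(unname(sc$targets), rep(15 - 1.1e-4, 2) / 5 * 5,
               tolerance = 1e-12)
  # the genotype attaining the max ratio hits s_model - delta exactly
  sc2 <- build_scaling(c(A = 10, B = 20), c(A = 2, B = 1), M_ref = 1,
                       v_bio_ref = 5)
  expect_equal(unname(sc2$targets["A"]), 15 - 1.1e-4, tolerance = 1e-12)
  expect_error(build_scaling(c(A = 1), c(A = -1), 1, 5), "positive")
})

test_that("genotype flux estimation is exact on identities and chains", {
  fx <- make_toy_model("minimal")
  ref <- solve_reference_fba(fx$model)
  # Z = reference, target = reference biomass: objective 0, identity
  est <- estimate_genotype_flux(fx$model, ref, ref$objective)
  expect_lt(est$objective, 1e-12)
  expect_equal(est$values, ref$values, tolerance = 1e-8)

  # pure chain with the band closed to an equality: all fluxes halve
  mod <- chain_model()
  suppressWarnings(refc <- solve_reference_fba(mod))
  est2 <- suppressWarnings(
    estimate_genotype_flux(mod, refc, 0.5 * refc$objective, ratios = NULL,
                           eps_band = 0))
  expect_equal(unname(est2$values), unname(0.5 * refc$values),
               tolerance = 1e-8)
})

test_that("genotype flux estimation matches the KKT oracle off the chain", {
  mod <- two_route_model(cap = 10)
  # reference with an unequal split across the two routes
  vref <- flux_distribution(c(uptake = 10, r1 = 7, r2 = 3, biomass = 10), mod)
  target <- 5
  est <- estimate_genotype_flux(mod, vref, target, ratios = NULL,
                                eps_band = 0.05)
  n <- 4
  w <- 1 / vref$values^2
  band <- netgs:::.band_rows(n, mod$biomass_index, target, 0.05)
  cons <- oracle_constraints(mod, extra_ineq = list(A = band$G, b = band$h))
  o <- oracle_qp(as.numeric(w), as.numeric(vref$values), cons)
  expect_identical(o$status, "optimal")
  expect_equal(unname(est$values), o$v, tolerance = 1e-6)
  expect_equal(est$objective, o$objective, tolerance = 1e-6)
})

test_that("infeasible biomass targets trigger logged band widening", {
  mod <- chain_model(cap = 10)
  suppressWarnings(ref <- solve_reference_fba(mod))
  # target above the uptake cap: only reachable after widening the band
  expect_warning(
    est <- estimate_genotype_flux(mod, ref, 11, ratios = NULL,
                                  eps_band = 0.05, max_widen = 3L),
    "widening")
  expect_lte(est$values[["biomass"]], 10 + 1e-8)
  # far out of reach: hard failure after the widening budget
  suppressWarnings(
    expect_error(estimate_genotype_flux(mod, ref, 100, ratios = NULL,
                                        eps_band = 0.01, max_widen = 2L),
                 "infeasible"))
})

test_that("robustness resampling reduces to the reference when e = 0", {
  fx <- make_toy_model("minimal")
  ref <- solve_reference_fba(fx$model)
  rob <- robust_reference(fx$model, ref, e = 0, n_samples = 3, seed = 5)
  expect_equal(rob$mean$values, ref$values, tolerance = 1e-6)
  for (s in rob$samples)
    expect_equal(s$values, ref$values, tolerance = 1e-6)

  # fixed seed: identical means across two runs
  r1 <- robust_reference(fx$model, ref, e = 0.05, n_samples = 5, seed = 11)
  r2 <- robust_reference(fx$model, ref, e = 0.05, n_samples = 5, seed = 11)
  expect_identical(r1$mean$values, r2$mean$values)

  # chain: biomass pin + stoichiometry fully determine the projection
  mod <- chain_model()
  suppressWarnings(refc <- solve_reference_fba(mod))
  robc <- robust_reference(mod, refc, e = 0.2, n_samples = 5, seed = 3,
                           ratios = NULL)
  for (s in robc$samples)
    expect_equal(s$values, refc$values, tolerance = 1e-6)
})

test_that("every emitted flux distribution satisfies the constraint contract", {
  fx <- make_toy_model("minimal")
  model <- fx$model
  ref <- solve_reference_fba(model)
  emitted <- list(ref, solve_reference_pfba(model))
  set.seed(42)
  for (k in 1:5) {
    target <- stats::runif(1, 0.3, 0.95) * ref$objective
    emitted <- c(emitted,
                 list(estimate_genotype_flux(model, ref, target)))
  }
  rob <- robust_reference(model, ref, e = 0.1, n_samples = 3, seed = 8)
  emitted <- c(emitted, rob$samples, list(rob$mean))
  for (fd in emitted) {
    expect_lt(steady_state_residual(model, fd), 1e-6)
    expect_true(all(fd$values >= model$lb - 1e-6))
    expect_true(all(fd$values <= model$ub + 1e-6))
  }
})

test_that("enlarging bounds never decreases the FBA biomass optimum", {
  for (s in 1:6) {
    mod <- random_small_model(3, 5, seed = 700 + s)
    r1 <- netgs:::.solve_lp(replace(numeric(5), mod$biomass_index, 1),
                            mod$S, numeric(3), NULL, NULL,
                            mod$lb, mod$ub, maximize = TRUE)
    r2 <- netgs:::.solve_lp(replace(numeric(5), mod$biomass_index, 1),
                            mod$S, numeric(3), NULL, NULL,
                            mod$lb - 1, mod$ub + 1, maximize = TRUE)
    if (r1$status == "optimal") {
      expect_identical(r2$status, "optimal")
      expect_gte(r2$value, r1$value - 1e-8)
    }
  }
})
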