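test_that("the E2 reference reduces to E1 under identical conditions", {
  fx <- make_toy_model("minimal")
  ref <- solve_reference_fba(fx$model)
  m1 <- set_biomass(fx$model, fx$compositions$E1)
  same <- reference_in_env2(m1, ref, biomass_ratio = 1)
  expect_equal(same$values, ref$values, tolerance = 1e-6)
  expect_error(reference_in_env2(m1, ref, biomass_ratio = -1), "positive")
})

test_that("a chain reference scales linearly with the biomass ratio", {
  mod <- chain_model()
  suppressWarnings(ref <- solve_reference_fba(mod))
  half <- suppressWarnings(
    reference_in_env2(mod, ref, biomass_ratio = 0.5, ratios = NULL,
                      eps_band = 0))
  expect_equal(unname(half$values), unname(0.5 * ref$values),
               tolerance = 1e-8)
})

test_that("the E2 reference projection matches the KKT oracle", {
  fx <- make_toy_model("minimal")
  mod <- fx$model
  ref <- solve_reference_fba(mod)
  m2 <- set_biomass(mod, fx$compositions$E2)
  out <- reference_in_env2(m2, ref, biomass_ratio = 0.7)
  n <- length(mod$reaction_ids)
  w <- 1 / ref$values^2
  band <- netgs:::.band_rows(n, m2$biomass_index, 0.7 * ref$objective, 0.05)
  cons <- oracle_constraints(m2, ratios = ratio_constraints_interval(),
                             extra_ineq = list(A = band$G, b = band$h))
  o <- oracle_qp(as.numeric(w), as.numeric(ref$values), cons)
  expect_identical(o$status, "optimal")
  expect_equal(unname(out$values), o$v, tolerance = 1e-6)
})

test_that("exchange ratios divide fluxes and guard zero denominators", {
  fx <- make_toy_model("minimal")
  mod <- fx$model
  ref <- solve_reference_fba(mod)
  xr1 <- exchange_ratios(ref, ref, mod$exchange_ids)
  expect_equal(unname(xr1$ratios), rep(1, 3), tolerance = 1e-12)

  v2 <- flux_distribution(0.71 * ref$values, mod)
  xr2 <- exchange_ratios(ref, v2, mod$exchange_ids)
  expect_equal(unname(xr2$ratios), rep(0.71, 3), tolerance = 1e-12)

  vz <- ref
  vz$values["EX_no3"] <- 0
  expect_warning(xr3 <- exchange_ratios(vz, v2, mod$exchange_ids),
                 "near-zero")
  expect_setequal(xr3$P, c("EX_photon", "EX_co2"))
})

test_that("unit exchange ratios reproduce the within-environment program", {
  fx <- make_toy_model("minimal")
  mod <- fx$model
  ref <- solve_reference_fba(mod)
  xr <- exchange_ratios(ref, ref, mod$exchange_ids)

  # feasible GEBVs: both programs return the identity, so ratio-1 bands are
  # satisfied exactly and the two results coincide
  gebv_feas <- ref$values
  a <- project_cross_env(mod, gebv_feas, xr)
  b <- project_gebv_to_steady_state(mod, gebv_feas)
  expect_equal(a$w$values, b$w$values, tolerance = 1e-6)
  expect_equal(a$growth_gebv, b$growth_gebv, tolerance = 1e-6)

  # infeasible GEBVs with the band opened to vacuity: still the same program
  gebv <- ref$values[setdiff(mod$reaction_ids, "biomass")] * 1.1
  xr_wide <- xr; xr_wide$eps <- 10
  a2 <- suppressWarnings(project_cross_env(mod, gebv, xr_wide))
  b2 <- suppressWarnings(project_gebv_to_steady_state(mod, gebv))
  expect_equal(a2$w$values, b2$w$values, tolerance = 1e-6)
})

test_that("an empty exchange set leaves the projection unconstrained", {
  fx <- make_toy_model("minimal")
  mod <- fx$model
  ref <- solve_reference_fba(mod)
  gebv <- ref$values[setdiff(mod$reaction_ids, "biomass")] * 0.9
  xr <- exchange_ratios(ref, ref, mod$exchange_ids)
  xr$P <- character(0); xr$ratios <- numeric(0)
  a <- project_cross_env(mod, gebv, xr)
  b <- project_gebv_to_steady_state(mod, gebv)
  expect_equal(a$w$values, b$w$values, tolerance = 1e-8)
})

test_that("a halved uptake ratio halves the chain growth prediction", {
  mod <- chain_model(cap = 1000)
  g <- c(uptake = 8, conv = 8)
  xr1 <- structure(list(ratios = c(uptake = 1), P = "uptake", eps = 0),
                   class = "exchange_ratio_set")
  xr05 <- structure(list(ratios = c(uptake = 0.5), P = "uptake", eps = 0),
                    class = "exchange_ratio_set")
  a <- project_cross_env(mod, g, xr1, ratios = NULL)
  b <- project_cross_env(mod, g, xr05, ratios = NULL)
  expect_equal(b$growth_gebv, 0.5 * a$growth_gebv, tolerance = 1e-8)
})

test_that("shrinking uptake ratios never increases chain growth", {
  mod <- chain_model(cap = 1000)
  g <- c(uptake = 8, conv = 8)
  xr <- function(cc) structure(list(ratios = c(uptake = cc), P = "uptake",
                                    eps = 0.02),
                               class = "exchange_ratio_set")
  growth <- vapply(c(1, 0.8, 0.5, 0.2), function(cc)
    project_cross_env(mod, g, xr(cc), ratios = NULL)$growth_gebv, numeric(1))
  expect_true(all(diff(growth) <= 1e-9))
})

test_that("the full cross-environment pipeline is exact when E2 = E1", {
  study <- tiny_study()
  panel <- study$panel; fx <- study$fx
  G <- subset_accessions(panel$genotypes, panel$genotypes$accession_ids[1:10])
  ref <- panel$reference$E1
  set <- suppressWarnings(fit_flux_models(panel$genotypes, panel$fluxes$E1))
  models_by_acc <- lapply(panel$compositions$E1[1:10], function(cp)
    set_biomass(fx$model, cp))

  same_ref <- reference_in_env2(set_biomass(fx$model, fx$compositions$E1),
                                ref, 1)
  xr <- exchange_ratios(ref, same_ref, fx$model$exchange_ids)
  expect_equal(unname(xr$ratios), rep(1, 3), tolerance = 1e-6)
  xr$eps <- 10                                    # vacuous bands at ratio 1
  gx <- suppressWarnings(
    predict_growth_cross_env(set, G, models_by_acc, xr))
  gw <- suppressWarnings(predict_growth(set, G, models_by_acc))
  expect_equal(gx, gw, tolerance = 1e-6, ignore_attr = TRUE)
})
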