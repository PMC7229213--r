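test_that("tabular model files parse into the expected structure", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tequation\tlb\tub\ttag",
               "uptake\t-> A\t0\t10\t",
               "conv\tA -> B\t0\t1000\t",
               "growth\tB ->\t0\t1000\tbiomass"),
             file.path(dir, "reactions.tsv"))
  writeLines(c("id", "A", "B"), file.path(dir, "metabolites.tsv"))
  mod <- read_model(dir, dialect = "tsv")
  expect_s3_class(mod, "metabolic_model")
  expect_identical(dim(mod$S), c(2L, 3L))
  expect_identical(mod$reaction_ids, c("uptake", "conv", "growth"))
  expect_equal(unname(mod$S[, "conv"]), c(-1, 1))
  expect_equal(unname(mod$ub), c(10, 1000, 1000))
  expect_equal(mod$biomass_index, 3L)
  expect_identical(mod$exchange_ids, "uptake")
})

test_that("missing or duplicate metadata in model files is rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("id\tequation\tlb\tub\ttag",
               "uptake\t-> A\t0\t10\t",
               "conv\tA ->\t0\t1000\t"),
             file.path(dir, "reactions.tsv"))
  writeLines(c("id", "A"), file.path(dir, "metabolites.tsv"))
  expect_error(read_model(dir, "tsv"), "biomass")
  writeLines(c("id\tequation\tlb\tub\ttag",
               "uptake\t-> A\t0\t10\t",
               "uptake\tA ->\t0\t1000\tbiomass"),
             file.path(dir, "reactions.tsv"))
  expect_error(read_model(dir, "tsv"), "duplicate")
  expect_error(read_model(file.path(dir, "nope.json")), "no such file")
})

test_that("write/read round trips are exact across all three dialects", {
  fx <- make_toy_model("minimal")
  mod <- fx$model
  for (dialect in c("tsv", "json", "sbml")) {
    path <- if (dialect == "tsv") withr::local_tempdir()
      else withr::local_tempfile(fileext = paste0(".", dialect))
    write_model(mod, path, dialect = dialect)
    back <- read_model(path, dialect = dialect)
    expect_identical(back$metabolite_ids, mod$metabolite_ids, label = dialect)
    expect_identical(back$reaction_ids, mod$reaction_ids, label = dialect)
    expect_equal(back$S, mod$S, tolerance = 0, label = dialect)
    expect_equal(back$lb, mod$lb, tolerance = 0, label = dialect)
    expect_equal(back$ub, mod$ub, tolerance = 0, label = dialect)
    expect_identical(back$biomass_index, mod$biomass_index, label = dialect)
    expect_identical(back$tags[sort(names(back$tags))],
                     mod$tags[sort(names(mod$tags))], label = dialect)
  }
})

test_that("SBML and TSV serializations load to identical models", {
  mod <- chain_model()
  d1 <- withr::local_tempdir()
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_model(mod, d1, "tsv"); write_model(mod, f2, "sbml")
  m1 <- read_model(d1, "tsv"); m2 <- read_model(f2, "sbml")
  expect_equal(m1$S, m2$S, tolerance = 0)
  expect_equal(m1$lb, m2$lb, tolerance = 0)
  expect_equal(m1$ub, m2$ub, tolerance = 0)
})

test_that("set_biomass substitutes only the biomass column, by value", {
  fx <- make_toy_model("minimal")
  mod <- fx$model
  comp <- model_biomass_composition(mod)
  same <- set_biomass(mod, comp)
  expect_equal(same$S, mod$S, tolerance = 0)

  S_before <- mod$S
  doubled <- comp
  doubled$coefficients <- 2 * doubled$coefficients
  m2 <- set_biomass(mod, doubled)
  expect_equal(m2$S[, mod$biomass_index], 2 * mod$S[, mod$biomass_index])
  expect_equal(m2$S[, -mod$biomass_index], mod$S[, -mod$biomass_index])
  # value semantics: the input model is untouched
  expect_identical(mod$S, S_before)

  expect_error(set_biomass(mod, biomass_composition(c(X99 = 1))), "X99")
  # idempotence
  expect_equal(set_biomass(m2, doubled)$S, m2$S, tolerance = 0)
})

test_that("biomass assembly converts units and merges protein correctly", {
  mm <- c(glucose = 180, sucrose = 342.3, glycine = 75.07, alanine = 89.09)
  comp <- assemble_biomass(
    data.frame(metabolite = "glucose", amount = 18, unit = "mg_per_gDW"),
    molar_masses = mm)
  expect_equal(unname(comp$coefficients["glucose"]), 100)

  # zero protein: amino-acid coefficients all zero
  comp0 <- assemble_biomass(
    data.frame(metabolite = "glucose", amount = 18, unit = "mg_per_gDW"),
    protein_total = 0, aa_fractions = c(glycine = 0.4, alanine = 0.6),
    molar_masses = mm)
  expect_equal(unname(comp0$coefficients[c("glycine", "alanine")]), c(0, 0))

  # protein-bound amino acids: 10 mg protein, mass fractions 0.4/0.6
  compP <- assemble_biomass(
    measured = NULL, protein_total = 10,
    aa_fractions = c(glycine = 0.4, alanine = 0.6), molar_masses = mm)
  expect_equal(unname(compP$coefficients["glycine"]), 10 * 0.4 / 75.07 * 1000)
  expect_equal(unname(compP$coefficients["alanine"]), 10 * 0.6 / 89.09 * 1000)

  # determinism and ordering invariance
  meas <- data.frame(metabolite = c("glucose", "sucrose"),
                     amount = c(5, 3), unit = "mg_per_gDW")
  a <- assemble_biomass(meas, 10, c(glycine = 0.4, alanine = 0.6),
                        fixed_components = c(cellwall = 7),
                        molar_masses = c(mm, cellwall = 1))
  b <- assemble_biomass(meas[2:1, ], 10, c(alanine = 0.6, glycine = 0.4),
                        fixed_components = c(cellwall = 7),
                        molar_masses = c(mm, cellwall = 1))
  expect_identical(a$coefficients, b$coefficients)

  expect_error(assemble_biomass(
    data.frame(metabolite = "unknownium", amount = 1, unit = "mg_per_gDW"),
    molar_masses = mm), "molar mass")
  expect_error(assemble_biomass(
    data.frame(metabolite = "glucose", amount = -1, unit = "mg_per_gDW"),
    molar_masses = mm), "negative")
  expect_error(assemble_biomass(NULL, 10, c(glycine = 0.7, alanine = 0.6),
                                molar_masses = mm), "sum to 1")
})

test_that("biomass composition CSV round trip preserves coefficients", {
  f <- withr::local_tempfile(fileext = ".csv")
  comps <- list(biomass_composition(c(starch = 2.58, sucrose = 1), "A1", "E1"),
                biomass_composition(c(starch = 2.1, sucrose = 1.2), "A2", "E1"))
  write_biomass_csv(comps, f)
  back <- read_biomass_csv(f)
  expect_length(back, 2)
  expect_equal(back[["A1.E1"]]$coefficients, comps[[1]]$coefficients)
  expect_equal(back[["A2.E1"]]$coefficients, comps[[2]]$coefficients)
})
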