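# Small networks built in code for unit tests.

# Linear chain: uptake (<= cap) -> conversion -> biomass. Fully determined:
# every flux equals the biomass flux at optimum.
chain_model <- function(cap = 10, k = 1) {
  mets <- c("A", "B")
  rxns <- c("uptake", "conv", "biomass")
  S <- matrix(0, 2, 3, dimnames = list(mets, rxns))
  S["A", "uptake"] <- 1
  S[c("A", "B"), "conv"] <- c(-1, 1)
  S["B", "biomass"] <- -k
  metabolic_model(mets, rxns, S, lb = c(0, 0, 0), ub = c(cap, 1000, 1000),
                  biomass = "biomass")
}

# Branch: uptake (<= cap) feeds carboxylation and oxygenation, which both
# drain the same pool; their products feed biomass 1:1.
branch_model <- function(cap = 10) {
  mets <- c("A", "C")
  rxns <- c("uptake", "carb", "oxy", "biomass")
  S <- matrix(0, 2, 4, dimnames = list(mets, rxns))
  S["A", "uptake"] <- 1
  S[c("A", "C"), "carb"] <- c(-1, 1)
  S[c("A", "C"), "oxy"] <- c(-1, 1)
  S["C", "biomass"] <- -1
  metabolic_model(mets, rxns, S, lb = rep(0, 4), ub = c(cap, 1000, 1000, 1000),
                  biomass = "biomass",
                  tags = c(carboxylation = "carb", oxygenation = "oxy"))
}

# Two equivalent parallel routes, each of capacity `cap`, jointly limited by
# an uptake of the same capacity: at the optimum either route may carry
# anything in [0, cap].
two_route_model <- function(cap = 10) {
  mets <- c("A", "B")
  rxns <- c("uptake", "r1", "r2", "biomass")
  S <- matrix(0, 2, 4, dimnames = list(mets, rxns))
  S["A", "uptake"] <- 1
  S[c("A", "B"), "r1"] <- c(-1, 1)
  S[c("A", "B"), "r2"] <- c(-1, 1)
  S["B", "biomass"] <- -1
  metabolic_model(mets, rxns, S, lb = rep(0, 4), ub = c(cap, cap, cap, 1000),
                  biomass = "biomass")
}

# Chain with a detached futile cycle through a side metabolite C (f1: B -> C,
# f2: C -> B). The cycle can spin at any rate without affecting biomass;
# pFBA must silence it.
cycle_model <- function(cap = 10) {
  mets <- c("A", "B", "C")
  rxns <- c("uptake", "conv", "f1", "f2", "biomass")
  S <- matrix(0, 3, 5, dimnames = list(mets, rxns))
  S["A", "uptake"] <- 1
  S[c("A", "B"), "conv"] <- c(-1, 1)
  S[c("B", "C"), "f1"] <- c(-1, 1)
  S[c("C", "B"), "f2"] <- c(-1, 1)
  S["B", "biomass"] <- -1
  metabolic_model(mets, rxns, S, lb = rep(0, 5),
                  ub = c(cap, 1000, 500, 500, 1000), biomass = "biomass")
}

# Random small mass-consistent network for oracle comparisons: m metabolites,
# n reactions with sparse integer stoichiometry, a mix of irreversible and
# reversible reactions, and a designated objective column.
random_small_model <- function(n_mets = 3, n_rxns = 5, seed) {
  set.seed(seed)
  repeat {
    S <- matrix(0, n_mets, n_rxns)
    for (j in seq_len(n_rxns)) {
      k <- sample(1:2, 1)
      rows <- sample(n_mets, k)
      S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
    }
    if (any(colSums(S != 0) == 0)) next
    rev <- stats::runif(n_rxns) < 0.3
    lb <- ifelse(rev, -stats::runif(n_rxns, 1, 10), 0)
    ub <- stats::runif(n_rxns, 1, 10)
    mets <- paste0("m", seq_len(n_mets))
    rxns <- paste0("r", seq_len(n_rxns))
    dimnames(S) <- list(mets, rxns)
    mod <- tryCatch(
      metabolic_model(mets, rxns, S, lb, ub, biomass = n_rxns),
      error = function(e) NULL)
    if (!is.null(mod)) return(mod)
  }
}

# Shared simulated study used by several test files (computed once).
tiny_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- make_toy_model("minimal")
      cfg <- sim_config(n_accessions = 60, n_markers = 120, n_qtl = 24,
                        seed = 2024)
      panel <- simulate_panel(fx, cfg, compute_fluxes = "E1")
      cache <<- list(fx = fx, cfg = cfg, panel = panel)
    }
    cache
  }
})
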