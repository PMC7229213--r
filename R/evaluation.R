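# Cross-validation orchestration, accuracy statistics and diagnostic checks.

#' Build a repeated k-fold cross-validation plan
#'
#' Balanced folds by shuffled round-robin: per repeat the accessions are
#' shuffled and fold labels 1..k assigned cyclically, so fold sizes differ by
#' at most one. Deterministic given the seed.
#'
#' @param accessions character vector of accession ids.
#' @param n_folds folds per repeat (default 3).
#' @param n_repeats repeats (default 50).
#' @param seed mandatory RNG seed.
#' @return object of class `cv_plan` with `fold_assignments`
#'   (repeats x accessions integer matrix).
#' @export
make_cv_plan <- function(accessions, n_folds = 3L, n_repeats = 50L, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  n <- length(accessions)
  if (n_folds > n) stop("more folds than accessions", call. = FALSE)
  set.seed(seed)
  fa <- matrix(NA_integer_, n_repeats, n,
               dimnames = list(NULL, accessions))
  for (r in seq_len(n_repeats))
    fa[r, sample(n)] <- rep_len(seq_len(n_folds), n)
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = seed,
                 fold_assignments = fa),
            class = "cv_plan")
}

#' Pearson prediction accuracy
#'
#' Product-moment correlation with an explicit degenerate-input error
#' instead of a silent NaN.
#'
#' @param x,y numeric vectors of equal length >= 3 with positive variance.
#' @return correlation coefficient.
#' @export
pearson_accuracy <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need equal lengths >= 3", call. = FALSE)
  if (stats::var(x) <= 0 || stats::var(y) <= 0)
    stop("zero variance input", call. = FALSE)
  stats::cor(x, y)
}

#' Two-sided paired t-test on accuracy vectors
#'
#' @param a,b numeric vectors of equal length >= 3; the paired differences
#'   must have positive variance.
#' @return list(`t`, `p`, `df`, `mean_difference`).
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("need equal lengths >= 3", call. = FALSE)
  if (stats::var(a - b) <= 0)
    stop("paired differences have zero variance", call. = FALSE)
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate))
}

#' Mantel correlation between two similarity/distance matrices
#'
#' Pearson correlation of the off-diagonal entries with a permutation
#' p-value (joint row/column permutations of one matrix), computed with
#' \code{vegan::mantel}.
#'
#' @param D1,D2 square symmetric matrices of equal shape (n >= 4).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list(`r`, `p`).
#' @export
mantel_test <- function(D1, D2, n_perm = 999L, seed = 1L) {
  for (D in list(D1, D2)) {
    D <- as.matrix(D)
    if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
      stop("inputs must be square symmetric matrices", call. = FALSE)
  }
  if (nrow(as.matrix(D1)) < 4L) stop("need n >= 4", call. = FALSE)
  if (!all(dim(as.matrix(D1)) == dim(as.matrix(D2))))
    stop("matrices must have the same shape", call. = FALSE)
  set.seed(seed)
  mt <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                      permutations = n_perm)
  list(r = unname(mt$statistic), p = mt$signif)
}

#' Per-reaction coefficient of variation of estimated fluxes
#'
#' `CV = sd / |mean|` per flux-matrix column; columns with mean below `tol`
#' are flagged `NA` (CV undefined).
#'
#' @param flux_matrix accessions x reactions matrix.
#' @param tol near-zero mean tolerance.
#' @return data.frame with `reaction_id`, `mean`, `sd`, `cv`.
#' @export
flux_cv <- function(flux_matrix, tol = 1e-9) {
  m <- colMeans(flux_matrix)
  s <- apply(flux_matrix, 2, stats::sd)
  data.frame(reaction_id = colnames(flux_matrix), mean = m, sd = s,
             cv = ifelse(abs(m) > tol, s / abs(m), NA_real_),
             row.names = NULL)
}

#' Check estimated fluxes against enzyme maximal rates
#'
#' Flags every (accession, reaction) whose absolute flux exceeds the
#' accession-specific V_max of the catalysing enzyme. Reactions without an
#' enzyme mapping are skipped with a warning.
#'
#' @param flux_matrix accessions x reactions matrix.
#' @param vmax accessions x enzymes matrix (or named vector shared across
#'   accessions) of maximal rates, same flux units.
#' @param mapping named character vector, reaction id -> enzyme id.
#' @return data.frame of violations: `accession`, `reaction_id`, `flux`,
#'   `vmax` (zero rows if all fluxes are feasible).
#' @export
vmax_check <- function(flux_matrix, vmax, mapping) {
  rxns <- intersect(colnames(flux_matrix), names(mapping))
  skipped <- setdiff(colnames(flux_matrix), names(mapping))
  if (length(skipped))
    warning(length(skipped), " reaction(s) without enzyme mapping skipped",
            call. = FALSE)
  if (is.null(dim(vmax)))
    vmax <- matrix(rep(vmax, each = nrow(flux_matrix)),
                   nrow = nrow(flux_matrix),
                   dimnames = list(rownames(flux_matrix), names(vmax)))
  out <- list()
  for (r in rxns) {
    enz <- mapping[[r]]
    if (!enz %in% colnames(vmax)) next
    bad <- abs(flux_matrix[, r]) > vmax[, enz]
    if (any(bad))
      out[[r]] <- data.frame(accession = rownames(flux_matrix)[bad],
                             reaction_id = r,
                             flux = flux_matrix[bad, r],
                             vmax = vmax[bad, enz], row.names = NULL)
  }
  if (!length(out))
    return(data.frame(accession = character(), reaction_id = character(),
                      flux = numeric(), vmax = numeric()))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Run repeated cross-validation of a growth-prediction pipeline
#'
#' For every (repeat, fold): train on the other folds, predict the held-out
#' accessions, record the Pearson correlation between measured fresh weight
#' and the prediction. Pipelines: `"classical_gs"` (rrBLUP directly on fresh
#' weight), `"netgs"` (per-reaction flux models projected to a growth GEBV),
#' `"netgs_cross_env"` (flux models trained in E1, projected with
#' exchange-ratio constraints, scored against E2 fresh weight).
#'
#' The `data` bundle is a list with elements: `genotypes`
#' (`genotype_matrix`), `phenotype` (named fresh weights in the scored
#' environment), `flux_matrix` (accessions x reactions, netgs pipelines),
#' `models_by_accession` (shared `metabolic_model` or named list), `ratios`,
#' optional `covariates`, `retained`, and for the cross-environment pipeline
#' `xr` (an [exchange_ratios()] object). With `leakage = "paper"` the
#' supplied flux matrix (estimated once on the full panel) is used for
#' training; with `"strict"` fluxes are re-estimated per training fold from
#' `reference`, `compositions`, `weights_E1`, `M_ref` in the bundle.
#'
#' @param plan a [make_cv_plan()].
#' @param pipeline one of `"classical_gs"`, `"netgs"`, `"netgs_cross_env"`.
#' @param data input bundle (see Details).
#' @param leakage `"paper"` (default) or `"strict"`.
#' @return object of class `accuracy_record`: `method`, `r` (per-evaluation
#'   vector with repeat/fold in attributes), `mean`, `sd`, `n_missing`.
#' @export
run_cv <- function(plan, pipeline = c("classical_gs", "netgs",
                                      "netgs_cross_env"),
                   data, leakage = c("paper", "strict")) {
  pipeline <- match.arg(pipeline)
  leakage <- match.arg(leakage)
  G <- data$genotypes
  y <- data$phenotype[G$accession_ids]
  rs <- numeric(0); reps <- integer(0); folds <- integer(0)
  for (rep_i in seq_len(plan$n_repeats)) {
    fold_of <- plan$fold_assignments[rep_i, G$accession_ids]
    for (f in seq_len(plan$n_folds)) {
      test <- G$accession_ids[fold_of == f]
      train <- setdiff(G$accession_ids, test)
      pred <- tryCatch(
        .cv_predict(pipeline, data, train, test, leakage),
        error = function(e) NULL)
      r <- if (!is.null(pred) && sum(!is.na(pred)) >= 3L &&
               stats::sd(pred, na.rm = TRUE) > 0 &&
               stats::sd(y[test][!is.na(pred)]) > 0)
        stats::cor(y[test], pred, use = "complete.obs") else NA_real_
      rs <- c(rs, r); reps <- c(reps, rep_i); folds <- c(folds, f)
    }
  }
  structure(list(method = pipeline, r = rs, repeat_id = reps, fold_id = folds,
                 mean = mean(rs, na.rm = TRUE), sd = stats::sd(rs, na.rm = TRUE),
                 n_missing = sum(is.na(rs))),
            class = "accuracy_record")
}

.cv_predict <- function(pipeline, data, train, test, leakage) {
  G <- data$genotypes
  Gtr <- subset_accessions(G, train)
  Gte <- subset_accessions(G, test)
  sub_cov <- function(ids) if (is.null(data$covariates)) NULL
    else data$covariates[ids, , drop = FALSE]
  if (pipeline == "classical_gs") {
    fit <- fit_rrblup(Gtr, data$phenotype[train], covariates = sub_cov(train))
    return(predict_gebv(fit, Gte, covariates = sub_cov(test)))
  }
  fm <- if (leakage == "strict") {
    est <- estimate_panel_fluxes(data$model, data$reference,
                                 data$compositions[train],
                                 data$weights_E1[train], data$M_ref,
                                 ratios = data$ratios)
    est$fluxes
  } else data$flux_matrix[train, , drop = FALSE]
  set <- suppressWarnings(
    fit_flux_models(Gtr, fm, covariates = sub_cov(train)))
  retained <- if (is.null(data$retained)) names(set$models)
    else intersect(data$retained, names(set$models))
  mba <- data$models_by_accession
  if (is.list(mba) && !inherits(mba, "metabolic_model")) mba <- mba[test]
  if (pipeline == "netgs")
    suppressWarnings(predict_growth(set, Gte, mba, retained = retained,
                                    ratios = data$ratios,
                                    covariates = sub_cov(test)))
  else
    suppressWarnings(predict_growth_cross_env(set, Gte, mba, data$xr,
                                              retained = retained,
                                              ratios = data$ratios,
                                              covariates = sub_cov(test)))
}

#' @export
print.accuracy_record <- function(x, ...) {
  cat("accuracy_record [", x$method, "]: mean r = ",
      format(x$mean, digits = 4), " (sd ", format(x$sd, digits = 3), ", ",
      length(x$r) - x$n_missing, "/", length(x$r), " evaluations)\n", sep = "")
  invisible(x)
}

#' Compare two accuracy records
#'
#' Mean difference recomputed from the stored per-evaluation vectors plus a
#' two-sided paired t-test.
#'
#' @param a,b `accuracy_record` objects over the same plan.
#' @return list(`mean_a`, `mean_b`, `difference`, `relative_gain`, `t`, `p`).
#' @export
compare_accuracy <- function(a, b) {
  ok <- !is.na(a$r) & !is.na(b$r)
  tt <- paired_t_test(a$r[ok], b$r[ok])
  list(mean_a = mean(a$r[ok]), mean_b = mean(b$r[ok]),
       difference = mean(a$r[ok]) - mean(b$r[ok]),
       relative_gain = (mean(a$r[ok]) - mean(b$r[ok])) / abs(mean(b$r[ok])),
       t = tt$t, p = tt$p)
}
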