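# rrBLUP mixed models for arbitrary quantitative traits (reaction fluxes or
# fresh weight), plus genotype-matrix preparation.
#
# Model: y = X b + Z u + e,  u ~ N(0, sigma_u^2 I_p),  e ~ N(0, sigma_e^2 I_n),
# with Z the column-centred dosage matrix. The variance ratio is estimated by
# REML profiled through a single eigendecomposition of Z Z' (exact in the
# n << p regime typical of accession panels).

#' Construct a genotype matrix
#'
#' @param dosages accessions x markers numeric matrix of allele dosages in
#'   \[0, 2\] (row/col names used as ids if `accession_ids`/`marker_ids`
#'   missing).
#' @param accession_ids,marker_ids identifier vectors.
#' @param marker_class optional per-marker label, e.g. `"enzymatic"` or
#'   `"genome_wide"`.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, accession_ids = rownames(dosages),
                            marker_ids = colnames(dosages),
                            marker_class = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(accession_ids) || is.null(marker_ids))
    stop("accession and marker ids are required", call. = FALSE)
  if (anyDuplicated(accession_ids) || anyDuplicated(marker_ids))
    stop("ids must be unique", call. = FALSE)
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  dimnames(dosages) <- list(accession_ids, marker_ids)
  if (!is.null(marker_class)) {
    marker_class <- rep_len(as.character(marker_class), ncol(dosages))
    names(marker_class) <- marker_ids
  }
  structure(list(accession_ids = as.character(accession_ids),
                 marker_ids = as.character(marker_ids),
                 dosages = dosages, marker_class = marker_class),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", nrow(x$dosages), " accessions x ",
      ncol(x$dosages), " markers\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix by accession
#' @param G a `genotype_matrix`; `accessions` ids to keep (in this order).
#' @return a `genotype_matrix`.
#' @export
subset_accessions <- function(G, accessions) {
  missing <- setdiff(accessions, G$accession_ids)
  if (length(missing))
    stop("unknown accessions: ", paste(missing, collapse = ", "), call. = FALSE)
  genotype_matrix(G$dosages[accessions, , drop = FALSE],
                  marker_class = G$marker_class)
}

#' Prepare a genotype matrix: dosage coding, imputation, MAF filter
#'
#' Accepts a numeric accessions x markers table (or CSV path with header =
#' marker ids and first column = accession ids). Missing dosages are mean
#' imputed per marker; markers with minor allele frequency below
#' `maf_threshold` are removed, as are constant (monomorphic) markers.
#'
#' @param raw matrix / data.frame of dosages, or a CSV path.
#' @param maf_threshold minimum minor allele frequency (default 0.05).
#' @param class_filter optional value of `marker_class` to keep (e.g.
#'   `"enzymatic"`), applied when `marker_class` is supplied.
#' @param marker_class optional per-marker class labels.
#' @return a `genotype_matrix`.
#' @export
prepare_genotypes <- function(raw, maf_threshold = 0.05, class_filter = NULL,
                              marker_class = NULL) {
  if (is.character(raw) && length(raw) == 1L) {
    df <- utils::read.csv(raw, stringsAsFactors = FALSE, check.names = FALSE)
    raw <- as.matrix(df[, -1, drop = FALSE])
    rownames(raw) <- df[[1]]
  }
  M <- as.matrix(raw)
  storage.mode(M) <- "double"
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    for (j in which(colSums(is.na(M)) > 0)) M[is.na(M[, j]), j] <- mu[j]
    message("mean-imputed missing dosages in ",
            sum(colSums(is.na(as.matrix(raw))) > 0), " marker(s)")
  }
  p <- colMeans(M) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_threshold & apply(M, 2, stats::var) > 0
  if (!is.null(class_filter)) {
    if (is.null(marker_class)) stop("class_filter needs marker_class", call. = FALSE)
    keep <- keep & (rep_len(marker_class, ncol(M)) == class_filter)
  }
  if (!any(keep)) stop("no markers pass the MAF filter", call. = FALSE)
  genotype_matrix(M[, keep, drop = FALSE],
                  marker_class = if (is.null(marker_class)) NULL
                                 else rep_len(marker_class, ncol(M))[keep])
}

#' Read dosages from a VCF file
#'
#' Extracts biallelic GT records as 0/1/2 dosage of the alternate allele;
#' multi-allelic records are skipped with a warning count. Requires the
#' `vcfR` package.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return accessions x markers dosage matrix (possibly with NAs), suitable
#'   for [prepare_genotypes()].
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf_dosages requires the vcfR package", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(vcf)
  biallelic <- !grepl(",", alt)
  if (any(!biallelic))
    warning(sum(!biallelic), " non-biallelic record(s) skipped", call. = FALSE)
  gt <- vcfR::extract.gt(vcf[biallelic, ], element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]))
  })
  t(dos)                                         # accessions x markers
}

#' Principal components of a genotype matrix
#'
#' Top-`k` principal components of the column-centred dosage matrix, for use
#' as fixed covariates capturing population structure.
#'
#' @param G a `genotype_matrix`.
#' @param k number of components (default 10); must be smaller than the
#'   number of accessions.
#' @return accessions x k matrix of PC scores, columns ordered by decreasing
#'   variance explained, with `attr(,"var_explained")`.
#' @export
compute_pcs <- function(G, k = 10L) {
  n <- nrow(G$dosages)
  if (k >= n) stop("k must be smaller than the number of accessions", call. = FALSE)
  pc <- stats::prcomp(G$dosages, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- G$accession_ids
  attr(scores, "var_explained") <- pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  scores
}

# REML profile log-likelihood over the variance ratio lambda = su^2 / se^2,
# after rotation by the eigenvectors of K = Z Z'.
.reml_ll <- function(log_lambda, d, yr, Xr) {
  lambda <- exp(log_lambda)
  Dg <- lambda * d + 1
  W <- 1 / Dg
  XtWX <- crossprod(Xr, Xr * W)
  XtWy <- crossprod(Xr, yr * W)
  beta <- solve(XtWX, XtWy)
  r <- yr - Xr %*% beta
  nq <- length(yr) - ncol(Xr)
  S <- sum(r^2 * W)
  -0.5 * (nq * log(S / nq) + sum(log(Dg)) + determinant(XtWX)$modulus[1])
}

#' Fit an rrBLUP model for one trait
#'
#' Ridge-regression BLUP: a linear mixed model with i.i.d. Gaussian marker
#' effects on the column-centred dosages, intercept (plus optional fixed
#' covariates such as genotype PCs), and variance components estimated by
#' REML via a single eigendecomposition of the marker cross-product.
#'
#' @param G a `genotype_matrix`.
#' @param y numeric trait vector (length = accessions; names checked against
#'   accession ids when present).
#' @param covariates optional accessions x q numeric matrix of fixed-effect
#'   covariates.
#' @param trait_id label stored on the model.
#' @param shrinkage optional fixed ridge parameter `lambda =
#'   sigma_e^2 / sigma_u^2`; when given, REML is skipped and the effects are
#'   the closed-form ridge solution.
#' @return object of class `flux_model` with fields `intercept`,
#'   `marker_effects`, `covariate_effects`, `variance_components`
#'   (`sigma2_marker`, `sigma2_residual`), `trait_id`, `cv_accuracy` (NA
#'   until filled by cross-validation).
#' @export
fit_rrblup <- function(G, y, covariates = NULL, trait_id = "",
                       shrinkage = NULL) {
  y <- as.numeric(y)
  n <- nrow(G$dosages)
  if (length(y) != n) stop("y length does not match accessions", call. = FALSE)
  if (stats::var(y) <= 0) stop("trait has zero variance", call. = FALSE)
  marker_means <- colMeans(G$dosages)
  Z <- sweep(G$dosages, 2, marker_means)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("covariates are collinear", call. = FALSE)

  if (is.null(shrinkage)) {
    K <- tcrossprod(Z)
    eig <- eigen(K, symmetric = TRUE)
    d <- pmax(eig$values, 0)
    yr <- crossprod(eig$vectors, y)
    Xr <- crossprod(eig$vectors, X)
    opt <- stats::optimize(.reml_ll, interval = c(-18, 18), d = d, yr = yr,
                           Xr = Xr, maximum = TRUE, tol = 1e-9)
    lambda <- exp(opt$maximum)                   # su^2 / se^2
    Dg <- lambda * d + 1
    W <- 1 / Dg
    beta <- solve(crossprod(Xr, Xr * W), crossprod(Xr, yr * W))
    r <- yr - Xr %*% beta
    se2 <- sum(r^2 * W) / (n - ncol(X))
    su2 <- lambda * se2
    u <- lambda * crossprod(Z, eig$vectors %*% (W * r))
  } else {
    lambda_ridge <- shrinkage                    # se^2 / su^2
    A <- crossprod(Z) + diag(lambda_ridge, ncol(Z))
    # GLS intercept under V = su^2 (ZZ'/lambda_ridge + I) reduces to OLS on X
    Vinv_lambda <- solve(tcrossprod(Z) / lambda_ridge + diag(n))
    beta <- solve(crossprod(X, Vinv_lambda %*% X),
                  crossprod(X, Vinv_lambda %*% y))
    u <- solve(A, crossprod(Z, y - X %*% beta))
    se2 <- NA_real_; su2 <- NA_real_
  }
  structure(list(intercept = beta[1],
                 covariate_effects = if (ncol(X) > 1) beta[-1] else NULL,
                 marker_effects = stats::setNames(as.numeric(u), G$marker_ids),
                 marker_means = marker_means,
                 variance_components = c(sigma2_marker = unname(su2),
                                         sigma2_residual = unname(se2)),
                 trait_id = trait_id, cv_accuracy = NA_real_),
            class = "flux_model")
}

#' Predict breeding values from a fitted rrBLUP model
#'
#' `y_hat = intercept + covariates %*% b + (dosages - training means) %*% u`.
#' Markers are aligned by id, not position.
#'
#' @param model a `flux_model` from [fit_rrblup()].
#' @param G a `genotype_matrix`; must contain every model marker.
#' @param covariates optional covariate matrix matching the model's fixed
#'   part.
#' @return named numeric vector of predictions per accession.
#' @export
predict_gebv <- function(model, G, covariates = NULL) {
  ids <- names(model$marker_effects)
  missing <- setdiff(ids, G$marker_ids)
  if (length(missing))
    stop("markers absent from genotypes: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...", call. = FALSE)
  Z <- sweep(G$dosages[, ids, drop = FALSE], 2, model$marker_means[ids])
  yhat <- model$intercept + as.numeric(Z %*% model$marker_effects)
  if (!is.null(model$covariate_effects)) {
    if (is.null(covariates)) stop("model was fitted with covariates", call. = FALSE)
    yhat <- yhat + as.numeric(as.matrix(covariates) %*% model$covariate_effects)
  }
  stats::setNames(yhat, G$accession_ids)
}

#' Cross-validated prediction accuracy of an rrBLUP model for one trait
#'
#' For each (repeat, fold) of the plan: fit on the other folds, predict the
#' held-out accessions, and record the Pearson correlation between observed
#' and predicted. Returns the per-evaluation vector and its mean.
#'
#' @param G a `genotype_matrix`; `y` named trait vector over its accessions.
#' @param plan a [make_cv_plan()] object.
#' @param covariates optional covariate matrix (rows = accessions).
#' @return list(`r` = per-evaluation correlations, `mean`, `sd`).
#' @export
cv_accuracy <- function(G, y, plan, covariates = NULL) {
  y <- y[G$accession_ids]
  sub_cov <- function(ids) if (is.null(covariates)) NULL
    else covariates[ids, , drop = FALSE]
  rs <- numeric(0)
  for (rep_i in seq_len(plan$n_repeats)) {
    fold_of <- plan$fold_assignments[rep_i, G$accession_ids]
    for (f in seq_len(plan$n_folds)) {
      test <- G$accession_ids[fold_of == f]
      train <- setdiff(G$accession_ids, test)
      fit <- fit_rrblup(subset_accessions(G, train), y[train],
                        covariates = sub_cov(train))
      pred <- predict_gebv(fit, subset_accessions(G, test),
                           covariates = sub_cov(test))
      rs <- c(rs, if (stats::sd(pred) > 0 && stats::sd(y[test]) > 0)
        stats::cor(y[test], pred) else NA_real_)
    }
  }
  list(r = rs, mean = mean(rs, na.rm = TRUE), sd = stats::sd(rs, na.rm = TRUE))
}

#' Fit rrBLUP models for every reaction flux
#'
#' One [fit_rrblup()] call per flux-matrix column; zero-variance columns
#' (fluxes fully determined by stoichiometry) are dropped from modelling with
#' a warning and reported in `dropped` with their constant value. When a CV
#' plan is supplied, per-reaction cross-validated accuracies are recorded.
#'
#' @param G a `genotype_matrix`.
#' @param flux_matrix accessions x reactions matrix of estimated fluxes over
#'   the non-zero support of the reference.
#' @param covariates optional covariate matrix.
#' @param cv_plan optional [make_cv_plan()]; enables `cv_accuracy` per model.
#' @return object of class `flux_model_set`: `models` (named list of
#'   `flux_model`), `dropped` (named constants), `training_accessions`.
#' @export
fit_flux_models <- function(G, flux_matrix, covariates = NULL, cv_plan = NULL) {
  flux_matrix <- as.matrix(flux_matrix)
  if (is.null(colnames(flux_matrix)))
    stop("flux_matrix needs reaction ids as column names", call. = FALSE)
  flux_matrix <- flux_matrix[G$accession_ids, , drop = FALSE]
  vars <- apply(flux_matrix, 2, stats::var)
  dropped <- colMeans(flux_matrix[, vars <= 1e-12, drop = FALSE])
  if (length(dropped))
    warning(length(dropped), " constant flux column(s) dropped from modelling",
            call. = FALSE)
  keep <- colnames(flux_matrix)[vars > 1e-12]
  models <- lapply(keep, function(rid) {
    m <- fit_rrblup(G, flux_matrix[, rid], covariates = covariates,
                    trait_id = rid)
    if (!is.null(cv_plan))
      m$cv_accuracy <- cv_accuracy(G, stats::setNames(flux_matrix[, rid],
                                                      G$accession_ids),
                                   cv_plan, covariates = covariates)$mean
    m
  })
  names(models) <- keep
  structure(list(models = models, dropped = dropped,
                 training_accessions = G$accession_ids),
            class = "flux_model_set")
}

#' @export
print.flux_model_set <- function(x, ...) {
  cat("flux_model_set: ", length(x$models), " reaction models (",
      length(x$dropped), " constant fluxes passed through)\n", sep = "")
  invisible(x)
}

#' Predict flux GEBVs for a set of accessions
#'
#' Evaluates every reaction model of a `flux_model_set` on a genotype matrix.
#' Constant (dropped) fluxes are passed through at their training value.
#'
#' @param set a `flux_model_set`; `G` a `genotype_matrix`.
#' @param covariates optional covariate matrix.
#' @return accessions x reactions matrix of flux GEBVs (modelled + constant
#'   columns).
#' @export
predict_flux_gebvs <- function(set, G, covariates = NULL) {
  cols <- lapply(set$models, predict_gebv, G = G, covariates = covariates)
  M <- do.call(cbind, cols)
  colnames(M) <- names(set$models)
  if (length(set$dropped)) {
    C <- matrix(rep(set$dropped, each = nrow(M)), nrow = nrow(M),
                dimnames = list(rownames(M), names(set$dropped)))
    M <- cbind(M, C)
  }
  M
}
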