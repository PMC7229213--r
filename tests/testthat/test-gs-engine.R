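test_that("MAF filtering removes rare and monomorphic markers", {
  n <- 50
  dos <- cbind(common = rep(c(0, 1, 2), length.out = n),
               rare = c(rep(1, 3), rep(0, n - 3)),      # freq 0.03
               mono = rep(1, n),                        # constant
               kept = rep(c(0, 2), length.out = n))
  rownames(dos) <- sprintf("a%02d", seq_len(n))
  G <- prepare_genotypes(dos, maf_threshold = 0.05)
  expect_setequal(G$marker_ids, c("common", "kept"))
  # threshold 0 retains all polymorphic markers
  G0 <- prepare_genotypes(dos, maf_threshold = 0)
  expect_setequal(G0$marker_ids, c("common", "rare", "kept"))
  expect_error(prepare_genotypes(dos[, "mono", drop = FALSE]), "MAF")
})

test_that("genotype CSV loading and missing-dosage imputation work", {
  f <- withr::local_tempfile(fileext = ".csv")
  dos <- matrix(c(0, 1, 2, 2, NA, 0, 1, 1, 2, 0, 1, 1), 4, 3,
                dimnames = list(paste0("a", 1:4), paste0("m", 1:3)))
  utils::write.csv(cbind(accession = rownames(dos), as.data.frame(dos)), f,
                   row.names = FALSE)
  expect_message(G <- prepare_genotypes(f, maf_threshold = 0), "imputed")
  expect_equal(unname(G$dosages["a1", "m2"]), mean(c(0, 1, 1)),
               tolerance = 1e-12)
})

test_that("VCF dosage extraction matches the GT field", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\tsnp2\tC\tT,G\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t300\tsnp3\tG\tA\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0"), f)
  expect_warning(dos <- read_vcf_dosages(f), "non-biallelic")
  expect_equal(dim(dos), c(3L, 2L))
  expect_equal(unname(dos[, "snp1"]), c(0, 1, 2))
  expect_equal(unname(dos[, "snp3"]), c(1, 2, 0))
})

test_that("principal components order variance and respect duplicates", {
  set.seed(9)
  dos <- matrix(rbinom(40 * 30, 2, 0.4), 40, 30,
                dimnames = list(sprintf("a%02d", 1:40), sprintf("m%02d", 1:30)))
  dos[2, ] <- dos[1, ]                           # duplicated accession rows
  G <- genotype_matrix(dos)
  pcs <- compute_pcs(G, k = 5)
  expect_equal(pcs[1, ], pcs[2, ], tolerance = 1e-10)
  ve <- attr(pcs, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))
  expect_error(compute_pcs(G, k = 40), "smaller")

  # rank-1 dosages: the first PC recovers the generating axis up to sign
  u <- rbinom(40, 2, 0.5)
  dos1 <- outer(u, rep(1, 10))
  dimnames(dos1) <- list(sprintf("a%02d", 1:40), sprintf("m%02d", 1:10))
  p1 <- compute_pcs(genotype_matrix(dos1), k = 1)
  expect_gt(abs(cor(p1[, 1], u)), 1 - 1e-10)
})

test_that("rrBLUP recovers a perfectly heritable single-marker trait", {
  set.seed(21)
  dos <- matrix(rbinom(60 * 40, 2, 0.5), 60, 40,
                dimnames = list(sprintf("a%02d", 1:60), sprintf("m%02d", 1:40)))
  G <- genotype_matrix(dos)
  y <- dos[, 7]
  fit <- fit_rrblup(G, y)
  expect_gt(cor(predict_gebv(fit, G), y), 0.99)
  expect_error(fit_rrblup(G, rep(1, 60)), "zero variance")
})

test_that("fixed-shrinkage effects equal the closed-form ridge solution", {
  set.seed(22)
  dos <- matrix(rbinom(30 * 50, 2, 0.5), 30, 50,
                dimnames = list(sprintf("a%02d", 1:30), sprintf("m%02d", 1:50)))
  G <- genotype_matrix(dos)
  y <- rnorm(30)
  for (lam in c(0.5, 2, 10)) {
    fit <- fit_rrblup(G, y, shrinkage = lam)
    Z <- sweep(dos, 2, colMeans(dos))
    oracle <- oracle_ridge(Z, y, lam)
    expect_equal(unname(fit$marker_effects), oracle$u, tolerance = 1e-8)
    expect_equal(unname(fit$intercept), oracle$beta, tolerance = 1e-8)
  }
})

test_that("rrBLUP is equivariant under marker permutation and trait shifts", {
  set.seed(23)
  dos <- matrix(rbinom(40 * 30, 2, 0.5), 40, 30,
                dimnames = list(sprintf("a%02d", 1:40), sprintf("m%02d", 1:30)))
  G <- genotype_matrix(dos)
  y <- as.numeric(dos %*% rnorm(30)) + rnorm(40)
  fit <- fit_rrblup(G, y)
  perm <- sample(30)
  Gp <- genotype_matrix(dos[, perm])
  fitp <- fit_rrblup(Gp, y)
  expect_equal(fitp$marker_effects[G$marker_ids], fit$marker_effects,
               tolerance = 1e-6)
  expect_equal(predict_gebv(fitp, Gp), predict_gebv(fit, G), tolerance = 1e-6)
  # adding a constant shifts predictions by exactly that constant
  fitc <- fit_rrblup(G, y + 100)
  expect_equal(predict_gebv(fitc, G), predict_gebv(fit, G) + 100,
               tolerance = 1e-6)
})

test_that("predict_gebv honours alignment, fitted values and row order", {
  set.seed(24)
  dos <- matrix(rbinom(30 * 20, 2, 0.5), 30, 20,
                dimnames = list(sprintf("a%02d", 1:30), sprintf("m%02d", 1:20)))
  G <- genotype_matrix(dos)
  y <- as.numeric(dos %*% rnorm(20)) + rnorm(30)
  fit <- fit_rrblup(G, y)
  pred <- predict_gebv(fit, G)
  # all-zero effects predict the intercept everywhere
  fit0 <- fit
  fit0$marker_effects[] <- 0
  expect_equal(unname(predict_gebv(fit0, G)), rep(fit$intercept, 30))
  # permuting accession rows permutes predictions identically
  ord <- sample(30)
  expect_equal(predict_gebv(fit, subset_accessions(G, G$accession_ids[ord])),
               pred[ord])
  Gm <- genotype_matrix(dos[, 1:10])
  expect_error(predict_gebv(fit, Gm), "absent")
})

test_that("per-reaction model fitting handles duplicates and constants", {
  set.seed(25)
  dos <- matrix(rbinom(40 * 30, 2, 0.5), 40, 30,
                dimnames = list(sprintf("a%02d", 1:40), sprintf("m%02d", 1:30)))
  G <- genotype_matrix(dos)
  f1 <- as.numeric(dos %*% rnorm(30)) + rnorm(40)
  fm <- cbind(r1 = f1, r2 = f1, r3 = rep(2.5, 40))
  rownames(fm) <- G$accession_ids
  expect_warning(set <- fit_flux_models(G, fm), "constant")
  expect_named(set$models, c("r1", "r2"))
  expect_equal(set$models$r1$marker_effects, set$models$r2$marker_effects,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(unname(set$dropped["r3"]), 2.5)
  # constant fluxes pass through prediction
  gebvs <- predict_flux_gebvs(set, G)
  expect_equal(unname(gebvs[, "r3"]), rep(2.5, 40))
  expect_equal(unname(gebvs[, "r1"]), unname(gebvs[, "r2"]), tolerance = 1e-8)
})

test_that("cross-validated accuracy rises with heritability", {
  set.seed(26)
  n <- 120; p <- 150
  dos <- matrix(rbinom(n * p, 2, 0.5), n, p,
                dimnames = list(sprintf("a%03d", 1:n), sprintf("m%03d", 1:p)))
  G <- genotype_matrix(dos)
  plan <- make_cv_plan(G$accession_ids, 3, 2, seed = 31)
  g <- as.numeric(scale(dos %*% rnorm(p)))
  acc <- vapply(c(0.2, 0.8), function(h2) {
    set.seed(h2 * 100)
    y <- sqrt(h2) * g + sqrt(1 - h2) * rnorm(n)
    names(y) <- G$accession_ids
    cv_accuracy(G, y, plan)$mean
  }, numeric(1))
  expect_gt(acc[2], acc[1])
  expect_gt(acc[2], 0.5)
})
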