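test_that("cis windows are strand-aware and clamped", {
  g <- list(group_id = "g", chromosome = "chr5", start = 5000000,
            end = 5050000, strand = "+")
  w <- define_cis_window(g)
  expect_equal(c(w$start, w$end), c(4000000, 6000000))
  g$strand <- "-"
  wm <- define_cis_window(g)
  expect_equal(wm$anchor, 5050000)
  expect_equal(c(wm$start, wm$end), c(4050000, 6050000))
  g2 <- list(group_id = "g", chromosome = "chr5", start = 200000,
             end = 250000, strand = "+")
  expect_equal(define_cis_window(g2)$start, 1)
  expect_equal(define_cis_window(g, chromosome_length = 5500000)$end, 5500000)
})

test_that("principal components match the eigendecomposition oracle", {
  set.seed(31)
  # data on a line: PC1 explains ~ everything
  t_ <- rnorm(50)
  line <- cbind(t_, 2 * t_, -t_) + matrix(rnorm(150, 0, 1e-6), 50)
  pcs <- compute_pcs(line, k = 1)
  expect_gt(cor(pcs[, 1], t_)^2, 0.999)
  # scores equal the eigendecomposition of the scaled data, up to sign
  x <- matrix(rnorm(60), 10, 6)
  xs <- scale(x)
  eig <- eigen(crossprod(xs) / (nrow(xs) - 1))
  scores_oracle <- xs %*% eig$vectors[, 1:3]
  pcs3 <- compute_pcs(x, k = 3)
  for (j in 1:3) {
    expect_equal(abs(cor(pcs3[, j], scores_oracle[, j])), 1,
                 tolerance = 1e-8)
  }
  # rotation invariance of covariance-PCA scores: an orthogonal rotation of
  # the data spans the same principal subspace
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  cc <- cancor(compute_pcs(x, k = 3, scale. = FALSE),
               compute_pcs(x %*% q, k = 3, scale. = FALSE))$cor
  expect_equal(cc, rep(1, 3), tolerance = 1e-6)
  expect_error(compute_pcs(x, k = 6), "smaller")
})

test_that("nominal scan reproduces closed-form OLS", {
  set.seed(32)
  n <- 20
  covs <- cbind(rnorm(n), rnorm(n))
  G <- matrix(stats::rbinom(n * 8, 2, 0.4), n, 8,
              dimnames = list(NULL, sprintf("chr1_%d_A_G", 1:8 * 100)))
  y <- 0.7 * G[, 3] + covs %*% c(0.5, -1) + rnorm(n)
  recs <- nominal_scan(drop(y), G, covariates = covs)
  for (j in seq_len(ncol(G))) {
    X <- cbind(1, covs, G[, j])
    o <- ols_closed_form(drop(y), X)
    expect_equal(recs$beta[j], o$beta[4], tolerance = 1e-10)
    expect_equal(recs$se[j], o$se[4], tolerance = 1e-10)
    expect_equal(recs$pvalue[j],
                 2 * pt(abs(o$beta[4] / o$se[4]), o$df, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # allele summaries
  expect_equal(recs$an, rep(2L * n, 8))
  expect_equal(recs$ac, as.integer(colSums(G)))
  # identity trait: beta 1 and essentially zero p
  r1 <- nominal_scan(G[, 1] + rnorm(n, 0, 1e-8), G[, 1, drop = FALSE],
                     min_variants = 1)
  expect_equal(r1$beta, 1, tolerance = 1e-6)
  expect_lt(r1$pvalue, 1e-12)
})

test_that("scan preconditions: variant count, variance, missing dosages", {
  set.seed(33)
  n <- 30
  G <- matrix(stats::rbinom(n * 4, 2, 0.4), n, 4)
  expect_error(nominal_scan(rnorm(n), G), class = "qtl_skip")
  expect_error(nominal_scan(rep(1, n),
                            cbind(G, stats::rbinom(n, 2, 0.4))),
               class = "qtl_skip")
  # pairwise-complete handling: records reflect the observed subset
  G5 <- cbind(G, v5 = stats::rbinom(n, 2, 0.4))
  colnames(G5) <- sprintf("chr1_%d_A_G", 1:5 * 10)
  G5[1:4, 2] <- NA
  y <- rnorm(n)
  recs <- nominal_scan(y, G5)
  expect_equal(recs$n[2], n - 4)
  o <- ols_closed_form(y[-(1:4)], cbind(1, G5[-(1:4), 2]))
  expect_equal(recs$beta[2], o$beta[2], tolerance = 1e-10)
  # monomorphic variant: record emitted with missing beta/se
  G5[, 3] <- 1
  recs2 <- nominal_scan(y, G5)
  expect_true(is.na(recs2$beta[3]))
  expect_equal(nrow(recs2), 5L)
})

test_that("residualised scan agrees with covariate-adjusted scan", {
  set.seed(34)
  n <- 60
  covs <- matrix(rnorm(n * 3), n)
  G <- matrix(rnorm(n * 5) + 1, n, 5,
              dimnames = list(NULL, sprintf("chr1_%d_A_G", 1:5 * 10)))
  G <- pmin(pmax(G, 0), 2)
  y <- rnorm(n)
  adj <- nominal_scan(y, G, covariates = covs)
  qz <- qr(cbind(1, covs))
  resid_scan <- nominal_scan(drop(qr.resid(qz, y)), qr.resid(qz, G),
                             covariates = NULL)
  expect_equal(adj$beta, resid_scan$beta, tolerance = 1e-8)
})

test_that("group permutation: floor on planted effects, reduction case", {
  set.seed(35)
  n <- 200
  dm <- simulate_genotypes(n, 10, maf = 0.4, seed = 36)
  g <- dm$dosage[, 5]
  y <- scale(2 * g + rnorm(n))  # ~2 sd effect
  res <- group_permutation(cbind(t1 = drop(y)), dm$dosage, n_perm = 1000,
                           seed = 37)
  expect_equal(res$empirical_p, 1 / 1001)
  expect_equal(unname(res$lead["variant"]), colnames(dm$dosage)[5])
  # single-trait group equals a single-trait permutation pass
  res2 <- group_permutation(cbind(t1 = drop(y), t2 = drop(y)),
                            dm$dosage, n_perm = 200, seed = 38)
  res3 <- group_permutation(cbind(t1 = drop(y)), dm$dosage, n_perm = 200,
                            seed = 38)
  expect_equal(res2$observed_p, res3$observed_p)
  expect_equal(res2$empirical_p, res3$empirical_p)
  # relabelling traits within the group leaves empirical p unchanged
  y2 <- rnorm(n)
  ra <- group_permutation(cbind(a = drop(y), b = y2), dm$dosage,
                          n_perm = 200, seed = 39)
  rb <- group_permutation(cbind(b = y2, a = drop(y)), dm$dosage,
                          n_perm = 200, seed = 39)
  expect_equal(ra$empirical_p, rb$empirical_p)
  expect_warning(group_permutation(cbind(t1 = drop(y)), dm$dosage,
                                   n_perm = 50, seed = 40), "100")
})

test_that("dataset FDR matches the brute-force Benjamini-Hochberg rule", {
  expect_length(dataset_fdr(setNames(rep(1, 10), paste0("g", 1:10))), 0)
  p <- setNames(c(1e-10, rep(1, 99)), paste0("g", 1:100))
  expect_equal(dataset_fdr(p), "g1")
  set.seed(41)
  for (i in 1:20) {
    m <- 50
    pv <- setNames(runif(m)^sample(1:3, 1), paste0("g", 1:m))
    q <- 0.01
    ps <- sort(pv)
    k <- max(c(0, which(ps <= seq_len(m) * q / m)))
    oracle <- if (k == 0) character(0) else names(ps)[seq_len(k)]
    expect_setequal(dataset_fdr(pv, level = q), oracle)
  }
})

test_that("exon effect profiles flag planted effects and cover the null", {
  set.seed(42)
  n <- 150
  g <- stats::rbinom(n, 2, 0.4)
  exons <- cbind(e1 = rnorm(n), e2 = drop(scale(g + rnorm(n, 0, 0.5))),
                 e3 = rnorm(n), e4 = rep(0, n))
  prof <- exon_effect_profile(g, exons)
  expect_equal(attr(prof, "excluded"), "e4")
  expect_true(prof$significant[prof$exon == "e2"])
  expect_false(any(prof$significant[prof$exon %in% c("e1", "e3")]))
  expect_equal(prof$ci_low, prof$beta - 1.96 * prof$se)
  # null 95% CI coverage across seeded replicates
  cover <- replicate(150, {
    gg <- stats::rbinom(40, 2, 0.4)
    pr <- exon_effect_profile(gg, cbind(e = rnorm(40)))
    pr$ci_low <= 0 && pr$ci_high >= 0
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})
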