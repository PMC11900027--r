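test_that("low-count filter applies both thresholds inclusively", {
  st <- de_settings() # min_count 10 in min_samples 8
  m <- make_counts(rbind(
    c(rep(10, 8), rep(0, 8)),   # exactly at both boundaries: retained
    rep(0, 16),                 # all zero: removed
    rep(9, 16),                 # never reaches min_count: removed
    c(rep(10, 7), rep(0, 9)),   # one sample short: removed
    rep(50, 16)                 # comfortably retained
  ))
  kept <- filter_low_counts(m, st)
  expect_identical(rownames(kept), c("g001", "g005"))
  # row-scan oracle over a random matrix
  set.seed(42)
  r <- make_counts(matrix(rpois(600, 9), nrow = 50))
  oracle <- apply(r, 1, function(row) sum(row >= 10) >= 8)
  expect_identical(rownames(filter_low_counts(r, st)),
                   rownames(r)[oracle])
  expect_warning(filter_low_counts(make_counts(matrix(0, 2, 16)), st),
                 "no genes")
})

test_that("median-of-ratios size factors match hand computations", {
  eq <- make_counts(matrix(7, 5, 4))
  expect_equal(unname(size_factors(eq)), rep(1, 4))
  # columns at x0.5, x1, x2 of a base profile
  m <- make_counts(rbind(c(2, 4, 8), c(2, 4, 8)))
  expect_equal(unname(size_factors(m)), c(0.5, 1, 2))
  # single sample: factor 1 by the degenerate-case convention
  expect_equal(unname(size_factors(make_counts(matrix(c(3, 9, 27), 3, 1)))),
               1)
  # fallback when no gene is expressed everywhere
  mz <- make_counts(rbind(c(4, 8, 0), c(0, 6, 12)))
  expect_true(all(size_factors(mz) > 0))
  expect_error(size_factors(make_counts(matrix(0, 2, 2))), "no gene")
})

test_that("scaling one sample scales its size factor and not the VST", {
  d <- generate_counts(small_config(seed = 8, n_genes = 200,
                                    library_size_range = c(1e6, 1e6)))
  m <- d$counts
  m2 <- m
  m2[, 3] <- as.integer(m2[, 3] * 2)
  sf1 <- size_factors(m)
  sf2 <- size_factors(m2)
  expect_equal(unname(sf2[3] / sf1[3]), 2, tolerance = 0.02)
  st <- de_settings()
  v1 <- vst_transform(m, sf1, st)
  v2 <- vst_transform(m2, sf2, st)
  expect_equal(v1[, 3], v2[, 3], tolerance = 0.05)
})

test_that("dispersion estimator floors Poisson-like and constant genes", {
  st <- de_settings()
  smp <- two_group_samples(20, 20)
  # constant gene
  const <- make_counts(matrix(100, 1, 40))
  expect_equal(unname(estimate_dispersion(const, rep(1, 40), smp, st)),
               st$dispersion_floor)
  # Poisson genes with large means land at the floor >= 95% of the time
  set.seed(7)
  pois <- make_counts(matrix(rpois(1000 * 40, 800), 1000, 40))
  disp <- estimate_dispersion(pois, rep(1, 40), smp, st)
  expect_gte(mean(disp <= st$dispersion_floor + 1e-12), 0.95)
})

test_that("dispersion estimator recovers a known NB dispersion", {
  st <- de_settings()
  smp <- two_group_samples(25, 25)
  set.seed(11)
  nb <- make_counts(matrix(rnbinom(1000 * 50, mu = 500, size = 1 / 0.2),
                           1000, 50))
  disp <- estimate_dispersion(nb, rep(1, 50), smp, st)
  expect_lt(abs(median(disp) - 0.2) / 0.2, 0.25)
})

test_that("identical groups give zero LFC and p near one", {
  base <- c(40, 80, 120, 200, 35)
  m <- make_counts(matrix(rep(base, 16), ncol = 16))
  smp <- two_group_samples(8, 8)
  de <- nb_wald(m, smp, de_settings(min_samples = 4), "treat")
  expect_equal(de$log2fc, rep(0, 5), tolerance = 1e-6)
  expect_true(all(de$pvalue > 0.999))
  expect_false(any(de$significant))
})

test_that("Wald z matches an independent Poisson GLM at floor dispersion", {
  set.seed(21)
  smp <- two_group_samples(6, 6)
  st <- de_settings(min_samples = 4, dispersion_floor = 1e-8,
                    dispersion_cap = 1e-6)
  mu <- rep(c(500, 650), c(6, 6))
  m <- make_counts(t(vapply(1:10, function(i) rpois(12, mu),
                            numeric(12))))
  fit <- schemeDE:::nb_fit_all(m, smp, st, factors = rep(1, 12),
                               dispersions = rep(1e-8, 10))
  de <- schemeDE:::de_result_from_fit(fit, "treat", st)
  for (i in 1:10) {
    g <- glm(m[i, ] ~ factor(smp$treatment, c("control", "treat")),
             family = poisson())
    z_oracle <- summary(g)$coefficients[2, 3]
    expect_lt(abs(de$wald_z[i] - z_oracle) / abs(z_oracle), 0.01)
  }
})

test_that("rank-deficient designs are rejected with the aliased columns", {
  d <- generate_counts(small_null_config(seed = 2, n_genes = 50))
  smp <- d$samples
  # make colony a copy of one treatment indicator: aliasing
  smp$colony <- as.integer(smp$treatment == "clothianidin_acute") + 1
  expect_error(nb_wald(d$counts, smp, de_settings(), "clothianidin_acute"),
               "rank deficient")
})

test_that("BH adjustment follows the step-up rule and handles NA", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, NA, 0.02, 0.8, NA)
  adj <- bh_adjust(p)
  expect_true(all(is.na(adj[is.na(p)])))
  # missing values are excluded from the number of tests
  expect_equal(adj[!is.na(p)], p.adjust(p[!is.na(p)], "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(5)
  for (i in 1:20) {
    x <- runif(50)
    a <- bh_adjust(x)
    expect_true(all(a <= 1))
    expect_equal(a, p.adjust(x, "BH"))
    expect_gte(min(a), min(x))
  }
})

test_that("the shifted-log VST has the documented fixed points", {
  st <- de_settings()
  m <- make_counts(matrix(c(0, 7, 15, 31), 1, 4))
  v <- vst_transform(m, rep(1, 4), st)
  expect_equal(unname(v[1, ]), c(0, 3, 4, 5))
  expect_error(vst_transform(m, c(1, -1, 1, 1), st), "positive")
  # doubling counts and factor together leaves the transform unchanged
  m2 <- make_counts(matrix(c(0, 14, 30, 62), 1, 4))
  expect_equal(unname(vst_transform(m2, rep(2, 4), st)),
               unname(v))
})

test_that("sample PCA agrees with a covariance eigendecomposition", {
  set.seed(9)
  x <- matrix(rnorm(20), 5, 4)
  rownames(x) <- paste0("g", 1:5); colnames(x) <- paste0("s", 1:4)
  pc <- pca_samples(x)
  expect_equal(sum(pc$var_explained), 1)
  cen <- x - rowMeans(x)
  ev <- eigen(crossprod(cen) / 1)  # sample-space inner product matrix
  lam <- ev$values / sum(ev$values)
  expect_equal(pc$var_explained[1:3], lam[1:3], tolerance = 1e-8)
  for (k in 1:3) {
    a <- pc$coordinates[, k]
    b <- ev$vectors[, k] * sqrt(ev$values[k])
    expect_equal(abs(sum(a * b)) / (sqrt(sum(a^2)) * sqrt(sum(b^2))), 1,
                 tolerance = 1e-8)
  }
  # samples on a line: PC1 carries all variance
  line <- outer(c(1, 2, 3), c(0, 1, 2, 5))
  dimnames(line) <- list(paste0("g", 1:3), paste0("s", 1:4))
  expect_equal(pca_samples(line)$var_explained[1], 1)
  # identical samples: zero variance everywhere, equal coordinates
  same <- make_counts(matrix(5, 4, 3))
  ps <- pca_samples(same)
  expect_true(all(ps$var_explained == 0))
  expect_equal(ps$coordinates[1, ], ps$coordinates[2, ])
})

test_that("estimated fold changes track the truth on synthetic data", {
  d <- generate_counts(synth_config(seed = 19))
  st <- de_settings()
  kept <- filter_low_counts(d$counts, st)
  de <- nb_wald(kept, d$samples, st, "clothianidin_acute")
  tl <- d$truth$lfc[match(de$gene_id, rownames(d$truth$lfc)),
                    "clothianidin_acute"]
  sel <- tl != 0
  rho <- cor(de$log2fc[sel], tl[sel], method = "spearman",
             use = "complete.obs")
  expect_gte(rho, 0.9)
})
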