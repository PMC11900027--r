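test_that("welch t matches hand computation and a permutation oracle", {
  w <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  w2 <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w2$t, -1.224745, tolerance = 1e-6)
  expect_equal(w2$df, 4, tolerance = 1e-9)
  # degenerate inputs
  expect_warning(wz <- welch_t(c(2, 2, 2), c(2, 2)), "undefined")
  expect_true(is.na(wz$p))
  wd <- welch_t(c(2, 2), c(3, 3))
  expect_equal(wd$p, 0)
  # permutation oracle on a 20-point fixture
  set.seed(14)
  x <- rnorm(10, 0.4); y <- rnorm(10)
  w3 <- welch_t(x, y)
  pooled <- c(x, y)
  tstat <- function(ix) {
    a <- pooled[ix]; b <- pooled[-ix]
    (mean(a) - mean(b)) / sqrt(var(a) / 10 + var(b) / 10)
  }
  perms <- replicate(4000, tstat(sample(20, 10)))
  p_perm <- mean(abs(perms) >= abs(w3$t))
  expect_lt(abs(w3$p - p_perm), 0.05)
  # symmetry in argument order
  w4 <- welch_t(y, x)
  expect_equal(w4$p, w3$p)
  expect_equal(w4$t, -w3$t)
})

test_that("2x2 chi-square matches hand values and chisq.test", {
  flat <- chi2_2x2(rbind(c(10, 10), c(10, 10)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  h <- chi2_2x2(rbind(c(20, 80), c(40, 60)))
  expect_equal(h$chi2, 9.52381, tolerance = 1e-5)
  for (corrected in c(FALSE, TRUE)) {
    tab <- rbind(c(12, 5), c(7, 21))
    mine <- chi2_2x2(tab, corrected = corrected)
    ref <- suppressWarnings(chisq.test(tab, correct = corrected))
    expect_equal(mine$chi2, unname(ref$statistic))
    expect_equal(mine$p, unname(ref$p.value))
  }
  # direction of evidence agrees with Fisher's exact test across tables
  tabs <- list(rbind(c(9, 1), c(2, 8)), rbind(c(2, 8), c(9, 1)),
               rbind(c(5, 5), c(6, 4)))
  chis <- vapply(tabs, function(t) chi2_2x2(t)$p, numeric(1))
  fish <- vapply(tabs, function(t) fisher.test(t)$p.value, numeric(1))
  expect_equal(order(chis), order(fish))
  expect_error(chi2_2x2(rbind(c(0, 0), c(1, 2))), "degenerate")
})

test_that("goodness-of-fit chi-square follows the textbook formula", {
  expect_equal(chi2_gof(c(30, 70), c(0.3, 0.7))$chi2, 0)
  g <- chi2_gof(c(55, 6), c(0.5, 0.5))
  expect_equal(g$chi2, 39.36066, tolerance = 1e-5)
  expect_equal(g$df, 1)
  expect_error(chi2_gof(c(5, 5), c(0.4, 0.5)), "sum to 1")
  expect_error(chi2_gof(c(5, 5, 5), c(0.5, 0.5, 0)), "sum to 1|positive")
})

test_that("large-change proportions contrast reproduces a strong split", {
  mk_de <- function(n_sig, n_large, seed) {
    set.seed(seed)
    lfc <- c(runif(n_large, 2.2, 6), runif(n_sig - n_large, 0.2, 1.8))
    data.frame(gene_id = sprintf("g%04d", seq_len(n_sig)),
               base_mean = 100, log2fc = lfc, se = 0.1, wald_z = 5,
               pvalue = 1e-4, fdr = 1e-3, significant = TRUE)
  }
  # exceedance fractions 3.61% vs 0.75% at plausible set sizes
  de_a <- mk_de(1440, 52, 1)   # 52/1440 = 3.61%
  de_b <- mk_de(800, 6, 2)     # 6/800   = 0.75%
  pr <- proportion_large_changes(de_a, de_b, threshold_log2 = 2)
  expect_equal(unname(pr$counts["a", "large"]), 52)
  expect_equal(unname(pr$counts["b", "large"]), 6)
  expect_gt(pr$chi2, 10)
  expect_lt(pr$p, 1e-3)
  # identical tables: no difference
  same <- proportion_large_changes(de_a, de_a)
  expect_equal(same$chi2, 0)
  # threshold 0: every gene is large in both, proportions identical
  z <- proportion_large_changes(de_a, de_b, threshold_log2 = 0)
  expect_equal(unname(z$proportions), c(1, 1))
  expect_equal(z$chi2, 0)
  expect_equal(z$p, 1)
})

test_that("top-k amplitude contrast behaves on fixtures and guards k", {
  mk <- function(lfc) data.frame(gene_id = sprintf("g%03d",
                                                   seq_along(lfc)),
                                 base_mean = 10, log2fc = lfc, se = 0.1,
                                 wald_z = 5, pvalue = 1e-5, fdr = 1e-4,
                                 significant = TRUE)
  de <- mk(seq(0.5, 5, length.out = 30))
  res <- top_k_amplitude(de, de, k = 10)
  expect_equal(res$ratio, 1)
  expect_equal(res$t, 0)
  de2 <- mk(2 * seq(0.5, 5, length.out = 30))
  res2 <- top_k_amplitude(de2, de, k = 10)
  expect_equal(res2$ratio, 2)
  expect_error(top_k_amplitude(de, de, k = 1), "at least 2")
  expect_error(top_k_amplitude(mk(c(1, 2)), de, k = 10), "significant")
  # ranking by fdr is available
  res3 <- top_k_amplitude(de, de, k = 5, rank_by = "fdr")
  expect_equal(res3$ratio, 1)
})

test_that("variance contrast recovers an exactly constructed SD ratio", {
  smp <- rbind(
    data.frame(sample_id = paste0("a", 1:8),
               treatment = rep(c("x_acute", "y_acute"), each = 4),
               compound = "x", scheme = "acute", colony = 1),
    data.frame(sample_id = paste0("c", 1:8),
               treatment = rep(c("x_chronic", "y_chronic"), each = 4),
               compound = "x", scheme = "chronic", colony = 1)
  )
  base <- c(-1.5, -0.5, 0.5, 1.5) # sd = sqrt(5/3), exactly
  n_genes <- 40
  de_flags <- rep(c(TRUE, FALSE), each = n_genes / 2)
  vst <- t(vapply(seq_len(n_genes), function(g) {
    f <- if (de_flags[g]) 1.2 else 1
    c(rep(f * base, 2), rep(base, 2)) + g
  }, numeric(16)))
  rownames(vst) <- sprintf("g%03d", seq_len(n_genes))
  colnames(vst) <- smp$sample_id
  vc <- variance_contrast(vst, smp, de_flags)
  expect_equal(vc$coefficient, log(1.2), tolerance = 1e-10)
  # swapping scheme labels flips the sign
  smp_sw <- smp
  smp_sw$scheme <- ifelse(smp$scheme == "acute", "chronic", "acute")
  vc_sw <- variance_contrast(vst, smp_sw, de_flags)
  expect_equal(vc_sw$coefficient, -log(1.2), tolerance = 1e-10)
  # zero-SD genes are excluded with a message
  vst0 <- rbind(vst, g999 = rep(1, 16))
  expect_message(vc0 <- variance_contrast(vst0, smp, c(de_flags, FALSE)),
                 "excluded")
  expect_equal(vc0$n_excluded, 1)
  expect_equal(vc0$coefficient, vc$coefficient, tolerance = 1e-10)
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  pool <- sprintf("g%02d", 1:10)
  de <- pool[1:5]
  ann <- list(inside = pool[1:5], outside = pool[6:10])
  res <- fisher_enrichment(de, ann, pool)
  expect_equal(res$p[res$term == "inside"], 1 / choose(10, 5))
  expect_equal(res$p[res$term == "outside"], 1)
  expect_equal(res$fdr, bh_adjust(res$p))
  # enumeration oracle on a pool of 12: draw every DE set of size 4
  pool2 <- sprintf("h%02d", 1:12)
  term <- pool2[1:5]
  all_de <- combn(12, 4, simplify = FALSE)
  for (a_obs in 0:3) {
    frac <- mean(vapply(all_de, function(ix)
      sum(ix <= 5) >= a_obs, logical(1)))
    expect_equal(phyper(a_obs - 1, 5, 7, 4, lower.tail = FALSE), frac)
  }
  expect_warning(res2 <- fisher_enrichment(de, list(empty = character(0),
                                                    ok = pool[1:3]), pool),
                 "skipped")
  expect_equal(res2$term, "ok")
})

test_that("KS distance is exact on separated samples and transform invariant", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  set.seed(6)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  k1 <- ks_two_sample(x, y)
  expect_gte(k1$D, 0); expect_lte(k1$D, 1)
  k2 <- ks_two_sample(exp(x), exp(y)) # monotone transform of both
  expect_equal(k1$D, k2$D)
})

test_that("skewness follows the moment definition and sign conventions", {
  expect_equal(skewness(c(1, 2, 3)), 0)
  x <- c(0, 0, 0, 1)
  m <- mean(x)
  oracle <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_equal(skewness(x), oracle)
  expect_gt(skewness(x), 0)
  expect_equal(skewness(-x), -skewness(x))
  expect_error(skewness(c(1, 1, 1)), "variance")
  expect_error(skewness(c(1, 2)), "three")
})
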